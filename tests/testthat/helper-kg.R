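# Shared fixtures, all built in code.

# minimal six-column record table (pituitary prolactinoma -> headache)
toy_records <- function() {
  data.frame(
    head_surface = c("垂体泌乳素腺瘤",
                     "垂体泌乳素腺瘤"),
    head_type = "disease",
    relation = c("Diseases_rel_Symptom", "Diseases_rel_Examination"),
    tail_surface = c("头痛", "磁共振"),
    tail_type = c("symptom", "examination"),
    source = "emr",
    stringsAsFactors = FALSE
  )
}

# random schema-valid graph over an ASCII alphabet
random_kg <- function(seed, n_diseases = 4, sources = c("emr", "web")) {
  withr::with_seed(seed, {
    sch <- kg_schema()
    rows <- list()
    surf <- function(k) {
      vapply(seq_len(k), function(i) {
        paste(sample(letters, sample(2:6, 1), replace = TRUE), collapse = "")
      }, character(1))
    }
    for (src in sources) {
      dis <- paste0("d", seq_len(n_diseases), "_", src)
      for (d in dis) {
        rl <- sample(sch$label, sample(2:5, 1), replace = TRUE)
        rl <- rl[sch$head_type[match(rl, sch$label)] == "disease"]
        for (r in rl) {
          tt <- sch$tail_type[sch$label == r]
          rows[[length(rows) + 1L]] <- data.frame(
            head_surface = d, head_type = "disease", relation = r,
            tail_surface = surf(1), tail_type = tt, source = src,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    kg_from_records(do.call(rbind, rows))
  })
}

# random same-type merge pairs for a graph
random_merges <- function(kg, seed, n = 3) {
  withr::with_seed(seed, {
    e <- kg$entities
    rows <- list()
    for (ty in unique(e$etype)) {
      ids <- e$id[e$etype == ty]
      if (length(ids) < 2) next
      k <- min(n, floor(length(ids) / 2))
      if (k < 1) next
      pick <- sample(ids, 2 * k)
      rows[[ty]] <- data.frame(
        id = pick[seq_len(k)], canonical = pick[k + seq_len(k)],
        provenance = "exact", score = 1, stringsAsFactors = FALSE
      )
    }
    if (!length(rows)) return(merge_map())
    merge_map(do.call(rbind, rows))
  })
}

# hand-built embedding object for exact-arithmetic score tests
manual_embedding <- function(E, R, P = NULL, model = "transE", etypes = NULL) {
  if (is.null(etypes)) {
    etypes <- ifelse(grepl("disease", rownames(E)), "disease", "symptom")
  }
  structure(list(
    E = E, R = R, P = P,
    entities = data.frame(id = rownames(E), etype = etypes,
                          stringsAsFactors = FALSE),
    config = embedding_config(model = model, dim = ncol(E), seed = 1L),
    loss = numeric(0)
  ), class = "kg_embedding")
}

# naive loop recomputation of the translation distance (independent oracle)
naive_score <- function(model, h, r, t, M = NULL, w = NULL) {
  d <- length(h)
  if (model == "transR") {
    hp <- numeric(d); tp <- numeric(d)
    for (j in seq_len(d)) {
      for (i in seq_len(d)) {
        hp[j] <- hp[j] + h[i] * M[i, j]
        tp[j] <- tp[j] + t[i] * M[i, j]
      }
    }
  } else if (model == "transH") {
    hp <- h - sum(w * h) * w
    tp <- t - sum(w * t) * w
  } else {
    hp <- h; tp <- t
  }
  s <- 0
  for (j in seq_len(d)) s <- s + (hp[j] + r[j] - tp[j])^2
  sqrt(s)
}

# brute-force character-set Jaccard (independent oracle, integer code sets)
brute_jaccard <- function(a, b) {
  sa <- unique(utf8ToInt(a))
  sb <- unique(utf8ToInt(b))
  inter <- 0
  for (x in sa) if (x %in% sb) inter <- inter + 1
  inter / (length(sa) + length(sb) - inter)
}

brute_jaccard_sets <- function(A, B) {
  sa <- unique(unlist(lapply(A, utf8ToInt)))
  sb <- unique(unlist(lapply(B, utf8ToInt)))
  if (length(sa) == 0 && length(sb) == 0) return(0)
  inter <- length(intersect(sa, sb))
  inter / length(union(sa, sb))
}

rand_cjk <- function(n, len_range = 2:6) {
  ab <- strsplit(intToUtf8(0x4E00:0x4EFF), "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(ab, sample(len_range, 1), replace = TRUE), collapse = "")
  }, character(1))
}
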