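default_alphabet <- function() {
  strsplit(intToUtf8(0x4E00:0x4EFF), "")[[1]]
}

default_suffixes <- c("感", "症", "样", "状")  # 感 症 样 状

# Per-head-entity mean tail counts, proportional to the relation inventory
# of a disease-centred clinical graph: symptoms dominate, surgeries are
# rare. Body-structure links are per symptom, not per disease.
default_tails_per_relation <- function() {
  c(
    "Diseases_rel_Symptom" = 15.8,
    "Diseases_rel_Surgery" = 0.28,
    "Diseases_rel_Medicines" = 1.23,
    "Diseases_rel_Examination" = 2.19,
    "Symptoms_rel_Body structure" = 0.30,
    "Diseases_rel_Treatment" = 0.55,
    "Diseases_attr_Pathogeny" = 0.61,
    "Diseases_attr_Department" = 0.36
  )
}

#' Configuration for the synthetic two-source benchmark
#'
#' Describes a ground-truth disease-centred graph and the two corrupted
#' source views derived from it: an `emr` view (clinical records, rich in
#' symptoms) and a `web` view (curated sites, rich in examinations,
#' treatments and name attributes). The default parameters are the
#' acceptance conditions of the package: `seed = 42`, `n_diseases = 50`,
#' `overlap = 0.6`, `variant_rate = 0.3`, `attr_coverage = 0.3`.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   benchmarks.
#' @param n_diseases Number of ground-truth diseases (>= 1).
#' @param tails_per_relation Named vector of mean tail counts per head
#'   entity and relation (Poisson means). See
#'   `kgfuse:::default_tails_per_relation`.
#' @param overlap Fraction of ground-truth tail entities present in both
#'   views (in `[0, 1]`).
#' @param variant_rate Probability that a shared entity's surface form is
#'   corrupted in exactly one view (in `[0, 1]`).
#' @param attr_coverage Fraction of diseases given alternative/English
#'   name attributes in the web view.
#' @param alphabet Character pool for generated surfaces (defaults to a
#'   fixed CJK block so character-set Jaccard behaves as on Chinese
#'   clinical terms; pass letters for an ASCII debugging mode).
#' @param synonym_lexicon Optional named list mapping a surface to its
#'   synonyms, used by the corruption operator.
#' @param neg_ratio Negative alignment pairs emitted per positive pair.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 42L, n_diseases = 50L,
                             tails_per_relation = default_tails_per_relation(),
                             overlap = 0.6, variant_rate = 0.3,
                             attr_coverage = 0.3,
                             alphabet = default_alphabet(),
                             synonym_lexicon = NULL, neg_ratio = 1) {
  if (n_diseases < 1) stop("n_diseases must be >= 1")
  for (p in c(overlap, variant_rate, attr_coverage)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("overlap, variant_rate and attr_coverage must lie in [0, 1]")
    }
  }
  tpr <- default_tails_per_relation()
  tpr[names(tails_per_relation)] <- tails_per_relation
  structure(list(
    seed = as.integer(seed), n_diseases = as.integer(n_diseases),
    tails_per_relation = tpr, overlap = overlap,
    variant_rate = variant_rate, attr_coverage = attr_coverage,
    alphabet = alphabet, synonym_lexicon = synonym_lexicon,
    neg_ratio = neg_ratio
  ), class = "generator_config")
}

random_surface <- function(n, alphabet, len = NULL) {
  vapply(seq_len(n), function(i) {
    l <- if (is.null(len)) sample(2:6, 1) else len
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
}

unique_surfaces <- function(n, alphabet, taken = character(0), len = NULL) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_surface(n - length(out), alphabet, len)
    cand <- setdiff(unique(cand), c(taken, out))
    out <- c(out, cand)
  }
  out
}

#' Corrupt a surface form with one lexical-variation operator
#'
#' Models the spelling variation between clinical records and web text
#' (e.g. two renderings of "headache" differing in one character). Exactly
#' one operator is drawn uniformly from: single-character substitution
#' from the alphabet pool, affix addition (a fixed suffix list), affix
#' drop (only if the surface is longer than two characters), and synonym
#' replacement (only on a lexicon hit). An inapplicable draw falls back to
#' substitution, which is always applicable. Uses the session RNG; seed
#' with `set.seed()` or [withr::with_seed()] for reproducibility.
#'
#' @param surface Non-empty string.
#' @param lexicon Optional named list of synonym vectors.
#' @param alphabet Substitution character pool.
#' @return The corrupted string, with attribute `"operator"` naming the
#'   operator actually applied.
#' @export
corrupt_surface <- function(surface, lexicon = NULL,
                            alphabet = default_alphabet()) {
  if (!nzchar(surface)) stop("cannot corrupt an empty surface")
  op <- sample(c("substitute", "affix_add", "affix_drop", "synonym"), 1)
  chars <- strsplit(surface, "")[[1]]
  if (op == "affix_drop" && length(chars) <= 2) op <- "substitute"
  if (op == "synonym" &&
      (is.null(lexicon) || is.null(lexicon[[surface]]) ||
       length(lexicon[[surface]]) == 0)) {
    op <- "substitute"
  }
  out <- switch(op,
    substitute = {
      i <- sample(length(chars), 1)
      repl <- sample(setdiff(alphabet, chars[i]), 1)
      chars[i] <- repl
      paste(chars, collapse = "")
    },
    affix_add = paste0(surface, sample(default_suffixes, 1)),
    affix_drop = paste(chars[-length(chars)], collapse = ""),
    synonym = sample(lexicon[[surface]], 1)
  )
  attr(out, "operator") <- op
  out
}

#' Generate a synthetic two-source benchmark
#'
#' Builds a schema-valid ground-truth graph (source tag `truth`) and two
#' overlapping corrupted views (`emr`, `web`) plus exhaustive alignment
#' labels:
#' \itemize{
#'   \item Tail entities are drawn from per-type pools with Zipf weights
#'     (common symptoms recur across diseases, as in real clinical data).
#'   \item Every disease appears in both views; each ground-truth tail
#'     entity appears in both views with probability `overlap`, otherwise
#'     only in its "home" view (symptoms and body structures in `emr`;
#'     examinations, treatments, medicines, surgeries and attribute values
#'     in `web`).
#'   \item A shared entity's surface is corrupted by [corrupt_surface()]
#'     in exactly one randomly chosen view with probability
#'     `variant_rate`; disease surfaces in the `emr` view are corrupted
#'     the same way, with the disease's alternative name acting as a
#'     synonym-lexicon entry.
#'   \item A fraction `attr_coverage` of diseases carries alternative- and
#'     English-name attributes in the web view; half of those also carry
#'     the English name (with shuffled letter case) in the emr view,
#'     enabling attribute-based head alignment.
#' }
#'
#' @param config A [generator_config()].
#' @return A `synthetic_benchmark`: `truth`, `view_emr`, `view_web` (`kg`
#'   objects), `tail_alignments` and `head_alignments` (labeled pair data
#'   frames with ids, surfaces, types and `label` in `{0, 1}`), and the
#'   `config`.
#' @export
generate_benchmark <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_benchmark_impl(config))
}

generate_benchmark_impl <- function(cfg) {
  n <- cfg$n_diseases
  ab <- cfg$alphabet
  tpr <- cfg$tails_per_relation

  pool_sizes <- c(
    symptom = max(20, round(4 * n)),
    examination = max(10, round(1.5 * n)),
    medicine = max(8, n),
    surgery = max(5, round(0.5 * n)),
    body_structure = max(8, n),
    treatment = max(8, round(0.8 * n)),
    pathogeny = max(8, n),
    department = 8
  )
  taken <- character(0)
  pools <- list()
  for (ty in names(pool_sizes)) {
    pools[[ty]] <- unique_surfaces(pool_sizes[[ty]], ab, taken)
    taken <- c(taken, pools[[ty]])
  }
  disease <- unique_surfaces(n, ab, taken, len = NULL)
  taken <- c(taken, disease)
  alias <- unique_surfaces(n, ab, taken)
  taken <- c(taken, alias)
  english <- unique_surfaces(n, letters, character(0), len = NULL)

  zipf <- function(m) (1 / seq_len(m)) / sum(1 / seq_len(m))
  draw_tails <- function(ty, mean) {
    pool <- pools[[ty]]
    k <- min(stats::rpois(1, mean), length(pool))
    if (k == 0) return(character(0))
    sample(pool, k, prob = zipf(length(pool)))
  }

  # ground-truth records: disease-headed relations
  rec <- list()
  sch <- kg_schema()
  rel_of_type <- stats::setNames(sch$label, sch$tail_type)
  for (i in seq_len(n)) {
    for (rl in setdiff(names(tpr), "Symptoms_rel_Body structure")) {
      ty <- sch$tail_type[sch$label == rl]
      tails <- draw_tails(ty, tpr[[rl]])
      if (length(tails)) {
        rec[[length(rec) + 1L]] <- data.frame(
          head_surface = disease[i], head_type = "disease", relation = rl,
          tail_surface = tails, tail_type = ty, source = "truth",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  truth_df <- do.call(rbind, rec)
  # symptom-headed body-structure links
  used_sym <- unique(truth_df$tail_surface[truth_df$tail_type == "symptom"])
  bs <- list()
  for (s in used_sym) {
    tails <- draw_tails("body_structure", tpr[["Symptoms_rel_Body structure"]])
    if (length(tails)) {
      bs[[length(bs) + 1L]] <- data.frame(
        head_surface = s, head_type = "symptom",
        relation = "Symptoms_rel_Body structure",
        tail_surface = tails, tail_type = "body_structure", source = "truth",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(bs)) truth_df <- rbind(truth_df, do.call(rbind, bs))
  # name attributes for every disease in the truth graph
  covered <- stats::runif(n) < cfg$attr_coverage
  name_df <- rbind(
    data.frame(head_surface = disease, head_type = "disease",
               relation = "Diseases_attr_Alternative name",
               tail_surface = alias, tail_type = "alternative_name",
               source = "truth", stringsAsFactors = FALSE),
    data.frame(head_surface = disease, head_type = "disease",
               relation = "Diseases_attr_English name",
               tail_surface = english, tail_type = "english_name",
               source = "truth", stringsAsFactors = FALSE)
  )
  truth_df <- rbind(truth_df, name_df)
  truth <- kg_from_records(truth_df)

  # ---- view assignment per ground-truth tail entity ----------------------
  emr_home <- c("symptom", "body_structure")
  tail_ent <- unique(truth_df[, c("tail_surface", "tail_type")])
  tail_ent <- tail_ent[!(tail_ent$tail_type %in%
                           c("alternative_name", "english_name")), , drop = FALSE]
  shared <- stats::runif(nrow(tail_ent)) < cfg$overlap
  home_emr <- tail_ent$tail_type %in% emr_home
  in_emr <- shared | home_emr
  in_web <- shared | !home_emr
  names(in_emr) <- names(in_web) <-
    paste(tail_ent$tail_type, tail_ent$tail_surface, sep = "\r")

  # surface corruption: shared entities corrupted in exactly one view
  corrupt_in <- ifelse(
    shared & stats::runif(nrow(tail_ent)) < cfg$variant_rate,
    sample(c("emr", "web"), nrow(tail_ent), replace = TRUE),
    "none"
  )
  variant <- tail_ent$tail_surface
  for (i in seq_len(nrow(tail_ent))) {
    if (corrupt_in[i] == "none") next
    v <- corrupt_variant(tail_ent$tail_surface[i], cfg, taken)
    variant[i] <- v
    taken <- c(taken, v)
  }
  vmap_emr <- ifelse(corrupt_in == "emr", variant, tail_ent$tail_surface)
  vmap_web <- ifelse(corrupt_in == "web", variant, tail_ent$tail_surface)
  names(vmap_emr) <- names(vmap_web) <- names(in_emr)

  # disease surfaces: emr side corrupted at variant_rate (alias may appear
  # as the record spelling); web side uses the canonical name
  lex <- cfg$synonym_lexicon
  if (is.null(lex)) lex <- list()
  d_corrupt <- stats::runif(n) < cfg$variant_rate
  d_emr <- disease
  for (i in which(d_corrupt)) {
    lx <- lex
    lx[[disease[i]]] <- unique(c(lx[[disease[i]]], alias[i]))
    v <- corrupt_variant(disease[i], cfg, taken, lexicon = lx)
    d_emr[i] <- v
    taken <- c(taken, v)
  }
  d_web <- disease

  view_df <- function(view) {
    dmap <- if (view == "emr") stats::setNames(d_emr, disease)
            else stats::setNames(d_web, disease)
    vmap <- if (view == "emr") vmap_emr else vmap_web
    pres <- if (view == "emr") in_emr else in_web
    df <- truth_df[!(truth_df$tail_type %in% c("alternative_name", "english_name")), ]
    key <- paste(df$tail_type, df$tail_surface, sep = "\r")
    df <- df[pres[key], , drop = FALSE]
    key <- key[pres[key]]
    # symptom-headed rows require the head symptom in this view too
    sh <- df$head_type == "symptom"
    hkey <- paste("symptom", df$head_surface, sep = "\r")
    df <- df[!sh | pres[hkey], , drop = FALSE]
    key <- paste(df$tail_type, df$tail_surface, sep = "\r")
    df$tail_surface <- unname(vmap[key])
    hs <- df$head_type == "symptom"
    df$head_surface[hs] <- unname(vmap[paste("symptom", df$head_surface[hs], sep = "\r")])
    df$head_surface[!hs] <- unname(dmap[df$head_surface[!hs]])
    df$source <- view
    df
  }
  emr_df <- view_df("emr")
  web_df <- view_df("web")
  # name attributes: web carries them for covered diseases; emr carries the
  # English name for half of those (case-shuffled; normalization folds it)
  web_df <- rbind(web_df, name_df[c(covered, covered), ] |>
                    transform(source = "web",
                              head_surface = rep(d_web[covered], 2)))
  emr_en <- covered & (stats::runif(n) < 0.5)
  if (any(emr_en)) {
    emr_df <- rbind(emr_df, data.frame(
      head_surface = d_emr[emr_en], head_type = "disease",
      relation = "Diseases_attr_English name",
      tail_surface = toupper(english[emr_en]), tail_type = "english_name",
      source = "emr", stringsAsFactors = FALSE
    ))
  }
  view_emr <- kg_from_records(emr_df)
  view_web <- kg_from_records(web_df)

  # ---- alignment labels --------------------------------------------------
  tail_al <- make_alignments(
    tail_ent, in_emr, in_web, vmap_emr, vmap_web,
    types = c("symptom", "examination"), neg_ratio = cfg$neg_ratio,
    view_emr = view_emr, view_web = view_web
  )
  head_al <- make_head_alignments(disease, d_emr, d_web, cfg$neg_ratio)

  structure(list(
    truth = truth, view_emr = view_emr, view_web = view_web,
    tail_alignments = tail_al, head_alignments = head_al, config = cfg
  ), class = "synthetic_benchmark")
}

# corrupted variant that avoids colliding with any existing surface
corrupt_variant <- function(surface, cfg, taken, lexicon = cfg$synonym_lexicon) {
  for (try in 1:20) {
    v <- corrupt_surface(surface, lexicon = lexicon, alphabet = cfg$alphabet)
    v <- as.character(v)
    if (!(v %in% taken) && nzchar(v)) return(v)
  }
  surface
}

make_alignments <- function(tail_ent, in_emr, in_web, vmap_emr, vmap_web,
                            types, neg_ratio, view_emr, view_web) {
  key <- paste(tail_ent$tail_type, tail_ent$tail_surface, sep = "\r")
  sel <- tail_ent$tail_type %in% types & in_emr[key] & in_web[key]
  pos <- data.frame(
    left_surface = unname(vmap_emr[key[sel]]),
    left_type = tail_ent$tail_type[sel],
    right_surface = unname(vmap_web[key[sel]]),
    right_type = tail_ent$tail_type[sel],
    truth = tail_ent$tail_surface[sel],
    label = rep(1L, sum(sel)), stringsAsFactors = FALSE
  )
  # negatives: same-type cross-view pairs over different truth entities
  negs <- list()
  for (ty in types) {
    p <- pos[pos$left_type == ty, , drop = FALSE]
    emr_all <- tail_ent[tail_ent$tail_type == ty & in_emr[key], , drop = FALSE]
    web_all <- tail_ent[tail_ent$tail_type == ty & in_web[key], , drop = FALSE]
    want <- round(nrow(p) * neg_ratio)
    if (want == 0 || nrow(emr_all) == 0 || nrow(web_all) == 0) next
    got <- 0; tries <- 0
    seen <- character(0)
    rows <- list()
    while (got < want && tries < want * 50) {
      tries <- tries + 1
      i <- sample(nrow(emr_all), 1)
      j <- sample(nrow(web_all), 1)
      if (emr_all$tail_surface[i] == web_all$tail_surface[j]) next
      kk <- paste(i, j)
      if (kk %in% seen) next
      seen <- c(seen, kk)
      got <- got + 1
      rows[[got]] <- data.frame(
        left_surface = unname(vmap_emr[paste(ty, emr_all$tail_surface[i], sep = "\r")]),
        left_type = ty,
        right_surface = unname(vmap_web[paste(ty, web_all$tail_surface[j], sep = "\r")]),
        right_type = ty,
        truth = NA_character_, label = 0L, stringsAsFactors = FALSE
      )
    }
    if (length(rows)) negs[[ty]] <- do.call(rbind, rows)
  }
  out <- rbind(pos, if (length(negs)) do.call(rbind, negs))
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(left_surface = character(), left_type = character(),
                      right_surface = character(), right_type = character(),
                      truth = character(), label = integer(),
                      left_id = character(), right_id = character(),
                      stringsAsFactors = FALSE))
  }
  out$left_id <- entity_id("emr", out$left_type, normalize_surface(out$left_surface))
  out$right_id <- entity_id("web", out$right_type, normalize_surface(out$right_surface))
  rownames(out) <- NULL
  out
}

make_head_alignments <- function(disease, d_emr, d_web, neg_ratio) {
  n <- length(disease)
  pos <- data.frame(
    left_surface = d_emr, left_type = "disease",
    right_surface = d_web, right_type = "disease",
    truth = disease, label = 1L, stringsAsFactors = FALSE
  )
  want <- round(n * neg_ratio)
  rows <- list()
  seen <- character(0)
  got <- 0; tries <- 0
  while (got < want && tries < want * 50 && n > 1) {
    tries <- tries + 1
    i <- sample(n, 1); j <- sample(n, 1)
    if (i == j) next
    kk <- paste(i, j)
    if (kk %in% seen) next
    seen <- c(seen, kk)
    got <- got + 1
    rows[[got]] <- data.frame(
      left_surface = d_emr[i], left_type = "disease",
      right_surface = d_web[j], right_type = "disease",
      truth = NA_character_, label = 0L, stringsAsFactors = FALSE
    )
  }
  out <- rbind(pos, if (length(rows)) do.call(rbind, rows))
  out$left_id <- entity_id("emr", "disease", normalize_surface(out$left_surface))
  out$right_id <- entity_id("web", "disease", normalize_surface(out$right_surface))
  rownames(out) <- NULL
  out
}

#' Write a benchmark to disk
#'
#' Emits `view_emr.tsv`, `view_web.tsv`, `truth.tsv` in the six-column
#' triple dialect plus `tail_alignments.tsv` / `head_alignments.tsv`
#' (`left_surface`, `left_type`, `right_surface`, `right_type`, `label`).
#'
#' @param bench A `synthetic_benchmark`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_triples(bench$view_emr, file.path(dir, "view_emr.tsv"))
  write_triples(bench$view_web, file.path(dir, "view_web.tsv"))
  write_triples(bench$truth, file.path(dir, "truth.tsv"))
  cols <- c("left_surface", "left_type", "right_surface", "right_type", "label")
  for (nm in c("tail_alignments", "head_alignments")) {
    con <- file(file.path(dir, paste0(nm, ".tsv")), open = "w", encoding = "UTF-8")
    utils::write.table(bench[[nm]][, cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read an alignment-label file
#'
#' @param path TSV with columns `left_surface`, `left_type`,
#'   `right_surface`, `right_type`, `label`.
#' @param left_source,right_source Source tags used to reconstruct ids.
#' @return Labeled pair data frame as produced by the generator.
#' @export
read_alignments <- function(path, left_source = "emr", right_source = "web") {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  df$label <- as.integer(df$label)
  df$left_id <- entity_id(left_source, df$left_type,
                          normalize_surface(df$left_surface))
  df$right_id <- entity_id(right_source, df$right_type,
                           normalize_surface(df$right_surface))
  df
}
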