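#' Build a closed entity merge map
#'
#' A merge map sends entity ids to canonical entity ids. Pairwise merges
#' are completed to their transitive closure with union-find, so the
#' resulting map is idempotent: `mapping[mapping[x]] == mapping[x]` and
#' every canonical id maps to itself. Per-pair provenance (which fusion
#' stage produced the merge) and the decision score are retained.
#'
#' The canonical representative of each component is the lexicographically
#' smallest id by default; [choose_canonical()] re-roots components by a
#' surface-form policy once entity metadata is available.
#'
#' @param pairs Data frame with columns `id`, `canonical` and optionally
#'   `provenance` (one of `exact`, `attribute`, `tail_model`, `head_model`)
#'   and `score`. May have zero rows.
#' @return An object of class `merge_map`: a data frame with columns `id`,
#'   `canonical`, `provenance`, `score` covering every non-root member of
#'   every merge component.
#' @export
merge_map <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    out <- data.frame(id = character(), canonical = character(),
                      provenance = character(), score = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("merge_map", "data.frame")))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("id", "canonical") %in% names(pairs))) {
    stop("pairs must have columns id, canonical")
  }
  if (is.null(pairs$provenance)) pairs$provenance <- "exact"
  ok <- c("exact", "attribute", "tail_model", "head_model")
  if (!all(pairs$provenance %in% ok)) {
    stop("provenance must be one of ", paste(ok, collapse = ", "))
  }
  if (is.null(pairs$score)) pairs$score <- NA_real_

  ids <- sort(unique(c(pairs$id, pairs$canonical)))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]  # path halving
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$id[i]); rb <- find(pairs$canonical[i])
    if (ra != rb) {
      # deterministic root: lexicographically smaller id wins
      if (ra < rb) parent[[rb]] <- ra else parent[[ra]] <- rb
    }
  }
  root <- vapply(ids, find, character(1))
  # respect the stated orientation where possible: members that only ever
  # appear on the canonical side are preferred as component roots;
  # otherwise the lexicographically smallest member is the root
  pure <- setdiff(unique(pairs$canonical), unique(pairs$id))
  for (comp in split(ids, root)) {
    cand <- intersect(comp, pure)
    r2 <- if (length(cand) > 0) min(cand) else min(comp)
    root[comp] <- r2
  }
  # provenance/score of a member: the pair row that first mentioned it
  prov <- stats::setNames(rep(NA_character_, length(ids)), ids)
  sc <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (i in rev(seq_len(nrow(pairs)))) {
    prov[pairs$id[i]] <- pairs$provenance[i]
    sc[pairs$id[i]] <- pairs$score[i]
  }
  # an id only ever seen on the canonical side inherits the pair's stage
  for (i in rev(seq_len(nrow(pairs)))) {
    if (is.na(prov[pairs$canonical[i]])) {
      prov[pairs$canonical[i]] <- pairs$provenance[i]
      sc[pairs$canonical[i]] <- pairs$score[i]
    }
  }
  keep <- root != ids
  out <- data.frame(
    id = ids[keep], canonical = unname(root[keep]),
    provenance = unname(prov[ids[keep]]), score = unname(sc[ids[keep]]),
    stringsAsFactors = FALSE
  )
  out$provenance[is.na(out$provenance)] <- "exact"
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("merge_map", "data.frame"))
}

#' Resolve entity ids through a merge map
#'
#' Ids absent from the map resolve to themselves.
#'
#' @param mm A `merge_map`.
#' @param ids Character vector of entity ids.
#' @return Character vector of canonical ids.
#' @export
mm_lookup <- function(mm, ids) {
  if (nrow(mm) == 0) return(ids)
  m <- stats::setNames(mm$canonical, mm$id)
  hit <- ids %in% names(m)
  ids[hit] <- unname(m[ids[hit]])
  ids
}

#' Concatenate merge maps and re-close
#'
#' Later stages must not overturn earlier ones; concatenation followed by
#' closure unions the components of all stages.
#'
#' @param ... `merge_map` objects.
#' @return A single closed `merge_map`.
#' @export
mm_combine <- function(...) {
  maps <- Filter(function(m) nrow(m) > 0, list(...))
  if (length(maps) == 0) return(merge_map())
  merge_map(do.call(rbind, lapply(maps, as.data.frame)))
}

#' Re-root merge components by a canonical-surface policy
#'
#' After fusion, each merge component needs one surviving surface form. The
#' default policy prefers the entity from `prefer_source` (the website
#' vocabulary is usually the curated one); among candidates it picks the
#' longest surface, breaking ties by id. Components are only re-rooted,
#' never changed.
#'
#' @param mm A `merge_map`.
#' @param entities Entity table of the graph the map applies to.
#' @param prefer_source Source tag preferred for the canonical entity.
#' @return A `merge_map` with the same components and policy-chosen roots.
#' @export
choose_canonical <- function(mm, entities, prefer_source = "web") {
  if (nrow(mm) == 0) return(mm)
  comp <- split(c(mm$id, mm$canonical), c(mm$canonical, mm$canonical))
  meta <- entities[match(unique(c(mm$id, mm$canonical)), entities$id), , drop = FALSE]
  pick <- function(members) {
    members <- unique(members)
    m <- meta[match(members, meta$id), , drop = FALSE]
    pref <- grepl(prefer_source, m$source, fixed = TRUE)
    ord <- order(!pref, -nchar(m$surface), m$id)
    members[ord[1]]
  }
  prov <- stats::setNames(mm$provenance, mm$id)
  sc <- stats::setNames(mm$score, mm$id)
  # old roots inherit the stage of a pair in their component
  root_prov <- tapply(mm$provenance, mm$canonical, function(x) x[1])
  root_sc <- tapply(mm$score, mm$canonical, function(x) x[1])
  prov <- c(prov, stats::setNames(unname(root_prov), names(root_prov)))
  sc <- c(sc, stats::setNames(unname(root_sc), names(root_sc)))
  rows <- lapply(names(comp), function(root) {
    members <- unique(c(comp[[root]], root))
    canon <- pick(members)
    others <- setdiff(members, canon)
    pv <- unname(prov[others])
    pv[is.na(pv)] <- "exact"
    data.frame(
      id = others, canonical = canon, provenance = pv,
      score = unname(sc[others]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("merge_map", "data.frame"))
}

#' Read / write merge maps as TSV
#'
#' Columns `entity_id`, `canonical_id`, `score`, `stage`.
#' @param mm A `merge_map`.
#' @param path File path.
#' @return `path` (write) or a `merge_map` (read).
#' @export
write_merges <- function(mm, path) {
  df <- data.frame(entity_id = mm$id, canonical_id = mm$canonical,
                   score = mm$score, stage = mm$provenance,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_merges
#' @export
read_merges <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  merge_map(data.frame(
    id = df$entity_id, canonical = df$canonical_id,
    provenance = df$stage, score = as.numeric(df$score),
    stringsAsFactors = FALSE
  ))
}
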