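#' Enumerate cross-source candidate entity pairs
#'
#' Blocking: only pairs of identical entity type are candidates, by
#' default the shared tail types (`symptom`, `examination`). An optional
#' cheap prefilter keeps only pairs sharing at least one character or
#' bigram, bounding the quadratic blow-up on large graphs; it is off by
#' default so the classifier sees every pair.
#'
#' @param kg_a,kg_b Source graphs (left/right).
#' @param types Entity types to pair.
#' @param prefilter If `TRUE`, drop pairs with zero character overlap and
#'   zero bigram cosine.
#' @return Data frame with columns `left_id`, `left_surface`, `right_id`,
#'   `right_surface`, `etype`.
#' @export
candidate_pairs <- function(kg_a, kg_b, types = c("symptom", "examination"),
                            prefilter = FALSE) {
  out <- list()
  for (ty in types) {
    ea <- kg_a$entities[kg_a$entities$etype == ty, , drop = FALSE]
    eb <- kg_b$entities[kg_b$entities$etype == ty, , drop = FALSE]
    if (nrow(ea) == 0 || nrow(eb) == 0) next
    g <- expand.grid(i = seq_len(nrow(ea)), j = seq_len(nrow(eb)))
    out[[ty]] <- data.frame(
      left_id = ea$id[g$i], left_surface = ea$surface[g$i],
      right_id = eb$id[g$j], right_surface = eb$surface[g$j],
      etype = ty, stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(out)) do.call(rbind, out) else data.frame(
    left_id = character(), left_surface = character(),
    right_id = character(), right_surface = character(),
    etype = character(), stringsAsFactors = FALSE
  )
  if (prefilter && nrow(pairs) > 0) {
    sets <- lapply(c(pairs$left_surface, pairs$right_surface), char_set)
    nl <- nrow(pairs)
    keep <- vapply(seq_len(nl), function(i) {
      any(sets[[i]] %in% sets[[nl + i]])
    }, logical(1))
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs <- pairs[order(pairs$left_id, pairs$right_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Greedy one-to-one matching of scored pairs
#'
#' Pairs scoring above the threshold are taken in descending score order
#' (ties broken by left then right id); a pair is kept only if neither
#' endpoint is already matched. Near-optimal for well-separated scores,
#' `O(n log n)`, and deterministic.
#'
#' @param pairs Data frame with `left_id`, `right_id`, `score`.
#' @param threshold Minimum (exclusive) score.
#' @return The matched subset of `pairs`.
#' @export
greedy_one_to_one <- function(pairs, threshold) {
  keep <- pairs[pairs$score > threshold, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$left_id, keep$right_id), , drop = FALSE]
  used_l <- character(0)
  used_r <- character(0)
  take <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    if (keep$left_id[i] %in% used_l || keep$right_id[i] %in% used_r) next
    take[i] <- TRUE
    used_l <- c(used_l, keep$left_id[i])
    used_r <- c(used_r, keep$right_id[i])
  }
  out <- keep[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tail-entity fusion
#'
#' Scores every cross-source candidate pair of the given tail types with
#' the trained pair classifier on (semantic, embedding-cosine, Jaccard)
#' features, keeps pairs above the decision threshold via greedy
#' one-to-one matching, closes the merges under union-find and chooses the
#' canonical surface (web form preferred, else the longer surface).
#'
#' @param kg_a,kg_b Source graphs (left = records, right = web).
#' @param classifier A trained [train_pair_classifier()] model.
#' @param emb Optional `kg_embedding` for the cosine feature.
#' @param scorer Semantic scorer (default bigram cosine).
#' @param threshold Decision threshold; defaults to the classifier
#'   config's.
#' @param types Tail entity types to fuse.
#' @param prefilter Passed to [candidate_pairs()].
#' @param prefer_source Canonical-surface preference.
#' @return List with `merges` (a closed `merge_map`, provenance
#'   `tail_model`), `matched` (the accepted pairs with scores) and
#'   `scores` (all scored candidate pairs).
#' @export
fuse_tails <- function(kg_a, kg_b, classifier, emb = NULL,
                       scorer = bigram_scorer(), threshold = NULL,
                       types = c("symptom", "examination"),
                       prefilter = FALSE, prefer_source = "web") {
  if (is.null(threshold)) threshold <- classifier$config$decision_threshold
  pairs <- candidate_pairs(kg_a, kg_b, types = types, prefilter = prefilter)
  if (nrow(pairs) == 0) {
    return(list(merges = merge_map(), matched = pairs, scores = pairs))
  }
  feats <- tail_features(pairs, emb = emb, scorer = scorer)
  feats$score <- predict_pairs(classifier, feats[, feature_columns("tail")])
  matched <- greedy_one_to_one(feats, threshold)
  if (nrow(matched) == 0) {
    return(list(merges = merge_map(), matched = matched, scores = feats))
  }
  mm <- merge_map(data.frame(
    id = matched$left_id, canonical = matched$right_id,
    provenance = "tail_model", score = matched$score,
    stringsAsFactors = FALSE
  ))
  ents <- rbind(kg_a$entities[, c("id", "surface", "etype", "source")],
                kg_b$entities[, c("id", "surface", "etype", "source")])
  mm <- choose_canonical(mm, ents, prefer_source = prefer_source)
  list(merges = mm, matched = matched, scores = feats)
}

#' Evaluate a merge map against labeled alignment pairs
#'
#' A labeled pair is predicted positive when its two ids resolve to the
#' same canonical entity.
#'
#' @param mm A `merge_map`.
#' @param alignments Labeled pairs with `left_id`, `right_id`, `label`.
#' @return `prf_metrics()` output.
#' @export
evaluate_merges <- function(mm, alignments) {
  pred <- mm_lookup(mm, alignments$left_id) == mm_lookup(mm, alignments$right_id)
  prf_metrics(pred, alignments$label)
}
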