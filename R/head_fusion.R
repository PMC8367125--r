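#' Attribute-based head (disease) alignment
#'
#' Merges cross-source disease pairs sharing any normalized name value:
#' the primary surface form, an alternative-name attribute value, or an
#' English-name attribute value (English names compare
#' case-insensitively; normalization lowercases them). Surface-to-
#' alternative-name matches are included, so a record spelled with a
#' disease's alias aligns to the canonical web entry. A value naming two
#' distinct diseases within one source is ambiguous: the value is skipped
#' and reported via a warning rather than guessed. Matching is greedy
#' one-to-one, exact-surface matches first.
#'
#' @param kg_a,kg_b Source graphs.
#' @param prefer_source Source tag whose entity becomes the canonical
#'   representative of each merged pair.
#' @return A closed `merge_map` with provenance `exact` (primary-surface
#'   match on both sides) or `attribute`.
#' @export
align_by_attribute <- function(kg_a, kg_b, prefer_source = "web") {
  va <- disease_name_values(kg_a)
  vb <- disease_name_values(kg_b)
  both <- intersect(names(va$map), names(vb$map))
  if (length(both) == 0) return(merge_map())
  cand <- data.frame(
    value = both,
    left = unname(va$map[both]), right = unname(vb$map[both]),
    exact = unname(va$is_surface[both] & vb$is_surface[both]),
    stringsAsFactors = FALSE
  )
  cand <- cand[order(!cand$exact, cand$value, cand$left, cand$right), , drop = FALSE]
  used_l <- character(0)
  used_r <- character(0)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    l <- cand$left[i]; r <- cand$right[i]
    if (l %in% used_l || r %in% used_r) next
    used_l <- c(used_l, l)
    used_r <- c(used_r, r)
    rows[[length(rows) + 1L]] <- data.frame(
      id = l, canonical = r,
      provenance = if (cand$exact[i]) "exact" else "attribute",
      score = 1, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(merge_map())
  mm <- merge_map(do.call(rbind, rows))
  ents <- rbind(kg_a$entities[, c("id", "surface", "etype", "source")],
                kg_b$entities[, c("id", "surface", "etype", "source")])
  choose_canonical(mm, ents, prefer_source = prefer_source)
}

# name value -> disease id map for one source graph; ambiguous values
# (one value, two diseases) are dropped with a warning
disease_name_values <- function(kg) {
  e <- kg$entities
  dis <- e[e$etype == "disease", , drop = FALSE]
  vals <- data.frame(value = dis$surface, id = dis$id, surface = TRUE,
                     stringsAsFactors = FALSE)
  sch <- kg_schema()
  attr_rel <- c("Diseases_attr_Alternative name", "Diseases_attr_English name")
  tr <- kg$triples[kg$triples$relation %in% attr_rel, , drop = FALSE]
  if (nrow(tr) > 0) {
    surf <- stats::setNames(e$surface, e$id)
    vals <- rbind(vals, data.frame(
      value = unname(surf[tr$tail_id]), id = tr$head_id, surface = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  vals <- unique(vals[, c("value", "id", "surface")])
  amb <- names(which(tapply(vals$id, vals$value, function(x) length(unique(x))) > 1))
  if (length(amb) > 0) {
    warning("ambiguous name value(s) within one source, skipped: ",
            paste(utils::head(amb, 3), collapse = ", "))
    vals <- vals[!(vals$value %in% amb), , drop = FALSE]
  }
  # one row per value; "surface" records whether the value is the primary name
  agg <- vals[order(vals$value, !vals$surface), , drop = FALSE]
  agg <- agg[!duplicated(agg$value), , drop = FALSE]
  list(map = stats::setNames(agg$id, agg$value),
       is_surface = stats::setNames(agg$surface, agg$value))
}

#' Structural head (disease) fusion
#'
#' Fuses the disease entities that attribute alignment left unmatched.
#' Remaining cross-source disease pairs are scored by the trained
#' classifier on structural features -- the count of identical canonical
#' tail nodes (hence tail fusion must run first), the Jaccard similarity
#' of the pooled characters of the two tail-surface sets, and the
#' embedding cosine of the heads -- then merged by greedy one-to-one
#' matching above the threshold and closed under union-find. Attribute
#' merges are never overturned: their endpoints are excluded from the
#' candidate set and the stage's map is combined on top of them.
#'
#' @param kg_a,kg_b Source graphs.
#' @param tail_merges Tail-stage `merge_map` (canonicalizes tails).
#' @param emb Optional `kg_embedding`.
#' @param classifier Trained head-pair classifier.
#' @param threshold Decision threshold; defaults to the classifier's.
#' @param attr_merges Attribute-stage `merge_map` already consumed.
#' @param prefer_source Canonical-surface preference.
#' @return List with `merges` (head-model stage only), `combined`
#'   (attribute + structural, closed), `matched` and `scores`.
#' @export
fuse_heads <- function(kg_a, kg_b, tail_merges, emb, classifier,
                       threshold = NULL, attr_merges = merge_map(),
                       prefer_source = "web") {
  if (is.null(threshold)) threshold <- classifier$config$decision_threshold
  taken <- unique(c(attr_merges$id, attr_merges$canonical))
  pairs <- candidate_pairs(kg_a, kg_b, types = "disease")
  pairs <- pairs[!(pairs$left_id %in% taken) & !(pairs$right_id %in% taken), ,
                 drop = FALSE]
  if (nrow(pairs) == 0) {
    return(list(merges = merge_map(), combined = attr_merges,
                matched = pairs, scores = pairs))
  }
  feats <- head_features(pairs, kg_a, kg_b, tail_merges = tail_merges, emb = emb)
  feats$score <- predict_pairs(classifier, feats[, feature_columns("head")])
  matched <- greedy_one_to_one(feats, threshold)
  mm <- if (nrow(matched) == 0) merge_map() else merge_map(data.frame(
    id = matched$left_id, canonical = matched$right_id,
    provenance = "head_model", score = matched$score,
    stringsAsFactors = FALSE
  ))
  if (nrow(mm) > 0) {
    ents <- rbind(kg_a$entities[, c("id", "surface", "etype", "source")],
                  kg_b$entities[, c("id", "surface", "etype", "source")])
    mm <- choose_canonical(mm, ents, prefer_source = prefer_source)
  }
  list(merges = mm, combined = mm_combine(attr_merges, mm),
       matched = matched, scores = feats)
}

#' Fusion report: per-relation counts and per-stage accuracy
#'
#' Recomputes, for a benchmark and a combined merge map, the per-relation
#' triple counts of the union graph before and after applying the merges,
#' plus precision/recall/F1 of the map against the benchmark's tail and
#' head alignment labels, and the merge counts per provenance stage.
#'
#' @param benchmark A `synthetic_benchmark`.
#' @param merges Combined closed `merge_map`.
#' @return A list serializable as JSON.
#' @export
fusion_report <- function(benchmark, merges) {
  un <- kg_union(benchmark$view_emr, benchmark$view_web)
  fused <- apply_merge(un, merges)
  rels <- kg_schema()$label
  count_by <- function(kg) {
    tab <- table(factor(kg$triples$relation, levels = rels))
    stats::setNames(as.integer(tab), rels)
  }
  before <- count_by(un)
  after <- count_by(fused)
  list(
    relations = lapply(stats::setNames(rels, rels), function(r) {
      list(before = unname(before[r]), after = unname(after[r]))
    }),
    triples_before = sum(before), triples_after = sum(after),
    entities_before = nrow(un$entities), entities_after = nrow(fused$entities),
    tail_metrics = evaluate_merges(merges, benchmark$tail_alignments),
    head_metrics = evaluate_merges(merges, benchmark$head_alignments),
    merges_by_stage = as.list(table(merges$provenance))
  )
}
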