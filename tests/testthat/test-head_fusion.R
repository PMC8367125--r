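attr_kg <- function(src, disease, alt = NULL, eng = NULL, syms = character(0)) {
  rows <- list()
  if (length(syms)) {
    rows[[1]] <- data.frame(
      head_surface = disease, head_type = "disease",
      relation = "Diseases_rel_Symptom", tail_surface = syms,
      tail_type = "symptom", source = src, stringsAsFactors = FALSE
    )
  }
  if (!is.null(alt)) {
    rows[[length(rows) + 1]] <- data.frame(
      head_surface = disease, head_type = "disease",
      relation = "Diseases_attr_Alternative name", tail_surface = alt,
      tail_type = "alternative_name", source = src, stringsAsFactors = FALSE
    )
  }
  if (!is.null(eng)) {
    rows[[length(rows) + 1]] <- data.frame(
      head_surface = disease, head_type = "disease",
      relation = "Diseases_attr_English name", tail_surface = eng,
      tail_type = "english_name", source = src, stringsAsFactors = FALSE
    )
  }
  kg_from_records(do.call(rbind, rows))
}

test_that("an alternative name aligns a record surface to the web entry", {
  # the canonical entry lists "GH adenoma" as alias; the record spells the
  # disease that way
  a <- attr_kg("emr", "GH adenoma", syms = "头痛")
  b <- attr_kg("web", "垂体生长激素腺瘤", alt = "GH adenoma", syms = "头痛")
  mm <- align_by_attribute(a, b)
  expect_equal(nrow(mm), 1)
  expect_equal(mm_lookup(mm, "emr|disease|GH adenoma"),
               "web|disease|垂体生长激素腺瘤")
  expect_equal(mm$provenance, "attribute")
})

test_that("exact same-surface matches carry the exact provenance", {
  a <- attr_kg("emr", "垂体瘤", syms = "头痛")
  b <- attr_kg("web", "垂体瘤", syms = "头晕")
  mm <- align_by_attribute(a, b)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$provenance, "exact")
})

test_that("English names align case-insensitively; no shared value, no merge", {
  a <- attr_kg("emr", "病甲", eng = "Pituitary Adenoma", syms = "头痛")
  b <- attr_kg("web", "病乙", eng = "pituitary adenoma", syms = "头晕")
  mm <- align_by_attribute(a, b)
  expect_equal(nrow(mm), 1)
  c1 <- attr_kg("emr", "病甲", syms = "头痛")
  c2 <- attr_kg("web", "病乙", syms = "头晕")
  expect_equal(nrow(align_by_attribute(c1, c2)), 0)
})

test_that("a value naming two diseases in one source is skipped with a warning", {
  a <- kg_from_records(data.frame(
    head_surface = c("病甲", "病乙"), head_type = "disease",
    relation = "Diseases_attr_Alternative name",
    tail_surface = c("同名", "同名"), tail_type = "alternative_name",
    source = "emr", stringsAsFactors = FALSE
  ))
  b <- attr_kg("web", "病丙", alt = "同名", syms = "头晕")
  expect_warning(mm <- align_by_attribute(a, b), "ambiguous")
  expect_equal(nrow(mm), 0)
})

test_that("identical canonical tail sets rank a true disease pair on top", {
  syms <- c("一", "二", "三", "四", "五")
  a <- kg_from_records(data.frame(
    head_surface = rep(c("病甲", "病乙"), each = 5), head_type = "disease",
    relation = "Diseases_rel_Symptom",
    tail_surface = c(syms, c("六", "七", "八", "九", "十")),
    tail_type = "symptom", source = "emr", stringsAsFactors = FALSE
  ))
  b <- kg_from_records(data.frame(
    head_surface = rep(c("病丙", "病丁"), each = 5), head_type = "disease",
    relation = "Diseases_rel_Symptom",
    tail_surface = c(syms, c("亖", "卅", "卌", "圦", "圧")),
    tail_type = "symptom", source = "web", stringsAsFactors = FALSE
  ))
  tails_mm <- merge_map(data.frame(
    id = entity_id("emr", "symptom", syms),
    canonical = entity_id("web", "symptom", syms), stringsAsFactors = FALSE
  ))
  pairs <- candidate_pairs(a, b, types = "disease")
  feats <- head_features(pairs, a, b, tail_merges = tails_mm, emb = NULL)
  top <- feats[order(-feats$same_tails), ][1, ]
  expect_equal(top$left_id, "emr|disease|病甲")
  expect_equal(top$right_id, "web|disease|病丙")
  expect_equal(top$same_tails, 5L)
  # disease without rel triples has zero structural features
  lonely <- attr_kg("emr", "孤病", eng = "lonely", syms = character(0))
  p2 <- candidate_pairs(lonely, b, types = "disease")
  f2 <- head_features(p2, lonely, b, tail_merges = tails_mm, emb = NULL)
  expect_true(all(f2$same_tails == 0))
  expect_true(all(f2$set_jaccard == 0))
})

test_that("attribute merges are never overturned by the structural stage", {
  b <- generate_benchmark(generator_config(seed = 33, n_diseases = 20))
  attr_mm <- align_by_attribute(b$view_emr, b$view_web)
  al <- b$head_alignments
  feats <- head_features(al, b$view_emr, b$view_web, emb = NULL)
  clf <- train_pair_classifier(feats[, c("same_tails", "set_jaccard", "transr_cos")],
                               al$label, pair_classifier_config("dtree", seed = 1))
  res <- fuse_heads(b$view_emr, b$view_web, tail_merges = merge_map(),
                    emb = NULL, classifier = clf, attr_merges = attr_mm)
  for (i in seq_len(nrow(attr_mm))) {
    expect_equal(mm_lookup(res$combined, attr_mm$id[i]),
                 mm_lookup(res$combined, attr_mm$canonical[i]))
  }
  # structural candidates exclude attribute-aligned endpoints
  expect_false(any(res$merges$id %in% c(attr_mm$id, attr_mm$canonical)))
})

test_that("the degenerate benchmark is solved by the attribute stage alone", {
  b <- generate_benchmark(generator_config(seed = 42, n_diseases = 20,
                                           overlap = 1.0, variant_rate = 0.0))
  mm <- align_by_attribute(b$view_emr, b$view_web)
  m <- evaluate_merges(mm, b$head_alignments)
  expect_equal(m$recall, 1.0)
})

test_that("fusion_report counts match a brute-force recount", {
  b <- generate_benchmark(generator_config(seed = 34, n_diseases = 10))
  un <- kg_union(b$view_emr, b$view_web)
  mm <- random_merges(un, seed = 1, n = 2)
  rep <- fusion_report(b, mm)
  # identity map: before == after
  rep0 <- fusion_report(b, merge_map())
  for (r in names(rep0$relations)) {
    expect_equal(rep0$relations[[r]]$before, rep0$relations[[r]]$after)
  }
  # oracle: rewrite every triple by lookup, dedup by brute force
  canon <- function(ids) mm_lookup(mm, ids)
  tr <- un$triples
  key <- unique(paste(canon(tr$head_id), tr$relation, canon(tr$tail_id), sep = "\r"))
  expect_equal(rep$triples_after, length(key))
  expect_lte(rep$triples_after, rep$triples_before)
})

test_that("perfect fusion on the uncorrupted benchmark restores truth counts", {
  b <- generate_benchmark(generator_config(seed = 35, n_diseases = 10,
                                           overlap = 1.0, variant_rate = 0.0))
  # ground-truth merge map: every emr entity onto its web twin
  emr <- b$view_emr$entities
  web <- b$view_web$entities
  shared <- merge(emr, web, by = c("surface", "etype"))
  mm <- merge_map(data.frame(id = shared$id.x, canonical = shared$id.y,
                             stringsAsFactors = FALSE))
  rep <- fusion_report(b, mm)
  sch <- kg_schema()
  truth_counts <- table(factor(b$truth$triples$relation, levels = sch$label))
  for (r in sch$label[!sch$is_attribute]) {
    expect_equal(rep$relations[[r]]$after, unname(truth_counts[r]),
                 info = r)
  }
})
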