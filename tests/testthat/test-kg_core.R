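test_that("loading builds a schema-valid graph and deduplicates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    head_surface = "垂体泌乳素腺瘤", head_type = "disease",
    relation = "Diseases_rel_Symptom",
    tail_surface = "头痛", tail_type = "symptom", source = "emr",
    stringsAsFactors = FALSE
  )
  con <- file(tmp, "w", encoding = "UTF-8")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  kg <- load_triples(tmp, "tsv")
  expect_equal(nrow(kg$entities), 2)
  expect_equal(nrow(kg$triples), 1)

  # same row twice collapses to one triple
  con <- file(tmp, "w", encoding = "UTF-8")
  write.table(rbind(df, df), con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  kg2 <- load_triples(tmp, "tsv")
  expect_equal(nrow(kg2$triples), 1)
  expect_identical(kg$triples, kg2$triples)
})

test_that("jsonl dialect loads the same graph as tsv", {
  df <- toy_records()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jl <- withr::local_tempfile(fileext = ".jsonl")
  con <- file(tsv, "w", encoding = "UTF-8")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  writeLines(vapply(seq_len(nrow(df)), function(i) {
    as.character(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE))
  }, character(1)), jl, useBytes = TRUE)
  a <- load_triples(tsv, "tsv")
  b <- load_triples(jl, "jsonl")
  expect_identical(a$entities, b$entities)
  expect_identical(a$triples, b$triples)
})

test_that("schema errors name the offending line", {
  df <- toy_records()
  df$tail_type[1] <- "medicine"  # wrong tail type for Diseases_rel_Symptom
  expect_error(kg_from_records(df), "line 1.*Diseases_rel_Symptom")
  df2 <- toy_records()
  df2$relation[2] <- "Diseases_rel_Nonsense"
  expect_error(kg_from_records(df2), "line 2.*unknown relation")
  df3 <- toy_records()
  df3$tail_type[2] <- "gene"
  expect_error(kg_from_records(df3), "unknown entity type")
})

test_that("the schema accepts exactly the ten printed signatures", {
  sch <- kg_schema()
  types <- entity_types()
  ok <- 0L
  bad <- 0L
  for (r in sch$label) {
    for (ht in types) {
      for (tt in types) {
        df <- data.frame(
          head_surface = "甲", head_type = ht, relation = r,
          tail_surface = "乙", tail_type = tt, source = "emr",
          stringsAsFactors = FALSE
        )
        valid <- ht == sch$head_type[sch$label == r] &&
          tt == sch$tail_type[sch$label == r]
        if (valid) {
          expect_silent(kg_from_records(df))
          ok <- ok + 1L
        } else {
          expect_error(kg_from_records(df))
          bad <- bad + 1L
        }
      }
    }
  }
  expect_equal(ok, 10L)
  expect_equal(bad, 10L * 11L * 11L - 10L)
})

test_that("surface normalization: NFKC, whitespace, English case", {
  expect_equal(normalize_surface("  头  痛 "), "头 痛")
  expect_equal(normalize_surface("ＧＨ　ａｄｅｎｏｍａ"), "GH adenoma")
  expect_equal(normalize_surface("GH Adenoma", "english_name"), "gh adenoma")
  # CJK is not case-folded (no case), ASCII outside english_name is kept
  expect_equal(normalize_surface("MRI"), "MRI")
})

test_that("intra-source dedup merges on normalized surface only", {
  df <- toy_records()
  df2 <- df
  df2$tail_surface[1] <- " 头痛 "  # same symptom, sloppy whitespace
  kg <- kg_from_records(rbind(df, df2))
  expect_equal(sum(kg$entities$etype == "symptom"), 1)
})

test_that("apply_merge collapses, is idempotent and monotone", {
  df <- data.frame(
    head_surface = c("病一", "病二"), head_type = "disease",
    relation = "Diseases_rel_Symptom",
    tail_surface = c("症一", "症二"), tail_type = "symptom",
    source = c("emr", "web"), stringsAsFactors = FALSE
  )
  kg <- kg_from_records(df)
  mm <- merge_map(data.frame(
    id = c("emr|symptom|症一", "emr|disease|病一"),
    canonical = c("web|symptom|症二", "web|disease|病二"),
    stringsAsFactors = FALSE
  ))
  fused <- apply_merge(kg, mm)
  expect_equal(nrow(fused$triples), 1)
  expect_lte(nrow(fused$triples), nrow(kg$triples))
  # idempotence
  expect_identical(apply_merge(fused, mm)$triples, fused$triples)
  # identity map
  expect_identical(apply_merge(kg, merge_map())$triples, kg$triples)
  # merged-away entities dropped, canonical keeps pooled source tags
  expect_false("emr|symptom|症一" %in% fused$entities$id)
  expect_equal(fused$entities$source[fused$entities$id == "web|symptom|症二"],
               "emr;web")
})

test_that("merges joining different entity types are rejected", {
  kg <- kg_from_records(toy_records())
  mm <- merge_map(data.frame(
    id = "emr|symptom|头痛", canonical = "emr|examination|磁共振",
    stringsAsFactors = FALSE
  ))
  expect_error(apply_merge(kg, mm), "different types")
})

test_that("Neo4j CSV export round-trips, including quoted commas", {
  df <- toy_records()
  df$tail_surface[2] <- "磁共振, 增强"   # comma inside a field
  kg <- kg_from_records(df)
  dir <- withr::local_tempdir()
  files <- export_neo4j_csv(kg, dir)
  expect_true(all(file.exists(files)))
  nodes <- readLines(files["nodes"], encoding = "UTF-8")
  expect_equal(length(nodes), nrow(kg$entities) + 1)  # header + rows
  back <- import_neo4j_csv(dir)
  expect_identical(back$entities[, c("id", "surface", "etype", "source")],
                   kg$entities[, c("id", "surface", "etype", "source")])
  expect_identical(back$triples, kg$triples)
})

test_that("N-Triples export round-trips and satisfies an RDF parser", {
  kg <- kg_from_records(toy_records())
  nt <- withr::local_tempfile(fileext = ".nt")
  export_ntriples(kg, nt)
  expect_equal(length(readLines(nt)), nrow(kg$triples))
  back <- import_ntriples(nt)
  expect_identical(back$entities[, c("id", "surface", "etype", "source")],
                   kg$entities[, c("id", "surface", "etype", "source")])
  expect_identical(back$triples, kg$triples)

  # empty graph -> empty file
  empty <- kg_new(data.frame(id = character(), surface = character(),
                             etype = character(), source = character()),
                  data.frame())
  nt2 <- withr::local_tempfile(fileext = ".nt")
  export_ntriples(empty, nt2)
  expect_equal(length(readLines(nt2)), 0)

  # independent RDF parser accepts the unicode escaping
  chk <- system2("python", c("-c", shQuote(paste0(
    "import rdflib,sys; g=rdflib.Graph(); g.parse('", nt,
    "', format='nt'); print(len(g))"
  ))), stdout = TRUE, stderr = TRUE)
  expect_equal(tail(chk, 1), as.character(nrow(kg$triples)))
})

test_that("ICD mapping annotates diseases and never drops them", {
  kg <- kg_from_records(toy_records())
  out <- map_icd(kg, c("垂体泌乳素腺瘤" = "D35.2"))
  e <- out$entities
  expect_equal(e$icd[e$etype == "disease"], "D35.2")
  expect_true(all(is.na(e$icd[e$etype != "disease"])))
  # empty table -> all unmapped, same entity count
  out2 <- map_icd(kg, character(0))
  expect_equal(out2$entities$icd[out2$entities$etype == "disease"], "unmapped")
  expect_equal(nrow(out2$entities), nrow(kg$entities))
})

test_that("ICD code reaches a disease matched through a merged alias", {
  # web knows the canonical name; the record uses an alias that attribute
  # fusion maps onto it; the ICD table only lists the canonical name
  emr <- kg_from_records(data.frame(
    head_surface = "泌乳素瘤", head_type = "disease",
    relation = "Diseases_rel_Symptom", tail_surface = "头痛",
    tail_type = "symptom", source = "emr", stringsAsFactors = FALSE
  ))
  web <- kg_from_records(data.frame(
    head_surface = "垂体泌乳素腺瘤", head_type = "disease",
    relation = "Diseases_attr_Alternative name", tail_surface = "泌乳素瘤",
    tail_type = "alternative_name", source = "web", stringsAsFactors = FALSE
  ))
  mm <- align_by_attribute(emr, web)
  fused <- apply_merge(kg_union(emr, web), mm)
  out <- map_icd(fused, c("垂体泌乳素腺瘤" = "D35.2"))
  dis <- out$entities[out$entities$etype == "disease", ]
  expect_equal(nrow(dis), 1)
  expect_equal(dis$icd, "D35.2")
})
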