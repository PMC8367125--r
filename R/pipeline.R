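#' Configuration for the end-to-end fusion pipeline
#'
#' Bundles the stage configurations for: synthetic benchmark generation,
#' embedding training on the union of the two views, tail fusion, head
#' fusion, and export. The full configuration is serialized alongside
#' every run for provenance, and a rerun with an identical configuration
#' reproduces identical artifacts.
#'
#' @param generator A [generator_config()].
#' @param embedding An [embedding_config()].
#' @param tail_classifier,head_classifier [pair_classifier_config()]s.
#' @param export_formats Subset of `c("neo4j", "ntriples")`.
#' @param prefer_source Canonical-surface preference after merges.
#' @param icd_table Optional named character vector of disease surface to
#'   ICD code.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            embedding = embedding_config(),
                            tail_classifier = pair_classifier_config("mlp"),
                            head_classifier = pair_classifier_config("mlp"),
                            export_formats = c("neo4j", "ntriples"),
                            prefer_source = "web",
                            icd_table = NULL,
                            log_level = c("info", "quiet")) {
  export_formats <- match.arg(export_formats, several.ok = TRUE)
  structure(list(
    generator = generator, embedding = embedding,
    tail_classifier = tail_classifier, head_classifier = head_classifier,
    export_formats = export_formats, prefer_source = prefer_source,
    icd_table = icd_table, log_level = match.arg(log_level)
  ), class = "pipeline_config")
}

#' Run the full fusion pipeline
#'
#' Executes simulate, embed, tail-fuse, head-fuse (attribute stage then
#' structural stage), merge application, ICD annotation and export, in
#' that order, writing each stage's artifacts under `out_dir`:
#' `benchmark/` (views, truth, labels), `embedding/`, `merges_tail.tsv`,
#' `merges_all.tsv`, `fused.tsv`, `report.json`, `config.yaml`, and the
#' requested export formats (`neo4j/`, `fused.nt`). A stage failure
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return The report list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$log_level == "info") message("[kgfuse] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("stage simulate")
  bench <- stage("simulate", {
    b <- generate_benchmark(config$generator)
    write_benchmark(b, file.path(out_dir, "benchmark"))
    b
  })

  say("stage embed")
  emb <- stage("embed", {
    un <- kg_union(bench$view_emr, bench$view_web)
    e <- train_embedding(un, config$embedding)
    save_embedding(e, file.path(out_dir, "embedding"))
    e
  })

  say("stage fuse-tail")
  tail_res <- stage("fuse-tail", {
    al <- bench$tail_alignments
    feats <- tail_features(al, emb = emb)
    clf <- train_pair_classifier(feats[, feature_columns("tail")], al$label,
                                 config$tail_classifier)
    res <- fuse_tails(bench$view_emr, bench$view_web, clf, emb = emb,
                      prefer_source = config$prefer_source)
    write_merges(res$merges, file.path(out_dir, "merges_tail.tsv"))
    res$classifier <- clf
    res
  })

  say("stage fuse-head")
  head_res <- stage("fuse-head", {
    attr_mm <- align_by_attribute(bench$view_emr, bench$view_web)
    al <- bench$head_alignments
    feats <- head_features(al, bench$view_emr, bench$view_web,
                           tail_merges = tail_res$merges, emb = emb)
    clf <- train_pair_classifier(feats[, feature_columns("head")], al$label,
                                 config$head_classifier)
    res <- fuse_heads(bench$view_emr, bench$view_web,
                      tail_merges = tail_res$merges, emb = emb,
                      classifier = clf, attr_merges = attr_mm,
                      prefer_source = config$prefer_source)
    res$classifier <- clf
    res$attr_merges <- attr_mm
    res
  })

  say("stage merge+export")
  report <- stage("merge+export", {
    un <- kg_union(bench$view_emr, bench$view_web)
    all_mm <- choose_canonical(mm_combine(tail_res$merges, head_res$combined),
                               un$entities, prefer_source = config$prefer_source)
    write_merges(all_mm, file.path(out_dir, "merges_all.tsv"))
    fused <- apply_merge(un, all_mm)
    if (!is.null(config$icd_table)) fused <- map_icd(fused, config$icd_table)
    write_triples(fused, file.path(out_dir, "fused.tsv"))
    if ("neo4j" %in% config$export_formats) {
      export_neo4j_csv(fused, file.path(out_dir, "neo4j"))
    }
    if ("ntriples" %in% config$export_formats) {
      export_ntriples(fused, file.path(out_dir, "fused.nt"))
    }
    rep <- fusion_report(bench, all_mm)
    rep$tail_classifier_metrics <- tail_res$classifier$metrics
    rep$head_classifier_metrics <- head_res$classifier$metrics
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })

  yaml::write_yaml(serialize_config(config), file.path(out_dir, "config.yaml"))
  say("done: ", out_dir)
  invisible(report)
}

# plain-list view of a pipeline config for provenance serialization
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  g <- strip(config$generator)
  g$alphabet <- paste(g$alphabet, collapse = "")
  list(
    generator = g,
    embedding = strip(config$embedding),
    tail_classifier = strip(config$tail_classifier),
    head_classifier = strip(config$head_classifier),
    export_formats = config$export_formats,
    prefer_source = config$prefer_source,
    icd_table = as.list(config$icd_table),
    log_level = config$log_level
  )
}
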