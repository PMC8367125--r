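#' Entity types of the disease-centred schema
#'
#' The closed set of node types allowed in the graph: one head type
#' (`disease`), the clinical tail types (`symptom`, `examination`,
#' `surgery`, `medicine`, `body_structure`, `treatment`, `pathogeny`,
#' `department`) and the two name-attribute types (`english_name`,
#' `alternative_name`). Unknown labels are rejected at load time.
#'
#' @return Character vector of valid entity type labels.
#' @export
entity_types <- function() {
  c(
    "disease", "symptom", "examination", "surgery", "medicine",
    "body_structure", "treatment", "pathogeny", "department",
    "english_name", "alternative_name"
  )
}

#' Relation inventory of the schema
#'
#' The ten admissible relation signatures. Each relation fixes the entity
#' type of its head and tail; `is_attribute` marks attribute relations
#' (label contains `attr`), whose tails are serialized as literals in RDF
#' export.
#'
#' @return A data frame with columns `label`, `head_type`, `tail_type`,
#'   `is_attribute`.
#' @export
kg_schema <- function() {
  s <- data.frame(
    label = c(
      "Diseases_rel_Symptom",
      "Diseases_rel_Surgery",
      "Diseases_rel_Medicines",
      "Diseases_rel_Examination",
      "Symptoms_rel_Body structure",
      "Diseases_rel_Treatment",
      "Diseases_attr_Pathogeny",
      "Diseases_attr_Department",
      "Diseases_attr_English name",
      "Diseases_attr_Alternative name"
    ),
    head_type = c(
      "disease", "disease", "disease", "disease", "symptom",
      "disease", "disease", "disease", "disease", "disease"
    ),
    tail_type = c(
      "symptom", "surgery", "medicine", "examination", "body_structure",
      "treatment", "pathogeny", "department", "english_name",
      "alternative_name"
    ),
    stringsAsFactors = FALSE
  )
  s$is_attribute <- grepl("_attr_", s$label, fixed = TRUE)
  s
}

#' Relation labels (convenience accessor)
#' @param attributes_only If `TRUE`, return only attribute relation labels.
#' @return Character vector of relation labels.
#' @export
relation_labels <- function(attributes_only = FALSE) {
  s <- kg_schema()
  if (attributes_only) s$label[s$is_attribute] else s$label
}

#' Normalize an entity surface form
#'
#' Applies Unicode NFKC normalization, strips surrounding whitespace and
#' collapses internal whitespace runs to a single space. CJK text is left
#' case-untouched; `english_name` attribute values are additionally
#' ASCII-lowercased so that English names compare case-insensitively.
#'
#' @param x Character vector of raw surface forms.
#' @param etype Entity type of the surfaces (scalar); only `english_name`
#'   changes behaviour.
#' @return Normalized character vector.
#' @export
normalize_surface <- function(x, etype = "symptom") {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- gsub("\\s+", " ", x, perl = TRUE)
  x <- trimws(x)
  if (identical(etype, "english_name")) x <- tolower(x)
  x
}

# Stable entity id: source, type and normalized surface joined with "|".
# Deterministic across runs so merges and exports are reproducible.
entity_id <- function(source, etype, surface) {
  paste(source, etype, surface, sep = "|")
}

# Inverse of entity_id(); surfaces may themselves contain "|".
split_entity_id <- function(id) {
  parts <- stringi::stri_split_fixed(id, "|", n = 3L, simplify = TRUE)
  data.frame(
    source = parts[, 1], etype = parts[, 2], surface = parts[, 3],
    stringsAsFactors = FALSE
  )
}

assert_entity_type <- function(etype, where = "") {
  bad <- setdiff(unique(etype), entity_types())
  if (length(bad) > 0) {
    stop(
      "unknown entity type(s) ", paste(sQuote(bad), collapse = ", "),
      if (nzchar(where)) paste0(" ", where),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
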