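#' Construct a knowledge graph from entity and triple tables
#'
#' Low-level constructor. Most users build graphs with [load_triples()] or
#' [generate_benchmark()]. Validates the schema: entity types must belong to
#' [entity_types()], relation labels to [kg_schema()], and each triple's
#' endpoint types must match the relation signature. Duplicate
#' (head, relation, tail) triples are collapsed, with their source tags
#' accumulated into a `;`-joined annotation.
#'
#' @param entities Data frame with columns `id`, `surface`, `etype`,
#'   `source` (an `icd` column is carried through if present).
#' @param triples Data frame with columns `head_id`, `relation`, `tail_id`,
#'   `source`.
#' @return An object of class `kg`.
#' @export
kg_new <- function(entities, triples) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  need_e <- c("id", "surface", "etype", "source")
  if (!all(need_e %in% names(entities))) {
    stop("entities must have columns ", paste(need_e, collapse = ", "))
  }
  need_t <- c("head_id", "relation", "tail_id", "source")
  if (nrow(triples) == 0 && length(names(triples)) == 0) {
    triples <- data.frame(
      head_id = character(), relation = character(),
      tail_id = character(), source = character(), stringsAsFactors = FALSE
    )
  }
  if (!all(need_t %in% names(triples))) {
    stop("triples must have columns ", paste(need_t, collapse = ", "))
  }
  if (anyDuplicated(entities$id)) {
    stop("duplicate entity ids: ",
         paste(utils::head(entities$id[duplicated(entities$id)], 3), collapse = ", "))
  }
  if (any(!nzchar(entities$surface))) stop("empty entity surface after normalization")
  if (any(!nzchar(entities$source))) stop("empty entity source tag")
  assert_entity_type(entities$etype, "in entity table")

  triples <- collapse_triples(triples)
  kg <- structure(
    list(entities = entities[, union(need_e, names(entities)), drop = FALSE],
         triples = triples),
    class = "kg"
  )
  validate_kg(kg)
  kg
}

# Collapse duplicate (head, relation, tail) rows; source tags become a
# sorted ";"-joined multiset annotation.
collapse_triples <- function(triples) {
  if (nrow(triples) == 0) {
    return(data.frame(
      head_id = character(), relation = character(),
      tail_id = character(), source = character(), stringsAsFactors = FALSE
    ))
  }
  key <- paste(triples$head_id, triples$relation, triples$tail_id, sep = "\r")
  src <- split(triples$source, key)
  first <- !duplicated(key)
  out <- triples[first, c("head_id", "relation", "tail_id"), drop = FALSE]
  srcs <- vapply(
    src[key[first]],
    function(s) paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";"),
    character(1)
  )
  out$source <- unname(srcs)
  out <- out[order(out$head_id, out$relation, out$tail_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_kg <- function(kg) {
  sch <- kg_schema()
  tr <- kg$triples
  bad_rel <- setdiff(unique(tr$relation), sch$label)
  if (length(bad_rel) > 0) {
    stop("unknown relation label(s): ", paste(sQuote(bad_rel), collapse = ", "),
         call. = FALSE)
  }
  etype <- stats::setNames(kg$entities$etype, kg$entities$id)
  miss <- setdiff(unique(c(tr$head_id, tr$tail_id)), names(etype))
  if (length(miss) > 0) {
    stop("triples reference unknown entities: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  if (nrow(tr) > 0) {
    ht <- stats::setNames(sch$head_type, sch$label)[tr$relation]
    tt <- stats::setNames(sch$tail_type, sch$label)[tr$relation]
    bad <- which(etype[tr$head_id] != ht | etype[tr$tail_id] != tt)
    if (length(bad) > 0) {
      i <- bad[1]
      stop(sprintf(
        "schema violation: relation %s requires (%s, %s) but got (%s, %s)",
        sQuote(tr$relation[i]),
        stats::setNames(sch$head_type, sch$label)[tr$relation[i]],
        stats::setNames(sch$tail_type, sch$label)[tr$relation[i]],
        etype[tr$head_id[i]], etype[tr$tail_id[i]]
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf(
    "<kg> %d entities, %d triples, sources: %s\n",
    nrow(x$entities), nrow(x$triples),
    paste(sort(unique(unlist(strsplit(x$entities$source, ";", fixed = TRUE)))),
          collapse = ", ")
  ))
  tab <- table(x$triples$relation)
  if (length(tab)) {
    for (r in names(tab)) cat(sprintf("  %-32s %5d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Load triples from a TSV or JSON-lines file
#'
#' Reads six-field triple records (`head_surface`, `head_type`, `relation`,
#' `tail_surface`, `tail_type`, `source`), normalizes surfaces with
#' [normalize_surface()], deduplicates entities within a source on
#' (normalized surface, type, source), validates every record against the
#' relation schema and collapses duplicate triples.
#'
#' @param path Path to the input file. The TSV dialect requires a header
#'   row with the six column names; the JSON-lines dialect expects one
#'   object per line with the same six keys.
#' @param dialect `"tsv"` or `"jsonl"`.
#' @return A `kg` object.
#' @export
load_triples <- function(path, dialect = c("tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                            colClasses = "character", encoding = "UTF-8",
                            check.names = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      as.data.frame(r[c("head_surface", "head_type", "relation",
                        "tail_surface", "tail_type", "source")],
                    stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(
      head_surface = character(), head_type = character(),
      relation = character(), tail_surface = character(),
      tail_type = character(), source = character(), stringsAsFactors = FALSE
    )
  }
  need <- c("head_surface", "head_type", "relation", "tail_surface",
            "tail_type", "source")
  if (!all(need %in% names(df))) {
    stop("triple file must have columns: ", paste(need, collapse = ", "))
  }
  kg_from_records(df[, need, drop = FALSE])
}

#' Build a knowledge graph from a six-column record table
#'
#' @param df Data frame with columns `head_surface`, `head_type`,
#'   `relation`, `tail_surface`, `tail_type`, `source`.
#' @return A `kg` object.
#' @export
kg_from_records <- function(df) {
  sch <- kg_schema()
  n <- nrow(df)
  if (n > 0) {
    bad <- which(!(df$relation %in% sch$label))
    if (length(bad) > 0) {
      stop(sprintf("line %d: unknown relation label %s",
                   bad[1], sQuote(df$relation[bad[1]])), call. = FALSE)
    }
    assert_entity_type(df$head_type, "in head_type column")
    assert_entity_type(df$tail_type, "in tail_type column")
    ht <- stats::setNames(sch$head_type, sch$label)[df$relation]
    tt <- stats::setNames(sch$tail_type, sch$label)[df$relation]
    bad <- which(df$head_type != ht | df$tail_type != tt)
    if (length(bad) > 0) {
      i <- bad[1]
      stop(sprintf(
        "line %d: relation %s requires types (%s, %s) but record has (%s, %s)",
        i, sQuote(df$relation[i]), ht[i], tt[i], df$head_type[i], df$tail_type[i]
      ), call. = FALSE)
    }
  }
  hs <- normalize_vec(df$head_surface, df$head_type)
  ts <- normalize_vec(df$tail_surface, df$tail_type)
  if (any(!nzchar(hs)) || any(!nzchar(ts))) {
    i <- which(!nzchar(hs) | !nzchar(ts))[1]
    stop(sprintf("line %d: empty surface after normalization", i), call. = FALSE)
  }
  ent <- data.frame(
    id = c(entity_id(df$source, df$head_type, hs),
           entity_id(df$source, df$tail_type, ts)),
    surface = c(hs, ts),
    etype = c(df$head_type, df$tail_type),
    source = c(df$source, df$source),
    stringsAsFactors = FALSE
  )
  ent <- ent[!duplicated(ent$id), , drop = FALSE]
  ent <- ent[order(ent$id), , drop = FALSE]
  rownames(ent) <- NULL
  tri <- data.frame(
    head_id = entity_id(df$source, df$head_type, hs),
    relation = df$relation,
    tail_id = entity_id(df$source, df$tail_type, ts),
    source = df$source,
    stringsAsFactors = FALSE
  )
  kg_new(ent, tri)
}

# normalize_surface() per-row with per-row etype
normalize_vec <- function(x, etype) {
  out <- normalize_surface(x)
  en <- etype == "english_name"
  if (any(en)) out[en] <- tolower(out[en])
  out
}

#' Write a knowledge graph as a six-column triple file
#'
#' Inverse of [load_triples()]: a triple whose source annotation carries
#' several tags is written once per tag.
#'
#' @param kg A `kg` object.
#' @param path Output path.
#' @param dialect `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_triples <- function(kg, path, dialect = c("tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  e <- kg$entities
  surf <- stats::setNames(e$surface, e$id)
  ety <- stats::setNames(e$etype, e$id)
  tr <- kg$triples
  srcs <- strsplit(tr$source, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(tr)), lengths(srcs))
  df <- data.frame(
    head_surface = surf[tr$head_id[idx]],
    head_type = ety[tr$head_id[idx]],
    relation = tr$relation[idx],
    tail_surface = surf[tr$tail_id[idx]],
    tail_type = ety[tr$tail_id[idx]],
    source = unlist(srcs),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  if (dialect == "tsv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Union of knowledge graphs
#'
#' Entities from different sources keep disjoint ids, so the union simply
#' concatenates and re-deduplicates. Used to train one embedding space over
#' both source views.
#'
#' @param ... `kg` objects.
#' @return A `kg` object.
#' @export
kg_union <- function(...) {
  kgs <- list(...)
  ent <- do.call(rbind, lapply(kgs, function(k) k$entities))
  tri <- do.call(rbind, lapply(kgs, function(k) k$triples))
  ent <- ent[!duplicated(ent$id), , drop = FALSE]
  ent <- ent[order(ent$id), , drop = FALSE]
  rownames(ent) <- NULL
  kg_new(ent, tri)
}

#' Rewrite a knowledge graph under an entity merge map
#'
#' Every triple endpoint is replaced by its canonical id; duplicate triples
#' created by the rewrite are collapsed (their source annotations pooled);
#' merged-away entities are dropped and the canonical entity's source
#' annotation accumulates the tags of everything merged into it. Entities
#' not mentioned by the map are untouched. The triple count never
#' increases.
#'
#' @param kg A `kg` object.
#' @param merges A [merge_map()].
#' @return The rewritten `kg`.
#' @export
apply_merge <- function(kg, merges) {
  stopifnot(inherits(kg, "kg"), inherits(merges, "merge_map"))
  ids <- kg$entities$id
  canon <- mm_lookup(merges, ids)
  etype <- stats::setNames(kg$entities$etype, ids)
  moved <- which(canon != ids)
  if (length(moved) > 0) {
    tgt <- canon[moved]
    unknown <- setdiff(tgt, ids)
    if (length(unknown) > 0) {
      stop("merge map targets entities absent from the graph: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    if (any(etype[ids[moved]] != etype[tgt])) {
      stop("merge joins entities of different types", call. = FALSE)
    }
  }
  map <- stats::setNames(canon, ids)
  ent <- kg$entities
  keep <- ent$id == map[ent$id]
  # canonical survivors absorb the source tags of everything merged into them
  grp <- split(ent$source, map[ent$id])
  ent2 <- ent[keep, , drop = FALSE]
  ent2$source <- vapply(
    grp[ent2$id],
    function(s) paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";"),
    character(1)
  )
  tr <- kg$triples
  tr$head_id <- unname(map[tr$head_id])
  tr$tail_id <- unname(map[tr$tail_id])
  ent2 <- ent2[order(ent2$id), , drop = FALSE]
  rownames(ent2) <- NULL
  kg_new(ent2, tr)
}

#' Annotate disease entities with ICD codes
#'
#' Dictionary lookup on the canonical (normalized) disease surface. Matched
#' diseases gain the code; unmatched diseases are annotated `"unmapped"`,
#' never dropped. Non-disease entities get `NA`.
#'
#' @param kg A `kg` object.
#' @param icd_table Named character vector mapping disease surface forms to
#'   ICD codes; names are normalized like entity surfaces before lookup.
#' @return The annotated `kg` (column `icd` on the entity table).
#' @export
map_icd <- function(kg, icd_table) {
  stopifnot(inherits(kg, "kg"))
  keys <- normalize_surface(names(icd_table))
  tbl <- stats::setNames(as.character(icd_table), keys)
  e <- kg$entities
  e$icd <- NA_character_
  dis <- e$etype == "disease"
  hit <- tbl[e$surface[dis]]
  hit[is.na(hit)] <- "unmapped"
  e$icd[dis] <- unname(hit)
  kg$entities <- e
  kg
}
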