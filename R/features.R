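char_set <- function(x) unique(strsplit(x, "", fixed = FALSE)[[1]])

#' Character-set Jaccard similarity of two surface forms
#'
#' Ratio of shared unique characters to the union of unique characters:
#' `|A n B| / (|A| + |B| - |A n B|)`. Character multiplicity and order are
#' ignored, so the measure is duplication- and permutation-invariant.
#' For short clinical terms in a character-based writing system this is a
#' strong lexical-variation signal (e.g. two spellings of "headache"
#' sharing the head character).
#'
#' @param a,b Non-empty strings.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_chars <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("jaccard_chars: empty operand")
  sa <- char_set(a)
  sb <- char_set(b)
  inter <- sum(sa %in% sb)
  inter / (length(sa) + length(sb) - inter)
}

#' Jaccard similarity of two sets of strings, pooled over characters
#'
#' Each set of strings is flattened to the union of the characters of its
#' members; the Jaccard coefficient is then computed on the two pooled
#' character sets. Word order within the sets is immaterial. Used for
#' head-entity structural similarity over the tail surface forms of two
#' diseases. The empty-vs-empty case is defined as 0.
#'
#' @param A,B Character vectors (possibly empty).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_sets <- function(A, B) {
  ca <- unique(unlist(strsplit(A, ""), use.names = FALSE))
  cb <- unique(unlist(strsplit(B, ""), use.names = FALSE))
  if (length(ca) == 0 && length(cb) == 0) return(0)
  inter <- sum(ca %in% cb)
  uni <- length(ca) + length(cb) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Default semantic scorer: character-bigram cosine
#'
#' Returns a scorer function mapping a pair of strings to `[0, 1]`: the
#' cosine of their character-bigram count vectors (a string shorter than
#' two characters falls back to unigrams). Deterministic, symmetric, and
#' `score(x, x) == 1`, so it satisfies the scorer contract. Any function
#' with those properties can replace it -- e.g. an adapter around a
#' fine-tuned transformer sentence encoder; no neural weights are shipped.
#'
#' @return A function `(a, b) -> numeric in [0, 1]`.
#' @export
bigram_scorer <- function() {
  grams <- function(x) {
    n <- nchar(x)
    if (n < 2) return(x)
    substring(x, 1:(n - 1), 2:n)
  }
  function(a, b) {
    ga <- grams(a)
    gb <- grams(b)
    ta <- table(ga)
    tb <- table(gb)
    common <- intersect(names(ta), names(tb))
    if (length(common) == 0) return(0)
    num <- sum(as.numeric(ta[common]) * as.numeric(tb[common]))
    num / (sqrt(sum(as.numeric(ta)^2)) * sqrt(sum(as.numeric(tb)^2)))
  }
}

#' Semantic similarity of two surfaces under a pluggable scorer
#'
#' @param a,b Strings.
#' @param scorer A scorer function as returned by [bigram_scorer()].
#' @return Score in `[0, 1]`.
#' @export
semantic_score <- function(a, b, scorer = bigram_scorer()) {
  out <- tryCatch(scorer(a, b), error = function(e) {
    stop("semantic scorer failed on (", a, ", ", b, "): ",
         conditionMessage(e), call. = FALSE)
  })
  as.numeric(out)
}

#' Number of identical canonical tail nodes of two head entities
#'
#' Counts canonical (post-tail-fusion) tail ids adjacent to `h1` in `kg1`
#' and to `h2` in `kg2` over the `rel_*` (non-attribute) relations. This is
#' the structural "same tail nodes" count used for head fusion, which is
#' why tail fusion must run first: without canonical ids, cross-source
#' tails never compare equal.
#'
#' @param h1,h2 Head entity ids.
#' @param kg1,kg2 The graphs containing them.
#' @param merges Tail-stage [merge_map()] (may be empty).
#' @return Non-negative integer.
#' @export
same_tail_count <- function(h1, h2, kg1, kg2, merges = merge_map()) {
  if (!(h1 %in% kg1$entities$id)) stop("unknown head id: ", h1)
  if (!(h2 %in% kg2$entities$id)) stop("unknown head id: ", h2)
  t1 <- rel_tails(kg1, h1)
  t2 <- rel_tails(kg2, h2)
  length(intersect(unique(mm_lookup(merges, t1)),
                   unique(mm_lookup(merges, t2))))
}

rel_tails <- function(kg, head) {
  sch <- kg_schema()
  rels <- sch$label[!sch$is_attribute]
  tr <- kg$triples
  tr$tail_id[tr$head_id == head & tr$relation %in% rels]
}

#' Tail-pair feature matrix
#'
#' For each candidate pair computes the three tail-fusion features:
#' `semantic` (pluggable scorer, default bigram cosine), `transr_cos`
#' (cosine of the two entities' embedding vectors) and `jaccard`
#' (character-set Jaccard of the surfaces). Pairs whose entities are
#' absent from the embedding vocabulary get `transr_cos = 0` and
#' `cos_missing = TRUE` (cosine-neutral imputation); the features are
#' never `NA`.
#'
#' @param pairs Data frame with columns `left_id`, `left_surface`,
#'   `right_id`, `right_surface` (as produced by [candidate_pairs()]).
#' @param emb A [train_embedding()] result, or `NULL` to impute all
#'   cosines.
#' @param scorer Semantic scorer function.
#' @return `pairs` with columns `semantic`, `transr_cos`, `jaccard`,
#'   `cos_missing` appended.
#' @export
tail_features <- function(pairs, emb = NULL, scorer = bigram_scorer()) {
  n <- nrow(pairs)
  sem <- numeric(n)
  jac <- numeric(n)
  for (i in seq_len(n)) {
    sem[i] <- semantic_score(pairs$left_surface[i], pairs$right_surface[i], scorer)
    jac[i] <- jaccard_chars(pairs$left_surface[i], pairs$right_surface[i])
  }
  cosv <- rep(0, n)
  miss <- rep(TRUE, n)
  if (!is.null(emb)) {
    have <- pairs$left_id %in% rownames(emb$E) & pairs$right_id %in% rownames(emb$E)
    if (any(have)) {
      cosv[have] <- embedding_cosine(emb, pairs$left_id[have], pairs$right_id[have])
      miss[have] <- FALSE
    }
  }
  pairs$semantic <- sem
  pairs$transr_cos <- cosv
  pairs$jaccard <- jac
  pairs$cos_missing <- miss
  pairs
}

#' Head-pair (structural) feature matrix
#'
#' For each disease pair computes `same_tails` (count of identical
#' canonical tail nodes, raw and unnormalized), `set_jaccard` (Jaccard of
#' the pooled characters of the two tail-surface sets) and `transr_cos`
#' (embedding cosine of the two heads, imputed 0 with `cos_missing` when
#' unavailable).
#'
#' @param pairs Data frame with columns `left_id`, `right_id`.
#' @param kg_a,kg_b Source graphs for the left/right entities.
#' @param tail_merges Tail-stage merge map (canonicalizes tails).
#' @param emb Embedding or `NULL`.
#' @return `pairs` with feature columns appended.
#' @export
head_features <- function(pairs, kg_a, kg_b, tail_merges = merge_map(),
                          emb = NULL) {
  surf_a <- stats::setNames(kg_a$entities$surface, kg_a$entities$id)
  surf_b <- stats::setNames(kg_b$entities$surface, kg_b$entities$id)
  n <- nrow(pairs)
  st <- integer(n)
  sj <- numeric(n)
  for (i in seq_len(n)) {
    t1 <- rel_tails(kg_a, pairs$left_id[i])
    t2 <- rel_tails(kg_b, pairs$right_id[i])
    st[i] <- length(intersect(unique(mm_lookup(tail_merges, t1)),
                              unique(mm_lookup(tail_merges, t2))))
    sj[i] <- jaccard_sets(unname(surf_a[t1]), unname(surf_b[t2]))
  }
  cosv <- rep(0, n)
  miss <- rep(TRUE, n)
  if (!is.null(emb)) {
    have <- pairs$left_id %in% rownames(emb$E) & pairs$right_id %in% rownames(emb$E)
    if (any(have)) {
      cosv[have] <- embedding_cosine(emb, pairs$left_id[have], pairs$right_id[have])
      miss[have] <- FALSE
    }
  }
  pairs$same_tails <- st
  pairs$set_jaccard <- sj
  pairs$transr_cos <- cosv
  pairs$cos_missing <- miss
  pairs
}

#' Write a feature matrix as TSV for audit
#' @param feats Feature data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feats, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(feats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
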