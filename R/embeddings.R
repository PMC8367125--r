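#' Configuration for translational knowledge-graph embeddings
#'
#' Hyperparameters for TransE/TransH/TransR training. Defaults follow the
#' conventions of the original translational-embedding literature:
#' embedding dimension 50, margin 1, learning rate 0.01, 500 epochs,
#' one corrupted triple per positive, batches of 128, uniform
#' initialization in `[-6/sqrt(dim), 6/sqrt(dim)]`.
#'
#' @param model One of `"transR"`, `"transE"`, `"transH"`.
#' @param dim Embedding dimension (>= 1).
#' @param margin Ranking-loss margin (> 0).
#' @param learning_rate SGD step size (> 0).
#' @param epochs Number of passes over the triples.
#' @param neg_per_pos Corrupted triples sampled per positive.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed; training is bit-reproducible given the seed.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(model = c("transR", "transE", "transH"),
                             dim = 50L, margin = 1, learning_rate = 0.01,
                             epochs = 500L, neg_per_pos = 1L,
                             batch_size = 128L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(dim >= 1, margin > 0, learning_rate > 0, epochs >= 0,
            neg_per_pos >= 1, batch_size >= 1)
  structure(list(
    model = model, dim = as.integer(dim), margin = margin,
    learning_rate = learning_rate, epochs = as.integer(epochs),
    neg_per_pos = as.integer(neg_per_pos),
    batch_size = as.integer(batch_size), seed = as.integer(seed)
  ), class = "embedding_config")
}

#' Train translational embeddings on a knowledge graph
#'
#' Minimizes the margin ranking loss
#' `sum(max(0, margin + f(h,r,t) - f(h',r,t')))` by mini-batch stochastic
#' gradient descent, where `f` is the model's translation distance
#' (TransE: `|h + r - t|`; TransH: projection onto the relation
#' hyperplane; TransR: `|h M_r + r - t M_r|` with a relation-specific
#' projection matrix `M_r`). Gradients are taken on the squared distance;
#' reported scores are the plain Euclidean norm. Negative triples corrupt
#' the head or the tail (equal probability) with a uniformly drawn entity
#' of the slot's schema type -- cross-type corruptions would be trivially
#' negative. Entity vectors are projected to the unit ball after every
#' batch. TransR projection matrices start at the identity, so at
#' initialization TransR scores coincide with TransE.
#'
#' @param kg A `kg` object with at least one triple.
#' @param config An [embedding_config()].
#' @return A `kg_embedding`: entity matrix `E` (rows named by id),
#'   relation matrix `R`, projections `P` (per-relation `dim x dim`
#'   matrix for TransR, unit normal vector for TransH), `entities`
#'   metadata, `loss` per-epoch training loss, and `config`.
#' @export
train_embedding <- function(kg, config = embedding_config()) {
  stopifnot(inherits(kg, "kg"))
  tr <- kg$triples
  if (nrow(tr) == 0) stop("cannot train embeddings on an empty graph")
  ents <- kg$entities[order(kg$entities$id), c("id", "etype")]
  rels <- sort(unique(tr$relation))
  d <- config$dim
  n <- nrow(ents)
  sch <- kg_schema()
  head_type <- stats::setNames(sch$head_type, sch$label)
  tail_type <- stats::setNames(sch$tail_type, sch$label)
  by_type <- split(seq_len(n), ents$etype)

  hi <- match(tr$head_id, ents$id)
  ti <- match(tr$tail_id, ents$id)
  ri <- match(tr$relation, rels)
  nt <- nrow(tr)

  # per-relation corruption pools (indices into the entity table)
  pool_h <- lapply(rels, function(r) by_type[[head_type[[r]]]])
  pool_t <- lapply(rels, function(r) by_type[[tail_type[[r]]]])
  for (j in seq_along(rels)) {
    hs <- length(pool_h[[j]]) < 2
    ts <- length(pool_t[[j]]) < 2
    if (hs && ts) {
      warning("relation ", sQuote(rels[j]),
              ": no alternative entities to corrupt; skipping negatives")
    } else if (hs || ts) {
      warning("relation ", sQuote(rels[j]), ": single entity on the ",
              if (hs) "head" else "tail",
              " side; corrupting only the other slot")
    }
  }

  withr::with_seed(config$seed, {
    b <- 6 / sqrt(d)
    E <- matrix(stats::runif(n * d, -b, b), n, d, dimnames = list(ents$id, NULL))
    R <- matrix(stats::runif(length(rels) * d, -b, b), length(rels), d,
                dimnames = list(rels, NULL))
    R <- R / pmax(sqrt(rowSums(R^2)), 1e-12)
    P <- switch(config$model,
      transR = stats::setNames(lapply(rels, function(r) diag(d)), rels),
      transH = {
        W <- matrix(stats::runif(length(rels) * d, -b, b), length(rels), d,
                    dimnames = list(rels, NULL))
        W / pmax(sqrt(rowSums(W^2)), 1e-12)
      },
      transE = NULL
    )
    E <- unit_ball(E)
    lr <- config$learning_rate
    loss_hist <- numeric(config$epochs)

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nt)
      ep_loss <- 0
      for (start in seq(1, nt, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, nt)]
        idx <- rep(idx, config$neg_per_pos)
        # corrupt head or tail with equal probability, within schema type
        corrupt_head <- stats::runif(length(idx)) < 0.5
        hn <- hi[idx]; tn <- ti[idx]
        for (j in unique(ri[idx])) {
          sel <- which(ri[idx] == j)
          ch <- sel[corrupt_head[sel]]
          ct <- sel[!corrupt_head[sel]]
          if (length(pool_h[[j]]) < 2) { ct <- c(ct, ch); ch <- integer(0) }
          if (length(pool_t[[j]]) < 2) { ch <- c(ch, ct); ct <- integer(0) }
          if (length(ch) > 0) hn[ch] <- draw_distinct(pool_h[[j]], hi[idx][ch])
          if (length(ct) > 0) tn[ct] <- draw_distinct(pool_t[[j]], ti[idx][ct])
        }
        real_neg <- hn != hi[idx] | tn != ti[idx]
        upd <- sgd_batch(E, R, P, config$model,
                         hi[idx][real_neg], ti[idx][real_neg], ri[idx][real_neg],
                         hn[real_neg], tn[real_neg], config$margin, lr)
        E <- upd$E; R <- upd$R; P <- upd$P
        ep_loss <- ep_loss + upd$loss
        touched <- unique(c(hi[idx], ti[idx], hn, tn))
        E[touched, ] <- unit_ball(E[touched, , drop = FALSE])
      }
      loss_hist[ep] <- ep_loss
    }
    structure(list(
      E = E, R = R, P = P, entities = ents, config = config,
      loss = loss_hist
    ), class = "kg_embedding")
  })
}

# scale rows with L2 norm > 1 back onto the unit sphere
unit_ball <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  over <- nrm > 1
  if (any(over)) M[over, ] <- M[over, , drop = FALSE] / nrm[over]
  M
}

# uniform draw from pool avoiding the original entity (pool size >= 2)
draw_distinct <- function(pool, orig) {
  out <- pool[sample.int(length(pool), length(orig), replace = TRUE)]
  while (any(bad <- out == orig)) {
    out[bad] <- pool[sample.int(length(pool), sum(bad), replace = TRUE)]
  }
  out
}

# one SGD step on a batch of (positive, negative) triple pairs
sgd_batch <- function(E, R, P, model, hp, tp, rr, hn, tn, margin, lr) {
  if (length(hp) == 0) return(list(E = E, R = R, P = P, loss = 0))
  d <- ncol(E)
  loss <- 0
  dE <- NULL; rows <- NULL  # accumulated entity-gradient rows
  add_grad <- function(ix, G) {
    rows <<- c(rows, ix)
    dE <<- rbind(dE, G)
  }
  for (j in unique(rr)) {
    sel <- which(rr == j)
    rl <- rownames(R)[j]
    Hp <- E[hp[sel], , drop = FALSE]; Tp <- E[tp[sel], , drop = FALSE]
    Hn <- E[hn[sel], , drop = FALSE]; Tn <- E[tn[sel], , drop = FALSE]
    rv <- R[j, ]
    if (model == "transE") {
      dp <- sweep(Hp - Tp, 2, rv, "+")
      dn <- sweep(Hn - Tn, 2, rv, "+")
    } else if (model == "transR") {
      M <- P[[rl]]
      dp <- sweep((Hp - Tp) %*% M, 2, rv, "+")
      dn <- sweep((Hn - Tn) %*% M, 2, rv, "+")
    } else { # transH
      w <- P[j, ]
      proj <- function(X) X - outer(drop(X %*% w), w)
      dp <- sweep(proj(Hp) - proj(Tp), 2, rv, "+")
      dn <- sweep(proj(Hn) - proj(Tn), 2, rv, "+")
    }
    fp <- rowSums(dp^2)
    fn <- rowSums(dn^2)
    act <- which(margin + fp - fn > 0)
    loss <- loss + sum(margin + fp[act] - fn[act])
    if (length(act) == 0) next
    dp <- dp[act, , drop = FALSE]; dn <- dn[act, , drop = FALSE]
    s <- sel[act]
    if (model == "transE") {
      add_grad(hp[s], 2 * dp); add_grad(tp[s], -2 * dp)
      add_grad(hn[s], -2 * dn); add_grad(tn[s], 2 * dn)
      R[j, ] <- R[j, ] - lr * colSums(2 * dp - 2 * dn)
    } else if (model == "transR") {
      M <- P[[rl]]
      Mt <- t(M)
      add_grad(hp[s], 2 * dp %*% Mt); add_grad(tp[s], -2 * dp %*% Mt)
      add_grad(hn[s], -2 * dn %*% Mt); add_grad(tn[s], 2 * dn %*% Mt)
      R[j, ] <- R[j, ] - lr * colSums(2 * dp - 2 * dn)
      gM <- 2 * (t(E[hp[s], , drop = FALSE] - E[tp[s], , drop = FALSE]) %*% dp) -
            2 * (t(E[hn[s], , drop = FALSE] - E[tn[s], , drop = FALSE]) %*% dn)
      P[[rl]] <- M - lr * gM
    } else { # transH
      w <- P[j, ]
      gproj <- function(D) D - outer(drop(D %*% w), w)
      add_grad(hp[s], 2 * gproj(dp)); add_grad(tp[s], -2 * gproj(dp))
      add_grad(hn[s], -2 * gproj(dn)); add_grad(tn[s], 2 * gproj(dn))
      R[j, ] <- R[j, ] - lr * colSums(2 * dp - 2 * dn)
      Xp <- E[hp[s], , drop = FALSE] - E[tp[s], , drop = FALSE]
      Xn <- E[hn[s], , drop = FALSE] - E[tn[s], , drop = FALSE]
      gw <- -2 * (colSums(drop(dp %*% w) * Xp) + colSums(drop(Xp %*% w) * dp)) +
             2 * (colSums(drop(dn %*% w) * Xn) + colSums(drop(Xn %*% w) * dn))
      w <- w - lr * gw
      P[j, ] <- w / max(sqrt(sum(w^2)), 1e-12)
    }
  }
  if (!is.null(rows)) {
    G <- rowsum(dE, group = rows)
    ix <- as.integer(rownames(G))
    E[ix, ] <- E[ix, ] - lr * G
  }
  list(E = E, R = R, P = P, loss = loss)
}

# translation distance for entity-index vectors under one relation
score_rows <- function(emb, hix, rlab, tix) {
  Hp <- emb$E[hix, , drop = FALSE]
  Tp <- emb$E[tix, , drop = FALSE]
  rv <- emb$R[rlab, ]
  m <- emb$config$model
  if (m == "transR") {
    M <- emb$P[[rlab]]
    Hp <- Hp %*% M; Tp <- Tp %*% M
  } else if (m == "transH") {
    w <- emb$P[rlab, ]
    Hp <- Hp - outer(drop(Hp %*% w), w)
    Tp <- Tp - outer(drop(Tp %*% w), w)
  }
  sqrt(rowSums(sweep(Hp - Tp, 2, rv, "+")^2))
}

#' Translation distance of one triple
#'
#' Returns `f(h, r, t)` under the embedding's model: the Euclidean norm of
#' the (projected) head plus relation minus (projected) tail. Lower is
#' more plausible.
#'
#' @param emb A `kg_embedding`.
#' @param h,t Entity ids.
#' @param r Relation label.
#' @return Non-negative score.
#' @export
score_triple <- function(emb, h, r, t) {
  hix <- match(h, rownames(emb$E))
  tix <- match(t, rownames(emb$E))
  if (is.na(hix)) stop("unknown entity id: ", h)
  if (is.na(tix)) stop("unknown entity id: ", t)
  if (!(r %in% rownames(emb$R))) stop("unknown relation: ", r)
  unname(score_rows(emb, hix, r, tix))
}

#' Cosine similarity of two embedded entities
#'
#' @param emb A `kg_embedding`.
#' @param a,b Entity ids (vectorized; recycled to equal length).
#' @return Cosine similarity in `[-1, 1]`.
#' @export
embedding_cosine <- function(emb, a, b) {
  ai <- match(a, rownames(emb$E))
  bi <- match(b, rownames(emb$E))
  if (anyNA(ai)) stop("unknown entity id: ", a[which(is.na(ai))[1]])
  if (anyNA(bi)) stop("unknown entity id: ", b[which(is.na(bi))[1]])
  A <- emb$E[ai, , drop = FALSE]
  B <- emb$E[bi, , drop = FALSE]
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop("cannot take cosine of a zero vector")
  unname(rowSums(A * B) / (na * nb))
}

#' hits@k link-prediction accuracy
#'
#' For each test triple, all embedded entities of the relation's tail type
#' are ranked by ascending translation distance `f(h, r, .)` (raw ranking,
#' no filtering of other true tails); ties are broken by entity id so the
#' measure is deterministic. Returns the fraction of test triples whose
#' true tail ranks within the top `k`.
#'
#' @param emb A `kg_embedding`.
#' @param test_triples Data frame with columns `head_id`, `relation`,
#'   `tail_id`.
#' @param k Positive integer cut-off.
#' @return Fraction in `[0, 1]`.
#' @export
hits_at_k <- function(emb, test_triples, k) {
  if (length(k) != 1 || is.na(k) || k < 1) stop("k must be a positive integer")
  tt <- as.data.frame(test_triples, stringsAsFactors = FALSE)
  if (nrow(tt) == 0) stop("no test triples")
  sch <- kg_schema()
  tail_type <- stats::setNames(sch$tail_type, sch$label)
  hits <- 0L
  for (rl in unique(tt$relation)) {
    sub <- tt[tt$relation == rl, , drop = FALSE]
    cand <- emb$entities$id[emb$entities$etype == tail_type[[rl]]]
    cand <- sort(cand)
    cix <- match(cand, rownames(emb$E))
    hix <- match(sub$head_id, rownames(emb$E))
    if (anyNA(hix) || anyNA(cix)) stop("test entities missing from embedding")
    # pairwise distances head x candidate via the expanded square
    Hp <- emb$E[hix, , drop = FALSE]
    Tc <- emb$E[cix, , drop = FALSE]
    m <- emb$config$model
    rv <- emb$R[rl, ]
    if (m == "transR") {
      M <- emb$P[[rl]]
      Hp <- Hp %*% M; Tc <- Tc %*% M
    } else if (m == "transH") {
      w <- emb$P[rl, ]
      Hp <- Hp - outer(drop(Hp %*% w), w)
      Tc <- Tc - outer(drop(Tc %*% w), w)
    }
    Hs <- sweep(Hp, 2, rv, "+")
    D2 <- outer(rowSums(Hs^2), rowSums(Tc^2), "+") - 2 * Hs %*% t(Tc)
    for (i in seq_len(nrow(sub))) {
      ci <- match(sub$tail_id[i], cand)
      if (is.na(ci)) stop("true tail not among candidates: ", sub$tail_id[i])
      s <- D2[i, ]
      rank <- sum(s < s[ci]) + sum(s == s[ci] & cand < cand[ci]) + 1L
      if (rank <= k) hits <- hits + 1L
    }
  }
  hits / nrow(tt)
}

#' Persist / reload an embedding as plain text
#'
#' Writes `entities.tsv` (id, type, vector), `relations.tsv`,
#' `projections.tsv` (flattened per-relation projection parameters) and
#' `manifest.json` (model, dim, seed) into a directory.
#'
#' @param emb A `kg_embedding`.
#' @param dir Output directory.
#' @return `dir` (save) or a `kg_embedding` (load).
#' @export
save_embedding <- function(emb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(M) apply(M, 1, function(v) paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(emb$entities$id, emb$entities$etype, fmt(emb$E), sep = "\t"),
             file.path(dir, "entities.tsv"), useBytes = TRUE)
  writeLines(paste(rownames(emb$R), fmt(emb$R), sep = "\t"),
             file.path(dir, "relations.tsv"), useBytes = TRUE)
  pl <- if (emb$config$model == "transR") {
    vapply(rownames(emb$R), function(r) {
      paste(sprintf("%.17g", as.numeric(emb$P[[r]])), collapse = "\t")
    }, character(1))
  } else if (emb$config$model == "transH") {
    vapply(rownames(emb$R), function(r) {
      paste(sprintf("%.17g", emb$P[r, ]), collapse = "\t")
    }, character(1))
  } else character(0)
  if (length(pl)) {
    writeLines(paste(rownames(emb$R), pl, sep = "\t"),
               file.path(dir, "projections.tsv"), useBytes = TRUE)
  }
  jsonlite::write_json(
    list(model = emb$config$model, dim = emb$config$dim,
         seed = emb$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  d <- as.integer(man$dim)
  et <- utils::read.delim(file.path(dir, "entities.tsv"), header = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  E <- as.matrix(apply(et[, -(1:2), drop = FALSE], 2, as.numeric))
  if (is.null(dim(E))) E <- matrix(E, nrow = nrow(et))
  rownames(E) <- et[[1]]
  rt <- utils::read.delim(file.path(dir, "relations.tsv"), header = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  R <- as.matrix(apply(rt[, -1, drop = FALSE], 2, as.numeric))
  if (is.null(dim(R))) R <- matrix(R, nrow = nrow(rt))
  rownames(R) <- rt[[1]]
  P <- NULL
  pj <- file.path(dir, "projections.tsv")
  if (file.exists(pj)) {
    pt <- utils::read.delim(pj, header = FALSE, colClasses = "character",
                            encoding = "UTF-8")
    if (man$model == "transR") {
      P <- stats::setNames(lapply(seq_len(nrow(pt)), function(i) {
        matrix(as.numeric(pt[i, -1]), d, d)
      }), pt[[1]])
    } else {
      P <- as.matrix(apply(pt[, -1, drop = FALSE], 2, as.numeric))
      if (is.null(dim(P))) P <- matrix(P, nrow = nrow(pt))
      rownames(P) <- pt[[1]]
    }
  }
  structure(list(
    E = E, R = R, P = P,
    entities = data.frame(id = et[[1]], etype = et[[2]], stringsAsFactors = FALSE),
    config = embedding_config(model = man$model, dim = d, seed = as.integer(man$seed)),
    loss = numeric(0)
  ), class = "kg_embedding")
}
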