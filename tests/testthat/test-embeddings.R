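test_that("score_triple handles exact-arithmetic cases", {
  # perfect translation: h == t, r = 0, identity projection -> 0
  E <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("emr|disease|a", "emr|symptom|b"), NULL))
  R <- matrix(0, 1, 2, dimnames = list("Diseases_rel_Symptom", NULL))
  emb <- manual_embedding(E, R, P = list("Diseases_rel_Symptom" = diag(2)),
                          model = "transR")
  expect_equal(score_triple(emb, "emr|disease|a", "Diseases_rel_Symptom",
                            "emr|symptom|b"), 0)
  # transE with h=(1,0), r=(0,1), t=(1,1) -> 0
  E2 <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("emr|disease|a", "emr|symptom|b"), NULL))
  R2 <- matrix(c(0, 1), 1, 2, dimnames = list("Diseases_rel_Symptom", NULL))
  emb2 <- manual_embedding(E2, R2, model = "transE")
  expect_equal(score_triple(emb2, "emr|disease|a", "Diseases_rel_Symptom",
                            "emr|symptom|b"), 0)
  expect_error(score_triple(emb2, "nope", "Diseases_rel_Symptom",
                            "emr|symptom|b"), "unknown entity")
})

test_that("scores match a naive-loop oracle for all three models", {
  withr::with_seed(5, {
    for (model in c("transE", "transH", "transR")) {
      for (rep in 1:20) {
        d <- sample(2:6, 1)
        h <- runif(d, -1, 1); t <- runif(d, -1, 1); r <- runif(d, -1, 1)
        M <- matrix(runif(d * d, -1, 1), d, d)
        w <- runif(d, -1, 1); w <- w / sqrt(sum(w^2))
        E <- rbind(h, t)
        rownames(E) <- c("emr|disease|h", "emr|symptom|t")
        R <- matrix(r, 1, d, dimnames = list("Diseases_rel_Symptom", NULL))
        P <- switch(model,
          transR = list("Diseases_rel_Symptom" = M),
          transH = matrix(w, 1, d, dimnames = list("Diseases_rel_Symptom", NULL)),
          transE = NULL)
        emb <- manual_embedding(E, R, P, model = model)
        got <- score_triple(emb, "emr|disease|h", "Diseases_rel_Symptom",
                            "emr|symptom|t")
        want <- naive_score(model, h, r, t, M = M, w = w)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("TransR with identity projections reproduces TransE exactly", {
  withr::with_seed(8, {
    d <- 5
    E <- matrix(runif(10 * d, -1, 1), 10, d,
                dimnames = list(paste0("emr|symptom|s", 1:10), NULL))
    rownames(E)[1:3] <- paste0("emr|disease|d", 1:3)
    R <- matrix(runif(d, -1, 1), 1, d, dimnames = list("Diseases_rel_Symptom", NULL))
    eR <- manual_embedding(E, R, P = list("Diseases_rel_Symptom" = diag(d)),
                           model = "transR")
    eE <- manual_embedding(E, R, model = "transE")
    for (i in 1:3) {
      for (j in 4:10) {
        expect_identical(
          score_triple(eR, rownames(E)[i], "Diseases_rel_Symptom", rownames(E)[j]),
          score_triple(eE, rownames(E)[i], "Diseases_rel_Symptom", rownames(E)[j])
        )
      }
    }
  })
})

test_that("epochs = 0 returns the seeded initialization, reproducibly", {
  kg <- random_kg(3, n_diseases = 3, sources = "emr")
  cfg <- embedding_config("transE", dim = 6, epochs = 0, seed = 99)
  a <- suppressWarnings(train_embedding(kg, cfg))
  b <- suppressWarnings(train_embedding(kg, cfg))
  expect_identical(a$E, b$E)
  expect_identical(a$R, b$R)
  expect_true(all(sqrt(rowSums(a$E^2)) <= 1 + 1e-12))
})

test_that("training is bit-reproducible and separates a trivial triple", {
  # one triple plus a spare disease so head corruption is possible
  df <- data.frame(
    head_surface = c("病甲", "病乙"), head_type = "disease",
    relation = "Diseases_rel_Symptom",
    tail_surface = c("症一", "症一"), tail_type = "symptom",
    source = "emr", stringsAsFactors = FALSE
  )
  kg <- kg_from_records(df[1, , drop = FALSE])
  spare <- kg_from_records(df)   # graph with the corrupting entity
  kg1 <- kg_new(spare$entities, kg$triples)
  cfg <- embedding_config("transE", dim = 8, epochs = 200, seed = 4)
  # a single symptom makes tail corruption impossible: warned, head-only
  expect_warning(emb <- train_embedding(kg1, cfg), "single entity")
  emb2 <- suppressWarnings(train_embedding(kg1, cfg))
  expect_identical(emb$E, emb2$E)
  pos <- score_triple(emb, "emr|disease|病甲", "Diseases_rel_Symptom",
                      "emr|symptom|症一")
  neg <- score_triple(emb, "emr|disease|病乙", "Diseases_rel_Symptom",
                      "emr|symptom|症一")
  expect_lt(pos, neg)
})

test_that("held-out positives score below false corrupted triples", {
  # two-view benchmark; hold out symptom edges, compare their scores with
  # corrupted triples whose tail is not a true tail of the head
  b <- generate_benchmark(generator_config(seed = 7, n_diseases = 30))
  un <- kg_union(b$view_emr, b$view_web)
  sym_tr <- which(un$triples$relation == "Diseases_rel_Symptom")
  syms <- un$entities$id[un$entities$etype == "symptom"]
  wins <- 0
  nrun <- 10
  for (s in seq_len(nrun)) {
    withr::with_seed(200 + s, {
      held <- sample(sym_tr, 40)
      tr_kg <- kg_new(un$entities, un$triples[-held, ])
      emb <- train_embedding(tr_kg, embedding_config("transE", dim = 16,
        epochs = 60, learning_rate = 0.02, margin = 2, seed = s))
      ho <- un$triples[held, ]
      pos <- numeric(0)
      neg <- numeric(0)
      for (i in seq_len(nrow(ho))) {
        h <- ho$head_id[i]
        true_tails <- un$triples$tail_id[un$triples$head_id == h]
        ft <- sample(setdiff(syms, true_tails), 5)
        pos <- c(pos, score_triple(emb, h, ho$relation[i], ho$tail_id[i]))
        neg <- c(neg, vapply(ft, function(t2) {
          score_triple(emb, h, ho$relation[i], t2)
        }, numeric(1)))
      }
      if (mean(pos) < mean(neg)) wins <- wins + 1
    })
  }
  expect_gte(wins, nrun - 1)
})

test_that("cosine similarity behaves and rejects zero vectors", {
  E <- matrix(c(1, 0, 0, 2, 1, 1, 0, 0), 4, 2, byrow = TRUE,
              dimnames = list(paste0("emr|symptom|s", 1:4), NULL))
  emb <- manual_embedding(E, matrix(0, 1, 2, dimnames = list("Diseases_rel_Symptom", NULL)))
  expect_equal(embedding_cosine(emb, "emr|symptom|s1", "emr|symptom|s1"), 1.0)
  expect_equal(embedding_cosine(emb, "emr|symptom|s1", "emr|symptom|s2"), 0.0)
  expect_error(embedding_cosine(emb, "emr|symptom|s1", "emr|symptom|s4"),
               "zero vector")
})

test_that("an entity cloned with identical neighbourhood embeds nearby", {
  base <- random_kg(31, n_diseases = 6, sources = "emr")
  dis <- base$entities$id[base$entities$etype == "disease"]
  target <- dis[1]
  clone_tr <- base$triples[base$triples$head_id == target, ]
  wins <- 0
  nrun <- 10
  for (s in seq_len(nrun)) {
    clone_id <- "web|disease|clone"
    ents <- rbind(base$entities,
                  data.frame(id = clone_id, surface = "clone",
                             etype = "disease", source = "web"))
    tr <- clone_tr
    tr$head_id <- clone_id
    tr$source <- "web"
    kg <- kg_new(ents, rbind(base$triples, tr))
    emb <- suppressWarnings(train_embedding(kg, embedding_config(
      "transE", dim = 12, epochs = 60, seed = s)))
    cos_pair <- embedding_cosine(emb, target, clone_id)
    withr::with_seed(s, {
      others <- setdiff(dis, target)
      rnd <- vapply(seq_len(20), function(i) {
        p <- sample(dis, 2)
        embedding_cosine(emb, p[1], p[2])
      }, numeric(1))
    })
    if (cos_pair > stats::median(rnd)) wins <- wins + 1
  }
  expect_gte(wins, round(0.9 * nrun))
})

test_that("hits@k: ceiling, monotonicity and determinism of ties", {
  kg <- random_kg(17, n_diseases = 4, sources = "emr")
  emb <- suppressWarnings(train_embedding(kg, embedding_config(
    "transE", dim = 6, epochs = 5, seed = 2)))
  tt <- kg$triples[kg$triples$relation == "Diseases_rel_Symptom", ]
  n_cand <- sum(kg$entities$etype == "symptom")
  expect_equal(hits_at_k(emb, tt, n_cand), 1.0)
  hs <- vapply(1:n_cand, function(k) hits_at_k(emb, tt, k), numeric(1))
  expect_true(all(diff(hs) >= 0))
  expect_error(hits_at_k(emb, tt, 0), "positive")
})

test_that("per-epoch loss trends downward, tolerating SGD noise", {
  # resampled negatives make raw epoch losses noisy; the trend test asks
  # that no epoch rises above the recent 5-epoch envelope and that the
  # final loss is a small fraction of the initial one
  b <- generate_benchmark(generator_config())
  un <- kg_union(b$view_emr, b$view_web)
  emb <- train_embedding(un, embedding_config("transR", dim = 16, epochs = 30,
                                              seed = 3))
  l <- emb$loss
  within_env <- vapply(6:length(l), function(t) {
    l[t] <= max(l[(t - 5):(t - 1)])
  }, logical(1))
  expect_gte(mean(within_env), 0.9)
  expect_lt(l[length(l)], 0.5 * l[1])
})

test_that("embeddings persist and reload with identical scores", {
  kg <- random_kg(23, n_diseases = 3, sources = "emr")
  for (model in c("transE", "transH", "transR")) {
    emb <- suppressWarnings(train_embedding(kg, embedding_config(
      model, dim = 5, epochs = 10, seed = 6)))
    dir <- withr::local_tempdir()
    save_embedding(emb, dir)
    back <- load_embedding(dir)
    tr <- kg$triples[1:5, ]
    for (i in seq_len(nrow(tr))) {
      expect_equal(
        score_triple(back, tr$head_id[i], tr$relation[i], tr$tail_id[i]),
        score_triple(emb, tr$head_id[i], tr$relation[i], tr$tail_id[i]),
        tolerance = 1e-12
      )
    }
  }
})
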