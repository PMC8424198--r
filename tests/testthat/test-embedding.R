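test_that("transition model normalizes similarity rows without self-loops", {
  S <- rbind(c(1, 0.2, 0.6, 0.2),
             c(0.2, 1, 0.25, 0.75),
             c(0.6, 0.25, 1, 0.15),
             c(0.2, 0.75, 0.15, 1))
  P <- transition_matrix(S)
  expect_equal(unname(diag(P)), rep(0, 4))
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(P[1, -1]), c(0.2, 0.6, 0.2))   # already normalized
  S2 <- rbind(c(1, 1, 3), c(1, 1, 0.5), c(3, 0.5, 1))
  expect_equal(unname(transition_matrix(S2)[1, -1]), c(0.25, 0.75))
  S3 <- diag(3)
  expect_error(transition_matrix(S3), "isolated")
})

test_that("walks alternate deterministically on a forced two-node graph", {
  P <- rbind(c(0, 1), c(1, 0))
  rownames(P) <- colnames(P) <- c("a", "b")
  corpus <- sample_walks(P, walks_per_node = 2, walk_length = 20, seed = 4)
  expect_length(corpus$walks, 4)
  expect_true(all(lengths(corpus$walks) == 20))
  w <- corpus$walks[[1]]
  expect_identical(w, rep(c(1L, 2L), 10))
  starts <- vapply(corpus$walks, `[`, 0L, 1L)
  expect_identical(as.integer(table(starts)), c(2L, 2L))
})

test_that("walk sampling is reproducible and respects the transition support", {
  sim <- small_sim(seed = 1, n = 10)
  P <- transition_matrix(sim$fs)
  c1 <- sample_walks(P, 3, 10, seed = 42)
  c2 <- sample_walks(P, 3, 10, seed = 42)
  expect_identical(c1, c2)
  for (w in c1$walks) {
    steps <- cbind(w[-length(w)], w[-1])
    expect_true(all(P[steps] > 0))
  }
})

test_that("first-step frequencies match the transition probabilities", {
  set.seed(8)
  S <- matrix(runif(25, 0.05, 1), 5, 5); S <- (S + t(S)) / 2; diag(S) <- 1
  P <- transition_matrix(S)
  corpus <- sample_walks(P, walks_per_node = 600, walk_length = 2, seed = 99)
  firsts <- t(vapply(corpus$walks, function(w) w[1:2], integer(2)))
  for (v in 1:5) {
    nxt <- firsts[firsts[, 1] == v, 2]
    emp <- tabulate(nxt, 5) / length(nxt)
    se <- sqrt(P[v, ] * (1 - P[v, ]) / length(nxt))
    expect_true(all(abs(emp - P[v, ]) <= 3 * pmax(se, 1e-12)))
  }
})

test_that("walk corpora round-trip through the plain-text format", {
  sim <- small_sim(seed = 2, n = 8)
  P <- transition_matrix(sim$fs)
  corpus <- sample_walks(P, 2, 6, seed = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_walks(corpus, f)
  back <- read_walks(f)
  expect_identical(back$names, corpus$names)   # node names already sorted
  expect_identical(back$walks, corpus$walks)
})

test_that("embedding training returns finite vectors of the requested width", {
  sim <- small_sim(seed = 3, n = 10)
  P <- transition_matrix(sim$fs)
  corpus <- sample_walks(P, 5, 10, seed = 2)
  E <- embed_nodes(corpus, feature_size = 16, window = 3, epochs = 3, seed = 7)
  expect_identical(dim(E), c(10L, 16L))
  expect_identical(rownames(E), corpus$names)
  expect_true(all(is.finite(E)))
})

test_that("embedding training is deterministic given corpus and seed", {
  sim <- small_sim(seed = 3, n = 10)
  corpus <- sample_walks(transition_matrix(sim$fs), 5, 10, seed = 2)
  E1 <- embed_nodes(corpus, feature_size = 8, seed = 7)
  E2 <- embed_nodes(corpus, feature_size = 8, seed = 7)
  expect_identical(E1, E2)
  expect_false(identical(E1, embed_nodes(corpus, feature_size = 8, seed = 8)))
})

test_that("a node missing from the corpus is rejected", {
  corpus <- structure(list(walks = list(c(1L, 2L), c(2L, 1L)),
                           names = c("a", "b", "c"), walk_length = 2,
                           walks_per_node = 1, seed = 1),
                      class = "walk_corpus")
  expect_error(embed_nodes(corpus, feature_size = 4), "absent")
})

test_that("distributionally equivalent nodes embed closer than random pairs", {
  # nodes 1 and 2 are twins (same similarity profile); compare their mean
  # embedding cosine across seeds with that of a non-twin pair
  S <- rbind(c(1.0, 0.9, 0.6, 0.1, 0.1, 0.3),
             c(0.9, 1.0, 0.6, 0.1, 0.1, 0.3),
             c(0.6, 0.6, 1.0, 0.2, 0.5, 0.4),
             c(0.1, 0.1, 0.2, 1.0, 0.8, 0.2),
             c(0.1, 0.1, 0.5, 0.8, 1.0, 0.7),
             c(0.3, 0.3, 0.4, 0.2, 0.7, 1.0))
  P <- transition_matrix(S)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  twin <- rnd <- numeric(10)
  for (s in 1:10) {
    corpus <- sample_walks(P, 30, 10, seed = s)
    E <- embed_nodes(corpus, feature_size = 16, window = 3, epochs = 5,
                     seed = s)
    twin[s] <- cosine(E[1, ], E[2, ])
    rnd[s] <- cosine(E[1, ], E[4, ])
  }
  expect_gt(mean(twin), mean(rnd))
})

test_that("embeddings round-trip through the word2vec text format", {
  sim <- small_sim(seed = 4, n = 8)
  corpus <- sample_walks(transition_matrix(sim$fs), 3, 8, seed = 3)
  E <- embed_nodes(corpus, feature_size = 6, seed = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(E, f)
  expect_equal(read_embeddings(f), E, tolerance = 1e-15)
})

test_that("embeddings separate the planted blocks of the synthetic data", {
  sim <- simulate_mda(n_mirna = 30, n_disease = 30, seed = 6)
  ctl <- small_control()
  fl <- hgmda:::variant_flags("dw_raw_gat_fc")
  SS <- semantic_similarity(sim$dags)
  inputs <- hgmda:::build_feature_inputs(sim$assoc, SS, sim$fs, ctl, fl,
                                         seeds = c(11, 12))
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  for (side in list(list(E = inputs$X[1:30, ], b = sim$blocks$disease),
                    list(E = inputs$X[31:60, ], b = sim$blocks$mirna))) {
    within <- c(); between <- c()
    for (i in 1:29) for (j in (i + 1):30) {
      cs <- cosine(side$E[i, ], side$E[j, ])
      if (side$b[i] == side$b[j]) within <- c(within, cs)
      else between <- c(between, cs)
    }
    expect_gt(mean(within), mean(between))
  }
})
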