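chain_dag <- function(n, prefix = "N") {
  # N1 -> N2 -> ... -> Nn, the disease's own term is the deepest node
  nodes <- paste0(prefix, seq_len(n))
  edges <- if (n > 1) cbind(nodes[-n], nodes[-1]) else NULL
  disease_dag(paste0("chain", n), terms = nodes[n], nodes = nodes,
              edges = edges)
}

test_that("semantic contributions decay geometrically up the ancestor chain", {
  d1 <- disease_dag("solo", terms = "T", nodes = "T", edges = NULL)
  sc1 <- semantic_contributions(d1)
  expect_equal(sc1$contributions, c(T = 1))
  expect_equal(sc1$semantic_value, 1)

  sc3 <- semantic_contributions(chain_dag(3))
  expect_equal(unname(sc3$contributions[c("N3", "N2", "N1")]),
               c(1, 0.5, 0.25))
  expect_equal(sc3$semantic_value, 1.75)

  sc_d <- semantic_contributions(chain_dag(3), delta = 0.3)
  expect_equal(unname(sc_d$contributions["N1"]), 0.09)
})

test_that("multi-path ancestors take the maximum contribution", {
  # A reaches the own term T directly (1 hop) and through B (2 hops)
  d <- disease_dag("dia", terms = "T", nodes = c("A", "B", "T"),
                   edges = rbind(c("A", "B"), c("A", "T"), c("B", "T")))
  sc <- semantic_contributions(d)
  expect_equal(unname(sc$contributions["A"]), 0.5)   # max(0.5, 0.25)
  expect_equal(unname(sc$contributions["B"]), 0.5)
})

test_that("cyclic graphs are rejected", {
  d <- disease_dag("cyc", terms = "A", nodes = c("A", "B"),
                   edges = rbind(c("A", "B"), c("B", "A")))
  expect_error(semantic_contributions(d), "cycle")
})

test_that("semantic similarity matches the worked chain example", {
  dags <- list(d2 = chain_dag(2), d3 = chain_dag(3))
  SS <- semantic_similarity(dags)
  # shared terms N1, N2: (0.25 + 0.5) + (0.5 + 1) over 1.75 + 1.5
  expect_equal(unname(SS["d2", "d3"]), 2.25 / 3.25, tolerance = 1e-12)
  expect_equal(unname(diag(SS)), c(1, 1))
})

test_that("disjoint DAGs have zero similarity", {
  dags <- list(a = chain_dag(3, "A"), b = chain_dag(3, "B"))
  SS <- semantic_similarity(dags)
  expect_equal(unname(SS["a", "b"]), 0)
})

test_that("recursive semantic similarity equals the path-enumeration oracle", {
  set.seed(101)
  for (rep in 1:100) {
    dags <- list(x = random_pool_dag(sample(2:12, 1)),
                 y = random_pool_dag(sample(2:12, 1)))
    SS <- semantic_similarity(dags)
    expect_equal(unname(SS["x", "y"]),
                 oracle_semantic_similarity(dags$x, dags$y),
                 tolerance = 1e-10)
    # structural invariants on the same draws
    expect_true(isSymmetric(SS))
    expect_true(all(SS >= 0 & SS <= 1))
    expect_equal(unname(diag(SS)), c(1, 1))
  }
})

test_that("GIP bandwidth follows the mean squared profile norm", {
  A <- diag(2); dimnames(A) <- list(c("m1", "m2"), c("d1", "d2"))
  A <- A * 1L; storage.mode(A) <- "integer"
  expect_equal(gip_bandwidth(A, "disease"), 1)       # mean norm^2 = 1
  expect_equal(gip_bandwidth(A, "disease", gamma_prime = 2), 2)
  A2 <- rbind(A, A); rownames(A2) <- c("m1", "m2", "m3", "m4")
  expect_equal(gip_bandwidth(A2, "disease"), 1 / 2)  # norms doubled -> halved
})

test_that("GIP kernel matches hand evaluation on the 2x2 identity", {
  A <- diag(2); dimnames(A) <- list(c("m1", "m2"), c("d1", "d2"))
  storage.mode(A) <- "integer"
  KD <- gip_kernel(A, "disease")
  expect_equal(unname(KD[1, 2]), exp(-2), tolerance = 1e-12)
  expect_equal(unname(diag(KD)), c(1, 1))
  KM <- gip_kernel(A, "mirna")
  expect_equal(unname(KM[1, 2]), exp(-2), tolerance = 1e-12)
})

test_that("GIP similarity never increases with profile Hamming distance", {
  set.seed(77)
  A <- matrix(rbinom(15 * 12, 1L, 0.4), 15, 12,
              dimnames = list(sprintf("m%02d", 1:15), sprintf("d%02d", 1:12)))
  if (any(rowSums(A) == 0)) A[rowSums(A) == 0, 1] <- 1L
  K <- gip_kernel(A, "mirna")
  hd <- as.matrix(dist(A, method = "manhattan"))
  for (rep in 1:200) {
    idx <- sample(15, 4)
    if (hd[idx[1], idx[2]] <= hd[idx[3], idx[4]]) {
      expect_gte(K[idx[1], idx[2]], K[idx[3], idx[4]])
    }
  }
})

test_that("similarity integration is the unconditional elementwise average", {
  S1 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  S2 <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(integrate_similarity(S1, S2)[1, 2], 0.5)
  expect_equal(integrate_similarity(S1, S1), S1)
  S0 <- S1; S0[1, 2] <- S0[2, 1] <- 0
  expect_equal(integrate_similarity(S0, S2)[1, 2], 0.3)
  expect_error(integrate_similarity(S1, matrix(1, 3, 3)), "shape")
})

test_that("integration with a zero semantic entry is half the GIP entry", {
  # two diseases with disjoint DAGs: SS = 0, so SD must equal KD / 2 there
  dags <- list(a = chain_dag(2, "A"), b = chain_dag(2, "B"))
  SS <- semantic_similarity(dags)
  A <- matrix(c(1L, 0L, 1L, 1L), 2, 2,
              dimnames = list(c("m1", "m2"), c("a", "b")))
  KD <- gip_kernel(A, "disease")
  SD <- integrate_similarity(SS, KD)
  expect_equal(SD["a", "b"], 0.5 * KD["a", "b"])
})

test_that("integrated similarities keep symmetry, unit diagonal and range", {
  set.seed(88)
  for (rep in 1:20) {
    A <- matrix(rbinom(12 * 10, 1L, 0.35), 12, 10,
                dimnames = list(sprintf("m%02d", 1:12), sprintf("d%02d", 1:10)))
    A[cbind(1:10, sample(10))] <- 1L    # no all-zero axes
    KD <- gip_kernel(A, "disease"); KM <- gip_kernel(A, "mirna")
    for (S in list(KD, KM)) {
      expect_true(isSymmetric(unname(S)))
      expect_equal(unname(diag(S)), rep(1, nrow(S)))
      expect_true(all(S > 0 & S <= 1))
    }
  }
})
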