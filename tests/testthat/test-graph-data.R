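test_that("association pair lists load into a deduplicated binary matrix", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tdisease",
               "m1\td1", "m2\td2", "m1\td2", "m1\td2"), f)
  A <- read_association_pairs(f)
  expect_identical(dim(A), c(2L, 2L))
  expect_identical(sum(A), 3L)                       # duplicate collapsed
  expect_identical(rownames(A), c("m1", "m2"))       # lexicographic order
  expect_identical(unname(A["m2", "d1"]), 0L)
})

test_that("names are canonicalized and optionally mapped", {
  expect_identical(canonicalize_names("  Breast   Neoplasms "),
                   "breast neoplasms")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hsa-miR-21\tBreast  Neoplasms",
               "hsa-mir-21\tbreast neoplasms"), f)
  A <- read_association_pairs(f)
  expect_identical(dim(A), c(1L, 1L))                # dialects collapse
  A2 <- read_association_pairs(f, name_map = c("breast neoplasms" = "breast cancer"))
  expect_identical(colnames(A2), "breast cancer")
})

test_that("malformed or empty association files fail loudly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("m1\td1", "m2\td2\textra"), f)
  expect_error(read_association_pairs(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_association_pairs(f), "empty")
})

test_that("association matrices round-trip through the pair-list format", {
  sim <- small_sim(seed = 2, n = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_association_pairs(sim$assoc, f)
  expect_identical(read_association_pairs(f), sim$assoc)
})

test_that("similarity matrices load with symmetrization, clipping, labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1 0.3", "0.3 1"), f)
  expect_equal(unname(read_similarity_matrix(f)), rbind(c(1, .3), c(.3, 1)))
  writeLines(c("1 0.2", "0.4 1"), f)                 # asymmetric -> averaged
  expect_equal(read_similarity_matrix(f)[1, 2], 0.3)
  writeLines(c("1 1.2", "1.2 1"), f)                 # out of range -> clipped
  expect_warning(S <- read_similarity_matrix(f), "clipped")
  expect_equal(unname(S[1, 2]), 1)
  writeLines(c("1.000001 0", "0 1"), f)              # diagonal forced to 1
  expect_silent(S <- read_similarity_matrix(f))
  expect_equal(unname(diag(S)), c(1, 1))
  writeLines(c("1 0 0", "0 1 0"), f)
  expect_error(read_similarity_matrix(f), "square")
})

test_that("labelled similarity matrices reorder to requested names", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tb\ta", "b\t1\t0.4", "a\t0.4\t1"), f)
  S <- read_similarity_matrix(f, names = c("a", "b"))
  expect_identical(rownames(S), c("a", "b"))
  expect_equal(unname(S["a", "b"]), 0.4)
  expect_error(read_similarity_matrix(f, names = c("a", "c")), "missing|cover")
  expect_error(read_similarity_matrix(f, names = c("a", "b", "c")),
               "does not match")
})

test_that("similarity matrices round-trip through the labelled TSV format", {
  sim <- small_sim(seed = 3, n = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(sim$fs, f)
  expect_equal(read_similarity_matrix(f, names = rownames(sim$fs)), sim$fs)
})

test_that("disease DAGs expand tree-number prefixes into ancestor graphs", {
  tt <- data.frame(disease = "x", tree_number = "C04.557")
  d <- build_disease_dags(tt)[["x"]]
  expect_setequal(d$nodes, c("C04", "C04.557"))
  expect_identical(nrow(d$edges), 1L)
  expect_identical(d$terms, "C04.557")

  tt2 <- data.frame(disease = c("y", "y"),
                    tree_number = c("C04.557", "C19.344"))
  d2 <- build_disease_dags(tt2)[["y"]]
  expect_identical(length(d2$nodes), 4L)             # union of two chains
  expect_identical(nrow(d2$edges), 2L)

  d3 <- build_disease_dags(data.frame(disease = "z", tree_number = "C04"))[["z"]]
  expect_identical(length(d3$nodes), 1L)
  expect_identical(nrow(d3$edges), 0L)
})

test_that("diseases without tree numbers become single-node DAGs with a warning", {
  tt <- data.frame(disease = c("a", "b"), tree_number = c("C01.5", NA))
  expect_warning(dags <- build_disease_dags(tt), "b")
  expect_identical(dags[["b"]]$nodes, "b")
  expect_warning(dags2 <- build_disease_dags(tt[1, ], diseases = c("a", "c")),
                 "c")
  expect_identical(dags2[["c"]]$nodes, "c")
})

test_that("built DAGs are acyclic for arbitrary tree-number tables", {
  set.seed(404)
  for (rep in 1:20) {
    segs <- function() paste(sample(sprintf("%03d", 1:6),
                                    sample(1:4, 1), replace = TRUE),
                             collapse = ".")
    tt <- data.frame(disease = sample(letters[1:3], 6, replace = TRUE),
                     tree_number = paste0("C", replicate(6, segs())))
    dags <- build_disease_dags(tt)
    for (d in dags) expect_silent(hgmda:::dag_topological_order(d))
  }
})

test_that("synthetic datasets have the configured shape and are reproducible", {
  sim <- simulate_mda(n_mirna = 20, n_disease = 15, seed = 9)
  expect_identical(dim(sim$assoc), c(20L, 15L))
  expect_identical(length(sim$dags), 15L)
  expect_identical(dim(sim$fs), c(20L, 20L))
  sim2 <- simulate_mda(n_mirna = 20, n_disease = 15, seed = 9)
  expect_identical(sim, sim2)
  expect_false(identical(sim, simulate_mda(n_mirna = 20, n_disease = 15,
                                           seed = 10)))
})

test_that("synthetic association density matches the binomial expectation", {
  sim <- simulate_mda(n_mirna = 40, n_disease = 40, n_blocks = 2,
                      p_within = 0.8, p_between = 0.05, seed = 21)
  within <- outer(sim$blocks$mirna, sim$blocks$disease, `==`)
  n_within <- sum(within); n_between <- sum(!within)
  expected <- n_within * 0.8 + n_between * 0.05
  tol <- 3 * sqrt(n_within * 0.8 * 0.2 + n_between * 0.05 * 0.95)
  expect_lt(abs(sum(sim$assoc) - expected), tol)
})

test_that("within-block density exceeds between-block density (binomial test)", {
  sim <- simulate_mda(n_mirna = 40, n_disease = 40, n_blocks = 2,
                      p_within = 0.6, p_between = 0.1, seed = 33)
  within <- outer(sim$blocks$mirna, sim$blocks$disease, `==`)
  between_rate <- mean(sim$assoc[!within])
  bt <- stats::binom.test(sum(sim$assoc[within]), sum(within),
                          p = between_rate, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})
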