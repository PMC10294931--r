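test_that("eigenvector weights recover known solutions", {
  # full symmetry: equal weights
  expect_equal(unname(derive_weights(matrix(1, 3, 3))),
               rep(1 / 3, 3), tolerance = 1e-12)

  # consistent matrix: normalized first column is the exact eigenvector
  m <- pairwise_matrix(rbind(c(1, 2, 4), c(1 / 2, 1, 2),
                             c(1 / 4, 1 / 2, 1)))
  expect_equal(unname(derive_weights(m)), c(4, 2, 1) / 7,
               tolerance = 1e-10)

  # round-trip recovery of a published 4-criterion weight vector
  w <- c(0.2488, 0.5502, 0.0826, 0.1184)
  expect_equal(unname(derive_weights(consistent_matrix(w))), w,
               tolerance = 1e-6)

  # names propagate from the matrix
  m2 <- consistent_matrix(c(a = 0.5, b = 0.3, c = 0.2))
  dimnames(m2) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_named(derive_weights(m2), c("a", "b", "c"))
})

test_that("lambda_max behaves like the dominant eigenvalue", {
  expect_equal(lambda_max(matrix(1, 1, 1)), 1)

  w <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(lambda_max(consistent_matrix(w)), 4, tolerance = 1e-9)

  # an inconsistent (cyclic) matrix, checked against a dense
  # eigendecomposition
  m <- rbind(c(1, 2, 1 / 2), c(1 / 2, 1, 4), c(2, 1 / 4, 1))
  expect_equal(lambda_max(m), eigen_oracle(m)$lambda, tolerance = 1e-9)
  expect_gt(lambda_max(m), 3)
})

test_that("CI and CR follow the defining arithmetic", {
  expect_equal(consistency_index(3, 3), 0)
  expect_equal(consistency_index(7, 7), 0)
  expect_equal(consistency_index(3.10, 3), 0.05)
  expect_equal(consistency_index(4.27, 4), 0.09)
  expect_equal(consistency_index(1, 1), 0)  # degenerate order
  expect_error(consistency_index(2.9, 3), "cannot be below")
  expect_error(consistency_index(3.2, 0), "integer >= 1")

  cr <- consistency_ratio(0.029, 3)
  expect_equal(cr$RI, 0.58)
  expect_equal(cr$CR, 0.029 / 0.58)
  expect_true(cr$consistent)

  cr2 <- consistency_ratio(0.15, 4)
  expect_equal(cr2$CR, 0.15 / 0.90, tolerance = 1e-12)
  expect_false(cr2$consistent)

  # RI = 0 orders: CR reported as 0, verdict from CI alone
  expect_true(consistency_ratio(0, 2)$consistent)
  expect_equal(consistency_ratio(0, 2)$CR, 0)
  expect_false(consistency_ratio(0.01, 2)$consistent)

  expect_error(consistency_ratio(0.05, 12), "Supply `ri_table`")
  expect_equal(consistency_ratio(0.05, 12,
                                 ri_table = rep(1.5, 12))$CR, 0.05 / 1.5)
})

test_that("invalid comparison matrices are rejected, repairable ones repaired", {
  expect_error(pairwise_matrix(rbind(c(1, 2), c(3, 1))), "not reciprocal")
  expect_error(pairwise_matrix(rbind(c(1, -2), c(-1 / 2, 1))), "> 0")
  expect_error(pairwise_matrix(matrix(1, 2, 3)), "square")
  expect_error(pairwise_matrix(rbind(c(2, 2), c(1 / 2, 1))), "diagonal")
  expect_warning(pairwise_matrix(rbind(c(1, 11), c(1 / 11, 1))),
                 "Saaty scale")

  # geometric-mean symmetrization repairs hand-entered asymmetry
  m <- rbind(c(1, 2.02), c(1 / 1.98, 1))
  fixed <- pairwise_matrix(m, symmetrize = TRUE)
  expect_equal(fixed[1, 2] * fixed[2, 1], 1, tolerance = 1e-12)
})

test_that("weights are permutation-equivariant and scale-invariant", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    w <- runif(n, 0.2, 1)
    m <- perturbed_matrix(w / sum(w), eps = 0.4)
    wt <- derive_weights(m)

    p <- sample(n)
    expect_equal(unname(derive_weights(m[p, p])), unname(wt[p]),
                 tolerance = 1e-9)

    # scaling the generating vector changes nothing: the derived
    # weights come out the same
    expect_equal(unname(derive_weights(consistent_matrix(10 * w))),
                 unname(derive_weights(consistent_matrix(w))),
                 tolerance = 1e-10)
  }
})

test_that("consistency_report ties the pieces together", {
  rep <- consistency_report(consistent_matrix(c(0.5, 0.25, 0.25)))
  expect_s3_class(rep, "consistency_report")
  expect_equal(rep$CI, 0, tolerance = 1e-9)
  expect_equal(rep$CR, 0, tolerance = 1e-9)
  expect_true(rep$consistent)
  expect_equal(sum(rep$weights), 1, tolerance = 1e-12)

  # strongly cyclic preferences fail the CR < 0.1 test
  cyc <- rbind(c(1, 5, 1 / 5), c(1 / 5, 1, 5), c(5, 1 / 5, 1))
  rep2 <- consistency_report(cyc)
  expect_false(rep2$consistent)
  expect_equal(rep2$lambda_max, eigen_oracle(cyc)$lambda,
               tolerance = 1e-9)
})

test_that("pairwise matrices round-trip through delimited files", {
  m <- consistent_matrix(c(0.5, 0.3, 0.2))
  dimnames(m) <- list(c("c1", "c2", "c3"), c("c1", "c2", "c3"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_matrix(pairwise_matrix(m), path)
  m2 <- read_pairwise_matrix(path)
  expect_equal(unclass(m2), m, tolerance = 1e-12,
               ignore_attr = "class")
  expect_identical(colnames(m2), c("c1", "c2", "c3"))
})
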