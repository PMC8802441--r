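test_that("fit_pca_factors satisfies the spectral identities", {
  set.seed(5)
  x <- matrix(rbinom(4000 * 6, 1, 0.3), 4000, 6,
              dimnames = list(NULL, paste0("C0", 1:6)))
  m <- fit_pca_factors(x)
  # independent codes: eigenvalues near 1
  expect_true(all(abs(m$eigenvalues - 1) < 0.15))
  # eigenvalues sum to the number of codes
  expect_equal(sum(m$eigenvalues), 6, tolerance = 1e-6)
  # per-column sum of squared loadings equals the eigenvalue
  expect_equal(unname(colSums(m$loadings^2)), m$eigenvalues, tolerance = 1e-8)
  # full reconstruction of the correlation matrix
  expect_equal(m$loadings %*% t(m$loadings), unname(stats::cor(x)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(fit_pca_factors(cbind(x, Z00 = 0L)), "Z00")
})

test_that("two perfectly correlated blocks give the block eigenstructure", {
  # exactly orthogonal binary prototypes -> exact block-diagonal correlation
  z1 <- rep(c(1L, 0L), each = 4)
  z2 <- rep(c(1L, 1L, 0L, 0L), 2)
  x <- cbind(z1, z1, z1, z2, z2, z2)
  colnames(x) <- paste0("B0", 1:6)
  m <- fit_pca_factors(x)
  expect_equal(m$eigenvalues, c(3, 3, 0, 0, 0, 0), tolerance = 1e-8)
  # distinct block sizes avoid the degenerate-eigenvalue rotation ambiguity
  x2 <- cbind(x[, 1:3], z2, z2)
  colnames(x2) <- paste0("B0", 1:5)
  defs <- define_factors(fit_pca_factors(x2), 2, cutoff = 0.2)
  expect_setequal(defs[[1]]$code_ids, paste0("B0", 1:3))
  expect_setequal(defs[[2]]$code_ids, paste0("B0", 4:5))
})

test_that("loadings are invariant (up to column sign) to row permutation", {
  set.seed(8)
  x <- matrix(rbinom(500 * 5, 1, .3), 500, 5,
              dimnames = list(NULL, paste0("C", 1:5)))
  m1 <- fit_pca_factors(x)
  m2 <- fit_pca_factors(x[sample(nrow(x)), ])
  expect_equal(abs(m1$loadings), abs(m2$loadings), tolerance = 1e-8)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-10)
})

stub_model <- function(ev) {
  structure(list(code_ids = paste0("c", seq_along(ev)), eigenvalues = ev,
                 loadings = matrix(0, length(ev), length(ev)),
                 cum_var = cumsum(ev) / sum(ev)), class = "factor_model")
}

test_that("factor-count criteria follow their definitions", {
  expect_equal(choose_n_factors(stub_model(c(3, 2, .5, .3, .2)),
                                criteria = "kaiser")$n_factors, 2L)
  expect_equal(choose_n_factors(stub_model(c(5, 1.2, 1.1, .4, .3)),
                                criteria = "scree_breakpoint")$n_factors, 1L)
  expect_equal(choose_n_factors(stub_model(c(2, 1.2, .5, .3)),
                                criteria = "cumulative_variance",
                                cum_var_target = 0.8)$n_factors, 2L)
  expect_error(choose_n_factors(stub_model(c(2, 1)), criteria = "auc_loop"),
               "auc_loop")
})

test_that("all criteria recover a planted 4-factor structure", {
  bps <- lapply(1:4, function(j)
    factor_blueprint(paste0("f", j), sprintf("%s%02d", LETTERS[j], 1:8),
                     p_ref = 0.25, target_or = 2.5, q_on = .9, q_bg = .02))
  sim <- simulate_matched_codes(2500L, bps, seed = 17L)
  x <- paired_matrix(sim$case, sim$reference)
  prs <- tiny_pairs(2500)
  model <- fit_pca_factors(x)
  pick <- choose_n_factors(model, criteria = c("kaiser", "scree_breakpoint",
                                               "auc_loop"),
                           x = x, pairs = prs, max_factors = 8L)
  expect_equal(pick$report$kaiser, 4L)
  expect_equal(pick$report$scree_breakpoint, 4L)
  # the in-sample AUC loop can overshoot (subset scores add resolution);
  # the median combiner settles on the planted count
  expect_gte(pick$report$auc_loop, 4L)
  expect_equal(pick$n_factors, 4L)
})

test_that("define_factors applies the cutoff with multi-membership and reports unassigned", {
  m <- stub_model(c(2, 1, .5))
  m$loadings <- matrix(c(0.5, 0.25, 0.0,
                         0.3, 0.10, 0.0,
                         0.15, 0.10, 0.05), 3, 3, byrow = TRUE,
                       dimnames = list(c("A01", "B01", "C01"),
                                       c("F01", "F02", "F03")))
  defs <- define_factors(m, 2, cutoff = 0.2)
  expect_setequal(defs[[1]]$code_ids, c("A01", "B01"))
  # A01 loads 0.5 and 0.25 -> member of both factors
  expect_true("A01" %in% defs[[2]]$code_ids)
  expect_equal(attr(defs, "unassigned"), "C01")
  expect_error(define_factors(m, 2, cutoff = 1.5), "cutoff")
  expect_error(define_factors(m, 5), "exceeds")
})

test_that("score_patients is binary any-of scoring and matches a brute-force loop", {
  defs <- list(structure(list(factor_id = "F01", code_ids = c("A01", "B02")),
                         class = "factor_definition"),
               structure(list(factor_id = "F02", code_ids = "C03"),
                         class = "factor_definition"))
  x <- matrix(c(1, 0, 0,
                0, 0, 0,
                1, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("A01", "B02", "C03")))
  s <- score_patients(x, defs)
  expect_equal(unname(s[, "F01"]), c(1L, 0L, 1L))
  expect_equal(unname(s[, "F02"]), c(0L, 0L, 1L))
  # random fixture vs set-intersection loop
  set.seed(9)
  xr <- matrix(rbinom(200 * 6, 1, .2), 200, 6,
               dimnames = list(sprintf("p%03d", 1:200),
                               c("A01", "B02", "C03", "D04", "E05", "F06")))
  defs2 <- list(structure(list(factor_id = "G1",
                               code_ids = c("A01", "D04", "F06")),
                          class = "factor_definition"))
  sr <- score_patients(xr, defs2)
  brute <- vapply(rownames(xr), function(p) {
    as.integer(length(intersect(colnames(xr)[xr[p, ] == 1],
                                defs2[[1]]$code_ids)) > 0)
  }, integer(1))
  expect_equal(unname(sr[, 1]), unname(brute))
  expect_error(score_patients(xr[, 1:2], defs2), "absent")
})

test_that("duplicate factor definitions from degenerate components are dropped", {
  m <- stub_model(c(2, 2, 1))
  m$loadings <- matrix(c(0.6, 0.6, 0.0,
                         0.5, 0.5, 0.0,
                         0.0, 0.0, 0.4), 3, 3, byrow = TRUE,
                       dimnames = list(c("A01", "B01", "C01"),
                                       c("F01", "F02", "F03")))
  expect_warning(defs <- define_factors(m, 3, cutoff = 0.2),
                 "over-extraction")
  expect_length(defs, 2)
  expect_setequal(defs[[1]]$code_ids, c("A01", "B01"))
  # opting out keeps the literal per-component definitions
  defs_all <- define_factors(m, 3, cutoff = 0.2, dedupe = FALSE)
  expect_length(defs_all, 3)
})
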