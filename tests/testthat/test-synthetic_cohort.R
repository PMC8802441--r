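test_that("case activation probability follows the logit shift", {
  expect_equal(case_activation_prob(0.10, 2.0), 2 / 11)
  expect_equal(case_activation_prob(0.3, 1.0), 0.3)
  # implied discordant-pair odds ratio is the target when q_on=1, q_bg=0
  p1 <- case_activation_prob(0.2, 3)
  expect_equal((p1 * (1 - 0.2)) / (0.2 * (1 - p1)), 3)
})

test_that("blueprint and config invariants are enforced", {
  expect_error(factor_blueprint("f", "A01", p_ref = 0, target_or = 2), "p_ref")
  expect_error(factor_blueprint("f", "A01", p_ref = .1, target_or = 2,
                                q_on = .5, q_bg = .5), "q_bg")
  expect_error(factor_blueprint("f", character(0), p_ref = .1, target_or = 2),
               "nonempty")
  bps <- list(factor_blueprint("a", "A01", .1, 2),
              factor_blueprint("b", "A01", .1, 2))
  expect_error(simulation_config(blueprints = bps), "disjoint")
  expect_error(
    simulation_config(correlation_targets = data.frame(
      f = "falls_syncope", g = "nope", rho_F = .2, rho_M = .1)),
    "undeclared")
})

test_that("infeasible correlation targets error naming the pairs", {
  bps <- list(factor_blueprint("a", "A01", .1, 2),
              factor_blueprint("b", "B01", .1, 2),
              factor_blueprint("c", "C01", .1, 2))
  tg <- data.frame(f = c("a", "a", "b"), g = c("b", "c", "c"),
                   rho_F = c(.9, .9, -.9), rho_M = c(0, 0, 0))
  cfg <- simulation_config(blueprints = bps, correlation_targets = tg,
                           n_pairs_by_sex = c(F = 10L, M = 0L))
  expect_error(generate_cohort(cfg), "not positive definite")
})

test_that("same seed and config reproduce the cohort byte-for-byte", {
  cfg <- simulation_config(n_pairs_by_sex = c(F = 60L, M = 40L),
                           n_noise_codes = 20L, seed = 99L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$visits, b$visits)
  expect_identical(a$truth, b$truth)
})

test_that("generated cohorts satisfy the matched design and carry all signal codes", {
  cfg <- simulation_config(n_pairs_by_sex = c(F = 80L, M = 80L),
                           n_noise_codes = 30L, seed = 5L)
  co <- generate_cohort(cfg)
  expect_silent(validate_patients(co$patients))
  expect_setequal(
    co$truth$signal_code_ids,
    unlist(lapply(cfg$blueprints, function(b) b$code_ids)))
  expect_equal(length(co$truth$noise_code_ids), 30L)
})

test_that("reference-arm marginal code prevalence matches p_ref*q_on + (1-p_ref)*q_bg", {
  bp <- list(factor_blueprint("f1", c("A01", "A02"), p_ref = 0.2,
                              target_or = 2, q_on = 0.8, q_bg = 0.05))
  n <- 5000L
  sim <- simulate_matched_codes(n, bp, seed = 21L)
  expected <- 0.2 * 0.8 + 0.8 * 0.05
  se <- sqrt(expected * (1 - expected) / n)
  for (code in c("A01", "A02"))
    expect_lt(abs(mean(sim$reference[, code]) - expected), 3 * se)
})

test_that("achieved latent correlations among cases match the targets within 0.05", {
  bps <- list(factor_blueprint("a", "A01", .3, 2),
              factor_blueprint("b", "B01", .3, 2),
              factor_blueprint("c", "C01", .2, 1.5))
  tg <- data.frame(f = c("a", "b"), g = c("b", "c"),
                   rho_F = c(.6, .25), rho_M = c(.1, .4))
  R <- injurypheno:::latent_corr_matrix(bps, tg, "F")
  sim <- simulate_matched_codes(5000L, bps, rho = R, seed = 77L)
  ach <- stats::cor(sim$normals_case)
  expect_lt(abs(ach["a", "b"] - 0.6), 0.05)
  expect_lt(abs(ach["b", "c"] - 0.25), 0.05)
  expect_lt(abs(ach["a", "c"] - 0.0), 0.05)
})

test_that("null configuration yields equal prevalences and an empty screen", {
  bps <- lapply(1:5, function(j)
    factor_blueprint(paste0("f", j), sprintf("A%02d", j), p_ref = .15,
                     target_or = 1, q_on = .9, q_bg = .02))
  cfg <- simulation_config(n_pairs_by_sex = c(F = 300L, M = 300L),
                           blueprints = bps, n_noise_codes = 50L,
                           correlation_targets = NULL, seed = 13L)
  co <- generate_cohort(cfg)
  m <- binarize_codes(co$visits, co$patients, event_window(30, 30))
  pi <- pair_index(co$patients)
  # case vs reference prevalence of signal codes agree in expectation
  ic <- match(pi$case, rownames(m)); ir <- match(pi$reference, rownames(m))
  sig <- intersect(co$truth$signal_code_ids, colnames(m))
  diff <- colMeans(m[ic, sig]) - colMeans(m[ir, sig])
  expect_lt(max(abs(diff)), 0.06)
  scr <- mcnemar_screen(m[, setdiff(colnames(m), "S06")], pi)
  expect_lte(length(scr$retained), 2L)
})

test_that("single-dataset screening controls the empirical FDR on null cohorts", {
  # null world: every code is null; empirical FDR = mean over replicates of
  # the false-discovery proportion (here every rejection is false)
  n_rep <- 500L
  fdp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_matched_codes(200L, list(), n_noise_codes = 100L,
                                  noise_prevalence = 0.05, seed = 3000L + r)
    b <- colSums(sim$case * (1L - sim$reference))
    cc <- colSums(sim$reference * (1L - sim$case))
    keep <- colSums(sim$case) + colSums(sim$reference) > 0
    rej <- by_adjust(mcnemar_test(b[keep], cc[keep])$p_value, 0.05)$rejected
    fdp[r] <- sum(rej) / max(1, sum(rej))
  }
  expect_lte(mean(fdp), 0.055)
})

test_that("visit offsets have the configured peak and baseline behaviour", {
  shape <- window_shape(peak = 10, decay = 30, span = 90, baseline = 1)
  off <- generate_visit_offsets(50000L, shape, seed = 8L)
  counts <- table(factor(off, levels = -90:90))
  expect_equal(as.integer(names(which.max(counts))), 0L)
  # expected per-day probability mass
  w <- injurypheno:::shape_weights(shape)
  p <- w / sum(w)
  for (d in c("-30", "30")) {
    expected <- 50000 * p[[d]]
    expect_lt(abs(counts[[d]] - expected), 3 * sqrt(expected))
  }
  # flat shape -> uniform offsets, detector returns the degenerate window
  flat <- generate_visit_offsets(20000L, window_shape(peak = 1), seed = 9L)
  cn <- stats::setNames(as.integer(table(factor(flat, levels = -90:90))),
                        -90:90)
  expect_equal(length(detect_event_window(cn)), 1)
  expect_error(window_shape(baseline = 0), "baseline")
})

test_that("fixtures round-trip losslessly and screen quickly", {
  cfg <- simulation_config(n_pairs_by_sex = c(F = 100L, M = 100L),
                           n_noise_codes = 30L, seed = 31L)
  co <- generate_cohort(cfg)
  dir <- tempfile("fixture")
  write_fixture(co, dir)
  back <- read_fixture(dir)
  expect_equal(back$patients, co$patients)
  expect_equal(back$visits, co$visits)
  expect_setequal(back$truth$signal_code_ids, co$truth$signal_code_ids)
  expect_equal(back$truth$factor_or, co$truth$factor_or)
  elapsed <- system.time({
    m <- binarize_codes(back$visits, back$patients, event_window(30, 30))
    mcnemar_screen(m, pair_index(back$patients))
  })[["elapsed"]]
  expect_lt(elapsed, 5)
})
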