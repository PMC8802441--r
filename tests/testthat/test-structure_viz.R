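test_that("correlation distance is definitional", {
  r <- matrix(c(1, .25, .25, 1), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  d <- correlation_distance(r)
  expect_equal(d["a", "b"], 0.75)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(correlation_distance(matrix(c(1, -1, -1, 1), 2))[1, 2], 2)
})

test_that("ward linkage matches singleton height and flags bad input", {
  d <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("x", "y"),
                                                     c("x", "y")))
  t2 <- ward_linkage(d)
  expect_equal(t2$height, 0.4)
  dup <- matrix(0, 3, 3); dup[3, 1:2] <- dup[1:2, 3] <- 1
  expect_equal(ward_linkage(dup)$height[1], 0)  # duplicate points merge at 0
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_linkage(bad), "symmetric")
  expect_error(ward_linkage(matrix(0, 1, 1)), "at least 2")
})

test_that("ward linkage equals the independent Lance-Williams agglomerator on small fixtures", {
  set.seed(51)
  for (n in c(5, 6, 8)) {
    for (rep in 1:3) {
      pts <- matrix(rnorm(n * 2), n, 2)
      d <- as.matrix(dist(pts))
      got <- ward_linkage(d)
      oracle <- brute_ward(d)
      expect_equal(got$height, oracle$heights, tolerance = 1e-10)
      expect_true(all(diff(got$height) >= -1e-12))  # Ward monotonicity
    }
  }
})

test_that("two tight triads merge internally before joining", {
  pts <- rbind(matrix(rnorm(6, sd = .01), 3, 2),
               matrix(rnorm(6, mean = 10, sd = .01), 3, 2))
  tr <- ward_linkage(as.matrix(dist(pts)))
  cl <- cut_linkage(tr, 2)
  expect_equal(unname(cl), c(1, 1, 1, 2, 2, 2))
  # the first four merges are all within-triad
  expect_true(all(tr$height[1:4] < 1))
  expect_gt(tr$height[5], 5)
})

test_that("three planted correlation blocks are recovered by the 3-cluster cut", {
  recover <- function(seed) {
    set.seed(seed)
    n <- 500
    blocks <- lapply(1:3, function(b) {
      z0 <- rnorm(n)
      sapply(1:3, function(j) {
        z <- sqrt(.5) * z0 + sqrt(.5) * rnorm(n)  # within-block rho 0.5
        (z > qnorm(.7)) * 1L
      })
    })
    x <- do.call(cbind, blocks)
    colnames(x) <- paste0("F", 1:9)
    r <- suppressWarnings(phi_matrix(x))
    if (ncol(r) < 9) return(FALSE)
    cl <- cut_linkage(ward_linkage(correlation_distance(r)), 3)
    truth <- rep(1:3, each = 3)
    length(unique(paste(cl, truth))) == 3
  }
  hits <- sum(vapply(1:100, function(s) recover(6000 + s), logical(1)))
  expect_gte(hits, 95)
})

test_that("cause profiles follow the range lookup with multi-designation", {
  pts <- make_patients(3)
  idx <- pts$index_date[match(pts$patient_id, pts$patient_id)]
  p <- pts$patient_id[1:3]
  vis <- data.frame(
    patient_id = c(p[1], p[2], p[2], p[3]),
    visit_date = pts$index_date[match(c(p[1], p[2], p[2], p[3]),
                                      pts$patient_id)],
    code = c("W19", "V43", "W19", "I10"))
  prof <- build_cause_profiles(vis, pts, event_window(30, 30))
  expect_true(prof$falls[prof$patient_id == p[1]])
  expect_false(prof$mvc[prof$patient_id == p[1]])
  expect_true(all(prof[prof$patient_id == p[2], c("mvc", "falls")] == TRUE))
  expect_false(any(unlist(prof[prof$patient_id == p[3],
                               c("falls", "struck", "mvc", "assault",
                                 "sports", "other")])))
  # unmapped external-cause code counts as other
  vis2 <- data.frame(patient_id = p[1], visit_date = vis$visit_date[1],
                     code = "X32")
  prof2 <- build_cause_profiles(vis2, pts, event_window(30, 30))
  expect_true(prof2$other[prof2$patient_id == p[1]])
})

test_that("cause/severity associations expose planted co-occurrence after masking", {
  set.seed(52)
  n <- 1500
  mk <- function(rho) {
    z <- copula_binaries(n, rho)
    scores <- cbind(F01 = z[, 1], F02 = rbinom(n, 1, .3))
    rownames(scores) <- sprintf("p%04d", 1:n)
    prof <- data.frame(patient_id = rownames(scores),
                       falls = z[, 2] == 1, struck = rbinom(n, 1, .2) == 1,
                       mvc = rbinom(n, 1, .1) == 1,
                       assault = rbinom(n, 1, .05) == 1,
                       sports = FALSE, other = FALSE,
                       age = rnorm(n, 40, 15), rural = rbinom(n, 1, .2),
                       income_quintile = sample(1:5, n, TRUE))
    cause_severity_matrix(scores, prof)
  }
  mF <- suppressWarnings(mk(0.5))
  mM <- suppressWarnings(mk(0.0))
  expect_true(all(c("falls", "struck") %in% colnames(mF$r)))
  expect_true(all(c("F01", "F02", "age") %in% rownames(mF$r)))
  masked <- mask_correlation_difference(mF$r, mF$n, mM$r, mM$n, q = 0.05)
  expect_gt(masked$F["F01", "falls"], 0)
  expect_equal(masked$M["F01", "falls"], 0)
  expect_gt(masked$diff["F01", "falls"], 0)
  # independent flag is masked to zero everywhere
  expect_equal(unname(masked$F["F02", "mvc"]), 0)
})

test_that("wordcloud weights follow the stated conventions", {
  s <- cbind(F01 = c(1, 1, 0, 0), F02 = c(1, 0, 0, 0))
  w <- wordcloud_weights(s)
  expect_equal(w$weight[w$factor_id == "F01"], 0.5)
  fits <- data.frame(factor_id = c("F01", "F02"), or = c(2.0, 1.2))
  wo <- wordcloud_weights(s, fits, weight_kind = "odds_ratio")
  expect_equal(wo$factor_id, c("F01", "F02"))  # sorted descending by OR
  expect_equal(wo$weight, c(2.0, 1.2))
  # infinite ORs (separation) are capped at the largest finite weight
  fits_inf <- data.frame(factor_id = c("F01", "F02"), or = c(1.2, Inf))
  wi <- wordcloud_weights(s, fits_inf, weight_kind = "odds_ratio")
  expect_true(wi$capped[wi$factor_id == "F02"])
  expect_true(all(is.finite(wi$weight)))
  expect_error(wordcloud_weights(s, fits[1, ], weight_kind = "odds_ratio"),
               "missing fits")
})

test_that("heatmap export orders by dendrogram leaves and round-trips", {
  set.seed(53)
  # two clean blocks -> leaf order groups blocks contiguously
  r <- diag(6)
  r[1:3, 1:3] <- .9; r[4:6, 4:6] <- .9; diag(r) <- 1
  ids <- paste0("F", 1:6)
  dimnames(r) <- list(ids, ids)
  perm <- c(1, 4, 2, 5, 3, 6)
  rp <- r[perm, perm]
  tree <- ward_linkage(correlation_distance(rp))
  ex <- export_heatmap(rp, tree, dir = tempfile("hm"))
  blk <- substr(ex$row_order, 2, 2) %in% c("1", "2", "3")
  expect_true(all(diff(which(blk)) == 1))  # block 1 leaves contiguous
  expect_equal(ex$values, rp[ex$row_order, ex$col_order])
  back <- as.matrix(utils::read.csv(ex$paths[1], row.names = 1,
                                    check.names = FALSE))
  expect_equal(back, ex$values, tolerance = 1e-12)
  bad_tree <- ward_linkage(correlation_distance(r[1:4, 1:4]))
  expect_error(export_heatmap(rp, bad_tree), "leaf sets")
})
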