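#' @title Sex differences in factor correlation structure
#' @description Per-sex phi-coefficient matrices of binary factor scores and
#'   the Fisher-transform machinery: within-sex z-tests of r' = 0, the
#'   between-sex z-test of r'_F - r'_M = 0, and BY-based FDR masking of the
#'   three hypothesis families so that heatmaps show only correlations that
#'   survive multiplicity control.
#' @name sex-correlation
NULL

#' Phi-coefficient correlation matrix of binary factor scores
#'
#' Pearson correlation of 0/1 columns equals the phi coefficient.  Factors
#' with zero variance in the supplied patients are excluded with a warning
#' (their correlations are undefined), not an error.
#'
#' @param scores `factor_scores` matrix restricted to the relevant patients
#'   (conventionally one sex's cases).
#' @param sex optional label (`"F"`/`"M"`) carried as an attribute.
#' @return correlation matrix of class `phi_matrix` with attributes `n`
#'   (patient count) and `sex`.
#' @export
phi_matrix <- function(scores, sex = NULL) {
  if (nrow(scores) < 4L)
    stop("need at least 4 patients (Fisher variance 1/(n-3))")
  v <- apply(scores, 2L, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance factors: ",
            paste(colnames(scores)[v == 0], collapse = ", "))
    scores <- scores[, v > 0, drop = FALSE]
  }
  r <- stats::cor(scores)
  diag(r) <- 1
  structure(r, n = nrow(scores), sex = sex,
            class = c("phi_matrix", class(r)))
}

#' Fisher z-transformation
#'
#' `r' = (1/2) log((1 + r)/(1 - r))`, an odd function of `r` with
#' approximate variance `1/(n - 3)` under bivariate normal sampling.
#'
#' @param r correlation(s) with `|r| < 1`.
#' @return transformed value(s).
#' @export
fisher_transform <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("|r| >= 1: Fisher transform is infinite; clamp degenerate entries")
  0.5 * log((1 + r) / (1 - r))
}

#' Within-sex z-test of a correlation
#'
#' `z = r' / sqrt(1/(n - 3))` with a two-sided standard-normal p-value.
#'
#' @param r correlation(s).
#' @param n patient count(s) used to compute `r` (>= 4).
#' @return data frame with `r`, `r_prime`, `n`, `z`, `p`.
#' @export
z_single <- function(r, n) {
  if (any(n < 4)) stop("n must be >= 4")
  rp <- fisher_transform(r)
  z <- rp / sqrt(1 / (n - 3))
  data.frame(r = r, r_prime = rp, n = n, z = z,
             p = 2 * stats::pnorm(-abs(z)))
}

#' Between-sex z-test of a correlation difference
#'
#' `z = (r'_F - r'_M) / sqrt(1/(n_F - 3) + 1/(n_M - 3))`, two-sided normal
#' p-value; antisymmetric in the two sexes.
#'
#' @param r_F,n_F female correlation(s) and count(s).
#' @param r_M,n_M male correlation(s) and count(s).
#' @return data frame with `r_F`, `r_M`, `r_prime_F`, `r_prime_M`, `n_F`,
#'   `n_M`, `z`, `p`.
#' @export
z_difference <- function(r_F, n_F, r_M, n_M) {
  if (any(c(n_F, n_M) < 4)) stop("n must be >= 4")
  rpf <- fisher_transform(r_F)
  rpm <- fisher_transform(r_M)
  z <- (rpf - rpm) / sqrt(1 / (n_F - 3) + 1 / (n_M - 3))
  data.frame(r_F = r_F, r_M = r_M, r_prime_F = rpf, r_prime_M = rpm,
             n_F = n_F, n_M = n_M, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Clamp |r| = 1 entries just inside the open interval so degenerate
# synthetic fixtures stay testable; returns the clamped vector with a flag.
clamp_r <- function(r, eps = 1e-12) {
  clamped <- abs(r) >= 1
  r[clamped] <- sign(r[clamped]) * (1 - eps)
  attr(r, "clamped") <- clamped
  r
}

#' All pairwise sex-correlation tests
#'
#' Builds the upper-triangle test table from two per-sex correlation
#' matrices: within-sex z-tests for each sex and the between-sex difference
#' test for every factor pair.  Entries with `|r| = 1` are clamped to
#' `+/-(1 - 1e-12)` and flagged.
#'
#' @param corr_F,corr_M `phi_matrix` objects over the same factors (female
#'   and male patients).
#' @return data frame with one row per unordered factor pair: `f`, `g`,
#'   `r_F`, `r_M`, `n_F`, `n_M`, the three z/p pairs, and `clamped`.
#' @export
sex_corr_tests <- function(corr_F, corr_M) {
  common <- intersect(colnames(corr_F), colnames(corr_M))
  if (length(common) < 2L) stop("need at least two shared factors")
  n_F <- attr(corr_F, "n") %||% stop("corr_F lacks an `n` attribute")
  n_M <- attr(corr_M, "n") %||% stop("corr_M lacks an `n` attribute")
  corr_F <- corr_F[common, common]
  corr_M <- corr_M[common, common]
  ut <- which(upper.tri(corr_F), arr.ind = TRUE)
  rF <- clamp_r(corr_F[ut])
  rM <- clamp_r(corr_M[ut])
  tf <- z_single(as.numeric(rF), n_F)
  tm <- z_single(as.numeric(rM), n_M)
  td <- z_difference(as.numeric(rF), n_F, as.numeric(rM), n_M)
  data.frame(f = common[ut[, 1L]], g = common[ut[, 2L]],
             r_F = as.numeric(rF), r_M = as.numeric(rM),
             n_F = n_F, n_M = n_M,
             z_F = tf$z, p_F = tf$p, z_M = tm$z, p_M = tm$p,
             z_diff = td$z, p_diff = td$p,
             clamped = attr(rF, "clamped") | attr(rM, "clamped"),
             stringsAsFactors = FALSE)
}

#' FDR-mask the three correlation hypothesis families
#'
#' Applies the BY procedure separately (the default, mirroring the three
#' separate hypothesis families: female r' = 0, male r' = 0, and
#' r'_F - r'_M = 0) or jointly, then builds masked square matrices:
#' non-significant entries are set to 0, significant entries keep the raw
#' `r` (or `r_F - r_M`); the per-sex diagonals are fixed at 1 and the
#' difference diagonal at 0.
#'
#' @param tests output of [sex_corr_tests()] covering each unordered pair
#'   exactly once.
#' @param q FDR level.
#' @param joint correct the three families together instead of separately.
#' @return object of class `sex_corr_mask`: matrices `F`, `M`, `diff`, and
#'   the augmented `tests` table (significance flags and BY-adjusted
#'   p-values per family).
#' @export
fdr_mask <- function(tests, q = 0.05, joint = FALSE) {
  key <- paste(pmin(tests$f, tests$g), pmax(tests$f, tests$g))
  if (anyDuplicated(key))
    stop("duplicate factor pairs in the test table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (joint) {
    all_by <- by_adjust(c(tests$p_F, tests$p_M, tests$p_diff), q = q)
    np <- nrow(tests)
    sig <- list(F = all_by$rejected[seq_len(np)],
                M = all_by$rejected[np + seq_len(np)],
                diff = all_by$rejected[2L * np + seq_len(np)])
    adj <- list(F = all_by$adjusted_p[seq_len(np)],
                M = all_by$adjusted_p[np + seq_len(np)],
                diff = all_by$adjusted_p[2L * np + seq_len(np)])
  } else {
    bys <- lapply(list(F = tests$p_F, M = tests$p_M, diff = tests$p_diff),
                  by_adjust, q = q)
    sig <- lapply(bys, `[[`, "rejected")
    adj <- lapply(bys, `[[`, "adjusted_p")
  }
  ids <- sort(unique(c(tests$f, tests$g)))
  build <- function(values, significant, diag_value) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    v <- ifelse(significant, values, 0)
    m[cbind(match(tests$f, ids), match(tests$g, ids))] <- v
    m[cbind(match(tests$g, ids), match(tests$f, ids))] <- v
    diag(m) <- diag_value
    m
  }
  tests$sig_F <- sig$F; tests$q_F <- adj$F
  tests$sig_M <- sig$M; tests$q_M <- adj$M
  tests$sig_diff <- sig$diff; tests$q_diff <- adj$diff
  structure(list(F = build(tests$r_F, sig$F, 1),
                 M = build(tests$r_M, sig$M, 1),
                 diff = build(tests$r_F - tests$r_M, sig$diff, 0),
                 tests = tests, q = q, joint = joint),
            class = "sex_corr_mask")
}
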