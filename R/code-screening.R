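#' @title Matched McNemar screening with Benjamini-Yekutieli FDR control
#' @description Screens every binary code against case status in a 1:1
#'   matched cohort: discordant-pair counts, McNemar tests (exact binomial
#'   for small discordant totals, chi-square otherwise), the
#'   Benjamini-Yekutieli step-up procedure at FDR level q, a matched
#'   odds-ratio (> 1) filter, and retention of the codes that survive in
#'   both the training and validation datasets.
#' @name code-screening
NULL

#' Discordant-pair counts for one code
#'
#' `b` counts pairs where the case carries the code and the reference does
#' not; `c` the reverse.  Concordant pairs enter only `n_pairs`.
#'
#' @param x a `code_matrix` (patients x codes, 0/1).
#' @param pairs matched patient table or a [pair_index()] data frame.
#' @param code_id column to tabulate.
#' @return list with `code_id`, `b`, `c`, `n_pairs`.
#' @export
discordant_counts <- function(x, pairs, code_id) {
  if (!code_id %in% colnames(x)) stop("code ", code_id, " absent from matrix")
  d <- discordant_table(x, pairs)
  as.list(d[d$code == code_id, ])
}

#' Discordant-pair counts for every code
#'
#' @inheritParams discordant_counts
#' @return data frame with one row per code: `code`, `b`, `c`, `n_pairs`,
#'   and `present` (TRUE unless the code occurs in neither arm).
#' @export
discordant_table <- function(x, pairs) {
  pi <- if (all(c("case", "reference") %in% names(pairs))) pairs
        else pair_index(pairs)
  ic <- match(pi$case, rownames(x))
  ir <- match(pi$reference, rownames(x))
  if (anyNA(ic) || anyNA(ir))
    stop("pairs reference patients absent from the code matrix")
  xc <- x[ic, , drop = FALSE]
  xr <- x[ir, , drop = FALSE]
  b <- colSums(xc * (1L - xr))
  cc <- colSums(xr * (1L - xc))
  present <- colSums(xc) + colSums(xr) > 0
  data.frame(code = colnames(x), b = as.integer(b), c = as.integer(cc),
             n_pairs = nrow(pi), present = present,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Matched McNemar test
#'
#' For `b + c < exact_threshold` discordant pairs, the exact two-sided
#' binomial test `p = min(1, 2 P(Bin(b+c, 1/2) <= min(b, c)))`; otherwise
#' the chi-square statistic `(b - c)^2 / (b + c)` on 1 df (no continuity
#' correction unless `correct = TRUE`).  `b + c = 0` gives `p = 1` by
#' convention.  Vectorized over `b` and `c`.
#'
#' @param b,c discordant-pair counts.
#' @param exact_threshold discordant total below which the exact test is used.
#' @param correct apply the Edwards continuity correction in the chi-square
#'   branch.
#' @return data frame with `b`, `c`, `method`, `statistic`, `p_value`, and
#'   the matched odds ratio `matched_or`.
#' @export
mcnemar_test <- function(b, c, exact_threshold = 25L, correct = FALSE) {
  stopifnot(length(b) == length(c), all(b >= 0), all(c >= 0))
  n <- b + c
  exact <- n < exact_threshold
  p <- numeric(length(b))
  stat <- rep(NA_real_, length(b))
  if (any(exact)) {
    p[exact] <- pmin(1, 2 * stats::pbinom(pmin(b, c)[exact], n[exact], 0.5))
    p[exact][n[exact] == 0L] <- 1
  }
  if (any(!exact)) {
    d <- abs(b - c)[!exact]
    if (correct) d <- pmax(d - 1, 0)
    stat[!exact] <- d^2 / n[!exact]
    p[!exact] <- stats::pchisq(stat[!exact], df = 1L, lower.tail = FALSE)
  }
  data.frame(b = b, c = c,
             method = ifelse(exact, "exact", "chi_square"),
             statistic = stat, p_value = p,
             matched_or = matched_odds_ratio(b, c),
             stringsAsFactors = FALSE)
}

#' Matched (discordant-pair) odds ratio
#'
#' `b / c`; `b > 0, c = 0` yields `Inf` (treated as > 1 in filters) and
#' `b = c = 0` yields `NaN` (undefined; fails the OR filter).  Vectorized.
#'
#' @param b,c discordant-pair counts.
#' @return numeric vector of odds ratios.
#' @export
matched_odds_ratio <- function(b, c) {
  out <- ifelse(b == 0 & c == 0, NaN, b / c)
  out[b > 0 & c == 0] <- Inf
  out
}

#' Benjamini-Yekutieli step-up procedure
#'
#' Sorts the p-values ascending and rejects the `k` smallest, where `k` is
#' the largest rank `i` with `p_(i) <= i q / (m H_m)` and
#' `H_m = sum_{j=1}^m 1/j` is the harmonic constant that makes the procedure
#' valid under arbitrary dependence.  Also returns step-up adjusted
#' p-values (monotone, equal to `stats::p.adjust(method = "BY")`).
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return object of class `by_outcome`: list with `m`, `q`, `k`,
#'   `thresholds` (per rank), `rejected` (logical, original order), and
#'   `adjusted_p`.
#' @export
by_adjust <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  stop_if_not_scalar_number(q, "q", 0, 1, strict = TRUE)
  m <- length(p)
  ord <- order(p)
  h <- sum(1 / seq_len(m))
  thr <- seq_len(m) * q / (m * h)
  k <- {
    hits <- which(p[ord] <= thr)
    if (length(hits)) max(hits) else 0L
  }
  rejected <- logical(m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  adj_sorted <- rev(cummin(rev(pmin(1, m * h * p[ord] / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  structure(list(m = m, q = q, k = k, thresholds = thr,
                 rejected = rejected, adjusted_p = adjusted),
            class = "by_outcome")
}

#' Single-dataset screening stage
#'
#' McNemar test on every code present in at least one arm, BY correction at
#' level `q`, then the matched-OR > 1 filter.  Codes absent from both arms
#' are skipped (they would pollute the number of tests `m`) and counted in
#' the audit.
#'
#' @param x a `code_matrix`.
#' @param pairs matched patient table or [pair_index()].
#' @param q FDR level.
#' @param exact_threshold passed to [mcnemar_test()].
#' @return list with `results` (per-code data frame: counts, p, adjusted p,
#'   rejection, OR, retained), the `by_outcome`, `retained` code ids, and an
#'   `audit` count vector.
#' @export
mcnemar_screen <- function(x, pairs, q = 0.05, exact_threshold = 25L) {
  d <- discordant_table(x, pairs)
  tested <- d$present
  res <- cbind(d, method = NA_character_, statistic = NA_real_,
               p_value = NA_real_, adjusted_p = NA_real_, rejected = FALSE,
               matched_or = NaN, retained = FALSE)
  by <- NULL
  if (any(tested)) {
    mc <- mcnemar_test(d$b[tested], d$c[tested],
                       exact_threshold = exact_threshold)
    by <- by_adjust(mc$p_value, q = q)
    res$method[tested] <- mc$method
    res$statistic[tested] <- mc$statistic
    res$p_value[tested] <- mc$p_value
    res$adjusted_p[tested] <- by$adjusted_p
    res$rejected[tested] <- by$rejected
    res$matched_or[tested] <- mc$matched_or
    res$retained <- res$rejected & !is.nan(res$matched_or) &
      res$matched_or > 1
  }
  audit <- c(n_codes = nrow(d), tested = sum(tested),
             skipped_absent = sum(!tested),
             by_rejected = sum(res$rejected), or_gt_1 = sum(
               res$rejected & !is.nan(res$matched_or) & res$matched_or > 1),
             retained = sum(res$retained))
  list(results = res, by = by, retained = res$code[res$retained],
       audit = audit)
}

#' Dual-dataset code screening
#'
#' Runs the single-dataset stage on the training and validation matrices
#' and retains the intersection: codes BY-significant with matched OR > 1
#' in both datasets.
#'
#' @param train,validation `code_matrix` objects sharing one code universe.
#' @param pairs matched patient table covering both datasets' patients (or a
#'   [pair_index()]); pairs are evaluated within the dataset that contains
#'   them.
#' @param q FDR level.
#' @param exact_threshold passed to [mcnemar_test()].
#' @return object of class `screen_report`: per-dataset stage results, the
#'   retained code set, and audit counts.
#' @export
screen_codes <- function(train, validation, pairs, q = 0.05,
                         exact_threshold = 25L) {
  if (!setequal(colnames(train), colnames(validation))) {
    diff <- union(setdiff(colnames(train), colnames(validation)),
                  setdiff(colnames(validation), colnames(train)))
    stop("training/validation code universes differ: ",
         paste(utils::head(diff, 10L), collapse = ", "))
  }
  pi <- if (all(c("case", "reference") %in% names(pairs))) pairs
        else pair_index(pairs)
  sub_pairs <- function(x) pi[pi$case %in% rownames(x) &
                                pi$reference %in% rownames(x), ]
  tr <- mcnemar_screen(train, sub_pairs(train), q, exact_threshold)
  va <- mcnemar_screen(validation, sub_pairs(validation), q, exact_threshold)
  retained <- intersect(tr$retained, va$retained)
  structure(list(training = tr, validation = va, retained = retained,
                 q = q,
                 audit = rbind(training = tr$audit, validation = va$audit)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("matched McNemar + BY screen (q =", x$q, ")\n")
  print(x$audit)
  cat("retained in both datasets:", length(x$retained), "codes\n")
  invisible(x)
}

#' Write a screen report as a delimited table
#'
#' One row per code and dataset with counts, p-values, matched OR, and
#' retention flags; the audit summary goes to a companion `.audit.csv`.
#'
#' @param report a `screen_report`.
#' @param path output CSV path.
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(report, path) {
  long <- rbind(cbind(dataset = "training", report$training$results),
                cbind(dataset = "validation", report$validation$results))
  long$retained_both <- long$code %in% report$retained
  utils::write.csv(long, path, row.names = FALSE)
  audit_path <- sub("\\.csv$", ".audit.csv", path)
  utils::write.csv(as.data.frame(report$audit), audit_path)
  invisible(c(path, audit_path))
}

#' False-discovery operating characteristics of the screening stage
#'
#' Simulates matched cohorts with a planted null + signal code structure
#' (signal codes are one-code factors with `q_on = 1`, `q_bg = 0`, so code
#' presence equals the latent activation and the matched odds ratio is
#' exactly `signal_or`), runs the McNemar test on every code and the BY
#' procedure at level `q`, and reports the per-replicate false-discovery
#' proportion: rejected null codes / max(1, total rejections).
#'
#' @param n_replicates number of simulated cohorts.
#' @param n_pairs matched pairs per cohort.
#' @param n_null,null_prevalence null codes at equal prevalence in both arms.
#' @param n_signal,signal_p_ref,signal_or planted signal block.
#' @param q FDR level.
#' @param exact_threshold passed to [mcnemar_test()].
#' @param seed integer; replicate r uses substream `seed * 10000 + r`.
#' @return list with `fdp` (per replicate), `mean_fdp`, `mean_power`
#'   (fraction of signal codes rejected), and the configuration.
#' @export
screening_fdr_study <- function(n_replicates = 200L, n_pairs = 2000L,
                                n_null = 500L, null_prevalence = 0.05,
                                n_signal = 50L, signal_p_ref = 0.10,
                                signal_or = 2, q = 0.05,
                                exact_threshold = 25L, seed = 1L) {
  bp <- lapply(seq_len(n_signal), function(j)
    factor_blueprint(sprintf("s%03d", j), sprintf("B%02d", j - 1L),
                     p_ref = signal_p_ref, target_or = signal_or,
                     q_on = 1, q_bg = 0))
  signal_ids <- vapply(bp, function(b) b$code_ids, character(1))
  fdp <- numeric(n_replicates)
  power <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_matched_codes(n_pairs, bp, n_noise_codes = n_null,
                                  noise_prevalence = null_prevalence,
                                  seed = seed * 10000L + r)
    b <- colSums(sim$case * (1L - sim$reference))
    cc <- colSums(sim$reference * (1L - sim$case))
    present <- colSums(sim$case) + colSums(sim$reference) > 0
    mc <- mcnemar_test(b[present], cc[present],
                       exact_threshold = exact_threshold)
    rej <- by_adjust(mc$p_value, q = q)$rejected
    codes <- colnames(sim$case)[present]
    is_null <- !(codes %in% signal_ids)
    fdp[r] <- sum(rej & is_null) / max(1, sum(rej))
    power[r] <- if (n_signal) sum(rej & !is_null) / n_signal else NA_real_
  }
  list(fdp = fdp, mean_fdp = mean(fdp), mean_power = mean(power),
       n_replicates = n_replicates, n_pairs = n_pairs, q = q, seed = seed)
}
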