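#' @title Matched-cohort data model and event-window machinery
#' @description Index-date derivation, event-window detection around the
#'   index date, binarization of diagnosis codes within the window, and
#'   pair-preserving dataset splitting for 1:1 matched case-reference
#'   cohorts.
#' @name cohort-model
NULL

#' Default case-defining diagnosis code prefixes (traumatic brain injury)
#'
#' The TBI case definition used for index-date derivation: skull/facial
#' fracture, optic-nerve and eye/orbit injuries, and intracranial injury
#' (S02.0, S02.1, S02.3, S02.7-S02.9, S04.0, S07.1, S06).  Prefixes are
#' matched after removing the decimal separator, so `"S06"` covers all S06.x
#' codes.
#'
#' @return character vector of code prefixes.
#' @export
tbi_case_codes <- function() {
  c("S020", "S021", "S023", "S027", "S028", "S029", "S040", "S071", "S06")
}

#' Construct an event window
#'
#' An inclusive window of integer day offsets around the index date.  Its
#' length is `days_before + days_after + 1` (so the canonical 30/30 window
#' spans 61 days).
#'
#' @param days_before,days_after non-negative integers.
#' @return an object of class `event_window`.
#' @export
event_window <- function(days_before, days_after) {
  stop_if_not_scalar_number(days_before, "days_before", lower = 0)
  stop_if_not_scalar_number(days_after, "days_after", lower = 0)
  structure(list(days_before = as.integer(days_before),
                 days_after = as.integer(days_after)),
            class = "event_window")
}

#' @export
length.event_window <- function(x) x$days_before + x$days_after + 1L

#' @export
print.event_window <- function(x, ...) {
  cat(sprintf("event window: -%d..+%d days around the index date (%d days)\n",
              x$days_before, x$days_after, length(x)))
  invisible(x)
}

#' Validate a matched patient table
#'
#' Checks the 1:1 matched design: every `pair_id` holds exactly one case and
#' one reference, and the two members agree on the matching covariates
#' (sex, age, rurality, income quintile).
#'
#' @param patients data frame with columns `patient_id`, `pair_id`,
#'   `cohort_arm` (`"case"`/`"reference"`), `sex` (`"F"`/`"M"`), `age`,
#'   `income_quintile`, `rural`, `index_date`.
#' @return the patient table, invisibly.
#' @export
validate_patients <- function(patients) {
  need <- c("patient_id", "pair_id", "cohort_arm", "sex", "age",
            "income_quintile", "rural", "index_date")
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("patient table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(patients$cohort_arm %in% c("case", "reference")))
    stop("cohort_arm must be 'case' or 'reference'")
  tab <- table(patients$pair_id, patients$cohort_arm)
  bad <- rownames(tab)[tab[, "case"] != 1L | tab[, "reference"] != 1L]
  if (length(bad))
    stop("pairs without exactly one case and one reference: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  for (v in c("sex", "age", "rural", "income_quintile")) {
    n_distinct <- tapply(patients[[v]], patients$pair_id,
                         function(z) length(unique(z)))
    if (any(n_distinct > 1L, na.rm = TRUE))
      stop("matching covariate '", v, "' differs within a pair")
  }
  invisible(patients)
}

#' Case/reference patient ids per pair
#'
#' @param patients matched patient table (see [validate_patients()]).
#' @return data frame with one row per pair: `pair_id`, `case`, `reference`.
#' @export
pair_index <- function(patients) {
  cs <- patients[patients$cohort_arm == "case", c("pair_id", "patient_id")]
  rf <- patients[patients$cohort_arm == "reference", c("pair_id", "patient_id")]
  m <- merge(cs, rf, by = "pair_id", suffixes = c("_case", "_ref"))
  if (nrow(m) != nrow(cs) || nrow(m) != nrow(rf))
    stop("incomplete pairs: every pair_id needs one case and one reference")
  data.frame(pair_id = m$pair_id, case = m$patient_id_case,
             reference = m$patient_id_ref, stringsAsFactors = FALSE)
}

#' Derive a patient's index date
#'
#' Cases anchor on their first visit carrying a case-defining code; reference
#' patients anchor on the midpoint of their visit span (floor of the average
#' of the earliest and latest visit dates, so an even span breaks ties
#' toward the earlier day).
#'
#' @param visits data frame of one patient's visits with columns
#'   `visit_date` and `code`.
#' @param arm `"case"` or `"reference"`.
#' @param case_codes code prefixes defining a case visit (matched after
#'   decimal-stripping); defaults to [tbi_case_codes()].
#' @return the index date (same class as `visit_date`).
#' @export
derive_index_date <- function(visits, arm = c("case", "reference"),
                              case_codes = tbi_case_codes()) {
  arm <- match.arg(arm)
  if (nrow(visits) == 0L) stop("patient has no visits")
  if (arm == "reference") {
    lo <- min(visits$visit_date)
    hi <- max(visits$visit_date)
    return(lo + floor(as.numeric(hi - lo) / 2))
  }
  flat <- gsub(".", "", toupper(visits$code), fixed = TRUE)
  hit <- Reduce(`|`, lapply(case_codes, function(p) startsWith(flat, p)))
  if (!any(hit)) {
    id <- if ("patient_id" %in% names(visits)) visits$patient_id[1L] else "<unknown>"
    stop("case patient ", id, " has no visit with a case-defining code")
  }
  min(visits$visit_date[hit])
}

#' Histogram of visit-day offsets around the index date
#'
#' Counts distinct (patient, day) visits at each integer offset from the
#' patient's index date, the input to [detect_event_window()].
#'
#' @param visits long visit table (`patient_id`, `visit_date`, `code`).
#' @param patients matched patient table supplying `index_date`.
#' @param span maximum absolute offset retained.
#' @return integer vector of counts named by offset, covering `-span..span`.
#' @export
offset_histogram <- function(visits, patients, span = 90L) {
  idx <- patients$index_date[match(visits$patient_id, patients$patient_id)]
  if (anyNA(idx)) stop("visits reference patients absent from the patient table")
  off <- as.integer(round(as.numeric(visits$visit_date - idx)))
  key <- !duplicated(paste(visits$patient_id, visits$visit_date))
  off <- off[key & abs(off) <= span]
  counts <- tabulate(off + span + 1L, nbins = 2L * span + 1L)
  names(counts) <- as.character(seq(-span, span))
  counts
}

#' Detect the event window around the index date
#'
#' Operationalizes the "stationary point" of the visit-offset histogram: the
#' baseline level is the median count over the outer third of the span (both
#' tails pooled) and its robust spread is `mad()` of the same counts.
#' Scanning outward from offset 0 on each side, the boundary is the first
#' offset whose (optionally smoothed) count lies within
#' `tolerance_k` robust deviations of the baseline *and* from which at least
#' `within_frac` of the remaining counts out to the span edge also lie
#' within that band.  The second condition makes the rule robust to the
#' sampling noise of real histograms without letting a single outlying day
#' drag the boundary to the edge of the span.
#'
#' @param counts integer histogram of visit counts named by integer offset
#'   (e.g. from [offset_histogram()]); must cover `-baseline_span..baseline_span`.
#' @param baseline_span maximum offset used; defaults to the largest offset
#'   covered on both sides.
#' @param tolerance_k half-width of the tolerance band in robust deviations.
#' @param smooth_days odd width of a centered moving average applied before
#'   scanning; the default 1 leaves counts raw, because smoothing widens a
#'   sharp stationary point by half the smoothing window.
#' @param within_frac minimum fraction of beyond-boundary counts that must
#'   sit inside the band.
#' @return an [event_window()].
#' @export
detect_event_window <- function(counts, baseline_span = NULL, tolerance_k = 2,
                                smooth_days = 1L, within_frac = 0.8) {
  off <- as.integer(names(counts))
  if (anyNA(off)) stop("`counts` must be named by integer offsets")
  counts <- counts[order(off)]
  off <- sort(off)
  span <- baseline_span %||% min(max(off), -min(off))
  if (span < 3L) stop("baseline span too short to estimate a baseline")
  if (min(off) > -span || max(off) < span)
    stop("histogram does not cover the baseline span on both sides of 0")
  keep <- off >= -span & off <= span
  off <- off[keep]; raw <- as.numeric(counts[keep])
  series <- raw
  if (smooth_days > 1L) {
    if (smooth_days %% 2L == 0L) stop("`smooth_days` must be odd")
    # edge-normalized moving average (mean of the available window)
    num <- stats::filter(raw, rep(1, smooth_days), sides = 2)
    den <- stats::filter(rep(1, length(raw)), rep(1, smooth_days), sides = 2)
    avail <- !is.na(num)
    series[avail] <- num[avail] / den[avail]
  }
  # the tolerance band comes from the *raw* outer-third counts: smoothing
  # shrinks and correlates the series, which biases a MAD taken on it
  outer <- abs(off) >= ceiling(2 * span / 3)
  base <- stats::median(raw[outer])
  dev <- stats::mad(raw[outer])
  in_band_raw <- abs(raw - base) <= tolerance_k * dev
  in_band_smooth <- abs(series - base) <= tolerance_k * dev
  scan_side <- function(direction) {
    side_off <- if (direction > 0) 0:span else 0:(-span)
    ix <- match(side_off, off)
    ok <- in_band_smooth[ix]
    n <- length(ok)
    # fraction of raw in-band counts from each position to the span edge
    okr <- in_band_raw[ix]
    frac_beyond <- rev(cumsum(rev(okr))) / rev(seq_len(n))
    hit <- which(ok & frac_beyond >= within_frac)
    if (!length(hit))
      stop("histogram never settles at baseline within the span; ",
           "widen `baseline_span`")
    abs(side_off[hit[1L]])
  }
  event_window(scan_side(-1L), scan_side(+1L))
}

#' Binarize diagnosis codes within the event window
#'
#' Builds the patients-by-codes binary matrix: cell `(p, c)` is 1 iff patient
#' `p` has at least one visit inside `[index - days_before, index + days_after]`
#' carrying a code whose three-character category is `c`.  Categories U98 and
#' U99 (provisional/temporary assignment codes) are dropped.  Patients with
#' no in-window visits keep an all-zero row.
#'
#' @param visits long visit table (`patient_id`, `visit_date`, `code`).
#' @param patients matched patient table supplying `index_date`.
#' @param window an [event_window()].
#' @param codes optional character vector fixing the code universe (columns);
#'   defaults to the categories observed in-window.
#' @param drop code categories excluded from the matrix.
#' @return integer 0/1 matrix of class `code_matrix` with patient ids as row
#'   names, code categories as column names, and the window as an attribute.
#' @export
binarize_codes <- function(visits, patients, window, codes = NULL,
                           drop = c("U98", "U99")) {
  stopifnot(inherits(window, "event_window"))
  idx <- patients$index_date[match(visits$patient_id, patients$patient_id)]
  if (anyNA(idx)) stop("visits reference patients absent from the patient table")
  off <- as.numeric(visits$visit_date - idx)
  inw <- off >= -window$days_before & off <= window$days_after
  cat3 <- normalize_codes(visits$code[inw])
  pid <- visits$patient_id[inw]
  keep <- !(cat3 %in% drop)
  cat3 <- cat3[keep]; pid <- pid[keep]
  universe <- sort(unique(codes %||% cat3))
  universe <- setdiff(universe, drop)
  m <- matrix(0L, nrow = nrow(patients), ncol = length(universe),
              dimnames = list(patients$patient_id, universe))
  use <- cat3 %in% universe
  if (any(use))
    m[cbind(match(pid[use], patients$patient_id),
            match(cat3[use], universe))] <- 1L
  structure(m, class = c("code_matrix", class(m)), window = window)
}

#' Split matched pairs into analysis datasets
#'
#' Random pair-level assignment into named partitions with largest-remainder
#' rounding of the target fractions, so realized sizes differ from the
#' rounded targets by at most one pair and both members of a pair always
#' share one assignment.
#'
#' @param pair_ids character vector of pair identifiers.
#' @param fractions named positive fractions summing to 1 (within 1e-9).
#' @param seed integer seed for the permutation.
#' @return object of class `dataset_split`: a named factor mapping pair_id
#'   to partition, with the fractions and seed as attributes.
#' @export
split_pairs <- function(pair_ids,
                        fractions = c(training = 0.5, validation = 0.25,
                                      testing = 0.25),
                        seed = 1L) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be positive and sum to 1")
  n <- length(pair_ids)
  if (n < length(fractions)) stop("fewer pairs than partitions")
  raw <- fractions * n
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- local_seed(seed, sample.int(n))
  lab <- rep(names(fractions), sizes)
  out <- factor(character(n), levels = names(fractions))
  out[perm] <- lab
  names(out) <- pair_ids
  structure(out, fractions = fractions, seed = seed,
            class = c("dataset_split", "factor"))
}
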