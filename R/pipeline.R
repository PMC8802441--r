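#' Run the full injury-event dissection pipeline
#'
#' Convenience wrapper chaining the modules end to end on a matched cohort:
#' event-window detection from the visit-offset histogram, pair-preserving
#' train/validation/test split, in-window code binarization, matched
#' McNemar + BY screening with dual-dataset retention, principal-component
#' factor construction at the loading cutoff, Haddon designation,
#' per-factor conditional logistic ORs, and the sex-correlation analysis
#' with FDR masking and Ward clustering.
#'
#' @param cohort an `injury_cohort` (tables from [generate_cohort()] /
#'   [read_fixture()] or equivalently shaped real data).
#' @param q FDR level used for screening and correlation masking.
#' @param window optional [event_window()]; detected from the histogram
#'   when `NULL`.
#' @param split_seed seed for [split_pairs()].
#' @param n_factors optional factor count; chosen by `criteria` when `NULL`.
#' @param criteria factor-count criteria for [choose_n_factors()].
#' @param cutoff loading cutoff for factor definitions.
#' @param map [haddon_map()] for designation.
#' @param fit_dataset partition used for the reported conditional-logistic
#'   ORs and the sex-correlation analysis.
#' @param case_codes case-defining code prefixes; their three-character
#'   categories are excluded from the screened universe (they are carried
#'   by construction in every case, so they would trivially dominate the
#'   screen and saturate any factor score containing them).
#' @return list with the window, split, screen report, factor model and
#'   definitions, designations, association table, sex-correlation mask,
#'   and Ward linkage trees.
#' @export
run_pipeline <- function(cohort, q = 0.05, window = NULL, split_seed = 1L,
                         n_factors = NULL,
                         criteria = c("kaiser", "scree_breakpoint"),
                         cutoff = 0.2, map = default_haddon_map(),
                         fit_dataset = "testing",
                         case_codes = tbi_case_codes()) {
  patients <- validate_patients(cohort$patients)
  visits <- cohort$visits
  if (is.null(window)) {
    hist <- offset_histogram(visits, patients)
    # empirical histograms are noisy; smooth before scanning for baseline
    window <- detect_event_window(hist, smooth_days = 7L)
  }
  pi <- pair_index(patients)
  split <- split_pairs(pi$pair_id, seed = split_seed)
  part_of <- function(part) {
    ids <- pi[split[pi$pair_id] == part, ]
    patients[patients$patient_id %in% c(ids$case, ids$reference), ]
  }
  # shared code universe across partitions, minus the case definition
  universe <- colnames(binarize_codes(visits, patients, window))
  universe <- setdiff(universe, unique(substr(case_codes, 1L, 3L)))
  mats <- lapply(c(training = "training", validation = "validation",
                   testing = "testing"), function(p) {
    pp <- part_of(p)
    binarize_codes(visits[visits$patient_id %in% pp$patient_id, ], pp,
                   window, codes = universe)
  })
  screen <- screen_codes(mats$training, mats$validation, pi, q = q)
  if (length(screen$retained) < 2L)
    stop("fewer than 2 codes retained; nothing to factor-analyze")

  x_train <- mats$training[, screen$retained, drop = FALSE]
  model <- fit_pca_factors(x_train)
  if (is.null(n_factors))
    n_factors <- choose_n_factors(model, criteria = criteria)$n_factors
  defs <- define_factors(model, n_factors, cutoff = cutoff)
  designations <- designate_factors(defs, map)

  fit_pat <- part_of(fit_dataset)
  x_fit <- binarize_codes(visits[visits$patient_id %in% fit_pat$patient_id, ],
                          fit_pat, window, codes = universe)
  scores <- score_patients(x_fit[, screen$retained, drop = FALSE], defs)
  covs <- data.frame(age = fit_pat$age, rural = as.numeric(fit_pat$rural),
                     income_quintile = fit_pat$income_quintile,
                     row.names = fit_pat$patient_id)
  fits <- associate_factors(scores, fit_pat, covariates = covs)

  case_scores <- function(sex) {
    ids <- fit_pat$patient_id[fit_pat$cohort_arm == "case" &
                                fit_pat$sex == sex]
    scores[ids, , drop = FALSE]
  }
  sexcorr <- NULL; trees <- NULL
  for (dummy in 1L) {
    cF <- tryCatch(phi_matrix(case_scores("F"), sex = "F"),
                   warning = function(w) suppressWarnings(
                     phi_matrix(case_scores("F"), sex = "F")))
    cM <- tryCatch(phi_matrix(case_scores("M"), sex = "M"),
                   warning = function(w) suppressWarnings(
                     phi_matrix(case_scores("M"), sex = "M")))
    if (ncol(cF) < 2L || ncol(cM) < 2L) break
    tests <- sex_corr_tests(cF, cM)
    sexcorr <- fdr_mask(tests, q = q)
    trees <- list(F = ward_linkage(correlation_distance(cF)),
                  M = ward_linkage(correlation_distance(cM)))
  }

  list(window = window, split = split, screen = screen, model = model,
       n_factors = n_factors, definitions = defs,
       designations = designations, association = fits,
       scores = scores, sex_correlation = sexcorr, trees = trees)
}
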