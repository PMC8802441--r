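#' @title Synthetic matched cohorts with planted ground truth
#' @description Generates 1:1 matched case-reference cohorts whose code
#'   occurrences follow a planted latent-factor block structure: each factor
#'   blueprint activates with a known case-vs-reference odds ratio, member
#'   codes are recorded conditionally on the activation, latent activations
#'   are correlated across factors through a Gaussian copula with sex-specific
#'   correlations, and visit dates peak at the index date.  Every downstream
#'   stage of the pipeline can therefore be tested against known truth
#'   without access-restricted health records.
#' @name synthetic-cohort
NULL

#' Define a latent factor blueprint
#'
#' A blueprint describes one planted phenotype: the codes that load on it,
#' the baseline probability of latent activation among reference patients,
#' the case-vs-reference odds ratio on the activation, and the emission
#' probabilities of member codes given activation (`q_on`) or not (`q_bg`).
#'
#' @param factor_id short identifier.
#' @param code_ids three-character code labels belonging to the factor.
#' @param p_ref baseline latent activation probability in references, in (0,1).
#' @param target_or case-vs-reference odds ratio for activation, > 0.  The
#'   case activation probability solves
#'   `logit(p_case) = logit(p_ref) + log(target_or)`.
#' @param q_on probability a member code is recorded given activation, (0,1].
#' @param q_bg probability a member code is recorded without activation,
#'   `[0, q_on)`.
#' @param haddon category labels from `{host, agent, environment}`.
#' @return object of class `factor_blueprint`.
#' @export
factor_blueprint <- function(factor_id, code_ids, p_ref, target_or,
                             q_on = 0.9, q_bg = 0.02, haddon = "host") {
  stop_if_not_scalar_number(p_ref, "p_ref", 0, 1, strict = TRUE)
  stop_if_not_scalar_number(target_or, "target_or", 0, Inf, strict = TRUE)
  stop_if_not_scalar_number(q_on, "q_on", 0, 1)
  stop_if_not_scalar_number(q_bg, "q_bg", 0, 1)
  if (q_on <= 0) stop("`q_on` must be positive")
  if (q_bg >= q_on) stop("`q_bg` must be < `q_on`")
  if (!length(code_ids)) stop("`code_ids` must be nonempty")
  if (!all(haddon %in% c("host", "agent", "environment")))
    stop("`haddon` categories must be host/agent/environment")
  structure(list(factor_id = as.character(factor_id),
                 code_ids = normalize_codes(code_ids),
                 p_ref = p_ref, target_or = target_or,
                 q_on = q_on, q_bg = q_bg, haddon = haddon),
            class = "factor_blueprint")
}

#' Case activation probability implied by a matched odds ratio
#'
#' `logit^-1(logit(p_ref) + log(or))`; e.g. `p_ref = 0.10, or = 2` gives
#' 2/11 = 0.1818...
#'
#' @param p_ref reference activation probability.
#' @param or target odds ratio.
#' @return case activation probability.
#' @export
case_activation_prob <- function(p_ref, or) {
  stats::plogis(stats::qlogis(p_ref) + log(or))
}

#' Visit-frequency shape around the index date
#'
#' Day `d` receives weight `baseline * (1 + (peak - 1) * max(0, 1 - |d|/decay))`:
#' a linear peak at the index date reaching baseline exactly at `+/-decay`
#' days, flat baseline beyond.  `peak = 1` (or `decay = 0`) is a flat shape.
#'
#' @param peak ratio of the day-0 rate to the baseline rate, >= 1.
#' @param decay days over which the peak decays to baseline.
#' @param span histogram half-width in days.
#' @param baseline baseline visit weight per day, > 0.
#' @return object of class `window_shape`.
#' @export
window_shape <- function(peak = 10, decay = 30L, span = 90L, baseline = 1) {
  stop_if_not_scalar_number(peak, "peak", 1, Inf)
  stop_if_not_scalar_number(decay, "decay", 0, Inf)
  stop_if_not_scalar_number(span, "span", 1, Inf)
  stop_if_not_scalar_number(baseline, "baseline", 0, Inf, strict = TRUE)
  structure(list(peak = peak, decay = as.integer(decay),
                 span = as.integer(span), baseline = baseline),
            class = "window_shape")
}

# Per-day sampling weights of a window_shape over -span..span.
shape_weights <- function(shape) {
  d <- seq(-shape$span, shape$span)
  excess <- if (shape$decay > 0) pmax(0, 1 - abs(d) / shape$decay) else 0
  w <- shape$baseline * (1 + (shape$peak - 1) * excess)
  names(w) <- as.character(d)
  w
}

#' Sample visit-day offsets relative to the index date
#'
#' @param n number of offsets to draw.
#' @param shape a [window_shape()].
#' @param seed optional integer seed (caller RNG state is preserved).
#' @return integer vector of day offsets in `-span..span`.
#' @export
generate_visit_offsets <- function(n, shape = window_shape(), seed = NULL) {
  stopifnot(inherits(shape, "window_shape"))
  w <- shape_weights(shape)
  draw <- function() sample(seq(-shape$span, shape$span), n,
                            replace = TRUE, prob = w)
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Assemble a simulation configuration
#'
#' The default configuration is the package's stated testing world: 2,000
#' pairs per sex, the illustrative blueprint set of [default_blueprints()],
#' 200 null noise codes at 5% prevalence in both arms, sex-specific latent
#' correlation targets from [default_correlation_targets()], and a visit
#' histogram peaking at 10x baseline and reaching baseline 30 days on each
#' side of the index date.
#'
#' @param n_pairs_by_sex named counts of pairs, e.g. `c(F = 2000, M = 2000)`.
#' @param blueprints list of [factor_blueprint()]s with disjoint code sets.
#' @param n_noise_codes number of null codes with equal prevalence in both arms.
#' @param noise_prevalence per-code null prevalence, in (0,1).
#' @param correlation_targets data frame with columns `f`, `g`, `rho_F`,
#'   `rho_M`: target correlations of the latent Gaussian activations.
#' @param shape a [window_shape()].
#' @param mean_extra_visits Poisson mean of visits beyond the anchor visit.
#' @param seed integer master seed; fixed seed implies byte-identical output.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs_by_sex = c(F = 2000L, M = 2000L),
                              blueprints = default_blueprints(),
                              n_noise_codes = 200L,
                              noise_prevalence = 0.05,
                              correlation_targets = default_correlation_targets(),
                              shape = window_shape(),
                              mean_extra_visits = 3,
                              seed = 1L) {
  stopifnot(all(c("F", "M") %in% names(n_pairs_by_sex)))
  stop_if_not_scalar_number(noise_prevalence, "noise_prevalence", 0, 1,
                            strict = TRUE)
  ids <- vapply(blueprints, function(b) b$factor_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate blueprint factor_ids")
  all_codes <- unlist(lapply(blueprints, function(b) b$code_ids))
  if (anyDuplicated(all_codes))
    stop("blueprint code sets must be disjoint; duplicated: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  if (!is.null(correlation_targets) && nrow(correlation_targets)) {
    unknown <- setdiff(c(correlation_targets$f, correlation_targets$g), ids)
    if (length(unknown))
      stop("correlation targets reference undeclared factors: ",
           paste(unknown, collapse = ", "))
    rho <- c(correlation_targets$rho_F, correlation_targets$rho_M)
    if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  }
  structure(list(n_pairs_by_sex = n_pairs_by_sex, blueprints = blueprints,
                 n_noise_codes = as.integer(n_noise_codes),
                 noise_prevalence = noise_prevalence,
                 correlation_targets = correlation_targets,
                 shape = shape, mean_extra_visits = mean_extra_visits,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Illustrative default blueprints
#'
#' Six phenotypes mirroring archetypes seen in injury-event factor analyses:
#' falls-and-syncope (host/agent), cardiometabolic disease (host), transport
#' collisions (agent), assault-and-alcohol (host/agent), abuse (environment),
#' and geriatric emergencies (host).  Odds ratios span 1.5-5, reference
#' activation 5-15%, with code emission q_on = 0.9 / q_bg = 0.02.
#'
#' @return list of [factor_blueprint()]s.
#' @export
default_blueprints <- function() {
  list(
    factor_blueprint("falls_syncope", c("W19", "W18", "R55", "R26"),
                     p_ref = 0.15, target_or = 2.0,
                     haddon = c("host", "agent")),
    factor_blueprint("cardiometabolic", c("I10", "E11", "E78", "I48"),
                     p_ref = 0.12, target_or = 1.5, haddon = "host"),
    factor_blueprint("transport", c("V43", "V47", "V29"),
                     p_ref = 0.05, target_or = 3.0, haddon = "agent"),
    factor_blueprint("assault_alcohol", c("X99", "Y04", "F10"),
                     p_ref = 0.05, target_or = 4.0,
                     haddon = c("host", "agent")),
    factor_blueprint("abuse", c("T74", "Y07"),
                     p_ref = 0.02, target_or = 5.0, haddon = "environment"),
    factor_blueprint("geriatric", c("N39", "E87", "F05"),
                     p_ref = 0.10, target_or = 1.8, haddon = "host")
  )
}

#' Default sex-specific latent correlation targets
#'
#' Falls-and-syncope vs cardiometabolic disease is planted with a strong
#' female and weak male latent correlation (0.6 vs 0.1), the pattern the
#' sex-difference test is designed to detect; transport vs assault-alcohol
#' carries a moderate male-dominant correlation.
#'
#' @return data frame with columns `f`, `g`, `rho_F`, `rho_M`.
#' @export
default_correlation_targets <- function() {
  data.frame(f = c("falls_syncope", "transport"),
             g = c("cardiometabolic", "assault_alcohol"),
             rho_F = c(0.6, 0.1), rho_M = c(0.1, 0.4),
             stringsAsFactors = FALSE)
}

# Latent Gaussian correlation matrix for one sex; errors (naming the pairs)
# when the assembled matrix is not positive definite.
latent_corr_matrix <- function(blueprints, targets, sex = c("F", "M")) {
  sex <- match.arg(sex)
  ids <- vapply(blueprints, function(b) b$factor_id, character(1))
  R <- diag(length(ids))
  dimnames(R) <- list(ids, ids)
  if (!is.null(targets) && nrow(targets)) {
    col <- paste0("rho_", sex)
    for (i in seq_len(nrow(targets))) {
      R[targets$f[i], targets$g[i]] <- targets[[col]][i]
      R[targets$g[i], targets$f[i]] <- targets[[col]][i]
    }
  }
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) {
    prs <- if (!is.null(targets) && nrow(targets))
      paste(sprintf("(%s,%s)", targets$f, targets$g), collapse = ", ")
    else "<none>"
    stop("infeasible correlation targets for sex ", sex,
         ": latent correlation matrix is not positive definite; ",
         "targets involved: ", prs)
  }
  R
}

# Draw n x k correlated standard normals given a correlation matrix.
correlated_normals <- function(n, R) {
  matrix(stats::rnorm(n * ncol(R)), n, ncol(R)) %*% chol(R)
}

#' Simulate matched binary code occurrences for one stratum
#'
#' The engine under [generate_cohort()], exposed so that screening-stage
#' operating characteristics (e.g. the false-discovery proportion of the
#' McNemar + BY stage) can be studied replicate-by-replicate without paying
#' for visit-table construction.  Latent activations are drawn by
#' thresholding correlated Gaussians at the activation quantile (cases at
#' the odds-ratio-shifted probability), member codes are emitted with
#' probability `q_on` given activation and `q_bg` otherwise, and noise codes
#' are i.i.d. at `noise_prevalence` in both arms.
#'
#' @param n_pairs number of matched pairs.
#' @param blueprints list of [factor_blueprint()]s.
#' @param n_noise_codes,noise_prevalence null-code block.
#' @param rho latent correlation matrix over blueprints (default identity).
#' @param noise_code_ids optional labels for the noise codes.
#' @param seed optional integer seed.
#' @return list with 0/1 matrices `case` and `reference`
#'   (`n_pairs` x codes), the latent activation matrices `active_case` /
#'   `active_reference`, and the raw case latent normals `normals_case`.
#' @export
simulate_matched_codes <- function(n_pairs, blueprints,
                                   n_noise_codes = 0L, noise_prevalence = 0.05,
                                   rho = NULL, noise_code_ids = NULL,
                                   seed = NULL) {
  run <- function() {
    k <- length(blueprints)
    ids <- vapply(blueprints, function(b) b$factor_id, character(1))
    R <- rho %||% diag(max(k, 1L))
    p_ref <- vapply(blueprints, function(b) b$p_ref, numeric(1))
    p_case <- mapply(case_activation_prob, p_ref,
                     vapply(blueprints, function(b) b$target_or, numeric(1)))
    act <- function(p) {
      if (!k) return(matrix(0L, n_pairs, 0L))
      z <- correlated_normals(n_pairs, R)
      a <- sweep(z, 2L, stats::qnorm(1 - p), `>`) * 1L
      attr(a, "normals") <- z
      a
    }
    a_case <- act(p_case)
    a_ref <- act(p_ref)
    emit <- function(active) {
      cols <- lapply(seq_len(k), function(j) {
        b <- blueprints[[j]]
        on <- active[, j] == 1L
        sapply(b$code_ids, function(code) {
          x <- integer(n_pairs)
          x[on] <- stats::rbinom(sum(on), 1L, b$q_on)
          if (b$q_bg > 0)
            x[!on] <- stats::rbinom(sum(!on), 1L, b$q_bg)
          x
        })
      })
      if (length(cols)) do.call(cbind, cols) else matrix(0L, n_pairs, 0L)
    }
    x_case <- emit(a_case)
    x_ref <- emit(a_ref)
    if (n_noise_codes > 0L) {
      noise_ids <- noise_code_ids %||% noise_code_pool(
        n_noise_codes, exclude = unlist(lapply(blueprints, `[[`, "code_ids")))
      nz <- function() matrix(stats::rbinom(n_pairs * n_noise_codes, 1L,
                                            noise_prevalence),
                              n_pairs, n_noise_codes,
                              dimnames = list(NULL, noise_ids))
      x_case <- cbind(x_case, nz())
      x_ref <- cbind(x_ref, nz())
    }
    dimnames(a_case) <- dimnames(a_ref) <- list(NULL, ids)
    list(case = x_case, reference = x_ref,
         active_case = a_case, active_reference = a_ref,
         normals_case = attr(a_case, "normals"))
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

# Deterministic pool of plausible null code labels, avoiding the excluded
# provisional categories (U98/U99), case-defining S-codes, and blueprint codes.
noise_code_pool <- function(n, exclude = character()) {
  letters_ok <- setdiff(LETTERS, c("U", "S"))
  pool <- as.vector(outer(letters_ok, sprintf("%02d", 0:99), paste0))
  pool <- setdiff(pool, exclude)
  if (n > length(pool)) stop("too many noise codes requested")
  pool[seq_len(n)]
}

#' Generate a matched case-reference cohort with ground truth
#'
#' Produces the patient table, the long visit table, and a ground-truth
#' record.  Matching covariates are drawn once per pair and copied to both
#' members (exact matching on sex, age, rurality, and income quintile); age
#' comes from a young/old two-component mixture so that age-structured
#' factors can be planted.  Every patient gets an anchor visit on the index
#' date (cases carry the concussion code S06.0 there) plus a Poisson number
#' of extra visits at offsets drawn from the configured window shape;
#' planted and noise codes are attached to in-window visits.  The master
#' seed is split into fixed per-stage substreams so each table is
#' individually reproducible.
#'
#' @param config a [simulation_config()].
#' @return object of class `injury_cohort`: list with `patients`, `visits`,
#'   `truth` (class `ground_truth`), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  bp <- config$blueprints
  ids <- vapply(bp, function(b) b$factor_id, character(1))
  sexes <- c("F", "M")
  seed0 <- config$seed %% 536870912L  # keep substream seeds < 2^31

  patients_l <- list(); visits_l <- list(); active_l <- list()
  code_cols <- NULL
  for (s_i in seq_along(sexes)) {
    sex <- sexes[s_i]
    n <- as.integer(config$n_pairs_by_sex[[sex]])
    if (n <= 0L) next
    rho <- latent_corr_matrix(bp, config$correlation_targets, sex)
    sim <- simulate_matched_codes(
      n, bp, config$n_noise_codes, config$noise_prevalence, rho = rho,
      seed = seed0 + 1000L * s_i)
    code_cols <- colnames(sim$case)

    cov <- local_seed(seed0 + 1000L * s_i + 1L, {
      old <- stats::runif(n) < 0.4
      age <- ifelse(old, stats::rnorm(n, 75, 8), stats::rnorm(n, 30, 12))
      data.frame(
        age = round(pmin(pmax(age, 0), 105), 1),
        income_quintile = sample(1:5, n, replace = TRUE),
        rural = stats::runif(n) < 0.15,
        index_date = as.Date("2008-01-01") +
          sample.int(2900L, n, replace = TRUE),
        severity = sample(c("unspecified", "mild", "moderate", "severe"),
                          n, replace = TRUE,
                          prob = c(0.43, 0.35, 0.04, 0.18)))
    })

    pair_id <- sprintf("%s%05d", sex, seq_len(n))
    mk <- function(arm, tag) {
      data.frame(patient_id = paste0(pair_id, tag), pair_id = pair_id,
                 cohort_arm = arm, sex = sex, cov[c("age", "income_quintile",
                                                    "rural", "index_date")],
                 severity = if (arm == "case") cov$severity else NA_character_,
                 stringsAsFactors = FALSE)
    }
    pts <- rbind(mk("case", "C"), mk("reference", "R"))
    patients_l[[sex]] <- pts
    active_l[[sex]] <- list(case = sim$active_case,
                            reference = sim$active_reference,
                            normals_case = sim$normals_case,
                            pair_id = pair_id)

    visits_l[[sex]] <- local_seed(seed0 + 1000L * s_i + 2L, {
      build_visits(pts, rbind(sim$case, sim$reference), config)
    })
  }
  patients <- do.call(rbind, patients_l)
  visits <- do.call(rbind, visits_l)
  rownames(patients) <- rownames(visits) <- NULL

  truth <- structure(list(
    signal_code_ids = sort(unlist(lapply(bp, `[[`, "code_ids"))),
    code_to_factor = stats::setNames(
      rep(ids, vapply(bp, function(b) length(b$code_ids), integer(1))),
      unlist(lapply(bp, `[[`, "code_ids"))),
    factor_or = stats::setNames(vapply(bp, function(b) b$target_or,
                                       numeric(1)), ids),
    factor_p_ref = stats::setNames(vapply(bp, function(b) b$p_ref,
                                          numeric(1)), ids),
    factor_haddon = stats::setNames(lapply(bp, `[[`, "haddon"), ids),
    pair_rho_by_sex = config$correlation_targets,
    noise_code_ids = setdiff(code_cols,
                             unlist(lapply(bp, `[[`, "code_ids"))),
    seed = config$seed), class = "ground_truth")

  structure(list(patients = patients, visits = visits, truth = truth,
                 config = config, activations = active_l),
            class = "injury_cohort")
}

# Visit-table construction for one sex block: anchor visit at offset 0 (cases
# carry S060 there), Poisson extra visits at shape-drawn offsets, and all
# recorded codes attached to uniformly chosen in-window visits.
build_visits <- function(pts, code_mat, config) {
  n <- nrow(pts)
  shape <- config$shape
  extra <- stats::rpois(n, config$mean_extra_visits)
  offs <- lapply(seq_len(n), function(i) {
    o <- if (extra[i] > 0)
      sample(seq(-shape$span, shape$span), extra[i], replace = TRUE,
             prob = shape_weights(shape))
    else integer(0)
    sort(unique(c(0L, o)))
  })
  win <- if (shape$decay > 0) shape$decay else shape$span
  pid_l <- vector("list", n); off_l <- vector("list", n)
  code_l <- vector("list", n)
  for (i in seq_len(n)) {
    o <- offs[[i]]
    inw <- o[abs(o) <= win]
    codes_i <- colnames(code_mat)[code_mat[i, ] == 1L]
    v_code <- character(0); v_off <- integer(0)
    if (pts$cohort_arm[i] == "case") { v_code <- "S060"; v_off <- 0L }
    if (length(codes_i)) {
      at <- inw[sample.int(length(inw), length(codes_i), replace = TRUE)]
      v_code <- c(v_code, codes_i); v_off <- c(v_off, at)
    }
    # anchor/extra visits with no planted code carry a filler encounter code
    bare <- setdiff(o, unique(v_off))
    if (length(bare)) { v_code <- c(v_code, rep("Z76", length(bare)))
                        v_off <- c(v_off, bare) }
    pid_l[[i]] <- rep(pts$patient_id[i], length(v_off))
    off_l[[i]] <- pts$index_date[i] + v_off
    code_l[[i]] <- v_code
  }
  out <- data.frame(patient_id = unlist(pid_l),
                    visit_date = as.Date(unlist(off_l),
                                         origin = "1970-01-01"),
                    code = unlist(code_l), stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$visit_date, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort fixture to delimited text files
#'
#' Writes `patients.csv`, `visits.csv` (comma-separated, header row) and
#' `ground_truth.json`; the fixture round-trips losslessly through
#' [read_fixture()].
#'
#' @param cohort an `injury_cohort` from [generate_cohort()].
#' @param dir writable directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "injury_cohort"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", dir)
  paths <- file.path(dir, c("patients.csv", "visits.csv", "ground_truth.json"))
  tryCatch({
    utils::write.csv(cohort$patients, paths[1L], row.names = FALSE)
    utils::write.csv(cohort$visits, paths[2L], row.names = FALSE)
    tr <- cohort$truth
    tr$factor_haddon <- lapply(tr$factor_haddon, as.list)
    # named atomic vectors lose names as JSON arrays; keep them as objects
    for (f in c("code_to_factor", "factor_or", "factor_p_ref"))
      tr[[f]] <- as.list(tr[[f]])
    jsonlite::write_json(unclass(tr), paths[3L], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = function(e) stop("failed writing fixture under ", dir, ": ",
                              conditionMessage(e)))
  invisible(paths)
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param dir directory containing `patients.csv`, `visits.csv`, and
#'   (optionally) `ground_truth.json`.
#' @return an `injury_cohort` (without the generator's internal activation
#'   record).
#' @export
read_fixture <- function(dir) {
  pf <- file.path(dir, "patients.csv")
  vf <- file.path(dir, "visits.csv")
  if (!file.exists(pf) || !file.exists(vf))
    stop("fixture directory ", dir, " is missing patients.csv/visits.csv")
  patients <- utils::read.csv(pf, stringsAsFactors = FALSE,
                              colClasses = c(index_date = "Date"))
  visits <- utils::read.csv(vf, stringsAsFactors = FALSE,
                            colClasses = c(visit_date = "Date"))
  gt <- file.path(dir, "ground_truth.json")
  truth <- NULL
  if (file.exists(gt)) {
    truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
    truth$code_to_factor <- unlist(truth$code_to_factor)
    truth$factor_or <- unlist(truth$factor_or)
    truth$factor_p_ref <- unlist(truth$factor_p_ref)
    class(truth) <- "ground_truth"
  }
  structure(list(patients = patients, visits = visits, truth = truth),
            class = "injury_cohort")
}
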