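#' @title Factor construction by the principal-components method
#' @description Eigendecomposition of the retained codes' Pearson
#'   correlation matrix, factor-count selection (Kaiser, scree breakpoint,
#'   cumulative variance, matched-AUC loop), factor definitions at a
#'   loading cutoff, and binary any-of factor scoring.
#' @name factor-construction
NULL

#' Fit principal-component factors to binary codes
#'
#' Decomposes the code-by-code Pearson correlation matrix (for 0/1 columns
#' this is the phi-coefficient matrix); loadings are eigenvector columns
#' scaled by the square root of their eigenvalue, ordered by descending
#' eigenvalue, with each column's largest-magnitude loading made positive.
#' No rotation is applied by default; `rotate = "varimax"` is available.
#'
#' @param x `code_matrix` restricted to the retained codes (or any numeric
#'   matrix with named columns).
#' @param n_factors optional number of loading columns to keep; eigenvalues
#'   are always reported in full.
#' @param rotate `"none"` (default) or `"varimax"` (applied to the kept
#'   columns).
#' @return object of class `factor_model`: `code_ids`, `eigenvalues`,
#'   `loadings`, `cum_var`.
#' @export
fit_pca_factors <- function(x, n_factors = NULL, rotate = c("none", "varimax")) {
  rotate <- match.arg(rotate)
  if (ncol(x) < 2L) stop("need at least 2 codes")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance code columns: ",
         paste(colnames(x)[v == 0], collapse = ", "))
  C <- stats::cor(x)
  ee <- eigen(C, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  L <- ee$vectors %*% diag(sqrt(ev), nrow = length(ev))
  # sign convention: dominant loading of each factor is positive
  flip <- apply(L, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  L <- sweep(L, 2L, flip, `*`)
  dimnames(L) <- list(colnames(x), sprintf("F%02d", seq_len(ncol(L))))
  if (!is.null(n_factors)) {
    if (n_factors > ncol(L)) stop("n_factors exceeds available components")
    L <- L[, seq_len(n_factors), drop = FALSE]
    if (rotate == "varimax" && n_factors > 1L) {
      L <- stats::varimax(L)$loadings[, , drop = FALSE]
      class(L) <- NULL
    }
  }
  structure(list(code_ids = colnames(x),
                 eigenvalues = ee$values,
                 loadings = L,
                 cum_var = cumsum(ee$values) / length(ee$values)),
            class = "factor_model")
}

#' Choose the number of factors
#'
#' Combines up to four criteria: `kaiser` (eigenvalues > 1),
#' `scree_breakpoint` (position of the largest second difference of the
#' eigenvalue sequence), `cumulative_variance` (smallest count reaching
#' `cum_var_target`), and `auc_loop` (count of leading factors maximizing
#' the matched-concordance AUC of a joint conditional-logistic fit on their
#' binary scores).  The final answer is the configured combiner of the
#' invoked criteria (default: median, rounded up).
#'
#' @param model a [factor_model][fit_pca_factors()] fitted with the maximal
#'   factor count.
#' @param criteria subset of
#'   `c("kaiser", "scree_breakpoint", "cumulative_variance", "auc_loop")`.
#' @param cum_var_target proportion of variance for `cumulative_variance`.
#' @param x,pairs code matrix and matched patient table (or [pair_index()]),
#'   required by `auc_loop`.
#' @param cutoff loading cutoff used when scoring inside `auc_loop`.
#' @param max_factors cap for the `auc_loop` search.
#' @param combine function reducing the per-criterion counts.
#' @return list with the per-criterion counts (`report`) and the combined
#'   `n_factors`.
#' @export
choose_n_factors <- function(model,
                             criteria = c("kaiser", "scree_breakpoint"),
                             cum_var_target = 0.8, x = NULL, pairs = NULL,
                             cutoff = 0.2, max_factors = NULL,
                             combine = function(v) ceiling(stats::median(v))) {
  criteria <- match.arg(criteria, c("kaiser", "scree_breakpoint",
                                    "cumulative_variance", "auc_loop"),
                        several.ok = TRUE)
  ev <- model$eigenvalues
  report <- list()
  if ("kaiser" %in% criteria)
    report$kaiser <- max(1L, sum(ev > 1))
  if ("scree_breakpoint" %in% criteria) {
    if (length(ev) < 3L) report$scree_breakpoint <- 1L
    else {
      d2 <- ev[seq_len(length(ev) - 2L)] - 2 * ev[seq(2L, length(ev) - 1L)] +
        ev[seq(3L, length(ev))]
      report$scree_breakpoint <- which.max(d2)
    }
  }
  if ("cumulative_variance" %in% criteria)
    report$cumulative_variance <- which(model$cum_var >= cum_var_target)[1L]
  if ("auc_loop" %in% criteria) {
    if (is.null(x) || is.null(pairs))
      stop("auc_loop requires the code matrix `x` and `pairs`")
    kmax <- min(max_factors %||% ncol(model$loadings), ncol(model$loadings))
    aucs <- vapply(seq_len(kmax), function(k) {
      defs <- suppressWarnings(define_factors(model, k, cutoff = cutoff))
      if (!length(defs)) return(0.5)
      sc <- score_patients(x, defs)
      fit <- fit_conditional_logit(sc, pairs)
      matched_auc(fit$linear_predictor, pairs)
    }, numeric(1))
    report$auc_loop <- which.max(aucs)
    attr(report$auc_loop, "auc") <- aucs
  }
  list(report = report,
       n_factors = as.integer(combine(unlist(report))))
}

#' Define factors at a loading cutoff
#'
#' A code joins every factor on which its absolute loading meets the cutoff
#' (multi-membership allowed); codes meeting no factor are reported in the
#' `unassigned` attribute, and empty factors are dropped with a warning.
#'
#' @param model a `factor_model`.
#' @param n_factors leading factors to define.
#' @param cutoff absolute-loading threshold in (0, 1); the conventional
#'   value is 0.2.
#' @param labels optional character labels (default: top-3 member codes).
#' @param dedupe drop factors whose code set duplicates an earlier factor's
#'   (with a warning).  Near-degenerate eigenvalue pairs routinely produce
#'   component pairs that select the same codes; the duplicates carry no
#'   additional phenotype and usually signal over-extraction.
#' @return list of `factor_definition` objects (`factor_id`, `label`,
#'   `code_ids`, `cutoff_used`), with attribute `unassigned`.
#' @export
define_factors <- function(model, n_factors, cutoff = 0.2, labels = NULL,
                           dedupe = TRUE) {
  stop_if_not_scalar_number(cutoff, "cutoff", 0, 1, strict = TRUE)
  if (n_factors > ncol(model$loadings))
    stop("n_factors exceeds the fitted loading columns")
  L <- model$loadings[, seq_len(n_factors), drop = FALSE]
  defs <- lapply(seq_len(n_factors), function(j) {
    members <- rownames(L)[abs(L[, j]) >= cutoff]
    structure(list(factor_id = colnames(L)[j],
                   label = if (!is.null(labels)) labels[j] else
                     paste(utils::head(members[order(-abs(L[members, j]))], 3L),
                           collapse = "+"),
                   code_ids = members,
                   loadings = L[members, j],
                   cutoff_used = cutoff),
              class = "factor_definition")
  })
  empty <- vapply(defs, function(d) length(d$code_ids) == 0L, logical(1))
  if (any(empty))
    warning("dropping empty factors: ",
            paste(vapply(defs[empty], `[[`, character(1), "factor_id"),
                  collapse = ", "))
  defs <- defs[!empty]
  if (dedupe && length(defs) > 1L) {
    keysets <- vapply(defs, function(d) paste(sort(d$code_ids),
                                              collapse = "|"), character(1))
    dup <- duplicated(keysets)
    if (any(dup)) {
      warning("dropping factors duplicating an earlier code set ",
              "(over-extraction): ",
              paste(vapply(defs[dup], `[[`, character(1), "factor_id"),
                    collapse = ", "))
      defs <- defs[!dup]
    }
  }
  assigned <- unique(unlist(lapply(defs, `[[`, "code_ids")))
  structure(defs, unassigned = setdiff(rownames(L), assigned))
}

#' Binary factor-based scores
#'
#' A patient scores 1 on a factor iff they carry at least one code in the
#' factor's definition, else 0.
#'
#' @param x `code_matrix` with the definitions' codes among its columns.
#' @param definitions list of `factor_definition`s.
#' @return 0/1 matrix (patients x factors) of class `factor_scores`.
#' @export
score_patients <- function(x, definitions) {
  unknown <- setdiff(unlist(lapply(definitions, `[[`, "code_ids")),
                     colnames(x))
  if (length(unknown))
    stop("definitions reference codes absent from the matrix: ",
         paste(unknown, collapse = ", "))
  s <- vapply(definitions, function(d) {
    as.integer(rowSums(x[, d$code_ids, drop = FALSE]) > 0)
  }, integer(nrow(x)))
  dimnames(s) <- list(rownames(x),
                      vapply(definitions, `[[`, character(1), "factor_id"))
  structure(s, class = c("factor_scores", class(s)))
}

#' Persist a factor model as two delimited tables
#'
#' @param model a `factor_model`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths of `eigenvalues.csv` and `loadings.csv`.
#' @export
write_factor_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "eigenvalues.csv")
  p2 <- file.path(dir, "loadings.csv")
  utils::write.csv(data.frame(component = seq_along(model$eigenvalues),
                              eigenvalue = model$eigenvalues,
                              cum_var = model$cum_var),
                   p1, row.names = FALSE)
  utils::write.csv(data.frame(code = rownames(model$loadings),
                              model$loadings, check.names = FALSE),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
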