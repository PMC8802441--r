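#' @title Factor clustering, cause/severity association maps, and exports
#' @description Ward-linkage hierarchical clustering of factors on
#'   correlation-based distance (d = 1 - r), external-cause and severity
#'   association matrices with sex-difference masking, word-cloud weight
#'   tables, and numeric heatmap exports ordered by the dendrogram.
#' @name structure-viz
NULL

#' Correlation-based distance
#'
#' `d(f, g) = 1 - r(f, g)`: zero diagonal, symmetric, the simplest reading
#' of a correlation-based distance (the chord alternative
#' `sqrt(2 (1 - r))` is a monotone transform and yields the same Ward merge
#' order on tight clusters).
#'
#' @param corr correlation matrix.
#' @return distance matrix with zero diagonal.
#' @export
correlation_distance <- function(corr) {
  d <- 1 - unclass(corr)
  diag(d) <- 0
  d
}

#' Ward-linkage agglomerative clustering
#'
#' Ward (minimum variance) merges on a precomputed distance matrix through
#' the Lance-Williams recurrence applied to the distances as supplied (the
#' "ward.D" convention, the common practice with correlation distances).
#' Merge heights are monotone non-decreasing.
#'
#' @param d symmetric distance matrix (zero diagonal) or `dist` object with
#'   at least 2 items.
#' @return object of class `linkage_tree`: `merge`, `height`, `order`
#'   (dendrogram leaf order), `labels`, and the underlying `hclust`.
#' @export
ward_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(d, method = "ward.D")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "linkage_tree")
}

#' Cut a linkage tree into k clusters
#'
#' @param tree a `linkage_tree`.
#' @param k number of clusters.
#' @return named integer cluster assignments.
#' @export
cut_linkage <- function(tree, k) {
  stats::cutree(tree$hclust, k = k)
}

#' Default external-cause code ranges
#'
#' Illustrative CDC-style mechanism ranges over 3-character external-cause
#' categories: falls W00-W19; struck by/against W20-W22 and W50-W52;
#' motor-vehicle collision V02-V79 (land-transport subset); assault
#' X85-Y09.  Entirely editable; sports flags come from a separate
#' user-supplied activity code list.
#'
#' @return data frame with `flag`, `from`, `to` (inclusive 3-character
#'   range bounds, compared lexicographically).
#' @export
default_cause_lookup <- function() {
  data.frame(flag = c("falls", "struck", "struck", "mvc", "assault"),
             from = c("W00", "W20", "W50", "V02", "X85"),
             to   = c("W19", "W22", "W52", "V79", "Y09"),
             stringsAsFactors = FALSE)
}

#' Build per-patient external-cause profiles
#'
#' A mechanism flag is set iff any in-window visit carries a code in its
#' range; flags are not mutually exclusive.  External-cause codes matching
#' no range (and not in `sports_codes`) set `other`.  Severity is taken
#' from the patient table's `severity` column when present.
#'
#' @param visits long visit table.
#' @param patients matched patient table (supplies `index_date` and,
#'   optionally, `severity`).
#' @param window an [event_window()].
#' @param cause_lookup range table as from [default_cause_lookup()].
#' @param sports_codes optional character vector of activity codes flagged
#'   as sports-related.
#' @return data frame keyed by `patient_id` with logical flags `falls`,
#'   `struck`, `mvc`, `assault`, `sports`, `other`, plus `severity`, `age`,
#'   `rural`, `income_quintile`, `sex`, `cohort_arm`.
#' @export
build_cause_profiles <- function(visits, patients, window,
                                 cause_lookup = default_cause_lookup(),
                                 sports_codes = character()) {
  stopifnot(inherits(window, "event_window"))
  idx <- patients$index_date[match(visits$patient_id, patients$patient_id)]
  off <- as.numeric(visits$visit_date - idx)
  inw <- off >= -window$days_before & off <= window$days_after
  code3 <- normalize_codes(visits$code[inw])
  pid <- visits$patient_id[inw]
  external <- grepl("^[VWXY]", code3)
  flags <- unique(cause_lookup$flag)
  prof <- data.frame(patient_id = patients$patient_id,
                     stringsAsFactors = FALSE)
  matched_any <- rep(FALSE, length(code3))
  for (f in flags) {
    rng <- cause_lookup[cause_lookup$flag == f, , drop = FALSE]
    hit <- rep(FALSE, length(code3))
    for (i in seq_len(nrow(rng)))
      hit <- hit | (code3 >= rng$from[i] & code3 <= rng$to[i])
    matched_any <- matched_any | hit
    prof[[f]] <- prof$patient_id %in% unique(pid[hit])
  }
  sports_hit <- code3 %in% normalize_codes(sports_codes, validate = FALSE)
  prof$sports <- prof$patient_id %in% unique(pid[sports_hit])
  other_hit <- external & !matched_any & !sports_hit
  prof$other <- prof$patient_id %in% unique(pid[other_hit])
  for (col in c("severity", "age", "rural", "income_quintile", "sex",
                "cohort_arm"))
    if (col %in% names(patients))
      prof[[col]] <- patients[[col]][match(prof$patient_id,
                                           patients$patient_id)]
  prof
}

#' Factor-by-cause/severity association matrix for one sex
#'
#' Pearson correlations between each factor score (plus age, rurality,
#' income quintile when available) and each external-cause flag and
#' severity indicator, among the supplied patients.  Constant indicators
#' are excluded with a warning.  The output feeds
#' [mask_correlation_difference()] for sex-difference maps.
#'
#' @param scores `factor_scores` for the patients of interest (typically
#'   one sex's cases).
#' @param profiles matching rows of [build_cause_profiles()].
#' @return list with the correlation matrix `r` (rows: factors+covariates,
#'   columns: cause/severity indicators) and `n`.
#' @export
cause_severity_matrix <- function(scores, profiles) {
  profiles <- profiles[match(rownames(scores), profiles$patient_id), ]
  left <- cbind(scores * 1.0)
  for (col in c("age", "rural", "income_quintile"))
    if (col %in% names(profiles)) left <- cbind(left, as.numeric(profiles[[col]]))
  colnames(left) <- c(colnames(scores),
                      intersect(c("age", "rural", "income_quintile"),
                                names(profiles)))
  right <- sapply(c("falls", "struck", "mvc", "assault", "sports", "other"),
                  function(f) as.numeric(profiles[[f]]))
  if ("severity" %in% names(profiles) && !all(is.na(profiles$severity))) {
    sev <- sapply(c("unspecified", "mild", "moderate", "severe"),
                  function(lev) as.numeric(profiles$severity == lev))
    right <- cbind(right, sev)
  }
  const <- apply(right, 2L, function(z) stats::var(z, na.rm = TRUE) == 0) |
    apply(right, 2L, anyNA)
  if (any(const)) {
    warning("excluding constant/NA indicators: ",
            paste(colnames(right)[const], collapse = ", "))
    right <- right[, !const, drop = FALSE]
  }
  keep_left <- apply(left, 2L, function(z) stats::var(z) > 0)
  if (!all(keep_left))
    warning("excluding constant variables: ",
            paste(colnames(left)[!keep_left], collapse = ", "))
  list(r = stats::cor(left[, keep_left, drop = FALSE], right),
       n = nrow(scores))
}

#' Mask a rectangular correlation difference between sexes
#'
#' Elementwise Fisher z-tests on two equally shaped correlation matrices:
#' within-sex tests of r = 0 and the between-sex difference test, each
#' BY-corrected as its own family; non-significant cells are zeroed.
#'
#' @param r_F,r_M correlation matrices of identical dimension.
#' @param n_F,n_M patient counts behind each matrix.
#' @param q FDR level.
#' @return list of masked matrices `F`, `M`, `diff` plus the long `tests`
#'   table.
#' @export
mask_correlation_difference <- function(r_F, n_F, r_M, n_M, q = 0.05) {
  stopifnot(all(dim(r_F) == dim(r_M)))
  rF <- clamp_r(as.numeric(r_F))
  rM <- clamp_r(as.numeric(r_M))
  tf <- z_single(as.numeric(rF), n_F)
  tm <- z_single(as.numeric(rM), n_M)
  td <- z_difference(as.numeric(rF), n_F, as.numeric(rM), n_M)
  sig <- lapply(list(F = tf$p, M = tm$p, diff = td$p),
                function(p) by_adjust(p, q = q)$rejected)
  shape <- function(v) matrix(v, nrow(r_F), ncol(r_F), dimnames = dimnames(r_F))
  list(F = shape(ifelse(sig$F, as.numeric(rF), 0)),
       M = shape(ifelse(sig$M, as.numeric(rM), 0)),
       diff = shape(ifelse(sig$diff, as.numeric(rF) - as.numeric(rM), 0)),
       tests = data.frame(row = rep(rownames(r_F), ncol(r_F)),
                          col = rep(colnames(r_F), each = nrow(r_F)),
                          r_F = as.numeric(rF), r_M = as.numeric(rM),
                          p_F = tf$p, p_M = tm$p, p_diff = td$p,
                          sig_F = sig$F, sig_M = sig$M, sig_diff = sig$diff,
                          stringsAsFactors = FALSE))
}

#' Word-cloud weight table
#'
#' Per-factor weights for word-cloud rendering: `proportion` is the mean
#' binary factor score among the supplied patients; `odds_ratio` takes the
#' fitted OR from an [associate_factors()] table.  Infinite ORs (from
#' separation) are capped at the largest finite weight and flagged.
#'
#' @param scores `factor_scores` for the patients of interest.
#' @param fits [associate_factors()] output (required for
#'   `weight_kind = "odds_ratio"`).
#' @param weight_kind `"proportion"` or `"odds_ratio"`.
#' @return data frame sorted by descending weight: `factor_id`, `weight`,
#'   `weight_kind`, `capped`.
#' @export
wordcloud_weights <- function(scores, fits = NULL,
                              weight_kind = c("proportion", "odds_ratio")) {
  weight_kind <- match.arg(weight_kind)
  if (weight_kind == "proportion") {
    w <- colMeans(scores)
    capped <- rep(FALSE, length(w))
    ids <- colnames(scores)
  } else {
    if (is.null(fits)) stop("odds_ratio weights require `fits`")
    miss <- setdiff(colnames(scores), fits$factor_id)
    if (length(miss)) stop("missing fits for factors: ",
                           paste(miss, collapse = ", "))
    ids <- colnames(scores)
    w <- fits$or[match(ids, fits$factor_id)]
    capped <- !is.finite(w)
    if (any(capped)) {
      cap <- max(w[is.finite(w)], 1)
      w[capped] <- cap
    }
  }
  out <- data.frame(factor_id = ids, weight = as.numeric(w),
                    weight_kind = weight_kind, capped = capped,
                    stringsAsFactors = FALSE)
  out[order(-out$weight), ]
}

#' Export a heatmap as ordered numeric tables
#'
#' Reorders rows/columns by the dendrogram leaf order of the supplied
#' trees (square matrices conventionally reuse one tree for both axes) and
#' writes the value matrix, the two order files, and the mask (when given)
#' as delimited text.  Image rendering is left to dedicated heatmap
#' packages; the numeric export is always written.
#'
#' @param m value matrix with row/column names.
#' @param tree_rows `linkage_tree` over the row ids.
#' @param tree_cols `linkage_tree` over the column ids (default: reuse
#'   `tree_rows`).
#' @param mask optional logical matrix marking cells to render neutral.
#' @param dir optional output directory; when `NULL` nothing is written.
#' @param prefix file-name prefix.
#' @return object of class `heatmap_export`: reordered `values`, `mask`,
#'   `row_order`, `col_order`, and written `paths` (if any).
#' @export
export_heatmap <- function(m, tree_rows, tree_cols = tree_rows, mask = NULL,
                           dir = NULL, prefix = "heatmap") {
  ro <- tree_rows$labels[tree_rows$order]
  co <- tree_cols$labels[tree_cols$order]
  if (!setequal(ro, rownames(m)) || !setequal(co, colnames(m)))
    stop("tree leaf sets do not match matrix row/column ids")
  vals <- m[ro, co, drop = FALSE]
  msk <- if (!is.null(mask)) mask[ro, co, drop = FALSE]
  paths <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(prefix, c("_values.csv", "_row_order.txt",
                                             "_col_order.txt", "_mask.csv")))
    utils::write.csv(vals, paths[1L])
    writeLines(ro, paths[2L])
    writeLines(co, paths[3L])
    if (!is.null(msk)) utils::write.csv(msk, paths[4L]) else
      paths <- paths[1:3]
  }
  structure(list(values = vals, mask = msk, row_order = ro, col_order = co,
                 paths = paths),
            class = "heatmap_export")
}
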