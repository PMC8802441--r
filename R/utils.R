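# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize ICD-10 code strings to three-character categories
#'
#' Removes a decimal separator if present, upper-cases, and truncates to the
#' first three characters (the diagnosis category shared with the WHO ICD-10
#' standard).
#'
#' @param codes character vector of ICD-10/ICD-10-CA codes (3-6 alphanumeric
#'   characters, optionally with a dot after the third).
#' @param validate error on strings that do not reduce to `[A-Z][0-9][0-9]`.
#' @return character vector of 3-character categories.
#' @export
normalize_codes <- function(codes, validate = TRUE) {
  out <- substr(gsub(".", "", toupper(as.character(codes)), fixed = TRUE), 1L, 3L)
  if (validate) {
    bad <- unique(codes[!grepl("^[A-Z][0-9]{2}$", out)])
    if (length(bad)) {
      stop("malformed ICD-10 code strings: ", paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
    }
  }
  out
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name))
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("`%s` = %s is outside %s%s, %s%s", name, format(x),
                 if (strict) "(" else "[", format(lower), format(upper),
                 if (strict) ")" else "]"))
  invisible(x)
}
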