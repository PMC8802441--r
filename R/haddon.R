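#' @title Haddon Matrix designation of factors
#' @description Designates each factor as host-, agent-, or
#'   environment-related (or a combination) by categorizing its member
#'   codes through an ordered prefix map.  Designation is domain judgment,
#'   not computation: the shipped default map is illustrative and fully
#'   editable.
#' @name haddon
NULL

#' Construct a Haddon prefix map
#'
#' An ordered list of (code-prefix, category) entries; the first matching
#' prefix wins and unmatched codes fall back to the default category, so
#' the map is total.
#'
#' @param prefix character vector of 1-3 character code prefixes.
#' @param category matching vector over `{host, agent, environment}`.
#' @param default category for unmatched codes.
#' @return data frame of class `haddon_map`.
#' @export
haddon_map <- function(prefix, category, default = "host") {
  cats <- c("host", "agent", "environment")
  if (!all(category %in% cats))
    stop("unknown Haddon category; use host/agent/environment")
  if (!default %in% cats) stop("unknown default category")
  if (any(nchar(prefix) < 1L | nchar(prefix) > 3L))
    stop("prefixes must be 1-3 characters")
  structure(data.frame(prefix = toupper(prefix), category = category,
                       stringsAsFactors = FALSE),
            default = default, class = c("haddon_map", "data.frame"))
}

#' Illustrative default Haddon map
#'
#' Disease and symptom chapters (A-R) map to host; transport, fall, and
#' strike external causes (V, W, X00-X59) to agent; maltreatment, assault,
#' care complications, and adverse social circumstances (T74, X85-Y09,
#' Y40-Y84, Z55-Z65) to environment.  Entries are ordered most-specific
#' first; ambiguous ranges (e.g. drug adversities Y40-Y59) are provisional
#' and meant to be edited.
#'
#' @return a [haddon_map()].
#' @export
default_haddon_map <- function() {
  env3 <- c("T74", sprintf("X%02d", 85:99), sprintf("Z%02d", 55:65),
            sprintf("Y8%d", 0:4))
  env2 <- c("Y0", "Y4", "Y5", "Y6", "Y7")
  agent2 <- sprintf("X%d", 0:5)
  agent1 <- c("V", "W")
  host1 <- LETTERS[1:18]  # chapters A..R
  haddon_map(prefix = c(env3, env2, agent2, agent1, host1),
             category = c(rep("environment", length(env3) + length(env2)),
                          rep("agent", length(agent2) + length(agent1)),
                          rep("host", length(host1))),
             default = "host")
}

# First-match categories for a vector of 3-character codes.
match_haddon <- function(codes, map) {
  vapply(codes, function(code) {
    hit <- which(startsWith(code, map$prefix))
    if (length(hit)) map$category[hit[1L]] else attr(map, "default")
  }, character(1))
}

#' Designate a factor on the Haddon Matrix
#'
#' Categorizes each member code through the map and renders the canonical
#' label for the category set: `H`, `A`, `E`, `H/A`, `H/E`, `A/E`, or
#' `H/A/E` (host before agent before environment).
#'
#' @param definition a `factor_definition` (or any list with nonempty
#'   `code_ids`).
#' @param map a [haddon_map()].
#' @return object of class `factor_designation`: `factor_id`, `categories`,
#'   `label`, and the per-code categories.
#' @export
designate_factor <- function(definition, map = default_haddon_map()) {
  codes <- definition$code_ids
  if (!length(codes)) stop("factor has no member codes")
  per_code <- match_haddon(normalize_codes(codes), map)
  cats <- c("host", "agent", "environment")
  present <- cats[cats %in% per_code]
  label <- paste(c(host = "H", agent = "A", environment = "E")[present],
                 collapse = "/")
  structure(list(factor_id = definition$factor_id %||% NA_character_,
                 categories = present, label = label,
                 code_categories = per_code),
            class = "factor_designation")
}

#' Designate a list of factors
#'
#' @param definitions list of `factor_definition`s.
#' @param map a [haddon_map()].
#' @return data frame with `factor_id`, `label`, and member categories.
#' @export
designate_factors <- function(definitions, map = default_haddon_map()) {
  rows <- lapply(definitions, function(d) {
    des <- designate_factor(d, map)
    data.frame(factor_id = des$factor_id, label = des$label,
               categories = paste(des$categories, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a Haddon map from a structured text file
#'
#' One `prefix: category` entry per line (order significant; `#` starts a
#' comment); an optional `default: <category>` line sets the fallback.
#'
#' @param path readable text file.
#' @return a [haddon_map()].
#' @export
load_haddon_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (!length(keep)) stop("empty Haddon map file: ", path)
  default <- "host"
  prefix <- character(0); category <- character(0)
  for (i in keep) {
    parts <- strsplit(lines[i], ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("malformed map entry at line ", i, " of ", path, ": ", lines[i])
    key <- trimws(parts[1L]); val <- trimws(parts[2L])
    if (!val %in% c("host", "agent", "environment"))
      stop("unknown category word at line ", i, " of ", path, ": ", val)
    if (tolower(key) == "default") default <- val
    else {
      if (!grepl("^[A-Za-z][A-Za-z0-9]{0,2}$", key))
        stop("malformed prefix at line ", i, " of ", path, ": ", key)
      prefix <- c(prefix, key); category <- c(category, val)
    }
  }
  if (!length(prefix)) stop("Haddon map file has no prefix entries: ", path)
  haddon_map(prefix, category, default = default)
}

#' Write a Haddon map in the `prefix: category` text format
#'
#' @param map a [haddon_map()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_haddon_map <- function(map, path) {
  writeLines(c(paste0(map$prefix, ": ", map$category),
               paste0("default: ", attr(map, "default"))), path)
  invisible(path)
}
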