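#' Load a chronostratigraphic time scale
#'
#' Reads a table mapping chronostratigraphic unit names (stages, epochs,
#' periods) to age intervals in millions of years ago (MYA). The package
#' bundles a table with Triassic through Holocene boundaries; a user-supplied
#' replacement with the same columns may be given instead, since published
#' time scales differ slightly between editions.
#'
#' @param path Path to a CSV with columns `unit`, `min_mya`, `max_mya` (and
#'   optionally `rank`). `NULL` (default) loads the bundled table.
#' @param version Version label recorded in output metadata. Defaults to the
#'   bundled table's label, or `"user"` for a user-supplied path.
#' @return A data frame of class `geo_time_scale` with attribute `version`.
#' @examples
#' gts <- load_time_scale()
#' resolve_age_range("Cenomanian", gts)
#' @export
load_time_scale <- function(path = NULL, version = NULL) {
  bundled <- is.null(path)
  if (bundled) {
    path <- system.file("extdata", "geotime_scale.csv", package = "fossilsieve")
    if (is.null(version)) version <- "fossilsieve-bundled-GTS2012"
  } else if (is.null(version)) {
    version <- "user"
  }
  gts <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("unit", "min_mya", "max_mya")
  miss <- setdiff(need, names(gts))
  if (length(miss) > 0) {
    stop("time scale table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- !(gts$min_mya < gts$max_mya)
  if (any(bad)) {
    stop("time scale entries with min >= max: ",
         paste(gts$unit[bad], collapse = ", "), call. = FALSE)
  }
  gts$key <- normalize_unit(gts$unit)
  if (anyDuplicated(gts$key)) {
    stop("duplicate unit names in time scale table", call. = FALSE)
  }
  attr(gts, "version") <- version
  class(gts) <- c("geo_time_scale", "data.frame")
  gts
}

# case-insensitive key with collapsed whitespace
normalize_unit <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Resolve a geologic age string to an interval in MYA
#'
#' Accepts a chronostratigraphic unit name ("Cenomanian"), a span of two unit
#' names joined by a hyphen or en-dash ("Campanian-Maastrichtian"), or an
#' explicit numeric range ("66-72 MYA"). Spans resolve to the union of the
#' named units' intervals; numeric input passes through unchanged (so the
#' operation is idempotent on already-numeric ages).
#'
#' @param geologic_age Character scalar to resolve.
#' @param gts A `geo_time_scale` from [load_time_scale()].
#' @return Numeric vector `c(min, max)` in MYA.
#' @export
resolve_age_range <- function(geologic_age, gts) {
  stopifnot(is.character(geologic_age), length(geologic_age) == 1)
  s <- trimws(geologic_age)
  # explicit numeric range, e.g. "66-72 MYA", "66.0 - 72 Ma", en-dash accepted
  num_pat <- "^([0-9]+\\.?[0-9]*)\\s*[-\u2013]\\s*([0-9]+\\.?[0-9]*)\\s*(mya|ma)?$"
  if (grepl(num_pat, s, ignore.case = TRUE)) {
    lo <- as.numeric(sub(num_pat, "\\1", s, ignore.case = TRUE))
    hi <- as.numeric(sub(num_pat, "\\2", s, ignore.case = TRUE))
    return(c(min(lo, hi), max(lo, hi)))
  }
  parts <- strsplit(s, "\\s*[-\u2013]\\s*")[[1]]
  keys <- normalize_unit(parts)
  idx <- match(keys, gts$key)
  if (anyNA(idx)) {
    unknown <- parts[is.na(idx)]
    cand <- unlist(lapply(normalize_unit(unknown), function(k) {
      gts$unit[agrep(k, gts$key, max.distance = 0.25)]
    }))
    stop("unknown chronostratigraphic unit(s): ",
         paste(unknown, collapse = ", "),
         if (length(cand) > 0) {
           paste0(" (did you mean: ", paste(unique(cand), collapse = ", "), "?)")
         } else "",
         call. = FALSE)
  }
  c(min(gts$min_mya[idx]), max(gts$max_mya[idx]))
}
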