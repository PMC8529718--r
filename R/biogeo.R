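#' @title Fossil chrono-biogeographic summaries
#' @description Aggregates fossil occurrence records into family x region x
#'   time-bin matrices to expose shifts in diversity through time.
#' @name biogeo_summary
NULL

#' Default time bins: Late Cretaceous to recent
#'
#' Three contiguous bins covering 0--100 MYA: Late Cretaceous (66--100),
#' Paleogene (23.03--66), Neogene-to-recent (0--23.03). Bin edges are
#' half-open `[min, max)` in MYA, so an age exactly at a boundary belongs to
#' the older bin it opens.
#'
#' @return Data frame with `label`, `min_mya`, `max_mya`, ordered youngest
#'   first.
#' @export
default_time_bins <- function() {
  data.frame(label = c("Neogene-to-recent", "Paleogene", "Late Cretaceous"),
             min_mya = c(0, 23.03, 66),
             max_mya = c(23.03, 66, 100),
             stringsAsFactors = FALSE)
}

validate_time_bins <- function(bins) {
  stopifnot(all(c("label", "min_mya", "max_mya") %in% names(bins)))
  bins <- bins[order(bins$min_mya), , drop = FALSE]
  if (any(bins$min_mya >= bins$max_mya)) stop("bins with min >= max", call. = FALSE)
  if (nrow(bins) > 1 &&
      any(abs(bins$min_mya[-1] - bins$max_mya[-nrow(bins)]) > 1e-9)) {
    stop("time bins must be contiguous and non-overlapping", call. = FALSE)
  }
  bins
}

#' Filter records for the biogeographic summary
#'
#' Drops records whose minimum age exceeds 100 MYA, records without a
#' family-level assignment, and records on the configured suspect list.
#'
#' @param records A registry data frame (needs `record_id`, `family`,
#'   `min_age`, and resolved ages).
#' @param max_min_age Oldest admissible minimum age (default 100 MYA).
#' @param suspect_ids Record ids to drop (default `c("220", "273", "294")`).
#' @return The retained records, with attribute `dropped` giving the counts
#'   per rule.
#' @export
filter_for_biogeo <- function(records, max_min_age = 100,
                              suspect_ids = c("220", "273", "294")) {
  too_old <- is.finite(records$min_age) & records$min_age > max_min_age
  no_family <- !nzchar(trimws(records$family))
  suspect <- records$record_id %in% suspect_ids
  unresolved <- !is.finite(records$min_age) | !is.finite(records$max_age)
  keep <- !(too_old | no_family | suspect | unresolved)
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- c(too_old = sum(too_old), no_family = sum(no_family),
                            suspect = sum(suspect), unresolved = sum(unresolved))
  out
}

#' Bin fossil occurrences by family, region and time
#'
#' Tallies records into (family, region, bin) cells. In the default
#' multi-assignment mode a record contributes to every bin its resolved
#' `[min_age, max_age]` interval overlaps; in `mode = "midpoint"` it is
#' assigned to the single bin containing its interval midpoint (half-open
#' `[min, max)` bins). Audit lists of record ids are kept per cell.
#'
#' @param records Filtered registry data frame.
#' @param bins Time bins (default [default_time_bins()]).
#' @param mode `"overlap"` (default) or `"midpoint"`.
#' @return Object of class `occurrence_matrix`: data frame of non-empty
#'   cells (`family`, `region`, `bin`, `count`, `record_ids`), with
#'   attributes `mode`, `bins`, and `unbinned` (ids spanning no bin, also
#'   warned about).
#' @export
bin_occurrences <- function(records, bins = default_time_bins(),
                            mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  bins <- validate_time_bins(bins)
  cells <- list()
  unbinned <- character(0)
  for (i in seq_len(nrow(records))) {
    lo <- records$min_age[i]; hi <- records$max_age[i]
    hit <- if (mode == "overlap") {
      which(lo < bins$max_mya & hi >= bins$min_mya)
    } else {
      mid <- (lo + hi) / 2
      which(mid >= bins$min_mya & mid < bins$max_mya)
    }
    if (length(hit) == 0) {
      unbinned <- c(unbinned, records$record_id[i])
      next
    }
    for (b in hit) {
      key <- paste(records$family[i], records$region[i], bins$label[b], sep = "\r")
      cells[[key]] <- c(cells[[key]], records$record_id[i])
    }
  }
  if (length(unbinned) > 0) {
    warning("record(s) spanning no time bin: ",
            paste(unbinned, collapse = ", "), call. = FALSE)
  }
  if (length(cells) == 0) {
    out <- data.frame(family = character(0), region = character(0),
                      bin = character(0), count = integer(0),
                      record_ids = character(0))
  } else {
    parts <- do.call(rbind, strsplit(names(cells), "\r", fixed = TRUE))
    out <- data.frame(family = parts[, 1], region = parts[, 2],
                      bin = parts[, 3],
                      count = vapply(cells, length, integer(1)),
                      record_ids = vapply(cells, paste, character(1),
                                          collapse = ";"),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$bin, out$family, out$region), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, mode = mode, bins = bins, unbinned = unbinned,
            class = c("occurrence_matrix", "data.frame"))
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("Occurrence matrix (", attr(x, "mode"), " binning): ",
      nrow(x), " non-empty cells, ", sum(x$count), " occurrences\n", sep = "")
  print(as.data.frame(x)[, c("family", "region", "bin", "count")],
        row.names = FALSE)
  invisible(x)
}

#' Plot an occurrence matrix as per-bin heatmaps
#' @param x An `occurrence_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.occurrence_matrix <- function(x, ...) {
  bins <- unique(x$bin)
  fams <- sort(unique(x$family))
  regs <- sort(unique(x$region))
  op <- graphics::par(mfrow = c(1, length(bins)), mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op))
  for (b in bins) {
    mat <- matrix(0, length(fams), length(regs), dimnames = list(fams, regs))
    sub <- x[x$bin == b, , drop = FALSE]
    mat[cbind(sub$family, sub$region)] <- sub$count
    graphics::image(seq_along(regs), seq_along(fams), t(mat), main = b,
                    xlab = "", ylab = "", axes = FALSE, ...)
    graphics::axis(1, seq_along(regs), regs, las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_along(fams), fams, las = 2, cex.axis = 0.7)
  }
  invisible(x)
}
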