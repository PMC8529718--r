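#' @title Fossil occurrence registries
#' @description A fossil registry is a plain data frame (class
#'   `fossil_registry`) with one row per occurrence record: a unique
#'   combination of locality, age and species. [load_registry()] resolves
#'   geologic ages to MYA intervals and assigns each record to a calibration
#'   node under a set of taxonomic rules.
#' @name fossil_registry
NULL

#' Sentinel value for records not assigned to any node
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Taxonomic node-assignment rules
#'
#' Rules mapping a record's taxonomy to a calibration node: a family-level
#' map, genus-level overrides that beat the family map (e.g. a genus that a
#' phylogeny places away from the rest of its nominal family), and an
#' exclusion list of genera/families that beats both (e.g. a genus believed
#' to represent an extinct clade). Records with an empty family are always
#' unassigned.
#'
#' @param family_node Named character vector or list: family -> node label.
#' @param genus_node Named character vector or list: genus -> node label.
#' @param exclude_genera,exclude_families Character vectors of taxa whose
#'   records are never assigned.
#' @return An object of class `node_rules`.
#' @export
node_rules <- function(family_node = character(), genus_node = character(),
                       exclude_genera = character(),
                       exclude_families = character()) {
  out <- list(
    family_node = unlist(family_node),
    genus_node = unlist(genus_node),
    exclude_genera = as.character(unlist(exclude_genera)),
    exclude_families = as.character(unlist(exclude_families))
  )
  class(out) <- "node_rules"
  out
}

#' Read node-assignment rules from a YAML config file
#'
#' @param path YAML file with keys `family_node`, `genus_node`,
#'   `exclude_genera`, `exclude_families` (all optional).
#' @return A `node_rules` object.
#' @export
read_node_rules <- function(path) {
  y <- yaml::read_yaml(path)
  node_rules(
    family_node = y$family_node %||% character(),
    genus_node = y$genus_node %||% character(),
    exclude_genera = y$exclude_genera %||% character(),
    exclude_families = y$exclude_families %||% character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a fossil record to a calibration node
#'
#' Precedence: exclusion list beats genus overrides, which beat the family
#' map. Records with an empty family field, or whose genus/family is
#' excluded, are unassigned. An unmapped family is a valid (unassigned)
#' outcome, reported via a warning by [load_registry()].
#'
#' @param family,genus Character scalars (may be empty strings).
#' @param rules A `node_rules` object.
#' @return A node label, or [UNASSIGNED].
#' @export
assign_node <- function(family, genus, rules) {
  stopifnot(inherits(rules, "node_rules"))
  family <- trimws(as.character(family %||% ""))
  genus <- trimws(as.character(genus %||% ""))
  if (is.na(family)) family <- ""
  if (is.na(genus)) genus <- ""
  if (nzchar(genus) && genus %in% rules$exclude_genera) return(UNASSIGNED)
  if (!nzchar(family) || family %in% rules$exclude_families) return(UNASSIGNED)
  if (nzchar(genus) && genus %in% names(rules$genus_node)) {
    return(unname(rules$genus_node[[genus]]))
  }
  if (family %in% names(rules$family_node)) {
    return(unname(rules$family_node[[family]]))
  }
  UNASSIGNED
}

registry_required_cols <- c("record_id", "taxon", "family", "genus",
                            "region", "geologic_age", "source", "suspect")

#' Load and validate a fossil registry
#'
#' Reads a registry CSV, resolves each record's geologic age to a MYA
#' interval against a time scale, and assigns each record to a calibration
#' node under the supplied rules. Records whose age string cannot be
#' resolved are quarantined (status `"QUARANTINED"`, excluded downstream)
#' rather than dropped or fatal, so one bad row cannot kill a large run.
#'
#' @param path Registry CSV. Required columns: `record_id`, `taxon`,
#'   `family`, `genus`, `region`, `geologic_age`, `source`, `suspect`.
#'   Optional: `min_age`, `max_age` (used as-is when both present and
#'   finite), `assigned_node` (ignored on input, recomputed).
#' @param rules A `node_rules` object (or path to a YAML rules file).
#' @param gts A `geo_time_scale` (default: the bundled table).
#' @return A `fossil_registry` data frame with populated `min_age`,
#'   `max_age`, `assigned_node` and `status` columns, and attributes
#'   `counts` (assigned/unassigned/quarantined) and `gts_version`.
#' @export
load_registry <- function(path, rules, gts = load_time_scale()) {
  if (is.character(rules)) rules <- read_node_rules(rules)
  stopifnot(inherits(rules, "node_rules"), inherits(gts, "geo_time_scale"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character"))
  miss <- setdiff(registry_required_cols, names(df))
  if (length(miss) > 0) {
    stop("registry is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as_registry(df, rules = rules, gts = gts)
}

#' Build a validated registry from an in-memory data frame
#'
#' Same validation, age resolution and node assignment as [load_registry()],
#' for registries constructed in code (e.g. by [simulate_fossils()]).
#'
#' @inheritParams load_registry
#' @param df Data frame with the registry columns.
#' @export
as_registry <- function(df, rules, gts = load_time_scale()) {
  n <- nrow(df)
  df$record_id <- as.character(df$record_id)
  if (anyDuplicated(df$record_id)) {
    stop("duplicate record_id values: ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("family", "genus", "region")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", trimws(as.character(df[[col]])))
  }
  df$suspect <- as.logical(df$suspect)
  if (is.null(df$min_age)) df$min_age <- NA_real_
  if (is.null(df$max_age)) df$max_age <- NA_real_

  df$status <- rep("ASSIGNED", n)
  df$assigned_node <- rep(UNASSIGNED, n)
  quarantine_reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    has_num <- is.finite(df$min_age[i]) && is.finite(df$max_age[i])
    if (!has_num) {
      rng <- tryCatch(resolve_age_range(as.character(df$geologic_age[i]), gts),
                      error = function(e) e)
      if (inherits(rng, "error")) {
        quarantine_reason[i] <- conditionMessage(rng)
        df$status[i] <- "QUARANTINED"
        next
      }
      df$min_age[i] <- rng[1]
      df$max_age[i] <- rng[2]
    }
    if (!(df$min_age[i] > 0 && df$min_age[i] < df$max_age[i])) {
      quarantine_reason[i] <- "resolved ages violate 0 < min < max"
      df$status[i] <- "QUARANTINED"
      next
    }
    df$assigned_node[i] <- assign_node(df$family[i], df$genus[i], rules)
    if (df$assigned_node[i] == UNASSIGNED) df$status[i] <- "UNASSIGNED"
  }
  unmapped <- unique(df$family[df$status == "UNASSIGNED" & nzchar(df$family) &
                               !(df$family %in% rules$exclude_families) &
                               !(df$genus %in% rules$exclude_genera)])
  unmapped <- setdiff(unmapped, names(rules$family_node))
  if (length(unmapped) > 0) {
    warning("families with no node rule left unassigned: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  counts <- c(assigned = sum(df$status == "ASSIGNED"),
              unassigned = sum(df$status == "UNASSIGNED"),
              quarantined = sum(df$status == "QUARANTINED"))
  attr(df, "counts") <- counts
  attr(df, "gts_version") <- attr(gts, "version")
  attr(df, "quarantine_reason") <- quarantine_reason
  class(df) <- c("fossil_registry", "data.frame")
  df
}

#' Write a registry to CSV
#'
#' Writes all columns, including the resolved ages, assignment and status,
#' so that reloading reproduces the records field-for-field.
#'
#' @param registry A `fossil_registry`.
#' @param path Output CSV path.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.fossil_registry <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("Fossil registry:", nrow(x), "records (",
      counts["assigned"], "assigned,", counts["unassigned"], "unassigned,",
      counts["quarantined"], "quarantined )\n")
  cat("Time scale:", attr(x, "gts_version"), "\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
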