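#' @title Fossil calibration screening
#' @description The package's core procedure: every node-assigned fossil is
#'   used alone to date the tree by penalized likelihood; the resulting ages
#'   at three monitored reference nodes are pooled across fossils; any
#'   fossil whose single-fossil chronogram falls strictly outside the
#'   interquartile region at one or more reference nodes is culled; fossils
#'   at nodes retaining three or fewer records are removed; and the oldest
#'   surviving minimum age per node becomes that node's calibration.
#' @name screening
NULL

#' Interquartile bounds of a set of node ages
#'
#' @param ages Numeric vector of at least 4 finite ages.
#' @param rule Quantile rule: `"linear"` (linear interpolation between order
#'   statistics, the default, recorded in report metadata) or `"hinges"`
#'   (Tukey hinges).
#' @return Named numeric vector `c(Q1, Q3)`. Bounds are inclusive: a fossil
#'   exactly at Q1 or Q3 survives.
#' @export
iqr_bounds <- function(ages, rule = c("linear", "hinges")) {
  rule <- match.arg(rule)
  ages <- ages[is.finite(ages)]
  if (length(ages) < 4) {
    stop("need at least 4 finite ages to compute interquartile bounds; ",
         "skip culling for smaller populations", call. = FALSE)
  }
  if (rule == "linear") {
    q <- stats::quantile(ages, c(0.25, 0.75), type = 7, names = FALSE)
  } else {
    f <- stats::fivenum(ages)
    q <- f[c(2, 4)]
  }
  c(Q1 = q[1], Q3 = q[2])
}

#' Remove fossils at weakly supported nodes
#'
#' Drops every fossil assigned to a node that retains three or fewer
#' fossils, applied after interquartile culling.
#'
#' @param survivors Data frame with columns `record_id` and `assigned_node`.
#' @param max_small Nodes with at most this many fossils are cleared
#'   (default 3).
#' @return List with `kept` and `removed` (both data frames); removed rows
#'   gain a `reason` column `"LOW_NODE_SUPPORT"`.
#' @export
apply_node_support_filter <- function(survivors, max_small = 3) {
  if (nrow(survivors) == 0) {
    return(list(kept = survivors, removed = cbind(survivors, reason = character(0))))
  }
  counts <- table(survivors$assigned_node)
  weak <- names(counts)[counts <= max_small]
  drop <- survivors$assigned_node %in% weak
  removed <- survivors[drop, , drop = FALSE]
  if (nrow(removed) > 0) removed$reason <- "LOW_NODE_SUPPORT"
  list(kept = survivors[!drop, , drop = FALSE], removed = removed)
}

#' Select minimum-age calibrations from surviving fossils
#'
#' Per node, the oldest surviving fossil's minimum age (the maximum over
#' survivors' `min_age`) becomes that node's minimum-age calibration. Nodes
#' without survivors get none.
#'
#' @param survivors Data frame with `record_id`, `assigned_node`, `min_age`.
#' @param node_defs Node-definition data frame (`node_label`, `taxonA`,
#'   `taxonB`) used to address the calibrated nodes by MRCA taxon pairs.
#' @return Calibration data frame: `node_label`, `taxonA`, `taxonB`,
#'   `min_age`, `max_age` (`NA`: minimum-only), `record_id` of the selected
#'   fossil.
#' @export
select_calibrations <- function(survivors, node_defs) {
  if (nrow(survivors) == 0) stop("no surviving fossils", call. = FALSE)
  out <- lapply(split(survivors, survivors$assigned_node), function(d) {
    i <- which.max(d$min_age)
    data.frame(node_label = d$assigned_node[i], min_age = d$min_age[i],
               max_age = NA_real_, record_id = d$record_id[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  j <- match(out$node_label, node_defs$node_label)
  if (anyNA(j)) {
    stop("node label(s) missing from node definitions: ",
         paste(out$node_label[is.na(j)], collapse = ", "), call. = FALSE)
  }
  out$taxonA <- node_defs$taxonA[j]
  out$taxonB <- node_defs$taxonB[j]
  out[, c("node_label", "taxonA", "taxonB", "min_age", "max_age", "record_id")]
}

#' Screen fossils by per-fossil penalized-likelihood dating
#'
#' Runs one penalized-likelihood dating per assigned fossil, the fossil's
#' resolved minimum and maximum ages constraining its assigned node; extracts
#' the three reference-node ages from each run; culls fossils strictly
#' outside the pooled interquartile region at any reference node; applies
#' the node-support filter; and selects the final minimum-age calibrations.
#'
#' Reference nodes may carry expected-age intervals (`expected_min`,
#' `expected_max`); these are echoed in the summary for reporting only and
#' never influence exclusion.
#'
#' @param phy A `phylogram`.
#' @param registry A `fossil_registry` (only `status == "ASSIGNED"` rows are
#'   screened).
#' @param node_defs Node definitions (`node_label`, `taxonA`, `taxonB`)
#'   covering every assigned node label.
#' @param ref_nodes Data frame of exactly three reference nodes
#'   (`node_label`, `taxonA`, `taxonB`, optional `expected_min`,
#'   `expected_max`).
#' @param lambda,restarts,seed,maxit Penalized-likelihood settings for the
#'   per-fossil runs (see [pl_chronogram_fit()]); `restarts` defaults to 2
#'   here since each run is a one-calibration problem.
#' @param quantile_rule Passed to [iqr_bounds()].
#' @param max_small Passed to [apply_node_support_filter()].
#' @return Object of class `screening_report`; see Details.
#' @details The report contains `table` (one row per screened fossil: run
#'   status, the three reference-node ages, survivor flag and reason codes),
#'   `iqr` (Q1/Q3 per reference node), `survivors`, `calibrations`, and
#'   `ref_summary` (per-reference-node mean/median before and after
#'   culling, plus any expected intervals).
#' @export
screen_fossils <- function(phy, registry, node_defs, ref_nodes,
                           lambda = 1, restarts = 2, seed = 1, maxit = 400,
                           quantile_rule = c("linear", "hinges"),
                           max_small = 3) {
  quantile_rule <- match.arg(quantile_rule)
  stopifnot(nrow(ref_nodes) == 3)
  fossils <- as.data.frame(registry)[registry$status == "ASSIGNED", , drop = FALSE]
  if (nrow(fossils) == 0) stop("no assigned fossils to screen", call. = FALSE)
  missing_defs <- setdiff(unique(fossils$assigned_node), node_defs$node_label)
  if (length(missing_defs) > 0) {
    stop("assigned node(s) without definitions: ",
         paste(missing_defs, collapse = ", "), call. = FALSE)
  }
  ref_ids <- resolve_node_queries(phy, ref_nodes)
  ref_labels <- ref_nodes$node_label

  nf <- nrow(fossils)
  run_status <- character(nf)
  ref_ages <- matrix(NA_real_, nf, 3,
                     dimnames = list(fossils$record_id, ref_labels))
  diag_msgs <- character(nf)
  for (i in seq_len(nf)) {
    j <- match(fossils$assigned_node[i], node_defs$node_label)
    cal <- data.frame(taxonA = node_defs$taxonA[j], taxonB = node_defs$taxonB[j],
                      min_age = fossils$min_age[i], max_age = fossils$max_age[i],
                      stringsAsFactors = FALSE)
    fit <- tryCatch(
      pl_chronogram_fit(phy, cal, lambda = lambda, restarts = restarts,
                        seed = seed, maxit = maxit),
      error = function(e) e)
    if (inherits(fit, "error")) {
      run_status[i] <- "RUN_FAILED"
      diag_msgs[i] <- conditionMessage(fit)
    } else {
      run_status[i] <- "RUN_OK"
      ref_ages[i, ] <- fit$ages[ref_ids]
    }
  }
  ok <- run_status == "RUN_OK"
  if (!any(ok)) {
    stop("all per-fossil dating runs failed; first diagnostics: ",
         paste(utils::head(diag_msgs, 3), collapse = " | "), call. = FALSE)
  }

  reasons <- vector("list", nf)
  excluded <- rep(FALSE, nf)
  excluded[!ok] <- TRUE
  for (i in which(!ok)) reasons[[i]] <- "RUN_FAILED"

  iqr <- NULL
  if (sum(ok) >= 4) {
    iqr <- data.frame(node_label = ref_labels, Q1 = NA_real_, Q3 = NA_real_)
    for (k in 1:3) {
      b <- iqr_bounds(ref_ages[ok, k], rule = quantile_rule)
      iqr$Q1[k] <- b["Q1"]; iqr$Q3[k] <- b["Q3"]
      out_k <- ok & (ref_ages[, k] < b["Q1"] | ref_ages[, k] > b["Q3"])
      for (i in which(out_k)) {
        reasons[[i]] <- c(reasons[[i]], paste0("OUTLIER_AT_", ref_labels[k]))
      }
      excluded <- excluded | out_k
    }
  } else {
    warning("fewer than 4 successful runs: interquartile culling skipped",
            call. = FALSE)
  }

  iqr_survivors <- fossils[!excluded, c("record_id", "assigned_node", "min_age"),
                           drop = FALSE]
  ns <- apply_node_support_filter(iqr_survivors, max_small = max_small)
  for (rid in ns$removed$record_id) {
    i <- match(rid, fossils$record_id)
    reasons[[i]] <- c(reasons[[i]], "LOW_NODE_SUPPORT")
    excluded[i] <- TRUE
  }
  survivors <- ns$kept
  calibrations <- if (nrow(survivors) > 0) {
    select_calibrations(survivors, node_defs)
  } else NULL

  surv_ok <- !excluded
  ref_summary <- data.frame(
    node_label = ref_labels,
    mean_before = colMeans(ref_ages[ok, , drop = FALSE]),
    median_before = apply(ref_ages[ok, , drop = FALSE], 2, stats::median),
    mean_after = colMeans(ref_ages[surv_ok, , drop = FALSE]),
    median_after = apply(ref_ages[surv_ok, , drop = FALSE], 2, stats::median),
    n_before = sum(ok), n_after = sum(surv_ok))
  if (!is.null(ref_nodes$expected_min)) {
    ref_summary$expected_min <- ref_nodes$expected_min
    ref_summary$expected_max <- ref_nodes$expected_max
  }

  tab <- data.frame(record_id = fossils$record_id,
                    assigned_node = fossils$assigned_node,
                    min_age = fossils$min_age, max_age = fossils$max_age,
                    run_status = run_status, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(ref_ages,
                                  col.names = paste0("age_", ref_labels)))
  names(tab)[(ncol(tab) - 2):ncol(tab)] <- paste0("age_", ref_labels)
  tab$survivor <- !excluded
  tab$reasons <- vapply(reasons, function(r) {
    if (is.null(r)) "" else paste(r, collapse = ";")
  }, character(1))
  rownames(tab) <- NULL

  structure(list(table = tab, iqr = iqr, survivors = survivors,
                 calibrations = calibrations, ref_summary = ref_summary,
                 quantile_rule = quantile_rule, lambda = lambda,
                 seed = seed, restarts = restarts,
                 n_attempted = nf, n_ok = sum(ok),
                 n_survivors = nrow(survivors)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Fossil screening report\n")
  cat("  attempted runs:", x$n_attempted, " successful:", x$n_ok,
      " survivors:", x$n_survivors, "\n")
  cat("  quantile rule:", x$quantile_rule, "  lambda:", x$lambda, "\n")
  if (!is.null(x$iqr)) {
    cat("  interquartile bounds at reference nodes:\n")
    print(x$iqr, row.names = FALSE)
  }
  if (!is.null(x$calibrations)) {
    cat("  selected minimum-age calibrations:\n")
    print(x$calibrations, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.screening_report <- function(object, ...) {
  object$ref_summary
}

#' Write a screening report to disk
#'
#' Writes the per-fossil table and selected calibrations as CSV and the full
#' report metadata as JSON under `dir`.
#'
#' @param report A `screening_report`.
#' @param dir Output directory (created if absent).
#' @export
write_screening_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "screening_table.csv"),
                   row.names = FALSE)
  if (!is.null(report$calibrations)) {
    utils::write.csv(report$calibrations,
                     file.path(dir, "selected_calibrations.csv"),
                     row.names = FALSE)
  }
  meta <- report[c("iqr", "ref_summary", "quantile_rule", "lambda", "seed",
                   "restarts", "n_attempted", "n_ok", "n_survivors")]
  jsonlite::write_json(meta, file.path(dir, "screening_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
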