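test_that("iqr_bounds matches hand-computed quartiles", {
  # linear interpolation (R quantile type 7): for 1,2,3,4 the quartiles are
  # 1 + 0.75*(2-1) = 1.75 and 3 + 0.25*(4-3) = 3.25
  b <- iqr_bounds(c(1, 2, 3, 4), rule = "linear")
  expect_equal(unname(b), c(1.75, 3.25))
  # Tukey hinges for 1,2,3,4: medians of the lower/upper halves
  h <- iqr_bounds(c(1, 2, 3, 4), rule = "hinges")
  expect_equal(unname(h), c(1.5, 3.5))
  # order invariance and agreement with stats::quantile on random data
  set.seed(1)
  v <- rlnorm(25, 4, 0.5)
  expect_equal(iqr_bounds(v), iqr_bounds(sample(v)))
  expect_equal(unname(iqr_bounds(v)),
               unname(quantile(v, c(0.25, 0.75), type = 7)))
  # too few ages is an explicit error, not silence
  expect_error(iqr_bounds(c(1, 2, 3)), "at least 4")
  expect_error(iqr_bounds(c(1, 2, 3, NA)), "at least 4")
})

test_that("the node-support filter boundary sits at exactly 3 fossils", {
  surv <- data.frame(
    record_id = sprintf("r%02d", 1:7),
    assigned_node = c(rep("nodeA", 4), rep("nodeB", 3)),
    min_age = 1:7)
  ns <- apply_node_support_filter(surv, max_small = 3)
  expect_identical(sort(ns$kept$record_id), sprintf("r%02d", 1:4))
  expect_identical(sort(ns$removed$record_id), sprintf("r%02d", 5:7))
  expect_true(all(ns$removed$reason == "LOW_NODE_SUPPORT"))
  # empty input passes through
  ns0 <- apply_node_support_filter(surv[0, ])
  expect_equal(nrow(ns0$kept), 0)
  expect_equal(nrow(ns0$removed), 0)
})

test_that("calibration selection is the max of minima, per node", {
  set.seed(3)
  surv <- data.frame(
    record_id = sprintf("r%02d", 1:20),
    assigned_node = sample(c("n15", "n16", "n17"), 20, replace = TRUE),
    min_age = round(runif(20, 10, 90), 2))
  defs <- data.frame(node_label = c("n15", "n16", "n17"),
                     taxonA = c("A", "B", "C"), taxonB = c("X", "Y", "Z"))
  cal <- select_calibrations(surv, defs)
  # brute-force oracle
  for (nd in unique(surv$assigned_node)) {
    rows <- surv[surv$assigned_node == nd, ]
    expect_equal(cal$min_age[cal$node_label == nd], max(rows$min_age))
    expect_identical(cal$record_id[cal$node_label == nd],
                     rows$record_id[which.max(rows$min_age)])
  }
  expect_true(all(is.na(cal$max_age)))
  # taxa are joined from the definitions
  expect_identical(cal$taxonA[cal$node_label == "n16"], "B")
  # unknown node labels are fatal
  expect_error(select_calibrations(
    data.frame(record_id = "r", assigned_node = "nope", min_age = 5), defs),
    "nope")
  expect_error(select_calibrations(surv[0, ], defs), "no surviving")
})

# small simulated screening problem reused below
screening_fixture <- function(n_fossils = 24, seed = 6) {
  cfg <- sim_config(n_tips = 8, n_fossils = n_fossils,
                    misleading_fraction = 0.2, alignment_length = 1500,
                    rate_log_sd = 0.15, seed = seed)
  sim <- simulate_tree(cfg)
  reg <- simulate_fossils(sim$truth, cfg)
  defs <- node_definitions(sim$truth$phy)
  n <- ape::Ntip(sim$truth$phy)
  # reference nodes: root plus the two oldest non-root internal nodes
  inner <- defs[order(-sim$truth$ages[defs$node]), ][1:3, ]
  list(sim = sim, reg = reg, defs = defs,
       refs = inner[, c("node_label", "taxonA", "taxonB")])
}

test_that("screening reports are internally consistent", {
  fx <- screening_fixture()
  rep <- screen_fossils(fx$sim$observed, fx$reg, fx$defs, fx$refs,
                        restarts = 1, seed = 1)
  tab <- rep$table
  expect_equal(nrow(tab), nrow(fx$reg))
  expect_equal(rep$n_ok, sum(tab$run_status == "RUN_OK"))
  # recompute the exclusion decision from the reported ages and bounds
  age_cols <- paste0("age_", fx$refs$node_label)
  ok <- tab$run_status == "RUN_OK"
  out <- !ok
  for (k in 1:3) {
    a <- tab[[age_cols[k]]]
    out <- out | (ok & (a < rep$iqr$Q1[k] | a > rep$iqr$Q3[k]))
  }
  # add the node-support stage
  iqr_surv <- tab[!out, ]
  weak <- names(which(table(iqr_surv$assigned_node) <= 3))
  out <- out | (tab$assigned_node %in% weak & !out)
  expect_identical(tab$survivor, !out)
  # survivors and calibrations agree with the table
  expect_identical(sort(rep$survivors$record_id),
                   sort(tab$record_id[tab$survivor]))
  expect_false(is.null(rep$calibrations))
  for (nd in rep$calibrations$node_label) {
    expect_equal(rep$calibrations$min_age[rep$calibrations$node_label == nd],
                 max(rep$survivors$min_age[rep$survivors$assigned_node == nd]))
  }
  # reason codes name the offending reference node
  flagged <- tab$reasons[!tab$survivor & ok]
  expect_true(all(grepl("OUTLIER_AT_|LOW_NODE_SUPPORT", flagged)))
})

test_that("screening is independent of the registry row order", {
  fx <- screening_fixture(n_fossils = 24, seed = 14)
  r1 <- screen_fossils(fx$sim$observed, fx$reg, fx$defs, fx$refs,
                       restarts = 1, seed = 1)
  perm <- fx$reg[rev(seq_len(nrow(fx$reg))), ]
  class(perm) <- class(fx$reg)
  r2 <- screen_fossils(fx$sim$observed, perm, fx$defs, fx$refs,
                       restarts = 1, seed = 1)
  expect_identical(sort(r1$survivors$record_id), sort(r2$survivors$record_id))
  o1 <- r1$calibrations[order(r1$calibrations$node_label), ]
  o2 <- r2$calibrations[order(r2$calibrations$node_label), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(r1$iqr, r2$iqr)
})

test_that("expected reference intervals are echoed but never act", {
  fx <- screening_fixture(n_fossils = 24, seed = 15)
  refs2 <- fx$refs
  refs2$expected_min <- c(1, 1, 1)      # absurd on purpose
  refs2$expected_max <- c(2, 2, 2)
  r1 <- screen_fossils(fx$sim$observed, fx$reg, fx$defs, fx$refs,
                       restarts = 1, seed = 1)
  r2 <- screen_fossils(fx$sim$observed, fx$reg, fx$defs, refs2,
                       restarts = 1, seed = 1)
  expect_identical(r1$table$survivor, r2$table$survivor)
  expect_true(all(c("expected_min", "expected_max") %in%
                  names(r2$ref_summary)))
  expect_false("expected_min" %in% names(r1$ref_summary))
})

test_that("quarantined and unassigned records are not screened", {
  fx <- screening_fixture(n_fossils = 12, seed = 16)
  reg <- fx$reg
  reg$status[1] <- "QUARANTINED"
  reg$status[2] <- "UNASSIGNED"
  class(reg) <- class(fx$reg)
  r <- screen_fossils(fx$sim$observed, reg, fx$defs, fx$refs,
                      restarts = 1, seed = 1)
  expect_equal(r$n_attempted, nrow(reg) - 2)
  expect_false(any(reg$record_id[1:2] %in% r$table$record_id))
})

test_that("screening reports write to disk completely", {
  fx <- screening_fixture(n_fossils = 12, seed = 17)
  r <- screen_fossils(fx$sim$observed, fx$reg, fx$defs, fx$refs,
                      restarts = 1, seed = 1)
  d <- tempfile()
  write_screening_report(r, d)
  expect_true(file.exists(file.path(d, "screening_table.csv")))
  expect_true(file.exists(file.path(d, "screening_report.json")))
  meta <- jsonlite::read_json(file.path(d, "screening_report.json"))
  expect_equal(meta$n_attempted, r$n_attempted)
  expect_identical(meta$quantile_rule, "linear")
  tab <- read.csv(file.path(d, "screening_table.csv"))
  expect_equal(nrow(tab), nrow(r$table))
  expect_output(print(r), "survivors")
})
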