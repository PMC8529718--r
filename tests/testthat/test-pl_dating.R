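# a small relaxed-clock problem reused across tests
small_problem <- function(seed = 4, n_tips = 6) {
  cfg <- sim_config(n_tips = n_tips, alignment_length = 1500,
                    rate_log_sd = 0.15, seed = seed)
  sim <- simulate_tree(cfg)
  defs <- node_definitions(sim$truth$phy)
  root_row <- defs[defs$node == ape::Ntip(sim$truth$phy) + 1L, ]
  root_age <- max(sim$truth$ages)
  cal <- data.frame(taxonA = root_row$taxonA, taxonB = root_row$taxonB,
                    min_age = root_age * 0.9, max_age = root_age * 1.1)
  list(sim = sim, cal = cal, defs = defs)
}

test_that("the analytic gradient matches central finite differences", {
  sp <- small_problem()
  prob <- pl_problem(sp$sim$observed, sp$cal)
  m <- prob$m; E <- nrow(prob$edge)
  set.seed(42)
  for (rep in 1:3) {
    par <- c(runif(m, -1, 1), log(0.003 * exp(rnorm(E, 0, 0.3))))
    g <- pl_neggrad(par, prob, lambda = 2)
    h <- 1e-6
    g_num <- vapply(seq_along(par), function(k) {
      e <- rep(0, length(par)); e[k] <- h
      (pl_negobj(par + e, prob, 2) - pl_negobj(par - e, prob, 2)) / (2 * h)
    }, numeric(1))
    scale <- pmax(abs(g_num), 1e-4)
    expect_lt(max(abs(g - g_num) / scale), 1e-4)
  }
})

test_that("with lambda = 0 fitted rates are the per-branch MLE x/t", {
  # two tips, root age pinned: the only free parameters are the two rates,
  # whose unpenalized MLE is count / duration
  phy <- read_phylogram(text = "(A:0.06,B:0.09);", alignment_length = 1000)
  cal <- data.frame(taxonA = "A", taxonB = "B", min_age = 20, max_age = 20)
  fit <- pl_chronogram_fit(phy, cal, lambda = 0, restarts = 1)
  expect_equal(max(fit$ages), 20)
  expect_equal(fit$rates, phy$edge.length / 20, tolerance = 1e-6)
})

test_that("noiseless strict-clock data are recovered essentially exactly", {
  cfg <- sim_config(n_tips = 10, clock = "strict", alignment_length = Inf,
                    seed = 21)
  sim <- simulate_tree(cfg)
  defs <- node_definitions(sim$truth$phy)
  root_row <- defs[defs$node == ape::Ntip(sim$truth$phy) + 1L, ]
  cal <- data.frame(taxonA = root_row$taxonA, taxonB = root_row$taxonB,
                    min_age = cfg$root_age, max_age = cfg$root_age)
  fit <- pl_chronogram_fit(sim$observed, cal, lambda = 1, restarts = 1)
  ids <- defs$node
  rel <- abs(fit$ages[ids] - sim$truth$ages[ids]) / sim$truth$ages[ids]
  expect_lt(max(rel), 0.01)
  expect_equal(fit$rates, sim$truth$rates, tolerance = 0.01)
})

test_that("fitted ages always satisfy the calibration bounds and ordering", {
  for (seed in 1:4) {
    sp <- small_problem(seed = seed)
    defs <- sp$defs
    inner <- defs[defs$node != ape::Ntip(sp$sim$truth$phy) + 1L, ][1, ]
    true_inner <- sp$sim$truth$ages[inner$node]
    cal <- rbind(sp$cal,
                 data.frame(taxonA = inner$taxonA, taxonB = inner$taxonB,
                            min_age = true_inner * 0.8,
                            max_age = true_inner * 1.05))
    fit <- pl_chronogram_fit(sp$sim$observed, cal, restarts = 2, seed = seed)
    prob <- fit$problem
    # every calibration bound holds
    for (i in seq_len(nrow(cal))) {
      nd <- mrca_node(prob$phy, cal$taxonA[i], cal$taxonB[i])
      expect_gte(fit$ages[nd], cal$min_age[i] - 1e-8)
      expect_lte(fit$ages[nd], cal$max_age[i] + 1e-8)
    }
    # parent strictly older than child everywhere
    durs <- fit$ages[prob$edge[, 1]] - fit$ages[prob$edge[, 2]]
    expect_true(all(durs >= 0))
  }
})

test_that("the optimizer matches the grid-search oracle on 4-taxon problems", {
  # a fast spot check; the full 64-problem comparison runs in the
  # acceptance suite
  for (seed in c(101, 102)) {
    for (rp in c(TRUE, FALSE)) {
      pr <- make_problem4(seed, rp)
      fit <- pl_chronogram_fit(pr$phy, pr$cal, lambda = 5, restarts = 3,
                               seed = 1)
      x <- pr$phy$edge.length * attr(pr$phy, "alignment_length")
      or <- oracle_grid_pl(pr$phy, x, 5, pr$bounds)
      ids <- 5:7
      rel <- abs(fit$ages[ids] - or$ages[ids]) / or$ages[ids]
      expect_lt(max(rel), 0.005)
    }
  }
})

test_that("fits are deterministic given the seed", {
  sp <- small_problem(seed = 8)
  f1 <- pl_chronogram_fit(sp$sim$observed, sp$cal, restarts = 3, seed = 99)
  f2 <- pl_chronogram_fit(sp$sim$observed, sp$cal, restarts = 3, seed = 99)
  expect_identical(f1$ages, f2$ages)
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$objective, f2$objective)
})

test_that("large lambda drives the fit toward a strict clock", {
  sp <- small_problem(seed = 12)
  fit <- pl_chronogram_fit(sp$sim$observed, sp$cal, lambda = 1e7, restarts = 2)
  expect_lt(diff(range(fit$rates)) / mean(fit$rates), 0.01)
})

test_that("the objective rejects zero durations on informative branches", {
  sp <- small_problem()
  prob <- pl_problem(sp$sim$observed, sp$cal)
  ages <- pl_ages_from_u(prob, rep(0, prob$m))
  # collapse one internal branch to zero duration
  inner <- prob$preorder[2]
  parent <- prob$edge[prob$edge_into[inner], 1]
  ages[inner] <- ages[parent]
  r <- rep(0.003, nrow(prob$edge))
  expect_identical(pl_objective(prob, r, ages, 1), -Inf)
})

test_that("unidentifiable or infeasible calibration sets are fatal", {
  phy <- read_phylogram(text = "((A:0.1,B:0.1):0.1,C:0.2);",
                        alignment_length = 1000)
  # minimum-only everywhere: no time-scale anchor
  cal <- data.frame(taxonA = "A", taxonB = "B", min_age = 10, max_age = NA)
  expect_error(pl_chronogram_fit(phy, cal), "unidentifiable")
  # maximum below a subtree minimum
  cal2 <- data.frame(taxonA = c("A", "A"), taxonB = c("B", "C"),
                     min_age = c(50, NA), max_age = c(NA, 40))
  expect_error(pl_problem(phy, cal2), "infeasible")
  # calibration resolving to a tip
  cal3 <- data.frame(taxonA = "A", taxonB = "A", min_age = 5, max_age = 10)
  expect_error(pl_problem(phy, cal3), "tip")
})

test_that("cross-validation scores a lambda grid and handles degenerate input", {
  cv1 <- cross_validate_lambda(fixture_phylogram(), data.frame(
    taxonA = "P_collare", taxonB = "R_typus", min_age = 180, max_age = 220),
    lambda_grid = 10)
  expect_equal(cv1$best_lambda, 10)
  expect_match(cv1$note, "degenerate")
  expect_error(cross_validate_lambda(fixture_phylogram(), NULL,
                                     lambda_grid = numeric(0)), "empty")

  sp <- small_problem(seed = 30)
  cv <- cross_validate_lambda(sp$sim$observed, sp$cal,
                              lambda_grid = c(0.1, 10, 1000))
  expect_equal(nrow(cv$scores), 3)
  expect_true(all(is.finite(cv$scores$score)))
  expect_true(cv$best_lambda %in% cv$scores$lambda)
})

test_that("with_seed leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(with_seed(1, runif(10)))
  expect_identical(.Random.seed, before)
  # and is reproducible in itself
  a <- with_seed(7, rnorm(3))
  b <- with_seed(7, rnorm(3))
  expect_identical(a, b)
})

test_that("S3 methods for pl_chronogram work", {
  sp <- small_problem(seed = 2)
  fit <- pl_chronogram_fit(sp$sim$observed, sp$cal, restarts = 1)
  expect_output(print(fit), "Penalized-likelihood")
  s <- summary(fit)
  expect_s3_class(s, "summary.pl_chronogram")
  expect_output(print(s), "objective")
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(unname(cf[paste0("n", ape::Ntip(sp$sim$truth$phy) + 1L)]),
               max(fit$ages))
})
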