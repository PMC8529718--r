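bayes_fixture <- function(seed = 4) {
  cfg <- sim_config(n_tips = 5, alignment_length = 1500, rate_log_sd = 0.3,
                    mean_rate = 0.29, seed = seed)
  sim <- simulate_tree(cfg)
  defs <- node_definitions(sim$truth$phy)
  inner <- defs[defs$node != ape::Ntip(sim$truth$phy) + 1L, ][1, ]
  cal <- data.frame(taxonA = inner$taxonA, taxonB = inner$taxonB,
                    min_age = sim$truth$ages[inner$node] * 0.8,
                    max_age = NA_real_)
  list(sim = sim, cal = cal, defs = defs)
}

test_that("mcmc_settings validates its inputs", {
  expect_error(mcmc_settings(generations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_settings(mean_rate = -1))
  expect_error(mcmc_settings(sample_every = 0))
  st <- mcmc_settings(generations = 1000, burn_in = 100)
  expect_s3_class(st, "mcmc_settings")
})

test_that("chains are bit-reproducible given the seed", {
  fx <- bayes_fixture()
  st <- mcmc_settings(generations = 2000, burn_in = 200, sample_every = 10,
                      root_max = 300, seed = 11)
  c1 <- run_mcmc(fx$sim$observed, fx$cal, st)
  c2 <- run_mcmc(fx$sim$observed, fx$cal, st)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  st$seed <- 12
  c3 <- run_mcmc(fx$sim$observed, fx$cal, st)
  expect_false(identical(c1$age_n6, c3$age_n6))
})

test_that("every sampled state satisfies the hard bounds", {
  fx <- bayes_fixture(seed = 7)
  st <- mcmc_settings(generations = 4000, burn_in = 400, sample_every = 5,
                      root_max = 260, seed = 3)
  ch <- run_mcmc(fx$sim$observed, fx$cal, st)
  ids <- attr(ch, "node_ids")
  ages <- as.matrix(ch[paste0("age_n", ids)])
  phy <- ape::reorder.phylo(fx$sim$observed, "cladewise")
  n <- ape::Ntip(phy)
  root <- n + 1L
  # root below its hard maximum
  expect_true(all(ages[, match(root, ids)] <= 260 + 1e-9))
  # calibration minimum respected at the calibrated node
  nd <- mrca_node(phy, fx$cal$taxonA, fx$cal$taxonB)
  expect_true(all(ages[, match(nd, ids)] >= fx$cal$min_age - 1e-9))
  # parent older than child on every internal edge, in every sample
  for (j in seq_len(nrow(phy$edge))) {
    p <- phy$edge[j, 1]; c <- phy$edge[j, 2]
    child_age <- if (c <= n) 0 else ages[, match(c, ids)]
    expect_true(all(ages[, match(p, ids)] - child_age >= 0))
  }
})

test_that("prior_only switches the likelihood off", {
  fx <- bayes_fixture(seed = 9)
  st <- mcmc_settings(generations = 1000, burn_in = 100, sample_every = 10,
                      root_max = 300, seed = 5)
  ch <- run_mcmc(fx$sim$observed, fx$cal, st, prior_only = TRUE)
  expect_true(all(ch$loglik == 0))
  expect_true(attr(ch, "prior_only"))
})

test_that("a root maximum below a calibration minimum is fatal", {
  fx <- bayes_fixture(seed = 10)
  st <- mcmc_settings(generations = 1000, burn_in = 100,
                      root_max = fx$cal$min_age * 0.5, seed = 1)
  expect_error(run_mcmc(fx$sim$observed, fx$cal, st), "root maximum")
})

test_that("ess behaves sensibly on iid, autocorrelated and constant input", {
  set.seed(2)
  x <- rnorm(2000)
  expect_gt(ess(x), 1200)          # iid: close to N
  y <- as.numeric(stats::filter(rnorm(2000), 0.9, method = "recursive"))
  expect_lt(ess(y), 500)           # strong autocorrelation: far below N
  expect_equal(ess(rep(3, 50)), 50)
  expect_equal(ess(c(1, 2)), 2)
})

test_that("posterior summaries match direct computation on the samples", {
  fx <- bayes_fixture(seed = 12)
  st <- mcmc_settings(generations = 3000, burn_in = 500, sample_every = 10,
                      root_max = 300, seed = 2, replicates = 2)
  fit <- mcmc_date(fx$sim$observed, fx$cal, st)
  summ <- fit$summary
  pooled <- do.call(rbind, lapply(fit$chains, function(ch) {
    as.data.frame(ch)[ch$generation > st$burn_in,
                      grep("^age_", names(ch)), drop = FALSE]
  }))
  for (k in seq_len(nrow(summ))) {
    v <- pooled[[summ$node[k]]]
    expect_equal(summ$mean[k], mean(v))
    expect_equal(summ$median[k], median(v))
    expect_equal(summ$ci_lower[k], unname(quantile(v, 0.025)))
    expect_equal(summ$ci_upper[k], unname(quantile(v, 0.975)))
  }
  # replicate deltas recompute from per-chain medians
  rd <- attr(summ, "replicate_delta")
  expect_false(is.null(rd))
  med <- sapply(fit$chains, function(ch) {
    d <- as.data.frame(ch)[ch$generation > st$burn_in, , drop = FALSE]
    median(d[[summ$node[1]]])
  })
  expect_equal(unname(rd[summ$node[1]]),
               diff(range(med)) / mean(med))
})

test_that("node_dating S3 methods and writers work", {
  fx <- bayes_fixture(seed = 13)
  st <- mcmc_settings(generations = 1500, burn_in = 300, sample_every = 10,
                      root_max = 300, seed = 2, replicates = 2)
  fit <- suppressWarnings(mcmc_date(fx$sim$observed, fx$cal, st))
  expect_output(print(fit), "Bayesian node dating")
  expect_identical(summary(fit), fit$summary)
  expect_named(coef(fit))
  d <- tempfile()
  write_node_dating(fit, d)
  expect_true(file.exists(file.path(d, "chain_1.csv")))
  expect_true(file.exists(file.path(d, "chain_2.csv")))
  expect_true(file.exists(file.path(d, "posterior_summary.csv")))
  expect_true(file.exists(file.path(d, "mcmc_metadata.json")))
  expect_true(file.exists(file.path(d, "posterior_mean_chronogram.nwk")))
})
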