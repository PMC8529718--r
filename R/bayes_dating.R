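#' @title Bayesian node dating under an independent-rates relaxed clock
#' @description A minimal MCMC node-dating stage consuming the minimum-age
#'   calibrations selected by [screen_fossils()]. Per-branch rates are
#'   i.i.d. lognormal with a fixed mean substitution rate; node ages carry a
#'   jointly uniform prior over the feasible region (parent older than
#'   child, calibration minima respected, root below a hard maximum); the
#'   branch-length likelihood is the same generalized-Poisson expected-count
#'   model used by the penalized-likelihood stage.
#' @name bayes_dating
NULL

#' MCMC settings for node dating
#'
#' Defaults follow common practice for this analysis scale: 500,000
#' generations sampled every 50 with a burn-in of 50,000; a fixed mean
#' substitution rate of 0.290696 substitutions/site per time unit, with one
#' time unit equal to 100 MY; a hard root maximum of 334 MYA; and two
#' replicate chains for convergence checking.
#'
#' @param generations Total MCMC generations (one generation = one full
#'   update sweep over all node ages and branch rates plus one whole-tree
#'   scaling move).
#' @param sample_every Thinning interval in generations.
#' @param burn_in Generations discarded (and used for step-size adaptation).
#' @param seed Integer seed; chains are bit-reproducible given the seed.
#' @param mean_rate Mean of the lognormal rate prior, substitutions/site per
#'   `time_unit` MY.
#' @param rate_log_sd Log-scale spread of the rate prior.
#' @param root_max Hard maximum root age, MYA.
#' @param time_unit MY per rate time unit (default 100).
#' @param replicates Number of replicate chains run by [mcmc_date()].
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(generations = 500000, sample_every = 50,
                          burn_in = 50000, seed = 1, mean_rate = 0.290696,
                          rate_log_sd = 0.5, root_max = 334, time_unit = 100,
                          replicates = 2) {
  stopifnot(burn_in < generations, sample_every >= 1, mean_rate > 0,
            rate_log_sd > 0, root_max > 0, replicates >= 1)
  structure(list(generations = generations, sample_every = sample_every,
                 burn_in = burn_in, seed = seed, mean_rate = mean_rate,
                 rate_log_sd = rate_log_sd, root_max = root_max,
                 time_unit = time_unit, replicates = replicates),
            class = "mcmc_settings")
}

#' Run one MCMC chain for node dating
#'
#' Proposals: per-node age slides drawn uniformly within the node's current
#' feasibility window (between its oldest child / own minimum and its
#' parent's age / own maximum), per-branch rate multipliers, and a
#' whole-tree age scaling move. Rate-multiplier and scaling step sizes adapt
#' toward reasonable acceptance during burn-in only. Every sampled state
#' satisfies all hard bounds by construction.
#'
#' @param phy A `phylogram`.
#' @param calibrations Calibration data frame (`taxonA`, `taxonB`,
#'   `min_age`, `max_age`); typically minimum-only rows from
#'   [select_calibrations()]. `root_max` from `settings` is applied on top.
#' @param settings An [mcmc_settings()] object.
#' @param prior_only If `TRUE` the likelihood is switched off and the chain
#'   samples the calibration-truncated prior.
#' @return An object of class `mcmc_chain`: data frame of sampled
#'   generations with internal node ages (MYA), mean rate, log-likelihood
#'   and log-posterior, plus attributes (settings, acceptance rates, node
#'   labels).
#' @export
run_mcmc <- function(phy, calibrations, settings = mcmc_settings(),
                     prior_only = FALSE) {
  stopifnot(inherits(settings, "mcmc_settings"))
  cal <- if (is.null(calibrations) || nrow(calibrations) == 0) NULL else {
    calibrations[, c("taxonA", "taxonB", "min_age", "max_age")]
  }
  prob <- pl_problem(phy, cal)   # validates feasibility, computes bounds
  if (prob$lower[prob$root] >= settings$root_max) {
    stop("root maximum is below a calibration minimum", call. = FALSE)
  }
  prob$max_cal[prob$root] <- min(prob$max_cal[prob$root], settings$root_max)
  n <- prob$n; m <- prob$m; root <- prob$root
  edge <- prob$edge; E <- nrow(edge)
  L <- prob$alignment_length
  x <- prob$x
  internal <- (n + 1):(n + m)
  min_cal <- prob$min_cal           # own minima only (not propagated)
  max_cal <- prob$max_cal
  children <- lapply(seq_len(n + m), function(nd) which(edge[, 1] == nd))
  edge_into <- prob$edge_into

  # rate prior: lognormal with mean = mean_rate / time_unit per MY
  mlog <- log(settings$mean_rate / settings$time_unit) - settings$rate_log_sd^2 / 2
  slog <- settings$rate_log_sd

  ages <- pl_ages_from_u(prob, rep(0, m))
  rates <- rep(exp(mlog), E)
  lw <- if (prior_only) 0 else 1
  edge1 <- edge[, 1]; edge2 <- edge[, 2]
  xpos <- x > 0
  inv2s2 <- 1 / (2 * slog^2)
  # per-edge log-likelihood (x log mu - mu) and lognormal rate log-density
  # (up to constants), inlined in the sweep below for speed
  ll_of <- function(r, t, j) {
    mu <- r * t * L
    (if (xpos[j]) x[j] * log(mu) else 0) - mu
  }
  t_all <- ages[edge1] - ages[edge2]
  ll_edge <- ifelse(xpos, x * log(rates * t_all * L), 0) - rates * t_all * L
  lpr_rate <- function(r) -log(r) - (log(r) - mlog)^2 * inv2s2

  rate_step <- 0.5
  scale_step <- 0.1
  ridge_step <- 0.3
  acc <- c(age = 0, rate = 0, scale = 0, ridge = 0)
  prop <- c(age = 0, rate = 0, scale = 0, ridge = 0)
  sum_x <- sum(x)
  root_hi <- min(settings$root_max, max_cal[root])

  gens <- settings$generations
  keep_n <- gens %/% settings$sample_every
  out_ages <- matrix(NA_real_, keep_n, m)
  out_meta <- matrix(NA_real_, keep_n, 3)
  row <- 0L
  nrand <- 4L * m + 2L * E + 4L

  with_seed(settings$seed, {
    for (g in seq_len(gens)) {
      rnd <- stats::runif(nrand)
      ri <- 0L
      # node age slides within local feasibility windows
      for (i in internal) {
        kid_edges <- children[[i]]
        lo <- max(ages[edge2[kid_edges]], min_cal[i])
        hi <- if (i == root) root_hi else {
          min(ages[edge1[edge_into[i]]], max_cal[i])
        }
        ri <- ri + 2L
        if (hi <= lo) next
        a_new <- lo + rnd[ri - 1L] * (hi - lo)
        aff <- c(kid_edges, if (i != root) edge_into[i])
        a_old <- ages[i]
        ages[i] <- a_new
        t_new <- ages[edge1[aff]] - ages[edge2[aff]]
        mu <- rates[aff] * t_new * L
        ll_new <- ifelse(xpos[aff], x[aff] * log(mu), 0) - mu
        d <- lw * (sum(ll_new) - sum(ll_edge[aff]))
        prop[1L] <- prop[1L] + 1
        if (is.finite(d) && log(rnd[ri]) < d) {
          ll_edge[aff] <- ll_new
          acc[1L] <- acc[1L] + 1
        } else {
          ages[i] <- a_old
        }
      }
      # compensated node slides: move the age and rescale the adjacent
      # branch rates so each affected expected count r*t is preserved
      # (likelihood-invariant); the rate prior and the Jacobian
      # prod(t_old/t_new) decide acceptance
      for (i in internal) {
        kid_edges <- children[[i]]
        lo <- max(ages[edge2[kid_edges]], min_cal[i])
        hi <- if (i == root) root_hi else {
          min(ages[edge1[edge_into[i]]], max_cal[i])
        }
        ri <- ri + 2L
        if (hi <= lo) next
        a_new <- lo + rnd[ri - 1L] * (hi - lo)
        aff <- c(kid_edges, if (i != root) edge_into[i])
        t_old <- ages[edge1[aff]] - ages[edge2[aff]]
        a_prev <- ages[i]
        ages[i] <- a_new
        t_new <- ages[edge1[aff]] - ages[edge2[aff]]
        if (any(t_new <= 0) || any(t_old <= 0)) { ages[i] <- a_prev; next }
        r_new <- rates[aff] * t_old / t_new
        d <- sum(lpr_rate(r_new)) - sum(lpr_rate(rates[aff])) +
          sum(log(t_old / t_new))
        prop[1L] <- prop[1L] + 1
        if (is.finite(d) && log(rnd[ri]) < d) {
          rates[aff] <- r_new
          mu <- r_new * t_new * L
          ll_edge[aff] <- ifelse(xpos[aff], x[aff] * log(mu), 0) - mu
          acc[1L] <- acc[1L] + 1
        } else {
          ages[i] <- a_prev
        }
      }
      # branch rate multipliers
      for (j in seq_len(E)) {
        ri <- ri + 2L
        lc <- rate_step * (rnd[ri - 1L] - 0.5)
        r_new <- rates[j] * exp(lc)
        t_j <- ages[edge1[j]] - ages[edge2[j]]
        ll_new <- ll_of(r_new, t_j, j)
        d <- lw * (ll_new - ll_edge[j]) +
          lpr_rate(r_new) - lpr_rate(rates[j]) + lc
        prop[2L] <- prop[2L] + 1
        if (is.finite(d) && log(rnd[ri]) < d) {
          rates[j] <- r_new
          ll_edge[j] <- ll_new
          acc[2L] <- acc[2L] + 1
        }
      }
      # whole-tree age scaling (likelihood change in closed form)
      cs <- exp(scale_step * (rnd[ri + 1L] - 0.5))
      new_int <- ages[internal] * cs
      feasible <- new_int[match(root, internal)] <= root_hi &&
        all(new_int >= min_cal[internal]) && all(new_int <= max_cal[internal])
      prop[3L] <- prop[3L] + 1
      if (feasible) {
        rtL <- sum(rates * (ages[edge1] - ages[edge2])) * L
        d <- lw * (sum_x * log(cs) - (cs - 1) * rtL) + m * log(cs)
        if (is.finite(d) && log(rnd[ri + 2L]) < d) {
          ages[internal] <- new_int
          t_all <- ages[edge1] - ages[edge2]
          ll_edge <- ifelse(xpos, x * log(rates * t_all * L), 0) -
            rates * t_all * L
          acc[3L] <- acc[3L] + 1
        }
      }
      # ridge move: ages * c, rates / c leaves the likelihood invariant;
      # only the rate prior, bounds and the Jacobian c^(m - E) act
      cr <- exp(ridge_step * (rnd[ri + 3L] - 0.5))
      new_int <- ages[internal] * cr
      feasible <- new_int[match(root, internal)] <= root_hi &&
        all(new_int >= min_cal[internal]) && all(new_int <= max_cal[internal])
      prop[4L] <- prop[4L] + 1
      if (feasible) {
        r_new <- rates / cr
        d <- sum(lpr_rate(r_new)) - sum(lpr_rate(rates)) + (m - E) * log(cr)
        if (is.finite(d) && log(rnd[ri + 4L]) < d) {
          ages[internal] <- new_int
          rates <- r_new
          t_all <- ages[edge1] - ages[edge2]
          ll_edge <- ifelse(xpos, x * log(rates * t_all * L), 0) -
            rates * t_all * L
          acc[4L] <- acc[4L] + 1
        }
      }
      # step-size adaptation, burn-in only
      if (g <= settings$burn_in && g %% 200 == 0) {
        rate_step <- min(5, max(0.01, rate_step * exp(acc[2L] / prop[2L] - 0.3)))
        scale_step <- min(2, max(0.001, scale_step * exp(acc[3L] / prop[3L] - 0.3)))
        ridge_step <- min(3, max(0.001, ridge_step * exp(acc[4L] / prop[4L] - 0.3)))
      }
      if (g %% settings$sample_every == 0) {
        row <- row + 1L
        out_ages[row, ] <- ages[internal]
        out_meta[row, ] <- c(g, mean(rates) * settings$time_unit,
                             lw * sum(ll_edge))
      }
    }
  })
  acc_rate <- acc / pmax(prop, 1)
  if (!prior_only && any(acc_rate[c("rate", "scale")] < 0.05 |
                         acc_rate[c("rate", "scale")] > 0.8)) {
    warning("acceptance rate outside [0.05, 0.8] after adaptation: ",
            paste(sprintf("%s=%.2f", names(acc_rate), acc_rate), collapse = " "),
            call. = FALSE)
  }
  chain <- data.frame(generation = out_meta[, 1], out_ages,
                      mean_rate = out_meta[, 2], loglik = out_meta[, 3])
  names(chain)[1 + seq_len(m)] <- paste0("age_n", internal)
  structure(chain, settings = settings, acceptance = acc_rate,
            node_ids = internal, prior_only = prior_only,
            class = c("mcmc_chain", "data.frame"))
}

#' Effective sample size of a chain
#'
#' Autocorrelation-time estimate using Geyer's initial positive sequence of
#' summed autocorrelation pairs.
#'
#' @param x Numeric vector of (thinned) samples.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  N <- length(x)
  if (N < 4 || stats::var(x) == 0) return(N)
  max_lag <- min(N - 2, 500)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  N / (1 + 2 * s)
}

#' Summarize posterior chains
#'
#' Applies burn-in and thinning, then reports per-node posterior mean,
#' median, 95% credible interval and effective sample size. With two or more
#' chains, replicate-agreement deltas (absolute difference of per-node
#' posterior medians, relative to their mean) are reported.
#'
#' @param chains An `mcmc_chain` or list of them (replicates).
#' @param burn_in Generations to discard (default: from the chain settings).
#' @param sample_every Additional thinning applied on top of the chain's own
#'   sampling interval (default 1 = none).
#' @return A `posterior_summary`: data frame of per-node summaries with
#'   attributes `replicate_delta` and `ess_flagged`.
#' @export
summarize_posterior <- function(chains, burn_in = NULL, sample_every = 1) {
  if (inherits(chains, "mcmc_chain")) chains <- list(chains)
  stopifnot(length(chains) >= 1)
  st <- attr(chains[[1]], "settings")
  if (is.null(burn_in)) burn_in <- st$burn_in
  age_cols <- grep("^age_", names(chains[[1]]), value = TRUE)
  thin <- function(ch) {
    ch <- ch[ch$generation > burn_in, , drop = FALSE]
    if (nrow(ch) == 0) stop("chain shorter than burn-in", call. = FALSE)
    ch[seq(1, nrow(ch), by = sample_every), , drop = FALSE]
  }
  thinned <- lapply(chains, thin)
  pooled <- do.call(rbind, lapply(thinned, function(ch) ch[age_cols]))
  summ <- data.frame(
    node = age_cols,
    mean = vapply(pooled, mean, numeric(1)),
    median = vapply(pooled, stats::median, numeric(1)),
    ci_lower = vapply(pooled, stats::quantile, numeric(1), probs = 0.025,
                      names = FALSE),
    ci_upper = vapply(pooled, stats::quantile, numeric(1), probs = 0.975,
                      names = FALSE),
    ess = vapply(thinned[[1]][age_cols], ess, numeric(1)),
    row.names = NULL)
  low_ess <- summ$node[summ$ess < 100]
  if (length(low_ess) > 0) {
    warning("effective sample size < 100 at node(s): ",
            paste(low_ess, collapse = ", "), call. = FALSE)
  }
  rep_delta <- NULL
  if (length(thinned) >= 2) {
    med <- sapply(thinned, function(ch) vapply(ch[age_cols], stats::median,
                                               numeric(1)))
    rng <- apply(med, 1, function(v) diff(range(v)))
    rep_delta <- rng / pmax(rowMeans(med), .Machine$double.eps)
    names(rep_delta) <- age_cols
  }
  structure(summ, replicate_delta = rep_delta, ess_flagged = low_ess,
            burn_in = burn_in, class = c("posterior_summary", "data.frame"))
}

#' Bayesian node dating with replicate chains
#'
#' Runs `settings$replicates` chains (seeds `seed`, `seed + 1`, ...),
#' summarizes the pooled posterior, and reports replicate-agreement deltas.
#'
#' @inheritParams run_mcmc
#' @return Object of class `node_dating`: `chains`, `summary`
#'   (a [summarize_posterior()] result), `settings`, `calibrations`, and the
#'   posterior-mean [chronogram()].
#' @export
mcmc_date <- function(phy, calibrations, settings = mcmc_settings(),
                      prior_only = FALSE) {
  chains <- lapply(seq_len(settings$replicates) - 1L, function(k) {
    st <- settings
    st$seed <- settings$seed + k
    run_mcmc(phy, calibrations, st, prior_only = prior_only)
  })
  summ <- summarize_posterior(chains)
  ids <- attr(chains[[1]], "node_ids")
  ages <- numeric(ape::Ntip(phy) + phy$Nnode)
  ages[ids] <- summ$mean
  chr <- chronogram(ape::reorder.phylo(phy, "cladewise"), ages)
  structure(list(chains = chains, summary = summ, settings = settings,
                 calibrations = calibrations, chronogram = chr),
            class = "node_dating")
}

#' @export
print.node_dating <- function(x, ...) {
  cat("Bayesian node dating (independent-rates relaxed clock)\n")
  st <- x$settings
  cat("  generations:", st$generations, " burn-in:", st$burn_in,
      " replicates:", st$replicates, "\n")
  cat("  mean rate:", st$mean_rate, "per", st$time_unit,
      "MY; root max:", st$root_max, "MYA\n")
  print(x$summary, row.names = FALSE)
  rd <- attr(x$summary, "replicate_delta")
  if (!is.null(rd)) {
    cat("  max replicate median delta:",
        format(max(rd), digits = 3), "\n")
  }
  invisible(x)
}

#' @export
summary.node_dating <- function(object, ...) object$summary

#' @export
coef.node_dating <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$node)
}

#' @export
plot.node_dating <- function(x, ...) {
  ape::plot.phylo(x$chronogram$phy, ...)
  ape::axisPhylo()
  invisible(x)
}

#' Write node-dating outputs
#'
#' Writes the chain tables and posterior summary as CSV, run metadata as
#' JSON, and the posterior-mean chronogram as newick under `dir`.
#'
#' @param fit A `node_dating`.
#' @param dir Output directory.
#' @export
write_node_dating <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fit$chains)) {
    utils::write.csv(as.data.frame(fit$chains[[i]]),
                     file.path(dir, sprintf("chain_%d.csv", i)),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(fit$summary),
                   file.path(dir, "posterior_summary.csv"), row.names = FALSE)
  meta <- c(unclass(fit$settings),
            list(replicate_delta = attr(fit$summary, "replicate_delta")))
  jsonlite::write_json(meta, file.path(dir, "mcmc_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_chronogram(fit$chronogram, file.path(dir, "posterior_mean_chronogram.nwk"))
  invisible(dir)
}
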