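#' @title Penalized-likelihood rate smoothing
#' @description Converts a phylogram (branch lengths in expected
#'   substitutions per site) into a chronogram (node ages in MYA) under a
#'   relaxed molecular clock: per-branch substitution rates are free, but
#'   differences between a branch's rate and its parent branch's rate are
#'   penalized, with a smoothing weight `lambda` trading clocklike behaviour
#'   against fit to the branch lengths.
#' @name pl_dating
NULL

#' Build a penalized-likelihood dating problem
#'
#' Resolves calibrations to internal nodes, derives per-node feasible age
#' bounds from the calibration set and the topology, and precomputes the
#' expected substitution count per branch (branch length times alignment
#' length).
#'
#' @param phy A `phylogram` (see [read_phylogram()]).
#' @param calibrations Data frame with columns `taxonA`, `taxonB`,
#'   `min_age`, `max_age` (either may be `NA` for one-sided bounds) and
#'   optionally `node_label`.
#' @return A `pl_problem` list.
#' @export
pl_problem <- function(phy, calibrations) {
  L <- attr(phy, "alignment_length")
  if (is.null(L)) stop("phylogram lacks alignment_length", call. = FALSE)
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- ape::Ntip(phy)
  m <- phy$Nnode
  root <- n + 1L
  edge <- phy$edge
  E <- nrow(edge)
  x <- phy$edge.length * L

  # edge index leading into each node (NA for root)
  edge_into <- rep(NA_integer_, n + m)
  edge_into[edge[, 2]] <- seq_len(E)
  parent_edge <- edge_into[edge[, 1]]          # NA for edges out of the root
  root_edges <- which(edge[, 1] == root)

  # preorder over internal nodes: cladewise edge order visits parents first
  pre <- unique(edge[, 1])
  stopifnot(pre[1] == root)

  # per-internal-node calibration bounds
  min_cal <- rep(0, n + m)
  max_cal <- rep(Inf, n + m)
  if (!is.null(calibrations) && nrow(calibrations) > 0) {
    for (i in seq_len(nrow(calibrations))) {
      nd <- mrca_node(phy, calibrations$taxonA[i], calibrations$taxonB[i])
      if (nd <= n) stop("calibration resolves to a tip", call. = FALSE)
      if (!is.na(calibrations$min_age[i])) {
        min_cal[nd] <- max(min_cal[nd], calibrations$min_age[i])
      }
      if (!is.na(calibrations$max_age[i])) {
        max_cal[nd] <- min(max_cal[nd], calibrations$max_age[i])
      }
    }
  }
  # subtree-propagated lower bounds: a node can never be younger than any
  # minimum-age calibration in its subtree
  lower <- min_cal
  for (j in rev(seq_len(E))) {             # postorder accumulation
    p <- edge[j, 1]; c <- edge[j, 2]
    lower[p] <- max(lower[p], lower[c])
  }
  infeas <- which(is.finite(max_cal) & max_cal < lower &
                  seq_along(max_cal) > n)
  if (length(infeas) > 0) {
    stop("infeasible calibration set: node(s) ",
         paste(infeas, collapse = ", "),
         " have a maximum age below a subtree minimum", call. = FALSE)
  }
  structure(list(phy = phy, n = n, m = m, root = root, edge = edge,
                 x = x, alignment_length = L, edge_into = edge_into,
                 parent_edge = parent_edge, root_edges = root_edges,
                 preorder = pre, lower = lower, max_cal = max_cal,
                 min_cal = min_cal, calibrations = calibrations),
            class = "pl_problem")
}

# clock-heuristic starting point: scale substitution-depth node heights so
# the first two-sided calibrated node sits at its window midpoint, then
# invert the age transform (clipped to the feasible interior)
pl_init_u <- function(prob) {
  n <- prob$n; m <- prob$m
  h <- numeric(n + m)                       # max subst path to descendant tips
  for (j in rev(seq_len(nrow(prob$edge)))) {
    p <- prob$edge[j, 1]; c <- prob$edge[j, 2]
    h[p] <- max(h[p], h[c] + prob$phy$edge.length[j])
  }
  two_sided <- which(prob$min_cal > 0 & is.finite(prob$max_cal))
  s <- if (length(two_sided) > 0) {
    c0 <- two_sided[1]
    (prob$min_cal[c0] + prob$max_cal[c0]) / 2 / max(h[c0], 1e-12)
  } else if (any(prob$min_cal > 0)) {
    c0 <- which.max(prob$min_cal)
    prob$min_cal[c0] / max(h[c0], 1e-12)
  } else 1
  target <- h * s
  u <- numeric(m)
  ages <- numeric(n + m)
  parent_of <- rep(NA_integer_, n + m)
  parent_of[prob$edge[, 2]] <- prob$edge[, 1]
  for (k in seq_along(prob$preorder)) {
    i <- prob$preorder[k]
    lo <- prob$lower[i]
    hi <- if (i == prob$root) prob$max_cal[i] else {
      min(ages[parent_of[i]], prob$max_cal[i])
    }
    if (!is.finite(hi)) {
      u[k] <- log(max(target[i] - lo, 1e-6))
      ages[i] <- lo + exp(u[k])
    } else if (hi - lo <= 0) {
      ages[i] <- lo
    } else {
      sfrac <- min(max((target[i] - lo) / (hi - lo), 0.02), 0.98)
      u[k] <- stats::qlogis(sfrac)
      ages[i] <- lo + (hi - lo) * sfrac
    }
  }
  u
}

# map unconstrained parameters u (one per internal node, preorder) to ages
pl_ages_from_u <- function(prob, u, grad = FALSE) {
  ages <- numeric(prob$n + prob$m)
  dA_du <- numeric(prob$n + prob$m)
  dA_dp <- numeric(prob$n + prob$m)
  parent_of <- rep(NA_integer_, prob$n + prob$m)
  parent_of[prob$edge[, 2]] <- prob$edge[, 1]
  for (k in seq_along(prob$preorder)) {
    i <- prob$preorder[k]
    lo <- prob$lower[i]
    if (i == prob$root) {
      hi <- prob$max_cal[i]
      if (is.finite(hi)) {
        w <- hi - lo
        if (w <= 0) { ages[i] <- lo; next }
        s <- stats::plogis(u[k])
        ages[i] <- lo + w * s
        dA_du[i] <- w * s * (1 - s)
      } else {
        eu <- exp(min(u[k], 50))
        ages[i] <- lo + eu
        dA_du[i] <- eu
      }
    } else {
      ap <- ages[parent_of[i]]
      hi <- min(ap, prob$max_cal[i])
      w <- hi - lo
      if (w <= 0) { ages[i] <- lo; next }
      s <- stats::plogis(u[k])
      ages[i] <- lo + w * s
      dA_du[i] <- w * s * (1 - s)
      if (ap < prob$max_cal[i]) dA_dp[i] <- s
    }
  }
  if (grad) list(ages = ages, dA_du = dA_du, dA_dp = dA_dp,
                 parent_of = parent_of)
  else ages
}

#' Penalized-likelihood objective
#'
#' The smoothed log-likelihood `sum_j [x_j log(r_j t_j) - r_j t_j] -
#' lambda * Phi(r)`, where `x_j` is the expected substitution count on
#' branch `j`, `t_j` its duration implied by `ages`, `r_j` its rate
#' (substitution counts per MY across the alignment), and `Phi` sums squared
#' rate differences between each non-root branch and its parent branch plus
#' the sample variance of the root's immediate descendant rates. Larger is
#' better. A zero duration on a branch with positive expected count yields
#' `-Inf` (infeasible proposal, not an error).
#'
#' @param problem A `pl_problem`.
#' @param rates Per-edge rates (ordered as `problem$edge`), counts/MY scale.
#' @param ages Node-age vector (MYA) indexed by ape node id; tips 0.
#' @param lambda Smoothing weight (>= 0).
#' @param weights Optional 0/1 per-edge weights on the likelihood term
#'   (used by cross-validation to leave a branch out).
#' @return Scalar objective (maximize).
#' @export
pl_objective <- function(problem, rates, ages, lambda, weights = NULL) {
  t <- ages[problem$edge[, 1]] - ages[problem$edge[, 2]]
  if (any(t < 0)) return(-Inf)
  x <- problem$x
  if (!is.null(weights)) x <- x * weights
  mu <- rates * t
  if (any(t == 0 & x > 0)) return(-Inf)
  pos <- x > 0
  ll <- sum(x[pos] * log(mu[pos])) - sum(if (is.null(weights)) mu else mu * weights)
  pe <- problem$parent_edge
  has_pe <- !is.na(pe)
  phi <- sum((rates[has_pe] - rates[pe[has_pe]])^2)
  if (length(problem$root_edges) > 1) {
    phi <- phi + stats::var(rates[problem$root_edges])
  }
  ll - lambda * phi
}

# negative objective and gradient in transformed parameters
# par = c(u[internal nodes, preorder], v = log rates[edges])
pl_negobj <- function(par, prob, lambda, weights = NULL) {
  m <- prob$m
  tr <- pl_ages_from_u(prob, par[seq_len(m)], grad = FALSE)
  r <- exp(par[m + seq_len(nrow(prob$edge))])
  val <- pl_objective(prob, r, tr, lambda, weights)
  if (!is.finite(val)) return(1e12)
  -val
}

pl_neggrad <- function(par, prob, lambda, weights = NULL) {
  m <- prob$m
  E <- nrow(prob$edge)
  tr <- pl_ages_from_u(prob, par[seq_len(m)], grad = TRUE)
  ages <- tr$ages
  r <- exp(par[m + seq_len(E)])
  t <- ages[prob$edge[, 1]] - ages[prob$edge[, 2]]
  t <- pmax(t, 1e-12)
  x <- prob$x
  w <- if (is.null(weights)) rep(1, E) else weights
  xe <- x * w

  # d obj / d t_j and accumulation onto node ages
  dt <- xe / t - r * w
  g_age <- numeric(prob$n + prob$m)
  for (j in seq_len(E)) {
    g_age[prob$edge[j, 1]] <- g_age[prob$edge[j, 1]] + dt[j]
    if (prob$edge[j, 2] > prob$n) {
      g_age[prob$edge[j, 2]] <- g_age[prob$edge[j, 2]] - dt[j]
    }
  }
  # backpropagate through the sequential age transform (reverse preorder)
  g_u <- numeric(m)
  for (k in rev(seq_along(prob$preorder))) {
    i <- prob$preorder[k]
    if (i != prob$root && tr$dA_dp[i] != 0) {
      g_age[tr$parent_of[i]] <- g_age[tr$parent_of[i]] + g_age[i] * tr$dA_dp[i]
    }
    g_u[k] <- g_age[i] * tr$dA_du[i]
  }
  # d obj / d r_j
  dr <- xe / r - t * w
  pe <- prob$parent_edge
  has_pe <- which(!is.na(pe))
  diffs <- r[has_pe] - r[pe[has_pe]]
  dphi <- numeric(E)
  for (idx in seq_along(has_pe)) {
    j <- has_pe[idx]
    dphi[j] <- dphi[j] + 2 * diffs[idx]
    dphi[pe[j]] <- dphi[pe[j]] - 2 * diffs[idx]
  }
  re <- prob$root_edges
  if (length(re) > 1) {
    mu_r <- mean(r[re])
    dphi[re] <- dphi[re] + 2 * (r[re] - mu_r) / (length(re) - 1)
  }
  dr <- dr - lambda * dphi
  g_v <- dr * r
  -c(g_u, g_v)
}

#' Estimate a chronogram by penalized likelihood
#'
#' Fits node ages and per-branch rates by maximizing the penalized
#' likelihood of [pl_objective()] with a quasi-Newton optimizer and multiple
#' random restarts. Node ages are parameterized sequentially from the root
#' down, each age constrained between its subtree's calibration floor and
#' its parent's age (and its own maximum, if any), so every iterate -- and
#' therefore the returned chronogram -- satisfies all calibration bounds and
#' parent-older-than-child exactly. Rates are optimized in log space.
#'
#' At least one calibration must carry both a finite minimum and a finite
#' maximum somewhere on the tree; otherwise the time scale is not
#' identifiable and an error is raised.
#'
#' @param phy A `phylogram`.
#' @param calibrations Calibration data frame (see [pl_problem()]).
#' @param lambda Smoothing weight (default 1). Ignored when
#'   `cross_validate = TRUE`.
#' @param cross_validate If `TRUE`, pick `lambda` from `lambda_grid` by
#'   [cross_validate_lambda()] first.
#' @param lambda_grid Candidate smoothing weights for cross-validation.
#' @param restarts Number of optimizer starts (>= 1); the first is
#'   deterministic, the rest are jittered using `seed`.
#' @param seed Integer seed making the fit deterministic.
#' @param maxit Maximum optimizer iterations per start.
#' @return An object of class `pl_chronogram`: the fitted [chronogram()]
#'   plus rates (substitutions/site/MY), objective value at the start and
#'   optimum, convergence flag, `lambda`, and `seed`.
#' @examples
#' phy <- read_phylogram(text = "((A:0.10,B:0.10):0.05,C:0.15);",
#'                       alignment_length = 1000)
#' cal <- data.frame(taxonA = "A", taxonB = "C", min_age = 9, max_age = 11)
#' fit <- pl_chronogram_fit(phy, cal)
#' coef(fit)
#' @export
pl_chronogram_fit <- function(phy, calibrations, lambda = 1,
                              cross_validate = FALSE,
                              lambda_grid = 10^seq(-2, 3, by = 1),
                              restarts = 5, seed = 1, maxit = 500) {
  stopifnot(restarts >= 1, lambda >= 0)
  cal <- calibrations
  ok <- !is.na(cal$min_age) & !is.na(cal$max_age)
  if (!any(ok)) {
    stop("need at least one calibration with both finite min and max age; ",
         "the time scale is otherwise unidentifiable", call. = FALSE)
  }
  if (cross_validate) {
    cv <- cross_validate_lambda(phy, calibrations, lambda_grid, seed = seed)
    lambda <- cv$best_lambda
  }
  prob <- pl_problem(phy, calibrations)
  m <- prob$m
  E <- nrow(prob$edge)

  with_seed(seed, {
    best <- NULL
    init_obj <- NA_real_
    u_heur <- pl_init_u(prob)
    for (rs in seq_len(restarts)) {
      u0 <- if (rs == 1) u_heur else if (rs == 2) rep(0, m) else {
        u_heur + stats::runif(m, -1.5, 1.5)
      }
      ages0 <- pl_ages_from_u(prob, u0)
      t0 <- pmax(ages0[prob$edge[, 1]] - ages0[prob$edge[, 2]], 1e-8)
      r0 <- max(sum(prob$x) / sum(t0), 1e-10)
      v0 <- rep(log(r0), E) + if (rs == 1) 0 else stats::rnorm(E, 0, 0.3)
      par0 <- c(u0, v0)
      if (rs == 1) init_obj <- -pl_negobj(par0, prob, lambda)
      fit <- tryCatch(
        stats::optim(par0, pl_negobj, pl_neggrad, prob = prob,
                     lambda = lambda, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best)) stop("optimizer failed on every restart", call. = FALSE)
  converged <- best$convergence == 0
  if (!converged) {
    warning("optimizer did not report convergence after ", restarts,
            " restart(s); returning best solution found", call. = FALSE)
  }
  ages <- pl_ages_from_u(prob, best$par[seq_len(m)])
  rates_counts <- exp(best$par[m + seq_len(E)])
  chr <- chronogram(prob$phy, ages, rates = rates_counts / prob$alignment_length)
  structure(list(chronogram = chr, ages = ages,
                 rates = rates_counts / prob$alignment_length,
                 objective = -best$value, init_objective = init_obj,
                 converged = converged, lambda = lambda, seed = seed,
                 restarts = restarts, problem = prob),
            class = "pl_chronogram")
}

#' @export
print.pl_chronogram <- function(x, ...) {
  cat("Penalized-likelihood chronogram fit\n")
  cat("  tips:", x$problem$n, "  lambda:", x$lambda,
      "  objective:", format(x$objective, digits = 8),
      "  converged:", x$converged, "\n")
  cat("  root age:", format(max(x$ages), digits = 6), "MYA\n")
  invisible(x)
}

#' @export
summary.pl_chronogram <- function(object, ...) {
  defs <- node_definitions(object$problem$phy)
  defs$age <- object$ages[defs$node]
  out <- list(node_ages = defs, lambda = object$lambda,
              objective = object$objective,
              init_objective = object$init_objective,
              converged = object$converged,
              rate_range = range(object$rates))
  class(out) <- "summary.pl_chronogram"
  out
}

#' @export
print.summary.pl_chronogram <- function(x, ...) {
  cat("PL chronogram fit (lambda =", x$lambda, ")\n")
  cat("objective:", format(x$objective, digits = 8),
      " (initial:", format(x$init_objective, digits = 8), ")\n")
  cat("rates (subst/site/MY):", format(x$rate_range, digits = 4), "\n")
  print(x$node_ages, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pl_chronogram <- function(object, ...) {
  n <- object$problem$n
  ids <- (n + 1):(n + object$problem$m)
  stats::setNames(object$ages[ids], paste0("n", ids))
}

#' @export
plot.pl_chronogram <- function(x, ...) {
  ape::plot.phylo(x$chronogram$phy, ...)
  ape::axisPhylo()
  invisible(x)
}

#' Choose the smoothing weight by leave-one-branch-out cross-validation
#'
#' For each candidate `lambda`, each terminal branch is left out of the
#' likelihood in turn; the refitted model predicts that branch's expected
#' substitution count from its fitted rate (driven, for the left-out branch,
#' by the smoothing penalty alone) and its duration, and the candidate is
#' scored by the summed chi-square-like prediction error
#' `(x_j - mu_j)^2 / mu_j`. The lambda minimizing the score wins; the full
#' score table is returned for audit.
#'
#' @inheritParams pl_chronogram_fit
#' @param lambda_grid Non-empty numeric vector of candidate weights.
#' @return List with `best_lambda`, `scores` (data frame lambda/score), and
#'   `note`.
#' @export
cross_validate_lambda <- function(phy, calibrations, lambda_grid, seed = 1,
                                  restarts = 1) {
  if (length(lambda_grid) == 0) stop("lambda_grid is empty", call. = FALSE)
  if (length(lambda_grid) == 1) {
    return(list(best_lambda = lambda_grid,
                scores = data.frame(lambda = lambda_grid, score = NA_real_),
                note = "degenerate grid: single candidate returned unscored"))
  }
  prob <- pl_problem(phy, calibrations)
  term <- which(prob$edge[, 2] <= prob$n & prob$x > 0)
  scores <- vapply(lambda_grid, function(lam) {
    err <- 0
    for (j in term) {
      w <- rep(1, nrow(prob$edge)); w[j] <- 0
      fit <- pl_fit_weighted(phy, calibrations, lam, w,
                             seed = seed, restarts = restarts)
      mu <- fit$rates_counts[j] * fit$durations[j]
      err <- err + (prob$x[j] - mu)^2 / max(mu, 1e-9)
    }
    err
  }, numeric(1))
  best <- lambda_grid[which.min(scores)]
  list(best_lambda = best,
       scores = data.frame(lambda = lambda_grid, score = scores),
       note = "leave-one-terminal-branch-out prediction error")
}

# internal: one weighted PL fit, returning count-scale rates and durations
pl_fit_weighted <- function(phy, calibrations, lambda, weights, seed = 1,
                            restarts = 1) {
  prob <- pl_problem(phy, calibrations)
  m <- prob$m; E <- nrow(prob$edge)
  with_seed(seed, {
    best <- NULL
    for (rs in seq_len(restarts)) {
      u0 <- if (rs == 1) rep(0, m) else stats::runif(m, -2, 2)
      ages0 <- pl_ages_from_u(prob, u0)
      t0 <- pmax(ages0[prob$edge[, 1]] - ages0[prob$edge[, 2]], 1e-8)
      r0 <- max(sum(prob$x * weights) / sum(t0 * weights), 1e-10)
      par0 <- c(u0, rep(log(r0), E))
      fit <- tryCatch(
        stats::optim(par0, pl_negobj, pl_neggrad, prob = prob,
                     lambda = lambda, weights = weights, method = "BFGS",
                     control = list(maxit = 400, reltol = 1e-11)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
  })
  if (is.null(best)) stop("weighted PL fit failed", call. = FALSE)
  ages <- pl_ages_from_u(prob, best$par[seq_len(m)])
  list(rates_counts = exp(best$par[m + seq_len(E)]),
       durations = ages[prob$edge[, 1]] - ages[prob$edge[, 2]],
       objective = -best$value)
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  eval.parent(substitute(code))
}
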