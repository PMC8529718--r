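# Shared fixtures and independent oracles used across the test files.

fixture_path <- function(...) {
  system.file("extdata", ..., package = "fossilsieve")
}

fixture_phylogram <- function(alignment_length = 1047) {
  read_phylogram(fixture_path("synthetic_carpet_phylogram.nwk"),
                 alignment_length = alignment_length)
}

fixture_registry <- function() {
  suppressWarnings(load_registry(
    fixture_path("synthetic_registry.csv"),
    rules = read_node_rules(fixture_path("node_rules.yaml"))))
}

fixture_node_defs <- function() {
  utils::read.csv(fixture_path("node_definitions.csv"), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Independent penalized-likelihood oracle: multi-pass grid search over the
# free internal node ages, profiling the rates at each grid point by direct
# maximization of the objective written out from scratch here (it shares no
# code with the package's optimizer).

# tree bookkeeping from a raw ape phylo
oracle_tree_info <- function(phy) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- ape::Ntip(phy)
  edge <- phy$edge
  E <- nrow(edge)
  edge_into <- rep(NA_integer_, n + phy$Nnode)
  edge_into[edge[, 2]] <- seq_len(E)
  list(phy = phy, n = n, m = phy$Nnode, root = n + 1L, edge = edge, E = E,
       edge_into = edge_into,
       parent_edge = edge_into[edge[, 1]],
       root_edges = which(edge[, 1] == n + 1L),
       preorder = unique(edge[, 1]))
}

oracle_objective <- function(info, x, rates, ages, lambda) {
  t <- ages[info$edge[, 1]] - ages[info$edge[, 2]]
  if (any(t <= 0 & x > 0)) return(-Inf)
  ll <- sum(x * log(rates * t) - rates * t)
  pe <- info$parent_edge
  has <- !is.na(pe)
  phi <- sum((rates[has] - rates[pe[has]])^2)
  if (length(info$root_edges) > 1) phi <- phi + stats::var(rates[info$root_edges])
  ll - lambda * phi
}

# quadratic form of the rate penalty: Phi(r) = r' Q r
oracle_penalty_matrix <- function(info) {
  E <- info$E
  Q <- matrix(0, E, E)
  pe <- info$parent_edge
  for (j in which(!is.na(pe))) {
    p <- pe[j]
    Q[j, j] <- Q[j, j] + 1
    Q[p, p] <- Q[p, p] + 1
    Q[j, p] <- Q[j, p] - 1
    Q[p, j] <- Q[p, j] - 1
  }
  re <- info$root_edges
  k <- length(re)
  if (k > 1) {
    C <- (diag(k) - matrix(1 / k, k, k)) / (k - 1)
    Q[re, re] <- Q[re, re] + C
  }
  Q
}

# profile the rates at fixed ages by damped Newton; the objective
# sum(x log r - t r) - lambda r'Qr is strictly concave in r (x > 0)
oracle_profile_rates <- function(info, x, ages, lambda, Q, r_start = NULL) {
  t <- ages[info$edge[, 1]] - ages[info$edge[, 2]]
  if (any(t <= 0)) return(list(value = -Inf, rates = NULL))
  obj <- function(r) sum(x * log(r * t) - r * t) - lambda * drop(r %*% Q %*% r)
  r <- if (is.null(r_start) || any(r_start <= 0)) x / t else r_start
  f <- obj(r)
  for (it in 1:60) {
    g <- x / r - t - 2 * lambda * drop(Q %*% r)
    H <- diag(x / r^2, nrow = length(r)) + 2 * lambda * Q
    d <- tryCatch(solve(H, g), error = function(e) g / diag(H))
    alpha <- 1
    repeat {
      r_new <- r + alpha * d
      if (all(r_new > 0)) {
        f_new <- obj(r_new)
        if (f_new >= f - 1e-12) break
      }
      alpha <- alpha / 2
      if (alpha < 1e-10) { r_new <- r; f_new <- f; break }
    }
    moved <- max(abs(r_new - r) / pmax(r, 1e-12))
    r <- r_new; f <- f_new
    if (moved < 1e-11) break
  }
  list(value = f, rates = r)
}

# exhaustive grid search with successive refinement over the free node ages;
# `bounds` is a list keyed by internal node id giving c(min, max); the root
# must be bounded. A node with min == max is held fixed at that age.
# Unlisted nodes range within (0, parent age). Each pass recenters the
# windows at the incumbent optimum +/- 2 grid spacings, clipped to the
# original bounds, so the search never loses the global feasible box.
oracle_grid_pl <- function(phy, x, lambda, bounds, n_grid = 11, passes = 5) {
  info <- oracle_tree_info(phy)
  Q <- oracle_penalty_matrix(info)
  internal <- info$preorder
  orig <- list()
  fixed_age <- rep(NA_real_, info$n + info$m)
  for (i in internal) {
    key <- as.character(i)
    b <- if (!is.null(bounds[[key]])) bounds[[key]] else c(0, NA)
    if (!is.na(b[2]) && b[2] - b[1] <= 1e-9) fixed_age[i] <- b[1]
    orig[[key]] <- b
  }
  free <- internal[is.na(fixed_age[internal])]
  m <- length(free)
  best <- list(value = -Inf, ages = NULL)
  r_warm <- NULL
  win <- NULL

  # one sequence of joint grid passes over the current windows
  run_joint_passes <- function(n_passes) {
   for (pass in seq_len(n_passes)) {
    combo_ages <- function(idx_vec) {
      ages <- numeric(info$n + info$m)
      ages[!is.na(fixed_age)] <- fixed_age[!is.na(fixed_age)]
      for (i in internal) {
        k <- match(i, free)
        if (is.na(k)) next      # fixed node, already set
        w <- win[[k]]
        lo <- w[1]
        hi <- w[2]
        if (i != info$root) {
          pa <- ages[info$edge[info$edge_into[i], 1]]
          hi <- if (is.na(hi)) pa else min(hi, pa)
        }
        if (is.na(hi) || hi <= lo) return(NULL)
        ages[i] <- lo + (hi - lo) * (idx_vec[k] - 1) / (n_grid - 1)
        if (i != info$root) {
          pa <- ages[info$edge[info$edge_into[i], 1]]
          if (ages[i] >= pa) return(NULL)
        }
      }
      ages
    }
    idx <- rep(1L, m)
    repeat {
      ages <- combo_ages(idx)
      if (!is.null(ages)) {
        pr <- oracle_profile_rates(info, x, ages, lambda, Q, r_warm)
        if (pr$value > best$value) {
          best <<- list(value = pr$value, ages = ages)
          r_warm <<- pr$rates
        }
      }
      k <- 1L
      repeat {
        idx[k] <- idx[k] + 1L
        if (idx[k] <= n_grid) break
        idx[k] <- 1L
        k <- k + 1L
        if (k > m) break
      }
      if (k > m) break
    }
    # recenter windows around the incumbent, clipped to the original bounds
    for (k in seq_len(m)) {
      i <- free[k]
      ob <- orig[[as.character(i)]]
      w <- win[[k]]
      hi_cur <- if (is.na(w[2])) best$ages[info$root] else w[2]
      span <- (hi_cur - w[1]) / (n_grid - 1) * 2
      ctr <- best$ages[i]
      lo_new <- max(ob[1], ctr - span)
      hi_new <- if (is.na(ob[2])) ctr + span else min(ob[2], ctr + span)
      # keep an original bound in play while the incumbent sits on the grid
      # point adjacent to it, so a boundary optimum is never clipped out of
      # the shrinking window (span is two grid spacings)
      if (ctr - ob[1] <= 0.55 * span) lo_new <- ob[1]
      if (!is.na(ob[2]) && ob[2] - ctr <= 0.55 * span) hi_new <- ob[2]
      win[[k]] <- c(lo_new, hi_new)
    }
    win <<- win
   }
  }

  # coordinate polish: 1D refined scans over each node's full conditional
  # feasible interval; recovers from any corner the joint grid got stuck in
  children_of <- lapply(seq_len(info$n + info$m),
                        function(i) info$edge[info$edge[, 1] == i, 2])
  run_polish <- function() {
   for (sweep in 1:8) {
    improved <- FALSE
    for (i in free) {
      ob <- orig[[as.character(i)]]
      ages <- best$ages
      lo <- max(ob[1], max(c(0, ages[children_of[[i]]])))
      hi <- if (i == info$root) ob[2] else {
        pa <- ages[info$edge[info$edge_into[i], 1]]
        if (is.na(ob[2])) pa else min(ob[2], pa)
      }
      if (!is.finite(hi) || hi - lo <= 1e-12) next
      w <- c(lo, hi)
      for (pass in 1:6) {
        cand <- seq(w[1], w[2], length.out = 21)
        vals <- vapply(cand, function(a) {
          ag <- ages; ag[i] <- a
          if (a > lo && a < hi || a == lo || a == hi) {
            # exclude exact ties with parent/child ages
            if (any(abs(a - ages[children_of[[i]]]) < 1e-12)) return(-Inf)
            oracle_profile_rates(info, x, ag, lambda, Q, r_warm)$value
          } else -Inf
        }, numeric(1))
        kbest <- which.max(vals)
        sp <- (w[2] - w[1]) / 20
        ctr <- cand[kbest]
        w <- c(max(lo, ctr - 2 * sp), min(hi, ctr + 2 * sp))
        if (vals[kbest] > best$value + 1e-10) {
          ages[i] <- ctr
          pr <- oracle_profile_rates(info, x, ages, lambda, Q, r_warm)
          best <<- list(value = pr$value, ages = ages)
          r_warm <<- pr$rates
          improved <- TRUE
        }
      }
    }
    if (!improved) break
   }
  }

  win <- orig[as.character(free)]
  run_joint_passes(passes)
  run_polish()
  # outer rounds: re-run the joint grid in a narrow box around the polished
  # incumbent, to climb diagonal ridges that single-coordinate moves cannot
  for (round in 1:4) {
    prev <- best$value
    frac <- 0.04 / round
    win <- lapply(seq_len(m), function(k) {
      i <- free[k]
      ob <- orig[[as.character(i)]]
      R <- if (is.na(ob[2])) best$ages[info$root] - ob[1] else ob[2] - ob[1]
      ctr <- best$ages[i]
      lo <- max(ob[1], ctr - frac * R)
      hi <- if (is.na(ob[2])) ctr + frac * R else min(ob[2], ctr + frac * R)
      c(lo, hi)
    })
    run_joint_passes(3)
    run_polish()
    if (best$value - prev < 1e-9 * max(1, abs(prev))) break
  }
  best
}

# random rooted 4-taxon PL dating problem; root_point = TRUE fixes the root
# age exactly (two free node ages), otherwise an internal min/max window
# plus a root maximum leaves three free node ages
make_problem4 <- function(seed, root_point) {
  set.seed(seed)
  shape <- sample(c("balanced", "caterpillar"), 1)
  nwk_t <- if (shape == "balanced") "((A:%f,B:%f):%f,(C:%f,D:%f):%f);" else
    "(((A:%f,B:%f):%f,C:%f):%f,D:%f);"
  root_age <- runif(1, 80, 250)
  if (shape == "balanced") {
    a1 <- root_age * runif(1, 0.3, 0.8)   # MRCA(A,B)
    a2 <- root_age * runif(1, 0.3, 0.8)   # MRCA(C,D)
    durs <- c(a1, a1, root_age - a1, a2, a2, root_age - a2)
    inner <- c(a1 = a1, a2 = a2)
  } else {
    a2 <- root_age * runif(1, 0.3, 0.8)   # MRCA(A,B,C)
    a1 <- a2 * runif(1, 0.3, 0.8)         # MRCA(A,B)
    durs <- c(a1, a1, a2 - a1, a2, root_age - a2, root_age)
    inner <- c(a1 = a1, a2 = a2)
  }
  L <- 800
  rate <- 0.003 * exp(rnorm(6, 0, 0.25))
  x <- rpois(6, rate * durs * L)
  x[x == 0] <- 1
  nwk <- do.call(sprintf, c(list(nwk_t), as.list(x / L)))
  phy <- read_phylogram(text = nwk, alignment_length = L)
  if (root_point) {
    cal <- data.frame(taxonA = "A", taxonB = "D",
                      min_age = root_age, max_age = root_age)
    bounds <- list("5" = c(root_age, root_age))
  } else {
    lo <- inner[2] * 0.85
    hi <- inner[2] * 1.15
    pair <- if (shape == "balanced") c("C", "D") else c("A", "C")
    cal <- data.frame(taxonA = c(pair[1], "A"), taxonB = c(pair[2], "D"),
                      min_age = c(lo, NA), max_age = c(hi, root_age * 1.3))
    node2 <- mrca_node(phy, pair[1], pair[2])
    bounds <- list("5" = c(0, root_age * 1.3))
    bounds[[as.character(node2)]] <- c(lo, hi)
  }
  list(phy = phy, cal = cal, bounds = bounds, shape = shape,
       truth = c(root = root_age, inner))
}

# brute-force MRCA: intersect root-to-tip ancestor chains
oracle_mrca <- function(phy, a, b) {
  anc <- function(tip) {
    node <- match(tip, phy$tip.label)
    path <- node
    while (node != ape::Ntip(phy) + 1L) {
      node <- phy$edge[phy$edge[, 2] == node, 1]
      path <- c(path, node)
    }
    path
  }
  pa <- anc(a)
  common <- intersect(pa, anc(b))
  # lowest common ancestor = first common node on a's upward path
  pa[pa %in% common][1]
}

# iid draws from the flat node-age prior over the feasible polytope
oracle_prior_draws <- function(phy, root_max, n_draws, seed) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- ape::Ntip(phy)
  m <- phy$Nnode
  edge <- phy$edge
  out <- matrix(NA_real_, n_draws, m)
  set.seed(seed)
  got <- 0
  while (got < n_draws) {
    a <- numeric(n + m)
    a[(n + 1):(n + m)] <- stats::runif(m, 0, root_max)
    if (all(a[edge[, 1]] > a[edge[, 2]])) {
      got <- got + 1
      out[got, ] <- a[(n + 1):(n + m)]
    }
  }
  out
}

# one draw of internal node ages from the flat feasible-polytope prior
# (uniform on [0, root_max] per internal node, rejected unless every parent
# is older than its child) -- used for simulation-based calibration
draw_polytope_ages <- function(phy, root_max, seed) {
  n <- ape::Ntip(phy); m <- phy$Nnode
  edge <- phy$edge
  with_seed(seed, {
    repeat {
      ages <- c(rep(0, n), stats::runif(m, 0, root_max))
      if (all(ages[edge[, 1]] > ages[edge[, 2]])) break
    }
    ages
  })
}
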