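# Penalized-likelihood divergence-time estimation on a fixed topology under
# hard minimum/maximum node-age constraints, with cross-validated smoothing
# selection (direct and subsampled-replicate schemes) and a chi-square
# molecular-clock likelihood-ratio test.
#
# Model: per-edge substitution counts x_k = round(length_k * n_sites) are
# Poisson with mean r_k * t_k * n_sites (r_k the edge rate, t_k the edge
# duration).  The objective is the negative Poisson log-likelihood plus
# lambda times an autocorrelation roughness penalty: squared parent-child
# rate differences over all non-root edges plus the variance of the rates on
# the root's child edges (Sanderson-style).  Node ages are optimised jointly
# with log rates; ages are parametrised per node as a fraction in [0,1]
# between the constraint-feasible envelope below (max of descendant minima)
# and above (min of own maximum and the parent's current age), which makes
# every iterate feasible by construction.

#' Assemble a penalized-likelihood dating problem
#'
#' Maps the calibrations onto nodes of the phylogram's topology, merges the
#' root constraint into the bound system, and validates feasibility.
#' Calibrated windows that sit strictly above an ancestor's maximum are
#' reported: a warning here, an error when fitting.
#'
#' @param phylo A [phylogram()].
#' @param calibrations A [calibration_set()] with taxa assigned, or `NULL`.
#'   Windows with `min == max` pin a node's age exactly.
#' @param root A [root_constraint()] giving the hard root window.
#' @param lambda Smoothing parameter (> 0); large values force clock-like
#'   rates.
#' @return List of class `"pl_problem"`.
#' @export
pl_problem <- function(phylo, calibrations = NULL,
                       root = root_constraint(), lambda = 0.0033) {
  stopifnot(inherits(phylo, "phylogram"), lambda > 0)
  tree <- phylo$tree
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  rootnode <- n + 1L
  minb <- rep(0, ntot)
  maxb <- rep(Inf, ntot)
  cal_nodes <- integer(0)
  if (!is.null(calibrations) && nrow(calibrations) > 0) {
    cal_nodes <- vapply(seq_len(nrow(calibrations)), function(i)
      map_to_node(tree, calibrations[i, ]), 0L)
    for (i in seq_along(cal_nodes)) {
      v <- cal_nodes[i]
      if (v <= n)
        stop("calibration '", calibrations$clade_label[i],
             "' maps to a tip; tips are fixed at age 0")
      minb[v] <- max(minb[v], calibrations$min_age[i])
      maxb[v] <- min(maxb[v], calibrations$max_age[i])
    }
  }
  if (!is.null(root)) {
    minb[rootnode] <- max(minb[rootnode], root$min_age)
    maxb[rootnode] <- min(maxb[rootnode], root$max_age)
  }
  pr <- structure(list(phylogram = phylo, tree = tree,
                       n_sites = phylo$n_sites, lambda = lambda,
                       calibrations = calibrations, cal_nodes = cal_nodes,
                       root = root, min_bound = minb, max_bound = maxb),
                  class = "pl_problem")
  chk <- tryCatch(pl_prepare(pr), error = function(e) e)
  if (inherits(chk, "error")) warning(conditionMessage(chk))
  pr
}

#' @export
print.pl_problem <- function(x, ...) {
  cat(sprintf(
    "PL dating problem: %d tips, %d calibrations, lambda = %g, %d sites\n",
    ape::Ntip(x$tree), length(x$cal_nodes), x$lambda, x$n_sites))
  invisible(x)
}

# Precompute index structures, substitution counts and feasibility envelopes.
pl_prepare <- function(problem) {
  tree <- problem$tree
  n <- ape::Ntip(tree)
  M <- tree$Nnode
  ntot <- n + M
  rootnode <- n + 1L
  pa <- tree$edge[, 1]
  ch <- tree$edge[, 2]
  E <- nrow(tree$edge)
  x <- round(tree$edge.length * problem$n_sites)
  if (any(x < 0)) stop("negative branch lengths in phylogram")
  parent_of <- rep(NA_integer_, ntot)
  parent_of[ch] <- pa
  pedge <- match(pa, ch)                      # parent edge of each edge
  root_edges <- which(is.na(pedge))
  pre_int <- preorder_internal(tree)
  minb <- problem$min_bound
  maxb <- problem$max_bound
  if (!is.finite(maxb[rootnode]))
    stop("the root needs a finite maximum age (supply a root constraint)")
  # lower envelope: max over own minimum and descendants' lower envelopes
  L <- numeric(ntot)
  kids <- split(ch, pa)
  for (v in rev(pre_int)) {
    L[v] <- max(minb[v], max(L[kids[[as.character(v)]]]))
  }
  # static upper envelope: min over own maximum and ancestors'
  U <- numeric(ntot)
  U[rootnode] <- maxb[rootnode]
  for (v in pre_int[-1]) U[v] <- min(maxb[v], U[parent_of[v]])
  bad <- pre_int[L[pre_int] > U[pre_int] + 1e-9]
  if (length(bad)) {
    v <- bad[1]
    below <- if (length(problem$cal_nodes))
      problem$calibrations$clade_label[
        which(abs(problem$calibrations$min_age - L[v]) < 1e-9)] else character(0)
    stop("infeasible constraint system at node ", v, ": required minimum ",
         signif(L[v], 6), " My exceeds allowed maximum ", signif(U[v], 6),
         " My", if (length(below)) paste0(
           " (descendant calibration '", below[1],
           "' vs an ancestor's maximum)") else "")
  }
  list(tree = tree, n = n, M = M, ntot = ntot, root = rootnode,
       pa = pa, ch = ch, E = E, x = x, lgx = lgamma(x + 1),
       n_sites = problem$n_sites, parent_of = parent_of, pedge = pedge,
       root_edges = root_edges, pre_int = pre_int, L = L, U = U,
       minb = minb, maxb = maxb,
       has_pe = !is.na(pedge), pe = pedge[!is.na(pedge)],
       u_pe = sort(unique(pedge[!is.na(pedge)])),
       u_pa = sort(unique(pa)))
}

# Ages from height fractions (forward pass of the feasible parametrisation).
# Returns ages plus per-internal-node hi and capped flag for the backward
# pass.
ages_from_fractions <- function(prep, f) {
  ages <- numeric(prep$ntot)
  Mn <- length(prep$pre_int)
  hi <- numeric(Mn)
  capped <- logical(Mn)
  for (idx in seq_len(Mn)) {
    v <- prep$pre_int[idx]
    if (v == prep$root) {
      h <- prep$U[v]
      capped[idx] <- TRUE  # root has no parent to propagate to
    } else {
      ap <- ages[prep$parent_of[v]]
      if (prep$maxb[v] < ap) { h <- prep$maxb[v]; capped[idx] <- TRUE }
      else h <- ap
    }
    hi[idx] <- h
    ages[v] <- prep$L[v] + f[idx] * (h - prep$L[v])
  }
  list(ages = ages, hi = hi, capped = capped)
}

# Objective + gradient in the (fraction, log-rate) parametrisation.
# clock = TRUE uses one shared log rate and no penalty.
pl_eval <- function(prep, lambda, par, clock = FALSE) {
  Mn <- length(prep$pre_int)
  f <- par[seq_len(Mn)]
  logr <- par[-seq_len(Mn)]
  r <- if (clock) rep(exp(logr), prep$E) else exp(logr)
  fw <- ages_from_fractions(prep, f)
  ages <- fw$ages
  t <- ages[prep$pa] - ages[prep$ch]
  teff <- pmax(t, 1e-9)
  mu <- r * teff * prep$n_sites
  value <- sum(mu - prep$x * log(mu) + prep$lgx)
  dphir <- NULL
  if (!clock) {
    dr <- r[prep$has_pe] - r[prep$pe]
    phi <- sum(dr * dr)
    rc <- r[prep$root_edges]
    m <- length(rc)
    if (m >= 2) phi <- phi + stats::var(rc)
    value <- value + lambda * phi
    dphir <- numeric(prep$E)
    dphir[prep$has_pe] <- 2 * dr
    s <- rowsum(2 * dr, prep$pe)
    dphir[prep$u_pe] <- dphir[prep$u_pe] - s[, 1]
    if (m >= 2)
      dphir[prep$root_edges] <- dphir[prep$root_edges] +
        2 * (rc - mean(rc)) / (m - 1)
  }
  # gradient wrt log rates
  resid <- mu - prep$x
  g_logr <- if (clock) sum(resid)
            else resid + lambda * dphir * r
  # gradient wrt ages, then back through the fraction transform
  dPdt <- (1 - prep$x / mu) * r * prep$n_sites * (t > 1e-9)
  g_age <- numeric(prep$ntot)
  s <- rowsum(dPdt, prep$pa)
  g_age[prep$u_pa] <- s[, 1]
  g_age[prep$ch] <- g_age[prep$ch] - dPdt
  a <- g_age
  gf <- numeric(Mn)
  for (idx in rev(seq_len(Mn))) {
    v <- prep$pre_int[idx]
    gf[idx] <- a[v] * (fw$hi[idx] - prep$L[v])
    if (!fw$capped[idx]) {
      p <- prep$parent_of[v]
      a[p] <- a[p] + a[v] * f[idx]
    }
  }
  list(value = value, gradient = c(gf, g_logr), ages = ages, rates = r,
       durations = t)
}

# optim wrapper with a shared cache so fn and gr evaluate the model once.
pl_optim <- function(prep, lambda, par0, clock = FALSE, maxit = 500,
                     factr = 1e4) {
  Mn <- length(prep$pre_int)
  E <- prep$E
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$res)
    res <- pl_eval(prep, lambda, par, clock)
    cache$par <- par
    cache$res <- res
    res
  }
  lower <- c(rep(0, Mn), rep(log(1e-9), if (clock) 1L else E))
  upper <- c(rep(1, Mn), rep(log(100), if (clock) 1L else E))
  out <- stats::optim(par0, fn = function(p) eval_at(p)$value,
                      gr = function(p) eval_at(p)$gradient,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr,
                                     lmm = 20))
  out
}

# Invert the fraction transform for a target age vector, clamping into the
# feasible envelope on the way down.
fractions_from_ages <- function(prep, ages) {
  Mn <- length(prep$pre_int)
  f <- numeric(Mn)
  cur <- ages
  for (idx in seq_len(Mn)) {
    v <- prep$pre_int[idx]
    hi <- if (v == prep$root) prep$U[v]
          else min(prep$maxb[v], cur[prep$parent_of[v]])
    a <- min(max(ages[v], prep$L[v]), hi)
    f[idx] <- if (hi - prep$L[v] > 1e-12) (a - prep$L[v]) / (hi - prep$L[v])
              else 0.5
    cur[v] <- a
  }
  f
}

# Starting parameter vectors: a depth-projection start (node ages
# proportional to the phylogram's own node depths, scaled into the root
# window), a flat start, and seeded jitters around the projection.
pl_starts <- function(prep, n_starts, seed, clock = FALSE) {
  Mn <- length(prep$pre_int)
  E <- if (clock) 1L else prep$E
  f0 <- rep(0.5, Mn)
  fw <- ages_from_fractions(prep, f0)
  tt <- sum(fw$ages[prep$pa] - fw$ages[prep$ch])
  r0 <- max(sum(prep$x) / (prep$n_sites * max(tt, 1e-9)), 1e-8)
  # depth projection: substitutions-per-site depth rescaled to the root age
  depth <- numeric(prep$ntot)
  for (idx in seq_along(prep$pre_int)) {   # preorder: parents first
    v <- prep$pre_int[idx]
    k <- which(prep$ch == v)
    depth[v] <- if (length(k)) depth[prep$pa[k]] + prep$x[k] / prep$n_sites
                else 0
  }
  depth[seq_len(prep$n)] <- NA            # tips not needed
  root_age0 <- (prep$L[prep$root] + prep$U[prep$root]) / 2
  maxd <- max(depth, na.rm = TRUE) + max(prep$x / prep$n_sites) / 2
  ages0 <- pmax(root_age0 * (1 - depth / max(maxd, 1e-12)), 0)
  ages0[seq_len(prep$n)] <- 0
  fA <- fractions_from_ages(prep, ages0)
  fwA <- ages_from_fractions(prep, fA)
  tA <- pmax(fwA$ages[prep$pa] - fwA$ages[prep$ch], 1e-6)
  rA <- pmin(pmax((prep$x / prep$n_sites) / tA, 1e-8), 50)
  logrA <- if (clock) log(max(sum(prep$x) /
                                (prep$n_sites * max(sum(tA), 1e-9)), 1e-8))
           else log(rA)
  starts <- list(c(fA, logrA), c(f0, rep(log(r0), E)))
  if (n_starts > length(starts)) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - 2L), function(s)
      c(pmin(pmax(fA + stats::rnorm(Mn, 0, 0.15), 0), 1),
        logrA + stats::rnorm(E, 0, 0.3))))
    starts <- c(starts, extra)
  }
  starts[seq_len(max(n_starts, 1L))]
}

#' Fit node ages and edge rates by penalized likelihood
#'
#' Minimises the penalized negative log-likelihood over node ages and edge
#' rates, subject to parent >= child ordering and every hard bound, using
#' multi-start L-BFGS-B with analytic gradients in a feasible-by-construction
#' parametrisation.  Deterministic for a fixed seed (the seed only drives the
#' multi-start jitter).
#'
#' @param problem A [pl_problem()].
#' @param n_starts Number of optimisation starts (first is deterministic).
#' @param seed Seed for the start jitter.
#' @param maxit,factr L-BFGS-B control parameters.
#' @param init Optional warm start: a parameter vector from a previous fit's
#'   `$par` (used alone, ahead of the regular starts).
#' @return Object of class `"pl_fit"`: `chronogram` (a `phylo` with edge
#'   lengths in My), `ages` (all nodes), `rates` (per edge,
#'   substitutions/site/My), `objective`, `par`, `convergence`.
#' @export
date_tree <- function(problem, n_starts = 5, seed = 1, maxit = 500,
                      factr = 1e4, init = NULL) {
  stopifnot(inherits(problem, "pl_problem"))
  prep <- pl_prepare(problem)
  starts <- if (!is.null(init)) list(init)
            else pl_starts(prep, n_starts, seed)
  best <- NULL
  for (p0 in starts) {
    out <- tryCatch(pl_optim(prep, problem$lambda, p0, maxit = maxit,
                             factr = factr),
                    error = function(e) NULL)
    if (!is.null(out) && (is.null(best) || out$value < best$value))
      best <- out
  }
  if (is.null(best)) stop("all optimisation starts failed")
  res <- pl_eval(prep, problem$lambda, best$par)
  ages <- res$ages
  # post-hoc feasibility assertion on every fit
  if (any(res$durations < -1e-9))
    stop("internal error: negative edge duration in fitted chronogram")
  viol <- which(ages < prep$minb - 1e-6 | ages > prep$maxb + 1e-6)
  if (length(viol))
    stop("internal error: fitted age violates a hard bound at node ",
         viol[1])
  chrono <- problem$tree
  chrono$edge.length <- pmax(res$durations, 0)
  structure(list(chronogram = chrono, ages = ages, rates = res$rates,
                 objective = best$value, par = best$par,
                 convergence = best$convergence, lambda = problem$lambda),
            class = "pl_fit")
}

#' @export
print.pl_fit <- function(x, ...) {
  ra <- max(x$ages)
  cat(sprintf(
    "PL fit: root age %.2f My, rate range [%.3g, %.3g] subst/site/My,\n",
    ra, min(x$rates), max(x$rates)))
  cat(sprintf("  penalized -lnL = %.4f (lambda = %g)\n", x$objective,
              x$lambda))
  invisible(x)
}

#' Penalized negative log-likelihood at given rates and ages
#'
#' The objective the fitter minimises, evaluated at user-supplied rates and
#' node ages: the full negative Poisson log-probability of the per-edge
#' substitution counts (factorial terms included) plus `lambda` times the
#' autocorrelation penalty (squared parent-child rate differences plus the
#' variance of the root's child-edge rates).
#'
#' @param problem A [pl_problem()].
#' @param rates Positive numeric vector, one rate per edge (edge-matrix row
#'   order).
#' @param ages Numeric vector of node ages indexed by node id (tips 0).
#' @return The penalized negative log-likelihood (a scalar).
#' @export
pl_objective <- function(problem, rates, ages) {
  prep <- pl_prepare(problem)
  stopifnot(length(rates) == prep$E, all(rates > 0),
            length(ages) == prep$ntot)
  viol <- which(ages < prep$minb - 1e-9 | ages > prep$maxb + 1e-9)
  if (length(viol))
    stop("age violates a hard bound at node ", viol[1])
  t <- ages[prep$pa] - ages[prep$ch]
  if (any(t < -1e-9))
    stop("ages do not respect the topology ordering (parent < child)")
  t <- pmax(t, 0)
  if (any(prep$x > 0 & t == 0))
    stop("non-positive duration on an edge with positive substitutions")
  mu <- rates * t * prep$n_sites
  pois <- ifelse(prep$x > 0, mu - prep$x * log(mu) + prep$lgx, mu)
  dr <- rates[prep$has_pe] - rates[prep$pe]
  phi <- sum(dr * dr)
  rc <- rates[prep$root_edges]
  if (length(rc) >= 2) phi <- phi + stats::var(rc)
  sum(pois) + problem$lambda * phi
}

#' Relative RMSE of recovered node ages against a known truth
#'
#' Root-mean-square error of the internal node ages, expressed as a fraction
#' of the true root age (error relative to tree height) -- per-node relative
#' errors are unbounded at near-present nodes, so tree-height normalisation
#' is the stable recovery metric.  Nodes are matched by bipartition.
#'
#' @param fit A [date_tree()] fit (or a chronogram `phylo`).
#' @param truth The true chronogram (`phylo`, edge lengths in My).
#' @return Relative RMSE (scalar).
#' @export
age_recovery_error <- function(fit, truth) {
  est <- if (inherits(fit, "pl_fit")) fit$chronogram else fit
  stopifnot(inherits(est, "phylo"), inherits(truth, "phylo"))
  ek <- clade_keys(est)
  tk <- clade_keys(truth)
  idx <- match(tk, ek)
  if (anyNA(idx)) stop("estimate and truth differ in topology")
  ta <- node_ages(truth)[as.integer(names(tk))]
  ea <- node_ages(est)[as.integer(names(ek)[idx])]
  sqrt(mean((ea - ta)^2)) / max(ta)
}

#' Chi-square likelihood-ratio test of the molecular clock
#'
#' Compares the free model (one Poisson mean per edge, maximised in closed
#' form) against the single-rate clock model (shared rate, ultrametric ages,
#' fitted by constrained optimisation with the root age fixed at 1 -- only
#' rate x time products are identifiable without calibrations).  The degrees
#' of freedom are the number of edges minus the number of identifiable clock
#' parameters (one age per internal node, the shared rate being absorbed by
#' the arbitrary time scale).
#'
#' @param phylo A [phylogram()].
#' @param n_starts,seed,maxit Optimisation controls for the clock fit.
#' @return List of class `"clock_test"`: `statistic`, `df`, `p_value`,
#'   `lnL_free`, `lnL_clock`.
#' @export
clock_test <- function(phylo, n_starts = 3, seed = 1, maxit = 500) {
  stopifnot(inherits(phylo, "phylogram"))
  problem <- structure(list(phylogram = phylo, tree = phylo$tree,
                            n_sites = phylo$n_sites, lambda = 1,
                            calibrations = NULL, cal_nodes = integer(0),
                            root = NULL, min_bound = NULL, max_bound = NULL),
                       class = "pl_problem")
  n <- ape::Ntip(phylo$tree)
  ntot <- n + phylo$tree$Nnode
  problem$min_bound <- rep(0, ntot)
  problem$max_bound <- rep(Inf, ntot)
  problem$min_bound[n + 1L] <- 1
  problem$max_bound[n + 1L] <- 1
  prep <- pl_prepare(problem)
  starts <- pl_starts(prep, n_starts, seed, clock = TRUE)
  best <- NULL
  for (p0 in starts) {
    out <- tryCatch(pl_optim(prep, 0, p0, clock = TRUE, maxit = maxit,
                             factr = 1e1),
                    error = function(e) NULL)
    if (!is.null(out) && (is.null(best) || out$value < best$value))
      best <- out
  }
  if (is.null(best)) stop("clock fit failed from every start")
  lnL_clock <- -best$value
  x <- prep$x
  lnL_free <- sum(ifelse(x > 0, x * log(x) - x - prep$lgx, 0))
  stat <- 2 * (lnL_free - lnL_clock)
  if (stat < -1e-6 * max(1, abs(lnL_free)))
    stop("free likelihood below clock likelihood: optimiser failure")
  stat <- max(stat, 0)
  df <- prep$E - length(prep$pre_int)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 lnL_free = lnL_free, lnL_clock = lnL_clock),
            class = "clock_test")
}

#' @export
print.clock_test <- function(x, ...) {
  cat(sprintf(
    "Molecular clock LRT: chi-square = %.3f, df = %d, p = %.4g\n",
    x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Geometric grid of candidate smoothing parameters
#'
#' The sequence `cvstart * cvmultstep^k` for `k = 0, 1, ...` while the value
#' stays at or above `cvstop`.  With the defaults (10, 0.0001, 0.9) this is
#' a 110-value grid.
#'
#' @param cvstart First (largest) value.
#' @param cvstop Smallest admissible value.
#' @param cvmultstep Multiplicative step in (0, 1).
#' @return Strictly decreasing numeric vector (a single value when
#'   `cvstart == cvstop`).
#' @export
smoothing_grid <- function(cvstart = 10, cvstop = 0.0001,
                           cvmultstep = 0.9) {
  if (!(cvmultstep > 0 && cvmultstep < 1))
    stop("cvmultstep must be in (0, 1)")
  if (!(cvstop > 0 && cvstop <= cvstart))
    stop("need 0 < cvstop <= cvstart")
  kmax <- floor(log(cvstop / cvstart) / log(cvmultstep) + 1e-9)
  cvstart * cvmultstep^(0:max(kmax, 0))
}

# Identify a calibration that makes the bound system infeasible on this
# topology (a descendant minimum above an ancestor maximum), or NULL if the
# system is feasible.  Used to prune calibration sets after tip subsampling,
# where clade MRCAs can shift and invert the original nesting.
feasibility_violation <- function(tree, cals, root) {
  if (is.null(cals) || nrow(cals) == 0) return(NULL)
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  minb <- rep(0, ntot); maxb <- rep(Inf, ntot)
  nodes <- vapply(seq_len(nrow(cals)), function(i)
    suppressWarnings(map_to_node(tree, cals[i, ])), 0L)
  for (i in seq_along(nodes)) {
    minb[nodes[i]] <- max(minb[nodes[i]], cals$min_age[i])
    maxb[nodes[i]] <- min(maxb[nodes[i]], cals$max_age[i])
  }
  if (!is.null(root)) {
    minb[n + 1L] <- max(minb[n + 1L], root$min_age)
    maxb[n + 1L] <- min(maxb[n + 1L], root$max_age)
  }
  pre_int <- preorder_internal(tree)
  parent_of <- parent_vec(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  L <- numeric(ntot)
  for (v in rev(pre_int)) L[v] <- max(minb[v], max(L[kids[[as.character(v)]]]))
  U <- numeric(ntot)
  U[n + 1L] <- maxb[n + 1L]
  for (v in pre_int[-1]) U[v] <- min(maxb[v], U[parent_of[v]])
  bad <- pre_int[L[pre_int] > U[pre_int] + 1e-9]
  if (!length(bad)) return(NULL)
  v <- bad[1]
  is_desc <- function(node, anc) {
    while (!is.na(node)) { if (node == anc) return(TRUE)
                           node <- parent_of[node] }
    FALSE
  }
  cand <- which(vapply(nodes, is_desc, TRUE, anc = v) &
                  cals$min_age > U[v] + 1e-9)
  if (!length(cand)) cand <- which(vapply(nodes, is_desc, TRUE, anc = v))
  cals$clade_label[cand[which.max(cals$min_age[cand])]]
}

# Drop calibrations until the bound system is feasible on this topology.
feasible_calibrations <- function(tree, cals, root) {
  while (!is.null(cals) && nrow(cals) > 0) {
    drop <- feasibility_violation(tree, cals, root)
    if (is.null(drop)) return(cals)
    cals <- cals[cals$clade_label != drop, , drop = FALSE]
  }
  NULL
}

# Precompute, once per tree, everything cross-validation needs per pruned
# terminal: the reduced phylogram, reduced calibrations, the identity of the
# merged sibling edge, the proportional attachment fraction and the observed
# substitution count of the pruned terminal.
cv_prepare <- function(phylo, calibrations, root, n_terminals, seed) {
  tree <- phylo$tree
  n <- ape::Ntip(tree)
  rootnode <- n + 1L
  if (is.null(n_terminals)) n_terminals <- min(n, 50L)
  if (n_terminals > n) stop("n_terminals exceeds the tip count")
  tips <- with_seed(seed, sample.int(n, n_terminals))
  par <- parent_vec(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  terminals <- list()
  skipped <- character(0)
  for (i in tips) {
    lab <- tree$tip.label[i]
    p <- par[i]
    if (p == rootnode) {
      skipped <- c(skipped, paste0(lab, " (parent is the root)"))
      next
    }
    sibs <- setdiff(kids[[as.character(p)]], i)
    if (length(sibs) != 1L) {
      skipped <- c(skipped, paste0(lab, " (polytomy at parent)"))
      next
    }
    s <- sibs
    g <- par[p]
    len_ps <- elen[[as.character(s)]]
    len_gp <- elen[[as.character(p)]]
    frac <- if (len_ps + len_gp > 0) len_ps / (len_ps + len_gp) else 0.5
    s_taxa <- if (s <= n) tree$tip.label[s]
              else ape::extract.clade(tree, s)$tip.label
    red_tree <- ape::drop.tip(tree, i)
    red_cals <- NULL
    ok <- TRUE
    if (!is.null(calibrations) && nrow(calibrations) > 0) {
      red_cals <- calibrations
      for (j in seq_len(nrow(calibrations))) {
        taxa <- setdiff(calibrations$taxa[[j]], lab)
        need <- if (calibrations$placement[j] == "crown") 2L else 1L
        if (length(taxa) < need) { ok <- FALSE; break }
        red_cals$taxa[[j]] <- taxa
      }
    }
    if (ok && !is.null(red_cals) &&
        !is.null(feasibility_violation(red_tree, red_cals, root)))
      ok <- FALSE
    if (!ok) {
      skipped <- c(skipped, paste0(lab, " (pruning disconnects a ",
                                   "calibration)"))
      next
    }
    terminals[[length(terminals) + 1L]] <- list(
      label = lab, observed = round(elen[[as.character(i)]] * phylo$n_sites),
      phylo = phylogram(red_tree, phylo$n_sites), cals = red_cals,
      s_taxa = s_taxa, frac = frac)
  }
  list(terminals = terminals, skipped = skipped)
}

# Score one lambda on a prepared cross-validation set.  Every lambda is
# fitted from the same deterministic cold starts: carrying warm starts
# across the grid would let fits at numerically weak penalties inherit the
# previous lambda's solution, masking the smoothing comparison.
cv_score_prepared <- function(cvp, lambda, root, error = "chisq",
                              n_starts = 2, maxit = 200) {
  terms <- numeric(0)
  for (j in seq_along(cvp$terminals)) {
    tm <- cvp$terminals[[j]]
    prob <- pl_problem(tm$phylo, tm$cals, root, lambda)
    fit <- date_tree(prob, n_starts = n_starts, maxit = maxit)
    red_tree <- tm$phylo$tree
    snode <- if (length(tm$s_taxa) == 1L)
      match(tm$s_taxa, red_tree$tip.label)
    else ape::getMRCA(red_tree, tm$s_taxa)
    gnode <- parent_vec(red_tree)[snode]
    t_attach <- fit$ages[snode] +
      (fit$ages[gnode] - fit$ages[snode]) * tm$frac
    eidx <- which(red_tree$edge[, 2] == snode)
    expected <- fit$rates[eidx] * t_attach * tm$phylo$n_sites
    terms <- c(terms,
               if (error == "chisq")
                 (tm$observed - expected)^2 / max(expected, 1e-8)
               else (tm$observed - expected)^2)
  }
  mean(terms)
}

#' Cross-validation prediction error for one smoothing value
#'
#' For each sampled terminal: prune it, refit the dating problem at `lambda`
#' on the reduced tree, and predict the pruned terminal's substitution count
#' as (rate of the merged sibling edge) x (attachment-point age) x
#' `n_sites`, the attachment age interpolated along the merged edge in
#' proportion to the original branch lengths.  The score is the mean
#' chi-square error `(obs - exp)^2 / exp` (or plain squared error).
#'
#' Terminals whose parent is the root, or whose pruning disconnects a
#' calibration, are skipped and listed in the `"skipped"` attribute.
#'
#' @param phylo A [phylogram()].
#' @param lambda Smoothing value to score.
#' @param calibrations Optional [calibration_set()] with taxa.
#' @param root A [root_constraint()].
#' @param n_terminals Number of terminals sampled (default
#'   `min(tip count, 50)`).
#' @param seed Seed for the terminal sample.
#' @param error `"chisq"` or `"squared"`.
#' @param maxit Optimiser iteration cap per pruned fit.
#' @return Mean prediction error (scalar) with attribute `"skipped"`.
#' @export
cv_score <- function(phylo, lambda, calibrations = NULL,
                     root = root_constraint(), n_terminals = NULL,
                     seed = 1, error = c("chisq", "squared"), maxit = 200) {
  error <- match.arg(error)
  cvp <- cv_prepare(phylo, calibrations, root, n_terminals, seed)
  if (length(cvp$terminals) == 0)
    stop("no usable terminals for cross-validation")
  res <- cv_score_prepared(cvp, lambda, root, error, maxit = maxit)
  structure(res, skipped = cvp$skipped)
}

#' Grid cross-validation of the smoothing parameter
#'
#' Scores every value of a (strictly decreasing) smoothing grid on the same
#' terminal sample, warm-starting each fit from the previous grid value, and
#' returns the best value (ties broken toward the smallest lambda).
#'
#' @inheritParams cv_score
#' @param grid Decreasing vector of smoothing values ([smoothing_grid()]).
#' @return List of class `"cv_result"`: `grid`, `scores`, `best_lambda`.
#' @export
grid_cv <- function(phylo, grid = smoothing_grid(), calibrations = NULL,
                    root = root_constraint(), n_terminals = NULL, seed = 1,
                    error = c("chisq", "squared"), maxit = 200) {
  error <- match.arg(error)
  stopifnot(all(diff(grid) < 0) || length(grid) == 1)
  cvp <- cv_prepare(phylo, calibrations, root, n_terminals, seed)
  if (length(cvp$terminals) == 0)
    stop("no usable terminals for cross-validation")
  scores <- vapply(grid, function(lam)
    cv_score_prepared(cvp, lam, root, error, maxit = maxit), 0)
  best <- min(grid[scores == min(scores)])
  structure(list(grid = grid, scores = scores, best_lambda = best,
                 skipped = cvp$skipped), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Smoothing CV over %d grid values: best lambda = %g\n",
              length(x$grid), x$best_lambda))
  invisible(x)
}

#' Subsampled-replicate cross-validation for large trees
#'
#' For trees too large for direct cross-validation: draw `n_replicates`
#' random subsamples keeping `keep_fraction` of the tips (pruning the rest
#' and summing lengths through suppressed nodes), run the grid
#' cross-validation on each replicate, record each replicate's best
#' smoothing value, and select the value chosen by the highest proportion of
#' replicates (ties broken toward the smaller value).  Calibrations that no
#' longer span two kept tips (crown) or lose all their taxa (stem) are
#' dropped per replicate; the root window is applied to each replicate's
#' root.
#'
#' @inheritParams grid_cv
#' @param n_replicates Number of pruned replicates.
#' @param keep_fraction Fraction of tips kept per replicate, in (0, 1];
#'   `keep_fraction * tip count` must be at least 4.
#' @return List of class `"subsampled_cv"`: `grid`, `best_lambdas` (one per
#'   replicate), `proportions` (named, summing to 1), `modal_lambda`,
#'   `modal_proportion`.
#' @export
subsampled_cv <- function(phylo, calibrations = NULL,
                          root = root_constraint(), n_replicates = 500,
                          keep_fraction = 0.10, grid = smoothing_grid(),
                          seed = 1, n_terminals = NULL, maxit = 200) {
  stopifnot(inherits(phylo, "phylogram"))
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0, 1]")
  n <- ape::Ntip(phylo$tree)
  keep <- round(keep_fraction * n)
  if (keep < 4) stop("keep_fraction x tip count must be >= 4")
  best_lambdas <- numeric(n_replicates)
  for (j in seq_len(n_replicates)) {
    kept <- with_seed(seed + j, sample(phylo$tree$tip.label, keep))
    red_tree <- ape::keep.tip(phylo$tree, kept)
    red_cals <- NULL
    if (!is.null(calibrations) && nrow(calibrations) > 0) {
      keep_rows <- logical(nrow(calibrations))
      taxa_new <- calibrations$taxa
      for (i in seq_len(nrow(calibrations))) {
        taxa <- intersect(calibrations$taxa[[i]], kept)
        need <- if (calibrations$placement[i] == "crown") 2L else 1L
        if (length(taxa) >= need &&
            !(calibrations$placement[i] == "stem" &&
              length(taxa) == length(kept))) {
          keep_rows[i] <- TRUE
          taxa_new[[i]] <- taxa
        }
      }
      if (any(keep_rows)) {
        red_cals <- calibrations[keep_rows, ]
        red_cals$taxa <- taxa_new[keep_rows]
        red_cals <- feasible_calibrations(red_tree, red_cals, root)
      }
    }
    cv <- grid_cv(phylogram(red_tree, phylo$n_sites), grid, red_cals, root,
                  n_terminals = n_terminals, seed = seed + j,
                  maxit = maxit)
    best_lambdas[j] <- cv$best_lambda
  }
  counts <- table(factor(best_lambdas, levels = sort(unique(grid))))
  proportions <- as.numeric(counts) / n_replicates
  names(proportions) <- names(counts)
  top <- which(proportions == max(proportions))
  modal <- min(as.numeric(names(proportions)[top]))
  structure(list(grid = grid, best_lambdas = best_lambdas,
                 proportions = proportions, modal_lambda = modal,
                 modal_proportion = max(proportions),
                 n_replicates = n_replicates,
                 keep_fraction = keep_fraction),
            class = "subsampled_cv")
}

#' @export
print.subsampled_cv <- function(x, ...) {
  cat(sprintf(
    "Subsampled CV: %d replicates keeping %.0f%% of tips\n",
    x$n_replicates, 100 * x$keep_fraction))
  cat(sprintf("  modal smoothing = %g (chosen by %.0f%% of replicates)\n",
              x$modal_lambda, 100 * x$modal_proportion))
  invisible(x)
}
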