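# Shared fixtures and independent oracles used across the suite.  Oracles
# are deliberately naive (plain loops, closed forms) and share no code with
# the implementation paths they check.

# A small fixed truth bundle for tests that just need a consistent problem.
fix_truth <- function(n_tips = 30, seed = 101, rate_log_sd = 0.2,
                      k_calibrations = 5, ...) {
  cfg <- sim_config(n_tips = n_tips, rate_log_sd = rate_log_sd,
                    seed = seed, ...)
  simulate_truth(cfg, k_calibrations = k_calibrations)
}

# Split a truth bundle's calibrations into the root window and the rest.
split_root_cal <- function(truth) {
  ri <- which(truth$calibrations$clade_label == "root")
  list(root = root_constraint(truth$calibrations$min_age[ri],
                              truth$calibrations$max_age[ri]),
       cals = truth$calibrations[-ri, ])
}

# Independent brute-force penalized objective: explicit loops over edges,
# dpois for the likelihood, textbook formulas for the penalty.
oracle_pl_objective <- function(tree, lengths, n_sites, lambda, rates,
                                ages) {
  E <- nrow(tree$edge)
  total <- 0
  for (k in seq_len(E)) {
    pa <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    x <- round(lengths[k] * n_sites)
    mu <- rates[k] * (ages[pa] - ages[ch]) * n_sites
    total <- total - stats::dpois(x, mu, log = TRUE)
  }
  phi <- 0
  for (k in seq_len(E)) {
    pa <- tree$edge[k, 1]
    parent_edge <- which(tree$edge[, 2] == pa)
    if (length(parent_edge) == 1)
      phi <- phi + (rates[k] - rates[parent_edge])^2
  }
  root <- ape::Ntip(tree) + 1L
  rc <- rates[tree$edge[, 1] == root]
  if (length(rc) >= 2) phi <- phi + sum((rc - mean(rc))^2) / (length(rc) - 1)
  total + lambda * phi
}

# Independent type-7 quantile: sort, then linear interpolation between
# order statistics at position 1 + p*(n-1).
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + p * (n - 1)
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Independent Monte-Carlo draw of the pure-birth (Yule) root age under the
# observation scheme of the simulator: the standing tree is observed at a
# uniform point of an exponential overshoot past the n-th speciation, so
# the root age is sum_{k=2}^{n-1} Exp(k b) + U * Exp(n b).
oracle_yule_root_age <- function(n_tips, birth) {
  sum(stats::rexp(n_tips - 2L, birth * (2:(n_tips - 1L)))) +
    stats::runif(1L) * stats::rexp(1L, birth * n_tips)
}

# Brute-force p-distance for equal-length sequences.
oracle_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[ok] != cb[ok]) / sum(ok)
}
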