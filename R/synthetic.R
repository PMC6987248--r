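# Synthetic-data generators: birth-death chronograms, autocorrelated
# log-normal rates, phylograms with optional Poisson substitution noise,
# fossil calibration windows and bootstrap pseudo-replicates.  These emulate
# the inputs of the dating pipeline so every stage can be tested offline
# against known truth.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators.  Defaults emulate
#' a plastid-barcode supermatrix study: a slow birth-death process (root ages
#' of order 100 My for ~100 tips), plastid-like substitution rates, moderate
#' autocorrelated rate heterogeneity and an alignment of 4,968 sites.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate Speciation rate, events/lineage/My.
#' @param death_rate Extinction rate, events/lineage/My (< `birth_rate`).
#' @param root_rate Substitution rate at the root, substitutions/site/My.
#' @param rate_log_sd Standard deviation of the per-edge log-rate jitter
#'   (geometric Brownian motion); 0 gives a strict clock.
#' @param n_sites Alignment length in columns.
#' @param poisson_noise Draw per-edge substitution counts from a Poisson
#'   distribution (`TRUE`) or use the noiseless expectation (`FALSE`).
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_tips = 100, birth_rate = 0.05, death_rate = 0,
                       root_rate = 0.002, rate_log_sd = 0.2,
                       n_sites = 4968, poisson_noise = TRUE, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > death_rate, death_rate >= 0,
            root_rate > 0, rate_log_sd >= 0, n_sites >= 1)
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 death_rate = death_rate, root_rate = root_rate,
                 rate_log_sd = rate_log_sd, n_sites = as.integer(n_sites),
                 poisson_noise = isTRUE(poisson_noise), seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  cat(sprintf("  %d tips; birth %.4g, death %.4g /lineage/My\n",
              x$n_tips, x$birth_rate, x$death_rate))
  cat(sprintf("  root rate %.4g subst/site/My, log-sd %.3g; %d sites%s\n",
              x$root_rate, x$rate_log_sd, x$n_sites,
              if (x$poisson_noise) " (Poisson noise)" else ""))
  invisible(x)
}

# One forward pass of the constant-rate birth-death process, stopped at the
# first passage of the extant lineage count to n_tips ("simple sampling").
# Returns NULL on extinction.
sim_bd_once <- function(n_tips, b, d) {
  cap <- 8L * n_tips + 64L
  parent <- integer(cap); t_birth <- numeric(cap); t_end <- rep(NA_real_, cap)
  parent[1] <- 0L; t_birth[1] <- 0
  active <- 1L
  nxt <- 2L
  t <- 0
  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    if (k == n_tips) break
    t <- t + stats::rexp(1L, k * (b + d))
    i <- active[sample.int(k, 1L)]
    if (d == 0 || stats::runif(1L) < b / (b + d)) {
      if (nxt + 1L > cap) { # grow storage
        cap <- cap * 2L
        length(parent) <- cap; length(t_birth) <- cap
        t_end <- c(t_end, rep(NA_real_, cap - length(t_end)))
      }
      t_end[i] <- t
      parent[c(nxt, nxt + 1L)] <- i
      t_birth[c(nxt, nxt + 1L)] <- t
      active <- c(active[active != i], nxt, nxt + 1L)
      nxt <- nxt + 2L
    } else {
      t_end[i] <- t
      active <- active[active != i]
    }
  }
  # observe the standing tree at a random time before the (n+1)th event, so
  # the youngest divergence has a positive age
  t <- t + stats::runif(1L) * stats::rexp(1L, n_tips * (b + d))
  m <- nxt - 1L
  list(parent = parent[seq_len(m)], t_birth = t_birth[seq_len(m)],
       t_end = t_end[seq_len(m)], T = t, extant = active)
}

# Assemble the reconstructed (extinct-pruned) tree of a sim_bd_once() run as
# a newick string; tips are labelled t1..tn in lineage order.
bd_to_newick <- function(sim) {
  m <- length(sim$parent)
  extant <- logical(m); extant[sim$extant] <- TRUE
  children <- split(seq_len(m), factor(sim$parent, levels = seq_len(m)))
  survives <- logical(m)
  for (i in rev(seq_len(m))) { # children have larger ids than parents
    kids <- children[[i]]
    survives[i] <- extant[i] || any(survives[kids])
  }
  tip_id <- cumsum(extant)
  rec <- function(i) {
    if (extant[i])
      return(list(str = paste0("t", tip_id[i]),
                  dur = sim$T - sim$t_birth[i]))
    kids <- children[[i]]
    kids <- kids[survives[kids]]
    if (length(kids) == 1L) {
      r <- rec(kids)
      r$dur <- r$dur + (sim$t_end[i] - sim$t_birth[i])
      return(r)
    }
    r1 <- rec(kids[1L]); r2 <- rec(kids[2L])
    list(str = sprintf("(%s:%.10f,%s:%.10f)", r1$str, r1$dur, r2$str, r2$dur),
         dur = sim$t_end[i] - sim$t_birth[i])
  }
  paste0(rec(1L)$str, ";")
}

#' Simulate an ultrametric chronogram under a birth-death process
#'
#' Constant-rate birth-death simulation conditioned on the number of extant
#' tips by simple sampling: the process runs forward until the extant lineage
#' count first reaches `n_tips`, extinct lineages are pruned, and runs that go
#' extinct are retried (up to `max_retries` times).  Tip ages are exactly 0
#' and node ages are in My.
#'
#' @param config A [sim_config()].
#' @param max_retries Number of fresh draws allowed after extinction before
#'   giving up with an error.
#' @return A rooted, binary, ultrametric `phylo` with `n_tips` tips.
#' @export
simulate_chronogram <- function(config, max_retries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    for (i in seq_len(max_retries + 1L)) {
      sim <- sim_bd_once(config$n_tips, config$birth_rate, config$death_rate)
      if (!is.null(sim)) {
        tr <- ape::read.tree(text = bd_to_newick(sim))
        return(tr)
      }
    }
    stop("birth-death simulation went extinct in all ", max_retries + 1L,
         " attempts; increase birth_rate relative to death_rate")
  })
}

#' Simulate autocorrelated log-normal edge rates on a chronogram
#'
#' Geometric Brownian motion down the tree: each edge's rate is its parent
#' edge's rate times `exp(N(-rate_log_sd^2/2, rate_log_sd))`; edges incident
#' to the root start from `root_rate`.  The drift term `-sd^2/2` makes the
#' expected rate constant along every root-to-tip path.
#'
#' @param chrono A rooted `phylo` chronogram.
#' @param config A [sim_config()]; `rate_log_sd = 0` gives every edge exactly
#'   `root_rate`.
#' @return Numeric vector of rates (substitutions/site/My), one per row of
#'   `chrono$edge`, named by the child node of each edge.
#' @export
simulate_rates <- function(chrono, config) {
  stopifnot(inherits(chrono, "phylo"), inherits(config, "sim_config"))
  sd <- config$rate_log_sd
  E <- nrow(chrono$edge)
  root <- ape::Ntip(chrono) + 1L
  # edge whose child is the parent node of edge k (NA for root children)
  pedge <- match(chrono$edge[, 1], chrono$edge[, 2])
  ord <- preorder_edges(chrono)
  with_seed(config$seed, {
    rates <- numeric(E)
    eps <- stats::rnorm(E, mean = -sd^2 / 2, sd = sd)
    for (k in ord) {
      base <- if (chrono$edge[k, 1] == root) config$root_rate
              else rates[pedge[k]]
      rates[k] <- base * exp(eps[k])
    }
    names(rates) <- chrono$edge[, 2]
    rates
  })
}

# Edge indices ordered so that every edge appears after its parent edge.
preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  match(paste(tr$edge[, 1], tr$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Convert a chronogram plus edge rates into a phylogram
#'
#' Noiseless edge lengths are `rate * duration` (expected substitutions per
#' site); with `poisson_noise` on, the substitution count over the alignment
#' is drawn as `Poisson(rate * duration * n_sites)` and divided by `n_sites`.
#'
#' @param chrono A rooted `phylo` chronogram (edge lengths in My).
#' @param rates Edge-rate vector as returned by [simulate_rates()] (one rate
#'   per edge, in `chrono$edge` row order).
#' @param config A [sim_config()] supplying `n_sites`, `poisson_noise` and
#'   `seed`.
#' @return A [phylogram()] on the same topology.
#' @export
chronogram_to_phylogram <- function(chrono, rates, config) {
  stopifnot(inherits(chrono, "phylo"), inherits(config, "sim_config"))
  E <- nrow(chrono$edge)
  if (length(rates) != E || anyNA(rates))
    stop("rates must cover all ", E, " edges; missing rate for edge(s) ",
         paste(which(is.na(rates[seq_len(E)])), collapse = ", "))
  mu <- unname(rates * chrono$edge.length)
  tr <- chrono
  if (config$poisson_noise) {
    tr$edge.length <- with_seed(config$seed,
      stats::rpois(E, mu * config$n_sites) / config$n_sites)
  } else {
    tr$edge.length <- mu
  }
  phylogram(tr, config$n_sites)
}

#' A phylogram: rooted tree with branch lengths in substitutions/site
#'
#' Light S3 container pairing a `phylo` object (edge lengths in expected
#' substitutions per site) with the alignment length that produced it, which
#' the Poisson branch-length likelihood needs.
#'
#' @param tree A rooted `phylo` with non-negative edge lengths.
#' @param n_sites Alignment length (columns), >= 1.
#' @return An object of class `"phylogram"`.
#' @export
phylogram <- function(tree, n_sites) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), n_sites >= 1)
  structure(list(tree = tree, n_sites = as.integer(n_sites)),
            class = "phylogram")
}

#' @export
print.phylogram <- function(x, ...) {
  cat(sprintf("Phylogram: %d tips, %d sites, total length %.4g subst/site\n",
              ape::Ntip(x$tree), x$n_sites, sum(x$tree$edge.length)))
  invisible(x)
}

#' Sample fossil-style calibration windows from a known chronogram
#'
#' Picks `k` distinct internal nodes (always including the root) and, for
#' each, draws a minimum age uniformly on (0, true age] and sets the maximum
#' to `min + width`; draws with `true age > max` are rejected and redrawn so
#' every window is guaranteed to contain the true age.  This emulates a
#' fossil table whose maxima are the minima plus a constant interval width.
#'
#' @param truth A rooted ultrametric `phylo` with known node ages.
#' @param k Number of calibrations (<= number of internal nodes).
#' @param width Interval width `max - min` in My (default the constant width
#'   of the packaged fossil table).
#' @param seed Integer seed or `NULL`.
#' @return A calibration data.frame (see [calibration_set()]), all crown
#'   placements, with a `"root"` entry whose window contains the true root
#'   age.
#' @export
sample_calibrations <- function(truth, k, width = 16.82, seed = NULL) {
  stopifnot(inherits(truth, "phylo"), width > 0)
  n <- ape::Ntip(truth)
  internal <- n + seq_len(truth$Nnode)
  if (k > length(internal))
    stop("k = ", k, " exceeds the number of internal nodes (",
         length(internal), ")")
  ages <- node_ages(truth)
  keys <- clade_keys(truth)
  with_seed(seed, {
    root <- n + 1L
    nodes <- c(root, sample(setdiff(internal, root), k - 1L))
    mins <- vapply(nodes, function(v) {
      a <- ages[v]
      repeat {
        m <- stats::runif(1, 0, a)
        if (a <= m + width) return(m)
      }
    }, 0)
    taxa <- lapply(nodes, function(v)
      strsplit(keys[[as.character(v)]], "\r", fixed = TRUE)[[1]])
    labels <- ifelse(nodes == root, "root", paste0("node_", nodes))
    calibration_set(clade_label = labels,
                    min_age = mins, max_age = mins + width,
                    placement = "crown", taxa = taxa,
                    fossil_name = paste0("synthetic_", labels))
  })
}

#' Bootstrap pseudo-replicate phylograms by Poisson length resampling
#'
#' Keeps the topology fixed (as the original study fixed the ML topology for
#' replicate dating) and redraws each edge's substitution count as
#' `Poisson(length * n_sites) / n_sites`, a site-resampling surrogate.
#'
#' @param phylo A [phylogram()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed or `NULL`.
#' @return List of `n_reps` [phylogram()] objects.
#' @export
make_bootstrap_phylograms <- function(phylo, n_reps, seed = NULL) {
  stopifnot(inherits(phylo, "phylogram"), n_reps >= 1)
  E <- nrow(phylo$tree$edge)
  mu <- phylo$tree$edge.length * phylo$n_sites
  with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      tr <- phylo$tree
      tr$edge.length <- stats::rpois(E, mu) / phylo$n_sites
      phylogram(tr, phylo$n_sites)
    })
  })
}

#' Simulate a complete truth bundle for recovery experiments
#'
#' Convenience wrapper: chronogram, autocorrelated edge rates, phylogram and
#' a calibration set whose windows contain the true node ages.
#'
#' @param config A [sim_config()].
#' @param k_calibrations Number of calibration windows (including the root).
#' @param cal_width Calibration interval width in My.
#' @return List with elements `chronogram`, `rates`, `phylogram`,
#'   `calibrations` and `ages` (true node ages).
#' @export
simulate_truth <- function(config, k_calibrations = 11, cal_width = 16.82) {
  chrono <- simulate_chronogram(config)
  seed2 <- if (is.null(config$seed)) NULL else config$seed + 1L
  rates <- simulate_rates(chrono, config)
  phylo <- chronogram_to_phylogram(chrono, rates, config)
  cals <- sample_calibrations(chrono, k_calibrations, cal_width, seed = seed2)
  list(chronogram = chrono, rates = rates, phylogram = phylo,
       calibrations = cals, ages = node_ages(chrono))
}

#' Generate a small synthetic taxonomy table
#'
#' Species are grouped into genera, families and orders with systematic
#' synthetic names, for exercising the constraint-tree builder and the QC
#' chain offline.
#'
#' @param n_orders Number of orders.
#' @param families_per_order Families within each order.
#' @param species_per_family Species within each family.
#' @param genera_per_family Genera the species of a family are spread over.
#' @return data.frame with columns `species`, `genus`, `family`, `order`.
#' @export
simulate_taxonomy <- function(n_orders = 3, families_per_order = 2,
                              species_per_family = 4, genera_per_family = 2) {
  rows <- list()
  for (o in seq_len(n_orders)) {
    for (f in seq_len(families_per_order)) {
      fam <- sprintf("Famo%df%d", o, f)
      for (s in seq_len(species_per_family)) {
        g <- ((s - 1L) %% genera_per_family) + 1L
        genus <- sprintf("Geno%df%dg%d", o, f, g)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sprintf("%s species%d", genus, s), genus = genus,
          family = fam, order = sprintf("Order%d", o),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Random in-frame coding sequence of n_codons codons (ATG start, no internal
# stops) under the given genetic code.
random_coding_sequence <- function(n_codons, genetic_code = "1") {
  gc <- Biostrings::getGeneticCode(genetic_code)
  ok <- names(gc)[gc != "*"]
  paste0("ATG", paste(sample(ok, n_codons - 1L, replace = TRUE),
                      collapse = ""))
}

# Substitute a fraction of positions with random different bases.
mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate species-labelled marker records for QC testing
#'
#' Each family gets a random in-frame coding reference sequence; species
#' sequences are substitution-mutated copies, so within-family similarity is
#' high and cross-family similarity is near-random.  Codon positions are
#' mutated at `within_rate` avoiding stop codons is NOT enforced, mirroring
#' real data where mutations can create artefacts; use low rates for clean
#' fixtures.
#'
#' @param taxonomy A taxonomy data.frame ([simulate_taxonomy()]).
#' @param marker `"rbcL"` or `"matK_trnK"`.
#' @param n_codons Length of the family reference in codons.
#' @param within_rate Per-base substitution probability species vs family
#'   reference.
#' @param accessions_per_species Accessions generated per species.
#' @param seed Integer seed or `NULL`.
#' @return List with `records` (data.frame: `species_name`, `marker`,
#'   `accession`, `sequence`), `references` (one per family, with `group`
#'   column), and `groups` (named vector species -> family).
#' @export
simulate_marker_records <- function(taxonomy, marker = "rbcL",
                                    n_codons = 200, within_rate = 0.01,
                                    accessions_per_species = 1, seed = NULL) {
  with_seed(seed, {
    fams <- unique(taxonomy$family)
    refseq <- vapply(fams, function(f) random_coding_sequence(n_codons), "")
    references <- data.frame(
      species_name = paste0(fams, " reference"), marker = marker,
      accession = paste0("REF_", fams), sequence = unname(refseq),
      group = fams, stringsAsFactors = FALSE)
    recs <- list()
    acc <- 0L
    for (i in seq_len(nrow(taxonomy))) {
      fam <- taxonomy$family[i]
      for (j in seq_len(accessions_per_species)) {
        acc <- acc + 1L
        recs[[acc]] <- data.frame(
          species_name = taxonomy$species[i], marker = marker,
          accession = sprintf("ACC%05d", acc),
          sequence = mutate_sequence(refseq[[fam]], within_rate),
          stringsAsFactors = FALSE)
      }
    }
    groups <- c(stats::setNames(taxonomy$family, taxonomy$species),
                stats::setNames(references$group, references$species_name))
    list(records = do.call(rbind, recs), references = references,
         groups = groups)
  })
}

#' Write a taxonomy table as TSV
#' @param taxonomy data.frame with `species`, `genus`, `family`, `order`.
#' @param path Output file.
#' @param header Optional provenance comment written as a first `#` line.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(taxonomy, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy TSV written by [write_taxonomy()]
#' @param path Input file.
#' @return data.frame with `species`, `genus`, `family`, `order`.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("species", "genus", "family", "order")
  if (!all(need %in% names(tab)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(tab$family)) || any(!nzchar(tab$order)))
    stop("every species needs a non-empty family and order")
  if (anyDuplicated(tab$species))
    stop("duplicate species rows in taxonomy table")
  tab
}
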