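# Birth-death chronograms, autocorrelated rates, phylogram conversion,
# calibration sampling and bootstrap replication.

test_that("simulated chronograms are binary, ultrametric, correctly sized", {
  for (n in c(2, 10, 200)) {
    tr <- simulate_chronogram(sim_config(n_tips = n, seed = n))
    expect_s3_class(tr, "phylo")
    expect_equal(ape::Ntip(tr), n)
    expect_equal(tr$Nnode, n - 1L)   # rooted binary
    expect_true(is_ultrametric(tr, tol = 1e-9))
    ages <- node_ages(tr)
    expect_true(all(abs(ages[seq_len(n)]) < 1e-8))
    expect_true(all(tr$edge.length > 0))
  }
})

test_that("chronogram simulation is bit-deterministic under a seed", {
  cfg <- sim_config(n_tips = 50, death_rate = 0.02, seed = 77)
  t1 <- ape::write.tree(simulate_chronogram(cfg))
  t2 <- ape::write.tree(simulate_chronogram(cfg))
  expect_identical(t1, t2)
  t3 <- ape::write.tree(simulate_chronogram(sim_config(n_tips = 50,
                                                       death_rate = 0.02,
                                                       seed = 78)))
  expect_false(identical(t1, t3))
})

test_that("pure-birth root ages match an independent Monte-Carlo oracle", {
  nrep <- 1000L
  b <- 1
  roots <- vapply(seq_len(nrep), function(i) {
    max(node_ages(simulate_chronogram(
      sim_config(n_tips = 64, birth_rate = b, death_rate = 0, seed = i))))
  }, 0)
  set.seed(4242)
  oracle <- vapply(seq_len(nrep), function(i) oracle_yule_root_age(64, b), 0)
  se <- sqrt(stats::var(roots) / nrep + stats::var(oracle) / nrep)
  expect_lt(abs(mean(roots) - mean(oracle)), 3 * se)
})

test_that("rate simulation is autocorrelated log-normal with -sd^2/2 drift", {
  cfg0 <- sim_config(n_tips = 20, rate_log_sd = 0, seed = 5)
  ch <- simulate_chronogram(cfg0)
  expect_equal(unname(simulate_rates(ch, cfg0)),
               rep(cfg0$root_rate, nrow(ch$edge)))

  cfg <- sim_config(n_tips = 5001, rate_log_sd = 0.3, seed = 6)
  big <- simulate_chronogram(cfg)
  rates <- simulate_rates(big, cfg)
  expect_identical(rates, simulate_rates(big, cfg))  # seed determinism
  # mean log child/parent ratio over ~10,000 edges vs closed form -sd^2/2
  pedge <- match(big$edge[, 1], big$edge[, 2])
  ratio <- log(rates[!is.na(pedge)] / rates[pedge[!is.na(pedge)]])
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - (-0.3^2 / 2)), 3 * se)
  expect_true(all(rates > 0))
})

test_that("phylogram lengths are rate x duration, with Poisson noise on", {
  cfg <- sim_config(n_tips = 10, rate_log_sd = 0.2, poisson_noise = FALSE,
                    seed = 8)
  ch <- simulate_chronogram(cfg)
  rates <- simulate_rates(ch, cfg)
  ph <- chronogram_to_phylogram(ch, rates, cfg)
  expect_equal(ph$tree$edge.length, unname(rates * ch$edge.length))
  # zero-duration edge gives zero length regardless of noise
  ch0 <- ch; ch0$edge.length[3] <- 0
  cfgn <- sim_config(n_tips = 10, poisson_noise = TRUE, seed = 8)
  phn <- chronogram_to_phylogram(ch0, rates, cfgn)
  expect_identical(phn$tree$edge.length[3], 0)
  # Poisson draws have the right mean: 1,000 draws of one edge
  mu <- 0.02
  draws <- vapply(seq_len(1000), function(i) {
    one <- ch; one$edge.length[] <- 0; one$edge.length[1] <- mu / rates[1]
    chronogram_to_phylogram(one, rates,
      sim_config(n_tips = 10, n_sites = 4968, seed = i))$tree$edge.length[1]
  }, 0)
  se <- sqrt(mu / 4968 / 1000)   # Poisson variance / n_sites^2, 1000 reps
  expect_lt(abs(mean(draws) - mu), 3 * se)
  # missing rates are an error naming the edge
  expect_error(chronogram_to_phylogram(ch, rates[-1], cfg), "edge")
})

test_that("noiseless clock round trip recovers durations exactly", {
  cfg <- sim_config(n_tips = 25, rate_log_sd = 0, poisson_noise = FALSE,
                    seed = 12)
  ch <- simulate_chronogram(cfg)
  ph <- chronogram_to_phylogram(ch, simulate_rates(ch, cfg), cfg)
  expect_equal(ph$tree$edge.length / cfg$root_rate, ch$edge.length)
})

test_that("sampled calibrations have constant width and contain the truth", {
  tr <- simulate_chronogram(sim_config(n_tips = 40, seed = 31))
  ages <- node_ages(tr)
  cals <- sample_calibrations(tr, 10, width = 16.82, seed = 3)
  expect_equal(nrow(cals), 10)
  expect_equal(cals$max_age - cals$min_age, rep(16.82, 10))
  expect_true("root" %in% cals$clade_label)
  for (i in seq_len(nrow(cals))) {
    node <- map_to_node(tr, cals[i, ])
    expect_gte(ages[node], cals$min_age[i])
    expect_lte(ages[node], cals$max_age[i])
  }
  # all internal nodes calibratable; one more is an error
  all_cals <- sample_calibrations(tr, tr$Nnode, seed = 4)
  expect_equal(nrow(all_cals), tr$Nnode)
  expect_error(sample_calibrations(tr, tr$Nnode + 1, seed = 4), "exceeds")
  expect_identical(sample_calibrations(tr, 10, seed = 9),
                   sample_calibrations(tr, 10, seed = 9))
})

test_that("bootstrap replicates keep topology and converge to the input", {
  truth <- fix_truth(n_tips = 15, seed = 55)
  ph <- truth$phylogram
  reps <- make_bootstrap_phylograms(ph, 20, seed = 2)
  expect_length(reps, 20)
  for (r in reps[1:3])
    expect_identical(sort(clade_keys(r$tree)), sort(clade_keys(ph$tree)))
  # n_sites -> infinity limit: lengths reproduce the input to 3 decimals
  big <- phylogram(ph$tree, 1e8)
  rep1 <- make_bootstrap_phylograms(big, 1, seed = 3)[[1]]
  expect_equal(rep1$tree$edge.length, ph$tree$edge.length, tolerance = 1e-3)
  # all-zero input stays zero
  z <- ph$tree; z$edge.length[] <- 0
  zrep <- make_bootstrap_phylograms(phylogram(z, 100), 2, seed = 4)
  expect_true(all(zrep[[1]]$tree$edge.length == 0))
})

test_that("the four simulation products share one topology", {
  truth <- fix_truth(n_tips = 20, seed = 66)
  k <- sort(clade_keys(truth$chronogram))
  expect_identical(sort(clade_keys(truth$phylogram$tree)), k)
  reps <- make_bootstrap_phylograms(truth$phylogram, 2, seed = 1)
  expect_identical(sort(clade_keys(reps[[2]]$tree)), k)
})

test_that("taxonomy and marker-record generators are consistent", {
  tax <- simulate_taxonomy(2, 2, 3)
  expect_equal(nrow(tax), 12)
  expect_false(anyDuplicated(tax$species) > 0)
  sim <- simulate_marker_records(tax, "rbcL", n_codons = 60, seed = 1)
  expect_equal(nrow(sim$records), nrow(tax))
  expect_true(all(sim$groups[sim$records$species_name] %in% tax$family))
  # round trip through FASTA
  tf <- tempfile(fileext = ".fasta")
  write_fasta_records(taxon_records(sim$records$species_name, "rbcL",
                                    sim$records$accession,
                                    sim$records$sequence), tf)
  back <- read_fasta_records(tf)
  expect_equal(back$sequence, sim$records$sequence)
  expect_equal(back$species_name, sim$records$species_name)
})
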