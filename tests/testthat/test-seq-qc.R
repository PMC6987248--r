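# Quality-control cascade: similarity screen, accession choice, ambiguity
# filter, conflicting duplicates, reading-frame screen, name validation and
# the assembled chain's bookkeeping invariants.

make_qc_fixture <- function(seed = 11) {
  tax <- simulate_taxonomy(2, 2, 3)
  sim <- simulate_marker_records(tax, "rbcL", n_codons = 120,
                                 within_rate = 0.01, seed = seed)
  rec <- taxon_records(sim$records$species_name, "rbcL",
                       sim$records$accession, sim$records$sequence)
  list(tax = tax, records = rec, references = sim$references,
       groups = sim$groups)
}

test_that("similarity screen keeps same-family hits, drops mislabels", {
  fx <- make_qc_fixture()
  v <- similarity_screen(fx$records[1, ], fx$references, fx$groups)
  expect_true(v$kept)
  # self-match: a record identical to a same-species reference
  ident <- fx$records[1, ]
  ident$sequence <- fx$references$sequence[
    fx$references$group == fx$groups[[ident$species_name]]]
  expect_true(similarity_screen(ident, fx$references, fx$groups)$kept)
  # constructed mislabel: sequence copied verbatim from another order's
  # reference but kept under its own name -> best hit is cross-group
  mis <- fx$records[1, ]
  own <- fx$groups[[mis$species_name]]
  mis$sequence <- fx$references$sequence[fx$references$group != own][1]
  vm <- similarity_screen(mis, fx$references, fx$groups)
  expect_false(vm$kept)
  expect_equal(vm$rule, "cross_group_hit")
  # too-short boundary: length 7 under word size 8
  short <- fx$records[1, ]; short$sequence <- "ACGTACG"
  vs <- similarity_screen(short, fx$references, fx$groups, word_size = 8)
  expect_false(vs$kept)
  expect_equal(vs$rule, "too_short")
  expect_error(similarity_screen(fx$records[1, ], fx$references[0, ],
                                 fx$groups), "empty")
})

test_that("best-accession choice is lexicographic and tie-stable", {
  base <- strrep("ACGT", 170)
  recs <- taxon_records(rep("Genus species", 3), "rbcL",
                        c("A3", "A1", "A2"),
                        c(base, base, paste0(substr(base, 1, 200), "NN",
                                             substr(base, 203, 680))))
  # single record returns itself
  expect_equal(select_best_accession(recs[1, ])$accession, "A3")
  # quality first: the two clean copies beat the ambiguous one; among the
  # identical pair the accession string breaks the tie
  expect_equal(select_best_accession(recs)$accession, "A1")
  # equal quality, lengths 650 vs 680: longer wins
  two <- taxon_records(rep("Genus species", 2), "rbcL", c("B1", "B2"),
                       c(strrep("ACGT", 170), substr(strrep("ACGT", 170),
                                                     1, 650)))
  expect_equal(select_best_accession(two)$accession, "B1")
  # three records, one divergent: one of the two identical ones wins on
  # mean pairwise similarity (verified by brute force: identity pair 1.0)
  div <- chartr("AC", "CA", base)
  three <- taxon_records(rep("Genus species", 3), "rbcL",
                         c("C3", "C1", "C2"), c(base, base, div))
  expect_true(select_best_accession(three)$accession %in% c("C1", "C3"))
  expect_error(select_best_accession(three[0, ]), "no records")
})

test_that("ambiguity filter applies the fraction and the 'multiple' rule", {
  rec <- function(seq) list(sequence = seq)
  clean <- strrep("ACGT", 250)
  expect_true(filter_ambiguous(rec(clean))$kept)
  one_n <- paste0(substr(clean, 1, 999), "N")
  expect_true(filter_ambiguous(rec(one_n), 0.01)$kept)
  two_n <- paste0(substr(clean, 1, 998), "NN")
  expect_false(filter_ambiguous(rec(two_n), 0.001)$kept)  # 0.002 > 0.001
  # 10 N in 500 bases at 1%: 2% > 1% -> dropped
  many <- paste0(substr(clean, 1, 490), strrep("N", 10))
  expect_false(filter_ambiguous(rec(substr(many, 1, 500)), 0.01)$kept)
  # short sequence: two Ns in 100 bases exceed a 1% ceiling
  short2 <- paste0(substr(clean, 1, 98), "NN")
  expect_false(filter_ambiguous(rec(short2), 0.01)$kept)
  expect_true(filter_ambiguous(rec(paste0(substr(clean, 1, 99), "N")),
                               0.01)$kept)
})

test_that("conflicting duplicates are removed, consistent ones collapsed", {
  base <- strrep("ACGT", 150)
  div <- chartr("AG", "GA", base)    # 50% divergent
  expect_gt(oracle_p_distance(base, div), 0.2)
  expect_equal(p_distance(base, div), oracle_p_distance(base, div))
  recs <- taxon_records(
    c("A sp", "A sp", "B sp", "B sp", "C sp"), "rbcL",
    paste0("X", 1:5), c(base, div, base, base, base))
  out <- drop_conflicting_duplicates(recs, max_divergence = 0.05)
  rep <- attr(out, "report")
  expect_equal(nrow(rep), 5)                       # conservation
  expect_false(any(out$species_name == "A sp"))    # conflicting pair gone
  expect_equal(sum(out$species_name == "B sp"), 1) # collapsed to one
  expect_equal(sum(out$species_name == "C sp"), 1) # singletons unchanged
  expect_match(rep$detail[rep$rule == "conflicting_duplicates"][1], "X1,X2")
})

test_that("frame screen drops frameshifts, internal stops, divergent AA", {
  set.seed(21)
  cds <- random_coding_sequence(120, "11")
  rec <- function(seq) list(sequence = seq)
  ref <- list(sequence = cds)
  expect_true(screen_frameshift(rec(cds), frame = 0, reference = ref)$kept)
  # one base deleted at position 30: downstream frame shifts
  del <- paste0(substr(cds, 1, 29), substr(cds, 31, nchar(cds)))
  v <- screen_frameshift(rec(del), frame = 0, reference = ref)
  expect_false(v$kept)
  expect_true(v$rule %in% c("frame_length", "internal_stop",
                            "aa_divergent"))
  # in-frame but with an internal stop codon
  stopins <- paste0(substr(cds, 1, 60), "TAA", substr(cds, 64, nchar(cds)))
  vs <- screen_frameshift(rec(stopins), frame = 0, reference = ref)
  expect_false(vs$kept)
  expect_equal(vs$rule, "internal_stop")
  # ORF-scan mode finds the coding span without a frame offset
  padded <- paste0("TT", cds)
  expect_true(screen_frameshift(rec(padded), frame = NA, reference = ref,
                                min_orf = 300)$kept)
  expect_error(screen_frameshift(rec(cds), frame = 0,
                                 genetic_code = "zz"), "genetic code")
})

test_that("name validation is a normalised conjunction of two checklists", {
  a <- checklist("A", c("Quercus robur", "Fagus sylvatica", "Acer rubrum"))
  b <- checklist("B", c("quercus  robur", "Acer rubrum", "Pinus nigra"))
  out <- validate_names(c("QUERCUS ROBUR", "Fagus sylvatica",
                          "Acer rubrum", "Pinus nigra"), a, b)
  # kept iff in both; case/whitespace variants normalise; order preserved
  expect_identical(out, c("Quercus robur", "Acer rubrum"))
  expect_true(all(out %in% a$valid_names) && all(out %in% b$valid_names))
  expect_error(validate_names("x", a, checklist("E", character(0))),
               "empty")
  # checklist file round trip with comments
  tf <- tempfile()
  writeLines(c("# a comment", "Quercus robur  ", "", "acer Rubrum"), tf)
  cl <- read_checklist(tf)
  expect_setequal(cl$valid_names, c("Quercus robur", "Acer rubrum"))
})

test_that("the full chain conserves records, is idempotent and order-free", {
  fx <- make_qc_fixture(seed = 31)
  # poison a few records: a mislabel, an ambiguous one, a frameshift
  recs <- fx$records
  own <- fx$groups[[recs$species_name[2]]]
  recs$sequence[2] <- fx$references$sequence[fx$references$group != own][1]
  recs$sequence[4] <- paste0(substr(recs$sequence[4], 1, 50), strrep("N", 9),
                             substr(recs$sequence[4], 60,
                                    nchar(recs$sequence[4])))
  recs$sequence[6] <- paste0(substr(recs$sequence[6], 1, 33),
                             substr(recs$sequence[6], 35,
                                    nchar(recs$sequence[6])))
  cla <- checklist("A", fx$tax$species)
  clb <- checklist("B", fx$tax$species[-1])   # first species invalid in B
  res <- run_qc(recs, fx$references, fx$groups, cla, clb)
  # conservation: one verdict per input record
  expect_equal(nrow(res$report), nrow(recs))
  expect_equal(sum(res$report$verdict == "kept") +
                 sum(res$report$verdict == "dropped"), nrow(recs))
  expect_equal(nrow(res$records), sum(res$report$verdict == "kept"))
  # the poisoned records fell to the right rules
  expect_equal(res$report$rule[1], "invalid_name")
  expect_equal(res$report$rule[2], "cross_group_hit")
  expect_equal(res$report$rule[4], "ambiguous")
  expect_true(res$report$rule[6] %in% c("frame_length", "internal_stop",
                                        "aa_divergent"))
  # idempotence: re-running on the kept output drops nothing
  res2 <- run_qc(res$records, fx$references, fx$groups, cla, clb)
  expect_equal(sort(res2$records$accession), sort(res$records$accession))
  # order independence: permuting the input leaves the kept set unchanged
  perm <- sample(nrow(recs))
  res3 <- run_qc(recs[perm, ], fx$references, fx$groups, cla, clb)
  expect_setequal(res3$records$accession, res$records$accession)
})

test_that("duplicate accessions collapse to one representative per species", {
  tax <- simulate_taxonomy(1, 1, 2)
  sim <- simulate_marker_records(tax, "rbcL", n_codons = 100,
                                 within_rate = 0.005,
                                 accessions_per_species = 3, seed = 8)
  recs <- taxon_records(sim$records$species_name, "rbcL",
                        sim$records$accession, sim$records$sequence)
  cl <- checklist("A", tax$species)
  res <- run_qc(recs, sim$references, sim$groups, cl, cl)
  expect_equal(nrow(res$records), 2)   # one per species
  expect_equal(nrow(res$report), 6)
})
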