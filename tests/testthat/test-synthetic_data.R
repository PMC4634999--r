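alt_of <- function(ref, pos) {
  setdiff(c("A", "C", "G", "T"), substr(ref$sequence, pos, pos))[1]
}

test_that("spiked allele fractions follow the binomial law", {
  ref <- random_reference(200, seed = 101)
  pos <- 100
  alt <- alt_of(ref, pos)
  vs <- variant_spec(ref$name, pos, substr(ref$sequence, pos, pos), alt,
                     "SNV", 0.5)
  reads <- simulate_reads(ref, list(vs),
                          simulation_profile(depth = 1000, read_length = 50,
                                             per_base_error = 0, seed = 1))
  pu <- build_pileup(reads, ref)
  est <- estimate_af(pu, pos, alt)
  sd <- sqrt(0.5 * 0.5 / est$depth)
  expect_lt(abs(est$af - 0.5), 3 * sd)

  # the 3.3% at 5,000x regime: alt count near 170 out of ~5,000
  vs2 <- variant_spec(ref$name, pos, substr(ref$sequence, pos, pos), alt,
                      "SNV", 0.034)
  reads2 <- simulate_reads(ref, list(vs2),
                           simulation_profile(depth = 5000, read_length = 50,
                                              per_base_error = 0, seed = 2))
  est2 <- estimate_af(build_pileup(reads2, ref), pos, alt)
  count <- est2$support_forward + est2$support_reverse
  mu <- est2$depth * 0.034
  expect_lt(abs(count - mu), 3 * sqrt(est2$depth * 0.034 * 0.966))
})

test_that("error-free reads reproduce the reference and generators are deterministic", {
  ref <- random_reference(150, seed = 7)
  prof <- simulation_profile(depth = 50, read_length = 40, per_base_error = 0,
                             seed = 3)
  reads <- simulate_reads(ref, NULL, prof)
  expect_true(all(reads$sequence ==
                    substring(ref$sequence, reads$start, reads$start + 39)))
  expect_true(validate_alignments(reads))
  expect_identical(reads, simulate_reads(ref, NULL, prof))

  prof0 <- simulation_profile(depth = 0, seed = 3)
  expect_equal(nrow(simulate_reads(ref, NULL, prof0)), 0)

  # orientation is close to 50/50
  big <- simulate_reads(ref, NULL, simulation_profile(depth = 2000,
                                                      read_length = 40,
                                                      seed = 4))
  frac_fwd <- mean(big$orientation == "forward")
  expect_lt(abs(frac_fwd - 0.5), 3 * sqrt(0.25 / nrow(big)))
})

test_that("variant specs are validated against the reference", {
  ref <- reference("r", "ACGTACGTAC")
  vs_bad <- variant_spec("r", 3, "A", "T", "SNV", 0.1)  # ref is G at 3
  expect_error(simulate_reads(ref, list(vs_bad), simulation_profile(depth = 5)),
               "does not match")
  expect_error(variant_spec("r", 1, "A", "T", "SNV", 1.2), "target_af")
})

test_that("deletion libraries inflate spanning carrier inserts by the deletion length", {
  dref <- reference("r", strrep("N", 40000))
  prof <- simulation_profile(insert_mu = 400, insert_sigma = 80, seed = 11)

  none <- simulate_deletion_library(dref, 5000, 18281, 5000, 0, prof)
  expect_true(all(abs(none$insert_size) <= 400 + 6 * 80))
  expect_false(any(none$insert_size > 1200))

  prof$seed <- 12
  lib <- simulate_deletion_library(dref, 5000, 18281, 20000, 0.03, prof)
  carriers <- lib[lib$carrier, ]
  expect_gt(nrow(carriers), 0)
  expect_lt(abs(mean(carriers$insert_size) - (400 + 13282)),
            4 * 80 / sqrt(nrow(carriers)) + 20)

  expect_equal(nrow(simulate_deletion_library(dref, 5000, 18281, 0, 0.1, prof)),
               0)
  expect_error(simulate_deletion_library(dref, 5000, 18281, 10, 1.5, prof),
               "carrier_fraction")
  expect_error(simulate_deletion_library(dref, 5000, 5500, 10, 0.1, prof),
               "1,000")

  # pair rendering round-trips through SAM with signed TLEN
  reads <- pairs_to_alignments(lib[1:5, ], dref)
  expect_true(validate_alignments(reads))
  expect_equal(sum(reads$insert_size), 0)  # +/- pairs cancel
})

test_that("amplicon pools hit the target mutant fraction and reverse-complement half the reads", {
  ctx <- random_reference(50, seed = 21)
  pos <- 25
  alt <- alt_of(ctx, pos)
  mut <- ctx$sequence
  substr(mut, pos, pos) <- alt
  q <- make_query_kmers(ctx$sequence,
                        list(pos = pos, ref = substr(ctx$sequence, pos, pos),
                             alt = alt))

  pool <- simulate_amplicon_pool(ctx$sequence, mut, af = 0.01,
                                 n_reads = 20000, per_base_error = 0,
                                 seed = 5)
  n_mut <- count_kmer(pool, q$mut)
  expect_lt(abs(n_mut - 200), 3 * sqrt(20000 * 0.01 * 0.99))
  n_rc <- sum(pool == reverse_complement(ctx$sequence) |
                pool == reverse_complement(mut))
  expect_lt(abs(n_rc / 20000 - 0.5), 3 * sqrt(0.25 / 20000))

  all_mut <- simulate_amplicon_pool(ctx$sequence, mut, af = 1,
                                    n_reads = 500, per_base_error = 0,
                                    seed = 6)
  expect_equal(count_kmer(all_mut, q$wt), 0)

  expect_identical(
    simulate_amplicon_pool(ctx$sequence, mut, 0.3, 1000, 0.002, seed = 9),
    simulate_amplicon_pool(ctx$sequence, mut, 0.3, 1000, 0.002, seed = 9))
  expect_error(simulate_amplicon_pool(ctx$sequence, mut, -0.1, 10), "af")
})

test_that("control panels land in the configured noise band", {
  panel <- simulate_control_panel("ACGT", "AAAA", n_controls = 25,
                                  error_rate_range = c(0.001, 0.001),
                                  n_reads = 1e5, seed = 13)
  expect_length(panel$afs, 25)
  expect_gt(panel$mean_af, 0.0005)
  expect_lt(panel$mean_af, 0.002)
  expect_true(panel$min_af <= panel$mean_af && panel$mean_af <= panel$max_af)

  zero <- simulate_control_panel("ACGT", "AAAA",
                                 error_rate_range = c(0, 0), seed = 1)
  expect_true(all(zero$afs == 0))
})

test_that("the packaged cohort table has the study's structure", {
  tab <- load_table1_fixture()
  expect_equal(nrow(tab), 53)
  expect_equal(sum(tab$status == "persistent_NMI"), 8)
  expect_equal(sum(tab$status == "heterozygous"), 19)
  expect_equal(sum(tab$status == "mosaic"), 26)
  expect_true(all(tab$af >= 0.0021 & tab$af <= 0.5, na.rm = TRUE))

  gen <- generate_cohort(seed = 99)
  expect_identical(gen, generate_cohort(seed = 99))
  expect_equal(nrow(gen), 53)
  expect_true(all(gen$status[gen$gene == "none"] == "persistent_NMI"))
})
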