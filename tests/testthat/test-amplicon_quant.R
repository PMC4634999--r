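test_that("SNV query k-mers are centered and unique", {
  ctx <- paste0(strrep("A", 15), "CGTGACGTTGCAAGTCCGGT", strrep("T", 15))
  pos <- 25  # the "C" of GCAAG... pick a base inside the unique core
  ref_b <- substr(ctx, pos, pos)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  q <- make_query_kmers(ctx, list(pos = pos, ref = ref_b, alt = alt_b), k = 20)
  expect_equal(nchar(q$wt), 20)
  expect_equal(nchar(q$mut), 20)
  diffs <- which(strsplit(q$wt, "")[[1]] != strsplit(q$mut, "")[[1]])
  expect_length(diffs, 1)
  expect_equal(diffs, 10)  # ceiling(k/2) left flank includes the variant

  # non-unique k-mer in a repetitive context is rejected
  rep_ctx <- strrep("ACGT", 20)
  expect_error(
    make_query_kmers(rep_ctx, list(pos = 40, ref = substr(rep_ctx, 40, 40),
                                   alt = "C"), k = 20),
    "not unique")
})

test_that("indel mutant k-mers span the junction", {
  ctx <- random_reference(60, seed = 3)$sequence
  pos <- 30
  # 2-nt deletion: mutant k-mer is 10 nt left of the junction + 10 nt right
  ref <- substr(ctx, pos, pos + 2)
  q <- make_query_kmers(ctx, list(pos = pos, ref = ref,
                                  alt = substr(ctx, pos, pos)), k = 20)
  expect_equal(q$mut, paste0(substr(ctx, pos - 9, pos),
                             substr(ctx, pos + 3, pos + 12)))
  expect_equal(q$wt, substr(ctx, pos - 9, pos + 10))

  # insertion: inserted bases appear right after the anchor
  qi <- make_query_kmers(ctx, list(pos = pos, ref = substr(ctx, pos, pos),
                                   alt = paste0(substr(ctx, pos, pos), "TTAG")),
                         k = 20)
  expect_equal(substr(qi$mut, 11, 14), "TTAG")
})

test_that("k-mer counting matches a naive scan and counts each read once", {
  set.seed(19)
  kmer <- "ACGTACGTTTGCAACGTGCA"
  reads <- vapply(1:500, function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  }, character(1))
  with_hit <- c(paste0("AAAAA", kmer, "TTTTT"),
                paste0("GG", reverse_complement(kmer), "CC"),
                paste0(kmer, reverse_complement(kmer)))  # both strands: once
  pool <- c(reads, with_hit)
  naive <- sum(vapply(pool, function(r) {
    grepl(kmer, r, fixed = TRUE) ||
      grepl(reverse_complement(kmer), r, fixed = TRUE)
  }, logical(1)))
  expect_equal(count_kmer(pool, kmer), naive)
  expect_gte(count_kmer(pool, kmer), 3L)
  expect_equal(count_kmer(pool, "GGGGGGGGGGGGGGGGGGGG"), 0L)
})

test_that("amplicon AF is count arithmetic, invariant to order and strand", {
  expect_equal(amplicon_af(2663, 952673), 2663 / 955336)
  expect_equal(round(100 * amplicon_af(2663, 952673), 2), 0.28)
  expect_equal(amplicon_af(0, 100), 0)
  expect_equal(amplicon_af(0, 0), 0)
  expect_equal(amplicon_af(7, 7), 0.5)

  ctx <- random_reference(50, seed = 23)
  pos <- 25
  alt <- setdiff(c("A", "C", "G", "T"), substr(ctx$sequence, pos, pos))[1]
  mut <- ctx$sequence; substr(mut, pos, pos) <- alt
  q <- make_query_kmers(ctx$sequence,
                        list(pos = pos, ref = substr(ctx$sequence, pos, pos),
                             alt = alt))
  pool <- simulate_amplicon_pool(ctx$sequence, mut, 0.05, 4000,
                                 per_base_error = 0, seed = 31)
  base <- quantify_amplicon(pool, q)
  shuffled <- quantify_amplicon(sample(pool), q)
  expect_equal(shuffled$af, base$af)
  flipped <- pool
  idx <- seq(1, length(pool), by = 3)
  flipped[idx] <- reverse_complement(flipped[idx])
  expect_equal(quantify_amplicon(flipped, q)$af, base$af)
  # SNV queries are mutually exclusive per read
  expect_lte(base$mutant_count + base$wt_count, length(pool))
})

test_that("panel comparison uses strict max exceedance plus a binomial tail", {
  panel <- control_panel(c(0.0007, 0.0011, 0.0016))
  res <- structure(list(mutant_count = 690L, wt_count = 99310L,
                        total_reads = 100000L, af = 0.0069,
                        panel_mean = NA_real_, panel_max = NA_real_,
                        above_noise = NA, binomial_p = NA_real_),
                   class = "amplicon_result")
  out <- compare_to_panel(res, panel)
  expect_true(out$above_noise)
  expect_lt(out$binomial_p, 1e-10)

  # AF equal to the panel max: not above noise
  res$mutant_count <- 160L; res$wt_count <- 99840L; res$af <- 0.0016
  expect_false(compare_to_panel(res, panel)$above_noise)

  # AF inside the panel range (the blood-sample situation)
  res$mutant_count <- 70L; res$wt_count <- 99930L; res$af <- 0.0007
  low <- compare_to_panel(res, panel)
  expect_false(low$above_noise)

  # binomial tail equals an exact summation on small counts
  res2 <- structure(list(mutant_count = 12L, wt_count = 4988L,
                         total_reads = 5000L, af = 12 / 5000,
                         panel_mean = NA_real_, panel_max = NA_real_,
                         above_noise = NA, binomial_p = NA_real_),
                    class = "amplicon_result")
  out2 <- compare_to_panel(res2, control_panel(c(0.001, 0.001)))
  exact <- sum(dbinom(12:5000, 5000, 0.001))
  expect_equal(out2$binomial_p, exact, tolerance = 1e-12)
})
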