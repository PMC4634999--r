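test_that("read filtering removes low-MAPQ reads exactly", {
  reads <- toy_reads(1:20, "ACGT", mapq = rep(c(60L, 0L, 19L, 20L), 5))
  cfg <- tier_config(min_mapping_quality = 20)
  kept <- filter_reads(reads, cfg)
  expect_equal(nrow(kept), 10)
  for (thr in c(0L, 10L, 20L, 61L)) {
    cfg <- tier_config(min_mapping_quality = thr)
    expect_equal(nrow(filter_reads(reads, cfg)), sum(reads$mapq >= thr))
  }
})

test_that("redundancy downsampling keeps min(group, cap) reads per start and orientation", {
  reads <- rbind(
    toy_reads(100, "ACGT", "forward", read_id = sprintf("f%03d", 1:120)),
    toy_reads(100, "ACGT", "reverse", read_id = sprintf("r%03d", 1:30)))
  ds <- downsample_redundancy(reads, 50)
  expect_equal(sum(ds$orientation == "forward"), 50)
  expect_equal(sum(ds$orientation == "reverse"), 30)

  set.seed(61)
  rand <- toy_reads(sample(1:15, 800, replace = TRUE), "ACGT",
                    sample(c("forward", "reverse"), 800, replace = TRUE),
                    read_id = sprintf("x%04d", 1:800))
  for (cap in c(1, 7, 50)) {
    ds <- downsample_redundancy(rand, cap)
    got <- table(paste(ds$start, ds$orientation))
    want <- pmin(table(paste(rand$start, rand$orientation)), cap)
    expect_equal(as.integer(got[names(want)]), as.integer(want))
  }

  # deterministic selection: highest MAPQ first, then read id
  grp <- toy_reads(5, "AAAA", mapq = c(10L, 60L, 60L, 30L),
                   read_id = c("d", "b", "a", "c"))
  kept <- downsample_redundancy(grp, 2)
  expect_setequal(kept$read_id, c("a", "b"))
})

test_that("pileups split counts by orientation and match a naive per-read scan", {
  ref <- reference("ref", "ACGTACGTACGTACGTACGT")
  one <- toy_reads(1, "ACGT")
  pu <- build_pileup(one, ref)
  expect_equal(nrow(pu$columns), 4)
  expect_true(all(pu$columns$depth_forward == 1L))
  expect_true(all(pu$columns$depth_reverse == 0L))

  mixed <- exact_af_reads(ref, 5, "G", 10, 10, 6)  # ref A at 5; 6F/4R alt G
  pu <- build_pileup(mixed, ref)
  expect_equal(pileup_count(pu, 5, "G", "forward"), 6L)
  expect_equal(pileup_count(pu, 5, "G", "reverse"), 4L)

  ref2 <- random_reference(80, seed = 71)
  pos <- 40
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref2$sequence, pos, pos))[1]
  vs <- variant_spec(ref2$name, pos, substr(ref2$sequence, pos, pos), alt,
                     "SNV", 0.1)
  reads <- simulate_reads(ref2, list(vs),
                          simulation_profile(depth = 500, read_length = 30,
                                             per_base_error = 0.005, seed = 5))
  pu <- build_pileup(reads, ref2)
  naive <- naive_pileup(reads, ref2)
  for (key in names(naive$counts)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    expect_equal(pileup_count(pu, as.integer(parts[1]), parts[2], parts[3]),
                 naive$counts[[key]], info = key)
  }
  # conservation: total counts equal total quality-passing bases
  expect_equal(sum(pu$columns$depth_forward + pu$columns$depth_reverse),
               sum(unlist(naive$counts)))
})

test_that("base-quality masking excludes bases but keeps the read", {
  ref <- reference("ref", "ACGTACGT")
  r <- toy_reads(1, "ACGT", qual = paste0("I", "!", "I", "I"))  # base 2 at Q0
  pu <- build_pileup(r, ref, config = tier_config(min_base_quality = 20))
  expect_equal(pu$columns$position, c(1L, 3L, 4L))
  expect_equal(sum(pu$columns$depth_forward), 3L)
})

test_that("indel observations key to the anchor base", {
  ref <- reference("ref", "ACGTACGTAC")
  del <- toy_reads(1, "ACTA", cigar = "3M2D1M")     # deletes 4-5, anchor 3
  ins <- toy_reads(1, "ACGGT", cigar = "3M2I2M")    # wait: consumes 3+2+2=7
  ins$sequence <- "ACGTTGT"; ins$qual <- strrep("I", 7)
  pu <- build_pileup(rbind(del, ins), ref)
  expect_setequal(pu$indels$key, c("D:2", "I:TT"))
  expect_true(all(pu$indels$position == 3L))
})

test_that("tiered calling reproduces the reported AF arithmetic", {
  ref <- reference("ref", strrep("A", 10))
  cfg <- tier_config()

  p17 <- exact_af_reads(ref, 5, "T", 1806, 10, 6)
  calls <- call_candidates(build_pileup(p17, ref), cfg, "sensitive")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$af, 10 / 1806)
  expect_equal(round(100 * calls$af, 2), 0.55)

  p32 <- exact_af_reads(ref, 5, "G", 5745, 41, 20)
  calls <- call_candidates(build_pileup(p32, ref), cfg, "sensitive")
  expect_equal(round(100 * calls$af, 2), 0.71)

  # 0.2% SNV is below the sensitive SNV cut-off
  low <- exact_af_reads(ref, 5, "T", 1000, 2, 1)
  expect_equal(nrow(call_candidates(build_pileup(low, ref), cfg, "sensitive")),
               0)
  # review tier requires 1%
  pct <- exact_af_reads(ref, 5, "T", 1000, 9, 5)
  expect_equal(nrow(call_candidates(build_pileup(pct, ref), cfg, "review")), 0)
  pct2 <- exact_af_reads(ref, 5, "T", 1000, 10, 5)
  expect_equal(nrow(call_candidates(build_pileup(pct2, ref), cfg, "review")), 1)
})

test_that("calls match an exhaustive brute-force enumeration on small read sets", {
  cfg <- tier_config(min_base_quality = 0)
  for (seed in 1:5) {
    set.seed(seed)
    ref <- random_reference(30, seed = seed + 100)
    n <- sample(10:50, 1)
    starts <- sample(1:20, n, replace = TRUE)
    seqs <- vapply(starts, function(s) {
      x <- substr(ref$sequence, s, s + 9)
      if (runif(1) < 0.5) {
        o <- sample(nchar(x), 1)
        substr(x, o, o) <- sample(c("A", "C", "G", "T"), 1)
      }
      x
    }, character(1))
    reads <- toy_reads(starts, seqs,
                       sample(c("forward", "reverse"), n, replace = TRUE),
                       contig = ref$name)
    calls <- call_candidates(build_pileup(reads, ref), cfg, "sensitive")

    # oracle: count every (pos, base) by scanning reads, apply thresholds
    expected <- 0L
    for (pos in 1:30) {
      cov <- which(starts <= pos & starts + 9 >= pos)
      if (!length(cov)) next
      bases <- substr(seqs[cov], pos - starts[cov] + 1, pos - starts[cov] + 1)
      rb <- substr(ref$sequence, pos, pos)
      for (b in setdiff(unique(bases), rb)) {
        sup <- sum(bases == b)
        if (sup / length(cov) >= 0.005 && sup >= 3) expected <- expected + 1L
      }
    }
    expect_equal(nrow(calls), expected, info = paste("seed", seed))
  }
})

test_that("threshold monotonicity: loosening thresholds never removes calls", {
  ref <- random_reference(60, seed = 81)
  pos <- 30
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref$sequence, pos, pos))[1]
  vs <- variant_spec(ref$name, pos, substr(ref$sequence, pos, pos), alt,
                     "SNV", 0.02)
  reads <- simulate_reads(ref, list(vs),
                          simulation_profile(depth = 800, read_length = 30,
                                             per_base_error = 0.01, seed = 9))
  pu <- build_pileup(reads, ref)
  key <- function(calls) paste(calls$position, calls$alt)
  strict <- call_candidates(pu, tier_config(snv_af = 0.01, snv_min_reads = 5),
                            "sensitive")
  loose <- call_candidates(pu, tier_config(snv_af = 0.005, snv_min_reads = 3),
                           "sensitive")
  expect_true(all(key(strict) %in% key(loose)))

  # raising the redundancy cap never decreases depth at the site
  depths <- vapply(c(5, 20, 50), function(cap) {
    estimate_af(build_pileup(downsample_redundancy(reads, cap), ref),
                pos, alt)$depth
  }, numeric(1))
  expect_true(all(diff(depths) >= 0))
})

test_that("single-orientation support is flagged", {
  calls <- data.frame(contig = "r", position = c(1L, 2L), ref = "A",
                      alt = "T", variant_type = "SNV", af = 0.01,
                      support_forward = c(5L, 1L), support_reverse = c(0L, 1L),
                      depth_total = 500L, tier = "sensitive", filters = "",
                      sample_id = "s", stringsAsFactors = FALSE)
  out <- apply_orientation_filter(calls)
  expect_equal(grepl("single_orientation", out$filters), c(TRUE, FALSE))

  # strand-asymmetric artifacts: flagged fraction equals a direct recount
  ref <- random_reference(100, seed = 91)
  reads <- simulate_reads(ref, NULL,
                          simulation_profile(depth = 600, read_length = 50,
                                             per_base_error = 1e-4,
                                             strand_asymmetry = 200, seed = 14))
  calls <- call_sample(reads, ref, tier_config(min_base_quality = 0))
  expect_gt(nrow(calls), 0)
  expect_equal(grepl("single_orientation", calls$filters),
               calls$support_forward == 0L | calls$support_reverse == 0L)
})

test_that("cross-sample recurrence is flagged while private variants pass", {
  mk <- function(pos, alt, sample) {
    data.frame(contig = "r", position = pos, ref = "A", alt = alt,
               variant_type = "SNV", af = 0.008, support_forward = 3L,
               support_reverse = 3L, depth_total = 700L, tier = "sensitive",
               filters = "", sample_id = sample, stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, c(
    lapply(sprintf("s%d", 1:5), function(s) mk(10L, "T", s)),
    list(mk(20L, "G", "s1"))))
  for (s in sprintf("s%d", 1:5)) {
    mine <- cohort[cohort$sample_id == s, ]
    out <- apply_panel_filter(mine, cohort)
    expect_true(all(grepl("panel_recurrent",
                          out$filters[out$position == 10L])))
    expect_false(any(grepl("panel_recurrent",
                           out$filters[out$position == 20L])))
  }
})

test_that("a recurrent artifact is separated from a true mosaic in a simulated cohort", {
  ref <- random_reference(60, seed = 55)
  art_pos <- 20; true_pos <- 40
  art_alt <- setdiff(c("A", "C", "G", "T"), substr(ref$sequence, art_pos, art_pos))[1]
  true_alt <- setdiff(c("A", "C", "G", "T"), substr(ref$sequence, true_pos, true_pos))[1]
  cfg <- tier_config()
  samples <- sprintf("s%02d", 1:12)
  all_calls <- list()
  for (i in seq_along(samples)) {
    vars <- list(variant_spec(ref$name, art_pos,
                              substr(ref$sequence, art_pos, art_pos),
                              art_alt, "SNV", 0.008))
    if (i == 1) {
      vars <- c(vars, list(variant_spec(ref$name, true_pos,
                                        substr(ref$sequence, true_pos, true_pos),
                                        true_alt, "SNV", 0.03)))
    }
    reads <- simulate_reads(ref, vars,
                            simulation_profile(depth = 2000, read_length = 30,
                                               per_base_error = 0,
                                               seed = 300 + i),
                            sample_id = samples[i])
    all_calls[[i]] <- call_sample(reads, ref, cfg, sample_id = samples[i])
  }
  cohort <- do.call(rbind, all_calls)
  s1 <- apply_panel_filter(all_calls[[1]], cohort, cfg)
  expect_true(any(grepl("panel_recurrent",
                        s1$filters[s1$position == art_pos])))
  true_call <- s1[s1$position == true_pos & s1$alt == true_alt, ]
  expect_equal(nrow(true_call), 1)
  expect_equal(true_call$filters, "")
})

test_that("detection floor: 0.2% is mostly missed at 500x and 1% is reliably called at 5,000x", {
  ref <- random_reference(150, seed = 42)
  pos <- 75
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref$sequence, pos, pos))[1]
  called_at <- function(af, depth, n_rep, seed0) {
    hits <- 0L
    for (i in seq_len(n_rep)) {
      vs <- variant_spec(ref$name, pos, substr(ref$sequence, pos, pos), alt,
                         "SNV", af)
      reads <- simulate_reads(ref, list(vs),
                              simulation_profile(depth = depth,
                                                 read_length = 50,
                                                 per_base_error = 0,
                                                 seed = seed0 + i))
      calls <- call_sample(reads, ref)
      hit <- any(calls$position == pos & calls$alt == alt &
                   calls$filters == "")
      hits <- hits + hit
    }
    hits / n_rep
  }
  expect_lt(called_at(0.002, 500, 40, 1000), 0.5)
  expect_gt(called_at(0.01, 5000, 40, 2000), 0.95)
})
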