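# MMRDness scoring: locus observation from CIGARs, per-length tabulation,
# log-transformed mean deleted fraction with the +1.1 normalization.

toy_catalog <- function() {
  # one 12-base A-run at 0-based [10, 22) on contig c1
  filter_by_length(
    scan_reference(c(c1 = paste0("CGTCGTCGTC", strrep("A", 12),
                                 "CGTCGTCGTC"))))
}

test_that("a CIGAR 1-base deletion inside the run marks the locus deleted", {
  cc <- toy_catalog()
  aln <- data.frame(contig = "c1", pos = 6, cigar = "10M1D16M")
  obs <- observe_loci(aln, cc, min_support = 1)
  expect_equal(obs$reads_total, 1)
  expect_equal(obs$reads_del1, 1)
  expect_true(obs$deleted)
})

test_that("deletions outside the run, of 2 bp, or insertions do not count", {
  cc <- toy_catalog()
  aln <- data.frame(
    contig = "c1",
    pos = c(6, 6, 6, 6),
    cigar = c("3M1D23M",   # deletion in the left flank
              "12M2D13M",  # 2-base deletion inside the run
              "12M2I15M",  # insertion inside the run
              "27M"))      # clean spanning read
  obs <- observe_loci(aln, cc)
  expect_equal(obs$reads_total, 4)
  expect_equal(obs$reads_del1, 0)
  expect_false(obs$deleted)
})

test_that("reads must span the run plus one flank base on each side", {
  cc <- toy_catalog()
  aln <- data.frame(contig = "c1",
                    pos = c(11, 10, 1),
                    cigar = c("12M", "13M", "30M"))
  # read 1 starts at the run start (no left flank), read 2 ends at the last
  # run base (no right flank): only read 3 spans
  obs <- observe_loci(aln, cc)
  expect_equal(obs$reads_total, 1)
})

test_that("loci with no spanning read are excluded, absent contigs warn", {
  cc <- toy_catalog()
  expect_warning(
    obs <- observe_loci(data.frame(contig = "other", pos = 1,
                                   cigar = "30M"), cc),
    "absent")
  expect_equal(nrow(obs), 0)
})

test_that("observed per-locus deletion fraction is calibrated at 1x", {
  rate <- 0.15
  cfg <- sim_config(seed = 31, genome_length = 300000,
                    locus_count_per_length = c(`12` = 10000),
                    slippage_del_rate = rate, coverage = 1)
  ref <- simulate_reference(cfg)
  rds <- simulate_locus_reads(ref$truth, cfg)
  obs <- observe_loci(rds$alignments, ref$truth)
  # locus-level deletion probability given >= 1 spanning read:
  # E[1 - (1-r)^N | N >= 1], N ~ Poisson(1)
  p_loc <- 1 - (exp(1 - rate) - 1) / (exp(1) - 1)
  phat <- mean(obs$deleted)
  se <- sqrt(p_loc * (1 - p_loc) / nrow(obs))
  expect_lt(abs(phat - p_loc), 3 * se)
})

test_that("length table groups observations and keeps empty bins", {
  obs <- data.frame(length = rep(10:15, each = 10),
                    deleted = rep(c(TRUE, TRUE, rep(FALSE, 8)), 6))
  tab <- build_length_table(obs)
  expect_equal(tab$n_loci, rep(10L, 6))
  expect_equal(tab$n_del, rep(2L, 6))
  expect_equal(nrow(build_length_table(obs[0, ])), 0)
  # brute-force group-by agreement on random observations
  set.seed(4)
  robs <- data.frame(length = sample(10:15, 500, replace = TRUE),
                     deleted = sample(c(TRUE, FALSE), 500, replace = TRUE))
  tab2 <- build_length_table(robs)
  for (L in 10:15) {
    expect_equal(tab2$n_loci[tab2$length == L], sum(robs$length == L))
    expect_equal(tab2$n_del[tab2$length == L],
                 sum(robs$deleted[robs$length == L]))
  }
})

test_that("score formula: log10 of the mean fraction plus the 1.1 offset", {
  # threshold point: uniform fraction 10^-1.1 gives score exactly 0
  thr <- 10^(-1.1)
  tab <- data.frame(length = 10:15, n_loci = 1e6,
                    n_del = round(1e6 * thr))
  res <- mmrdness_score(tab)
  expect_equal(res$score, log10(round(1e6 * thr) / 1e6) + 1.1)

  tab01 <- data.frame(length = 10:15, n_loci = 10, n_del = 1)
  expect_equal(mmrdness_score(tab01)$score, log10(0.1) + 1.1)
  expect_equal(mmrdness_score(tab01)$call, "MMRD")

  # independently hand-computed arithmetic case
  tab2 <- data.frame(length = 10:15, n_loci = 100,
                     n_del = c(3, 5, 8, 12, 15, 20))
  res2 <- mmrdness_score(tab2)
  expect_equal(res2$mean_fraction, 0.105)
  expect_equal(res2$raw_score, -0.97881070093006, tolerance = 1e-12)
  expect_equal(res2$score, 0.12118929906994, tolerance = 1e-10)
  expect_equal(res2$call, "MMRD")
})

test_that("empty bins are excluded and recorded; all-empty is an error", {
  tab <- data.frame(length = 10:15, n_loci = c(0, 100, 100, 100, 100, 0),
                    n_del = c(0, 10, 10, 10, 10, 0))
  res <- mmrdness_score(tab)
  expect_equal(res$provenance$excluded_lengths, c(10L, 15L))
  expect_equal(res$mean_fraction, 0.1)
  expect_error(mmrdness_score(data.frame(length = 10:15, n_loci = 0,
                                         n_del = 0)), "empty")
})

test_that("all-clean sample yields the -Inf sentinel and proficiency", {
  tab <- data.frame(length = 10:15, n_loci = 100, n_del = 0)
  res <- mmrdness_score(tab, pseudocount = 0)
  expect_identical(res$raw_score, -Inf)
  expect_equal(res$call, "MMR-proficient")
  expect_true(res$provenance$zero_mean_fraction)
  # a pseudocount keeps the score finite
  expect_true(is.finite(mmrdness_score(tab, pseudocount = 0.5)$score))
})

test_that("classification is by sign with the boundary assigned proficient", {
  expect_equal(classify_mmrd(0.3), "MMRD")
  expect_equal(classify_mmrd(-0.5), "MMR-proficient")
  expect_equal(classify_mmrd(0), "MMR-proficient")
})

test_that("score is monotone in deletions and scale invariant", {
  set.seed(8)
  for (i in 1:25) {
    n_loci <- sample(50:500, 6, replace = TRUE)
    n_del <- vapply(n_loci, function(n) sample(1:n, 1), integer(1))
    tab <- data.frame(length = 10:15, n_loci = n_loci, n_del = n_del)
    s0 <- mmrdness_score(tab)$score
    # bump one bin's deletions
    j <- sample(which(tab$n_del < tab$n_loci), 1)
    tab2 <- tab
    tab2$n_del[j] <- tab2$n_del[j] + 1L
    expect_gte(mmrdness_score(tab2)$score, s0)
    # multiply all counts by a constant: unchanged at pseudocount 0
    tab3 <- tab
    tab3$n_loci <- tab3$n_loci * 7L
    tab3$n_del <- tab3$n_del * 7L
    expect_equal(mmrdness_score(tab3)$score, s0)
  }
})

test_that("SAM and in-memory alignment routes give identical observations", {
  cfg <- sim_config(seed = 51, slippage_del_rate = 0.3)
  ref <- simulate_reference(cfg)
  cc <- filter_by_length(scan_reference(ref$sequence))
  rds <- simulate_locus_reads(ref$truth, cfg, reference = ref$sequence)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(rds$alignments, sam, c(sim1 = cfg$genome_length))
  obs_mem <- observe_loci(rds$alignments, cc)
  obs_sam <- observe_loci(sam, cc)
  expect_equal(obs_sam, obs_mem)
})
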