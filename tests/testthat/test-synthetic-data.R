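# The simulators are the evidence base for everything downstream: they must
# be deterministic in the seed, return machine-readable truth, and be
# statistically calibrated to their configured parameters.

test_that("simulated reference embeds exactly the configured maximal runs", {
  cfg <- sim_config(seed = 11, genome_length = 100,
                    locus_count_per_length = c(`12` = 1))
  ref <- simulate_reference(cfg)
  seq <- as.character(ref$sequence)[[1]]
  expect_equal(nchar(seq), 100)
  runs <- oracle_scan_runs(seq)
  runs12 <- runs[runs$length >= 10, ]
  expect_equal(nrow(runs12), 1)
  expect_equal(runs12$length, 12)
  expect_equal(ref$truth$start, runs12$start)
  expect_equal(ref$truth$base, runs12$base)
})

test_that("reference simulation is a pure function of the seed", {
  cfg <- sim_config(seed = 99)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(as.character(a$sequence), as.character(b$sequence))
  expect_identical(a$truth, b$truth)
})

test_that("truth catalog matches an independent homopolymer scan", {
  cfg <- sim_config(seed = 7)  # 10 loci per length 10..15
  ref <- simulate_reference(cfg)
  runs <- oracle_scan_runs(as.character(ref$sequence)[[1]], "sim1")
  runs <- runs[runs$length >= 10 & runs$length <= 15, ]
  rownames(runs) <- NULL
  expect_equal(ref$truth$start, runs$start)
  expect_equal(ref$truth$end, runs$end)
  expect_equal(ref$truth$base, runs$base)
})

test_that("reference placement fails loudly when the genome is too small", {
  cfg <- sim_config(seed = 1, genome_length = 50,
                    locus_count_per_length = c(`15` = 10))
  expect_error(simulate_reference(cfg), "genome_length")
})

test_that("slippage rate 0 and 1 are the degenerate read regimes", {
  ref <- simulate_reference(sim_config(seed = 3))
  clean <- simulate_locus_reads(ref$truth,
                                sim_config(seed = 3, slippage_del_rate = 0))
  expect_false(any(grepl("D", clean$alignments$cigar)))
  expect_false(any(clean$truth$deleted))
  alldel <- simulate_locus_reads(
    ref$truth, sim_config(seed = 3, slippage_del_rate = 1, coverage = 5))
  expect_true(all(grepl("1D", alldel$alignments$cigar)))
  expect_true(all(alldel$truth$deleted))
})

test_that("empirical read-level deletion fraction is calibrated", {
  rate <- 0.2
  cfg <- sim_config(seed = 17, genome_length = 300000,
                    locus_count_per_length = c(`12` = 10000),
                    slippage_del_rate = rate)
  ref <- simulate_reference(cfg)
  rds <- simulate_locus_reads(ref$truth, cfg)
  n <- nrow(rds$alignments)
  phat <- mean(grepl("D", rds$alignments$cigar))
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(phat - rate), 3 * se)
  # CIGAR encoding agrees with the per-read truth sidecar
  expect_identical(grepl("D", rds$alignments$cigar), rds$truth$deleted)
})

test_that("caller emission covers the certainty, null, and calibrated cases", {
  cfg1 <- sim_config(seed = 5, caller_overlap = 1, n_variants = 200,
                     indel_fraction = 0.2)
  sim1 <- simulate_caller_vcfs(cfg1)
  for (cs in sim1$callers) expect_identical(cs, sim1$truth)

  cfg0 <- sim_config(seed = 5, caller_overlap = 0, n_variants = 200)
  sim0 <- simulate_caller_vcfs(cfg0)
  cons0 <- merge_consensus(sim0$callers)
  expect_equal(nrow(cons0$snv) + nrow(cons0$indel), 0)

  cfg <- sim_config(seed = 29, caller_overlap = 0.8, caller_count = 4,
                    n_variants = 1000)
  sim <- simulate_caller_vcfs(cfg)
  key <- function(d) paste(d$contig, d$pos, d$ref, d$alt)
  in2 <- rowSums(sapply(sim$callers,
                        function(cs) key(sim$truth) %in% key(cs))) >= 2
  p <- oracle_consensus_prob(0.8, 4)
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(mean(in2) - p), 3 * se)
})

test_that("catalog simulation draws from the mixture-weighted channels", {
  S <- synthetic_signatures()
  one <- simulate_catalog(S, sim_config(seed = 2, mixture = c(SBS1 = 1),
                                        n_mutations = 20000))
  # single component: counts proportional to the column within multinomial noise
  p <- S[, "SBS1"]
  expect_lt(max(abs(as.numeric(one$catalog) / 20000 - p)),
            5 * sqrt(max(p) * (1 - min(p)) / 20000))

  zero <- simulate_catalog(S, sim_config(seed = 2, n_mutations = 0))
  expect_equal(sum(zero$catalog), 0)

  mix <- c(SBS6 = 0.8, SBS1 = 0.2)
  sim <- simulate_catalog(S, sim_config(seed = 4, mixture = mix,
                                        n_mutations = 10000))
  pm <- as.numeric(S[, names(mix)] %*% mix)
  dev <- abs(as.numeric(sim$catalog) - 10000 * pm)
  tol <- 5 * sqrt(10000 * pm * (1 - pm)) + 3
  expect_true(all(dev <= tol))
  expect_equal(sim$truth, mix)

  expect_error(
    simulate_catalog(S, sim_config(seed = 1, mixture = c(SBS99 = 1))),
    "unknown signature")
})

test_that("panel simulation injects recoverable shifts with strict stutter", {
  stable <- simulate_panel_profile(sim_config(seed = 8))
  expect_equal(panel_msi(stable$normal, stable$test)$sample_call,
               "MS-Stable")

  two <- simulate_panel_profile(sim_config(
    seed = 8, panel_shifts = default_panel_shifts("BAT-25" = 4,
                                                  "NR-21" = 5)))
  res <- panel_msi(two$normal, two$test)
  expect_equal(sum(res$loci$shift >= 3), 2)

  for (s in 1:200) {
    shifts <- default_panel_shifts()
    shifts[] <- sample(0:5, 5, replace = TRUE)
    pr <- simulate_panel_profile(sim_config(seed = 1000 + s,
                                            panel_shifts = shifts))
    res <- panel_msi(pr$normal, pr$test)
    got <- setNames(res$loci$shift, res$loci$locus)
    expect_equal(got[names(shifts)], shifts)
  }
})

test_that("every simulator is deterministic and leaves the RNG untouched", {
  cfg <- sim_config(seed = 123, n_variants = 50, n_mutations = 100)
  ref <- simulate_reference(cfg)
  set.seed(777)
  before <- .Random.seed
  a <- list(simulate_locus_reads(ref$truth, cfg),
            simulate_caller_vcfs(cfg),
            simulate_catalog(synthetic_signatures(), cfg),
            simulate_panel_profile(cfg))
  expect_identical(.Random.seed, before)
  b <- list(simulate_locus_reads(ref$truth, cfg),
            simulate_caller_vcfs(cfg),
            simulate_catalog(synthetic_signatures(), cfg),
            simulate_panel_profile(cfg))
  expect_identical(a, b)
})
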