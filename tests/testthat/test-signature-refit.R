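# Catalog channelization and NNLS signature refitting.

test_that("channel order is the 96 lexicographic COSMIC labels", {
  ch <- sbs_channels()
  expect_length(ch, 96)
  expect_false(any(duplicated(ch)))
  expect_identical(ch, sort(ch))
  expect_equal(ch[1], "A[C>A]A")
  expect_true(all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", ch)))
})

test_that("SNVs are channelized with pyrimidine normalization", {
  # C>T at context ACA
  cat1 <- build_catalog(data.frame(contig = "c1", pos = 2, ref = "C",
                                   alt = "T"), c(c1 = "ACAG"))
  expect_equal(sum(cat1), 1)
  expect_equal(as.integer(cat1["A[C>T]A"]), 1L)

  # G>A on the forward strand T G A: counted as C>T in revcomp context T[C>T]A
  cat2 <- build_catalog(data.frame(contig = "c1", pos = 2, ref = "G",
                                   alt = "A"), c(c1 = "TGAG"))
  expect_equal(as.integer(cat2[oracle_channel("TGA", "A")]), 1L)
  expect_equal(sum(cat2), 1)
})

test_that("ref mismatches are an error and edge SNVs are skipped", {
  expect_error(build_catalog(data.frame(contig = "c1", pos = 2, ref = "T",
                                        alt = "A"), c(c1 = "ACAG")),
               "mismatch")
  expect_warning(
    cat0 <- build_catalog(data.frame(contig = "c1", pos = 1, ref = "A",
                                     alt = "T"), c(c1 = "ACAG")),
    "edge")
  expect_equal(sum(cat0), 0)
})

test_that("catalog equals an independent per-variant channelizer", {
  set.seed(19)
  seq <- random_seq(5000)
  pos <- sample(2:4999, 1000)
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  snvs <- data.frame(contig = "c1", pos = pos, ref = ref, alt = alt)
  got <- build_catalog(snvs, c(c1 = seq))
  trio <- substring(seq, pos - 1, pos + 1)
  want <- table(factor(mapply(oracle_channel, trio, alt),
                       levels = sbs_channels()))
  expect_equal(as.integer(got), as.integer(want))
  expect_equal(sum(got), 1000)
})

test_that("refit recovers pure and noiseless two-component catalogs", {
  S <- synthetic_signatures()
  fit <- refit_signatures(setNames(1000 * S[, "SBS6"], rownames(S)), S)
  expect_equal(unname(fit$contribution_pct["SBS6"]), 100, tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-9)
  expect_equal(fit$cosine, 1, tolerance = 1e-12)

  y <- 600 * S[, "SBS6"] + 400 * S[, "SBS1"]
  fit2 <- refit_signatures(setNames(y, rownames(S)), S)
  expect_equal(unname(fit2$contribution_pct[c("SBS6", "SBS1")]),
               c(60, 40), tolerance = 1e-6)
  # oracle: unconstrained least squares on the two true columns
  A <- S[, c("SBS6", "SBS1")]
  e <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(unname(fit2$exposures[c("SBS6", "SBS1")]), c(e),
               tolerance = 1e-6)
  expect_error(refit_signatures(setNames(numeric(96), sbs_channels()), S),
               "empty")
})

test_that("permuting signature columns permutes exposures identically", {
  S <- synthetic_signatures()
  cat96 <- simulate_catalog(S, sim_config(seed = 33))$catalog
  fit <- refit_signatures(cat96, S)
  perm <- c(3, 1, 4, 2)
  fitp <- refit_signatures(cat96, S[, perm])
  expect_equal(fitp$exposures[names(fit$exposures)], fit$exposures,
               tolerance = 1e-8)
})

test_that("residual norm is bounded by the catalog norm", {
  S <- synthetic_signatures()
  set.seed(12)
  for (i in 1:10) {
    y <- setNames(rpois(96, 20), sbs_channels())
    fit <- refit_signatures(y, S)
    expect_lte(fit$residual_norm, sqrt(sum(y^2)) + 1e-9)
    expect_true(all(fit$exposures >= 0))
  }
})

test_that("contribution error shrinks as the catalog grows", {
  S <- synthetic_signatures()
  truth <- c(SBS6 = 0.8, SBS1 = 0.2)
  err_at <- function(n) {
    errs <- vapply(1:20, function(s) {
      cfg <- sim_config(seed = 300 + s, mixture = truth, n_mutations = n)
      fit <- refit_signatures(simulate_catalog(S, cfg)$catalog, S)
      mean(abs(fit$contribution_pct[names(truth)] - 100 * truth))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(10000), err_at(1000))
})

test_that("MMRD signature fraction sums the configured id set", {
  S <- synthetic_signatures()
  fit <- refit_signatures(setNames(1000 * S[, "SBS6"], rownames(S)), S)
  expect_equal(mmrd_signature_fraction(fit, "SBS6"), 100, tolerance = 1e-9)
  expect_equal(mmrd_signature_fraction(fit, c("SBS1", "SBS5")), 0,
               tolerance = 1e-9)
  # default id set: the MMRD-associated signatures present in the matrix
  expect_gte(mmrd_signature_fraction(fit), 100 - 1e-9)
  expect_error(mmrd_signature_fraction(fit, "SBS77"), "unknown")
})

test_that("the shipped synthetic matrix file matches its generator", {
  path <- system.file("extdata", "signatures_synthetic_96x4.tsv",
                      package = "mmrdkit")
  S <- read_signature_matrix(path)
  expect_equal(S, synthetic_signatures(), tolerance = 1e-12)
  expect_equal(unname(colSums(S)), rep(1, 4), tolerance = 1e-9)
  bad <- synthetic_signatures()
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(validate <- refit_signatures(
    setNames(rep(1, 96), sbs_channels()), bad), "sum to 1")
})
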