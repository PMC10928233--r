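#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' object. The defaults are the study conditions the read-outs were designed
#' for: mononucleotide loci of 10--15 bp, mean coverage 1 read per locus
#' (low-pass whole-genome sequencing at ~1x), four somatic callers merged at
#' two-caller consensus, and an SBS6-dominant mutation-signature mixture.
#'
#' @param seed Integer seed. Every `simulate_*()` function is a pure function
#'   of its arguments and this seed: identical configs give bit-identical
#'   output. Internally each simulator uses `seed` plus a fixed small offset
#'   so that the stages draw independent streams.
#' @param genome_length Total reference length in bases.
#' @param locus_count_per_length Named integer vector: number of embedded
#'   microsatellite loci for each run length (names are the lengths, default
#'   10 loci at each of 10..15 bp).
#' @param slippage_del_rate Probability that a read spanning a locus carries a
#'   1-bp deletion of the run. This is the proxy for MMR status: polymerase
#'   slippage uncorrected by mismatch repair.
#' @param coverage Mean reads per locus (Poisson); default 1, emulating 1x
#'   low-pass sequencing.
#' @param n_mutations Number of SNVs drawn when simulating a 96-channel
#'   mutation catalog.
#' @param mixture Named non-negative weights over signature ids, summing to 1;
#'   the ground-truth signature mixture for catalog simulation.
#' @param caller_count Number of somatic variant callers to emulate (>= 2).
#' @param caller_overlap Probability that each caller independently reports a
#'   true variant.
#' @param n_variants Number of true somatic variants to simulate.
#' @param caller_fp_rate Expected caller-private false positives per caller,
#'   as a fraction of `n_variants` (default 0).
#' @param indel_fraction Fraction of true variants simulated as 1-bp indels
#'   rather than SNVs.
#' @param panel_shifts Named numeric vector mapping panel locus names to the
#'   allele-length shift (bp) injected into the test profile; default all five
#'   Promega mononucleotide loci at shift 0 (microsatellite-stable).
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, slippage_del_rate = 0.2)
#' cfg$coverage
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       locus_count_per_length = setNames(rep(10L, 6), 10:15),
                       slippage_del_rate = 0.1,
                       coverage = 1,
                       n_mutations = 10000L,
                       mixture = c(SBS6 = 0.8, SBS1 = 0.2),
                       caller_count = 4L,
                       caller_overlap = 0.8,
                       n_variants = 1000L,
                       caller_fp_rate = 0,
                       indel_fraction = 0.1,
                       panel_shifts = setNames(
                         rep(0, 5),
                         c("BAT-25", "BAT-26", "NR-21", "NR-24", "MONO-27"))) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  prob_in_01 <- function(p, what) {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop(sprintf("%s must be a probability in [0, 1]", what))
    }
  }
  prob_in_01(slippage_del_rate, "slippage_del_rate")
  prob_in_01(caller_overlap, "caller_overlap")
  prob_in_01(indel_fraction, "indel_fraction")
  if (caller_fp_rate < 0) stop("caller_fp_rate must be >= 0")
  if (coverage <= 0) stop("coverage must be > 0")
  if (is.null(names(locus_count_per_length)) ||
      anyNA(as.integer(names(locus_count_per_length)))) {
    stop("locus_count_per_length must be named by run length")
  }
  if (any(locus_count_per_length < 0)) stop("locus counts must be >= 0")
  if (length(mixture)) {
    if (is.null(names(mixture))) stop("mixture must be named by signature id")
    if (any(mixture < 0)) stop("mixture weights must be non-negative")
    if (abs(sum(mixture) - 1) > 1e-9) {
      stop("mixture weights must sum to 1 (within 1e-9)")
    }
  }
  if (caller_count < 2L) stop("caller_count must be >= 2")
  if (!is.null(panel_shifts) && is.null(names(panel_shifts))) {
    stop("panel_shifts must be named by panel locus")
  }
  structure(list(
    seed = seed,
    genome_length = as.integer(genome_length),
    locus_count_per_length = setNames(as.integer(locus_count_per_length),
                                      names(locus_count_per_length)),
    slippage_del_rate = slippage_del_rate,
    coverage = coverage,
    n_mutations = as.integer(n_mutations),
    mixture = mixture,
    caller_count = as.integer(caller_count),
    caller_overlap = caller_overlap,
    n_variants = as.integer(n_variants),
    caller_fp_rate = caller_fp_rate,
    indel_fraction = indel_fraction,
    panel_shifts = panel_shifts
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (seed", x$seed, ")\n")
  cat("  genome:", x$genome_length, "bp;",
      sum(x$locus_count_per_length), "microsatellite loci (",
      paste(range(as.integer(names(x$locus_count_per_length))),
            collapse = "-"), "bp )\n")
  cat("  slippage 1-bp deletion rate:", x$slippage_del_rate,
      "; coverage:", x$coverage, "x\n")
  cat("  somatic truth:", x$n_variants, "variants,", x$caller_count,
      "callers at overlap", x$caller_overlap, "\n")
  if (length(x$mixture)) {
    cat("  signature mixture:",
        paste(sprintf("%s=%.2f", names(x$mixture), x$mixture),
              collapse = ", "), "\n")
  }
  invisible(x)
}
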