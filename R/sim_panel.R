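# Panel-profile simulator: stutter-shaped peak tables for the five
# mononucleotide loci, with a configurable allele-length shift injected into
# the test sample at each locus.

PANEL_BASELINE_BP <- c("BAT-25" = 124, "BAT-26" = 116, "NR-21" = 103,
                       "NR-24" = 132, "MONO-27" = 142)

# One locus profile: main peak with stutter side-peaks at +/-1 bp (50% of the
# main height) and +/-2 bp (25%), each with +/-10% multiplicative jitter so
# heights are realistic while the main > stutter ordering stays strict.
stutter_profile <- function(locus, main_bp, main_height = 1000) {
  offs <- c(-2L, -1L, 0L, 1L, 2L)
  rel <- c(0.25, 0.5, 1, 0.5, 0.25)
  jit <- runif(length(offs), 0.9, 1.1)
  data.frame(locus = locus,
             allele_length_bp = main_bp + offs,
             peak_height = main_height * rel * jit,
             stringsAsFactors = FALSE)
}

#' Simulate a normal/test pair of panel peak profiles
#'
#' The normal profile has one stutter-shaped peak cluster per configured
#' locus, centred on a realistic amplicon size; the test profile's main peak
#' is moved by `panel_shifts[locus]` bp toward shorter alleles (deletions,
#' the direction microsatellite instability takes at mononucleotide runs).
#' Stutter peaks flank the main allele at 50% and 25% of its height.
#'
#' @param config A [sim_config()]; `panel_shifts` names the loci and gives
#'   the injected shift in bp for each.
#' @return List with `normal` and `test` peak-profile data frames (columns
#'   `locus`, `allele_length_bp`, `peak_height`) and `truth` (the injected
#'   shifts).
#' @examples
#' pr <- simulate_panel_profile(sim_config(seed = 2,
#'   panel_shifts = c("BAT-25" = 4, "BAT-26" = 0, "NR-21" = 5,
#'                    "NR-24" = 0, "MONO-27" = 0)))
#' panel_msi(pr$normal, pr$test)
#' @export
simulate_panel_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  shifts <- config$panel_shifts
  if (is.null(shifts) || length(shifts) == 0L) {
    stop("config$panel_shifts must name at least one locus")
  }
  base_bp <- PANEL_BASELINE_BP[names(shifts)]
  # loci outside the default panel get deterministic sizes near 100 bp
  unknown <- is.na(base_bp)
  base_bp[unknown] <- 100 + 7 * seq_len(sum(unknown))
  with_seed(config$seed + 4L, {
    normal <- do.call(rbind, lapply(seq_along(shifts), function(i) {
      stutter_profile(names(shifts)[i], base_bp[i])
    }))
    test <- do.call(rbind, lapply(seq_along(shifts), function(i) {
      stutter_profile(names(shifts)[i], base_bp[i] - shifts[i])
    }))
    list(normal = normal, test = test, truth = shifts)
  })
}
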