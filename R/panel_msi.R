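# Five-locus mononucleotide panel MSI classification from fragment-analysis
# peak profiles (BAT-25, BAT-26, NR-21, NR-24, MONO-27): pick the highest
# peak flanked by lower (stutter) peaks as the representative allele, score a
# locus unstable at a >= 3 bp shift from the normal allele, and call the
# sample MSI-High at >= 2 unstable loci, MSI-Low at 1, MS-Stable at 0.

#' Representative allele of a peak profile
#'
#' Among peaks whose immediate neighbours (by allele length, in the sorted
#' profile) both have strictly lower height, returns the allele length of the
#' highest; a boundary peak cannot satisfy the flanking rule, so if no
#' interior peak does (monotone or degenerate electropherograms) the global
#' maximum is used. Height ties break toward the shorter allele
#' (deletion-biased MSI).
#'
#' @param peaks Data frame with columns `allele_length_bp`, `peak_height`.
#' @return Representative allele length (bp).
#' @examples
#' representative_allele(data.frame(allele_length_bp = 120:122,
#'                                  peak_height = c(100, 500, 300)))
#' @export
representative_allele <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    stop("empty peak list: no alleles to select from")
  }
  if (any(peaks$peak_height < 0)) stop("peak heights must be >= 0")
  if (anyDuplicated(peaks$allele_length_bp)) {
    stop("allele lengths must be unique within a locus")
  }
  ord <- order(peaks$allele_length_bp)
  len <- peaks$allele_length_bp[ord]
  h <- peaks$peak_height[ord]
  n <- length(h)
  cand <- if (n >= 3L) {
    which(h[2:(n - 1L)] > h[1:(n - 2L)] & h[2:(n - 1L)] > h[3:n]) + 1L
  } else integer()
  if (length(cand) == 0L) cand <- seq_len(n)  # fallback: global maximum
  best <- cand[h[cand] == max(h[cand])]
  len[best[which.min(len[best])]]
}

#' Allele-length shift and locus instability
#'
#' @param test,normal Representative allele lengths (bp) in the test and
#'   normal sample.
#' @param threshold Shift (bp) at or above which the locus is unstable
#'   (default 3; a <= 2 bp shift is stable).
#' @return List with `shift` (absolute bp difference) and `unstable`.
#' @export
locus_shift <- function(test, normal, threshold = 3) {
  shift <- abs(test - normal)
  list(shift = shift, unstable = shift >= threshold)
}

#' Sample-level MSI call from per-locus instability flags
#'
#' @param unstable Logical vector of per-locus instability flags (assayed
#'   loci only).
#' @param msi_high_min Minimum unstable loci for MSI-High (default 2).
#' @return `"MSI-High"`, `"MSI-Low"`, or `"MS-Stable"`.
#' @export
classify_sample <- function(unstable, msi_high_min = 2L) {
  if (length(unstable) == 0L) stop("no assayed loci: cannot classify sample")
  k <- sum(unstable)
  if (k >= msi_high_min) "MSI-High" else if (k >= 1L) "MSI-Low" else "MS-Stable"
}

#' Classify MSI status from paired panel peak profiles
#'
#' Runs the full panel read-out: representative-allele selection per locus in
#' the normal and test profiles, per-locus shift and instability, and the
#' sample-level call. Loci missing from either profile reduce the assayed
#' denominator and are flagged.
#'
#' @param normal,test Peak profiles: data frames with columns `locus`,
#'   `allele_length_bp`, `peak_height`, or TSV paths with those columns.
#' @param shift_threshold Instability shift threshold in bp (default 3).
#' @param msi_high_min Minimum unstable loci for MSI-High (default 2).
#' @return Object of class `"panel_msi"`: per-locus table (`locus`,
#'   `normal_allele`, `test_allele`, `shift`, `unstable`), `sample_call`,
#'   `unstable_count`, `n_assayed`, and `incomplete_panel` flag.
#' @export
panel_msi <- function(normal, test, shift_threshold = 3, msi_high_min = 2L) {
  normal <- as_panel_profile(normal)
  test <- as_panel_profile(test)
  loci <- intersect(unique(normal$locus), unique(test$locus))
  dropped <- setdiff(union(unique(normal$locus), unique(test$locus)), loci)
  if (length(loci) == 0L) stop("no locus present in both profiles")
  if (length(dropped)) {
    warning("loci missing from one profile, excluded from the assay: ",
            paste(dropped, collapse = ", "))
  }
  per <- lapply(loci, function(lc) {
    na <- representative_allele(normal[normal$locus == lc, , drop = FALSE])
    ta <- representative_allele(test[test$locus == lc, , drop = FALSE])
    ls <- locus_shift(ta, na, shift_threshold)
    data.frame(locus = lc, normal_allele = na, test_allele = ta,
               shift = ls$shift, unstable = ls$unstable,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  structure(list(
    loci = tab,
    unstable_count = sum(tab$unstable),
    n_assayed = nrow(tab),
    sample_call = classify_sample(tab$unstable, msi_high_min),
    incomplete_panel = nrow(tab) < 5L,
    provenance = list(shift_threshold = shift_threshold,
                      msi_high_min = msi_high_min,
                      dropped_loci = dropped)
  ), class = "panel_msi")
}

as_panel_profile <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- read_panel_profile(x)
  need <- c("locus", "allele_length_bp", "peak_height")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("panel profile needs columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Read/write panel peak profiles as TSV
#'
#' Columns: `locus`, `allele_length_bp`, `peak_height` (one row per peak),
#' emulating an exported capillary-electrophoresis peak table.
#'
#' @param profile Peak-profile data frame.
#' @param path TSV path.
#' @return `write_panel_profile()` returns `path` invisibly;
#'   `read_panel_profile()` returns the data frame.
#' @export
write_panel_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_profile
#' @export
read_panel_profile <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.panel_msi <- function(x, ...) {
  cat("Panel MSI classification\n")
  print(x$loci, row.names = FALSE)
  cat(sprintf("\n  unstable loci: %d of %d assayed (shift >= %g bp)\n",
              x$unstable_count, x$n_assayed,
              x$provenance$shift_threshold))
  cat("  sample call:", x$sample_call, "\n")
  if (x$incomplete_panel) cat("  note: fewer than 5 panel loci assayed\n")
  invisible(x)
}
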