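# Reference simulator: a single contig with embedded maximal mononucleotide
# runs separated by repeat-free spacers (adjacent spacer bases always differ),
# so the embedded loci are the only homopolymers of length >= 2.

# Random spacer with no two equal adjacent bases; first/last base constrained
# so flanking a run never extends it.
random_spacer <- function(len, avoid_first = NULL, avoid_last = NULL) {
  first <- sample(setdiff(DNA_BASES, avoid_first), 1L)
  if (len == 1L) {
    if (!is.null(avoid_last) && first == avoid_last) {
      first <- sample(setdiff(DNA_BASES, c(avoid_first, avoid_last)), 1L)
    }
    return(first)
  }
  steps <- sample.int(3L, len - 1L, replace = TRUE)
  idx <- (match(first, DNA_BASES) - 1L + cumsum(steps)) %% 4L
  out <- c(first, DNA_BASES[idx + 1L])
  if (!is.null(avoid_last) && out[len] == avoid_last) {
    out[len] <- sample(setdiff(DNA_BASES, c(out[len - 1L], avoid_last)), 1L)
  }
  paste(out, collapse = "")
}

#' Simulate a reference sequence with embedded microsatellites
#'
#' Builds a single-contig reference containing exactly the configured number
#' of maximal mononucleotide runs per length, separated by repeat-free spacers
#' of at least 5 bp, and returns the exact truth catalog of embedded loci.
#'
#' @param config A [sim_config()].
#' @param fasta Optional path; when given, the sequence is written as FASTA.
#' @return A list with `sequence` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (a BED-like data frame: `contig`, `start` 0-based, `end`
#'   exclusive, `base`, `length`, sorted by position).
#' @examples
#' ref <- simulate_reference(sim_config(seed = 7))
#' head(ref$truth)
#' @export
simulate_reference <- function(config, fasta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$locus_count_per_length
  lens <- as.integer(names(counts))
  with_seed(config$seed, {
    locus_len <- rep(lens, counts)
    n <- length(locus_len)
    if (n == 0L) stop("no loci configured in locus_count_per_length")
    locus_len <- locus_len[sample.int(length(locus_len))]
    base <- sample(DNA_BASES, n, replace = TRUE)
    min_flank <- 5L
    needed <- sum(locus_len) + (n + 1L) * min_flank
    if (config$genome_length < needed) {
      stop(sprintf(paste0(
        "genome_length %d cannot place %d loci (%d repeat bases) with ",
        "%d-base non-repeat flanks: need at least %d bases"),
        config$genome_length, n, sum(locus_len), min_flank, needed))
    }
    extra <- config$genome_length - needed
    spacer_len <- min_flank +
      as.vector(rmultinom(1L, extra, rep(1, n + 1L)))
    pieces <- character(2L * n + 1L)
    start0 <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      sp <- random_spacer(spacer_len[i],
                          avoid_first = if (i > 1L) base[i - 1L] else NULL,
                          avoid_last = base[i])
      pieces[2L * i - 1L] <- sp
      pos <- pos + spacer_len[i]
      start0[i] <- pos
      pieces[2L * i] <- strrep(base[i], locus_len[i])
      pos <- pos + locus_len[i]
    }
    pieces[2L * n + 1L] <- random_spacer(spacer_len[n + 1L],
                                         avoid_first = base[n])
    seq <- paste(pieces, collapse = "")
    truth <- data.frame(
      contig = "sim1",
      start = start0,
      end = start0 + locus_len,
      base = base,
      length = locus_len,
      stringsAsFactors = FALSE
    )
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    dss <- Biostrings::DNAStringSet(setNames(seq, "sim1"))
    if (!is.null(fasta)) Biostrings::writeXStringSet(dss, fasta)
    list(sequence = dss, truth = truth)
  })
}
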