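# Read simulator for the microsatellite-slippage substrate: aligned records
# only (the genome-wide MSI score operates post-alignment), each spanning one
# locus with both flanks; a slippage read carries a 1-base deletion inside
# the run, encoded in its CIGAR.

#' Simulate locus-spanning reads with slippage deletions
#'
#' Draws `Poisson(coverage)` reads per microsatellite locus. Each read spans
#' the full run plus 5--15 bp of flank on both sides; independently with
#' probability `slippage_del_rate` it carries a deletion of exactly one run
#' base (CIGAR `xM1Dy M`), the read-level signature of uncorrected polymerase
#' slippage.
#'
#' @param truth Locus catalog data frame (`contig`, `start`, `end`, `base`,
#'   `length`), e.g. the `truth` element of [simulate_reference()].
#' @param config A [sim_config()] (uses `coverage`, `slippage_del_rate`,
#'   `genome_length`, `seed`).
#' @param reference Optional reference (path/`DNAStringSet`/character); when
#'   supplied, read sequences are taken from it, otherwise SEQ is `*`.
#' @param sam Optional path; when given, records are written as SAM via
#'   [write_sam()].
#' @return A list with `alignments` (data frame: `qname`, `flag`, `contig`,
#'   `pos` 1-based leftmost, `mapq`, `cigar`, `seq`) and `truth` (per-read
#'   ground truth: `qname`, `locus_index` into the input catalog, `deleted`).
#' @examples
#' ref <- simulate_reference(sim_config(seed = 3))
#' rds <- simulate_locus_reads(ref$truth, sim_config(seed = 3))
#' head(rds$alignments)
#' @export
simulate_locus_reads <- function(truth, config, reference = NULL, sam = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$slippage_del_rate
  glen <- config$genome_length
  with_seed(config$seed + 1L, {
    n_per <- rpois(nrow(truth), config$coverage)
    idx <- rep(seq_len(nrow(truth)), n_per)
    m <- length(idx)
    empty <- data.frame(qname = character(), flag = integer(),
                        contig = character(), pos = integer(),
                        mapq = integer(), cigar = character(),
                        seq = character(), stringsAsFactors = FALSE)
    if (m == 0L) {
      return(list(alignments = empty,
                  truth = data.frame(qname = character(),
                                     locus_index = integer(),
                                     deleted = logical())))
    }
    st <- truth$start[idx]
    en <- truth$end[idx]
    fl <- sample(5:15, m, replace = TRUE)
    fr <- sample(5:15, m, replace = TRUE)
    rstart0 <- pmax(0L, st - fl)
    rend0 <- pmin(glen, en + fr)
    del <- rbinom(m, 1L, rate) == 1L
    delpos0 <- pmin(st + floor(runif(m) * (en - st)), en - 1L)
    a <- delpos0 - rstart0
    b <- rend0 - delpos0 - 1L
    cigar <- ifelse(del,
                    paste0(a, "M1D", b, "M"),
                    paste0(rend0 - rstart0, "M"))
    seqs <- "*"
    if (!is.null(reference)) {
      refchr <- as_reference_chr(reference)
      chr <- refchr[truth$contig[idx]]
      full <- substr(chr, rstart0 + 1L, rend0)
      seqs <- ifelse(del,
                     paste0(substr(full, 1L, a),
                            substr(full, a + 2L, nchar(full))),
                     full)
    }
    aln <- data.frame(
      qname = sprintf("read_%06d", seq_len(m)),
      flag = 0L,
      contig = truth$contig[idx],
      pos = rstart0 + 1L,
      mapq = 60L,
      cigar = cigar,
      seq = seqs,
      stringsAsFactors = FALSE
    )
    read_truth <- data.frame(qname = aln$qname, locus_index = idx,
                             deleted = del, stringsAsFactors = FALSE)
    if (!is.null(sam)) {
      contigs <- setNames(glen, truth$contig[1L])
      write_sam(aln, sam, contigs)
    }
    list(alignments = aln, truth = read_truth)
  })
}

#' Write alignment records as SAM
#'
#' Minimal unsorted SAM v1.6 writer for simulated alignment frames.
#'
#' @param alignments Data frame as produced by [simulate_locus_reads()].
#' @param path Output path (`.sam`).
#' @param contigs Named integer vector of contig lengths for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, contigs) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      as.integer(contigs)))
  seqf <- alignments$seq
  seqf[is.na(seqf) | seqf == ""] <- "*"
  qual <- ifelse(seqf == "*", "*", strrep("I", nchar(seqf)))
  body <- paste(alignments$qname, alignments$flag, alignments$contig,
                alignments$pos, alignments$mapq, alignments$cigar,
                "*", 0L, 0L, seqf, qual, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
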