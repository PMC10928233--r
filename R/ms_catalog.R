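# Microsatellite locus catalog: maximal mononucleotide runs in a reference,
# length-filtered to the 10-15 bp window the genome-wide MSI score uses.
# Coordinates are 0-based half-open (BED convention) throughout.

new_locus_catalog <- function(df, length_filter = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("locus_catalog", "data.frame"),
            length_filter = length_filter)
}

#' Scan a reference for mononucleotide microsatellite runs
#'
#' Finds every maximal homopolymer run of length >= 2 in each contig. Runs of
#' `N` are excluded; runs abutting contig ends still count as maximal. The
#' scan is the denominator source for the genome-wide MMRDness score.
#'
#' @param x Reference: FASTA path, `DNAStringSet`, or (named) character
#'   vector of contig sequences. Only `A`/`C`/`G`/`T`/`N` are permitted.
#' @return A `locus_catalog`: data frame with columns `contig`, `start`
#'   (0-based), `end` (exclusive), `base`, `length`, sorted by
#'   (contig, start).
#' @examples
#' scan_reference(c(chr1 = "CCAAAAAAAAAAAAGG"))
#' @export
scan_reference <- function(x) {
  ref <- as_reference_chr(x)
  bad <- grepl("[^ACGTN]", ref)
  if (any(bad)) {
    stop("non-nucleotide symbols (not A/C/G/T/N) in contig(s): ",
         paste(names(ref)[bad], collapse = ", "))
  }
  out <- lapply(names(ref), function(ctg) {
    s <- ref[[ctg]]
    if (nchar(s) == 0L) return(NULL)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= 2L & r$values %in% DNA_BASES
    if (!any(keep)) return(NULL)
    data.frame(contig = ctg,
               start = ends[keep] - r$lengths[keep],
               end = ends[keep],
               base = r$values[keep],
               length = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(contig = character(), start = integer(),
                     end = integer(), base = character(),
                     length = integer(), stringsAsFactors = FALSE)
  }
  df <- df[order(df$contig, df$start), , drop = FALSE]
  new_locus_catalog(df)
}

#' Filter a locus catalog by run length
#'
#' Retains loci with `min_len <= length <= max_len` (both ends inclusive);
#' the default 10--15 bp window is the score's operating range.
#'
#' @param catalog A `locus_catalog` (or compatible data frame).
#' @param min_len,max_len Inclusive length bounds in bases.
#' @return The filtered `locus_catalog`, with the filter recorded in the
#'   `length_filter` attribute.
#' @export
filter_by_length <- function(catalog, min_len = 10L, max_len = 15L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  keep <- catalog$length >= min_len & catalog$length <= max_len
  new_locus_catalog(as.data.frame(catalog)[keep, , drop = FALSE],
                    length_filter = c(min_len, max_len))
}

#' Tabulate a locus catalog by run length
#'
#' @param catalog A (filtered) `locus_catalog`.
#' @return Data frame `length`, `n_loci` — the total number of genomic loci at
#'   each observed length; empty for an empty catalog.
#' @export
tabulate_by_length <- function(catalog) {
  if (nrow(catalog) == 0L) {
    return(data.frame(length = integer(), n_loci = integer()))
  }
  tab <- table(catalog$length)
  data.frame(length = as.integer(names(tab)),
             n_loci = as.integer(tab))
}

#' Read/write a locus catalog as BED-like TSV
#'
#' Columns: `contig`, `start` (0-based), `end` (exclusive), `base`, `length`.
#'
#' @param catalog A `locus_catalog`.
#' @param path TSV path.
#' @return `write_catalog()` returns `path` invisibly; `read_catalog()`
#'   returns a `locus_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "base", "length")
  if (!all(need %in% names(df))) {
    stop("catalog TSV must have columns: ", paste(need, collapse = ", "))
  }
  new_locus_catalog(df[need])
}
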