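# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

DNA_BASES <- c("A", "C", "G", "T")

# Normalise a reference given as FASTA path, DNAStringSet, or character vector
# to a named character vector of contig sequences.
as_reference_chr <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", x, ignore.case = TRUE)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet") || methods::is(x, "DNAString")) {
    x <- as.character(x)
  }
  if (!is.character(x)) {
    stop("reference must be a FASTA path, DNAStringSet, or character vector")
  }
  if (is.null(names(x))) {
    names(x) <- if (length(x) == 1L) "sim1" else paste0("contig", seq_along(x))
  }
  # FASTA descriptions: keep the first word as the contig name
  names(x) <- sub("\\s.*$", "", names(x))
  toupper(x)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
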