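# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: regex-based run scanning, string-level
# channelization, and closed-form probability.

# Maximal homopolymer runs of length >= 2 via regex backreferences.
oracle_scan_runs <- function(seq, contig = "c1") {
  m <- gregexpr("([ACGT])\\1+", seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), base = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  st <- as.integer(m)
  ln <- attr(m, "match.length")
  data.frame(contig = contig, start = st - 1L, end = st - 1L + ln,
             base = substr(rep(seq, length(st)), st, st),
             length = ln, stringsAsFactors = FALSE)
}

# Trinucleotide channel of one SNV via independent string ops.
oracle_channel <- function(trio, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mid <- substr(trio, 2, 2)
  if (mid %in% c("A", "G")) {
    trio <- paste(rev(comp[strsplit(trio, "")[[1]]]), collapse = "")
    alt <- comp[[alt]]
    mid <- substr(trio, 2, 2)
  }
  paste0(substr(trio, 1, 1), "[", mid, ">", alt, "]", substr(trio, 3, 3))
}

# P(a true variant is reported by >= 2 of k independent callers at rate p).
oracle_consensus_prob <- function(p, k) {
  1 - (1 - p)^k - k * p * (1 - p)^(k - 1)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

default_panel_shifts <- function(...) {
  sh <- setNames(rep(0, 5), c("BAT-25", "BAT-26", "NR-21", "NR-24",
                              "MONO-27"))
  upd <- c(...)
  sh[names(upd)] <- upd
  sh
}
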