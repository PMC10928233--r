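# Consensus-caller somatic burden: merge per-caller variant sets on a
# left-normalized (contig, pos, ref, alt) identity, keep variants shared by
# >= 2 callers (SNVs and indels partitioned), and report tumor mutation
# burden as somatic SNVs per callable megabase with the strict >10 mut/Mb
# hypermutator call.

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel")
}

# Left-normalize one variant: trim shared trailing bases, then shared
# leading bases (advancing pos), always keeping at least one base each.
normalize_variants <- function(df) {
  ref <- df$ref; alt <- df$alt; pos <- df$pos
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  df$ref <- ref; df$alt <- alt; df$pos <- pos
  df$variant_class <- variant_class(df$ref, df$alt)
  df
}

split_multiallelic <- function(df) {
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
  out$alt <- unlist(alts)
  rownames(out) <- NULL
  out
}

#' Read one caller's VCF into a variant frame
#'
#' Multi-allelic records are split into one alt per row, indels are
#' left-normalized, and non-PASS records are excluded by default.
#'
#' @param path VCF path (v4.x).
#' @param keep_filtered Keep records whose FILTER is not PASS/`.`
#'   (default FALSE).
#' @return Data frame `contig`, `pos`, `ref`, `alt`, `variant_class`.
#' @export
read_caller_vcf <- function(path, keep_filtered = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  df <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   filter = fix$FILTER %||% ".",
                   stringsAsFactors = FALSE)
  if (!keep_filtered) {
    df <- df[is.na(df$filter) | df$filter %in% c("PASS", "."), , drop = FALSE]
  }
  df$filter <- NULL
  df <- split_multiallelic(df)
  normalize_variants(df)
}

check_contig_consistency <- function(sets) {
  ctgs <- unique(unlist(lapply(sets, function(s) unique(s$contig))))
  norm <- sub("^chr", "", ctgs)
  dup <- norm[duplicated(norm)]
  if (length(dup)) {
    clash <- ctgs[norm %in% dup]
    stop("inconsistent contig naming across callers: ",
         paste(sort(clash), collapse = " vs "))
  }
  invisible(TRUE)
}

#' Merge per-caller variant sets into a consensus
#'
#' A variant (identified by left-normalized contig, position, ref, alt after
#' multi-allelic splitting) is retained when reported by at least
#' `min_callers` callers. SNVs and indels are partitioned; each consensus
#' record keeps its supporting-caller list.
#'
#' @param caller_sets Named list: one variant frame (or VCF path) per caller.
#' @param min_callers Minimum supporting callers (default 2).
#' @return Object of class `"consensus_variants"`: list with `snv` and
#'   `indel` data frames (`contig`, `pos`, `ref`, `alt`, `variant_class`,
#'   `callers`, `n_callers`) plus `n_callers_total`.
#' @export
merge_consensus <- function(caller_sets, min_callers = 2L) {
  if (min_callers > length(caller_sets)) {
    stop("min_callers (", min_callers, ") exceeds the number of callers (",
         length(caller_sets), ")")
  }
  if (is.null(names(caller_sets)) || any(names(caller_sets) == "")) {
    names(caller_sets) <- paste0("caller", seq_along(caller_sets))
  }
  sets <- lapply(caller_sets, function(s) {
    if (is.character(s)) s <- read_caller_vcf(s)
    s <- split_multiallelic(s)
    s <- normalize_variants(s)
    # identity de-duplication within a caller
    s[!duplicated(paste(s$contig, s$pos, s$ref, s$alt)), , drop = FALSE]
  })
  check_contig_consistency(sets)
  all_df <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (nrow(s) == 0L) return(NULL)
    data.frame(contig = s$contig, pos = s$pos, ref = s$ref, alt = s$alt,
               variant_class = s$variant_class, caller = nm,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      variant_class = character(), callers = character(),
                      n_callers = integer(), stringsAsFactors = FALSE)
  if (is.null(all_df)) {
    return(structure(list(snv = empty, indel = empty,
                          n_callers_total = length(sets)),
                     class = "consensus_variants"))
  }
  key <- paste(all_df$contig, all_df$pos, all_df$ref, all_df$alt, sep = "\r")
  supp <- split(all_df$caller, key)
  first <- all_df[!duplicated(key), , drop = FALSE]
  fkey <- key[!duplicated(key)]
  first$callers <- vapply(supp[fkey], function(cc) {
    paste(sort(cc), collapse = ",")
  }, character(1))
  first$n_callers <- lengths(supp[fkey])
  first$caller <- NULL
  cons <- first[first$n_callers >= min_callers, , drop = FALSE]
  cons <- cons[order(cons$contig, cons$pos, cons$ref, cons$alt), ,
               drop = FALSE]
  rownames(cons) <- NULL
  structure(list(
    snv = cons[cons$variant_class == "SNV", , drop = FALSE],
    indel = cons[cons$variant_class == "indel", , drop = FALSE],
    n_callers_total = length(sets)
  ), class = "consensus_variants")
}

#' @export
print.consensus_variants <- function(x, ...) {
  cat("Consensus somatic variants (", x$n_callers_total, "callers )\n")
  cat("  SNVs:", nrow(x$snv), "  indels:", nrow(x$indel), "\n")
  invisible(x)
}

#' Tumor mutation burden from consensus SNVs
#'
#' TMB is the number of distinct consensus somatic SNVs divided by the
#' callable genome size in megabases (default ~50 Mb, a whole-exome callable
#' footprint). Indels are excluded from the count; a combined SNV+indel rate
#' is reported separately and never used for the hypermutator call.
#'
#' @param x A `"consensus_variants"` object or a variant data frame with a
#'   `variant_class` column.
#' @param callable_mb Callable megabases (> 0, default 50).
#' @param threshold Hypermutator threshold in mut/Mb (default 10, strict).
#' @return Object of class `"tmb_result"`: `snv_count`, `indel_count`,
#'   `callable_mb`, `tmb`, `tmb_snv_indel`, `hypermutant`, `threshold`.
#' @examples
#' df <- data.frame(contig = "1", pos = 1:100, ref = "C", alt = "T",
#'                  variant_class = "SNV")
#' compute_tmb(df, callable_mb = 50)
#' @export
compute_tmb <- function(x, callable_mb = 50, threshold = 10) {
  if (!is.numeric(callable_mb) || callable_mb <= 0) {
    stop("callable_mb must be > 0")
  }
  if (inherits(x, "consensus_variants")) {
    snv <- x$snv
    indel_count <- nrow(x$indel)
  } else {
    x <- x[!duplicated(paste(x$contig, x$pos, x$ref, x$alt)), , drop = FALSE]
    snv <- x[x$variant_class == "SNV", , drop = FALSE]
    indel_count <- sum(x$variant_class != "SNV")
  }
  snv_count <- nrow(snv)
  tmb <- snv_count / callable_mb
  structure(list(
    snv_count = snv_count,
    indel_count = indel_count,
    callable_mb = callable_mb,
    tmb = tmb,
    tmb_snv_indel = (snv_count + indel_count) / callable_mb,
    hypermutant = classify_hypermutant(tmb, threshold),
    threshold = threshold
  ), class = "tmb_result")
}

#' Hypermutator classification
#'
#' A sample is a hypermutator when its TMB strictly exceeds the threshold
#' (default 10 mut/Mb); a sample at exactly the threshold is not.
#'
#' @param x A `"tmb_result"` or a numeric TMB in mut/Mb.
#' @param threshold Strict threshold in mut/Mb (default 10).
#' @return Logical.
#' @export
classify_hypermutant <- function(x, threshold = 10) {
  tmb <- if (inherits(x, "tmb_result")) x$tmb else as.numeric(x)
  is.finite(tmb) && tmb > threshold
}

#' @export
print.tmb_result <- function(x, ...) {
  cat("Tumor mutation burden\n")
  cat(sprintf("  %d consensus SNVs / %g callable Mb = %.2f mut/Mb\n",
              x$snv_count, x$callable_mb, x$tmb))
  cat(sprintf("  (SNV+indel rate: %.2f mut/Mb, not used for the call)\n",
              x$tmb_snv_indel))
  cat(sprintf("  hypermutator (> %g mut/Mb): %s\n", x$threshold,
              x$hypermutant))
  invisible(x)
}

#' Write a variant frame as a minimal VCF v4.2
#'
#' @param df Variant frame (`contig`, `pos`, `ref`, `alt`, optionally
#'   `callers`).
#' @param path Output path.
#' @param contig_lengths Named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(df, path, contig_lengths = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##source=mmrdkit",
              "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting callers\">")
  if (!is.null(contig_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths),
                                as.integer(contig_lengths)))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- if ("callers" %in% names(df) && nrow(df) > 0L) {
    paste0("CALLERS=", df$callers)
  } else rep(".", nrow(df))
  body <- if (nrow(df) == 0L) character() else {
    paste(df$contig, df$pos, ".", df$ref, df$alt, ".", "PASS", info,
          sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
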