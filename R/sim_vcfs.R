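# Multi-caller somatic call-set simulator: a shared truth set of SNVs and
# 1-bp indels, each emitted by each caller independently with probability
# caller_overlap, plus optional caller-private false positives.

#' Simulate per-caller somatic variant sets with known truth
#'
#' Draws `n_variants` true somatic variants (a configurable fraction as 1-bp
#' insertions/deletions, the rest SNVs) at distinct positions on one contig.
#' Each caller reports each true variant independently with probability
#' `caller_overlap`; each caller additionally emits
#' `Poisson(caller_fp_rate * n_variants)` private false positives (default
#' rate 0).
#'
#' @param config A [sim_config()] (uses `n_variants`, `caller_count`,
#'   `caller_overlap`, `caller_fp_rate`, `indel_fraction`, `genome_length`,
#'   `seed`).
#' @param reference Optional reference; when supplied, true ref alleles are
#'   read from it, otherwise drawn at random.
#' @param dir Optional directory; when given, one VCF per caller plus
#'   machine-readable truth sidecars (`truth.tsv`, `truth.json`) are written.
#' @return List with `truth` (data frame `contig`, `pos`, `ref`, `alt`,
#'   `variant_class`) and `callers` (named list of per-caller frames of the
#'   same shape).
#' @export
simulate_caller_vcfs <- function(config, reference = NULL, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  k <- config$caller_count
  glen <- config$genome_length
  if (n >= glen - 1L) stop("genome_length too small for n_variants")
  with_seed(config$seed + 2L, {
    pos <- sort(sample.int(glen - 1L, n))
    refchr <- if (!is.null(reference)) as_reference_chr(reference)[[1L]]
    ref1 <- if (!is.null(reference)) {
      substr(rep(refchr, n), pos, pos)
    } else sample(DNA_BASES, n, replace = TRUE)
    # SNV alt: one of the three other bases
    alt_snv <- DNA_BASES[(match(ref1, DNA_BASES) - 1L +
                            sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
    is_indel <- runif(n) < config$indel_fraction
    is_del <- is_indel & runif(n) < 0.5
    next_base <- if (!is.null(reference)) {
      substr(rep(refchr, n), pos + 1L, pos + 1L)
    } else sample(DNA_BASES, n, replace = TRUE)
    ins_base <- sample(DNA_BASES, n, replace = TRUE)
    ref <- ifelse(is_del, paste0(ref1, next_base), ref1)
    alt <- ifelse(is_del, ref1,
                  ifelse(is_indel, paste0(ref1, ins_base), alt_snv))
    truth <- data.frame(contig = "sim1", pos = pos, ref = ref, alt = alt,
                        variant_class = variant_class(ref, alt),
                        stringsAsFactors = FALSE)
    callers <- setNames(vector("list", k), paste0("caller", seq_len(k)))
    fp_lambda <- config$caller_fp_rate * n
    for (j in seq_len(k)) {
      emit <- rbinom(n, 1L, config$caller_overlap) == 1L
      cs <- truth[emit, , drop = FALSE]
      nfp <- if (fp_lambda > 0) rpois(1L, fp_lambda) else 0L
      if (nfp > 0L) {
        fpos <- sample(setdiff(seq_len(glen - 1L), pos), nfp)
        fref <- if (!is.null(reference)) {
          substr(rep(refchr, nfp), fpos, fpos)
        } else sample(DNA_BASES, nfp, replace = TRUE)
        falt <- DNA_BASES[(match(fref, DNA_BASES) - 1L +
                             sample.int(3L, nfp, replace = TRUE)) %% 4L + 1L]
        fp <- data.frame(contig = "sim1", pos = fpos, ref = fref,
                         alt = falt, variant_class = "SNV",
                         stringsAsFactors = FALSE)
        cs <- rbind(cs, fp)
      }
      cs <- cs[order(cs$pos), , drop = FALSE]
      rownames(cs) <- NULL
      callers[[j]] <- cs
    }
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (nm in names(callers)) {
        write_vcf(callers[[nm]], file.path(dir, paste0(nm, ".vcf")),
                  contig_lengths = c(sim1 = glen))
      }
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           dataframe = "rows")
    }
    list(truth = truth, callers = callers)
  })
}
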