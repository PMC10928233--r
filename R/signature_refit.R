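# Mutational-signature refitting: build the 96-channel trinucleotide catalog
# from consensus SNVs (pyrimidine-normalized, channels in lexicographic
# COSMIC order) and decompose it onto a reference signature matrix by
# non-negative least squares.

#' The 96 single-base-substitution channels
#'
#' Channel labels `5'[ref>alt]3'` with pyrimidine-normalized reference (C or
#' T), in lexicographic COSMIC order (the order of the COSMIC download
#' files). This order is written into every catalog and matrix output.
#'
#' @return Character vector of 96 channel labels.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(three = DNA_BASES, sub = subs, five = DNA_BASES,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$five, "[", grid$sub, "]", grid$three))
}

new_mutation_catalog <- function(counts) {
  ch <- sbs_channels()
  stopifnot(length(counts) == 96L)
  structure(setNames(as.integer(counts), ch), class = "mutation_catalog")
}

#' Build a 96-channel mutation catalog from SNVs
#'
#' Assigns each SNV to its trinucleotide-context channel. Variants with a
#' purine reference (A/G) are reverse-complemented — variant and flanking
#' context together — before assignment, the standard pyrimidine
#' normalization. Counts sum to the number of contributing SNVs.
#'
#' @param snvs Data frame with `contig`, `pos` (1-based), `ref`, `alt`
#'   (single-base each); rows that are not SNVs are ignored.
#' @param reference Reference: FASTA path, `DNAStringSet`, or named
#'   character vector, covering every SNV's contig.
#' @return A `"mutation_catalog"`: named integer vector of 96 channel counts.
#' @examples
#' cat96 <- build_catalog(
#'   data.frame(contig = "c1", pos = 2, ref = "C", alt = "T"),
#'   c(c1 = "ACA"))
#' cat96[cat96 > 0]
#' @export
build_catalog <- function(snvs, reference) {
  ref <- as_reference_chr(reference)
  snvs <- snvs[nchar(snvs$ref) == 1L & nchar(snvs$alt) == 1L, , drop = FALSE]
  counts <- setNames(integer(96L), sbs_channels())
  if (nrow(snvs) == 0L) return(new_mutation_catalog(counts))
  missing <- setdiff(unique(snvs$contig), names(ref))
  if (length(missing)) {
    stop("SNV contig(s) absent from reference: ",
         paste(missing, collapse = ", "))
  }
  chrlen <- nchar(ref)[snvs$contig]
  at_edge <- snvs$pos <= 1L | snvs$pos >= chrlen
  if (any(at_edge)) {
    warning(sum(at_edge), " SNV(s) at contig edges lack trinucleotide ",
            "context and were skipped")
    snvs <- snvs[!at_edge, , drop = FALSE]
    if (nrow(snvs) == 0L) return(new_mutation_catalog(counts))
  }
  trio <- substr(ref[snvs$contig], snvs$pos - 1L, snvs$pos + 1L)
  obs_ref <- substr(trio, 2L, 2L)
  bad <- obs_ref != snvs$ref
  if (any(bad)) {
    stop("ref allele mismatch with reference sequence at: ",
         paste(utils::head(paste0(snvs$contig[bad], ":", snvs$pos[bad],
                                  " (VCF ", snvs$ref[bad], ", reference ",
                                  obs_ref[bad], ")"), 5L),
               collapse = "; "))
  }
  purine <- snvs$ref %in% c("A", "G")
  trio[purine] <- revcomp_chr(trio[purine])
  alt <- snvs$alt
  alt[purine] <- revcomp_chr(alt[purine])
  chan <- paste0(substr(trio, 1L, 1L), "[", substr(trio, 2L, 2L), ">", alt,
                 "]", substr(trio, 3L, 3L))
  tab <- table(factor(chan, levels = sbs_channels()))
  new_mutation_catalog(as.integer(tab))
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("96-channel mutation catalog:", sum(x), "SNVs\n")
  nz <- x[x > 0]
  top <- sort(nz, decreasing = TRUE)
  cat("  top channels:",
      paste(sprintf("%s=%d", names(utils::head(top, 5L)),
                    utils::head(top, 5L)), collapse = ", "), "\n")
  invisible(x)
}

validate_signature_matrix <- function(S) {
  if (nrow(S) != 96L) stop("signature matrix must have 96 rows")
  if (!setequal(rownames(S), sbs_channels())) {
    stop("signature matrix row names must be the 96 SBS channels")
  }
  S <- S[sbs_channels(), , drop = FALSE]
  if (any(S < 0)) stop("signature matrix entries must be >= 0")
  cs <- colSums(S)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("signature column(s) do not sum to 1 (within 1e-6): ",
         paste(colnames(S)[abs(cs - 1) > 1e-6], collapse = ", "))
  }
  S
}

#' Read/write a signature reference matrix (COSMIC download format)
#'
#' TSV with the channel label in the first column (`Type`) and one column
#' per signature; rows are reordered to lexicographic channel order and
#' columns validated to sum to 1.
#'
#' @param path TSV path.
#' @param S 96 x k numeric matrix, rownames = channels.
#' @return `read_signature_matrix()` returns the validated matrix;
#'   `write_signature_matrix()` returns `path` invisibly.
#' @export
read_signature_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  S <- as.matrix(df[, -1L, drop = FALSE])
  rownames(S) <- df[[1L]]
  validate_signature_matrix(S)
}

#' @rdname read_signature_matrix
#' @export
write_signature_matrix <- function(S, path) {
  S <- validate_signature_matrix(S)
  df <- data.frame(Type = rownames(S), S, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic 96x4 signature matrix
#'
#' A deterministic stand-in for a COSMIC-style reference matrix, shipped so
#' refitting is testable without any download. Columns are labelled with
#' familiar ids and qualitatively mimic their namesakes — SBS1 concentrates
#' C>T at NpCpG (5-methylcytosine deamination), SBS6 (the MMRD hallmark)
#' spreads C>T over non-CpG contexts with some T>C, SBS5 is flat
#' ("clock-like"), SBS15 is C>A-weighted — but the values are synthetic, not
#' COSMIC estimates.
#'
#' @return 96 x 4 column-stochastic matrix (`SBS1`, `SBS5`, `SBS6`,
#'   `SBS15`).
#' @export
synthetic_signatures <- function() {
  ch <- sbs_channels()
  background <- rep(1 / 96, 96L)
  peak <- function(sel, mass) {
    p <- background * (1 - mass)
    p[sel] <- p[sel] + mass / sum(sel)
    p
  }
  is_ct <- grepl("\\[C>T\\]", ch)
  s1 <- peak(is_ct & endsWith(ch, "G"), 0.75)
  s6 <- (1 - 0.6 - 0.15) * background
  sel6 <- is_ct & !endsWith(ch, "G")
  s6[sel6] <- s6[sel6] + 0.6 / sum(sel6)
  sel6b <- grepl("\\[T>C\\]", ch)
  s6[sel6b] <- s6[sel6b] + 0.15 / sum(sel6b)
  s5 <- background
  s15 <- peak(grepl("\\[C>A\\]", ch), 0.75)
  S <- cbind(SBS1 = s1, SBS5 = s5, SBS6 = s6, SBS15 = s15)
  rownames(S) <- ch
  validate_signature_matrix(S)
}

#' Refit a mutation catalog against a signature matrix
#'
#' Estimates non-negative signature exposures `e` minimizing
#' `||catalog - S e||_2` (non-negative least squares), and reports exposures,
#' percentage contributions, the reconstructed catalog, its cosine
#' similarity to the observed catalog, and the residual norm.
#'
#' @param catalog A `"mutation_catalog"` (or named 96-vector of counts) with
#'   total > 0.
#' @param signatures 96 x k column-stochastic matrix (see
#'   [read_signature_matrix()], [synthetic_signatures()]).
#' @return Object of class `"signature_refit"` with elements `exposures`,
#'   `contribution_pct`, `reconstruction`, `cosine`, `residual_norm`,
#'   `catalog`, `signature_ids`, `provenance` (including a rank-deficiency
#'   flag). `coef()`, `fitted()`, `residuals()`, `print()` and `plot()`
#'   methods are available.
#' @examples
#' S <- synthetic_signatures()
#' cat96 <- simulate_catalog(S, sim_config(seed = 5))$catalog
#' fit <- refit_signatures(cat96, S)
#' coef(fit)
#' @export
refit_signatures <- function(catalog, signatures) {
  S <- validate_signature_matrix(signatures)
  y <- as.numeric(catalog)
  if (!is.null(names(catalog))) {
    if (!setequal(names(catalog), rownames(S))) {
      stop("catalog channel names do not match the signature matrix")
    }
    y <- as.numeric(catalog[rownames(S)])
  }
  if (length(y) != 96L) stop("catalog must have 96 channels")
  if (sum(y) <= 0) stop("catalog is empty: nothing to refit")
  fit <- pracma::lsqnonneg(S, y)
  exposures <- setNames(pmax(fit$x, 0), colnames(S))
  recon <- as.numeric(S %*% exposures)
  resid_norm <- sqrt(sum((y - recon)^2))
  cosine <- if (sum(recon^2) > 0) {
    sum(y * recon) / (sqrt(sum(y^2)) * sqrt(sum(recon^2)))
  } else 0
  tot <- sum(exposures)
  pct <- if (tot > 0) 100 * exposures / tot else exposures * 0
  rank_def <- qr(S)$rank < ncol(S)
  structure(list(
    exposures = exposures,
    contribution_pct = pct,
    reconstruction = setNames(recon, rownames(S)),
    cosine = cosine,
    residual_norm = resid_norm,
    catalog = setNames(y, rownames(S)),
    signature_ids = colnames(S),
    provenance = list(method = "non-negative least squares",
                      channel_order = "lexicographic COSMIC",
                      rank_deficient = rank_def)
  ), class = "signature_refit")
}

#' @export
coef.signature_refit <- function(object, ...) object$exposures

#' @export
fitted.signature_refit <- function(object, ...) object$reconstruction

#' @export
residuals.signature_refit <- function(object, ...) {
  object$catalog - object$reconstruction
}

#' @export
print.signature_refit <- function(x, ...) {
  cat("Signature refit (non-negative least squares)\n")
  df <- data.frame(signature = x$signature_ids,
                   exposure = round(x$exposures, 1),
                   contribution_pct = round(x$contribution_pct, 2))
  print(df[order(-df$exposure), ], row.names = FALSE)
  cat(sprintf("  cosine(catalog, reconstruction) = %.4f; residual norm = %.1f\n",
              x$cosine, x$residual_norm))
  if (x$provenance$rank_deficient) {
    cat("  warning: rank-deficient signature matrix; exposures unstable\n")
  }
  invisible(x)
}

#' @export
plot.signature_refit <- function(x, ...) {
  m <- rbind(observed = x$catalog, reconstructed = x$reconstruction)
  barplot(m, beside = TRUE, las = 2, cex.names = 0.35,
          legend.text = rownames(m),
          main = sprintf("Catalog refit (cosine %.3f)", x$cosine), ...)
  invisible(x)
}

#' Total MMRD-signature contribution
#'
#' Sums the percentage contributions of the MMRD-associated signatures.
#' Defaults to the MMRD ids present in the fit: `Signature.6` (COSMIC V2) or
#' the V3 set `SBS6`, `SBS15`, `SBS21`, `SBS26`, `SBS44`.
#'
#' @param fit A `"signature_refit"`.
#' @param mmrd_ids Character vector of signature ids to sum; unknown ids are
#'   an error.
#' @return Percentage in `[0, 100]`.
#' @export
mmrd_signature_fraction <- function(fit, mmrd_ids = NULL) {
  ids <- fit$signature_ids
  if (is.null(mmrd_ids)) {
    mmrd_ids <- intersect(c("Signature.6", "SBS6", "SBS15", "SBS21",
                            "SBS26", "SBS44"), ids)
    if (length(mmrd_ids) == 0L) {
      stop("no default MMRD signature id present; supply mmrd_ids")
    }
  }
  unknown <- setdiff(mmrd_ids, ids)
  if (length(unknown)) {
    stop("unknown signature id(s): ", paste(unknown, collapse = ", "))
  }
  sum(fit$contribution_pct[mmrd_ids])
}
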