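# Catalog simulator: multinomial draws from a mixture-weighted channel
# distribution, the fixture for signature-recovery testing.

#' Simulate a 96-channel mutation catalog from a signature mixture
#'
#' Draws `n_mutations` channel assignments multinomially from the
#' mixture-weighted channel distribution `S %*% w` and retains the true
#' weights, so refitting can be checked against ground truth.
#'
#' @param signatures 96 x k column-stochastic signature matrix.
#' @param config A [sim_config()] (uses `mixture`, `n_mutations`, `seed`).
#' @return List with `catalog` (a `"mutation_catalog"`) and `truth` (the
#'   mixture weights).
#' @examples
#' sim <- simulate_catalog(synthetic_signatures(), sim_config(seed = 9))
#' sum(sim$catalog)
#' @export
simulate_catalog <- function(signatures, config) {
  stopifnot(inherits(config, "sim_config"))
  S <- validate_signature_matrix(signatures)
  mix <- config$mixture
  unknown <- setdiff(names(mix), colnames(S))
  if (length(unknown)) {
    stop("mixture references unknown signature(s): ",
         paste(unknown, collapse = ", "))
  }
  p <- as.numeric(S[, names(mix), drop = FALSE] %*% mix)
  with_seed(config$seed + 3L, {
    counts <- if (config$n_mutations > 0L) {
      rmultinom(1L, config$n_mutations, p)[, 1L]
    } else integer(96L)
    list(catalog = new_mutation_catalog(counts), truth = mix)
  })
}

#' Read/write a 96-channel catalog as TSV
#'
#' Two columns, `channel` and `count`, with channels in lexicographic COSMIC
#' order.
#'
#' @param catalog A `"mutation_catalog"`.
#' @param path TSV path.
#' @return `write_mutation_catalog()` returns `path` invisibly;
#'   `read_mutation_catalog()` returns a `"mutation_catalog"`.
#' @export
write_mutation_catalog <- function(catalog, path) {
  write.table(data.frame(channel = names(catalog),
                         count = as.integer(catalog)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_catalog
#' @export
read_mutation_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!setequal(df$channel, sbs_channels())) {
    stop("catalog TSV channels do not match the 96 SBS channels")
  }
  new_mutation_catalog(df$count[match(sbs_channels(), df$channel)])
}
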