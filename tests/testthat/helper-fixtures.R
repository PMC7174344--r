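# Shared fixtures: a fixed synthetic signature reference and catalog
# builders used across test files. Everything is generated in code under
# fixed seeds; no data files.

SIGS <- make_signature_set(seed = 20)

# expected catalog from a known signature mixture, as exact counts
mixture_catalog <- function(sigs, exposures) {
  y <- as.numeric(sigs[, names(exposures), drop = FALSE] %*% exposures)
  stats::setNames(y, rownames(sigs))
}

# multinomial draw of n mutations from a signature mixture
sample_catalog <- function(sigs, fractions, n, seed = 1) {
  p <- as.numeric(sigs[, names(fractions), drop = FALSE] %*% fractions)
  set.seed(seed)
  stats::setNames(as.numeric(stats::rmultinom(1, n, p)), rownames(sigs))
}

# records with explicit trinucleotide context, pyrimidine representation
records_from_classes <- function(classes, chrom = "chr1",
                                 pos = seq_along(classes) * 1000L,
                                 sample = "s1", ...) {
  mutation_records(
    chrom = chrom, pos = pos,
    ref = substr(classes, 3, 3), alt = substr(classes, 5, 5),
    sample = sample,
    context5 = substr(classes, 1, 1), context3 = substr(classes, 7, 7),
    ...)
}
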