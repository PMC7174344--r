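#' @useDynLib chronomm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(ch) {
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

#' Enumerate the pyrimidine-centred substitution classes
#'
#' Returns the fixed, documented ordering of single-base-substitution
#' classes: the six pyrimidine substitution types (C>A, C>G, C>T, T>A,
#' T>C, T>G) in that order, and within each type the flanking contexts in
#' alphabetical order (5' flank varying slowest). This matches the row
#' order of COSMIC v3 reference signature files, so published signature
#' TSVs align without reordering.
#'
#' @param resolution 96 (one flanking base each side, trinucleotide
#'   context) or 1536 (two bases each side, pentanucleotide context).
#' @return Character vector of class labels such as `"A[C>A]A"` (96) or
#'   `"AA[C>A]AA"` (1536).
#' @export
#' @examples
#' head(sbs_classes(96))
#' length(sbs_classes(1536))
sbs_classes <- function(resolution = 96) {
  resolution <- match_resolution(resolution)
  k <- if (resolution == 96L) 1L else 2L
  flanks <- BASES
  if (k == 2L) {
    flanks <- as.vector(t(outer(BASES, BASES, paste0)))
  }
  unlist(lapply(SUBSTITUTIONS, function(sub) {
    as.vector(t(outer(flanks, flanks,
                      function(l, r) paste0(l, "[", sub, "]", r))))
  }), use.names = FALSE)
}

match_resolution <- function(resolution) {
  resolution <- as.integer(resolution)
  if (!resolution %in% c(96L, 1536L)) {
    stop("resolution must be 96 or 1536, got ", resolution)
  }
  resolution
}

#' Cosine similarity between two non-negative vectors
#'
#' @param u,v Numeric non-negative vectors of equal length; neither may be
#'   all zero.
#' @return A number in \[0, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have the same length")
  if (any(u < 0) || any(v < 0)) stop("u and v must be non-negative")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  min(1, sum(u * v) / (nu * nv))
}

#' Construct a table of somatic single-nucleotide variants
#'
#' Builds the canonical mutation-record data.frame used throughout the
#' package and enforces its invariants. Missing optional columns are
#' filled with defaults (`patient` = `sample`, read counts `NA`,
#' `tx_strand` `NA`, `clonality` `"unknown"`).
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Single reference/alternate bases (A/C/G/T, ref != alt).
#' @param sample Sample identifiers.
#' @param patient Patient identifiers (default: `sample`).
#' @param alt_reads,total_reads Read counts (`NA` allowed).
#' @param context5,context3 Up to two flanking reference bases on each
#'   side of the mutated base, reference-strand orientation.
#' @param tx_strand One of `"transcribed"`, `"untranscribed"`,
#'   `"intergenic"`, `"ambiguous"`, or `NA`.
#' @param clonality One of `"clonal"`, `"subclonal"`, `"unknown"`.
#' @return A `data.frame` with one row per SNV.
#' @export
mutation_records <- function(chrom, pos, ref, alt, sample,
                             patient = sample,
                             alt_reads = NA_integer_,
                             total_reads = NA_integer_,
                             context5 = NA_character_,
                             context3 = NA_character_,
                             tx_strand = NA_character_,
                             clonality = "unknown") {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    sample = as.character(sample), patient = as.character(patient),
    alt_reads = as.integer(rep_len(alt_reads, n)),
    total_reads = as.integer(rep_len(total_reads, n)),
    context5 = toupper(as.character(rep_len(context5, n))),
    context3 = toupper(as.character(rep_len(context3, n))),
    tx_strand = as.character(rep_len(tx_strand, n)),
    clonality = as.character(rep_len(clonality, n)),
    stringsAsFactors = FALSE
  )
  validate_mutation_records(df)
}

validate_mutation_records <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "pos", "ref", "alt", "sample")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("missing mutation columns: ",
                            paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(df)
  if (any(df$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (!all(df$ref %in% BASES) || !all(df$alt %in% BASES)) {
    stop("ref and alt must be single bases A/C/G/T")
  }
  if (any(df$ref == df$alt)) stop("ref must differ from alt")
  has_counts <- !is.na(df$alt_reads) & !is.na(df$total_reads)
  if (any(has_counts & (df$alt_reads > df$total_reads | df$alt_reads < 0))) {
    stop("alt_reads must satisfy 0 <= alt_reads <= total_reads")
  }
  df
}

# Normalize one record batch to the pyrimidine strand; returns the class
# label per record, or NA where the context is unusable (contains N).
classify_records <- function(records, resolution = 96) {
  resolution <- match_resolution(resolution)
  k <- if (resolution == 96L) 1L else 2L
  ref <- records$ref; alt <- records$alt
  c5 <- records$context5; c3 <- records$context3
  if (any(is.na(c5) | is.na(c3))) {
    i <- which(is.na(c5) | is.na(c3))[1]
    stop(sprintf("record %s:%d %s>%s lacks flanking context",
                 records$chrom[i], records$pos[i], ref[i], alt[i]))
  }
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    nref <- ref; nalt <- alt
    nref[pur] <- unname(COMPLEMENT[ref[pur]])
    nalt[pur] <- unname(COMPLEMENT[alt[pur]])
    t5 <- c5; t3 <- c3
    c5[pur] <- revcomp(t3[pur])
    c3[pur] <- revcomp(t5[pur])
    ref <- nref; alt <- nalt
  }
  l5 <- nchar(c5); l3 <- nchar(c3)
  if (any(l5 < k | l3 < k)) {
    i <- which(l5 < k | l3 < k)[1]
    stop(sprintf("record %s:%d needs %d flanking base(s) each side for resolution %d",
                 records$chrom[i], records$pos[i], k, resolution))
  }
  # innermost k bases on each side
  f5 <- substr(c5, l5 - k + 1L, l5)
  f3 <- substr(c3, 1L, k)
  lab <- paste0(f5, "[", ref, ">", alt, "]", f3)
  lab[grepl("N", paste0(f5, f3), fixed = TRUE)] <- NA_character_
  lab
}

#' Build a substitution-class mutation catalog
#'
#' Counts mutations over the 96 trinucleotide-context classes (or 1536
#' pentanucleotide classes) after pyrimidine-strand normalization:
#' purine-reference mutations are reverse-complemented together with
#' their flanking context. Records whose context contains `N` are
#' excluded and counted in the `n_excluded` attribute.
#'
#' @param records Mutation records (see [mutation_records()]) carrying
#'   `context5`/`context3`.
#' @param resolution 96 or 1536.
#' @param sample Optional sample id stored on the catalog; defaults to
#'   the single sample present (or `"pooled"`).
#' @return Integer vector of class `"mutation_catalog"`, named by
#'   [sbs_classes()], with attributes `resolution`, `sample`,
#'   `n_excluded`.
#' @export
build_catalog <- function(records, resolution = 96, sample = NULL) {
  resolution <- match_resolution(resolution)
  classes <- sbs_classes(resolution)
  if (is.null(sample)) {
    s <- unique(records$sample)
    sample <- if (length(s) == 1) s else "pooled"
  }
  counts <- integer(length(classes))
  names(counts) <- classes
  n_excluded <- 0L
  if (nrow(records) > 0) {
    lab <- classify_records(records, resolution)
    n_excluded <- sum(is.na(lab))
    tab <- table(factor(lab[!is.na(lab)], levels = classes))
    counts <- as.integer(tab)
    names(counts) <- classes
  }
  structure(counts, class = "mutation_catalog",
            resolution = resolution, sample = sample,
            n_excluded = n_excluded)
}

#' Collapse a 1536-class catalog to the 96-class catalog
#'
#' Sums counts over the outer flanking bases, keeping the inner
#' trinucleotide context.
#'
#' @param catalog A 1536-class catalog from [build_catalog()].
#' @return A 96-class `"mutation_catalog"`.
#' @export
collapse_catalog <- function(catalog) {
  if (attr(catalog, "resolution") != 1536L) {
    stop("collapse_catalog expects a 1536-class catalog")
  }
  lab <- names(catalog)
  # "AA[C>A]AA": inner flank chars 2 and 8 around the bracketed type
  inner <- paste0(substr(lab, 2, 2), substr(lab, 3, 7), substr(lab, 8, 8))
  classes96 <- sbs_classes(96)
  out <- vapply(split(as.integer(catalog), factor(inner, levels = classes96)),
                sum, integer(1))
  structure(out, class = "mutation_catalog",
            resolution = 96L, sample = attr(catalog, "sample"),
            n_excluded = attr(catalog, "n_excluded"))
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("<mutation_catalog> sample=%s resolution=%d total=%d excluded=%d\n",
              attr(x, "sample"), attr(x, "resolution"), sum(x),
              attr(x, "n_excluded")))
  invisible(x)
}
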