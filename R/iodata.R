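#' Read somatic SNVs from VCF or tab-separated text
#'
#' Accepts either a VCF 4.x file (parsed with \pkg{VariantAnnotation};
#' multi-allelic records are expanded, non-SNV rows skipped and counted)
#' or a TSV with header columns `chrom, pos, ref, alt, sample`
#' (optionally `patient, alt_reads, total_reads, context5, context3,
#' clonality`). Positions are 1-based in both dialects.
#'
#' For VCF input, read counts are taken from the `AD` genotype field
#' (ref,alt depths; `total_reads` is their sum); when absent the counts
#' are `NA` and a warning is emitted. The sample column is the VCF
#' genotype sample name (or `sample_map$sample` for site-only VCFs).
#'
#' @param path Path to a `.vcf` or tabular file.
#' @param sample_map Optional one-row data.frame (or named list) with
#'   `sample` and `patient` used to fill identifiers not present in the
#'   file.
#' @return Mutation records (see [mutation_records()]) with an attribute
#'   `n_skipped`: number of non-SNV rows excluded.
#' @export
read_mutations <- function(path, sample_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_mutations_vcf(path, sample_map)
  } else {
    read_mutations_tsv(path, sample_map)
  }
}

read_mutations_tsv <- function(path, sample_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("TSV must have header columns chrom, pos, ref, alt")
  }
  if (!"sample" %in% names(df)) {
    df$sample <- if (!is.null(sample_map)) sample_map$sample else "sample1"
  }
  is_snv <- df$ref %in% BASES & df$alt %in% BASES
  n_skipped <- sum(!is_snv)
  df <- df[is_snv, , drop = FALSE]
  out <- mutation_records(
    chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
    sample = df$sample,
    patient = if ("patient" %in% names(df)) df$patient
              else if (!is.null(sample_map) && !is.null(sample_map$patient))
                sample_map$patient else df$sample,
    alt_reads = if ("alt_reads" %in% names(df)) df$alt_reads else NA_integer_,
    total_reads = if ("total_reads" %in% names(df)) df$total_reads else NA_integer_,
    context5 = if ("context5" %in% names(df)) df$context5 else NA_character_,
    context3 = if ("context3" %in% names(df)) df$context3 else NA_character_,
    clonality = if ("clonality" %in% names(df)) df$clonality else "unknown"
  )
  if (!"alt_reads" %in% names(df)) {
    warning("no read-count columns in ", basename(path),
            "; alt_reads/total_reads set to NA")
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

read_mutations_vcf <- function(path, sample_map = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) == 0) {
    out <- mutation_records(character(0), integer(0), character(0),
                            character(0), character(0))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% BASES & alt %in% BASES
  n_skipped <- sum(!is_snv)

  geno <- VariantAnnotation::geno(vcf)
  vcf_samples <- colnames(vcf)
  sample_id <- if (length(vcf_samples) >= 1) vcf_samples[1]
               else if (!is.null(sample_map)) sample_map$sample else "sample1"
  alt_reads <- rep(NA_integer_, length(ref))
  total_reads <- rep(NA_integer_, length(ref))
  if ("AD" %in% names(geno) && length(vcf_samples) >= 1 &&
      length(ref) > 0) {
    ad <- geno$AD
    if (is.array(ad) && length(dim(ad)) == 3) {
      # expand() reshapes Number=R fields to variants x samples x 2
      refd <- as.integer(ad[, 1, 1])
      alt_reads <- as.integer(ad[, 1, 2])
    } else {
      adl <- ad[, 1]
      get_i <- function(v, i) {
        if (length(v) >= i && !is.na(v[i])) as.integer(v[i]) else NA_integer_
      }
      refd <- vapply(adl, get_i, integer(1), i = 1L)
      alt_reads <- vapply(adl, get_i, integer(1), i = 2L)
    }
    total_reads <- refd + alt_reads
  } else {
    warning("VCF has no AD genotype field; read counts set to NA")
  }

  keep <- which(is_snv)
  out <- mutation_records(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep], alt = alt[keep],
    sample = sample_id,
    patient = if (!is.null(sample_map) && !is.null(sample_map$patient))
      sample_map$patient else sample_id,
    alt_reads = alt_reads[keep], total_reads = total_reads[keep]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write mutation records as a minimal VCF 4.2 file
#'
#' Emits one genotype column carrying the `AD` (ref,alt) depths so that
#' [read_mutations()] round-trips the records.
#'
#' @param records Mutation records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations_vcf <- function(records, path) {
  sample_id <- if (nrow(records)) records$sample[1] else "sample1"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  ord <- order(records$chrom, records$pos)
  r <- records[ord, , drop = FALSE]
  ad <- ifelse(is.na(r$alt_reads), ".,.",
               paste0(r$total_reads - r$alt_reads, ",", r$alt_reads))
  body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
                "GT:AD", paste0("0/1:", ad), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write mutation records as TSV
#' @param records Mutation records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Annotate transcriptional strand relative to the pyrimidine strand
#'
#' For each mutation, after pyrimidine-strand normalization: if the
#' position falls inside a gene whose annotated strand carries the
#' pyrimidine, the mutation is on the *untranscribed* (coding) strand; if
#' the gene is on the opposite strand it is *transcribed*; positions
#' outside all genes are *intergenic*; positions covered by genes on both
#' strands are *ambiguous* (and excluded from strand-bias testing).
#'
#' @param records Mutation records.
#' @param gene_intervals data.frame with `chrom, start, end, strand`
#'   (`+`/`-`), or a path to a BED (0-based half-open) or GFF3 (1-based
#'   closed) file; the dialect is chosen from the file extension.
#' @return `records` with `tx_strand` filled in.
#' @export
annotate_strand <- function(records, gene_intervals) {
  genes <- read_intervals(gene_intervals)
  if (nrow(records) == 0) return(records)
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end),
                              strand = genes$strand)
  m <- GenomicRanges::GRanges(records$chrom,
                              IRanges::IRanges(records$pos, records$pos))
  hits <- GenomicRanges::findOverlaps(m, g, ignore.strand = TRUE)
  strand_by_mut <- split(as.character(GenomicRanges::strand(g))[S4Vectors::subjectHits(hits)],
                         S4Vectors::queryHits(hits))
  # strand on which the pyrimidine of the normalized class sits
  pyr_strand <- ifelse(records$ref %in% c("C", "T"), "+", "-")
  tx <- rep("intergenic", nrow(records))
  for (q in names(strand_by_mut)) {
    i <- as.integer(q)
    s <- unique(strand_by_mut[[q]])
    if (length(s) > 1) {
      tx[i] <- "ambiguous"
    } else {
      tx[i] <- if (s == pyr_strand[i]) "untranscribed" else "transcribed"
    }
  }
  records$tx_strand <- tx
  records
}

read_intervals <- function(x) {
  if (is.data.frame(x)) {
    need <- c("chrom", "start", "end", "strand")
    if (!all(need %in% names(x))) {
      stop("interval data.frame needs columns: ", paste(need, collapse = ", "))
    }
    return(x)
  }
  if (!file.exists(x)) stop("interval file not found: ", x)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading BED/GFF intervals requires the rtracklayer package")
  }
  gr <- tryCatch(rtracklayer::import(x),
                 error = function(e) stop("cannot parse intervals in ", x,
                                          ": ", conditionMessage(e)))
  s <- as.character(GenomicRanges::strand(gr))
  bad <- which(!s %in% c("+", "-"))
  if (length(bad)) {
    stop("interval without +/- strand at row ", bad[1], " of ", x)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = s, stringsAsFactors = FALSE)
}

#' APOBEC3A/3B tetranucleotide ratio (YTCA vs RTCA)
#'
#' APOBEC mutations arise at TpC dinucleotides; the identity of the base
#' two positions 5' of the mutated cytosine separates the two dominant
#' deaminase isoforms: a pyrimidine (Y = C/T, giving YTCA) is the
#' APOBEC3A-like context, a purine (R = A/G, RTCA) the APOBEC3B-like
#' context. Qualifying mutations are, after pyrimidine normalization,
#' C>T or C>G (configurable) with T at the -1 position and two bases of
#' 5' context available.
#'
#' @param records Mutation records with 2 bases of 5' context.
#' @param substitutions Substitution types that qualify (default C>T and
#'   C>G; the inclusion rule is configurable because different cohorts
#'   restrict to C>T only).
#' @return List of class `"apobec3_ratio"`: `n_ytca`, `n_rtca`, `ratio`
#'   (`NA` and flagged `undefined` when `n_rtca` is 0), `n_qualifying`.
#' @export
apobec_tetranucleotide <- function(records, substitutions = c("C>T", "C>G")) {
  if (nrow(records) == 0) {
    return(structure(list(n_ytca = 0L, n_rtca = 0L, ratio = NA_real_,
                          undefined = TRUE, n_qualifying = 0L),
                     class = "apobec3_ratio"))
  }
  ref <- records$ref; alt <- records$alt
  c5 <- records$context5; c3 <- records$context3
  pur <- ref %in% c("A", "G")
  nref <- ref; nalt <- alt
  nref[pur] <- unname(COMPLEMENT[ref[pur]])
  nalt[pur] <- unname(COMPLEMENT[alt[pur]])
  t5 <- c5
  c5[pur] <- revcomp(c3[pur])
  c3[pur] <- revcomp(t5[pur])
  sub <- paste0(nref, ">", nalt)
  ok <- sub %in% substitutions & !is.na(c5) & nchar(c5) >= 2
  minus1 <- substr(c5[ok], nchar(c5[ok]), nchar(c5[ok]))
  minus2 <- substr(c5[ok], nchar(c5[ok]) - 1L, nchar(c5[ok]) - 1L)
  tpc <- minus1 == "T" & minus2 %in% BASES
  n_ytca <- sum(tpc & minus2 %in% c("C", "T"))
  n_rtca <- sum(tpc & minus2 %in% c("A", "G"))
  structure(list(n_ytca = as.integer(n_ytca), n_rtca = as.integer(n_rtca),
                 ratio = if (n_rtca > 0) n_ytca / n_rtca else NA_real_,
                 undefined = n_rtca == 0,
                 n_qualifying = as.integer(n_ytca + n_rtca)),
            class = "apobec3_ratio")
}

#' @export
print.apobec3_ratio <- function(x, ...) {
  cat(sprintf("<apobec3_ratio> YTCA=%d RTCA=%d ratio=%s\n", x$n_ytca,
              x$n_rtca, if (x$undefined) "undefined" else
                format(x$ratio, digits = 4)))
  invisible(x)
}

#' Fill flanking context from a reference FASTA
#'
#' Looks up `k` reference bases on each side of every mutation. Requires
#' the \pkg{Rsamtools}/\pkg{Biostrings} stack; pre-annotated
#' `context5`/`context3` columns are the alternative when no FASTA is
#' available.
#'
#' @param records Mutation records.
#' @param fasta Path to an (indexed) FASTA file.
#' @param k Flanking bases per side (1 for 96 classes, 2 for 1536).
#' @return `records` with `context5`/`context3` replaced.
#' @export
add_context_from_fasta <- function(records, fasta, k = 2) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("FASTA context lookup requires the Rsamtools package")
  }
  fa <- Rsamtools::FaFile(fasta)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  gr5 <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(pmax(1L, records$pos - k),
                                                 records$pos - 1L))
  gr3 <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$pos + 1L,
                                                 records$pos + k))
  records$context5 <- as.character(Rsamtools::scanFa(fa, gr5))
  records$context3 <- as.character(Rsamtools::scanFa(fa, gr3))
  records
}
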