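#' Validate a reference signature matrix
#'
#' @param probs Numeric matrix, classes x signatures; every column must
#'   be non-negative and sum to 1 (tolerance 1e-8). Row names are class
#'   labels, column names signature names.
#' @return The matrix, with columns renormalized exactly to 1.
#' @export
signature_matrix <- function(probs) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) stop("signature matrix needs column names")
  if (any(probs < 0)) stop("signature probabilities must be non-negative")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-8)) {
    stop("signature columns must sum to 1 (worst deviation ",
         format(max(abs(cs - 1))), ")")
  }
  sweep(probs, 2, cs, "/")
}

#' Read a COSMIC-style signature reference TSV
#'
#' First column holds class labels (e.g. `"A[C>A]A"`), one column per
#' signature. Rows are reordered to the canonical [sbs_classes()] order.
#'
#' @param path TSV path.
#' @return A validated signature matrix.
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labs
  classes <- sbs_classes(if (nrow(m) == 1536) 1536 else 96)
  if (!setequal(labs, classes)) {
    stop("signature TSV classes do not match the ", length(classes),
         "-class canon")
  }
  signature_matrix(m[classes, , drop = FALSE])
}

nnls_fit <- function(A, b) {
  res <- .nnls_cpp(A, as.numeric(b))
  x <- as.numeric(res$x)
  names(x) <- colnames(A)
  x
}

#' Non-negative least-squares signature exposures
#'
#' Fits the catalog as a non-negative linear combination of signature
#' columns (on raw counts), then rescales the solution so that exposures
#' sum to the catalog total, keeping them in mutation units.
#'
#' @param catalog A [build_catalog()] result (or named count vector
#'   aligned with the signature rows).
#' @param sigs Signature matrix (classes x signatures).
#' @return Named non-negative exposure vector summing to the catalog
#'   total.
#' @export
fit_exposures <- function(catalog, sigs) {
  sigs <- signature_matrix(sigs)
  y <- as.numeric(catalog)
  if (length(y) != nrow(sigs)) {
    stop("catalog length ", length(y), " does not match signature rows ",
         nrow(sigs))
  }
  total <- sum(y)
  if (total <= 0) stop("catalog is all zero")
  x <- nnls_fit(sigs, y)
  s <- sum(x)
  if (s > 0) x <- x * (total / s)
  x
}

#' Sequentially censored signature fitting
#'
#' Refits the catalog repeatedly, each round proposing to drop the least
#' contributing non-protected signature (by current exposure fraction;
#' ties drop the alphabetically last name). The drop is accepted -- the
#' signature is censored permanently -- when it lowers the cosine
#' similarity between the observed catalog and its reconstruction by
#' less than `threshold` relative to the current fit; otherwise the
#' signature is restored and censoring stops. The clock-like signatures
#' (by default SBS1 and SBS5) are never candidates for removal.
#'
#' @param catalog Mutation catalog.
#' @param sigs Signature matrix.
#' @param threshold Maximum tolerated cosine-similarity drop per removal
#'   (default 0.01).
#' @param always_keep Protected signature names (default SBS1, SBS5;
#'   names absent from `sigs` are ignored).
#' @param reevaluate If `TRUE` (default) contributions are re-ranked
#'   after every accepted removal; `FALSE` censors in the order of the
#'   initial ranking.
#' @return A `"fit_result"`: `exposures` (named over all input
#'   signatures, censored at 0), `fractions`, `retained`, `censored`,
#'   `reconstruction`, `cosine`, `low_confidence` (catalog total < 50).
#' @export
censored_fit <- function(catalog, sigs, threshold = 0.01,
                         always_keep = c("SBS1", "SBS5"),
                         reevaluate = TRUE) {
  if (threshold <= 0) stop("threshold must be > 0")
  sigs <- signature_matrix(sigs)
  y <- as.numeric(catalog)
  total <- sum(y)
  low_conf <- total < 50
  if (low_conf) {
    warning("catalog has ", total, " mutations (< 50); fit is low-confidence")
  }
  if (total <= 0) stop("catalog is all zero")
  protected <- intersect(always_keep, colnames(sigs))

  # lean refit used inside the censoring loop (inputs already validated)
  refit <- function(cols) {
    A <- sigs[, cols, drop = FALSE]
    x <- nnls_fit(A, y)
    s <- sum(x)
    if (s > 0) x <- x * (total / s)
    recon <- as.numeric(A %*% x)
    list(x = x, cosine = cosine_similarity(y, recon))
  }

  current <- colnames(sigs)
  cur <- refit(current)
  x <- cur$x
  cos_cur <- cur$cosine
  censored <- character(0)

  # ascending exposure; ties put the alphabetically last name first
  initial_order <- names(x)[order(x, -xtfrm(names(x)))]
  repeat {
    candidates <- setdiff(current, protected)
    if (length(candidates) == 0) break
    drop_name <- if (reevaluate) {
      pick_least(x[candidates])
    } else {
      remaining <- initial_order[initial_order %in% candidates]
      if (!length(remaining)) break
      remaining[1]
    }
    trial <- setdiff(current, drop_name)
    tr <- refit(trial)
    if (cos_cur - tr$cosine < threshold) {
      censored <- c(censored, drop_name)
      current <- trial
      x <- tr$x
      cos_cur <- tr$cosine
    } else {
      break
    }
  }

  exposures <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
  exposures[current] <- x
  recon <- as.numeric(sigs[, current, drop = FALSE] %*% x)
  structure(list(
    exposures = exposures,
    fractions = exposures / sum(exposures),
    retained = current,
    censored = censored,
    reconstruction = recon,
    cosine = cosine_similarity(y, recon),
    threshold = threshold,
    low_confidence = low_conf,
    total = total
  ), class = "fit_result")
}

pick_least <- function(x) {
  m <- min(x)
  tied <- names(x)[x == m]
  sort(tied)[length(tied)]
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> total=%g cosine=%.4f retained=%s censored=%s%s\n",
              x$total, x$cosine, paste(x$retained, collapse = ","),
              paste(x$censored, collapse = ","),
              if (x$low_confidence) " [low-confidence]" else ""))
  invisible(x)
}

#' Multinomial bootstrap confidence intervals for exposures
#'
#' Each bootstrap draw resamples the catalog as
#' Multinomial(total, empirical class fractions), reruns [censored_fit()]
#' (signatures censored in a draw contribute 0), and the 2.5th/97.5th
#' percentiles across draws give the interval per signature.
#'
#' @param catalog Mutation catalog.
#' @param sigs Signature matrix.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Integer seed; the draw stream is local to this call.
#' @param ... Passed to [censored_fit()].
#' @return data.frame (class `"exposure_ci"`) with columns `signature`,
#'   `point`, `lo`, `hi`; attribute `n_boot`.
#' @export
bootstrap_exposures <- function(catalog, sigs, n_boot = 1000, seed = 42, ...) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  sigs <- signature_matrix(sigs)
  y <- as.numeric(catalog)
  total <- sum(y)
  point <- suppressWarnings(censored_fit(y, sigs, ...))$exposures
  draws <- with_local_seed(seed, {
    p <- y / total
    vapply(seq_len(n_boot), function(i) {
      yb <- as.numeric(stats::rmultinom(1, total, p))
      suppressWarnings(censored_fit(yb, sigs, ...))$exposures
    }, numeric(ncol(sigs)))
  })
  qs <- apply(draws, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(signature = colnames(sigs), point = unname(point),
                    lo = qs[1, ], hi = qs[2, ], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("exposure_ci", "data.frame"), n_boot = n_boot,
            seed = seed)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Transcriptional strand-bias test
#'
#' Exact conditional test of transcribed vs untranscribed mutation
#' counts against a 1:1 rate ratio (the two-rate Poisson test, which
#' conditions on the total and reduces to a binomial test), with
#' Benjamini-Hochberg adjustment across groups. Ambiguous-strand and
#' intergenic mutations must already be excluded from the counts.
#'
#' @param counts data.frame with columns `group`, `n_transcribed`,
#'   `n_untranscribed`.
#' @return data.frame (class `"strand_bias"`) adding `rate_ratio`
#'   (transcribed / untranscribed; 0 or `Inf` at boundaries, flagged),
#'   `p_value`, `q_value`, `boundary`.
#' @export
strand_bias_test <- function(counts) {
  stopifnot(all(c("group", "n_transcribed", "n_untranscribed") %in%
                  names(counts)))
  empty <- counts$n_transcribed + counts$n_untranscribed == 0
  if (any(empty)) {
    warning(sum(empty), " group(s) with no stranded mutations skipped")
    counts <- counts[!empty, , drop = FALSE]
  }
  p <- mapply(function(a, b) {
    stats::poisson.test(c(a, b), r = 1)$p.value
  }, counts$n_transcribed, counts$n_untranscribed)
  rr <- ifelse(counts$n_untranscribed > 0,
               counts$n_transcribed / counts$n_untranscribed,
               Inf)
  rr[counts$n_transcribed == 0 & counts$n_untranscribed > 0] <- 0
  out <- data.frame(counts, rate_ratio = rr, p_value = p,
                    q_value = stats::p.adjust(p, "BH"),
                    boundary = counts$n_transcribed == 0 |
                      counts$n_untranscribed == 0,
                    stringsAsFactors = FALSE)
  structure(out, class = c("strand_bias", "data.frame"))
}

#' Assign an extracted signature to the reference catalog
#'
#' Computes the cosine similarity of an extracted (de novo) signature
#' profile against every reference signature and against the best
#' non-negative linear combination of every reference pair. The profile
#' is called a known single signature when its best single cosine
#' reaches `single_min` (or comes within `pair_margin` of the best
#' pair), a two-signature composite when only the pair reaches
#' `single_min`, and novel otherwise.
#'
#' @param extracted Numeric profile over the reference classes.
#' @param reference Signature matrix.
#' @param single_min Acceptance cosine (default 0.9).
#' @param pair_margin Margin within which the simpler single-signature
#'   call is preferred over a pair (default 0.01).
#' @return List of class `"sig_assignment"`: `single` (name, cosine),
#'   `pair` (names, weights summing to 1, cosine), `chosen`.
#' @export
assign_to_reference <- function(extracted, reference, single_min = 0.9,
                                pair_margin = 0.01) {
  reference <- signature_matrix(reference)
  v <- as.numeric(extracted)
  if (length(v) != nrow(reference)) stop("resolution mismatch")
  singles <- apply(reference, 2, cosine_similarity, u = v)
  best_single <- names(which.max(singles))
  best_single_cos <- max(singles)

  nm <- colnames(reference)
  best_pair <- NULL; best_pair_cos <- -1; best_w <- c(NA, NA)
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in seq((i + 1), length(nm))) {
        A <- reference[, c(i, j), drop = FALSE]
        w <- nnls_fit(A, v)
        fit <- as.numeric(A %*% w)
        if (sum(fit) == 0) next
        cc <- cosine_similarity(v, fit)
        if (cc > best_pair_cos) {
          best_pair_cos <- cc
          best_pair <- nm[c(i, j)]
          best_w <- if (sum(w) > 0) w / sum(w) else w
        }
      }
    }
  }
  chosen <- if (best_single_cos >= single_min) "single"
  else if (best_pair_cos >= single_min) {
    if (best_single_cos >= best_pair_cos - pair_margin) "single" else "pair"
  } else "novel"
  structure(list(
    single = list(name = best_single, cosine = best_single_cos),
    pair = list(names = best_pair, weights = unname(best_w),
                cosine = best_pair_cos),
    chosen = chosen
  ), class = "sig_assignment")
}

#' Per-bin signature fitting along the genome
#'
#' Pools the supplied records, divides each chromosome into fixed-width
#' bins (default 1 Mb) and runs [censored_fit()] on the catalog of every
#' bin. Bins with fewer than `min_count` mutations report zero exposures
#' and are flagged out of any correlation. When a numeric feature track
#' (one value per bin, same binning) is supplied, the Pearson
#' correlation of each signature's per-bin exposure with the track is
#' computed over the flagged-in bins.
#'
#' @param records Mutation records with context.
#' @param sigs Signature matrix.
#' @param bin_size Bin width in bp (default 1e6).
#' @param min_count Minimum mutations for a bin to be fit (default 50).
#' @param feature Optional numeric vector, one value per emitted bin (in
#'   the row order of the result).
#' @param ... Passed to [censored_fit()].
#' @return data.frame with `chrom`, `bin_start`, `bin_end`, `n`,
#'   `fitted`, one exposure column per signature; attribute
#'   `feature_cor` (named Pearson r) when `feature` given.
#' @export
binned_fit <- function(records, sigs, bin_size = 1e6, min_count = 50,
                       feature = NULL, ...) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  sigs <- signature_matrix(sigs)
  bin <- floor((records$pos - 1) / bin_size)
  key <- paste(records$chrom, bin, sep = ":")
  groups <- split(seq_len(nrow(records)), key)
  ord <- order(vapply(strsplit(names(groups), ":"), `[`, character(1), 1),
               as.numeric(vapply(strsplit(names(groups), ":"), `[`,
                                 character(1), 2)))
  groups <- groups[ord]
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    parts <- strsplit(g, ":")[[1]]
    b <- as.numeric(parts[2])
    n <- length(idx)
    expo <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
    fitted <- n >= min_count
    if (fitted) {
      cat_bin <- build_catalog(records[idx, , drop = FALSE],
                               resolution = nrow(sigs))
      expo <- suppressWarnings(censored_fit(cat_bin, sigs, ...))$exposures
    }
    c(list(chrom = parts[1], bin_start = b * bin_size + 1,
           bin_end = (b + 1) * bin_size, n = n, fitted = fitted),
      as.list(expo))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                               check.names = FALSE)))
  if (!is.null(feature)) {
    if (length(feature) != nrow(out)) {
      stop("feature track must have one value per bin (", nrow(out), ")")
    }
    keep <- out$fitted
    cors <- vapply(colnames(sigs), function(s) {
      if (sum(keep) < 3) return(NA_real_)
      stats::cor(out[[s]][keep], feature[keep])
    }, numeric(1))
    attr(out, "feature_cor") <- cors
  }
  out
}
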