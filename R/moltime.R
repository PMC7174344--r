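MOLTIME_FLOOR <- 50L  # minimum clonal mutations per timed gain

# supported copy-number scenarios: allele counts, total CN, and the
# mutation multiplicities each can produce
CN_SCENARIOS <- list(
  gain_2_1      = list(major = 2L, minor = 1L, cnt = 3L, mults = c(1L, 2L)),
  cnloh_2_0     = list(major = 2L, minor = 0L, cnt = 2L, mults = c(1L, 2L)),
  tetra_2_2_sync = list(major = 2L, minor = 2L, cnt = 4L, mults = c(1L, 2L)),
  tetra_3_1_seq = list(major = 3L, minor = 1L, cnt = 4L, mults = c(1L, 2L, 3L)),
  tetra_4_0_seq = list(major = 4L, minor = 0L, cnt = 4L, mults = c(1L, 2L, 4L))
)

get_scenario <- function(scenario) {
  if (!scenario %in% names(CN_SCENARIOS)) {
    stop("unknown copy-number scenario: ", scenario, " (supported: ",
         paste(names(CN_SCENARIOS), collapse = ", "), ")")
  }
  CN_SCENARIOS[[scenario]]
}

#' Expected purity-corrected variant allele fraction
#'
#' For a clonal mutation present on `m` of the `total_cn` tumour copies
#' in a sample of purity `purity`, the expected VAF is
#' `m * purity / (purity * total_cn + 2 * (1 - purity))` (the denominator
#' counts tumour copies plus the two normal-cell copies). At purity 1 in
#' a trisomic region this gives 2/3 (about 66\%) for a mutation acquired
#' before the gain (m = 2) and 1/3 (33\%) for a single-copy mutation.
#'
#' @param m Mutation multiplicity (copies carrying the mutation).
#' @param purity Tumour purity in (0, 1].
#' @param total_cn Total copy number of the segment.
#' @return Expected VAF in (0, 1].
#' @export
#' @examples
#' expected_vaf(2, 1, 3)  # 0.667: pre-gain mutation in a trisomy
#' expected_vaf(1, 1, 3)  # 0.333
expected_vaf <- function(m, purity, total_cn) {
  if (any(m < 1) || any(m > total_cn)) {
    stop("multiplicity must satisfy 1 <= m <= total_cn")
  }
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  m * purity / (purity * total_cn + 2 * (1 - purity))
}

#' Assign clonal mutations in a gained segment to allelic multiplicities
#'
#' Fits a mixture over the multiplicities the copy-number scenario
#' supports and labels each mutation with its maximum-responsibility
#' component. The default mixture is binomial with component success
#' probabilities fixed at [expected_vaf()] for each multiplicity (only
#' the mixing weights are free, estimated by EM); `method = "gaussian"`
#' frees the component means as well (initialised at the expected VAFs),
#' as a fallback for miscalibrated purity.
#'
#' Estimation is refused (counts still returned) below the 50-mutation
#' floor used for timing chromosomal gains.
#'
#' @param records Clonal mutation records inside the segment, with
#'   `alt_reads`/`total_reads`.
#' @param purity Tumour purity.
#' @param scenario One of `gain_2_1`, `cnloh_2_0`, `tetra_2_2_sync`,
#'   `tetra_3_1_seq`, `tetra_4_0_seq`.
#' @param method `"binomial"` (fixed means) or `"gaussian"`.
#' @param max_iter,tol EM controls.
#' @return List of class `"multiplicity_counts"`: `counts` (named by
#'   multiplicity), `labels` (per mutation), `weights`, `scenario`,
#'   `n`, `estimable` (`FALSE` below the floor).
#' @export
assign_multiplicity <- function(records, purity, scenario,
                                method = c("binomial", "gaussian"),
                                max_iter = 200, tol = 1e-8) {
  method <- match.arg(method)
  if (missing(purity) || is.null(purity) || is.na(purity)) {
    stop("purity is required to compute expected VAFs")
  }
  sc <- get_scenario(scenario)
  alt <- records$alt_reads; tot <- records$total_reads
  if (any(is.na(alt) | is.na(tot))) stop("records need read counts")
  n <- length(alt)
  mults <- sc$mults
  p_m <- expected_vaf(mults, purity, sc$cnt)
  k <- length(mults)

  w <- rep(1 / k, k)
  mu <- p_m
  loglik_old <- -Inf
  resp <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      resp[, j] <- w[j] * stats::dbinom(alt, tot, mu[j])
    }
    rs <- rowSums(resp)
    rs[rs == 0] <- .Machine$double.xmin
    loglik <- sum(log(rs))
    resp <- resp / rs
    w <- colMeans(resp)
    if (method == "gaussian") {
      # free means via weighted VAF (quasi-binomial update)
      vaf <- alt / pmax(tot, 1)
      mu <- colSums(resp * vaf) / pmax(colSums(resp), 1e-12)
      mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    }
    if (abs(loglik - loglik_old) < tol * (1 + abs(loglik))) break
    loglik_old <- loglik
  }
  labels <- mults[max.col(resp, ties.method = "first")]
  counts <- stats::setNames(
    vapply(mults, function(m) sum(labels == m), integer(1)),
    paste0("n", mults))
  structure(list(counts = counts, labels = labels, weights = w,
                 means = mu, scenario = scenario, n = n,
                 estimable = n >= MOLTIME_FLOOR),
            class = "multiplicity_counts")
}

#' Molecular time of a chromosomal gain
#'
#' Converts multiplicity counts into the relative time pi of the gain
#' within the clonal lineage's mutational history, assuming mutations
#' accrue on each chromosomal copy at a constant per-copy rate. The
#' corrected ratio of duplicated to non-duplicated mutations gives, per
#' scenario (counts `n1`, `n2`, `n3`, `n4` by multiplicity):
#' \describe{
#'   \item{gain_2_1}{pi = 3 n2 / (2 n2 + n1)}
#'   \item{cnloh_2_0, tetra_2_2_sync}{pi = 2 n2 / (2 n2 + n1)}
#'   \item{tetra_3_1_seq}{pi1 = 4 n3 / (3 n3 + 2 n2 + n1),
#'     pi2 = 4 (n3 + n2) / (3 n3 + 2 n2 + n1)}
#'   \item{tetra_4_0_seq}{pi1 = 4 n4 / (4 n4 + 2 n2 + n1),
#'     pi2 = (4 n4 + 2 n2) / (4 n4 + 2 n2 + n1)}
#' }
#' Raw ratios outside \[0, 1\] (sampling noise) are clipped and flagged.
#'
#' @param counts Named numeric vector (`n1`, `n2`, and `n3`/`n4` for the
#'   sequential tetrasomies) or a `"multiplicity_counts"` object.
#' @param scenario Copy-number scenario name.
#' @return List of class `"molecular_time"`: `pi1`, `pi2` (`NA` for
#'   single-event scenarios), `scenario`, `clipped`.
#' @export
molecular_time <- function(counts, scenario) {
  if (inherits(counts, "multiplicity_counts")) {
    if (!counts$estimable) {
      stop("gain has ", counts$n, " clonal mutations; the timing floor is ",
           MOLTIME_FLOOR, " (estimation refused)")
    }
    counts <- counts$counts
  }
  sc <- get_scenario(scenario)
  cnt <- function(nm) if (nm %in% names(counts)) as.numeric(counts[[nm]]) else 0
  n1 <- cnt("n1"); n2 <- cnt("n2"); n3 <- cnt("n3"); n4 <- cnt("n4")
  if (n1 + n2 + n3 + n4 == 0) stop("all multiplicity counts are zero")
  pi2 <- NA_real_
  if (scenario == "gain_2_1") {
    pi1 <- 3 * n2 / (2 * n2 + n1)
  } else if (scenario %in% c("cnloh_2_0", "tetra_2_2_sync")) {
    pi1 <- 2 * n2 / (2 * n2 + n1)
  } else if (scenario == "tetra_3_1_seq") {
    d <- 3 * n3 + 2 * n2 + n1
    pi1 <- 4 * n3 / d
    pi2 <- 4 * (n3 + n2) / d
  } else { # tetra_4_0_seq
    d <- 4 * n4 + 2 * n2 + n1
    pi1 <- 4 * n4 / d
    pi2 <- (4 * n4 + 2 * n2) / d
  }
  clipped <- pi1 > 1 || pi1 < 0 || (!is.na(pi2) && (pi2 > 1 || pi2 < 0))
  pi1 <- min(1, max(0, pi1))
  if (!is.na(pi2)) pi2 <- min(1, max(0, max(pi1, pi2)))
  structure(list(pi1 = pi1, pi2 = pi2, scenario = scenario,
                 clipped = clipped),
            class = "molecular_time")
}

#' Bootstrap confidence interval for molecular time
#'
#' Resamples the multiplicity counts as a multinomial of the same total,
#' recomputes pi per draw and reports the 2.5th/97.5th percentile
#' interval.
#'
#' @inheritParams molecular_time
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed (RNG state local to the call).
#' @return `"molecular_time"` list with `ci1 = c(lo, hi)`, `ci2` (for
#'   two-event scenarios), `n_boot`, and the bootstrap draws in
#'   `boot_pi1`/`boot_pi2`.
#' @export
bootstrap_moltime <- function(counts, scenario, n_boot = 1000, seed = 42) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (inherits(counts, "multiplicity_counts")) {
    if (!counts$estimable) {
      stop("gain has ", counts$n, " clonal mutations; the timing floor is ",
           MOLTIME_FLOOR, " (estimation refused)")
    }
    counts <- counts$counts
  }
  pt <- molecular_time(counts, scenario)
  cn <- as.numeric(counts)
  total <- sum(cn)
  draws <- with_local_seed(seed, {
    mat <- stats::rmultinom(n_boot, total, cn / total)
    apply(mat, 2, function(col) {
      cc <- stats::setNames(as.numeric(col), names(counts))
      mt <- molecular_time(cc, scenario)
      c(mt$pi1, if (is.na(mt$pi2)) NA_real_ else mt$pi2)
    })
  })
  if (is.null(dim(draws))) draws <- rbind(draws, NA_real_)
  pt$boot_pi1 <- draws[1, ]
  pt$ci1 <- unname(stats::quantile(draws[1, ], c(0.025, 0.975)))
  if (!is.na(pt$pi2)) {
    pt$boot_pi2 <- draws[2, ]
    pt$ci2 <- unname(stats::quantile(draws[2, ], c(0.025, 0.975)))
  }
  pt$n_boot <- n_boot
  pt
}

#' Group chromosomal gains into shared time windows
#'
#' Given the bootstrap molecular-time draws of several gains from one
#' patient, clusters the gains per bootstrap draw (complete-linkage
#' hierarchical clustering on |pi_i - pi_j|, tree cut at `cut_height` in
#' pi units) and takes a consensus across draws: gains that co-cluster
#' in a majority of draws merge into one window. Windows are numbered in
#' time order (1 = earliest).
#'
#' @param boot_pi Matrix of bootstrap pi draws, one column per gain
#'   (rows = draws), or a list of `bootstrap_moltime` results whose
#'   `boot_pi1` are used.
#' @param cut_height Tree-cut height in pi units (default 0.15).
#' @return Integer window index per gain (named when columns are named).
#' @export
cluster_time_windows <- function(boot_pi, cut_height = 0.15) {
  if (is.list(boot_pi) && !is.matrix(boot_pi)) {
    boot_pi <- do.call(cbind, lapply(boot_pi, `[[`, "boot_pi1"))
  }
  g <- ncol(boot_pi)
  if (g == 1) return(stats::setNames(1L, colnames(boot_pi)))
  together <- matrix(0, g, g)
  n_draws <- nrow(boot_pi)
  for (d in seq_len(n_draws)) {
    v <- boot_pi[d, ]
    cl <- stats::cutree(stats::hclust(stats::dist(v), "complete"),
                        h = cut_height)
    together <- together + outer(cl, cl, "==")
  }
  consensus <- together / n_draws
  final <- stats::cutree(stats::hclust(stats::as.dist(1 - consensus),
                                       "single"), h = 0.5)
  # gains whose CIs all overlap a common region belong to one window:
  # merge clusters whose pooled 95% intervals share a point
  ci <- apply(boot_pi, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  repeat {
    ids <- unique(final)
    merged <- FALSE
    for (a in ids) {
      for (b in ids) {
        if (a >= b) next
        members <- which(final %in% c(a, b))
        if (max(ci[1, members]) <= min(ci[2, members])) {
          final[final == b] <- a
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # renumber windows by mean pi (earliest first)
  mean_pi <- colMeans(boot_pi)
  win_order <- rank(vapply(split(mean_pi, final), mean, numeric(1)))
  out <- as.integer(win_order[as.character(final)])
  names(out) <- colnames(boot_pi)
  out
}

#' SBS5-only multiplicity counts for a gained segment
#'
#' The absolute-timing workflow repeats the molecular-time estimate with
#' clock (SBS5) mutations only: clonal mutations in the segment are
#' first assigned to multiplicities from their VAFs, then each
#' multiplicity group's mini-catalog is refit by [censored_fit()] and
#' the group's SBS5 exposure taken as its SBS5 count.
#'
#' @param records Clonal mutation records inside the gained segment,
#'   with read counts and context.
#' @param purity Tumour purity.
#' @param scenario Copy-number scenario.
#' @param sigs Signature matrix.
#' @param ... Passed to [censored_fit()].
#' @return Named numeric vector (`n1`, `n2`, ...) of estimated SBS5
#'   mutations per multiplicity.
#' @export
sbs5_multiplicity_counts <- function(records, purity, scenario, sigs, ...) {
  amc <- assign_multiplicity(records, purity, scenario)
  mults <- get_scenario(scenario)$mults
  out <- stats::setNames(numeric(length(mults)), paste0("n", mults))
  for (m in mults) {
    idx <- which(amc$labels == m)
    if (!length(idx)) next
    cat_m <- build_catalog(records[idx, , drop = FALSE],
                           resolution = nrow(sigs))
    fit <- suppressWarnings(censored_fit(cat_m, sigs, ...))
    out[[paste0("n", m)]] <- fit$exposures[["SBS5"]]
  }
  out
}

#' Decide whether a tetrasomy arose in one or two time windows
#'
#' Two sequential gains of the same allele leave an intermediary
#' mutation cluster: mutations acquired between the gains sit on two of
#' the four copies (VAF 50\% at purity 1). The tetrasomy is called
#' `two_windows` when at least `k` mutations are assigned to the
#' intermediate multiplicity-2 component; otherwise the gains are
#' indistinguishable in time (`one_window`).
#'
#' @param assignment A `"multiplicity_counts"` result for a sequential
#'   tetrasomy scenario (`tetra_3_1_seq` or `tetra_4_0_seq`).
#' @param k Minimum intermediate-cluster size (default 10).
#' @return `"one_window"` or `"two_windows"`.
#' @export
detect_intermediate_stage <- function(assignment, k = 10) {
  scenario <- assignment$scenario
  if (!scenario %in% c("tetra_3_1_seq", "tetra_4_0_seq")) {
    stop("intermediary-stage detection applies to sequential tetrasomies ",
         "(tetra_3_1_seq, tetra_4_0_seq), not ", scenario)
  }
  n2 <- assignment$counts[["n2"]]
  if (n2 >= k) "two_windows" else "one_window"
}
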