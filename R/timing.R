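MULTIGAIN_FLOOR <- 100L  # SBS5 mutations needed in a collapsed multi-gain event

#' Phylogenetic mutation categories across multiple samples
#'
#' Classifies each mutation of a multi-sample patient: *early clonal*
#' when clonal in every sample (pre-MRCA), *late clonal* when clonal in
#' at least one but not all samples, *subclonal* when clonal in none.
#' `absent` counts as "not clonal".
#'
#' @param clonality Character matrix mutations x samples, entries in
#'   `{"clonal", "subclonal", "absent"}`; needs >= 2 columns.
#' @return Character vector `early_clonal`/`late_clonal`/`subclonal` per
#'   mutation (row).
#' @export
classify_phylo_category <- function(clonality) {
  clonality <- as.matrix(clonality)
  if (ncol(clonality) < 2) stop("need >= 2 samples per patient")
  bad <- !clonality %in% c("clonal", "subclonal", "absent")
  if (any(bad)) stop("clonality entries must be clonal/subclonal/absent")
  all_absent <- apply(clonality == "absent", 1, all)
  if (any(all_absent)) {
    stop("mutation(s) absent in every sample (rows ",
         paste(utils::head(which(all_absent)), collapse = ","), ")")
  }
  is_clonal <- clonality == "clonal"
  ifelse(apply(is_clonal, 1, all), "early_clonal",
         ifelse(apply(is_clonal, 1, any), "late_clonal", "subclonal"))
}

#' Selection classes between diagnosis and relapse
#'
#' A mutation clonal in both samples sits on the trunk (`clonal`);
#' otherwise it is `positive` when its cancer cell fraction rises by
#' more than `delta` from diagnosis to relapse, `negative` when it falls
#' by more than `delta`, and `neutral` in between.
#'
#' @param ccf_dx,ccf_rel Cancer cell fractions in \[0, 1\] (`NA` yields
#'   `NA` with a warning).
#' @param clonal_dx,clonal_rel Logical clonality flags per sample.
#' @param delta CCF change threshold (default 0.1).
#' @return Character vector of classes.
#' @export
classify_selection <- function(ccf_dx, ccf_rel, clonal_dx, clonal_rel,
                               delta = 0.1) {
  ok_range <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok_range(ccf_dx) || !ok_range(ccf_rel)) stop("CCFs must be in [0, 1]")
  out <- ifelse(clonal_dx & clonal_rel, "clonal",
                ifelse(ccf_rel - ccf_dx > delta, "positive",
                       ifelse(ccf_rel - ccf_dx < -delta, "negative",
                              "neutral")))
  if (any(is.na(out))) {
    warning(sum(is.na(out)), " mutation(s) with missing CCF left unlabeled")
  }
  out
}

#' Absolute age at the most recent common ancestor
#'
#' Under the through-origin clock, the MRCA emerged when the clonal
#' lineage had accumulated its (early) clonal SBS5 burden:
#' `age = burden / rate`. Estimates beyond the sampling age are capped
#' there and flagged. The interval combines the fitting CI of the burden
#' and the rate CI by Monte Carlo (see [propagate_uncertainty()]).
#'
#' @param burden Clonal SBS5 burden (point estimate, > 0).
#' @param rate Patient mutation rate per year (> 0).
#' @param age_at_sampling Age in years at sampling.
#' @param burden_ci,rate_ci Optional `c(lo, hi)` intervals.
#' @param n_mc,seed Monte Carlo controls for the CI.
#' @return List of class `"event_age"`: `event = "mrca"`, `age`,
#'   `ci`, `capped`, `inputs`.
#' @export
mrca_age <- function(burden, rate, age_at_sampling,
                     burden_ci = NULL, rate_ci = NULL,
                     n_mc = 1000, seed = 42) {
  if (burden <= 0) stop("clonal SBS5 burden must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  age <- burden / rate
  capped <- age > age_at_sampling
  ci <- propagate_uncertainty(
    age_fun = function(b, p, r) b / r,
    burden = burden, burden_ci = burden_ci,
    pi = 1, pi_ci = NULL,
    rate = rate, rate_ci = rate_ci,
    cap = age_at_sampling, n_mc = n_mc, seed = seed)
  age <- min(age, age_at_sampling)
  structure(list(event = "mrca", age = age, ci = ci, capped = capped,
                 inputs = list(burden = burden, burden_ci = burden_ci,
                               rate = rate, rate_ci = rate_ci,
                               age_at_sampling = age_at_sampling)),
            class = "event_age")
}

#' Absolute age of a collapsed multi-gain event
#'
#' Repeats the molecular-time estimate on SBS5-only multiplicity counts
#' (the clock signature measures time directly) and anchors it to the
#' MRCA age: the clonal lineage spans conception to MRCA under the
#' through-origin clock, so `age_at_gain = pi * age_at_mrca`. Events
#' with `<=` 100 SBS5 mutations are refused. Two-window scenarios yield
#' one age per window, ordered.
#'
#' @param sbs5_counts Named SBS5 multiplicity counts (`n1`, `n2`, ...).
#' @param scenario Copy-number scenario.
#' @param age_mrca MRCA age in years (see [mrca_age()]).
#' @param age_mrca_ci Optional `c(lo, hi)`.
#' @param n_boot,seed Bootstrap controls for the molecular time.
#' @param n_mc Monte Carlo draws for CI propagation.
#' @return List of `"event_age"` objects (one per window).
#' @export
multigain_age <- function(sbs5_counts, scenario, age_mrca,
                          age_mrca_ci = NULL, n_boot = 1000, n_mc = 1000,
                          seed = 42) {
  total <- sum(as.numeric(sbs5_counts))
  if (total <= MULTIGAIN_FLOOR) {
    stop("collapsed multi-gain event has ", total,
         " SBS5 mutations; more than ", MULTIGAIN_FLOOR, " are required")
  }
  mt <- bootstrap_moltime(sbs5_counts, scenario, n_boot = n_boot,
                          seed = seed)
  windows <- list(list(event = "gain_window_1", pi = mt$pi1, ci = mt$ci1))
  if (!is.na(mt$pi2)) {
    windows <- c(windows, list(list(event = "gain_window_2", pi = mt$pi2,
                                    ci = mt$ci2)))
  }
  out <- lapply(windows, function(w) {
    ci <- propagate_uncertainty(
      age_fun = function(b, p, r) b * p,
      burden = age_mrca, burden_ci = age_mrca_ci,
      pi = w$pi, pi_ci = w$ci,
      rate = 1, rate_ci = NULL,
      n_mc = n_mc, seed = seed + 1)
    structure(list(event = w$event, age = w$pi * age_mrca, ci = ci,
                   capped = FALSE,
                   inputs = list(pi = w$pi, pi_ci = w$ci,
                                 age_mrca = age_mrca,
                                 age_mrca_ci = age_mrca_ci,
                                 n_sbs5 = total, scenario = scenario)),
              class = "event_age")
  })
  # enforce window ordering (bootstrap noise can invert near-equal pis)
  if (length(out) == 2 && out[[2]]$age < out[[1]]$age) out <- out[c(2, 1)]
  out
}

#' Monte Carlo propagation of component uncertainties into an event age
#'
#' Samples each uncertain component independently -- uniform over the
#' fitting interval for the burden and the molecular time, normal for
#' the rate (mean at the point estimate, SD from the Wald interval) --
#' recomputes the age and returns the 2.5th/97.5th percentiles.
#' Zero-width (or absent) intervals collapse to the point estimate.
#'
#' @param age_fun Function `(burden, pi, rate) -> age`.
#' @param burden,pi,rate Point estimates.
#' @param burden_ci,pi_ci,rate_ci Optional `c(lo, hi)` intervals.
#' @param cap Optional upper cap applied to each draw (sampling age).
#' @param n_mc Number of draws (default 1000).
#' @param seed Integer seed.
#' @return `c(lo, hi)`.
#' @export
propagate_uncertainty <- function(age_fun, burden, pi = 1, rate = 1,
                                  burden_ci = NULL, pi_ci = NULL,
                                  rate_ci = NULL, cap = Inf,
                                  n_mc = 1000, seed = 42) {
  chk <- function(ci, point, what) {
    if (is.null(ci)) return(NULL)
    if (length(ci) != 2 || ci[1] > ci[2]) {
      stop(what, " interval must be an ordered (lo, hi) pair")
    }
    ci
  }
  burden_ci <- chk(burden_ci, burden, "burden")
  pi_ci <- chk(pi_ci, pi, "pi")
  rate_ci <- chk(rate_ci, rate, "rate")
  no_width <- function(ci) is.null(ci) || diff(ci) == 0
  if (no_width(burden_ci) && no_width(pi_ci) && no_width(rate_ci)) {
    point <- min(age_fun(burden, pi, rate), cap)
    return(c(point, point))
  }
  ages <- with_local_seed(seed, {
    b <- if (no_width(burden_ci)) rep(burden, n_mc)
         else stats::runif(n_mc, burden_ci[1], burden_ci[2])
    p <- if (no_width(pi_ci)) rep(pi, n_mc)
         else stats::runif(n_mc, pi_ci[1], pi_ci[2])
    r <- if (no_width(rate_ci)) rep(rate, n_mc)
         else {
           sd_r <- diff(rate_ci) / (2 * stats::qnorm(0.975))
           pmax(stats::rnorm(n_mc, rate, sd_r), 1e-6)
         }
    pmin(age_fun(b, p, r), cap)
  })
  unname(stats::quantile(ages, c(0.025, 0.975)))
}

#' Split patients into APOBEC-high and APOBEC-low
#'
#' Among patients with any APOBEC activity (burden > 0), the threshold
#' is the 75th percentile of their burdens; a patient is `high` when at
#' or above it. Patients with zero burden are `low`.
#'
#' @param burden Named numeric APOBEC burdens per patient (>= 0).
#' @return List: `class` (named `"high"`/`"low"`), `threshold` (`NA`
#'   when no patient has APOBEC activity).
#' @export
apobec_quartile_split <- function(burden) {
  if (length(burden) == 0) stop("empty cohort")
  if (any(burden < 0)) stop("burdens must be >= 0")
  active <- burden[burden > 0]
  if (!length(active)) {
    return(list(class = stats::setNames(rep("low", length(burden)),
                                        names(burden)),
                threshold = NA_real_))
  }
  thr <- unname(stats::quantile(active, 0.75))
  cls <- ifelse(burden > 0 & burden >= thr, "high", "low")
  list(class = stats::setNames(cls, names(burden)), threshold = thr)
}
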