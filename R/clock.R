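#' Cohort regression of signature burden on age
#'
#' Ordinary least squares of per-patient mutation burden on age at
#' sampling, with intercept. This is the cohort-level screen for
#' clock-like behaviour of a signature (a positive, significant slope).
#'
#' @param burden Numeric burden per patient.
#' @param age Age in years per patient.
#' @return List: `slope`, `ci` (95\%), `p_value`, `intercept`, `model`.
#' @export
regress_burden_age <- function(burden, age) {
  if (length(burden) != length(age)) stop("burden and age lengths differ")
  if (length(age) < 3) stop("need at least 3 patients")
  if (stats::var(age) == 0) stop("age is constant; slope unidentifiable")
  fit <- stats::lm(burden ~ age)
  sm <- summary(fit)
  ci <- stats::confint(fit)["age", ]
  list(slope = unname(stats::coef(fit)["age"]),
       ci = unname(ci),
       p_value = sm$coefficients["age", "Pr(>|t|)"],
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       model = fit)
}

#' Through-origin random-slope mixed model for the SBS5 clock
#'
#' Fits `burden_ij = (beta + b_i) * age_ij + e_ij` with
#' `b_i ~ N(0, sigma_b^2)`, no intercept (a lineage has zero mutations
#' at conception), by REML via \pkg{lme4}. `beta` is the population
#' mutation rate per year, `sigma_b` the between-patient SD of rates,
#' and the shrunken per-patient rates are `beta + b_i`.
#'
#' When fewer than two patients contribute two or more observations the
#' between-patient SD is not identifiable; the function falls back to a
#' fixed-slope model (`sd_between = NA`) with a warning.
#'
#' @param obs data.frame with columns `patient`, `age`, `burden`
#'   (root-to-tip signature burden per sample).
#' @return List of class `"rate_model"`: `beta`, `beta_ci` (95\% Wald),
#'   `sd_between`, `sigma`, `rates` (named per-patient), `model`,
#'   `unidentifiable`.
#' @export
fit_lme_rate <- function(obs) {
  stopifnot(all(c("patient", "age", "burden") %in% names(obs)))
  if (length(unique(obs$patient)) < 2) stop("need at least 2 patients")
  if (any(obs$age <= 0)) stop("ages must be positive")
  n_multi <- sum(table(obs$patient) >= 2)
  if (n_multi < 2) {
    warning("fewer than 2 patients with repeated observations; ",
            "between-patient SD unidentifiable, fitting fixed slope")
    fit <- stats::lm(burden ~ 0 + age, data = obs)
    beta <- unname(stats::coef(fit))
    se <- summary(fit)$coefficients["age", "Std. Error"]
    rates <- stats::setNames(rep(beta, length(unique(obs$patient))),
                             unique(obs$patient))
    return(structure(list(beta = beta,
                          beta_ci = beta + c(-1, 1) * 1.96 * se,
                          sd_between = NA_real_,
                          sigma = summary(fit)$sigma,
                          rates = rates, model = fit,
                          unidentifiable = TRUE),
                     class = "rate_model"))
  }
  fit <- lme4::lmer(burden ~ 0 + age + (0 + age | patient), data = obs,
                    REML = TRUE,
                    control = lme4::lmerControl(optimizer = "bobyqa",
                                                check.conv.singular = "ignore"))
  beta <- unname(lme4::fixef(fit)["age"])
  se <- sqrt(as.numeric(stats::vcov(fit)["age", "age"]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_b <- vc$sdcor[vc$grp == "patient" & vc$var1 == "age"][1]
  re <- lme4::ranef(fit)$patient
  rates <- stats::setNames(beta + re[, "age"], rownames(re))
  # patients present in obs but absent from ranef (cannot happen with
  # lmer, kept for safety) fall back to beta
  missing <- setdiff(unique(obs$patient), names(rates))
  if (length(missing)) {
    rates <- c(rates, stats::setNames(rep(beta, length(missing)), missing))
  }
  structure(list(beta = beta,
                 beta_ci = beta + c(-1, 1) * 1.96 * se,
                 sd_between = sd_b,
                 sigma = stats::sigma(fit),
                 rates = rates, model = fit,
                 unidentifiable = FALSE),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf(
    "<rate_model> rate=%.2f/yr (95%% CI %.2f-%.2f), between-patient SD=%s, %d patients\n",
    x$beta, x$beta_ci[1], x$beta_ci[2],
    if (is.na(x$sd_between)) "NA" else sprintf("%.2f", x$sd_between),
    length(x$rates)))
  invisible(x)
}

#' Quadratic-age sensitivity check for the clock model
#'
#' Refits the clock with an additional fixed quadratic age term,
#' allowing the mutation rate to increase parabolically with age, and
#' compares it to the linear model by maximum likelihood (AIC and
#' likelihood-ratio test). The linear clock is declared adequate ("no
#' improvement") unless the quadratic model improves AIC by more than 2.
#'
#' @param obs As in [fit_lme_rate()].
#' @return List: `aic_linear`, `aic_quadratic`, `delta_aic`
#'   (quadratic - linear), `lrt_p`, `beta_linear`, `beta_quadratic`,
#'   `verdict` (`"no improvement"` or `"quadratic preferred"`).
#' @export
quadratic_sensitivity <- function(obs) {
  stopifnot(all(c("patient", "age", "burden") %in% names(obs)))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore",
                            check.scaleX = "ignore")
  lin <- lme4::lmer(burden ~ 0 + age + (0 + age | patient), data = obs,
                    REML = FALSE, control = ctrl)
  quad <- lme4::lmer(burden ~ 0 + age + I(age^2) + (0 + age | patient),
                     data = obs, REML = FALSE, control = ctrl)
  comp <- stats::anova(lin, quad)
  delta <- stats::AIC(quad) - stats::AIC(lin)
  list(aic_linear = stats::AIC(lin),
       aic_quadratic = stats::AIC(quad),
       delta_aic = delta,
       lrt_p = comp$`Pr(>Chisq)`[2],
       beta_linear = unname(lme4::fixef(lin)["age"]),
       beta_quadratic = unname(lme4::fixef(quad)["age"]),
       verdict = if (delta >= -2) "no improvement" else "quadratic preferred")
}

#' Eligibility filter for clock calibration
#'
#' Excludes samples whose mutation landscape breaks the clock
#' assumptions: hypermutated tumours (> `max_snv` SNVs, where the
#' age-burden correlation is lost) and near-double genome duplications
#' (ploidy > `max_ploidy`).
#'
#' @param samples data.frame with `sample`, `n_snv`, and optionally
#'   `ploidy` (`NA` allowed: included with a warning).
#' @param max_snv SNV cap (default 10000).
#' @param max_ploidy Ploidy cap (default 4).
#' @return `samples` with logical `included` and character `reason`
#'   columns.
#' @export
eligibility_filter <- function(samples, max_snv = 10000, max_ploidy = 4) {
  stopifnot(all(c("sample", "n_snv") %in% names(samples)))
  if (!"ploidy" %in% names(samples)) samples$ploidy <- NA_real_
  if (any(is.na(samples$ploidy))) {
    warning("missing ploidy for ",
            paste(samples$sample[is.na(samples$ploidy)], collapse = ", "),
            "; included without a ploidy check")
  }
  hyper <- samples$n_snv > max_snv
  high_ploidy <- !is.na(samples$ploidy) & samples$ploidy > max_ploidy
  samples$included <- !hyper & !high_ploidy
  samples$reason <- ifelse(hyper, "hypermutation",
                           ifelse(high_ploidy, "ploidy", ""))
  samples
}
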