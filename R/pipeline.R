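#' Default run configuration
#'
#' All thresholds default to the analytic constants of the MM timing
#' workflow: censoring threshold 0.01 (cosine), kataegis rule 6
#' mutations / 1000 bp mean spacing, SV proximity window 1 Mb, 50
#' clonal mutations per timed gain, more than 100 SBS5 mutations per
#' collapsed multi-gain event, hypermutation cap 10,000 SNVs, ploidy
#' cap 4, 1000 bootstrap draws.
#'
#' @param ... Overrides, e.g. `seed = 7`, `n_boot = 200`.
#' @return Named list of class `"run_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    censor_threshold = 0.01,
    kataegis_min_n = 6,
    kataegis_max_mean_imd = 1000,
    sv_window = 1e6,
    moltime_floor = 50,
    multigain_floor = 100,
    snv_cap = 10000,
    ploidy_cap = 4,
    n_boot = 1000,
    seed = 42,
    out_dir = NULL,
    simulate = list(n_patients = 3, mean_rate = 38.8, sd_rate = 7.1)
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("censor_threshold", "kataegis_min_n", "kataegis_max_mean_imd",
           "sv_window", "moltime_floor", "multigain_floor", "snv_cap",
           "ploidy_cap", "n_boot")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("config field ", nm, " must be a positive number")
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#' @param path YAML file; missing fields take [default_config()] values.
#' @return `"run_config"` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(default_config, user)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg[order(names(cfg))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full timing pipeline on a simulated cohort
#'
#' Executes catalog building, censored signature fitting, kataegis
#' detection, molecular-time estimation of the gained segment, clock
#' calibration across the cohort, and landmark-event timing, in order.
#' Each stage failure aborts with the stage name. When `out_dir` is set
#' the per-patient and cohort tables are written as TSV, stamped with
#' the configuration hash.
#'
#' @param config A `"run_config"` (see [default_config()]); its
#'   `simulate` block sizes the synthetic cohort.
#' @param sigs Signature matrix (default: synthetic reference).
#' @return List: `fits`, `kataegis`, `moltime`, `clock`, `events`
#'   (per-patient event ages), `config_hash`.
#' @export
run_pipeline <- function(config = default_config(),
                         sigs = make_signature_set()) {
  config <- validate_config(config)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  message("run_pipeline [config ", hash, "]")

  sim <- stage("simulate", simulate_cohort(
    n_patients = config$simulate$n_patients,
    mean_rate = config$simulate$mean_rate,
    sd_rate = config$simulate$sd_rate,
    sigs = sigs,
    seed = config$seed))

  fits <- stage("fit", lapply(sim, function(p) {
    samples <- unique(p$records$sample)
    first <- p$records$sample == samples[1]
    cl <- p$records[first & p$records$clonality == "clonal", , drop = FALSE]
    list(
      clonal = suppressWarnings(censored_fit(
        build_catalog(cl), sigs, threshold = config$censor_threshold)),
      # per-sample root-to-tip burden (clonal + private) feeds the clock
      total = lapply(stats::setNames(samples, samples), function(s) {
        suppressWarnings(censored_fit(
          build_catalog(p$records[p$records$sample == s, , drop = FALSE]),
          sigs, threshold = config$censor_threshold))
      }))
  }))

  kat <- stage("kataegis", lapply(sim, function(p) {
    ev <- detect_kataegis(p$records, min_n = config$kataegis_min_n,
                          max_mean_imd = config$kataegis_max_mean_imd)
    annotate_sv_proximity(ev, p$breakpoints, window = config$sv_window)
  }))

  mol <- stage("moltime", lapply(sim, function(p) {
    if (is.null(p$truth$purity)) stop("purity missing")
    seg <- p$segments[p$segments$major > p$segments$minor |
                        p$segments$minor == 0, , drop = FALSE][1, ]
    inseg <- p$records$chrom == seg$chrom &
      p$records$pos >= seg$start & p$records$pos <= seg$end &
      p$records$clonality == "clonal"
    amc <- assign_multiplicity(p$records[inseg, , drop = FALSE],
                               purity = p$truth$purity,
                               scenario = p$truth$scenario)
    bootstrap_moltime(amc, p$truth$scenario,
                      n_boot = config$n_boot, seed = config$seed)
  }))

  clock <- stage("clock", {
    obs <- do.call(rbind, lapply(sim, function(p) {
      f <- fits[[p$truth$patient]]
      data.frame(patient = p$truth$patient,
                 sample = names(f$total),
                 age = p$truth$age_sampling,
                 burden = vapply(f$total, function(x)
                   x$exposures[["SBS5"]], numeric(1)),
                 stringsAsFactors = FALSE)
    }))
    if (nrow(obs) >= 2) suppressWarnings(fit_lme_rate(obs)) else NULL
  })

  events <- stage("time-events", lapply(sim, function(p) {
    pid <- p$truth$patient
    f <- fits[[pid]]
    rate <- if (!is.null(clock)) clock$rates[[pid]] else p$truth$rate_per_year
    mrca <- mrca_age(burden = f$clonal$exposures[["SBS5"]], rate = rate,
                     age_at_sampling = p$truth$age_sampling[1],
                     seed = config$seed)
    if (is.null(p$truth$purity)) stop("purity missing")
    first_sample <- p$records$sample[1]
    seg <- p$records$sample == first_sample &
      p$records$chrom == SIM_GAINED_CHROM &
      p$records$clonality == "clonal"
    counts <- sbs5_multiplicity_counts(
      p$records[seg, , drop = FALSE], p$truth$purity, p$truth$scenario,
      sigs, threshold = config$censor_threshold)
    gains <- tryCatch(
      multigain_age(counts, p$truth$scenario,
                    age_mrca = mrca$age, age_mrca_ci = mrca$ci,
                    n_boot = config$n_boot, seed = config$seed),
      error = function(e) list())
    c(list(mrca = mrca), gains)
  }))

  out <- list(fits = fits, kataegis = kat, moltime = mol, clock = clock,
              events = events, config_hash = hash, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, sim)
  out
}

write_pipeline_outputs <- function(out, sim) {
  dir.create(out$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- out$config_hash; df }
  fit_tab <- do.call(rbind, lapply(names(out$fits), function(p) {
    f <- out$fits[[p]]$clonal
    data.frame(patient = p, signature = names(f$exposures),
               exposure = unname(f$exposures),
               fraction = unname(f$fractions),
               censored = names(f$exposures) %in% f$censored,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(stamp(fit_tab),
                     file.path(out$config$out_dir, "fit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ev_tab <- do.call(rbind, lapply(names(out$events), function(p) {
    do.call(rbind, lapply(out$events[[p]], function(e) {
      data.frame(patient = p, event = e$event, age = e$age,
                 lo = e$ci[1], hi = e$ci[2], stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(stamp(ev_tab),
                     file.path(out$config$out_dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
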