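#' Synthetic well-separated signature set
#'
#' Builds a reference of sparse random signature columns for closed-loop
#' testing: each signature concentrates its probability on a few
#' substitution classes, and columns are resampled until every pairwise
#' cosine similarity is below `max_cosine`, so mixtures are identifiable
#' by construction. Column names default to the processes this package
#' cares about (clock SBS1/SBS5, APOBEC SBS2/SBS13, AID SBS9/SBS84,
#' SBS8, SBS18, and the treatment signature SBS-MM1); the profiles are
#' synthetic stand-ins, not COSMIC estimates. A user-supplied COSMIC
#' TSV (see [read_signatures()]) is the production alternative.
#'
#' @param n_classes 96 or 1536.
#' @param sig_names Signature (column) names.
#' @param seed Integer seed.
#' @param n_support Number of high-probability classes per signature.
#' @param max_cosine Pairwise cosine ceiling (default 0.3).
#' @return Signature matrix (classes x signatures), columns sum to 1.
#' @export
make_signature_set <- function(n_classes = 96,
                               sig_names = c("SBS1", "SBS2", "SBS5",
                                             "SBS8", "SBS9", "SBS13",
                                             "SBS18", "SBS84", "SBS-MM1"),
                               seed = 1, n_support = 8, max_cosine = 0.3) {
  classes <- sbs_classes(n_classes)
  k <- length(sig_names)
  with_local_seed(seed, {
    draw_col <- function() {
      p <- rep(1e-4, length(classes))
      sup <- sample.int(length(classes), n_support)
      p[sup] <- stats::rgamma(n_support, shape = 2)
      p / sum(p)
    }
    m <- matrix(0, length(classes), k,
                dimnames = list(classes, sig_names))
    for (j in seq_len(k)) {
      repeat {
        cand <- draw_col()
        ok <- if (j == 1) TRUE else
          all(apply(m[, seq_len(j - 1), drop = FALSE], 2,
                    cosine_similarity, u = cand) < max_cosine)
        if (ok) { m[, j] <- cand; break }
      }
    }
    signature_matrix(m)
  })
}

context_from_class <- function(labels) {
  # invert a 96-class label into (ref, alt, context5, context3) on the
  # pyrimidine strand, then flip half the records to the purine strand
  # so strand normalization is exercised
  ref <- substr(labels, 3, 3)
  alt <- substr(labels, 5, 5)
  c5 <- substr(labels, 1, 1)
  c3 <- substr(labels, 7, 7)
  flip <- stats::runif(length(labels)) < 0.5
  data.frame(
    ref = ifelse(flip, unname(COMPLEMENT[ref]), ref),
    alt = ifelse(flip, unname(COMPLEMENT[alt]), alt),
    context5 = ifelse(flip, unname(COMPLEMENT[c3]), c5),
    context3 = ifelse(flip, unname(COMPLEMENT[c5]), c3),
    stringsAsFactors = FALSE)
}

#' Default synthetic patient parameters
#'
#' The stated world of the generator: an SBS5 rate around the population
#' mean of MM genomes, a single-allele gain (trisomy) acquired in the
#' patient's twenties, MRCA in midlife, sampling in the seventh decade,
#' AID activity confined to the pre-gain epoch and APOBEC appearing
#' later, WGS-like depth 60x and purity 0.8.
#'
#' @param patient Patient id.
#' @param rate_per_year Genome-wide SBS5 mutations per year.
#' @param age_gain1,age_gain2,age_mrca,age_sampling Event ages (years);
#'   `age_gain2 = NA` for a single gain. `age_sampling` may be a vector
#'   of distinct ages, one tumour sample taken at each (all after the
#'   MRCA).
#' @param scenario Copy-number scenario of the gained segment.
#' @param purity,depth Sample purity and sequencing depth.
#' @param activities Named list of per-epoch signature activity
#'   fractions (`pre_gain`, `gain_to_mrca`, `post_mrca`), each summing
#'   to 1 and giving SBS5 positive weight.
#' @param n_kataegis Number of planted kataegis clusters.
#' @param kataegis_size Mutations per planted cluster.
#' @return List of class `"patient_truth"`.
#' @export
patient_truth <- function(patient = "P1", rate_per_year = 38.8,
                          age_gain1 = 20, age_gain2 = NA,
                          age_mrca = 50, age_sampling = 65,
                          scenario = "gain_2_1",
                          purity = 0.8, depth = 60,
                          activities = list(
                            pre_gain = c(SBS5 = 0.55, SBS1 = 0.1,
                                         SBS9 = 0.35),
                            gain_to_mrca = c(SBS5 = 0.7, SBS1 = 0.1,
                                             SBS2 = 0.1, SBS13 = 0.1),
                            post_mrca = c(SBS5 = 0.6, SBS1 = 0.1,
                                          SBS2 = 0.15, SBS13 = 0.15)),
                          n_kataegis = 2, kataegis_size = 10) {
  age_sampling <- sort(as.numeric(age_sampling))
  ages <- c(age_gain1, if (!is.na(age_gain2)) age_gain2, age_mrca,
            age_sampling[1])
  if (any(diff(ages) <= 0) || any(ages <= 0) ||
      anyDuplicated(age_sampling)) {
    stop("event ages must be positive and strictly increasing ",
         "(gain1 < gain2 < mrca < samplings)")
  }
  if (rate_per_year <= 0) stop("rate must be positive")
  for (e in names(activities)) {
    a <- activities[[e]]
    if (abs(sum(a) - 1) > 1e-6) stop("activities in epoch ", e,
                                     " must sum to 1")
    if (!"SBS5" %in% names(a) || a[["SBS5"]] <= 0) {
      stop("every epoch needs positive SBS5 activity")
    }
  }
  structure(list(patient = patient, rate_per_year = rate_per_year,
                 age_gain1 = age_gain1, age_gain2 = age_gain2,
                 age_mrca = age_mrca, age_sampling = age_sampling,
                 scenario = scenario, purity = purity, depth = depth,
                 activities = activities, n_kataegis = n_kataegis,
                 kataegis_size = kataegis_size),
            class = "patient_truth")
}

SIM_GENOME <- list(chroms = paste0("chr", 1:5), length = 1e8)  # 5 x 100 Mb
SIM_GAINED_CHROM <- "chr1"

#' Simulate one patient's somatic mutation data with full ground truth
#'
#' Generates clonal and subclonal SNVs over a simplified 500-Mb genome
#' (five 100-Mb chromosomes; chr1 carries the gained segment). SBS5
#' accumulates at `rate_per_year` genome-wide along the clonal lineage;
#' each epoch's other signatures scale relative to SBS5 by the epoch
#' activity fractions. Mutations landing on the gained allele before the
#' gain become duplicated (multiplicity 2, or 3/4 under tetrasomy
#' scenarios); the extra post-gain copies contribute additional
#' single-copy mutations. Read counts are Binomial(depth, expected VAF).
#' Kataegis clusters (APOBEC classes, ~100-bp inter-mutation spacing)
#' are planted next to simulated SV breakpoints.
#'
#' @param truth A [patient_truth()].
#' @param sigs Signature matrix used to draw substitution classes.
#' @param seed Integer seed.
#' @return List: `records` (mutation records with per-mutation truth
#'   columns `true_signature`, `true_epoch`, `true_multiplicity`,
#'   `true_kataegis`), `segments` (allele-specific copy-number table),
#'   `breakpoints`, `truth`.
#' @export
simulate_patient <- function(truth, sigs = make_signature_set(), seed = 1) {
  stopifnot(inherits(truth, "patient_truth"))
  sc <- get_scenario(truth$scenario)
  with_local_seed(seed, {
    g_len <- SIM_GENOME$length
    n_chrom <- length(SIM_GENOME$chroms)
    f_seg <- 1 / n_chrom  # gained segment fraction (whole chr1)

    two_gains <- !is.na(truth$age_gain2) &&
      truth$scenario %in% c("tetra_3_1_seq", "tetra_4_0_seq")
    t1 <- truth$age_gain1
    t2 <- if (two_gains) truth$age_gain2 else NA
    tm <- truth$age_mrca
    ts <- truth$age_sampling  # one or more sampling ages

    # draw one batch of mutations for a (signature, epoch) cell; reads
    # are drawn later, per sample, from the stored expected VAF
    draw_batch <- function(sig, epoch, span, act, ccf) {
      a5 <- act[["SBS5"]]
      lam <- truth$rate_per_year * span * act[[sig]] / a5
      batches <- list(c(n = stats::rpois(1, lam), seg_only = 0L))
      if (epoch != "pre_gain") {
        # the gained segment carries extra copies after the gain(s)
        lam_extra <- lam * f_seg * (sc$cnt - 2L) / 2
        batches <- c(batches,
                     list(c(n = stats::rpois(1, lam_extra), seg_only = 1L)))
      }
      out <- list()
      for (b in batches) {
        n <- b[["n"]]
        if (n == 0) next
        cls <- sample(rownames(sigs), n, replace = TRUE, prob = sigs[, sig])
        chrom <- if (b[["seg_only"]] == 1L) rep(SIM_GAINED_CHROM, n)
                 else sample(SIM_GENOME$chroms, n, replace = TRUE)
        pos <- sample.int(g_len, n, replace = TRUE)
        in_seg <- chrom == SIM_GAINED_CHROM
        mult <- rep(1L, n)
        if (epoch == "pre_gain") {
          # half the pre-gain segment mutations sit on the allele that
          # later duplicates (the other half on the minor allele, which
          # a minor = 0 scenario loses entirely)
          on_gained <- in_seg & stats::runif(n) < 0.5
          mult[on_gained] <- max(sc$mults)
          if (truth$scenario == "tetra_2_2_sync") mult[in_seg] <- 2L
          if (sc$minor == 0L) {
            keep <- !(in_seg & mult == 1L)
            chrom <- chrom[keep]; pos <- pos[keep]; cls <- cls[keep]
            mult <- mult[keep]; in_seg <- in_seg[keep]
            n <- sum(keep)
            if (n == 0) next
          }
        } else if (epoch == "gain_to_mrca" && two_gains) {
          # between sequential gains: mutations on the duplicating copy
          # reach the intermediate multiplicity 2
          acquired_between <- in_seg & stats::runif(n) <
            ((t2 - t1) / (tm - t1)) *
            (if (truth$scenario == "tetra_3_1_seq") 1 / sc$cnt else 2 / sc$cnt)
          mult[acquired_between] <- 2L
        }
        cnt <- ifelse(in_seg, sc$cnt, 2L)
        p_vaf <- ccf * mult * truth$purity /
          (truth$purity * cnt + 2 * (1 - truth$purity))
        ctx <- context_from_class(cls)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, ref = ctx$ref, alt = ctx$alt,
          context5 = ctx$context5, context3 = ctx$context3,
          p_vaf = p_vaf,
          clonality = if (epoch == "post_mrca") "subclonal" else "clonal",
          true_signature = sig, true_epoch = epoch,
          true_multiplicity = mult, true_kataegis = FALSE,
          stringsAsFactors = FALSE)
      }
      if (length(out)) do.call(rbind, out) else NULL
    }

    gather <- function(epoch, span, ccf) {
      act <- truth$activities[[epoch]]
      do.call(rbind, Filter(Negate(is.null), lapply(
        names(act), draw_batch, epoch = epoch, span = span, act = act,
        ccf = ccf)))
    }

    clonal_mut <- rbind(gather("pre_gain", t1, 1),
                        gather("gain_to_mrca", tm - t1, 1))

    # SV breakpoints and planted kataegis clusters beside them (clonal)
    n_sv <- max(2L, truth$n_kataegis)
    breakpoints <- data.frame(
      chrom = sample(SIM_GENOME$chroms, n_sv, replace = TRUE),
      pos = sample.int(g_len - 2e6, n_sv) + 1e6,
      stringsAsFactors = FALSE)
    apobec_sigs <- intersect(c("SBS2", "SBS13"), colnames(sigs))
    for (kk in seq_len(truth$n_kataegis)) {
      bp <- breakpoints[kk, ]
      start <- bp$pos + sample.int(5e4, 1)
      gaps <- pmax(1, stats::rpois(truth$kataegis_size - 1, 100))
      kpos <- start + cumsum(c(0, gaps))
      ksig <- sample(apobec_sigs, 1)
      cls <- sample(rownames(sigs), truth$kataegis_size, replace = TRUE,
                    prob = sigs[, ksig])
      ctx <- context_from_class(cls)
      clonal_mut <- rbind(clonal_mut, data.frame(
        chrom = bp$chrom, pos = kpos, ref = ctx$ref, alt = ctx$alt,
        context5 = ctx$context5, context3 = ctx$context3,
        p_vaf = truth$purity / (truth$purity * 2 + 2 * (1 - truth$purity)),
        clonality = "clonal",
        true_signature = ksig, true_epoch = "kataegis",
        true_multiplicity = 1L, true_kataegis = TRUE,
        stringsAsFactors = FALSE))
    }

    with_reads <- function(mut, sample_id) {
      n <- nrow(mut)
      tot <- stats::rpois(n, truth$depth)
      tot[tot == 0] <- 1L
      mut$alt_reads <- stats::rbinom(n, tot, mut$p_vaf)
      mut$total_reads <- tot
      mut$sample <- sample_id
      mut
    }

    # every sample observes the clonal lineage plus its own private
    # subclonal mutations acquired after the MRCA
    per_sample <- lapply(seq_along(ts), function(k) {
      sid <- paste0(truth$patient, "_T", k)
      private <- gather("post_mrca", ts[k] - tm, 0.4)
      rbind(with_reads(clonal_mut, sid),
            if (!is.null(private)) with_reads(private, sid))
    })
    mut <- do.call(rbind, per_sample)
    mut <- mut[order(mut$sample, mut$chrom, mut$pos), , drop = FALSE]

    records <- mutation_records(
      chrom = mut$chrom, pos = mut$pos, ref = mut$ref, alt = mut$alt,
      sample = mut$sample, patient = truth$patient,
      alt_reads = mut$alt_reads, total_reads = mut$total_reads,
      context5 = mut$context5, context3 = mut$context3,
      clonality = mut$clonality)
    records$true_signature <- mut$true_signature
    records$true_epoch <- mut$true_epoch
    records$true_multiplicity <- mut$true_multiplicity
    records$true_kataegis <- mut$true_kataegis

    segments <- data.frame(
      chrom = SIM_GENOME$chroms,
      start = 1L, end = g_len,
      major = ifelse(SIM_GENOME$chroms == SIM_GAINED_CHROM, sc$major, 1L),
      minor = ifelse(SIM_GENOME$chroms == SIM_GAINED_CHROM, sc$minor, 1L),
      clonal = TRUE, stringsAsFactors = FALSE)

    list(records = records, segments = segments,
         breakpoints = breakpoints, truth = truth)
  })
}

#' Simulate a cohort with population-level rate variation
#'
#' Draws per-patient SBS5 rates from a normal distribution truncated at
#' `min_rate`, event ages consistent with each patient's sampling age,
#' and runs [simulate_patient()] for each. Optionally writes each
#' patient's VCF, segment TSV and truth TSV plus a manifest JSON.
#'
#' @param n_patients Number of patients.
#' @param mean_rate,sd_rate Population mean and between-patient SD of
#'   the SBS5 rate (defaults 38.8 and 7.1 mutations/year, the MM
#'   whole-genome estimates).
#' @param seed Integer seed.
#' @param min_rate Truncation floor for rates (default 5/year).
#' @param sigs Signature matrix handed to [simulate_patient()].
#' @param age_gain_range,age_mrca_range,age_sampling_range Uniform
#'   ranges for event ages.
#' @param samples_range Inclusive range for the number of samples per
#'   patient (each at its own sampling age; default single-sample).
#' @param out_dir Optional output directory.
#' @param ... Passed to [patient_truth()] (e.g. `scenario`, `purity`).
#' @return List of per-patient [simulate_patient()] results, with a
#'   `manifest` attribute recording all parameters and seeds.
#' @export
simulate_cohort <- function(n_patients, mean_rate = 38.8, sd_rate = 7.1,
                            seed = 1, min_rate = 5,
                            sigs = make_signature_set(),
                            age_gain_range = c(15, 25),
                            age_mrca_range = c(35, 55),
                            age_sampling_range = c(55, 75),
                            samples_range = c(1, 1),
                            out_dir = NULL, ...) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (sd_rate < 0) stop("sd_rate must be >= 0")
  params <- with_local_seed(seed, {
    rates <- numeric(n_patients)
    for (i in seq_len(n_patients)) {
      repeat {
        r <- stats::rnorm(1, mean_rate, sd_rate)
        if (r > min_rate) { rates[i] <- r; break }
      }
    }
    df <- data.frame(
      patient = sprintf("P%03d", seq_len(n_patients)),
      rate = rates,
      age_gain1 = stats::runif(n_patients, age_gain_range[1],
                               age_gain_range[2]),
      age_mrca = stats::runif(n_patients, age_mrca_range[1],
                              age_mrca_range[2]),
      n_samples = sample(samples_range[1]:samples_range[2], n_patients,
                         replace = TRUE),
      seed = seed + seq_len(n_patients),
      stringsAsFactors = FALSE)
    df$age_sampling <- lapply(df$n_samples, function(k) {
      sort(stats::runif(k, age_sampling_range[1], age_sampling_range[2]))
    })
    df
  })
  cohort <- lapply(seq_len(n_patients), function(i) {
    tr <- patient_truth(patient = params$patient[i],
                        rate_per_year = params$rate[i],
                        age_gain1 = params$age_gain1[i],
                        age_mrca = params$age_mrca[i],
                        age_sampling = params$age_sampling[[i]], ...)
    simulate_patient(tr, sigs = sigs, seed = params$seed[i])
  })
  names(cohort) <- params$patient
  manifest <- list(n_patients = n_patients, mean_rate = mean_rate,
                   sd_rate = sd_rate, seed = seed, min_rate = min_rate,
                   params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in names(cohort)) {
      write_mutations_vcf(cohort[[p]]$records,
                          file.path(out_dir, paste0(p, ".vcf")))
      utils::write.table(cohort[[p]]$segments,
                         file.path(out_dir, paste0(p, "_segments.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cohort[[p]]$records,
                         file.path(out_dir, paste0(p, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(cohort, "manifest") <- manifest
  cohort
}

#' Simulate root-to-tip clock observations for a cohort
#'
#' The minimal generative model behind the mixed-effects clock: each
#' patient draws a rate from N(`mean_rate`, `sd_rate`) truncated at
#' `min_rate`, contributes 1-3 samples at ages uniform in `age_range`,
#' and each sample's root-to-tip SBS5 burden is Poisson(rate x age).
#'
#' @param n_patients Cohort size (default 49 patients, the timeable MM
#'   whole-genome cohort size).
#' @param mean_rate,sd_rate Population parameters (defaults 38.8, 7.1).
#' @param age_range Sampling age range in years (default 40-80).
#' @param seed Integer seed.
#' @param min_rate Truncation floor (default 5).
#' @return data.frame `patient`, `sample`, `age`, `burden`, `true_rate`.
#' @export
simulate_branch_burdens <- function(n_patients = 49, mean_rate = 38.8,
                                    sd_rate = 7.1, age_range = c(40, 80),
                                    seed = 1, min_rate = 5) {
  with_local_seed(seed, {
    out <- list()
    for (i in seq_len(n_patients)) {
      repeat {
        r <- stats::rnorm(1, mean_rate, sd_rate)
        if (r > min_rate) break
      }
      k <- sample(1:3, 1)
      ages <- sort(stats::runif(k, age_range[1], age_range[2]))
      out[[i]] <- data.frame(
        patient = sprintf("P%03d", i),
        sample = sprintf("P%03d_S%d", i, seq_len(k)),
        age = ages,
        burden = stats::rpois(k, r * ages),
        true_rate = r, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
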