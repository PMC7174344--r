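#' Detect kataegis events
#'
#' Kataegis is localized hypermutation: a run of at least `min_n`
#' consecutive mutations whose mean inter-mutation distance (IMD) is at
#' most `max_mean_imd` bp. Runs are grown greedily along each chromosome
#' (per sample): a run keeps extending while its mean IMD stays within
#' the ceiling, is emitted when it holds at least `min_n` mutations, and
#' the scan resumes after the run, so events never overlap. Mutations at
#' identical positions are collapsed to one before IMD computation.
#'
#' With `strict_gaps = TRUE` a run additionally breaks at any single gap
#' larger than `max_mean_imd` (per-gap variant of the rule; the
#' mean-based definition is the default).
#'
#' @param records Mutation records for one sample (multiple samples are
#'   processed independently and results concatenated).
#' @param min_n Minimum run length (default 6).
#' @param max_mean_imd Mean IMD ceiling in bp (default 1000).
#' @param ig_intervals Optional data.frame `chrom,start,end` of
#'   immunoglobulin loci; overlapping events are labelled `ig = TRUE`.
#' @param strict_gaps Break runs at any single gap > `max_mean_imd`.
#' @return data.frame of class `"kataegis_events"`: `sample`, `chrom`,
#'   `start`, `end` (1-based inclusive), `n_mutations`, `mean_imd`,
#'   `ig`, plus a list-column `idx` of row indices into `records`.
#' @export
detect_kataegis <- function(records, min_n = 6, max_mean_imd = 1000,
                            ig_intervals = NULL, strict_gaps = FALSE) {
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_mutations = integer(0), mean_imd = numeric(0),
                      ig = logical(0))
  empty$idx <- list()
  if (nrow(records) == 0) {
    return(structure(empty, class = c("kataegis_events", "data.frame")))
  }
  ord <- order(records$sample, records$chrom, records$pos)
  if (!identical(ord, seq_len(nrow(records)))) {
    message("kataegis: input not sorted by (sample, chrom, pos); sorting")
  }
  events <- list()
  for (s in unique(records$sample[ord])) {
    for (chr in unique(records$chrom[records$sample == s])) {
      sel <- which(records$sample == s & records$chrom == chr)
      sel <- sel[order(records$pos[sel])]
      sel <- sel[!duplicated(records$pos[sel])]
      pos <- records$pos[sel]
      n <- length(pos)
      i <- 1L
      while (i <= n) {
        j <- i
        # extend while the run mean IMD stays within the ceiling
        while (j < n) {
          gap <- pos[j + 1L] - pos[j]
          if (strict_gaps && gap > max_mean_imd) break
          mean_imd_next <- (pos[j + 1L] - pos[i]) / (j + 1L - i)
          if (mean_imd_next > max_mean_imd) break
          j <- j + 1L
        }
        if (j - i + 1L >= min_n) {
          events[[length(events) + 1L]] <- list(
            sample = s, chrom = chr, start = pos[i], end = pos[j],
            n_mutations = j - i + 1L,
            mean_imd = (pos[j] - pos[i]) / (j - i),
            idx = sel[i:j])
        }
        i <- j + 1L
      }
    }
  }
  if (!length(events)) {
    return(structure(empty, class = c("kataegis_events", "data.frame")))
  }
  out <- data.frame(
    sample = vapply(events, `[[`, character(1), "sample"),
    chrom = vapply(events, `[[`, character(1), "chrom"),
    start = vapply(events, `[[`, numeric(1), "start"),
    end = vapply(events, `[[`, numeric(1), "end"),
    n_mutations = vapply(events, `[[`, integer(1), "n_mutations"),
    mean_imd = vapply(events, `[[`, numeric(1), "mean_imd"),
    stringsAsFactors = FALSE)
  out$ig <- FALSE
  if (!is.null(ig_intervals)) {
    for (k in seq_len(nrow(ig_intervals))) {
      hit <- out$chrom == ig_intervals$chrom[k] &
        out$start <= ig_intervals$end[k] & out$end >= ig_intervals$start[k]
      out$ig <- out$ig | hit
    }
  }
  out$idx <- lapply(events, `[[`, "idx")
  structure(out, class = c("kataegis_events", "data.frame"))
}

#' Annotate kataegis events with structural-variant proximity
#'
#' For each event, the distance to the nearest SV breakpoint on the same
#' chromosome is the minimum over the event's two endpoints (0 when a
#' breakpoint falls inside the event). Events closer than `window` are
#' flagged proximal.
#'
#' @param events Result of [detect_kataegis()].
#' @param breakpoints data.frame with `chrom`, `pos` (one row per SV
#'   breakend), or a BEDPE-style table with `chrom1,pos1,chrom2,pos2`
#'   which is unrolled into breakends.
#' @param window Proximity window in bp (default 1e6).
#' @return `events` with `sv_distance` (`NA` when no same-chromosome
#'   breakpoint exists) and `sv_proximal` columns.
#' @export
annotate_sv_proximity <- function(events, breakpoints, window = 1e6) {
  if (all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(breakpoints))) {
    breakpoints <- data.frame(
      chrom = c(breakpoints$chrom1, breakpoints$chrom2),
      pos = c(breakpoints$pos1, breakpoints$pos2),
      stringsAsFactors = FALSE)
  }
  dist <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    bp <- breakpoints$pos[breakpoints$chrom == events$chrom[i]]
    if (!length(bp)) next
    inside <- bp >= events$start[i] & bp <= events$end[i]
    d <- if (any(inside)) 0 else min(pmin(abs(bp - events$start[i]),
                                          abs(bp - events$end[i])))
    dist[i] <- d
  }
  events$sv_distance <- dist
  events$sv_proximal <- !is.na(dist) & dist < window
  events
}

#' Classify the dominant mutational process of a kataegis event
#'
#' Builds the event's mini-catalog and runs [censored_fit()] with the
#' clock signatures plus the kataegis-relevant processes: canonical AID
#' (SBS84), non-canonical AID (SBS9) and APOBEC (SBS2 + SBS13, grouped).
#' The dominant process is the largest grouped exposure fraction. Events
#' below the 50-mutation guard carry a low-confidence flag.
#'
#' @param event One row of a [detect_kataegis()] result (with `idx`).
#' @param records The mutation records the events were detected in.
#' @param sigs Signature matrix containing at least SBS2, SBS9, SBS13,
#'   SBS84 plus the protected clock signatures.
#' @param ... Passed to [censored_fit()].
#' @return List of class `"kataegis_class"`: `dominant` in
#'   `{"APOBEC", "nc-AID", "c-AID", "other"}`, `fractions` (grouped),
#'   `low_confidence`, `fit`.
#' @export
classify_kataegis <- function(event, records, sigs, ...) {
  idx <- if (is.list(event$idx)) event$idx[[1]] else event$idx
  ev_rec <- records[idx, , drop = FALSE]
  if (any(is.na(ev_rec$context5) | is.na(ev_rec$context3))) {
    stop(sprintf("kataegis event %s:%d-%d has mutations without context",
                 event$chrom, event$start, event$end))
  }
  cat_ev <- build_catalog(ev_rec, resolution = nrow(sigs))
  fit <- suppressWarnings(censored_fit(cat_ev, sigs, ...))
  fr <- fit$fractions
  grp <- c(
    APOBEC = sum(fr[intersect(c("SBS2", "SBS13"), names(fr))]),
    `nc-AID` = if ("SBS9" %in% names(fr)) fr[["SBS9"]] else 0,
    `c-AID` = if ("SBS84" %in% names(fr)) fr[["SBS84"]] else 0)
  grp <- c(grp, other = max(0, 1 - sum(grp)))
  structure(list(dominant = names(grp)[which.max(grp)],
                 fractions = grp,
                 low_confidence = fit$low_confidence,
                 fit = fit),
            class = "kataegis_class")
}
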