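mk_rec <- function(pos, chrom = "chr1", sample = "s1") {
  mutation_records(chrom = chrom, pos = as.integer(pos), ref = "C",
                   alt = "T", sample = sample, context5 = "T",
                   context3 = "A")
}

test_that("detection implements the >=6 / <=1kb mean-IMD rule", {
  # 6 mutations spaced 500 bp: one event
  ev <- detect_kataegis(mk_rec(seq(1000, 3500, by = 500)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_mutations, 6L)
  expect_equal(ev$mean_imd, 500)
  expect_equal(ev$start, 1000)
  expect_equal(ev$end, 3500)

  # 5 mutations 100 bp apart: below the length floor
  expect_equal(nrow(detect_kataegis(mk_rec(seq(100, 500, by = 100)))), 0)

  # 6 mutations 1100 bp apart: mean IMD above the ceiling
  expect_equal(nrow(detect_kataegis(mk_rec(seq(0, 5500, by = 1100) + 1))), 0)
})

test_that("detection is order-invariant, idempotent, duplicate-safe", {
  pos <- c(seq(1000, 3500, by = 500), 100000, 250000)
  r <- mk_rec(pos)
  shuffled <- r[sample(nrow(r)), ]
  e1 <- detect_kataegis(r)
  e2 <- suppressMessages(detect_kataegis(shuffled))
  expect_equal(e1$start, e2$start)
  expect_equal(e1$n_mutations, e2$n_mutations)

  # duplicated positions collapse before IMD computation
  dup <- mk_rec(c(1000, 1000, 1500, 2000, 2500, 3000, 3500))
  e3 <- detect_kataegis(dup)
  expect_equal(e3$n_mutations, 6L)

  # a far-away extra mutation never removes an event
  e4 <- detect_kataegis(mk_rec(c(seq(1000, 3500, by = 500), 10000)))
  expect_equal(e4$start[1], 1000)
  expect_equal(e4$n_mutations[1], 6L)
})

test_that("mean-based rule tolerates one large gap; strict mode breaks", {
  # 7 mutations: six 100 bp apart then a 1900 bp jump; mean stays <= 1kb
  pos <- c(seq(1000, 1500, by = 100), 3400)
  loose <- detect_kataegis(mk_rec(pos))
  expect_equal(loose$n_mutations, 7L)
  # strict mode breaks at the 1900 bp gap, leaving the 6-run event
  strict <- detect_kataegis(mk_rec(pos), strict_gaps = TRUE)
  expect_equal(strict$n_mutations, 6L)
  expect_equal(strict$end, 1500)
})

test_that("events never overlap and immunoglobulin loci are flagged", {
  pos <- c(seq(1000, 3500, by = 500), seq(100000, 102500, by = 500))
  ig <- data.frame(chrom = "chr1", start = 90000, end = 110000)
  ev <- detect_kataegis(mk_rec(pos), ig_intervals = ig)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$end[-nrow(ev)] < ev$start[-1]))
  expect_equal(ev$ig, c(FALSE, TRUE))
})

test_that("SV proximity annotation measures endpoint distance", {
  ev <- detect_kataegis(mk_rec(seq(2e6, 2e6 + 2500, by = 500)))
  bp <- data.frame(chrom = c("chr1", "chr2"), pos = c(2002500 + 4e5, 100))
  out <- annotate_sv_proximity(ev, bp, window = 1e6)
  expect_equal(out$sv_distance, 4e5)
  expect_true(out$sv_proximal)

  out2 <- annotate_sv_proximity(ev, bp[2, , drop = FALSE])
  expect_true(is.na(out2$sv_distance))
  expect_false(out2$sv_proximal)

  # BEDPE-style input unrolls into breakends; inside-event distance is 0
  bedpe <- data.frame(chrom1 = "chr1", pos1 = 2e6 + 100,
                      chrom2 = "chr5", pos2 = 1)
  out3 <- annotate_sv_proximity(ev, bedpe)
  expect_equal(out3$sv_distance, 0)
})

test_that("planted clusters are found with no false events (property)", {
  set.seed(71)
  n_rep <- 25
  found <- 0; false_events <- 0
  for (rep in seq_len(n_rep)) {
    # background 1 mutation/Mb over 100 Mb + one 10-mutation cluster
    bg <- sort(sample.int(1e8, 100))
    start <- sample.int(9e7, 1)
    cluster <- start + cumsum(c(0, pmax(1, rpois(9, 100))))
    ev <- detect_kataegis(mk_rec(sort(c(bg, cluster))))
    hit <- any(ev$start <= min(cluster) + 1000 &
                 ev$end >= max(cluster) - 1000)
    if (hit) found <- found + 1
    false_events <- false_events + max(0, nrow(ev) - 1)
  }
  expect_equal(found, n_rep)      # sensitivity 1.0
  expect_equal(false_events, 0)   # no background runs qualify
})

test_that("classification identifies the generating process", {
  sim_event <- function(sig, n = 30) {
    cls <- sample(rownames(SIGS), n, replace = TRUE, prob = SIGS[, sig])
    records_from_classes(cls, pos = 5000 + cumsum(c(0, rep(100, n - 1))))
  }
  for (cs in list(c("SBS2", "APOBEC"), c("SBS13", "APOBEC"),
                  c("SBS9", "nc-AID"), c("SBS84", "c-AID"))) {
    set.seed(72)
    rec <- sim_event(cs[1], 60)
    ev <- detect_kataegis(rec)
    out <- classify_kataegis(ev[1, ], rec, SIGS)
    expect_equal(out$dominant, cs[2])
    expect_false(out$low_confidence)
  }
  # a 6-mutation event carries the low-confidence flag
  set.seed(73)
  rec6 <- sim_event("SBS2", 6)
  ev6 <- detect_kataegis(rec6)
  out6 <- classify_kataegis(ev6[1, ], rec6, SIGS)
  expect_true(out6$low_confidence)

  # contextless mutations are fatal
  rec_nc <- mk_rec(seq(1000, 3500, by = 500))
  rec_nc$context5 <- NA_character_
  ev_nc <- detect_kataegis(rec_nc)
  expect_error(classify_kataegis(ev_nc[1, ], rec_nc, SIGS), "context")
})

test_that("APOBEC enrichment near SVs is directional (cohort property)", {
  set.seed(74)
  n_apobec_prox <- 0; n_prox <- 0; n_apobec_dist <- 0; n_dist <- 0
  for (rep in 1:10) {
    bp_pos <- 5e6
    recs <- list(); where <- c()
    for (i in 1:4) {
      near <- i <= 2  # half the clusters planted near the breakpoint
      sig <- if (near) sample(c("SBS2", "SBS13"), 1) else "SBS9"
      start <- if (near) bp_pos + sample.int(2e5, 1) else
        2e7 + sample.int(5e7, 1)
      cls <- sample(rownames(SIGS), 10, replace = TRUE, prob = SIGS[, sig])
      recs[[i]] <- records_from_classes(
        cls, pos = start + cumsum(c(0, rep(100, 9))))
    }
    rec <- do.call(rbind, recs)
    rec <- rec[order(rec$pos), ]
    ev <- detect_kataegis(rec)
    ev <- annotate_sv_proximity(ev, data.frame(chrom = "chr1", pos = bp_pos))
    for (i in seq_len(nrow(ev))) {
      cl <- classify_kataegis(ev[i, ], rec, SIGS)
      apo <- cl$dominant == "APOBEC"
      if (ev$sv_proximal[i]) {
        n_prox <- n_prox + 1; n_apobec_prox <- n_apobec_prox + apo
      } else {
        n_dist <- n_dist + 1; n_apobec_dist <- n_apobec_dist + apo
      }
    }
  }
  expect_gt(n_apobec_prox / n_prox, n_apobec_dist / max(1, n_dist))
})
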