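test_that("aberration score applies the strict ploidy +/- margin rule", {
  expect_identical(aberration_score(2.61, 2, 0.6), 1L)
  expect_identical(aberration_score(2.60, 2, 0.6), 0L)  # strictly greater
  expect_identical(aberration_score(1.40, 2, 0.6), 0L)  # strictly less
  expect_identical(aberration_score(1.39, 2, 0.6), -1L)
  # non-integer ploidy, vectorized
  expect_identical(aberration_score(c(4.0, 3.3, 2.6), 3.3, 0.6),
                   c(1L, 0L, -1L))
  expect_error(aberration_score(-1, 2), "total_cn")
  expect_error(aberration_score(2, 0), "ploidy")
})

test_that("aberration score is antisymmetric around ploidy", {
  for (ploidy in c(1.8, 2, 2.7, 3.4)) {
    x <- setdiff(seq(0.05, 1.5, by = 0.05), 0.6)
    expect_identical(aberration_score(ploidy + x, ploidy, 0.6),
                     -aberration_score(pmax(0, ploidy - x), ploidy, 0.6))
  }
})

test_that("GII is the probe-weighted aberrant fraction", {
  seg <- data.frame(total_cn = c(3.0, 2.0), n_probes = c(60, 40))
  expect_equal(genomic_instability_index(seg, 2), 0.6)
  flat <- data.frame(total_cn = rep(2, 5), n_probes = rep(10, 5))
  expect_equal(genomic_instability_index(flat, 2), 0)
  wg <- data.frame(total_cn = rep(4, 3), n_probes = c(1, 2, 3))
  expect_equal(genomic_instability_index(wg, 2), 1)
  expect_error(genomic_instability_index(flat[0, ], 2), "no segments")
})

test_that("GII is invariant under segment splitting", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 8
    seg <- data.frame(total_cn = sample(c(1, 2, 3, 4), n, replace = TRUE),
                      n_probes = sample(10:100, n))
    i <- sample(n, 1)
    a <- sample(seg$n_probes[i] - 1, 1)
    split <- rbind(seg[-i, ],
                   data.frame(total_cn = seg$total_cn[i],
                              n_probes = c(a, seg$n_probes[i] - a)))
    expect_equal(genomic_instability_index(split, 2),
                 genomic_instability_index(seg, 2))
  }
})

test_that("adjusted logR matches gamma * log2(CN / ploidy)", {
  expect_equal(adjusted_logr(2, 2, 0.55), 0)
  expect_equal(adjusted_logr(4, 2, 0.55), 0.55)
  # frozen 30-digit evaluation of 0.55 * log2(1.5)
  expect_equal(adjusted_logr(3, 2, 0.55), 0.3217293753966359,
               tolerance = 1e-14)
  out <- adjusted_logr(c(0, 2), 2)
  expect_identical(attr(out, "floored"), c(TRUE, FALSE))
  expect_equal(out[1], 0.55 * log2(0.05 / 2))
  expect_error(adjusted_logr(2, 0), "ploidy")
})

test_that("adjusted logR is strictly increasing, zero only at ploidy", {
  cn <- seq(0.5, 6, by = 0.25)
  lr <- adjusted_logr(cn, 2.3)
  expect_true(all(diff(lr) > 0))
  expect_equal(sum(abs(lr) < 1e-12), 0)
  expect_equal(adjusted_logr(2.3, 2.3), 0)
})

test_that("bins take the score of the segment covering their midpoint", {
  genome <- data.frame(chrom = "1", length = 5e6)
  bins <- make_bins(genome, 1e6)
  # one segment spanning 3 bins, one gap, midpoint rule on a split bin
  seg <- make_segments("1", c(1, 3600001), c(3e6, 5e6), c(4, 2))
  sc <- bin_profile(seg, 2, bins)
  expect_identical(sc[1:3], rep(1L, 3))
  expect_true(is.na(sc[4]))  # midpoint 3.5M falls in the gap
  expect_identical(sc[5], 0L)  # bin 5 midpoint 4.5M in second segment
  # two segments split bin 4; its midpoint lies in the second
  seg2 <- make_segments("1", c(1, 3400001), c(3.4e6, 5e6), c(4, 1))
  expect_identical(bin_profile(seg2, 2, bins)[4], -1L)
})

test_that("frequencies count gains and losses among informative profiles", {
  genome <- data.frame(chrom = "1", length = 2e6)
  bins <- make_bins(genome, 1e6)
  segs <- do.call(rbind, lapply(1:10, function(i) {
    cn <- if (i <= 4) 4 else if (i == 5) 1 else 2
    make_segments("1", 1, 2e6, cn, sample_id = sprintf("S%02d", i))
  }))
  samples <- data.frame(sample_id = sprintf("S%02d", 1:10), ploidy = 2)
  fr <- aberration_frequencies(segs, samples, bins)
  expect_equal(fr$gain_pct, c(40, 40))
  expect_equal(fr$loss_pct, c(10, 10))
  expect_equal(fr$n_informative, c(10L, 10L))
  # flat cohort
  flat <- do.call(rbind, lapply(1:3, function(i)
    make_segments("1", 1, 2e6, 2, sample_id = paste0("F", i))))
  fr0 <- aberration_frequencies(flat,
                                data.frame(sample_id = paste0("F", 1:3),
                                           ploidy = 2), bins)
  expect_true(all(fr0$gain_pct == 0 & fr0$loss_pct == 0))
})

test_that("frequencies agree with a naive per-bin recount on a cohort", {
  co <- simulate_cohort(sim_config(seed = 5, n_patients = 7,
                                   genome = default_genome(6)))
  sm <- co$samples[co$samples$timepoint_weeks == 0, ]
  fr <- aberration_frequencies(co$segments, sm, co$bins)
  # independent oracle: loop over bins and samples, interval scan
  for (b in sample(nrow(co$bins), 12)) {
    gain <- 0; loss <- 0; n <- 0
    for (i in seq_len(nrow(sm))) {
      seg <- co$segments[co$segments$sample_id == sm$sample_id[i], ]
      hit <- seg[seg$chrom == co$bins$chrom[b] &
                 seg$start <= co$bins$mid[b] & seg$end >= co$bins$mid[b], ]
      if (nrow(hit) != 1) next
      n <- n + 1
      if (hit$total_cn > sm$ploidy[i] + 0.6) gain <- gain + 1
      if (hit$total_cn < sm$ploidy[i] - 0.6) loss <- loss + 1
    }
    expect_equal(fr$n_informative[b], n)
    if (n > 0) {
      expect_equal(fr$gain_pct[b], 100 * gain / n)
      expect_equal(fr$loss_pct[b], 100 * loss / n)
    }
  }
  ok <- fr$n_informative > 0
  expect_true(all(fr$gain_pct[ok] + fr$loss_pct[ok] <= 100))
})

test_that("gene logR uses the covering segment; gaps and unknown chroms are NA", {
  seg <- make_segments("1", c(1, 2000001), c(1e6, 3e6), c(4, 2))
  ann <- data.frame(gene = c("A", "B", "C"), chrom = c("1", "1", "9"),
                    start = c(1000, 1500000, 100), end = c(2000, 1500100, 200))
  expect_warning(lr <- gene_logr(seg, 2, ann), "chromosomes absent")
  expect_equal(unname(lr["A"]), 0.55)
  expect_true(is.na(lr["B"]))  # midpoint in the gap between segments
  expect_true(is.na(lr["C"]))
})

test_that("gene logR matches a brute-force interval lookup on a cohort", {
  co <- simulate_cohort(sim_config(seed = 9, n_patients = 4,
                                   genome = default_genome(5), n_genes = 40))
  sm <- co$samples[co$samples$quality == "good", ][1:3, ]
  lr <- gene_logr_matrix(co$segments, sm, co$annotation)
  for (i in seq_len(nrow(sm))) {
    seg <- co$segments[co$segments$sample_id == sm$sample_id[i], ]
    for (g in sample(nrow(co$annotation), 15)) {
      mid <- floor((co$annotation$start[g] + co$annotation$end[g]) / 2)
      hit <- seg[seg$chrom == co$annotation$chrom[g] & seg$start <= mid &
                 seg$end >= mid, ]
      if (nrow(hit) == 1) {
        expect_equal(lr[g, i],
                     0.55 * log2(max(hit$total_cn, 0.05) / sm$ploidy[i]),
                     tolerance = 1e-12)
      } else {
        expect_true(is.na(lr[g, i]))
      }
    }
  }
})
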