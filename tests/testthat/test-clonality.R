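test_that("reference selection prefers good week 0, then good week 12", {
  s <- function(q0, q12) data.frame(timepoint_weeks = c(0, 12, 25),
                                    quality = c(q0, q12, "good"))
  expect_equal(select_reference(s("good", "good")), 0)
  expect_equal(select_reference(s("poor", "good")), 12)
  expect_true(is.na(select_reference(s("poor", "poor"))))
  expect_true(is.na(select_reference(s("non_aberrant", "non_aberrant"))))
})

test_that("implied ACF inverts the normal/tumor mixture", {
  expect_equal(implied_acf(2.6, 3), 0.6)
  expect_equal(implied_acf(2.0, 3), 0)
  expect_equal(implied_acf(1.4, 1), 0.6)
  expect_equal(implied_acf(c(3.2, 0.8), c(3, 1)), c(1, 1))  # clamped
  expect_error(implied_acf(2.5, 2), "uninformative")
})

test_that("sample ACF estimation: passthrough, exact point mass, noisy mode", {
  tracked <- data.frame(chrom = "1", mid = seq(5e5, 9.5e6, by = 1e6),
                        state_total = rep(c(3, 1), 5),
                        aberration_class = rep(c("gain", "loss"), 5),
                        clonality = "clonal")
  # good profile returns its own fitted ACF untouched
  good <- data.frame(acf = 0.73, quality = "good")
  expect_equal(estimate_sample_acf(good, NULL, tracked), 0.73)
  # noise-free: all implied values coincide at the true ACF
  rho <- 0.4
  seg <- make_segments("1", seq(1, 9.1e6, by = 1e6),
                       seq(1e6, 1e7, by = 1e6),
                       2 * (1 - rho) + rho * rep(c(3, 1), 5))
  poor <- data.frame(acf = NA_real_, quality = "poor")
  expect_equal(estimate_sample_acf(poor, seg, tracked), 0.4)
  # fewer than 3 informative segments -> unknown
  expect_true(is.na(estimate_sample_acf(poor, seg, tracked[1:2, ])))
  # noisy: density mode within 0.05 of truth in >= 95% of 100 samples
  set.seed(21)
  tracked30 <- data.frame(chrom = "1", mid = seq(5e5, 29.5e6, by = 1e6),
                          state_total = rep(c(3, 1), 15),
                          aberration_class = rep(c("gain", "loss"), 15),
                          clonality = "clonal")
  hits <- replicate(100, {
    bulk <- 2 * (1 - rho) + rho * rep(c(3, 1), 15) + rnorm(30, 0, 0.05)
    seg_n <- make_segments("1", seq(1, 29.1e6, by = 1e6),
                           seq(1e6, 3e7, by = 1e6), bulk)
    abs(estimate_sample_acf(poor, seg_n, tracked30) - rho) <= 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("segment categorization keeps single-aberrant-state segments", {
  seg <- make_segments(
    "1", c(1, 1e6 + 1, 2e6 + 1, 3e6 + 1, 4e6 + 1),
    c(1e6, 2e6, 3e6, 4e6, 5e6),
    total_cn = c(3, 2, 1.6, 2, 2.5),
    minor_cn = c(1, 1, 0.6, 0, 1),
    state2_total = c(NA, NA, 2, NA, 3),
    state2_minor = c(NA, NA, 1, NA, 1),
    frac_state1 = c(NA, NA, 0.4, NA, 0.5))
  # rows: clonal gain; normal; subclonal loss (state 1 at 40%);
  # clonal LOH; subclonal mixture of two aberrant states (3 and ... ) ->
  # last row: state1 = (2.5 - 0.5*3)/0.5 = 2 total, minor (1-0.5)/0.5 = 1
  # -> normal + gain = exactly one aberrant state, kept as gain at 50%
  out <- categorize_segments(seg, ploidy = 2.1)
  expect_equal(nrow(out), 4)
  expect_equal(out$aberration_class, c("gain", "loss", "LOH", "gain"))
  expect_equal(out$clonality, c("clonal", "subclonal", "clonal", "subclonal"))
  expect_equal(out$carrier_ref, c(1, 0.4, 1, 0.5))
  expect_equal(out$state_total, c(3, 1, 2, 3))
  expect_error(categorize_segments(seg, ploidy = 3.6), "not diploid")
})

test_that("a subclonal mixture of two aberrant states is not trackable", {
  seg <- make_segments("1", 1, 1e6, total_cn = 2, minor_cn = 0.5,
                       state2_total = 3, state2_minor = 1,
                       frac_state1 = 0.5)
  # state1 = (2 - 0.5*3)/0.5 = 1 (loss), state2 = 3 (gain): both aberrant
  expect_equal(nrow(categorize_segments(seg, 2)), 0)
})

test_that("carrier fraction inversion solves the mixture at each time point", {
  expect_equal(track_cna_fraction(2.25, NA, 3, "gain", 0.5), 0.5)
  expect_equal(track_cna_fraction(2.0, NA, 3, "gain", 0.5), 0)
  expect_equal(track_cna_fraction(1.7, NA, 1, "loss", 0.6), 0.5)
  # LOH is solved on the minor-allele dimension: bulk_minor = 1 - acf*f
  expect_equal(track_cna_fraction(2, 0.75, 2, "LOH", 0.5), 0.5)
  expect_equal(track_cna_fraction(2, 1.0, 2, "LOH", 0.5), 0)
  # tumor absent -> undefined
  expect_true(is.na(track_cna_fraction(2.25, NA, 3, "gain", 0)))
  expect_true(is.na(track_cna_fraction(2.25, NA, 3, "gain", NA)))
})

test_that("change calls respect the dead zone and missing data", {
  expect_equal(call_change(0.3, 0.6, 0.05), "increase")
  expect_equal(call_change(0.6, 0.3, 0.05), "decrease")
  expect_equal(call_change(0.50, 0.52, 0.05), "unchanged")
  expect_equal(call_change(0.5, NA, 0.05), "unchanged")
  expect_equal(call_change(c(0, 1), c(1, 0), 0.05),
               c("increase", "decrease"))
})

test_that("selection statistic matches the goodness-of-fit form", {
  out <- selection_chisq(13, 0)
  expect_equal(out$chi2, 13)
  # frozen independent evaluation: erfc(sqrt(13/2)) at 30 digits
  expect_equal(out$p, 0.000311490976767384, tolerance = 1e-12)
  expect_equal(selection_chisq(5, 5)$chi2, 0)
  expect_equal(selection_chisq(5, 5)$p, 1)
  expect_true(is.na(selection_chisq(0, 0)$chi2))
  # symmetry in the counts
  expect_equal(selection_chisq(3, 11), selection_chisq(11, 3))
})

test_that("selection scan counts, tests and directs per bin and class", {
  bins <- make_bins(data.frame(chrom = "1", length = 5e6), 1e6)
  mk <- function(change, n, bin) data.frame(
    patient_id = sprintf("P%02d", seq_len(n)), ref_week = 0, week = 12,
    chrom = "1", start = bins$start[bin], end = bins$end[bin],
    mid = bins$mid[bin], aberration_class = "gain", state_total = 3,
    clonality = "subclonal", carrier_ref = 0.3, f_ref = 0.3,
    f_t = if (change == "increase") 0.6 else 0.1, change = change,
    stringsAsFactors = FALSE)
  tracking <- structure(list(tracked = rbind(mk("increase", 13, 2),
                                             mk("decrease", 4, 4))),
                        class = "cna_tracking")
  sel <- selection_scan(tracking, bins)
  expect_equal(nrow(sel), 2)
  b2 <- sel[sel$bin == 2, ]
  expect_equal(c(b2$n_increase, b2$n_decrease), c(13L, 0L))
  expect_equal(b2$chi2, 13)
  expect_equal(b2$direction, "positive")
  # swapping all increase/decrease labels flips directions, keeps p
  flipped <- tracking
  flipped$tracked$change <- ifelse(tracking$tracked$change == "increase",
                                   "decrease", "increase")
  sel2 <- selection_scan(flipped, bins)
  expect_equal(sel2$p, sel$p)
  expect_equal(sel2[sel2$bin == 2, "direction"], "negative")
  # conflicting calls from one patient/week cancel to unchanged
  confl <- structure(list(tracked = rbind(mk("increase", 1, 2),
                                          mk("decrease", 1, 2))),
                     class = "cna_tracking")
  expect_error(selection_scan(confl, bins), NA)
  expect_equal(nrow(selection_scan(confl, bins)), 0)
})

test_that("each patient contributes at most two counts per bin and class", {
  co <- simulate_cohort(sim_config(seed = 13, n_patients = 12,
                                   genome = default_genome(8), n_genes = 12))
  tr <- track_cohort(co$segments, co$samples)
  tt <- tr$tracked[tr$tracked$change != "unchanged", ]
  # per patient, bin and class: at most one informative comparison per
  # follow-up week, hence at most two overall
  key <- paste(tt$patient_id, tt$chrom, floor((tt$mid - 1) / 1e6),
               tt$aberration_class)
  expect_true(all(table(paste(key, tt$week)) <= 1))
  expect_true(all(table(key) <= 2))
})

test_that("aneuploid reference samples are excluded from tracking only", {
  co <- simulate_cohort(sim_config(seed = 31, n_patients = 8,
                                   genome = default_genome(6),
                                   frac_aneuploid = 1, n_genes = 12))
  tr <- track_cohort(co$segments, co$samples)
  expect_true(all(tr$exclusions$reason %in%
                    c("reference_not_diploid", "no_good_reference")))
  expect_true(any(tr$exclusions$reason == "reference_not_diploid"))
  expect_equal(nrow(tr$exclusions), 8)
  expect_null(tr$tracked)
})
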