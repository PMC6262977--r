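#' Choose the reference sample for a patient
#'
#' The reference for clonal tracking is the diagnosis (week 0) biopsy when its
#' copy-number fit is good; otherwise the week-12 biopsy when good; otherwise
#' the patient cannot be tracked.
#'
#' @param samples the patient's sample metadata rows (`timepoint_weeks`,
#'   `quality`).
#' @return the reference week (0 or 12), or NA if the patient is excluded.
#' @export
select_reference <- function(samples) {
  stopifnot(nrow(samples) >= 1)
  for (wk in c(0, 12)) {
    i <- which(samples$timepoint_weeks == wk)
    if (length(i) == 1 && samples$quality[i] == "good") return(wk)
  }
  NA_real_
}

#' Aberrant cell fraction implied by one clonal segment
#'
#' For a segment clonal in the reference with integer aberrant total state
#' `s != 2`, a bulk (unadjusted) copy number `b` observed in a mixture of
#' normal (2 copies) and tumor cells implies purity
#' `rho = (b - 2) / (s - 2)`, clamped to [0, 1]. Vectorized.
#'
#' @param observed_bulk_cn bulk total copy number.
#' @param aberrant_state integer total copy-number state of the tumor cells
#'   (must differ from 2).
#' @return implied ACF in [0, 1].
#' @export
#' @examples
#' implied_acf(2.6, 3)  # 0.6
#' implied_acf(1.4, 1)  # 0.6
implied_acf <- function(observed_bulk_cn, aberrant_state) {
  if (any(aberrant_state == 2))
    stop("aberrant_state = 2 is uninformative for purity")
  pmin(1, pmax(0, (observed_bulk_cn - 2) / (aberrant_state - 2)))
}

# Bulk (unadjusted) total/minor copy number of one sample's segments.
# Good-quality profiles store tumor-cell-adjusted values alongside a known
# ACF, so bulk is reconstructed; other profiles store bulk directly.
bulk_segments <- function(segments, acf, quality) {
  out <- segments
  if (identical(quality, "good") && !is.na(acf)) {
    out$bulk_total <- 2 * (1 - acf) + acf * segments$total_cn
    out$bulk_minor <- (1 - acf) * 1 + acf * segments$minor_cn
  } else {
    out$bulk_total <- segments$total_cn
    out$bulk_minor <- segments$minor_cn
  }
  out
}

#' Estimate a sample's aberrant cell fraction
#'
#' Good-quality profiles return their own fitted ACF untouched. For other
#' (non-flat) profiles the ACF is re-estimated as the main peak of the
#' density of per-segment implied ACFs over the reference sample's clonal
#' gains and losses: a Gaussian kernel with Silverman's bandwidth evaluated
#' on the grid 0.01-1.00 (step 0.01), returning the argmax. When the implied
#' values are (numerically) a single point mass the bandwidth degenerates and
#' their median is returned directly.
#'
#' @param sample_row one row of sample metadata (`acf`, `quality`).
#' @param segments the sample's segment table.
#' @param tracked_ref reference aberrations from [categorize_segments()];
#'   only clonal gains/losses inform the density.
#' @param min_segments minimum informative segments for the density route.
#'   Default 3.
#' @return estimated ACF in [0, 1], or NA when not estimable.
#' @export
estimate_sample_acf <- function(sample_row, segments, tracked_ref,
                                min_segments = 3) {
  if (identical(sample_row$quality, "good") && !is.na(sample_row$acf))
    return(sample_row$acf)
  inf <- tracked_ref[tracked_ref$clonality == "clonal" &
                     tracked_ref$aberration_class %in% c("gain", "loss"), ,
                     drop = FALSE]
  if (nrow(inf) < min_segments) return(NA_real_)
  bulk <- segment_value_at(segments, inf$chrom, inf$mid, "total_cn")
  ok <- !is.na(bulk)
  if (sum(ok) < min_segments) return(NA_real_)
  vals <- implied_acf(bulk[ok], inf$state_total[ok])
  h <- tryCatch(stats::bw.nrd0(vals), error = function(e) 0)
  if (!is.finite(h) || h < 1e-8) return(stats::median(vals))
  grid <- seq(0.01, 1.00, by = 0.01)
  dens <- vapply(grid,
                 function(g) mean(stats::dnorm((g - vals) / h)) / h,
                 numeric(1))
  grid[which.max(dens)]
}

#' Categorize reference aberrations for tracking
#'
#' On a diploid reference (ploidy below the cut), keeps segments with exactly
#' one aberrant copy-number state — clonal aberrant segments, or subclonal
#' mixtures of one aberrant and one normal (2+1) state — and classifies each
#' as gain (total state > 2), loss (total state < 2), or LOH (total state 2
#' with minor allele 0), clonal or subclonal, with its reference carrier
#' fraction (1 for clonal).
#'
#' @param segments the reference sample's segment table (tumor-adjusted
#'   values; columns `chrom`, `start`, `end`, `total_cn`, `minor_cn`, and
#'   optionally `state2_total`, `state2_minor`, `frac_state1`).
#' @param ploidy reference sample ploidy.
#' @param diploid_cut maximum ploidy treated as diploid. Default 3.
#' @return data.frame of tracked aberrations: `chrom`, `start`, `end`, `mid`,
#'   `aberration_class`, `state_total`, `state_minor`, `clonality`,
#'   `carrier_ref`.
#' @export
categorize_segments <- function(segments, ploidy, diploid_cut = 3) {
  if (ploidy >= diploid_cut)
    stop("reference sample is not diploid (ploidy >= ", diploid_cut,
         "); patient excluded from clonality tracking")
  has_sub <- if ("frac_state1" %in% names(segments)) {
    !is.na(segments$frac_state1) & segments$frac_state1 < 1 &
      !is.na(segments$state2_total)
  } else rep(FALSE, nrow(segments))
  rows <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    if (!has_sub[i]) {
      st <- round(segments$total_cn[i])
      sm <- round(segments$minor_cn[i])
      if (is.na(st) || is.na(sm) || (st == 2 && sm == 1)) next
      rows[[i]] <- data.frame(state_total = st, state_minor = sm,
                              clonality = "clonal", carrier_ref = 1)
    } else {
      f1 <- segments$frac_state1[i]
      s2t <- segments$state2_total[i]; s2m <- segments$state2_minor[i]
      s1t <- round((segments$total_cn[i] - (1 - f1) * s2t) / f1)
      s1m <- round((segments$minor_cn[i] - (1 - f1) * s2m) / f1)
      ab1 <- !(s1t == 2 && s1m == 1)
      ab2 <- !(s2t == 2 && s2m == 1)
      if (ab1 == ab2) next  # zero or two aberrant states: not trackable
      if (ab1) {
        rows[[i]] <- data.frame(state_total = s1t, state_minor = s1m,
                                clonality = "subclonal", carrier_ref = f1)
      } else {
        rows[[i]] <- data.frame(state_total = s2t, state_minor = s2m,
                                clonality = "subclonal", carrier_ref = 1 - f1)
      }
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mid = numeric(0),
                      aberration_class = character(0),
                      state_total = integer(0), state_minor = integer(0),
                      clonality = character(0), carrier_ref = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[keep])
  seg <- segments[keep, , drop = FALSE]
  out <- cbind(data.frame(chrom = as.character(seg$chrom), start = seg$start,
                          end = seg$end,
                          mid = floor((seg$start + seg$end) / 2),
                          stringsAsFactors = FALSE), out)
  out$aberration_class <- ifelse(out$state_total > 2, "gain",
                          ifelse(out$state_total < 2, "loss",
                          ifelse(out$state_minor == 0, "LOH", NA)))
  out <- out[!is.na(out$aberration_class), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "mid", "aberration_class", "state_total",
          "state_minor", "clonality", "carrier_ref")]
}

#' Carrier fraction of a tracked aberration at one time point
#'
#' Assuming the aberrant copy-number state per cell is unchanged over time,
#' the fraction `f` of tumor cells bearing the aberration solves the mixture
#' equation at that time point. For gains/losses on the total-copy dimension:
#' `bulk_total = 2 + acf * f * (state - 2)`; for copy-neutral LOH on the
#' minor-allele dimension: `bulk_minor = 1 - acf * f`. Results are clamped to
#' [0, 1]; an unknown or zero ACF (no tumor cells) yields NA. Vectorized.
#'
#' @param bulk_total,bulk_minor observed bulk copy numbers at the time point.
#' @param state_total integer aberrant total state (from the reference).
#' @param aberration_class "gain", "loss" or "LOH".
#' @param acf the sample's aberrant cell fraction at that time point.
#' @return carrier fraction in [0, 1] or NA.
#' @export
#' @examples
#' track_cna_fraction(2.25, NA, 3, "gain", 0.5)  # 0.5
track_cna_fraction <- function(bulk_total, bulk_minor, state_total,
                               aberration_class, acf) {
  n <- length(bulk_total)
  acf <- rep_len(acf, n)
  f <- rep(NA_real_, n)
  usable <- !is.na(acf) & acf > 0
  is_loh <- aberration_class == "LOH"
  i <- usable & !is_loh & !is.na(bulk_total)
  f[i] <- (bulk_total[i] - 2) / (acf[i] * (state_total[i] - 2))
  j <- usable & is_loh & !is.na(bulk_minor)
  f[j] <- (1 - bulk_minor[j]) / acf[j]
  pmin(1, pmax(0, f))
}

#' Call an increase or decrease in carrier fraction
#'
#' Relative to the reference sample, a follow-up carrier fraction is an
#' "increase" when it exceeds the reference fraction by more than `delta`, a
#' "decrease" when it falls short by more than `delta`, and "unchanged"
#' otherwise (the dead zone keeps symmetric estimation noise out of the
#' selection counts). Missing fractions are "unchanged". Vectorized.
#'
#' @param f_ref reference carrier fraction(s) in [0, 1].
#' @param f_t follow-up carrier fraction(s) in [0, 1] or NA.
#' @param delta dead-zone half-width. Default 0.05.
#' @return character vector: "increase", "decrease" or "unchanged".
#' @export
call_change <- function(f_ref, f_t, delta = 0.05) {
  stopifnot(all(f_ref >= 0 & f_ref <= 1, na.rm = TRUE),
            all(f_t >= 0 & f_t <= 1, na.rm = TRUE))
  out <- rep("unchanged", length(f_t))
  out[!is.na(f_t) & !is.na(f_ref) & (f_t - f_ref) > delta] <- "increase"
  out[!is.na(f_t) & !is.na(f_ref) & (f_ref - f_t) > delta] <- "decrease"
  out
}

#' Track clonal and subclonal aberrations across time points
#'
#' Runs the full time-course engine over a cohort: per patient, select the
#' reference sample, keep diploid references, categorize trackable
#' aberrations, estimate follow-up ACFs (own fit, density peak, or manual
#' zero-cellularity rule), back-calculate each aberration's carrier fraction
#' at each follow-up, and call increases/decreases relative to the reference.
#'
#' @param segments cohort segment table (all samples).
#' @param samples sample metadata (`sample_id`, `patient_id`,
#'   `timepoint_weeks`, `ploidy`, `acf`, `quality`, `pathologist_pct`).
#' @param config [analysis_config()].
#' @return list of class `"cna_tracking"`: `tracked` (one row per aberration
#'   per follow-up with `carrier_ref` — the Battenberg mixture fraction at
#'   the reference — plus the mixture-inversion estimates `f_ref` and `f_t`
#'   and the `change` call), `acf_estimates` (per sample), `exclusions`
#'   (per patient with reason).
#' @export
track_cohort <- function(segments, samples, config = analysis_config()) {
  patients <- unique(samples$patient_id)
  tracked_all <- list(); acf_all <- list(); excl <- list()
  for (pt in patients) {
    ps <- samples[samples$patient_id == pt, , drop = FALSE]
    ref_wk <- select_reference(ps)
    if (is.na(ref_wk)) {
      excl[[pt]] <- data.frame(patient_id = pt, reason = "no_good_reference")
      next
    }
    ref_row <- ps[ps$timepoint_weeks == ref_wk, , drop = FALSE]
    if (ref_row$ploidy >= config$diploid_ploidy_cut) {
      excl[[pt]] <- data.frame(patient_id = pt, reason = "reference_not_diploid")
      next
    }
    ref_seg <- segments[segments$sample_id == ref_row$sample_id, ,
                        drop = FALSE]
    tracked <- categorize_segments(ref_seg, ref_row$ploidy,
                                   config$diploid_ploidy_cut)
    if (nrow(tracked) == 0) {
      excl[[pt]] <- data.frame(patient_id = pt, reason = "no_trackable_cna")
      next
    }
    # carrier fractions are estimated by the same mixture inversion at every
    # time point, the reference included, so estimation noise enters both
    # sides of an increase/decrease comparison symmetrically; the Battenberg
    # mixture fraction itself only fixes the aberrant state and the
    # clonal/subclonal label
    blk_ref <- bulk_segments(ref_seg, ref_row$acf, "good")
    bt_ref <- segment_value_at(blk_ref, tracked$chrom, tracked$mid,
                               "bulk_total")
    bm_ref <- segment_value_at(blk_ref, tracked$chrom, tracked$mid,
                               "bulk_minor")
    f_ref_est <- track_cna_fraction(bt_ref, bm_ref, tracked$state_total,
                                    tracked$aberration_class, ref_row$acf)
    follow <- ps[ps$timepoint_weeks > ref_wk, , drop = FALSE]
    if (nrow(follow) == 0) {
      excl[[pt]] <- data.frame(patient_id = pt, reason = "no_followup_samples")
      next
    }
    for (k in seq_len(nrow(follow))) {
      srow <- follow[k, , drop = FALSE]
      seg_t <- segments[segments$sample_id == srow$sample_id, , drop = FALSE]
      if (identical(srow$quality, "non_aberrant")) {
        sibs <- ps[ps$sample_id != srow$sample_id, , drop = FALSE]
        acf_t <- resolve_nonaberrant_cellularity(
          "non_aberrant", srow$timepoint_weeks, srow$pathologist_pct,
          sibling_aberrant = sibs$quality != "non_aberrant")
      } else {
        acf_t <- estimate_sample_acf(srow, seg_t, tracked)
      }
      acf_all[[paste(pt, srow$timepoint_weeks)]] <-
        data.frame(sample_id = srow$sample_id, patient_id = pt,
                   timepoint_weeks = srow$timepoint_weeks, acf = acf_t,
                   route = if (identical(srow$quality, "good") &&
                               !is.na(srow$acf)) "fitted"
                           else if (identical(srow$quality, "non_aberrant"))
                             "manual" else "density_peak",
                   stringsAsFactors = FALSE)
      blk <- bulk_segments(seg_t, acf_t, srow$quality)
      bt <- segment_value_at(blk, tracked$chrom, tracked$mid, "bulk_total")
      bm <- segment_value_at(blk, tracked$chrom, tracked$mid, "bulk_minor")
      f_t <- if (is.na(acf_t) || acf_t == 0) {
        rep(NA_real_, nrow(tracked))
      } else {
        track_cna_fraction(bt, bm, tracked$state_total,
                           tracked$aberration_class, acf_t)
      }
      tracked_all[[paste(pt, srow$timepoint_weeks)]] <- data.frame(
        patient_id = pt, ref_week = ref_wk, week = srow$timepoint_weeks,
        chrom = tracked$chrom, start = tracked$start, end = tracked$end,
        mid = tracked$mid, aberration_class = tracked$aberration_class,
        state_total = tracked$state_total, clonality = tracked$clonality,
        carrier_ref = tracked$carrier_ref, f_ref = f_ref_est, f_t = f_t,
        change = call_change(f_ref_est, f_t, config$change_delta),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    tracked = if (length(tracked_all)) do.call(rbind, c(tracked_all,
                                                        make.row.names = FALSE))
              else NULL,
    acf_estimates = if (length(acf_all)) do.call(rbind, c(acf_all,
                                                  make.row.names = FALSE))
                    else NULL,
    exclusions = if (length(excl)) do.call(rbind, c(excl,
                                                    make.row.names = FALSE))
                 else data.frame(patient_id = character(0),
                                 reason = character(0))),
    class = "cna_tracking")
}

#' @export
print.cna_tracking <- function(x, ...) {
  n_pt <- if (is.null(x$tracked)) 0 else length(unique(x$tracked$patient_id))
  n_cna <- if (is.null(x$tracked)) 0 else nrow(unique(
    x$tracked[, c("patient_id", "chrom", "start")]))
  cat(sprintf("CNA tracking: %d patients, %d tracked aberrations, %d excluded\n",
              n_pt, n_cna, nrow(x$exclusions)))
  invisible(x)
}

#' Goodness-of-fit statistic for selection counts
#'
#' Under no selection, increases and decreases of a segment's carrier
#' fraction are equally likely, so with `I` increases and `D` decreases the
#' one-degree-of-freedom statistic `(I - D)^2 / (I + D)` is chi-squared
#' distributed; the p-value is the upper tail. Vectorized; `I + D = 0` gives
#' NA (uninformative).
#'
#' @param n_increase,n_decrease non-negative counts.
#' @return data.frame `chi2`, `p`.
#' @export
#' @examples
#' selection_chisq(13, 0)  # chi2 = 13, p = 3.11e-4
selection_chisq <- function(n_increase, n_decrease) {
  stopifnot(all(n_increase >= 0), all(n_decrease >= 0))
  tot <- n_increase + n_decrease
  chi2 <- ifelse(tot > 0, (n_increase - n_decrease)^2 / tot, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chi2 = chi2, p = p)
}

#' Genome scan for subclones under selection
#'
#' Sums carrier-fraction increases and decreases per genome bin and
#' aberration class across all patients' follow-up comparisons, tests each
#' informative bin with the chi-squared goodness-of-fit statistic against a
#' 50/50 expectation, and applies Benjamini-Hochberg correction within each
#' aberration class. A bin is under positive selection when increases
#' dominate at q below `alpha`, negative when decreases dominate.
#'
#' Each patient contributes at most one count per bin, class and follow-up
#' week (conflicting calls from overlapping aberrations cancel to
#' "unchanged").
#'
#' @param tracking result of [track_cohort()].
#' @param bins bin table from [make_bins()].
#' @param classes aberration classes to scan. Default gain, loss, LOH.
#' @param alpha FDR threshold for the direction call. Default 0.05.
#' @param arm optional per-patient arm labels (named character vector) to
#'   restrict the scan to one arm; default pools both arms.
#' @return data.frame `bin`, `chrom`, `start`, `end`, `class`, `n_increase`,
#'   `n_decrease`, `chi2`, `p`, `q`, `direction`.
#' @export
selection_scan <- function(tracking, bins, classes = c("gain", "loss", "LOH"),
                           alpha = 0.05, arm = NULL) {
  tr <- tracking$tracked
  if (is.null(tr) || nrow(tr) == 0) stop("nothing tracked")
  if (!is.null(arm)) tr <- tr[tr$patient_id %in% names(arm), , drop = FALSE]
  tr <- tr[tr$change %in% c("increase", "decrease") &
           tr$aberration_class %in% classes, , drop = FALSE]
  results <- list()
  bin_tab <- data.frame(chrom = bins$chrom, start = bins$start,
                        end = bins$end, bin = as.numeric(bins$bin))
  if (nrow(tr) > 0) {
    # expand each informative comparison to the bins its interval spans
    # (bin-midpoint coverage rule)
    expanded <- lapply(seq_len(nrow(tr)), function(i) {
      hit <- bins$bin[bins$chrom == tr$chrom[i] & bins$mid >= tr$start[i] &
                      bins$mid <= tr$end[i]]
      if (length(hit) == 0) return(NULL)
      data.frame(bin = hit, patient_id = tr$patient_id[i], week = tr$week[i],
                 class = tr$aberration_class[i], change = tr$change[i],
                 stringsAsFactors = FALSE)
    })
    expanded <- do.call(rbind, expanded)
  } else expanded <- NULL
  for (cl in classes) {
    ex <- if (is.null(expanded)) NULL
          else expanded[expanded$class == cl, , drop = FALSE]
    if (is.null(ex) || nrow(ex) == 0) next
    # one count per patient/week/bin; conflicting calls cancel
    key <- paste(ex$bin, ex$patient_id, ex$week, sep = "\r")
    agg <- tapply(ex$change, key, function(ch) {
      u <- unique(ch)
      if (length(u) == 1) u else "unchanged"
    })
    bin_id <- as.numeric(vapply(strsplit(names(agg), "\r"), `[`, "", 1))
    inc <- tapply(agg == "increase", bin_id, sum)
    dec <- tapply(agg == "decrease", bin_id, sum)
    ids <- as.numeric(names(inc))
    informative <- inc + dec > 0
    if (!any(informative)) next
    ids <- ids[informative]; inc <- inc[informative]; dec <- dec[informative]
    stat <- selection_chisq(inc, dec)
    q <- benjamini_hochberg(stat$p)
    direction <- rep("none", length(ids))
    direction[inc > dec & q < alpha] <- "positive"
    direction[dec > inc & q < alpha] <- "negative"
    m <- match(ids, bin_tab$bin)
    results[[cl]] <- data.frame(
      bin = ids, chrom = bin_tab$chrom[m], start = bin_tab$start[m],
      end = bin_tab$end[m], class = cl, n_increase = as.integer(inc),
      n_decrease = as.integer(dec), chi2 = stat$chi2, p = stat$p, q = q,
      direction = direction, stringsAsFactors = FALSE)
  }
  if (length(results) == 0)
    return(data.frame(bin = numeric(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      class = character(0), n_increase = integer(0),
                      n_decrease = integer(0), chi2 = numeric(0),
                      p = numeric(0), q = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(results, make.row.names = FALSE))
  out[order(out$class, out$bin), ]
}
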