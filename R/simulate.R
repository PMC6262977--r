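# Synthetic serial-biopsy cohort generator.
#
# Emulates the statistical structure of ASCAT/Battenberg-style input to the
# pipeline: per-sample segment tables mixing normal (2+1) and tumor cells,
# clonal aberrations, subclones whose carrier fractions drift (or are pushed
# by planted selection), response-dependent cellularity trajectories, flat
# profiles when the tumor disappears, and an expression matrix with a
# configurable fraction of genes linear in gene-level adjusted logR.

WEEKS <- c(0, 12, 25)

# internal generative constants (documented in the methods vignette):
# responders carry more aberrations (emulating the observed association of
# genomic instability with response), and proliferation-gene expression rises
# with the sample's true instability fraction.
.cna_rate_group_factor <- c(GR = 1.4, IR = 1.0, NR = 0.6)
.prolif_gii_slope <- 3

clamp01 <- function(x) pmin(1, pmax(0, x))

# Alternating CNA / normal-gap tiling of one sample's genome.
# cnas: data.frame chrom,start,end (bin-aligned, non-overlapping) + index col.
tile_sample_segments <- function(genome, cnas) {
  pieces <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- as.character(genome$chrom[i]); len <- genome$length[i]
    cn <- cnas[cnas$chrom == ch, , drop = FALSE]
    cn <- cn[order(cn$start), , drop = FALSE]
    bounds <- c(1, as.vector(rbind(cn$start, cn$end + 1)), len + 1)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1
    cna_id <- rep(NA_integer_, length(starts))
    if (nrow(cn) > 0) cna_id[seq(2, by = 2, length.out = nrow(cn))] <- cn$idx
    keep <- ends >= starts
    pieces[[i]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], cna_id = cna_id[keep],
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, pieces)
}

# Draw the CNA landscape of one patient. Returns a data.frame with one row
# per aberration; carrier fractions per week in f_w0/f_w12/f_w25.
draw_patient_cnas <- function(config, bins, free, base_t, base_m, group,
                              null_mode) {
  rows <- list()
  take_bins <- function(width) {
    if (length(free) == 0) return(NULL)
    b <- if (length(free) == 1) free else sample(free, 1)
    out <- b
    if (width == 2 && (b + 1) %in% free &&
        bins$chrom[b + 1] == bins$chrom[b]) out <- c(b, b + 1)
    free <<- setdiff(free, out)
    out
  }
  state_of <- function(type) {
    switch(type,
           gain1 = c(base_t + 1, base_m),
           gain2 = c(base_t + 2, base_m),
           loss  = c(base_t - 1, max(0, base_m - 1)),
           LOH   = c(base_t, 0))
  }
  add_cna <- function(type, f, kind, locus = NA_integer_, width = NULL) {
    if (is.null(width)) width <- sample(1:2, 1, prob = c(0.7, 0.3))
    bs <- take_bins(width)
    if (is.null(bs)) return(invisible(NULL))
    st <- state_of(type)
    rows[[length(rows) + 1]] <<- data.frame(
      chrom = bins$chrom[bs[1]], start = bins$start[bs[1]],
      end = bins$end[bs[length(bs)]], state_total = st[1],
      state_minor = st[2], kind = kind, f_w0 = f[1], f_w12 = f[2],
      f_w25 = f[3], locus = locus, stringsAsFactors = FALSE)
  }
  # planted selection loci (in null mode the same subclones drift neutrally)
  if (!is.null(config$selection_loci)) {
    for (l in seq_len(nrow(config$selection_loci))) {
      loc <- config$selection_loci[l, ]
      free <- setdiff(free, loc$bin)
      carried <- stats::runif(1) < loc$carrier_prob
      if (!carried) next
      if (null_mode) {
        f0 <- stats::runif(1, 0.3, 0.7)
        steps <- stats::rnorm(2, 0, config$subclone_step_sd)
        f <- clamp01(c(f0, f0 + steps[1], f0 + sum(steps)))
      } else if (loc$direction == "positive") {
        f0 <- stats::runif(1, 0.15, 0.35)
        f <- clamp01(c(f0, f0 + loc$delta, f0 + 2 * loc$delta))
      } else {
        f0 <- stats::runif(1, 0.65, 0.85)
        f <- clamp01(c(f0, f0 - loc$delta, f0 - 2 * loc$delta))
      }
      st <- state_of("gain1")
      rows[[length(rows) + 1]] <- data.frame(
        chrom = bins$chrom[loc$bin], start = bins$start[loc$bin],
        end = bins$end[loc$bin], state_total = st[1], state_minor = st[2],
        kind = "subclonal", f_w0 = f[1], f_w12 = f[2], f_w25 = f[3],
        locus = l, stringsAsFactors = FALSE)
    }
  }
  # clonal aberrations; the first four are gains/losses so the density route
  # for follow-up purity always has informative segments
  n_cl <- max(4, stats::rpois(1, config$cna_rate *
                                 .cna_rate_group_factor[[group]]))
  for (j in seq_len(n_cl)) {
    type <- if (j <= 4) sample(c("gain1", "gain2", "loss"), 1,
                               prob = c(0.5, 0.1, 0.4))
            else sample(c("gain1", "gain2", "loss", "LOH"), 1,
                        prob = c(0.35, 0.1, 0.3, 0.25))
    add_cna(type, c(1, 1, 1), "clonal")
  }
  # neutral subclones: bounded additive carrier-fraction steps
  ns <- config$n_subclones[1] +
    sample.int(config$n_subclones[2] - config$n_subclones[1] + 1, 1) - 1
  for (s in seq_len(ns)) {
    f0 <- stats::runif(1, 0.3, 0.7)
    steps <- stats::rnorm(2, 0, config$subclone_step_sd)
    f <- clamp01(c(f0, f0 + steps[1], f0 + sum(steps)))
    k <- max(1, stats::rpois(1, config$subclone_cna_rate))
    for (j in seq_len(k))
      add_cna(sample(c("gain1", "loss", "LOH"), 1, prob = c(0.45, 0.35, 0.2)),
              f, "subclonal")
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out$idx <- seq_len(nrow(out))
  out
}

#' Simulate a serial-biopsy copy-number cohort
#'
#' Generates a full synthetic cohort under the configured study conditions:
#' for each patient an arm, a response group with matching tumor sizes, a
#' clonal/subclonal aberration landscape, and up to three biopsies (weeks 0,
#' 12, 25) whose observed bulk segment copy number is the normal/tumor
#' mixture `2(1-rho) + rho(n_clonal + sum_s f_s (n_s - n_clonal))` plus
#' Gaussian noise; plus a gene annotation and an expression matrix in which a
#' configurable fraction of genes is linear in gene-level adjusted logR.
#' Ground truth (ACFs, carrier fractions, coupling) is returned for
#' parameter-recovery validation.
#'
#' @param config a [sim_config()].
#' @return list of class `"cna_cohort"` with elements `segments`, `samples`,
#'   `clinical`, `expression`, `annotation`, `bins`, `truth` (list:
#'   `patients`, `cnas`, `genes`), `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7, n_patients = 4))
#' nrow(cohort$samples)
simulate_cohort <- function(config) {
  simulate_impl(config, null_mode = FALSE)
}

#' Simulate a null cohort (no selection)
#'
#' Identical generative process to [simulate_cohort()] except that every
#' subclone's carrier fraction drifts by symmetric mean-zero steps — planted
#' selection loci included — so no locus is under selection and
#' increase/decrease counts are exchangeable under the scan's null.
#'
#' @inheritParams simulate_cohort
#' @return see [simulate_cohort()].
#' @export
simulate_null_cohort <- function(config) {
  simulate_impl(config, null_mode = TRUE)
}

simulate_impl <- function(config, null_mode) {
  stopifnot(inherits(config, "cna_sim_config"))
  set.seed(config$seed)
  bins <- make_bins(config$genome, config$bin_size)
  gamma <- 0.55
  genome_len <- sum(config$genome$length)

  seg_list <- list(); samp_list <- list(); clin_list <- list()
  truth_pt <- list(); truth_cna <- list()
  patient_cnas <- list(); patient_base <- list()

  groups <- c("GR", "IR", "NR")
  rr_range <- list(GR = c(0, 0.0976), IR = c(0.106, 0.83), NR = c(0.903, 1.6))
  pcr_prob <- c(GR = 0.67, IR = 0.05, NR = 0)

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    group <- sample(groups, 1, prob = config$response_mix)
    arm <- if (stats::runif(1) < config$arm_fraction) "combination"
           else "chemotherapy"
    rr <- stats::runif(1, rr_range[[group]][1], rr_range[[group]][2])
    size_dx <- max(26, stats::rlnorm(1, log(40), 0.25))
    size_surgery <- rr * size_dx
    pcr <- stats::runif(1) < pcr_prob[[group]]
    aneuploid <- stats::runif(1) < config$frac_aneuploid
    base_t <- if (aneuploid) 2 * config$ploidy_baseline else
      config$ploidy_baseline
    base_m <- base_t / 2
    acf_true <- clamp01(stats::rnorm(3, config$purity_means[group, ],
                                     config$purity_spread))

    cnas <- draw_patient_cnas(config, bins, bins$bin, base_t, base_m, group,
                              null_mode)
    patient_cnas[[pid]] <- cnas
    patient_base[[pid]] <- base_t
    tiles <- tile_sample_segments(config$genome,
                                  if (is.null(cnas))
                                    data.frame(chrom = character(0),
                                               start = numeric(0),
                                               end = numeric(0),
                                               idx = integer(0))
                                  else cnas)
    width <- tiles$end - tiles$start + 1

    q_wk0 <- if (stats::runif(1) < config$p_poor_reference) "poor" else "good"
    q_fup <- ifelse(stats::runif(2) < config$p_good_followup, "good", "poor")
    missing_fup <- stats::runif(2) < config$p_missing_followup
    quality <- c(q_wk0, q_fup)

    for (w in 1:3) {
      if (w > 1 && missing_fup[w - 1]) next
      wk <- WEEKS[w]
      sid <- sprintf("%s_w%02d", pid, wk)
      rho <- acf_true[w]
      f_w <- if (is.null(cnas)) numeric(0) else cnas[[paste0("f_w", wk)]]
      avg_t <- rep(base_t, nrow(tiles)); avg_m <- rep(base_m, nrow(tiles))
      covered <- !is.na(tiles$cna_id)
      if (any(covered)) {
        ci <- tiles$cna_id[covered]
        avg_t[covered] <- f_w[ci] * cnas$state_total[ci] +
          (1 - f_w[ci]) * base_t
        avg_m[covered] <- f_w[ci] * cnas$state_minor[ci] +
          (1 - f_w[ci]) * base_m
      }
      ploidy_s <- sum(avg_t * width) / genome_len
      gii_true <- sum(width[abs(avg_t - ploidy_s) > 0.6]) / genome_len
      qual <- quality[w]
      if (rho < config$nonaberrant_acf) qual <- "non_aberrant"

      if (qual == "non_aberrant") {
        # tumor signal below detectability: flat bulk profile
        flat <- data.frame(chrom = as.character(config$genome$chrom),
                           start = 1, end = config$genome$length,
                           stringsAsFactors = FALSE)
        nb <- nrow(flat)
        bt <- 2 + stats::rnorm(nb, 0, config$noise_sd)
        bm <- 1 + stats::rnorm(nb, 0, config$noise_sd / 2)
        seg_list[[sid]] <- data.frame(
          sample_id = sid, chrom = flat$chrom, start = flat$start,
          end = flat$end,
          n_probes = pmax(1, round(config$genome$length / 1e6 *
                                     config$probes_per_mb)),
          total_cn = pmax(0, bt), minor_cn = pmax(0, pmin(bm, bt)),
          state2_total = NA_real_, state2_minor = NA_real_,
          frac_state1 = NA_real_, stringsAsFactors = FALSE)
        samp_list[[sid]] <- data.frame(
          sample_id = sid, patient_id = pid, timepoint_weeks = wk,
          ploidy = 2, acf = NA_real_, quality = "non_aberrant",
          pathologist_pct = 0, stringsAsFactors = FALSE)
      } else {
        bulk_t <- 2 * (1 - rho) + rho * avg_t +
          stats::rnorm(nrow(tiles), 0, config$noise_sd)
        bulk_m <- (1 - rho) + rho * avg_m +
          stats::rnorm(nrow(tiles), 0, config$noise_sd / 2)
        bulk_t <- pmax(0, bulk_t)
        bulk_m <- pmax(0, pmin(bulk_m, bulk_t))
        if (qual == "good") {
          tot <- pmax(0, (bulk_t - 2 * (1 - rho)) / rho)
          mino <- pmax(0, (bulk_m - (1 - rho)) / rho)
          mino <- pmin(mino, tot)
          acf_rec <- rho
        } else {
          tot <- bulk_t; mino <- bulk_m
          acf_rec <- NA_real_
        }
        if (any(covered)) {
          ci <- tiles$cna_id
          fseg <- rep(NA_real_, nrow(tiles))
          fseg[covered] <- f_w[ci[covered]]
          sub <- covered & !is.na(fseg) & fseg > 0 & fseg < 1 &
            qual == "good"
        } else {
          fseg <- rep(NA_real_, nrow(tiles))
          sub <- rep(FALSE, nrow(tiles))
        }
        seg_list[[sid]] <- data.frame(
          sample_id = sid, chrom = tiles$chrom, start = tiles$start,
          end = tiles$end,
          n_probes = pmax(1, round(width / 1e6 * config$probes_per_mb)),
          total_cn = tot, minor_cn = mino,
          state2_total = ifelse(sub, base_t, NA_real_),
          state2_minor = ifelse(sub, base_m, NA_real_),
          frac_state1 = ifelse(sub, fseg, NA_real_),
          stringsAsFactors = FALSE)
        samp_list[[sid]] <- data.frame(
          sample_id = sid, patient_id = pid, timepoint_weeks = wk,
          ploidy = ploidy_s, acf = acf_rec, quality = qual,
          pathologist_pct = round(100 * rho), stringsAsFactors = FALSE)
      }
      samp_list[[sid]]$gii_true <- gii_true
    }

    clin_list[[pid]] <- data.frame(
      patient_id = pid, arm = arm, size_dx = size_dx,
      size_surgery = size_surgery, pcr = pcr, stringsAsFactors = FALSE)
    truth_pt[[pid]] <- data.frame(
      patient_id = pid, group = group, arm = arm, rr = rr, pcr = pcr,
      aneuploid = aneuploid, base_ploidy = base_t, acf_w0 = acf_true[1],
      acf_w12 = acf_true[2], acf_w25 = acf_true[3], stringsAsFactors = FALSE)
    if (!is.null(cnas))
      truth_cna[[pid]] <- cbind(data.frame(patient_id = pid,
                                           stringsAsFactors = FALSE),
                                cnas[, c("chrom", "start", "end",
                                         "state_total", "state_minor", "kind",
                                         "f_w0", "f_w12", "f_w25", "locus")])
  }

  segments <- do.call(rbind, c(seg_list, make.row.names = FALSE))
  samples <- do.call(rbind, c(samp_list, make.row.names = FALSE))
  gii_true_by_sample <- stats::setNames(samples$gii_true, samples$sample_id)
  samples$gii_true <- NULL
  clinical <- do.call(rbind, c(clin_list, make.row.names = FALSE))
  truth <- list(patients = do.call(rbind, c(truth_pt,
                                            make.row.names = FALSE)),
                cnas = if (length(truth_cna))
                  do.call(rbind, c(truth_cna, make.row.names = FALSE))
                  else NULL)

  # ---- gene annotation & expression -------------------------------------
  prolif <- c("CCNB1", "UBE2C", "BIRC5", "NDC80", "CDC20", "PTTG1", "RRM2",
              "MKI67", "TYMS", "CEP55", "NUF2")
  ng <- max(config$n_genes, length(prolif))
  gene_names <- c(prolif, sprintf("GENE%03d", seq_len(ng - length(prolif))))
  gbin <- sample(bins$bin, ng, replace = TRUE)
  annotation <- data.frame(gene = gene_names, chrom = bins$chrom[gbin],
                           start = bins$mid[gbin] - 500,
                           end = bins$mid[gbin] + 499,
                           stringsAsFactors = FALSE)
  coupled <- rep(FALSE, ng)
  coupled[sample(ng, round(config$expr_coupling_fraction * ng))] <- TRUE
  base_expr <- stats::rnorm(ng, 7, 1)

  # true tumor-cell logR per gene and sample (noise-free, from the drawn
  # aberration landscape)
  logr_true <- matrix(0, ng, nrow(samples),
                      dimnames = list(gene_names, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    pid <- samples$patient_id[i]
    wk <- samples$timepoint_weeks[i]
    cnas <- patient_cnas[[pid]]
    base_t <- patient_base[[pid]]
    avg <- rep(base_t, ng)
    if (!is.null(cnas)) {
      f_w <- cnas[[paste0("f_w", wk)]]
      gmid <- bins$mid[gbin]
      gchr <- bins$chrom[gbin]
      for (k in seq_len(nrow(cnas))) {
        hit <- gchr == cnas$chrom[k] & gmid >= cnas$start[k] &
          gmid <= cnas$end[k]
        if (any(hit))
          avg[hit] <- f_w[k] * cnas$state_total[k] + (1 - f_w[k]) * base_t
      }
    }
    ploidy_s <- samples$ploidy[i]
    if (samples$quality[i] == "non_aberrant") ploidy_s <- base_t
    logr_true[, i] <- gamma * log2(pmax(avg, 0.05) / ploidy_s)
  }

  expression <- base_expr + config$expr_slope * logr_true *
    matrix(coupled, ng, nrow(samples)) +
    matrix(stats::rnorm(ng * nrow(samples), 0, config$expr_noise_sd), ng)
  # tumor-free biopsies express normal tissue, not tumor copy number
  flat_cols <- samples$quality == "non_aberrant"
  if (any(flat_cols))
    expression[, flat_cols] <- base_expr +
      matrix(stats::rnorm(ng * sum(flat_cols), 0, config$expr_noise_sd), ng)
  # proliferation genes track instability
  expression[seq_along(prolif), ] <-
    expression[seq_along(prolif), , drop = FALSE] +
    rep(.prolif_gii_slope * gii_true_by_sample[samples$sample_id],
        each = length(prolif))
  dimnames(expression) <- list(gene_names, samples$sample_id)

  # expected filter-scale correlation, from the realized week-0 logR spread
  wk0 <- samples$sample_id[samples$timepoint_weeks == 0 &
                           samples$quality == "good"]
  sd0 <- apply(logr_true[, wk0, drop = FALSE], 1, stats::sd)
  r_true <- ifelse(coupled & sd0 > 0,
                   config$expr_slope * sd0 /
                     sqrt(config$expr_slope^2 * sd0^2 +
                          config$expr_noise_sd^2),
                   0)
  truth$genes <- data.frame(gene = gene_names, coupled = coupled,
                            slope = ifelse(coupled, config$expr_slope, 0),
                            sd_logr_w0 = sd0, r_true = r_true,
                            stringsAsFactors = FALSE)

  structure(list(segments = segments, samples = samples, clinical = clinical,
                 expression = expression, annotation = annotation,
                 bins = bins, truth = truth, config = config,
                 null_cohort = null_mode),
            class = "cna_cohort")
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d samples, %d segments, %d genes%s\n",
              nrow(x$truth$patients), nrow(x$samples), nrow(x$segments),
              nrow(x$annotation), if (x$null_cohort) " (null cohort)" else ""))
  invisible(x)
}
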