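#' Analysis configuration
#'
#' Bundles the tunable thresholds of the copy-number time-course analysis.
#' Defaults reproduce the published analysis settings: segments are called
#' gained/lost when total copy number deviates from sample ploidy by more than
#' 0.6 copies, adjusted log-ratios are compressed by the array-noise factor
#' gamma = 0.55, genes enter differential testing only when their adjusted
#' logR correlates with mRNA expression at Pearson r >= 0.5, and response
#' groups are cut at shrinkage ratios 0.10 (good response) and 0.90
#' (no response).
#'
#' @param aberration_margin copies above/below ploidy beyond which a segment
#'   is called gained/lost (strict inequality). Default 0.6.
#' @param gamma array-noise factor multiplying log2(CN / ploidy). Default 0.55.
#' @param expr_corr_threshold minimum Pearson correlation between gene-level
#'   adjusted logR and mRNA expression for a gene to be retained. Default 0.5.
#' @param change_delta minimum carrier-fraction change (dead zone) for an
#'   increase/decrease call when tracking subclones. Default 0.05.
#' @param rr_gr_cut response-ratio below which a patient is a good responder
#'   (GR; > 90 percent shrinkage). Default 0.10.
#' @param rr_nr_cut response-ratio above which a patient is a non-responder
#'   (NR; < 10 percent shrinkage). Default 0.90.
#' @param diploid_ploidy_cut reference samples with ploidy below this are
#'   treated as diploid and eligible for clonal/subclonal tracking. Default 3.
#' @param fdr_alpha Benjamini-Hochberg FDR threshold. Default 0.05.
#' @param cn_floor copy number substituted for zero before the log transform
#'   (keeps logR finite; flagged in output). Default 0.05.
#' @param welch use Welch's t-test instead of the classic pooled-variance
#'   Student test. Default FALSE.
#' @param filter_timepoint week whose samples feed the expression-correlation
#'   filter and the differential test (0 = diagnosis). Default 0.
#' @param proliferation_genes genes averaged into the proliferation score.
#'   Default: the 11 proliferation genes of the PAM50 signature, with the
#'   NDC80 partner gene given as "NUF2".
#' @return A list of class `"cna_analysis_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$gamma
analysis_config <- function(aberration_margin = 0.6,
                            gamma = 0.55,
                            expr_corr_threshold = 0.5,
                            change_delta = 0.05,
                            rr_gr_cut = 0.10,
                            rr_nr_cut = 0.90,
                            diploid_ploidy_cut = 3.0,
                            fdr_alpha = 0.05,
                            cn_floor = 0.05,
                            welch = FALSE,
                            filter_timepoint = 0,
                            proliferation_genes = c("CCNB1", "UBE2C", "BIRC5",
                                                    "NDC80", "CDC20", "PTTG1",
                                                    "RRM2", "MKI67", "TYMS",
                                                    "CEP55", "NUF2")) {
  stopifnot(is.numeric(aberration_margin), length(aberration_margin) == 1,
            aberration_margin > 0, aberration_margin < 1)
  stopifnot(is.numeric(gamma), gamma > 0)
  stopifnot(expr_corr_threshold > 0, expr_corr_threshold < 1)
  stopifnot(change_delta >= 0, change_delta < 1)
  stopifnot(rr_gr_cut > 0, rr_nr_cut < Inf, rr_gr_cut < rr_nr_cut)
  stopifnot(diploid_ploidy_cut > 0)
  stopifnot(fdr_alpha > 0, fdr_alpha < 1)
  stopifnot(cn_floor > 0)
  stopifnot(is.logical(welch), length(welch) == 1)
  stopifnot(is.character(proliferation_genes), length(proliferation_genes) >= 1)
  structure(list(aberration_margin = aberration_margin,
                 gamma = gamma,
                 expr_corr_threshold = expr_corr_threshold,
                 change_delta = change_delta,
                 rr_gr_cut = rr_gr_cut,
                 rr_nr_cut = rr_nr_cut,
                 diploid_ploidy_cut = diploid_ploidy_cut,
                 fdr_alpha = fdr_alpha,
                 cn_floor = cn_floor,
                 welch = welch,
                 filter_timepoint = filter_timepoint,
                 proliferation_genes = proliferation_genes),
            class = "cna_analysis_config")
}

#' @export
print.cna_analysis_config <- function(x, ...) {
  cat("Copy-number analysis configuration\n")
  cat(sprintf("  aberration margin : +/- %.2f copies around ploidy\n",
              x$aberration_margin))
  cat(sprintf("  gamma (logR)      : %.2f\n", x$gamma))
  cat(sprintf("  expression filter : Pearson r >= %.2f (week %d)\n",
              x$expr_corr_threshold, x$filter_timepoint))
  cat(sprintf("  response cuts     : GR < %.2f, NR > %.2f\n",
              x$rr_gr_cut, x$rr_nr_cut))
  cat(sprintf("  change dead zone  : %.2f; FDR alpha %.2f\n",
              x$change_delta, x$fdr_alpha))
  invisible(x)
}

#' Default miniature genome
#'
#' A desk-scale genome used by the synthetic-cohort generator: `n_chrom`
#' chromosomes of `chrom_length` bp each. Real genome coordinates can be
#' supplied instead wherever a genome table is accepted.
#'
#' @param n_chrom number of chromosomes. Default 22.
#' @param chrom_length length of each chromosome in bp. Default 1e7.
#' @return data.frame with columns `chrom`, `length`.
#' @export
default_genome <- function(n_chrom = 22, chrom_length = 1e7) {
  data.frame(chrom = as.character(seq_len(n_chrom)),
             length = rep(as.numeric(chrom_length), n_chrom),
             stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative conditions of a synthetic serial-biopsy cohort:
#' trial design (arms, response-group mix, three biopsies at weeks 0/12/25),
#' per-group tumor-cellularity trajectories, clonal and subclonal aberration
#' rates, planted selection loci, measurement noise, and expression coupling.
#'
#' The response mix defaults to the trial proportions 33:68:22 (GR:IR:NR).
#' Cellularity trajectories emulate the observed treatment course: good
#' responders lose their aberrant cell fraction almost entirely by week 25
#' while non-responders retain most of theirs.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_patients number of patients (>= 1).
#' @param genome data.frame `chrom`,`length` (see [default_genome()]).
#' @param bin_size genome bin width in bp (> 0). Default 1e6.
#' @param arm_fraction probability of assignment to the combination arm.
#' @param response_mix probabilities of GR/IR/NR; must sum to 1.
#' @param purity_means 3x3 matrix (rows GR/IR/NR, cols weeks 0/12/25) of mean
#'   aberrant cell fractions.
#' @param purity_spread s.d. of the per-sample ACF draw around its group mean.
#' @param ploidy_baseline tumor ploidy of diploid patients. Default 2.
#' @param frac_aneuploid fraction of patients simulated as genome-doubled
#'   (ploidy ~ 4; excluded from clonality tracking downstream). Default 0.1.
#' @param n_subclones integer range (length-2) of subclones per tumor.
#' @param cna_rate expected clonal aberrations per genome.
#' @param subclone_cna_rate expected aberrations per subclone.
#' @param subclone_step_sd s.d. of the neutral per-interval carrier-fraction
#'   step (mean-zero Gaussian, clamped to [0,1]).
#' @param selection_loci NULL or data.frame with columns `bin` (1-based index
#'   into the genome bin grid), `direction` ("positive"/"negative"), `delta`
#'   (carrier-fraction change per treatment interval), `carrier_prob`
#'   (probability a patient carries the planted subclone).
#' @param noise_sd s.d. of Gaussian noise on observed bulk total copy number
#'   (half that on the minor allele). Default 0.05.
#' @param p_good_followup probability a follow-up biopsy has a good
#'   purity/ploidy fit of its own (otherwise its ACF must be re-estimated from
#'   the reference segments).
#' @param p_poor_reference probability the week-0 biopsy is unusable, pushing
#'   reference selection to week 12.
#' @param p_missing_followup probability a follow-up biopsy was not obtained.
#' @param nonaberrant_acf ACF below which a sample presents as a flat
#'   ("non-aberrant") profile with pathologist tumor percent 0.
#' @param probes_per_mb SNP-array probes per Mb. Default 100.
#' @param n_genes genes in the annotation/expression matrix. Default 200.
#' @param expr_coupling_fraction fraction of genes whose expression is linear
#'   in gene-level adjusted logR.
#' @param expr_slope expression units per logR unit for coupled genes.
#' @param expr_noise_sd s.d. of expression noise.
#' @return A list of class `"cna_sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_patients = 5)
sim_config <- function(seed = 1L,
                       n_patients = 20L,
                       genome = default_genome(),
                       bin_size = 1e6,
                       arm_fraction = 0.5,
                       response_mix = c(GR = 33, IR = 68, NR = 22) / 123,
                       purity_means = rbind(GR = c(0.65, 0.30, 0.00),
                                            IR = c(0.65, 0.45, 0.25),
                                            NR = c(0.65, 0.55, 0.50)),
                       purity_spread = 0.05,
                       ploidy_baseline = 2,
                       frac_aneuploid = 0.1,
                       n_subclones = c(1L, 3L),
                       cna_rate = 10,
                       subclone_cna_rate = 2,
                       subclone_step_sd = 0.15,
                       selection_loci = NULL,
                       noise_sd = 0.05,
                       p_good_followup = 0.7,
                       p_poor_reference = 0.05,
                       p_missing_followup = 0.05,
                       nonaberrant_acf = 0.05,
                       probes_per_mb = 100,
                       n_genes = 200L,
                       expr_coupling_fraction = 0.5,
                       expr_slope = 2,
                       expr_noise_sd = 0.3) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (bin_size <= 0) stop("bin_size must be positive")
  if (bin_size * probes_per_mb / 1e6 < 1)
    stop("bins smaller than one probe are not allowed")
  if (abs(sum(response_mix) - 1) > 1e-8) stop("response_mix must sum to 1")
  stopifnot(all(response_mix >= 0))
  stopifnot(arm_fraction >= 0, arm_fraction <= 1)
  stopifnot(all(purity_means >= 0), all(purity_means <= 1),
            nrow(purity_means) == 3, ncol(purity_means) == 3)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(purity_spread >= 0, subclone_step_sd >= 0, expr_noise_sd >= 0)
  stopifnot(expr_coupling_fraction >= 0, expr_coupling_fraction <= 1)
  stopifnot(p_good_followup >= 0, p_good_followup <= 1)
  stopifnot(length(n_subclones) == 2, n_subclones[1] >= 0,
            n_subclones[2] >= n_subclones[1])
  if (!is.null(selection_loci)) {
    stopifnot(is.data.frame(selection_loci),
              all(c("bin", "direction", "delta") %in% names(selection_loci)),
              all(selection_loci$direction %in% c("positive", "negative")))
    if (is.null(selection_loci$carrier_prob))
      selection_loci$carrier_prob <- 1
    stopifnot(all(selection_loci$carrier_prob >= 0),
              all(selection_loci$carrier_prob <= 1))
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 genome = genome, bin_size = bin_size,
                 arm_fraction = arm_fraction,
                 response_mix = response_mix, purity_means = purity_means,
                 purity_spread = purity_spread,
                 ploidy_baseline = ploidy_baseline,
                 frac_aneuploid = frac_aneuploid,
                 n_subclones = as.integer(n_subclones),
                 cna_rate = cna_rate, subclone_cna_rate = subclone_cna_rate,
                 subclone_step_sd = subclone_step_sd,
                 selection_loci = selection_loci,
                 noise_sd = noise_sd,
                 p_good_followup = p_good_followup,
                 p_poor_reference = p_poor_reference,
                 p_missing_followup = p_missing_followup,
                 nonaberrant_acf = nonaberrant_acf,
                 probes_per_mb = probes_per_mb,
                 n_genes = as.integer(n_genes),
                 expr_coupling_fraction = expr_coupling_fraction,
                 expr_slope = expr_slope,
                 expr_noise_sd = expr_noise_sd),
            class = "cna_sim_config")
}

#' @export
print.cna_sim_config <- function(x, ...) {
  cat("Synthetic serial-biopsy cohort configuration\n")
  cat(sprintf("  %d patients, %d chromosomes x %.0f Mb, %.0f kb bins\n",
              x$n_patients, nrow(x$genome), mean(x$genome$length) / 1e6,
              x$bin_size / 1e3))
  cat(sprintf("  clonal CNA rate %.1f, subclones %d-%d, noise sd %.3f\n",
              x$cna_rate, x$n_subclones[1], x$n_subclones[2], x$noise_sd))
  if (!is.null(x$selection_loci))
    cat(sprintf("  %d planted selection locus/loci\n", nrow(x$selection_loci)))
  invisible(x)
}
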