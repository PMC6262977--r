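# Shared fixture builders. All fixtures are constructed in code; no files.

# A deterministic, noise-free simulation configuration: every biopsy present,
# every week-0 profile good, no aneuploid patients.
noise_free_config <- function(seed = 1, n_patients = 6, ...) {
  sim_config(seed = seed, n_patients = n_patients, noise_sd = 0,
             purity_spread = 0, p_poor_reference = 0, p_missing_followup = 0,
             frac_aneuploid = 0, ...)
}

# Minimal single-sample segment table (clonal unless state2/frac given).
make_segments <- function(chrom, start, end, total_cn, minor_cn = NULL,
                          n_probes = NULL, state2_total = NA_real_,
                          state2_minor = NA_real_, frac_state1 = NA_real_,
                          sample_id = "S1") {
  n <- length(start)
  if (is.null(minor_cn)) minor_cn <- pmin(1, total_cn)
  if (is.null(n_probes)) n_probes <- round((end - start + 1) / 1e4)
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             start = start, end = end, n_probes = pmax(1, n_probes),
             total_cn = total_cn, minor_cn = minor_cn,
             state2_total = rep_len(state2_total, n),
             state2_minor = rep_len(state2_minor, n),
             frac_state1 = rep_len(frac_state1, n),
             stringsAsFactors = FALSE)
}

# Match tracked rows to ground-truth aberrations; returns a data.frame with
# the recovered and true carrier fractions at the tracked week.
match_tracked_truth <- function(tracking, truth_cnas) {
  tt <- tracking$tracked
  key_t <- paste(tt$patient_id, tt$chrom, tt$start)
  key_g <- paste(truth_cnas$patient_id, truth_cnas$chrom, truth_cnas$start)
  m <- match(key_t, key_g)
  data.frame(tt,
             f_true = ifelse(tt$week == 12, truth_cnas$f_w12[m],
                             truth_cnas$f_w25[m]),
             f_true_ref = truth_cnas$f_w0[m])
}

# True follow-up ACF table keyed like tracking$acf_estimates.
match_acf_truth <- function(tracking, truth_patients) {
  ae <- tracking$acf_estimates
  m <- match(ae$patient_id, truth_patients$patient_id)
  ae$acf_true <- ifelse(ae$timepoint_weeks == 12,
                        truth_patients$acf_w12[m],
                        truth_patients$acf_w25[m])
  ae
}
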