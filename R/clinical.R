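#' Response ratio
#'
#' Tumor size at surgery divided by tumor size at diagnosis. Vectorized.
#'
#' @param size_dx tumor diameter at diagnosis (> 0).
#' @param size_surgery tumor diameter at surgery (>= 0; 0 means complete
#'   radiological disappearance).
#' @return response ratio(s), >= 0.
#' @export
#' @examples
#' response_ratio(40, 0)   # 0
#' response_ratio(40, 94)  # 2.35
response_ratio <- function(size_dx, size_surgery) {
  if (any(size_dx <= 0)) stop("size_dx must be > 0")
  if (any(size_surgery < 0)) stop("size_surgery must be >= 0")
  size_surgery / size_dx
}

#' Three-group response classification
#'
#' Good response (GR) when shrinkage exceeds 90% (ratio strictly below the GR
#' cut), no response (NR) when shrinkage is under 10% (ratio strictly above
#' the NR cut), intermediate (IR) otherwise; ratios exactly at a cut are IR.
#' Vectorized.
#'
#' @param rr response ratio(s), >= 0.
#' @param gr_cut GR boundary. Default 0.10.
#' @param nr_cut NR boundary. Default 0.90.
#' @return factor with levels GR, IR, NR.
#' @export
#' @examples
#' classify_response(c(0.0976, 0.5, 0.903))  # GR IR NR
classify_response <- function(rr, gr_cut = 0.10, nr_cut = 0.90) {
  if (any(rr < 0, na.rm = TRUE)) stop("response ratio must be >= 0")
  out <- rep("IR", length(rr))
  out[rr < gr_cut] <- "GR"
  out[rr > nr_cut] <- "NR"
  out[is.na(rr)] <- NA
  factor(out, levels = c("GR", "IR", "NR"))
}

#' Manual cellularity call for non-aberrant profiles
#'
#' Purity fitting needs enough aberrant DNA; samples without it come back
#' "non-aberrant" and their tumor cell fraction must be resolved manually:
#' a flat profile with a pathologist estimate of 0% tumor cells gets ACF 0;
#' a non-aberrant profile at week 0 or 12 while other time points are
#' aberrant is considered unknown (NA); otherwise unknown.
#'
#' @param quality quality flag of the sample; must be `"non_aberrant"`.
#' @param timepoint_weeks the sample's time point (0, 12 or 25).
#' @param pathologist_pct pathologist tumor percent for the sample (NA if
#'   unavailable).
#' @param sibling_aberrant logical vector: are the patient's other time
#'   points aberrant?
#' @return ACF 0 or NA (unknown).
#' @export
resolve_nonaberrant_cellularity <- function(quality, timepoint_weeks,
                                            pathologist_pct,
                                            sibling_aberrant = logical(0)) {
  if (!identical(quality, "non_aberrant"))
    stop("resolve_nonaberrant_cellularity applies only to non-aberrant profiles")
  if (!is.na(pathologist_pct) && pathologist_pct == 0)
    return(0)
  if (timepoint_weeks %in% c(0, 12) && any(sibling_aberrant))
    return(NA_real_)
  NA_real_
}

#' Proliferation score
#'
#' Per-sample arithmetic mean of the normalized expression of a proliferation
#' gene list; the default list is the 11 proliferation genes of the PAM50
#' signature (with the NDC80-partner gene supplied as NUF2; the list is
#' configurable so an alternative symbol can be used).
#'
#' @param expression genes x samples numeric matrix with rownames.
#' @param genes gene symbols to average. Default: PAM50 proliferation genes.
#' @return named numeric vector, one score per sample (column).
#' @export
#' @examples
#' m <- matrix(2, nrow = 11, ncol = 3,
#'             dimnames = list(analysis_config()$proliferation_genes, NULL))
#' proliferation_score(m)  # 2 2 2
proliferation_score <- function(expression,
                                genes = analysis_config()$proliferation_genes) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  present <- intersect(genes, rownames(expression))
  if (length(present) == 0)
    stop("none of the proliferation genes are present in the matrix")
  missing <- setdiff(genes, present)
  if (length(missing) > 0)
    warning("proliferation genes absent from matrix: ",
            paste(missing, collapse = ", "))
  colMeans(expression[present, , drop = FALSE], na.rm = TRUE)
}

#' Build the clinical table for a cohort
#'
#' Derives response ratio and response group from the recorded tumor sizes,
#' validating any pre-existing columns against the derivation.
#'
#' @param clinical data.frame with `patient_id`, `arm`, `size_dx`,
#'   `size_surgery`, `pcr`.
#' @param config [analysis_config()].
#' @return the clinical data.frame with `rr` and `response_group` filled in.
#' @export
derive_response <- function(clinical, config = analysis_config()) {
  clinical$rr <- response_ratio(clinical$size_dx, clinical$size_surgery)
  clinical$response_group <- classify_response(clinical$rr, config$rr_gr_cut,
                                               config$rr_nr_cut)
  clinical
}
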