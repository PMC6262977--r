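#' Aberration score of a segment
#'
#' Classifies total copy number relative to sample ploidy: `+1` (gain, also
#' covering amplification — the two are one event) when strictly greater than
#' `ploidy + margin`, `-1` (deletion) when strictly less than
#' `ploidy - margin`, else `0`. Vectorized over `total_cn`.
#'
#' @param total_cn tumor-adjusted total copy number (>= 0); NA propagates.
#' @param ploidy sample ploidy (> 0).
#' @param margin copies of tolerance around ploidy. Default 0.6.
#' @return integer vector in {-1, 0, +1}.
#' @export
#' @examples
#' aberration_score(c(2.61, 2.60, 1.39), ploidy = 2)  # +1, 0, -1
aberration_score <- function(total_cn, ploidy, margin = 0.6) {
  if (any(total_cn < 0, na.rm = TRUE)) stop("total_cn must be >= 0")
  if (any(ploidy <= 0)) stop("ploidy must be > 0")
  if (margin <= 0) stop("margin must be > 0")
  score <- integer(length(total_cn))
  score[total_cn > ploidy + margin] <- 1L
  score[total_cn < ploidy - margin] <- -1L
  score[is.na(total_cn)] <- NA_integer_
  score
}

#' Genomic instability index
#'
#' Fraction of probes across the genome whose segment copy number deviates
#' from sample ploidy (by more than `margin` copies, the same rule used for
#' the segment aberration score). Probe counts are the weighting unit.
#'
#' @param segments data.frame with columns `total_cn` and `n_probes`.
#' @param ploidy sample ploidy.
#' @param margin aberration margin. Default 0.6.
#' @return GII in [0, 1].
#' @export
#' @examples
#' seg <- data.frame(total_cn = c(3, 2), n_probes = c(60, 40))
#' genomic_instability_index(seg, ploidy = 2)  # 0.6
genomic_instability_index <- function(segments, ploidy, margin = 0.6) {
  stopifnot(is.data.frame(segments),
            all(c("total_cn", "n_probes") %in% names(segments)))
  keep <- !is.na(segments$total_cn) & !is.na(segments$n_probes)
  segments <- segments[keep, , drop = FALSE]
  if (nrow(segments) == 0) stop("profile has no segments with probe counts")
  if (any(segments$n_probes < 1)) stop("n_probes must be >= 1")
  score <- aberration_score(segments$total_cn, ploidy, margin)
  sum(segments$n_probes[score != 0]) / sum(segments$n_probes)
}

#' Purity/ploidy-adjusted log ratio
#'
#' Total copy number divided by sample ploidy, log2-transformed and compressed
#' by the array-noise factor gamma: `gamma * log2(total_cn / ploidy)`. A zero
#' copy number is floored at `cn_floor` before the log so the result stays
#' finite; such values carry attribute `"floored"`.
#'
#' @param total_cn tumor-adjusted total copy number (vectorized).
#' @param ploidy sample ploidy (> 0).
#' @param gamma array-noise factor. Default 0.55.
#' @param cn_floor substitute for zero copies. Default 0.05.
#' @return numeric vector of adjusted logR values; attribute `floored` is a
#'   logical vector marking floored entries when any occurred.
#' @export
#' @examples
#' adjusted_logr(c(2, 4, 3), ploidy = 2)  # 0, 0.55, 0.55*log2(1.5)
adjusted_logr <- function(total_cn, ploidy, gamma = 0.55, cn_floor = 0.05) {
  if (any(ploidy <= 0)) stop("ploidy must be > 0")
  if (any(total_cn < 0, na.rm = TRUE)) stop("total_cn must be >= 0")
  floored <- !is.na(total_cn) & total_cn <= 0
  cn <- ifelse(floored, cn_floor, total_cn)
  out <- gamma * log2(cn / ploidy)
  if (any(floored)) attr(out, "floored") <- floored
  out
}

#' Tile a genome into fixed-width bins
#'
#' Bins are half-open `[start, start + bin_size)` in concept, stored 1-based
#' inclusive; the last bin of a chromosome is truncated at its length.
#'
#' @param genome data.frame `chrom`, `length`.
#' @param bin_size bin width in bp.
#' @return data.frame `bin` (1-based global index), `chrom`, `start`, `end`,
#'   `mid` (midpoint used by the segment-covers-midpoint rule).
#' @export
make_bins <- function(genome, bin_size = 1e6) {
  stopifnot(bin_size > 0)
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    data.frame(chrom = as.character(genome$chrom[i]), start = starts,
               end = ends, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin <- seq_len(nrow(out))
  out$mid <- floor((out$start + out$end) / 2)
  out[, c("bin", "chrom", "start", "end", "mid")]
}

# Value of per-segment column `col` at positions (chrom, pos) for ONE
# sample's sorted, non-overlapping segment table; NA where no segment covers.
segment_value_at <- function(segments, chrom, pos, col) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(seg) == 0) next
    ord <- order(seg$start)
    seg <- seg[ord, , drop = FALSE]
    idx <- findInterval(pos[sel], seg$start)
    hit <- idx >= 1 & idx <= nrow(seg)
    hit[hit] <- pos[sel][hit] <= seg$end[idx[hit]]
    out[sel[hit]] <- seg[[col]][idx[hit]]
  }
  out
}

# Row index of the covering segment, NA when uncovered (same midpoint rule).
segment_index_at <- function(segments, chrom, pos) {
  segments$..row <- seq_len(nrow(segments))
  segment_value_at(segments, chrom, pos, "..row")
}

#' Per-bin aberration scores of one profile
#'
#' Each bin takes the aberration score of the segment covering its midpoint;
#' bins whose midpoint falls in a gap between segments are NA.
#'
#' @param segments one sample's segment data.frame (`chrom`, `start`, `end`,
#'   `total_cn`).
#' @param ploidy sample ploidy.
#' @param bins bin table from [make_bins()].
#' @param margin aberration margin. Default 0.6.
#' @return integer vector of scores, one per bin row.
#' @export
bin_profile <- function(segments, ploidy, bins, margin = 0.6) {
  cn <- segment_value_at(segments, bins$chrom, bins$mid, "total_cn")
  aberration_score(cn, ploidy, margin)
}

#' Cross-sample gain/loss frequencies per genome bin
#'
#' For every bin, the percentage of profiles scoring +1 (gain) and -1 (loss)
#' among profiles with a non-missing score there.
#'
#' @param segments segment data.frame for many samples (column `sample_id`).
#' @param samples sample metadata data.frame (`sample_id`, `ploidy`).
#' @param bins bin table from [make_bins()].
#' @param margin aberration margin. Default 0.6.
#' @return data.frame `bin`, `chrom`, `start`, `end`, `gain_pct`, `loss_pct`,
#'   `n_informative`.
#' @export
aberration_frequencies <- function(segments, samples, bins, margin = 0.6) {
  stopifnot(nrow(samples) >= 1)
  scores <- vapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    seg <- segments[segments$sample_id == sid, , drop = FALSE]
    bin_profile(seg, samples$ploidy[i], bins, margin)
  }, integer(nrow(bins)))
  scores <- matrix(scores, nrow = nrow(bins))
  n_inf <- rowSums(!is.na(scores))
  gain <- rowSums(scores == 1L, na.rm = TRUE)
  loss <- rowSums(scores == -1L, na.rm = TRUE)
  data.frame(bin = bins$bin, chrom = bins$chrom, start = bins$start,
             end = bins$end,
             gain_pct = ifelse(n_inf > 0, 100 * gain / n_inf, NA_real_),
             loss_pct = ifelse(n_inf > 0, 100 * loss / n_inf, NA_real_),
             n_informative = n_inf, stringsAsFactors = FALSE)
}

#' Gene-level adjusted logR for one sample
#'
#' Each gene takes the adjusted logR of the segment covering the gene's
#' midpoint (deterministic for genes straddling a breakpoint); genes in
#' uncovered gaps, or on chromosomes absent from the profile, are NA (the
#' latter with a warning).
#'
#' @param segments one sample's segment data.frame.
#' @param ploidy sample ploidy.
#' @param annotation data.frame `gene`, `chrom`, `start`, `end` (1-based).
#' @param gamma array-noise factor. Default 0.55.
#' @param cn_floor floor for zero copies. Default 0.05.
#' @return named numeric vector of adjusted logR, one entry per gene.
#' @export
gene_logr <- function(segments, ploidy, annotation, gamma = 0.55,
                      cn_floor = 0.05) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  unknown <- setdiff(unique(annotation$chrom), unique(segments$chrom))
  if (length(unknown) > 0)
    warning("annotation chromosomes absent from profile: ",
            paste(unknown, collapse = ", "))
  mid <- floor((annotation$start + annotation$end) / 2)
  cn <- segment_value_at(segments, annotation$chrom, mid, "total_cn")
  out <- rep(NA_real_, nrow(annotation))
  ok <- !is.na(cn)
  if (any(ok)) out[ok] <- adjusted_logr(cn[ok], ploidy, gamma, cn_floor)
  names(out) <- annotation$gene
  out
}

#' Gene-by-sample matrix of adjusted logR
#'
#' Applies [gene_logr()] across samples and assembles a genes x samples
#' matrix, the input to the expression-correlation filter and the
#' differential test.
#'
#' @inheritParams aberration_frequencies
#' @param annotation gene annotation data.frame.
#' @param gamma array-noise factor.
#' @param cn_floor floor for zero copies.
#' @return numeric matrix, rownames genes, colnames sample ids.
#' @export
gene_logr_matrix <- function(segments, samples, annotation, gamma = 0.55,
                             cn_floor = 0.05) {
  mat <- vapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    seg <- segments[segments$sample_id == sid, , drop = FALSE]
    suppressWarnings(gene_logr(seg, samples$ploidy[i], annotation, gamma,
                               cn_floor))
  }, numeric(nrow(annotation)))
  mat <- matrix(mat, nrow = nrow(annotation),
                dimnames = list(annotation$gene, samples$sample_id))
  mat
}
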