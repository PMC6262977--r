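#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Wraps the standard step-up procedure (via [stats::p.adjust()]): sorted
#' p-values are scaled by m/rank and a running minimum from the largest rank
#' downwards enforces monotonicity; results are capped at 1 and returned in
#' the input order.
#'
#' @param p p-values in (0, 1].
#' @return q-values (adjusted p-values), same order as input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
benjamini_hochberg <- function(p) {
  if (any(is.na(p))) stop("p-values must not be NA")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p
#'
#' Sample Pearson correlation with the usual t-approximation p-value
#' (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs, nonzero
#'   variance).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Expression-correlation filter
#'
#' Retains genes whose purity/ploidy-adjusted logR correlates with mRNA
#' expression at Pearson r at or above the threshold (pairwise-complete
#' observations). Genes with fewer than 3 complete pairs, or zero variance in
#' either vector (r undefined), are dropped; dropped-for-data genes are
#' reported in a warning. Besides selecting dosage-sensitive genes this
#' removes most germline copy-number variants, which have little expression
#' effect.
#'
#' @param logr genes x samples matrix of adjusted logR.
#' @param expression genes x samples expression matrix (columns matched to
#'   `logr` by name).
#' @param threshold minimum Pearson r. Default 0.5.
#' @return data.frame `gene`, `r`, `n` for all evaluable genes, with
#'   attribute `kept`: the character vector of retained genes.
#' @export
expression_correlation_filter <- function(logr, expression, threshold = 0.5) {
  common_s <- intersect(colnames(logr), colnames(expression))
  common_g <- intersect(rownames(logr), rownames(expression))
  if (length(common_s) < 3) stop("need >= 3 shared samples")
  if (length(common_g) == 0) stop("no shared genes")
  logr <- logr[common_g, common_s, drop = FALSE]
  expression <- expression[common_g, common_s, drop = FALSE]
  res <- lapply(common_g, function(g) {
    x <- logr[g, ]; y <- expression[g, ]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) return(data.frame(gene = g, r = NA_real_, n = sum(ok)))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(gene = g, r = NA_real_, n = sum(ok)))
    data.frame(gene = g, r = stats::cor(x[ok], y[ok]), n = sum(ok))
  })
  res <- do.call(rbind, res)
  dropped <- res$gene[is.na(res$r)]
  if (length(dropped) > 0)
    warning(length(dropped),
            " gene(s) dropped (zero variance or < 3 complete pairs)")
  attr(res, "kept") <- res$gene[!is.na(res$r) & res$r >= threshold]
  res
}

#' Differential adjusted logR between extreme response groups
#'
#' Per gene, a two-sided two-sample t-test of mean adjusted logR in good
#' responders (GR) versus non-responders (NR) — classic pooled-variance
#' Student's test by default, Welch optionally — followed by
#' Benjamini-Hochberg correction across all tested genes.
#'
#' @param logr genes x samples matrix of adjusted logR.
#' @param groups factor/character of GR/NR labels, one per column of `logr`
#'   (other labels are ignored).
#' @param welch use Welch's unequal-variance test. Default FALSE.
#' @param fdr_alpha FDR threshold used to flag significance. Default 0.05.
#' @return data.frame `gene`, `mean_gr`, `mean_nr`, `t_stat`, `p`, `q`,
#'   `direction` ("gain_in_GR" when GR mean exceeds NR mean), `significant`.
#'   Genes with fewer than 2 complete observations in either group are
#'   skipped (recorded in attribute `skipped`).
#' @export
differential_logr <- function(logr, groups, welch = FALSE, fdr_alpha = 0.05) {
  stopifnot(ncol(logr) == length(groups))
  gr <- which(groups == "GR"); nr <- which(groups == "NR")
  rows <- lapply(rownames(logr), function(g) {
    x <- logr[g, gr]; y <- logr[g, nr]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2 ||
        (stats::sd(x) == 0 && stats::sd(y) == 0))
      return(NULL)
    tt <- stats::t.test(x, y, var.equal = !welch)
    data.frame(gene = g, mean_gr = mean(x), mean_nr = mean(y),
               t_stat = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  skipped <- rownames(logr)[vapply(rows, is.null, logical(1))]
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no testable genes")
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out$direction <- ifelse(out$mean_gr > out$mean_nr, "gain_in_GR",
                          "loss_in_GR")
  out$significant <- out$q < fdr_alpha
  attr(out, "skipped") <- skipped
  out
}

#' Compare genomic instability between patient groups
#'
#' Two groups: classic pooled-variance Student's t-test (Welch optional).
#' Three or more groups: one-way analysis of variance.
#'
#' @param gii numeric vector of genomic instability indices.
#' @param groups group labels, one per element of `gii`.
#' @param welch for the two-group case, use Welch's test. Default FALSE.
#' @return list with `test` ("t" or "anova"), `statistic`, `p`,
#'   `group_means`, `group_n`.
#' @export
compare_gii_groups <- function(gii, groups, welch = FALSE) {
  ok <- !is.na(gii) & !is.na(groups)
  gii <- gii[ok]; groups <- droplevels(factor(groups[ok]))
  n <- table(groups)
  if (length(n) < 2 || any(n < 2))
    stop("need >= 2 groups with >= 2 members each")
  means <- tapply(gii, groups, mean)
  if (length(n) == 2) {
    tt <- stats::t.test(gii ~ groups, var.equal = !welch)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         group_means = means, group_n = as.vector(n))
  } else {
    fit <- stats::aov(gii ~ groups)
    tab <- summary(fit)[[1]]
    list(test = "anova", statistic = tab[["F value"]][1],
         p = tab[["Pr(>F)"]][1], group_means = means, group_n = as.vector(n))
  }
}

#' Merge significant genes into genomic regions
#'
#' Genes significant in the differential test are merged into unique genomic
#' regions when their intervals fall in the same or adjacent genome bins,
#' giving a locus-level summary of the gene-level result.
#'
#' @param diff result of [differential_logr()] (significant rows are used).
#' @param annotation gene annotation (`gene`, `chrom`, `start`, `end`).
#' @param bins bin table from [make_bins()].
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_genes`,
#'   `genes` (comma-separated).
#' @export
significant_regions <- function(diff, annotation, bins) {
  sig <- diff$gene[diff$significant]
  ann <- annotation[annotation$gene %in% sig, , drop = FALSE]
  if (nrow(ann) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_genes = integer(0),
                      genes = character(0), stringsAsFactors = FALSE))
  mid <- floor((ann$start + ann$end) / 2)
  bin_of <- segment_value_at(
    data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
               bin = as.numeric(bins$bin)), ann$chrom, mid, "bin")
  ann <- ann[!is.na(bin_of), , drop = FALSE]
  bin_of <- bin_of[!is.na(bin_of)]
  ord <- order(bin_of)
  ann <- ann[ord, , drop = FALSE]; bin_of <- bin_of[ord]
  region <- cumsum(c(1, diff(bin_of) > 1))
  out <- lapply(split(seq_along(region), region), function(i) {
    data.frame(chrom = ann$chrom[i[1]], start = min(ann$start[i]),
               end = max(ann$end[i]), n_genes = length(i),
               genes = paste(ann$gene[i], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
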