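# End-to-end orchestration: response classification -> instability scoring
# and frequency profiles -> proliferation and group comparisons ->
# expression-correlation filter -> differential logR -> clonality tracking
# -> selection scan; every stage writes its table and the run closes with a
# JSON manifest recording counts and exclusions.

#' Run the full time-course pipeline
#'
#' Executes every analysis stage on a cohort (an in-memory `"cna_cohort"` /
#' [read_cohort()] list, or a directory path readable by [read_cohort()])
#' and writes result tables, frequency/selection plots and a run manifest to
#' `out_dir`. A stage failure halts the run with the stage name; the
#' manifest written so far is preserved.
#'
#' @param cohort cohort list or directory path.
#' @param out_dir output directory.
#' @param config [analysis_config()].
#' @param plots write per-bin frequency and selection plots (PDF). Default
#'   TRUE.
#' @return invisibly, a list with the stage results (`clinical`, `gii`,
#'   `frequencies`, `comparisons`, `filter`, `differential`, `regions`,
#'   `tracking`, `selection`, `manifest`).
#' @export
run_pipeline <- function(cohort, out_dir, config = analysis_config(),
                         plots = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config)[
                     !vapply(unclass(config), is.function, logical(1))],
                   started = format(Sys.time(), tz = "UTC"),
                   n_patients = nrow(cohort$clinical),
                   n_samples = nrow(cohort$samples),
                   n_segments = nrow(cohort$segments),
                   stages = list())
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(completed = TRUE)
    out
  }
  bins <- cohort$bins
  samples <- cohort$samples
  segments <- cohort$segments

  # 1. clinical response derivation -------------------------------------
  clinical <- stage("response", derive_response(cohort$clinical, config))
  write_clinical(clinical, file.path(out_dir, "response.csv"))
  manifest$stages$response$group_n <-
    as.list(table(clinical$response_group))

  # 2. genomic instability + frequency profiles -------------------------
  gii <- stage("gii", {
    data.frame(sample_id = samples$sample_id,
               patient_id = samples$patient_id,
               timepoint_weeks = samples$timepoint_weeks,
               gii = vapply(seq_len(nrow(samples)), function(i) {
                 seg <- segments[segments$sample_id == samples$sample_id[i], ]
                 genomic_instability_index(seg, samples$ploidy[i],
                                           config$aberration_margin)
               }, numeric(1)), stringsAsFactors = FALSE)
  })
  utils::write.table(gii, file.path(out_dir, "gii.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  freqs <- stage("frequencies", {
    out <- list()
    for (wk in sort(unique(samples$timepoint_weeks))) {
      sm <- samples[samples$timepoint_weeks == wk, , drop = FALSE]
      fr <- aberration_frequencies(segments, sm, bins,
                                   config$aberration_margin)
      fr$timepoint_weeks <- wk
      out[[as.character(wk)]] <- fr
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
  utils::write.table(freqs, file.path(out_dir, "frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 3. proliferation score + group comparisons --------------------------
  comparisons <- stage("comparisons", {
    prolif <- tryCatch(
      proliferation_score(cohort$expression, config$proliferation_genes),
      error = function(e) NULL)
    wk0 <- samples[samples$timepoint_weeks == 0, , drop = FALSE]
    m <- merge(gii[gii$timepoint_weeks == 0, ], clinical, by = "patient_id")
    out <- list()
    grp <- droplevels(factor(m$response_group))
    if (nlevels(grp) >= 2 && all(table(grp) >= 2))
      out$gii_by_response <- compare_gii_groups(m$gii, m$response_group,
                                                config$welch)
    pcr_tab <- table(m$pcr)
    if (length(pcr_tab) == 2 && all(pcr_tab >= 2))
      out$gii_by_pcr <- compare_gii_groups(m$gii,
                                           ifelse(m$pcr, "pCR", "non-pCR"),
                                           config$welch)
    if (!is.null(prolif)) {
      ids <- intersect(wk0$sample_id, names(prolif))
      g0 <- gii$gii[match(ids, gii$sample_id)]
      if (length(ids) >= 3 && stats::sd(g0) > 0 &&
          stats::sd(prolif[ids]) > 0)
        out$gii_vs_proliferation <- pearson_correlation(g0, prolif[ids])
      out$proliferation <- data.frame(sample_id = names(prolif),
                                      score = unname(prolif),
                                      stringsAsFactors = FALSE)
    }
    out
  })
  if (!is.null(comparisons$proliferation))
    utils::write.table(comparisons$proliferation,
                       file.path(out_dir, "proliferation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # 4. expression-correlation filter ------------------------------------
  wk0_good <- samples[samples$timepoint_weeks == config$filter_timepoint &
                      samples$quality == "good", , drop = FALSE]
  logr0 <- stage("filter", suppressWarnings({
    lr <- gene_logr_matrix(segments, wk0_good, cohort$annotation,
                           config$gamma, config$cn_floor)
    colnames(lr) <- wk0_good$sample_id
    lr
  }))
  filt <- stage("filter", suppressWarnings(
    expression_correlation_filter(logr0, cohort$expression,
                                  config$expr_corr_threshold)))
  utils::write.table(filt, file.path(out_dir, "expression_filter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- attr(filt, "kept")
  manifest$stages$filter$n_kept <- length(kept)
  manifest$stages$filter$n_tested <- nrow(filt)

  # 5. differential logR, GR vs NR --------------------------------------
  diff_res <- stage("differential", {
    groups <- clinical$response_group[match(wk0_good$patient_id,
                                            clinical$patient_id)]
    if (length(kept) == 0 || sum(groups == "GR") < 2 ||
        sum(groups == "NR") < 2) NULL
    else {
      d <- differential_logr(logr0[kept, , drop = FALSE], groups,
                             config$welch, config$fdr_alpha)
      d$expr_corr <- filt$r[match(d$gene, filt$gene)]
      d
    }
  })
  regions <- NULL
  if (!is.null(diff_res)) {
    ann <- cohort$annotation
    m <- match(diff_res$gene, ann$gene)
    diff_out <- cbind(diff_res[, "gene", drop = FALSE],
                      ann[m, c("chrom", "start", "end")],
                      diff_res[, setdiff(names(diff_res), "gene")])
    utils::write.table(diff_out, file.path(out_dir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    regions <- significant_regions(diff_res, ann, bins)
    utils::write.table(regions, file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$differential$n_significant <- sum(diff_res$significant)
    manifest$stages$differential$n_regions <-
      if (is.null(regions)) 0 else nrow(regions)
  }

  # 6. clonality tracking ------------------------------------------------
  tracking <- stage("clonality", track_cohort(segments, samples, config))
  if (!is.null(tracking$tracked))
    utils::write.table(tracking$tracked, file.path(out_dir, "tracked.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tracking$acf_estimates))
    utils::write.table(tracking$acf_estimates,
                       file.path(out_dir, "acf_estimates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest$stages$clonality$n_excluded <- nrow(tracking$exclusions)
  manifest$stages$clonality$exclusions <- if (nrow(tracking$exclusions) > 0)
    as.list(table(tracking$exclusions$reason)) else list()
  manifest$stages$clonality$n_tracked_patients <-
    if (is.null(tracking$tracked)) 0
    else length(unique(tracking$tracked$patient_id))

  # 7. selection scan -----------------------------------------------------
  selection <- stage("selection", {
    if (is.null(tracking$tracked) || nrow(tracking$tracked) == 0) NULL
    else selection_scan(tracking, bins, alpha = config$fdr_alpha)
  })
  if (!is.null(selection))
    utils::write.table(selection, file.path(out_dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  if (plots) {
    grDevices::pdf(file.path(out_dir, "frequency_plots.pdf"), width = 10,
                   height = 4)
    for (wk in unique(freqs$timepoint_weeks))
      plot_frequencies(freqs[freqs$timepoint_weeks == wk, ],
                       main = sprintf("Aberration frequencies, week %d", wk))
    grDevices::dev.off()
    if (!is.null(selection) && nrow(selection) > 0) {
      grDevices::pdf(file.path(out_dir, "selection_plots.pdf"), width = 10,
                     height = 4)
      for (cl in unique(selection$class))
        plot_selection(selection[selection$class == cl, ],
                       main = sprintf("Selection scan, %s", cl))
      grDevices::dev.off()
    }
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  res <- list(clinical = clinical, gii = gii, frequencies = freqs,
              comparisons = comparisons, filter = filt,
              differential = diff_res, regions = regions,
              tracking = tracking, selection = selection,
              manifest = manifest)
  invisible(res)
}

#' Per-bin gain/loss frequency plot
#'
#' @param freq one time point's rows of the frequency table.
#' @param main plot title.
#' @export
plot_frequencies <- function(freq, main = "Aberration frequencies") {
  graphics::plot(freq$bin, freq$gain_pct, type = "h", col = "firebrick",
                 ylim = c(-100, 100), xlab = "genome bin",
                 ylab = "% samples (gain up, loss down)", main = main)
  graphics::segments(freq$bin, 0, freq$bin, -freq$loss_pct,
                     col = "forestgreen")
  graphics::abline(h = 0, col = "grey40")
  chg <- which(diff(as.integer(factor(freq$chrom, unique(freq$chrom)))) != 0)
  graphics::abline(v = freq$bin[chg] + 0.5, col = "grey85", lty = 3)
  invisible(NULL)
}

#' Per-bin selection-scan plot
#'
#' @param sel one class's rows of the selection table.
#' @param main plot title.
#' @export
plot_selection <- function(sel, main = "Selection scan") {
  graphics::plot(sel$bin, sel$n_increase, type = "h", col = "forestgreen",
                 ylim = range(c(sel$n_increase, -sel$n_decrease)),
                 xlab = "genome bin", ylab = "patients (increase up, decrease down)",
                 main = main)
  graphics::segments(sel$bin, 0, sel$bin, -sel$n_decrease, col = "firebrick")
  sig <- sel$direction != "none"
  if (any(sig))
    graphics::points(sel$bin[sig],
                     ifelse(sel$direction[sig] == "positive",
                            sel$n_increase[sig] + 0.5,
                            -sel$n_decrease[sig] - 0.5),
                     pch = 8)
  invisible(NULL)
}

#' Summarize a completed run
#'
#' Reads the result tables from a run directory and prints (and returns)
#' per-group GII summaries, the top differential genes, and the selected
#' bins with their increase/decrease counts and FDR. Idempotent across
#' reruns.
#'
#' @param out_dir a directory produced by [run_pipeline()].
#' @param n_top rows to show per table. Default 10.
#' @return invisibly, a list of summary tables.
#' @export
report <- function(out_dir, n_top = 10) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest found: run incomplete or '", out_dir,
         "' is not a run directory")
  out <- list()
  cl <- read_clinical(file.path(out_dir, "response.csv"))
  gii <- utils::read.delim(file.path(out_dir, "gii.tsv"),
                           stringsAsFactors = FALSE)
  m <- merge(gii[gii$timepoint_weeks == 0, ], cl, by = "patient_id")
  out$gii_by_group <- do.call(rbind, lapply(split(m$gii, m$response_group),
    function(x) data.frame(n = length(x), mean_gii = mean(x),
                           sd_gii = stats::sd(x))))
  cat("Week-0 genomic instability by response group:\n")
  print(round(out$gii_by_group, 4))
  diff_path <- file.path(out_dir, "differential.tsv")
  if (file.exists(diff_path)) {
    d <- utils::read.delim(diff_path, stringsAsFactors = FALSE)
    d <- d[order(d$q), ]
    out$top_differential <- utils::head(d, n_top)
    cat("\nTop differential genes (GR vs NR):\n")
    print(out$top_differential[, c("gene", "mean_gr", "mean_nr", "t_stat",
                                   "p", "q")], row.names = FALSE)
  }
  sel_path <- file.path(out_dir, "selection.tsv")
  if (file.exists(sel_path)) {
    s <- utils::read.delim(sel_path, stringsAsFactors = FALSE)
    s <- s[order(s$q), ]
    out$top_selection <- utils::head(s, n_top)
    cat("\nTop selection-scan bins:\n")
    print(out$top_selection[, c("bin", "chrom", "class", "n_increase",
                                "n_decrease", "chi2", "q", "direction")],
          row.names = FALSE)
  } else {
    cat("\nSelection scan: no bins tested\n")
    out$top_selection <- NULL
  }
  invisible(out)
}
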