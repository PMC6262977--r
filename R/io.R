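# Readers and writers for the cohort's tab/comma-separated formats.
# Segment tables are 1-based inclusive; chromosome labels are accepted with
# or without a "chr" prefix and normalized (prefix stripped) on read.

SEGMENT_COLS <- c("sample_id", "chrom", "start", "end", "n_probes",
                  "total_cn", "minor_cn", "state2_total", "state2_minor",
                  "frac_state1")

norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read a segment table
#'
#' Tab-separated, one row per segment, with the ASCAT/Battenberg-style
#' columns `sample_id, chrom, start, end, n_probes, total_cn, minor_cn,
#' state2_total, state2_minor, frac_state1` (the last three optional /
#' NA for clonal segments). Validation failures (start > end, negative copy
#' numbers, overlapping segments within a sample) are hard errors naming the
#' offending line.
#'
#' @param path file path.
#' @return data.frame of segments, sorted by sample, chromosome, start.
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "chrom", "start", "end", "n_probes",
                    "total_cn", "minor_cn"), names(seg))
  if (length(need) > 0)
    stop("segment file missing column(s): ", paste(need, collapse = ", "))
  for (col in c("state2_total", "state2_minor", "frac_state1"))
    if (is.null(seg[[col]])) seg[[col]] <- NA_real_
  seg$chrom <- norm_chrom(seg$chrom)
  line <- seq_len(nrow(seg)) + 1  # header is line 1
  bad <- which(seg$start > seg$end)
  if (length(bad) > 0)
    stop("start > end at line ", bad[1] + 1, " of ", path)
  bad <- which(seg$total_cn < 0 | seg$minor_cn < 0)
  if (length(bad) > 0)
    stop("negative copy number at line ", bad[1] + 1, " of ", path)
  bad <- which(seg$n_probes < 1)
  if (length(bad) > 0)
    stop("n_probes < 1 at line ", bad[1] + 1, " of ", path)
  # overlap check within sample x chromosome
  key <- paste(seg$sample_id, seg$chrom, sep = "\r")
  for (k in unique(key)) {
    i <- which(key == k)
    o <- i[order(seg$start[i])]
    if (length(o) > 1 && any(seg$start[o][-1] <= seg$end[o][-length(o)]))
      stop("overlapping segments for sample ", seg$sample_id[i[1]],
           " chromosome ", seg$chrom[i[1]], " in ", path)
  }
  seg[order(seg$sample_id, seg$chrom, seg$start), SEGMENT_COLS]
}

#' @rdname read_segments
#' @param segments segment data.frame to write.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments[, SEGMENT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write sample metadata
#'
#' Tab-separated with columns `sample_id, patient_id, timepoint_weeks,
#' ploidy, acf, quality, pathologist_pct`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "patient_id", "timepoint_weeks", "ploidy",
                    "acf", "quality"), names(s))
  if (length(need) > 0)
    stop("sample metadata missing column(s): ", paste(need, collapse = ", "))
  if (!all(s$timepoint_weeks %in% c(0, 12, 25)))
    stop("timepoint_weeks must be one of 0, 12, 25")
  if (any(s$ploidy <= 0)) stop("ploidy must be > 0")
  bad <- !is.na(s$acf) & (s$acf < 0 | s$acf > 1)
  if (any(bad)) stop("acf outside [0, 1]")
  if (any(is.na(s$acf) & s$quality == "good"))
    stop("acf may be unknown only when quality != good")
  s
}

#' @rdname read_sample_meta
#' @param samples sample metadata data.frame to write.
#' @export
write_sample_meta <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write the clinical table
#'
#' Comma-separated with columns `patient_id, arm, size_dx, size_surgery,
#' pcr` (and optionally derived `rr`, `response_group`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("patient_id", "arm", "size_dx", "size_surgery", "pcr"),
                  names(cl))
  if (length(need) > 0)
    stop("clinical table missing column(s): ", paste(need, collapse = ", "))
  if (!all(cl$arm %in% c("chemotherapy", "combination")))
    stop("arm must be chemotherapy or combination")
  cl$pcr <- as.logical(cl$pcr)
  cl
}

#' @rdname read_clinical
#' @param clinical clinical data.frame to write.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write an expression matrix
#'
#' Tab-separated, genes in rows (first column `gene`), samples in columns.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "gene") stop("first column must be 'gene'")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param expression genes x samples matrix to write.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write gene annotation
#'
#' BED-like tab-separated file `chrom, start, end, gene` with 0-based
#' half-open coordinates on disk, converted to 1-based inclusive internally.
#'
#' @param path file path.
#' @return data.frame `gene, chrom, start, end` (1-based inclusive).
#' @export
read_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("chrom", "start", "end", "gene"), names(a))
  if (length(need) > 0)
    stop("annotation missing column(s): ", paste(need, collapse = ", "))
  data.frame(gene = a$gene, chrom = norm_chrom(a$chrom), start = a$start + 1,
             end = a$end, stringsAsFactors = FALSE)
}

#' @rdname read_annotation
#' @param annotation 1-based annotation data.frame to write.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(
    data.frame(chrom = annotation$chrom, start = annotation$start - 1,
               end = annotation$end, gene = annotation$gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits every table the pipeline readers consume — segments, sample
#' metadata, clinical, expression, annotation — plus ground-truth TSVs and a
#' YAML snapshot of the simulation configuration.
#'
#' @param cohort a `"cna_cohort"` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cna_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_sample_meta(cohort$samples, file.path(dir, "samples.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_annotation(cohort$annotation, file.path(dir, "genes.tsv"))
  utils::write.table(cohort$truth$patients,
                     file.path(dir, "truth_patients.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth$cnas))
    utils::write.table(cohort$truth$cnas, file.path(dir, "truth_cnas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$genome <- list(chrom = as.character(cfg$genome$chrom),
                     length = cfg$genome$length)
  cfg$purity_means <- list(GR = cfg$purity_means["GR", ],
                           IR = cfg$purity_means["IR", ],
                           NR = cfg$purity_means["NR", ])
  if (!is.null(cfg$selection_loci)) cfg$selection_loci <- as.list(cfg$selection_loci)
  yaml::write_yaml(c(unclass(cfg), list(null_cohort = cohort$null_cohort)),
                   file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a cohort directory
#'
#' Loads the tables written by [write_cohort()] (ground truth and the config
#' snapshot are optional).
#'
#' @param dir directory path.
#' @param genome genome table used to rebuild the bin grid; when NULL it is
#'   reconstructed from the config snapshot if present, else inferred from
#'   the segment extents.
#' @param bin_size bin width for the rebuilt grid. Default 1e6.
#' @return list with the same table elements as a `"cna_cohort"`.
#' @export
read_cohort <- function(dir, genome = NULL, bin_size = 1e6) {
  out <- list(
    segments = read_segments(file.path(dir, "segments.tsv")),
    samples = read_sample_meta(file.path(dir, "samples.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.csv")),
    expression = read_expression(file.path(dir, "expression.tsv")),
    annotation = read_annotation(file.path(dir, "genes.tsv")))
  cfg_path <- file.path(dir, "sim_config.yaml")
  if (is.null(genome) && file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    genome <- data.frame(chrom = as.character(cfg$genome$chrom),
                         length = cfg$genome$length,
                         stringsAsFactors = FALSE)
    bin_size <- cfg$bin_size
  }
  if (is.null(genome)) {
    agg <- stats::aggregate(end ~ chrom, data = out$segments, FUN = max)
    genome <- data.frame(chrom = agg$chrom, length = agg$end,
                         stringsAsFactors = FALSE)
  }
  out$bins <- make_bins(genome, bin_size)
  tp <- file.path(dir, "truth_patients.tsv")
  if (file.exists(tp)) {
    out$truth <- list(
      patients = utils::read.delim(tp, stringsAsFactors = FALSE),
      cnas = if (file.exists(file.path(dir, "truth_cnas.tsv")))
        utils::read.delim(file.path(dir, "truth_cnas.tsv"),
                          stringsAsFactors = FALSE) else NULL,
      genes = if (file.exists(file.path(dir, "truth_genes.tsv")))
        utils::read.delim(file.path(dir, "truth_genes.tsv"),
                          stringsAsFactors = FALSE) else NULL)
    out$truth$cnas$chrom <- as.character(out$truth$cnas$chrom)
  }
  out$segments$chrom <- as.character(out$segments$chrom)
  out
}
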