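#' Pipeline run configuration
#'
#' Collects the file paths and analysis settings for an end-to-end run.
#' All referenced input paths must exist at validation time.
#'
#' @param vcf_a_dir,vcf_b_dir directories of per-sample VCFs from callers
#'   A and B (one `<sample_id>.vcf` each).
#' @param sample_map_path sample -> breed -> population TSV/CSV.
#' @param out_dir output directory (created on run).
#' @param read_counts_path optional read-count TSV (with `.trc` sidecar);
#'   enables the V_ST scan.
#' @param genes_path optional gene BED (chrom, start, end, name).
#' @param external_catalogue_path optional external CNVR BED for the
#'   cross-catalogue comparison.
#' @param filter a [filter_params()] object.
#' @param vst_percentile outlier percentile for the scan.
#' @param seed stored in the run manifest (the pipeline itself is
#'   deterministic; the seed documents the upstream simulation).
#' @return a validated list of class `"run_config"`.
#' @export
run_config <- function(vcf_a_dir, vcf_b_dir, sample_map_path, out_dir,
                       read_counts_path = NULL, genes_path = NULL,
                       external_catalogue_path = NULL,
                       filter = filter_params(),
                       vst_percentile = 0.99, seed = NA_integer_) {
  for (p in c(vcf_a_dir, vcf_b_dir, sample_map_path,
              read_counts_path, genes_path, external_catalogue_path))
    if (!is.null(p) && !file.exists(p)) stop("run_config: path not found: ", p)
  structure(list(vcf_a_dir = vcf_a_dir, vcf_b_dir = vcf_b_dir,
                 sample_map_path = sample_map_path, out_dir = out_dir,
                 read_counts_path = read_counts_path,
                 genes_path = genes_path,
                 external_catalogue_path = external_catalogue_path,
                 filter = filter, vst_percentile = vst_percentile,
                 seed = seed),
            class = "run_config")
}

read_caller_dir <- function(dir, caller) {
  files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  do.call(rbind, lapply(files, function(f) {
    parse_sv_vcf(f, sub("\\.vcf$", "", basename(f)), caller)
  }))
}

#' Run the full CNV/CNVR/V_ST pipeline
#'
#' Sequences the analysis: parse both callers' VCFs, filter on evidence
#' and precision, intersect per sample into consensus CNV, apply length
#' cut-offs, merge into per-population and global CNVR, compute summary
#' and sharing tables, run the V_ST scan (when read counts are supplied)
#' with gene annotation, and compare against an external catalogue (when
#' supplied). All tables are written to `config$out_dir` together with a
#' machine-readable run manifest (parameters and per-stage record
#' counts).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every intermediate product (`cnv`,
#'   `cnvr_global`, `cnvr_population`, `table1`, `table2`, `sharing`,
#'   `vst`, `comparison`, `stage_counts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  smap <- tryCatch(read_sample_map(config$sample_map_path),
                   error = function(e) fail("sample_map", e))
  rec_a <- tryCatch(read_caller_dir(config$vcf_a_dir, "A"),
                    error = function(e) fail("parse_vcf_a", e))
  rec_b <- tryCatch(read_caller_dir(config$vcf_b_dir, "B"),
                    error = function(e) fail("parse_vcf_b", e))

  cnv <- tryCatch(consensus_cnv(rec_a, rec_b, config$filter),
                  error = function(e) fail("consensus", e))
  stage_counts <- attr(cnv, "stage_counts")
  write_bed(cnv[, c("chrom", "start", "end", "state", "sample_id")],
            file.path(config$out_dir, "cnv.bed"))

  cnvr_g <- tryCatch(merge_cnv(cnv, "global", smap, nrow(smap)),
                     error = function(e) fail("cnvr_global", e))
  cnvr_p <- tryCatch(merge_cnv(cnv, "per_population", smap),
                     error = function(e) fail("cnvr_population", e))
  write_bed(cnvr_g[, c("chrom", "start", "end", "state", "n_carrier_samples")],
            file.path(config$out_dir, "cnvr_global.bed"))
  write_bed(cnvr_p[, c("chrom", "start", "end", "state", "scope_group")],
            file.path(config$out_dir, "cnvr_population.bed"))

  tab1 <- summarize_cnv_by_population(cnv, smap)
  tab2 <- summarize_cnvr(cnvr_g)
  write.table(tab1, file.path(config$out_dir, "cnv_by_population.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tab2, file.path(config$out_dir, "cnvr_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sharing <- tryCatch(cnvr_sharing(cnvr_g, smap),
                      error = function(e) fail("sharing", e))
  write.table(sharing[, setdiff(names(sharing), "carrier_samples")],
              file.path(config$out_dir, "cnvr_sharing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  vst_res <- NULL
  if (!is.null(config$read_counts_path)) {
    rct <- tryCatch(read_read_counts(config$read_counts_path),
                    error = function(e) fail("read_counts", e))
    norm <- tryCatch(gc_adjust(rct), error = function(e) fail("normalize", e))
    vst_res <- tryCatch(vst_scan(norm, smap, percentile = config$vst_percentile),
                        error = function(e) fail("vst", e))
    genes <- if (!is.null(config$genes_path))
      read_bed(config$genes_path, extra_cols = "name") else NULL
    vst_res <- annotate_genes(vst_res, genes)
    write.table(vst_res, file.path(config$out_dir, "vst.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  comparison <- NULL
  if (!is.null(config$external_catalogue_path)) {
    ext <- read_bed(config$external_catalogue_path)
    ours <- intervals_from_granges(GenomicRanges::reduce(
      granges_from_intervals(cnvr_g)))
    comparison <- tryCatch(compare_cnvr_sets(ours, ext),
                           error = function(e) fail("compare", e))
    write.table(data.frame(metric = names(comparison),
                           value = unlist(comparison)),
                file.path(config$out_dir, "catalogue_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    filter = unclass(config$filter),
    vst_percentile = config$vst_percentile,
    stage_counts = as.list(stage_counts),
    n_samples = nrow(smap),
    n_cnvr_global = nrow(cnvr_g))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cnv = cnv, cnvr_global = cnvr_g, cnvr_population = cnvr_p,
                 table1 = tab1, table2 = tab2, sharing = sharing,
                 vst = vst_res, comparison = comparison,
                 stage_counts = stage_counts, sample_map = smap))
}

#' Write the per-population and per-state summary tables
#'
#' Emits the per-population CNV descriptive table and the per-state CNVR
#' summary to TSV files.
#'
#' @param outputs a [run_pipeline()] result list (or one with `cnv`,
#'   `cnvr_global`, `sample_map`).
#' @param dir output directory.
#' @return the two tables, invisibly.
#' @export
make_summary_tables <- function(outputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab1 <- summarize_cnv_by_population(outputs$cnv, outputs$sample_map)
  tab2 <- summarize_cnvr(outputs$cnvr_global)
  write.table(tab1, file.path(dir, "cnv_by_population.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tab2, file.path(dir, "cnvr_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(table1 = tab1, table2 = tab2))
}

#' Simple summary plots
#'
#' CNV length histogram (log10 bp, by state) and a per-chromosome V_ST
#' scatter for the across-all comparison with its 99th-percentile
#' threshold line.
#'
#' @param cnv consensus CNV calls.
#' @param vst_result a [vst_scan()] result (optional).
#' @param file PDF path.
#' @return `file`, invisibly.
#' @export
plot_summaries <- function(cnv, vst_result = NULL, file = "summary_plots.pdf") {
  grDevices::pdf(file, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  len <- log10(cnv$end - cnv$start)
  graphics::hist(len[cnv$state == "loss"], breaks = 40, col = "steelblue",
                 main = "CNV length by state", xlab = "log10 length (bp)")
  if (any(cnv$state == "gain"))
    graphics::hist(len[cnv$state == "gain"], breaks = 40, col = "orange",
                   add = TRUE)
  graphics::legend("topright", fill = c("steelblue", "orange"),
                   legend = c("loss", "gain"))
  if (!is.null(vst_result)) {
    allr <- vst_result[vst_result$comparison == "all" &
                         is.finite(vst_result$v_st), ]
    if (nrow(allr) > 0) {
      chrf <- factor(allr$chrom)
      graphics::plot(seq_len(nrow(allr)), allr$v_st,
                     col = as.integer(chrf), pch = 20,
                     xlab = "locus (genome order)", ylab = "V_ST",
                     main = "Across-population V_ST by chromosome")
      graphics::abline(h = allr$threshold[1], lty = 2)
    }
  }
  invisible(file)
}
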