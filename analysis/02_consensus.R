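#!/usr/bin/env Rscript
# Stage 2: evidence filtering and two-caller consensus CNV.
#
# Applies the operating point used throughout (precise calls only,
# PE + SR >= 5, upper cut-off 3 Mb, lower cut-off 50 bp after
# intersection), intersects the two call sets per sample, and writes the
# per-sample consensus CNV with the per-population descriptive table.

suppressMessages(library(cnvpop))

cohort_dir <- "results/cohort"
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

smap <- read_sample_map(file.path(cohort_dir, "sample_map.tsv"))
read_dir <- function(sub, caller) {
  files <- sort(list.files(file.path(cohort_dir, sub), pattern = "\\.vcf$",
                           full.names = TRUE))
  do.call(rbind, lapply(files, function(f)
    parse_sv_vcf(f, sub("\\.vcf$", "", basename(f)), caller)))
}
rec_a <- read_dir("vcf_a", "A")
rec_b <- read_dir("vcf_b", "B")

cnv <- consensus_cnv(rec_a, rec_b, filter_params())
sc <- attr(cnv, "stage_counts")
write_bed(cnv[, c("chrom", "start", "end", "state", "sample_id")],
          file.path(out_dir, "cnv.bed"))
tab1 <- summarize_cnv_by_population(cnv, smap)
write.table(tab1, file.path(out_dir, "cnv_by_population.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("record counts through the filter stages:\n")
print(sc)
len <- cnv$end - cnv$start
cat(sprintf("consensus CNV: %d (%.1f%% losses); length mean %.0f bp, median %.0f bp\n",
            nrow(cnv), 100 * mean(cnv$state == "loss"), mean(len), median(len)))
cat("wrote", file.path(out_dir, "cnv.bed"), "and cnv_by_population.tsv\n")
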