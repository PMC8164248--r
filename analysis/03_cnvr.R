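#!/usr/bin/env Rscript
# Stage 3: CNV regions, sharing, and catalogue comparison.
#
# Merges the consensus CNV into population-level and global CNVR
# (book-ended intervals merge, bedtools-style), summarizes them by copy
# state, derives sharing/private status across breeds and populations,
# and compares the largest population's CNVR catalogue against the global
# map with the directional-coverage overlap report.

suppressMessages(library(cnvpop))

cohort_dir <- "results/cohort"
out_dir <- "results/analysis"
smap <- read_sample_map(file.path(cohort_dir, "sample_map.tsv"))
cnv <- read_bed(file.path(out_dir, "cnv.bed"),
                extra_cols = c("state", "sample_id"))

cnvr_g <- merge_cnv(cnv, "global", smap, nrow(smap))
cnvr_p <- merge_cnv(cnv, "per_population", smap)
write_bed(cnvr_g[, c("chrom", "start", "end", "state", "n_carrier_samples")],
          file.path(out_dir, "cnvr_global.bed"))
write_bed(cnvr_p[, c("chrom", "start", "end", "state", "scope_group")],
          file.path(out_dir, "cnvr_population.bed"))

tab2 <- summarize_cnvr(cnvr_g)
write.table(tab2, file.path(out_dir, "cnvr_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("global CNVR by copy state:\n")
print(tab2)

sharing <- cnvr_sharing(cnvr_g, smap)
write.table(sharing[, setdiff(names(sharing), "carrier_samples")],
            file.path(out_dir, "cnvr_sharing.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sh <- attr(sharing, "summary")
cat(sprintf("sharing: %d/%d CNVR in all breeds (%.1f%%), %d in all populations (%.1f%%), %d private to one breed\n",
            sh[["n_in_all_breeds"]], sh[["n_regions"]],
            100 * sh[["n_in_all_breeds"]] / sh[["n_regions"]],
            sh[["n_in_all_populations"]],
            100 * sh[["n_in_all_populations"]] / sh[["n_regions"]],
            sh[["n_private_to_breed"]]))

# catalogue comparison: biggest population's CNVR vs the global map
big_pop <- names(which.max(table(smap$population_code)))
pop_set <- cnvr_p[cnvr_p$scope_group == big_pop, c("chrom", "start", "end")]
cmp <- compare_cnvr_sets(pop_set, cnvr_g[, c("chrom", "start", "end")])
write.table(data.frame(metric = names(cmp), value = unlist(cmp)),
            file.path(out_dir, "catalogue_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%s CNVR vs global: %d of %d overlap; %.1f Mb intersection (%.1f%% of %s, %.1f%% of global)\n",
            big_pop, cmp$n_x_overlapping, cmp$n_x,
            cmp$intersection_bp / 1e6,
            100 * cmp$frac_x_in_intersection, big_pop,
            100 * cmp$frac_y_in_intersection))
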