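#' Merge CNV calls into CNV regions (CNVR)
#'
#' Pools calls over the samples in scope and merges any calls overlapping
#' by at least 1 bp into maximal non-overlapping regions. Region state is
#' `"loss"` or `"gain"` when all member calls agree and `"both"` when the
#' carriers include at least one loss and one gain. Carrier samples (and,
#' when a sample map is supplied, breeds and populations) are recorded per
#' region, along with the cohort carrier frequency.
#'
#' @param calls consensus CNV calls (columns `sample_id`, `chrom`, `start`,
#'   `end`, `state`).
#' @param scope `"global"` (one region set over all samples),
#'   `"per_population"` or `"per_breed"` (one region set per group; a
#'   `scope_group` column identifies the group).
#' @param sample_map sample map (required for grouped scopes and for
#'   breed/population carrier annotation).
#' @param n_cohort_samples denominator for the carrier frequency; defaults
#'   to the number of distinct samples in `calls` (global scope) or in the
#'   group.
#' @return a `data.frame` of CNVR with carrier annotations; carrier sets
#'   are semicolon-joined strings.
#' @export
merge_cnv <- function(calls, scope = c("global", "per_population", "per_breed"),
                      sample_map = NULL, n_cohort_samples = NULL) {
  scope <- match.arg(scope)
  if (scope != "global" && is.null(sample_map))
    stop("merge_cnv: sample_map is required for scope '", scope, "'")
  if (scope == "global") {
    out <- merge_one_group(calls, sample_map, n_cohort_samples)
    if (nrow(out) > 0) out <- cbind(scope_group = "global", out)
    return(out)
  }
  key <- if (scope == "per_population") "population_code" else "breed_code"
  grp_of <- setNames(sample_map[[key]], sample_map$sample_id)
  miss <- setdiff(unique(calls$sample_id), names(grp_of))
  if (length(miss) > 0)
    stop("merge_cnv: sample(s) missing from sample map: ",
         paste(miss, collapse = ", "))
  groups <- sort(unique(grp_of[calls$sample_id]))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- calls[grp_of[calls$sample_id] == g, , drop = FALSE]
    n_g <- sum(grp_of == g)
    r <- merge_one_group(sub, sample_map, n_g)
    if (nrow(r) > 0) cbind(scope_group = g, r) else NULL
  }))
  if (is.null(out)) out <- cbind(scope_group = character(0),
                                 merge_one_group(calls[0, , drop = FALSE], sample_map, 1))
  rownames(out) <- NULL
  out
}

merge_one_group <- function(calls, sample_map = NULL, n_cohort_samples = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      n_carrier_samples = integer(0),
                      carrier_samples = character(0),
                      carrier_breeds = character(0),
                      carrier_populations = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  if (is.null(n_cohort_samples))
    n_cohort_samples <- length(unique(calls$sample_id))
  gr <- granges_from_intervals(calls)
  # book-ended CNV merge into one region (bedtools-merge semantics)
  reg <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(gr, reg)
  ri <- S4Vectors::subjectHits(hits); ci <- S4Vectors::queryHits(hits)
  reg_df <- intervals_from_granges(reg)
  by_region <- split(ci, ri)
  idx <- as.integer(names(by_region))
  state <- vapply(by_region, function(m) {
    st <- unique(calls$state[m])
    if (length(st) > 1) "both" else st
  }, "")
  carriers <- lapply(by_region, function(m) sort(unique(calls$sample_id[m])))
  breeds <- pops <- rep(NA_character_, length(by_region))
  if (!is.null(sample_map)) {
    b_of <- setNames(sample_map$breed_code, sample_map$sample_id)
    p_of <- setNames(sample_map$population_code, sample_map$sample_id)
    breeds <- vapply(carriers, function(s) paste(sort(unique(b_of[s])), collapse = ";"), "")
    pops <- vapply(carriers, function(s) paste(sort(unique(p_of[s])), collapse = ";"), "")
  }
  out <- data.frame(chrom = reg_df$chrom[idx], start = reg_df$start[idx],
                    end = reg_df$end[idx], state = unname(state),
                    n_carrier_samples = lengths(carriers),
                    carrier_samples = vapply(carriers, paste, "", collapse = ";"),
                    carrier_breeds = unname(breeds),
                    carrier_populations = unname(pops),
                    frequency = lengths(carriers) / n_cohort_samples,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of a CNVR set by copy state
#'
#' Per state (loss/gain/both) and overall: region count, mean, median,
#' minimum and maximum length, and coverage (summed length; regions are
#' non-overlapping so this is the union length).
#'
#' @param regions a CNVR table from [merge_cnv()].
#' @return a `data.frame` with one row per state plus an `overall` row.
#' @export
summarize_cnvr <- function(regions) {
  states <- c("loss", "gain", "both")
  len <- regions$end - regions$start
  row_for <- function(lab, l) {
    data.frame(state = lab, n = length(l),
               mean_len = if (length(l)) mean(l) else NA_real_,
               median_len = if (length(l)) median(l) else NA_real_,
               min_len = if (length(l)) min(l) else NA_real_,
               max_len = if (length(l)) max(l) else NA_real_,
               coverage_bp = sum(l), stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(states, function(s) row_for(s, len[regions$state == s])))
  rbind(per, row_for("overall", len))
}

#' Per-population CNV descriptive statistics
#'
#' Count and length statistics (mean, median, min, max) of per-sample CNV
#' calls, by population and copy state, with an overall row per
#' population.
#'
#' @param calls consensus CNV calls.
#' @param sample_map sample map assigning populations.
#' @return a `data.frame`, one row per (population, state) plus overall
#'   rows; empty states get `n = 0` and `NA` statistics.
#' @export
summarize_cnv_by_population <- function(calls, sample_map) {
  p_of <- setNames(sample_map$population_code, sample_map$sample_id)
  miss <- setdiff(unique(calls$sample_id), names(p_of))
  if (length(miss) > 0)
    stop("sample(s) missing from sample map: ", paste(miss, collapse = ", "))
  pops <- sort(unique(sample_map$population_code))
  len <- calls$end - calls$start
  pop <- p_of[calls$sample_id]
  do.call(rbind, lapply(pops, function(p) {
    n_samp <- sum(sample_map$population_code == p)
    rows <- lapply(c("loss", "gain", "overall"), function(s) {
      l <- if (s == "overall") len[pop == p] else len[pop == p & calls$state == s]
      data.frame(population = p, n_samples = n_samp, state = s, n = length(l),
                 mean_len = if (length(l)) mean(l) else NA_real_,
                 median_len = if (length(l)) median(l) else NA_real_,
                 min_len = if (length(l)) min(l) else NA_real_,
                 max_len = if (length(l)) max(l) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
}

#' Sharing and privacy of CNVR across breeds and populations
#'
#' For each region: the number of carrier breeds and populations, whether
#' it is present in every breed / every population, whether it is private
#' to a single breed / single population, and the cohort carrier
#' frequency.
#'
#' @param regions CNVR from [merge_cnv()] (carrier sets populated).
#' @param sample_map the cohort sample map.
#' @return `regions` with sharing columns appended; attribute `"summary"`
#'   holds cohort-level counts (regions in all breeds, private regions,
#'   ...).
#' @export
cnvr_sharing <- function(regions, sample_map) {
  b_of <- setNames(sample_map$breed_code, sample_map$sample_id)
  p_of <- setNames(sample_map$population_code, sample_map$sample_id)
  carrier_list <- strsplit(regions$carrier_samples, ";", fixed = TRUE)
  miss <- setdiff(unique(unlist(carrier_list)), sample_map$sample_id)
  if (length(miss) > 0)
    stop("carrier sample(s) absent from sample map: ", paste(miss, collapse = ", "))
  n_breeds <- length(unique(sample_map$breed_code))
  n_pops <- length(unique(sample_map$population_code))
  n_samples <- nrow(sample_map)
  reg_breeds <- lapply(carrier_list, function(s) unique(b_of[s]))
  reg_pops <- lapply(carrier_list, function(s) unique(p_of[s]))
  out <- regions
  out$n_breeds <- lengths(reg_breeds)
  out$n_populations <- lengths(reg_pops)
  out$frequency <- lengths(carrier_list) / n_samples
  out$present_in_all_breeds <- out$n_breeds == n_breeds
  out$present_in_all_populations <- out$n_populations == n_pops
  out$private_to_breed <- out$n_breeds == 1
  out$private_to_population <- out$n_populations == 1
  attr(out, "summary") <- c(
    n_regions = nrow(out),
    n_in_all_breeds = sum(out$present_in_all_breeds),
    n_in_all_populations = sum(out$present_in_all_populations),
    n_private_to_breed = sum(out$private_to_breed),
    n_private_to_population = sum(out$private_to_population))
  out
}

#' Overlap report between two CNVR catalogues
#'
#' Both sets must each be internally non-overlapping. Reports how many X
#' regions overlap at least one Y region (and vice versa), the total
#' intersection length, the fraction of each catalogue's coverage inside
#' the intersection, and the union length of all mutually overlapping
#' region pairs.
#'
#' @param set_x,set_y interval tables (`chrom`, `start`, `end`).
#' @return a named list with the overlap statistics.
#' @export
compare_cnvr_sets <- function(set_x, set_y) {
  check_disjoint <- function(df, lab) {
    if (nrow(df) < 2) return(invisible())
    gr <- granges_from_intervals(df)
    if (length(GenomicRanges::reduce(gr, min.gapwidth = 0L)) < length(gr) ||
        sum(GenomicRanges::width(GenomicRanges::reduce(gr, min.gapwidth = 0L))) <
        sum(GenomicRanges::width(gr)))
      stop("compare_cnvr_sets: set ", lab, " is internally overlapping")
  }
  check_disjoint(set_x, "X"); check_disjoint(set_y, "Y")
  gg <- align_seqlevels(granges_from_intervals(set_x),
                        granges_from_intervals(set_y))
  gx <- gg$x; gy <- gg$y
  hits <- GenomicRanges::findOverlaps(gx, gy, minoverlap = 1L)
  inter <- GenomicRanges::intersect(gx, gy)
  cov_x <- sum(GenomicRanges::width(gx)); cov_y <- sum(GenomicRanges::width(gy))
  ov_pairs <- GenomicRanges::reduce(c(gx[unique(S4Vectors::queryHits(hits))],
                                      gy[unique(S4Vectors::subjectHits(hits))]))
  list(n_x = nrow(set_x), n_y = nrow(set_y),
       n_x_overlapping = length(unique(S4Vectors::queryHits(hits))),
       n_y_overlapping = length(unique(S4Vectors::subjectHits(hits))),
       intersection_bp = sum(GenomicRanges::width(inter)),
       coverage_x_bp = cov_x, coverage_y_bp = cov_y,
       frac_x_in_intersection = if (cov_x > 0) sum(GenomicRanges::width(inter)) / cov_x else 0,
       frac_y_in_intersection = if (cov_y > 0) sum(GenomicRanges::width(inter)) / cov_y else 0,
       union_of_overlapping_pairs_bp = sum(GenomicRanges::width(ov_pairs)))
}
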