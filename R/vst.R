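#' V_ST copy-number population-differentiation statistic
#'
#' For a copy-number intensity signal (here normalized read counts used as
#' log-R-ratio proxies), `V_ST = (V_T - V_S) / V_T`, where `V_T` is the
#' variance of the signal over all individuals pooled and `V_S` is the
#' average within-population variance. Sample variances use the n-1
#' denominator and `V_S` weights populations by `n_i - 1` by default.
#' Populations with fewer than 2 values are excluded from the comparison;
#' a locus with `V_T = 0` (or fewer than 2 usable populations) is
#' non-informative and gets `v_st = NA`.
#'
#' @param values_by_population named list mapping population label to a
#'   numeric vector of per-sample values.
#' @param weights `"nminus1"` (default), `"n"` or `"equal"` weighting of
#'   the within-population variances.
#' @return a list with `v_st`, `v_t`, `v_s`, `n` (total values used) and
#'   `populations_used`.
#' @export
compute_vst <- function(values_by_population,
                        weights = c("nminus1", "n", "equal")) {
  weights <- match.arg(weights)
  vals <- lapply(values_by_population, function(x) x[is.finite(x)])
  usable <- lengths(vals) >= 2
  if (sum(usable) < 2)
    return(list(v_st = NA_real_, v_t = NA_real_, v_s = NA_real_,
                n = sum(lengths(vals[usable])),
                populations_used = names(vals)[usable]))
  vals <- vals[usable]
  pooled <- unlist(vals, use.names = FALSE)
  v_t <- var(pooled)
  n_i <- lengths(vals)
  w <- switch(weights, nminus1 = n_i - 1, n = n_i, equal = rep(1, length(n_i)))
  v_i <- vapply(vals, var, 0.0)
  v_s <- sum(w * v_i) / sum(w)
  v_st <- if (v_t > 0) (v_t - v_s) / v_t else NA_real_
  list(v_st = v_st, v_t = v_t, v_s = v_s, n = length(pooled),
       populations_used = names(vals))
}

# vectorized per-locus V_ST over a matrix (loci x samples)
vst_rows <- function(mat, pop, weights = "nminus1") {
  pops <- unique(pop)
  n_i <- vapply(pops, function(p) sum(pop == p), 0L)
  use <- n_i >= 2
  if (sum(use) < 2) return(rep(NA_real_, nrow(mat)))
  pops <- pops[use]
  cols <- pop %in% pops
  m <- mat[, cols, drop = FALSE]
  pp <- pop[cols]
  n <- ncol(m)
  row_var <- function(x) {
    mu <- rowMeans(x)
    rowSums((x - mu)^2) / (ncol(x) - 1)
  }
  v_t <- row_var(m)
  n_i <- vapply(pops, function(p) sum(pp == p), 0L)
  w <- switch(weights, nminus1 = n_i - 1, n = n_i, equal = rep(1, length(pops)))
  v_within <- sapply(pops, function(p) row_var(m[, pp == p, drop = FALSE]))
  v_s <- as.numeric(v_within %*% w) / sum(w)
  ifelse(v_t > 0, (v_t - v_s) / v_t, NA_real_)
}

#' Genome-wide V_ST scan over CNV loci
#'
#' Computes V_ST per locus for every pairwise population comparison and
#' across all populations (`"all"`). Within each comparison, the
#' 99th-percentile threshold (linear interpolation over that comparison's
#' finite V_ST values) flags loci strictly above it as highly
#' differentiated. Rows flagged other than `"ok"` in the normalized
#' matrix are excluded.
#'
#' @param norm a `"normalized_matrix"` from [gc_adjust()], or a plain
#'   loci x samples matrix.
#' @param sample_map sample map covering the matrix columns.
#' @param comparisons list of comparisons; each is a character vector of
#'   population codes or the string `"all"`. Default: all pairs plus
#'   `"all"`.
#' @param percentile outlier percentile (default 0.99).
#' @param weights passed to the V_ST computation.
#' @return a `data.frame`: one row per (locus, comparison) with `v_st`,
#'   the comparison threshold and `is_differentiated`.
#' @export
vst_scan <- function(norm, sample_map, comparisons = NULL,
                     percentile = 0.99, weights = "nminus1") {
  if (inherits(norm, "normalized_matrix")) {
    mat <- norm$values
    regions <- norm$regions
    ok <- norm$flags == "ok"
  } else {
    mat <- as.matrix(norm)
    regions <- NULL
    ok <- rep(TRUE, nrow(mat))
  }
  samples <- colnames(mat)
  p_of <- setNames(sample_map$population_code, sample_map$sample_id)
  miss <- setdiff(samples, names(p_of))
  if (length(miss) > 0)
    stop("vst_scan: sample(s) missing from sample map: ",
         paste(miss, collapse = ", "))
  pop <- unname(p_of[samples])
  all_pops <- sort(unique(pop))
  if (is.null(comparisons)) {
    comparisons <- if (length(all_pops) >= 2)
      c(utils::combn(all_pops, 2, simplify = FALSE), list("all")) else list("all")
  }
  locus_id <- if (!is.null(regions))
    paste0(regions$chrom, ":", regions$start, "-", regions$end) else
      if (!is.null(rownames(mat))) rownames(mat) else as.character(seq_len(nrow(mat)))

  out <- lapply(comparisons, function(cmp) {
    if (identical(cmp, "all") || identical(cmp, c("all"))) {
      label <- "all"; cols <- rep(TRUE, length(pop))
    } else {
      unknown <- setdiff(cmp, all_pops)
      if (length(unknown) > 0)
        stop("vst_scan: unknown population label(s): ",
             paste(unknown, collapse = ", "))
      label <- paste(cmp, collapse = "_vs_")
      cols <- pop %in% cmp
    }
    v <- rep(NA_real_, nrow(mat))
    v[ok] <- vst_rows(mat[ok, cols, drop = FALSE], pop[cols], weights)
    fin <- is.finite(v)
    thr <- if (any(fin)) unname(quantile(v[fin], percentile, type = 7)) else NA_real_
    data.frame(locus = locus_id,
               chrom = if (!is.null(regions)) regions$chrom else NA_character_,
               start = if (!is.null(regions)) regions$start else NA_integer_,
               end = if (!is.null(regions)) regions$end else NA_integer_,
               comparison = label, v_st = v, threshold = thr,
               is_differentiated = fin & !is.na(thr) & v > thr,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate differentiated loci with overlapping genes
#'
#' Attaches to each scan row the names of genes overlapping the locus by
#' at least 1 bp (half-open convention: touching intervals do not
#' overlap). With no gene table, the `genes` column is empty.
#'
#' @param results a [vst_scan()] result with locus coordinates.
#' @param genes interval table with columns `chrom`, `start`, `end`,
#'   `name` (BED-like, 0-based half-open), or `NULL`.
#' @param flagged_only annotate only differentiated loci (default) or all.
#' @return `results` with a `genes` column (semicolon-joined names).
#' @export
annotate_genes <- function(results, genes = NULL, flagged_only = TRUE) {
  results$genes <- ""
  if (is.null(genes) || nrow(genes) == 0 || nrow(results) == 0) return(results)
  rows <- if (flagged_only) which(results$is_differentiated) else seq_len(nrow(results))
  if (length(rows) == 0) return(results)
  loci <- results[rows, c("chrom", "start", "end")]
  gg <- align_seqlevels(granges_from_intervals(loci),
                        granges_from_intervals(genes))
  gr_l <- gg$x; gr_g <- gg$y
  hits <- GenomicRanges::findOverlaps(gr_l, gr_g, minoverlap = 1L)
  if (length(hits) == 0) return(results)
  ann <- tapply(genes$name[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits),
                function(x) paste(sort(unique(x)), collapse = ";"))
  results$genes[rows[as.integer(names(ann))]] <- unname(ann)
  results
}
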