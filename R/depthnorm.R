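#' Assemble a region-by-sample read-count table
#'
#' @param regions interval table (`chrom`, `start`, `end`) of the CNV loci.
#' @param counts region x sample matrix of non-negative read counts.
#' @param trc per-sample total mapped reads (library size), named by
#'   sample.
#' @param gc per-region GC fraction in `[0, 1]`.
#' @param mappability per-region mappability fraction in `(0, 1]`.
#' @return a list of class `"read_count_table"`.
#' @export
read_count_table <- function(regions, counts, trc, gc, mappability) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(regions),
            length(gc) == nrow(regions),
            length(mappability) == nrow(regions),
            length(trc) == ncol(counts),
            all(counts >= 0), all(trc >= 1),
            all(gc >= 0 & gc <= 1),
            all(mappability > 0 & mappability <= 1),
            all(regions$end - regions$start >= 1))
  if (is.null(colnames(counts))) colnames(counts) <- names(trc)
  stopifnot(identical(colnames(counts), names(trc)))
  structure(list(regions = regions, counts = counts, trc = trc,
                 gc = gc, mappability = mappability),
            class = "read_count_table")
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * RC / (TRC * S)` for read count `RC` over a region of `S`
#' bp in a library of `TRC` mapped reads. Vectorized; all three arguments
#' are recycled.
#'
#' @param rc read count(s), non-negative.
#' @param trc total mapped reads in the library, positive.
#' @param s region size in bp, positive.
#' @return RPKM value(s).
#' @export
rpkm <- function(rc, trc, s) {
  if (any(trc <= 0)) stop("rpkm: TRC must be positive")
  if (any(s <= 0)) stop("rpkm: region size must be positive")
  1e9 * rc / (trc * s)
}

rpkm_matrix <- function(rct) {
  s <- rct$regions$end - rct$regions$start
  sweep(rct$counts / s, 2, rct$trc, "/") * 1e9
}

# GC bins of `bin_width`, sparser bins (< min_occupancy regions) merged
# with the next bin(s); the trailing remainder joins the last full bin.
gc_bin_groups <- function(gc, bin_width = 0.01, min_occupancy = 20L) {
  bin <- floor(gc / bin_width + 1e-9)
  ub <- sort(unique(bin))
  counts <- vapply(ub, function(b) sum(bin == b), 0L)
  group <- integer(length(ub))
  g <- 1L; acc <- 0L
  for (i in seq_along(ub)) {
    group[i] <- g
    acc <- acc + counts[i]
    if (acc >= min_occupancy && i < length(ub)) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0 && acc < min_occupancy && g > 1L)
    group[group == g] <- g - 1L   # fold a sparse trailing group back
  group[match(bin, ub)]
}

#' GC-content and mappability adjustment of an RPKM matrix
#'
#' Per sample, with `m` the median RPKM over all regions and `m_GC` the
#' median RPKM of the regions in the same GC bin, the adjusted value is
#' `RPKM * m / m_GC`; the result is then divided by the region's
#' mappability fraction. The adjusted values serve as log-R-ratio proxies
#' for the differentiation scan.
#'
#' Regions whose GC bin has a zero median for some sample are flagged
#' `unadjustable` (values set `NA`) rather than silently dropped; regions
#' with mappability below `mappability_floor` are flagged `low_mappability`
#' but still adjusted.
#'
#' @param rct a [read_count_table()], or a plain RPKM matrix (then `gc`
#'   and `mappability` must be given).
#' @param gc,mappability per-region covariates (taken from `rct` when it
#'   is a `read_count_table`).
#' @param bin_width GC bin width (fraction, default 0.01).
#' @param min_occupancy minimum regions per GC bin; sparser bins are
#'   merged with neighbours.
#' @param mappability_floor flag regions below this mappability.
#' @param log2_ratio return `log2(adjusted / cohort median)` instead of
#'   the linear adjusted scale (default linear).
#' @return a list of class `"normalized_matrix"`: `values` (region x
#'   sample), `flags` (per-region character), and the binning metadata.
#' @export
gc_adjust <- function(rct, gc = NULL, mappability = NULL,
                      bin_width = 0.01, min_occupancy = 20L,
                      mappability_floor = 0.5, log2_ratio = FALSE) {
  if (inherits(rct, "read_count_table")) {
    mat <- rpkm_matrix(rct)
    gc <- rct$gc; mappability <- rct$mappability
    regions <- rct$regions
  } else {
    mat <- as.matrix(rct)
    if (is.null(gc) || is.null(mappability))
      stop("gc_adjust: gc and mappability required with a plain matrix")
    regions <- NULL
  }
  stopifnot(length(gc) == nrow(mat), length(mappability) == nrow(mat))
  grp <- gc_bin_groups(gc, bin_width, min_occupancy)
  adj <- mat
  unadjustable <- rep(FALSE, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    m <- median(mat[, j])
    m_gc <- tapply(mat[, j], grp, median)
    mg <- as.numeric(m_gc[as.character(grp)])
    bad <- mg == 0
    adj[, j] <- ifelse(bad, NA_real_, mat[, j] * m / mg)
    unadjustable <- unadjustable | bad
  }
  adj <- adj / mappability
  flags <- rep("ok", nrow(mat))
  flags[mappability < mappability_floor] <- "low_mappability"
  flags[unadjustable] <- "unadjustable"
  if (any(unadjustable))
    message("gc_adjust: ", sum(unadjustable),
            " region(s) unadjustable (zero GC-bin median); excluded downstream")
  if (log2_ratio) {
    med <- apply(adj, 1, median, na.rm = TRUE)
    adj <- log2(sweep(adj, 1, ifelse(med > 0, med, NA_real_), "/"))
  }
  structure(list(values = adj, flags = flags, gc = gc,
                 mappability = mappability, regions = regions,
                 bin_width = bin_width, bin_group = grp),
            class = "normalized_matrix")
}

#' Write / read a read-count table as TSV
#'
#' The main table has columns `chrom`, `start`, `end`, `gc`,
#' `mappability`, then one column per sample; per-sample total mapped
#' reads go to a two-column sidecar TSV (`sample_id`, `trc`).
#'
#' @param rct a [read_count_table()].
#' @param path main TSV path; the sidecar is `<path>.trc`.
#' @return `path` (write) or a `read_count_table` (read).
#' @export
write_read_counts <- function(rct, path) {
  df <- cbind(rct$regions[, c("chrom", "start", "end")],
              gc = rct$gc, mappability = rct$mappability,
              as.data.frame(rct$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(rct$trc), trc = unname(rct$trc)),
              paste0(path, ".trc"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  trc_df <- read.table(paste0(path, ".trc"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  samples <- setdiff(names(df), c("chrom", "start", "end", "gc", "mappability"))
  counts <- as.matrix(df[, samples, drop = FALSE])
  read_count_table(df[, c("chrom", "start", "end")], counts,
                   setNames(trc_df$trc, trc_df$sample_id)[samples],
                   df$gc, df$mappability)
}
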