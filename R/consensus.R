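#' SV filter parameters
#'
#' Bundles the post-calling filter settings: whether imprecise calls are
#' used, the evidence stringency (minimum PE + SR), the lower and upper
#' length cut-offs and the stage at which the lower cut-off applies.
#'
#' The medium stringency (PE + SR >= 5) is the documented operating point;
#' `low` (3) and `stringent` (8) are extrapolated presets and can be
#' overridden with `t_override`.
#'
#' @param use_imprecise keep calls flagged IMPRECISE? Default `FALSE`.
#' @param stringency `"low"`, `"medium"` or `"stringent"`.
#' @param t_override optional integer overriding the preset evidence
#'   threshold.
#' @param min_len lower CNV length cut-off in bp (default 50; an interval of
#'   exactly `min_len` is retained).
#' @param max_len upper length cut-off in bp (default 3e6; 1e7 is the
#'   documented alternative).
#' @param min_len_stage apply `min_len` `"before_intersect"` (to raw caller
#'   records) or `"after_intersect"` (to consensus segments; default).
#' @param drop_hom_ref drop records genotyped homozygous-reference before
#'   intersection? Default `FALSE`.
#' @return a list of class `"filter_params"`.
#' @export
filter_params <- function(use_imprecise = FALSE,
                          stringency = c("medium", "low", "stringent"),
                          t_override = NULL,
                          min_len = 50L, max_len = 3000000L,
                          min_len_stage = c("after_intersect", "before_intersect"),
                          drop_hom_ref = FALSE) {
  stringency <- match.arg(stringency)
  min_len_stage <- match.arg(min_len_stage)
  t <- if (!is.null(t_override)) as.integer(t_override) else
    switch(stringency, low = 3L, medium = 5L, stringent = 8L)
  stopifnot(min_len >= 1, max_len > min_len, t >= 0)
  structure(list(use_imprecise = use_imprecise, stringency = stringency,
                 t = t, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_len_stage = min_len_stage,
                 drop_hom_ref = drop_hom_ref),
            class = "filter_params")
}

#' Filter SV records on evidence, precision and length
#'
#' Retains records with PE + SR evidence at or above the stringency
#' threshold, drops imprecise records unless allowed, always drops records
#' longer than `max_len`, and applies the lower length cut-off here only
#' when `min_len_stage = "before_intersect"`.
#'
#' @param records an SV record table ([sv_records()]).
#' @param params a [filter_params()] object.
#' @return the retained subset of `records`.
#' @export
filter_sv <- function(records, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  len <- records$end - records$start
  keep <- (records$pe + records$sr) >= params$t
  if (!params$use_imprecise) keep <- keep & !records$imprecise
  keep <- keep & (len <= params$max_len)
  if (params$min_len_stage == "before_intersect")
    keep <- keep & (len >= params$min_len)
  if (params$drop_hom_ref)
    keep <- keep & records$genotype != "hom_ref"
  records[keep, , drop = FALSE]
}

#' Intersect two callers' call sets into consensus CNV
#'
#' For every pair of records, one from each caller, on the same chromosome
#' with the same SV type and at least 1 bp overlap, emits one consensus
#' call covering the overlap segment. One long record in one set
#' overlapping k short records in the other yields k consensus calls.
#' Duplicate segments with identical (sample, chrom, start, end, state)
#' are collapsed to one.
#'
#' @param set_a,set_b SV record tables from callers A and B for the same
#'   sample.
#' @return a `data.frame` of consensus CNV calls with columns `sample_id`,
#'   `chrom`, `start`, `end`, `state` (`"loss"` for DEL, `"gain"` for DUP)
#'   and the source intervals from each caller.
#' @export
intersect_callsets <- function(set_a, set_b) {
  sa <- unique(set_a$sample_id); sb <- unique(set_b$sample_id)
  if (length(sa) > 1 || length(sb) > 1 ||
      (length(sa) == 1 && length(sb) == 1 && sa != sb))
    stop("intersect_callsets: both call sets must come from one sample")
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      state = character(0),
                      a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)

  out <- lapply(c("DEL", "DUP"), function(tp) {
    a <- set_a[set_a$sv_type == tp, , drop = FALSE]
    b <- set_b[set_b$sv_type == tp, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) return(empty)
    gg <- align_seqlevels(granges_from_intervals(a), granges_from_intervals(b))
    gra <- gg$x; grb <- gg$y
    hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = 1L)
    if (length(hits) == 0) return(empty)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    seg <- GenomicRanges::pintersect(gra[qi], grb[si])
    seg_df <- intervals_from_granges(seg)
    data.frame(sample_id = a$sample_id[qi],
               chrom = seg_df$chrom, start = seg_df$start, end = seg_df$end,
               state = if (tp == "DEL") "loss" else "gain",
               a_start = a$start[qi], a_end = a$end[qi],
               b_start = b$start[si], b_end = b$end[si],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[!duplicated(out[, c("sample_id", "chrom", "start", "end", "state")]), ,
             drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply CNV length cut-offs to consensus calls
#'
#' Drops consensus segments shorter than `min_len` (when the lower cut-off
#' is applied after intersection) or longer than `max_len`; the result is
#' the per-sample CNV set used downstream.
#'
#' @param calls consensus calls from [intersect_callsets()].
#' @param params a [filter_params()] object.
#' @return the retained subset of `calls`.
#' @export
derive_cnv <- function(calls, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  len <- calls$end - calls$start
  keep <- len <= params$max_len
  if (params$min_len_stage == "after_intersect")
    keep <- keep & (len >= params$min_len)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample consensus CNV for a whole cohort
#'
#' Convenience wrapper: filters each caller's records, intersects per
#' sample, and applies the length cut-offs.
#'
#' @param records_a,records_b SV record tables pooled over samples (column
#'   `sample_id` distinguishes them).
#' @param params a [filter_params()] object.
#' @return consensus CNV calls for all samples, plus attribute
#'   `"stage_counts"` with record counts at each filter stage.
#' @export
consensus_cnv <- function(records_a, records_b, params = filter_params()) {
  fa <- filter_sv(records_a, params)
  fb <- filter_sv(records_b, params)
  samples <- union(unique(fa$sample_id), unique(fb$sample_id))
  calls <- do.call(rbind, lapply(samples, function(s) {
    intersect_callsets(fa[fa$sample_id == s, , drop = FALSE],
                       fb[fb$sample_id == s, , drop = FALSE])
  }))
  if (is.null(calls))
    calls <- intersect_callsets(fa[0, , drop = FALSE], fb[0, , drop = FALSE])
  cnv <- derive_cnv(calls, params)
  attr(cnv, "stage_counts") <- c(raw_a = nrow(records_a), raw_b = nrow(records_b),
                                 filtered_a = nrow(fa), filtered_b = nrow(fb),
                                 consensus = nrow(calls), cnv = nrow(cnv))
  cnv
}
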