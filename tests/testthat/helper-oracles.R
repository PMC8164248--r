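# Independent brute-force oracles for the interval operations, kept free of
# the package's GenomicRanges-based implementations.

# all-pairs O(n^2) intersection of two call sets (one sample, one chrom set)
oracle_intersect <- function(set_a, set_b) {
  out <- list()
  for (i in seq_len(nrow(set_a))) for (j in seq_len(nrow(set_b))) {
    if (set_a$chrom[i] != set_b$chrom[j]) next
    if (set_a$sv_type[i] != set_b$sv_type[j]) next
    s <- max(set_a$start[i], set_b$start[j])
    e <- min(set_a$end[i], set_b$end[j])
    if (e - s >= 1)
      out[[length(out) + 1]] <- data.frame(
        chrom = set_a$chrom[i], start = s, end = e,
        state = if (set_a$sv_type[i] == "DEL") "loss" else "gain",
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0)))
  df <- do.call(rbind, out)
  df <- unique(df)
  df[order(df$chrom, df$start, df$end, df$state), , drop = FALSE]
}

# boolean-mask union of intervals on a single toy chromosome of length L
oracle_union_mask <- function(starts, ends, L) {
  mask <- logical(L)
  for (i in seq_along(starts)) mask[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(mask)
  pos <- cumsum(c(0, r$lengths))
  data.frame(start = pos[-length(pos)][r$values], end = pos[-1][r$values])
}

# boolean-mask intersection length of two interval sets on one toy chrom
oracle_intersection_bp <- function(x, y, L) {
  mx <- logical(L); my <- logical(L)
  for (i in seq_len(nrow(x))) mx[(x$start[i] + 1):x$end[i]] <- TRUE
  for (i in seq_len(nrow(y))) my[(y$start[i] + 1):y$end[i]] <- TRUE
  sum(mx & my)
}

# random SV record set on a toy genome
random_records <- function(n, sample_id = "s1", caller = "A",
                           chroms = c("chr1", "chr2"), L = 10000,
                           del_frac = 0.8) {
  start <- sample.int(L - 200, n, replace = TRUE)
  len <- sample(5:300, n, replace = TRUE)
  sv_records(sample_id = sample_id, caller = caller,
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = pmin(start + len, L),
             sv_type = ifelse(runif(n) < del_frac, "DEL", "DUP"),
             pe = 5L, sr = 5L)
}

# tiny two-caller fixture builder for one sample
calls_df <- function(chrom, start, end, state = "loss", sample_id = "s1") {
  data.frame(sample_id = sample_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             state = state, stringsAsFactors = FALSE)
}

write_test_vcf <- function(path, body_lines, sample = "s1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"pe\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"sr\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"i\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    body_lines), path)
  path
}
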