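#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a multi-breed goat WGS
#' cohort at desk scale: five geographic populations subdivided into
#' breeds, a CNV landscape dominated by deletions (96.6%), log-normal
#' deletion lengths with median 1.3 kb (mean about 2.3 kb), a
#' heavier-tailed duplication length distribution (median about 1.4 kb,
#' mean about 31.5 kb), two imperfect breakpoint callers, and per-locus
#' read counts with GC and mappability covariates. Truth lengths are
#' truncated at 2.8 Mb, matching the observed CNV length range.
#'
#' @param seed RNG seed; the whole bundle is deterministic given it.
#' @param populations named list: population code -> named integer vector
#'   of samples per breed.
#' @param n_cnv_loci number of true CNV loci to place.
#' @param n_chrom,chrom_length autosome count and common length (bp).
#' @param deletion_fraction fraction of loci that are deletions.
#' @param del_meanlog,del_sdlog,dup_meanlog,dup_sdlog log-normal length
#'   parameters for deletions and duplications.
#' @param min_truth_len,max_truth_len truth length truncation bounds (bp).
#' @param carrier_freq_range per-locus cohort carrier probability is drawn
#'   uniformly from this range.
#' @param hom_fraction fraction of carriers homozygous for the variant.
#' @param detection_prob per-caller detection probability (length 1 or 2,
#'   callers A/B).
#' @param jitter_sd breakpoint jitter standard deviation (bp).
#' @param false_call_rate expected false calls per caller per sample, as a
#'   fraction of that sample's detected true calls (length 1 or 2).
#' @param imprecise_prob probability a call is flagged IMPRECISE.
#' @param pe_mean,sr_mean Poisson means of the PE and SR evidence counts
#'   (the defaults make a call pass the PE + SR >= 5 filter with
#'   probability about 0.9).
#' @param n_differentiated_loci loci planted with a between-population
#'   copy-number shift.
#' @param diff_effect copy-number shift (copies) at planted loci.
#' @param gc_bias_coef strength of the multiplicative GC bias
#'   `exp(coef * (gc - 0.45))` on expected counts.
#' @param mean_trc,trc_cv per-sample total mapped reads: mean and CV.
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @param n_genes genes in the synthetic gene BED.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       populations = list(
                         BOE = c(BOE = 4L),
                         EAF = c(ABR = 3L, GAL = 3L, KEF = 2L, SEA = 2L),
                         MAD = c(AND = 3L, MEN = 3L),
                         SAF = c(MSH = 3L, THY = 3L),
                         WAF = c(NAI = 3L, SDN = 3L)),
                       n_cnv_loci = 2000L,
                       n_chrom = 4L, chrom_length = 3e7,
                       deletion_fraction = 0.966,
                       del_meanlog = log(1300), del_sdlog = sqrt(2 * log(2300 / 1300)),
                       dup_meanlog = log(1400), dup_sdlog = sqrt(2 * log(31500 / 1400)),
                       min_truth_len = 50L, max_truth_len = 2.8e6,
                       carrier_freq_range = c(0.05, 0.5),
                       hom_fraction = 0.2,
                       detection_prob = 0.95,
                       jitter_sd = 20,
                       false_call_rate = 0.05,
                       imprecise_prob = 0.1,
                       pe_mean = 4.5, sr_mean = 3.5,
                       n_differentiated_loci = 20L,
                       diff_effect = 1L,
                       gc_bias_coef = 1,
                       mean_trc = 3e7, trc_cv = 0.1,
                       nb_size = 50,
                       n_genes = 300L) {
  cfg <- as.list(environment())
  cfg$detection_prob <- rep(detection_prob, length.out = 2)
  cfg$false_call_rate <- rep(false_call_rate, length.out = 2)
  names(cfg$detection_prob) <- names(cfg$false_call_rate) <- c("A", "B")
  stopifnot(all(cfg$detection_prob >= 0 & cfg$detection_prob <= 1),
            all(cfg$false_call_rate >= 0),
            deletion_fraction >= 0, deletion_fraction <= 1,
            imprecise_prob >= 0, imprecise_prob <= 1,
            min_truth_len >= 50, max_truth_len > min_truth_len,
            chrom_length > max_truth_len,
            n_cnv_loci >= 1)
  structure(cfg, class = "sim_config")
}

sample_map_from_config <- function(cfg) {
  rows <- do.call(rbind, lapply(names(cfg$populations), function(p) {
    br <- cfg$populations[[p]]
    do.call(rbind, lapply(names(br), function(b)
      data.frame(breed_code = b, population_code = p, n = br[[b]],
                 stringsAsFactors = FALSE)))
  }))
  df <- rows[rep(seq_len(nrow(rows)), rows$n), c("breed_code", "population_code")]
  df$sample_id <- sprintf("S%03d", seq_len(nrow(df)))
  validate_sample_map(df[, c("sample_id", "breed_code", "population_code")])
}

# place n non-overlapping loci; lengths from the configured truncated
# log-normals; error when placement keeps colliding
place_loci <- function(cfg) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  draw_len <- function(is_del, n) {
    l <- ifelse(is_del,
                rlnorm(n, cfg$del_meanlog, cfg$del_sdlog),
                rlnorm(n, cfg$dup_meanlog, cfg$dup_sdlog))
    round(pmin(pmax(l, cfg$min_truth_len), cfg$max_truth_len))
  }
  n <- cfg$n_cnv_loci
  is_del <- runif(n) < cfg$deletion_fraction
  len <- draw_len(is_del, n)
  if (sum(len) > 0.8 * cfg$n_chrom * cfg$chrom_length)
    stop("simulate_cohort: loci cannot be placed; total locus length ",
         "exceeds 80% of the genome")
  # place longest-first so rare megabase duplications land while the genome
  # is still sparse; shorter colliding loci are simply redrawn
  ord <- order(len, decreasing = TRUE)
  len_s <- len[ord]
  chrom_s <- character(n); start_s <- numeric(n)
  todo <- seq_len(n)
  for (iter in 1:100) {
    chrom_s[todo] <- sample(chroms, length(todo), replace = TRUE)
    start_s[todo] <- floor(runif(length(todo), 1, cfg$chrom_length - len_s[todo]))
    gr <- GenomicRanges::GRanges(chrom_s,
                                 IRanges::IRanges(start_s + 1, start_s + len_s))
    ov <- GenomicRanges::findOverlaps(gr, gr)
    ov <- ov[S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)]
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    # of each overlapping pair, redraw the shorter/fresher index
    fixed <- !(seq_len(n) %in% todo)
    redo <- unique(qh[!fixed[qh] & (fixed[sh] | sh < qh)])
    if (length(redo) == 0) { todo <- integer(0); break }
    todo <- sort(redo)
  }
  if (length(todo) > 0)
    stop("simulate_cohort: could not place ", length(todo),
         " locus/loci without overlap; reduce n_cnv_loci or lengths")
  chrom <- character(n); start <- numeric(n)
  chrom[ord] <- chrom_s; start[ord] <- start_s
  data.frame(locus_id = sprintf("L%05d", seq_len(cfg$n_cnv_loci)),
             chrom = chrom, start = as.integer(start),
             end = as.integer(start + len),
             sv_type = ifelse(is_del, "DEL", "DUP"),
             stringsAsFactors = FALSE)
}

genotype_from_cn <- function(cn, sv_type) {
  ifelse(cn == 2, "hom_ref",
         ifelse(sv_type == "DEL",
                ifelse(cn == 0, "hom_alt", "het"),
                ifelse(cn >= 4, "hom_alt", "het")))
}

#' Simulate a two-caller synthetic cohort with ground truth
#'
#' Generates true CNV loci, per-sample integer copy numbers (with
#' `n_differentiated_loci` planted between-population shifts), two noisy
#' caller call sets (detection dropout, breakpoint jitter, Poisson PE/SR
#' evidence, IMPRECISE flags, one-sided false calls), a region-by-sample
#' read-count table driven by copy number with GC bias and mappability
#' attenuation, a sample map and a synthetic gene set. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes per-sample
#'   caller VCFs (`vcf_a/`, `vcf_b/`), `sample_map.tsv`,
#'   `read_counts.tsv` (+ `.trc` sidecar), `genes.bed` and
#'   `truth_cnv.bed`.
#' @return a list: `records_a`/`records_b` (pooled SV record tables),
#'   `sample_map`, `read_counts` (a [read_count_table()]), `genes`,
#'   and `truth` (loci, per-sample copy-number matrix, per-sample true
#'   CNV table, planted differentiated locus ids, target populations).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  smap <- sample_map_from_config(config)
  n_s <- nrow(smap)
  loci <- place_loci(config)
  n_l <- nrow(loci)

  # planted differentiated loci: one target population per locus gets a
  # uniform one-copy shift; other populations stay copy-neutral there
  pops <- names(config$populations)
  n_diff <- min(config$n_differentiated_loci, n_l)
  diff_idx <- if (n_diff > 0) sort(sample.int(n_l, n_diff)) else integer(0)
  diff_pop <- if (n_diff > 0)
    pops[(seq_len(n_diff) - 1) %% length(pops) + 1] else character(0)

  # copy-number matrix: baseline 2; carriers shift by locus type
  cn <- matrix(2L, nrow = n_l, ncol = n_s,
               dimnames = list(loci$locus_id, smap$sample_id))
  p_carrier <- runif(n_l, config$carrier_freq_range[1], config$carrier_freq_range[2])
  carrier <- matrix(runif(n_l * n_s) < p_carrier, nrow = n_l)  # recycles by row
  hom <- matrix(runif(n_l * n_s) < config$hom_fraction, nrow = n_l)
  shift <- ifelse(loci$sv_type == "DEL", -1L, 1L)
  cn <- cn + carrier * (1L + hom) * shift
  if (n_diff > 0) {
    for (k in seq_len(n_diff)) {
      i <- diff_idx[k]
      in_pop <- smap$population_code == diff_pop[k]
      cn[i, ] <- 2L
      cn[i, in_pop] <- 2L + config$diff_effect * shift[i]
    }
  }
  cn[cn < 0L] <- 0L

  truth_cnv <- {
    w <- which(cn != 2L, arr.ind = TRUE)
    data.frame(sample_id = smap$sample_id[w[, 2]],
               locus_id = loci$locus_id[w[, 1]],
               chrom = loci$chrom[w[, 1]],
               start = loci$start[w[, 1]], end = loci$end[w[, 1]],
               state = ifelse(loci$sv_type[w[, 1]] == "DEL", "loss", "gain"),
               copy_number = cn[w], stringsAsFactors = FALSE)
  }
  truth_cnv <- truth_cnv[order(truth_cnv$sample_id, truth_cnv$chrom,
                               truth_cnv$start), ]
  rownames(truth_cnv) <- NULL

  records <- lapply(c(A = "A", B = "B"), function(cl) {
    det_p <- config$detection_prob[[cl]]
    w <- which(cn != 2L, arr.ind = TRUE)
    det <- runif(nrow(w)) < det_p
    w <- w[det, , drop = FALSE]
    n <- nrow(w)
    jit <- function(n) as.integer(round(rnorm(n, 0, config$jitter_sd)))
    s <- pmax(1L, loci$start[w[, 1]] + jit(n))
    e <- loci$end[w[, 1]] + jit(n)
    e <- pmax(e, s + 1L)
    true_rec <- sv_records(
      sample_id = smap$sample_id[w[, 2]], caller = cl,
      chrom = loci$chrom[w[, 1]], start = s, end = e,
      sv_type = loci$sv_type[w[, 1]],
      pe = rpois(n, config$pe_mean), sr = rpois(n, config$sr_mean),
      imprecise = runif(n) < config$imprecise_prob,
      genotype = genotype_from_cn(cn[w], loci$sv_type[w[, 1]]))
    # one-sided false calls, uniform over the genome
    fr <- config$false_call_rate[[cl]]
    per_sample_det <- tabulate(w[, 2], nbins = n_s)
    n_false <- rpois(n_s, fr * per_sample_det)
    if (sum(n_false) > 0) {
      sid <- rep(smap$sample_id, n_false)
      nf <- length(sid)
      is_del <- runif(nf) < config$deletion_fraction
      fl <- round(pmin(pmax(ifelse(is_del,
                                   rlnorm(nf, config$del_meanlog, config$del_sdlog),
                                   rlnorm(nf, config$dup_meanlog, config$dup_sdlog)),
                            config$min_truth_len), config$max_truth_len))
      fchrom <- sample(sprintf("chr%d", seq_len(config$n_chrom)), nf, replace = TRUE)
      fs <- floor(runif(nf, 1, config$chrom_length - fl))
      false_rec <- sv_records(
        sample_id = sid, caller = cl, chrom = fchrom,
        start = as.integer(fs), end = as.integer(fs + fl),
        sv_type = ifelse(is_del, "DEL", "DUP"),
        pe = rpois(nf, config$pe_mean), sr = rpois(nf, config$sr_mean),
        imprecise = runif(nf) < config$imprecise_prob,
        genotype = "het")
      true_rec <- rbind(true_rec, false_rec)
    }
    true_rec <- true_rec[order(true_rec$sample_id, true_rec$chrom,
                               true_rec$start, true_rec$end), ]
    rownames(true_rec) <- NULL
    true_rec
  })

  # read counts at the true loci, scaled by copy number, GC and mappability
  gc <- runif(n_l, 0.3, 0.6)
  mapp <- runif(n_l, 0.85, 1)
  trc <- round(rnorm(n_s, config$mean_trc, config$trc_cv * config$mean_trc))
  trc <- pmax(trc, 1)
  names(trc) <- smap$sample_id
  s_len <- loci$end - loci$start
  genome <- config$n_chrom * config$chrom_length
  gcb <- exp(config$gc_bias_coef * (gc - 0.45))
  mu <- (cn / 2) * outer(s_len * gcb * mapp / genome, trc)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_size),
                   nrow = n_l, dimnames = dimnames(cn))
  rct <- read_count_table(loci[, c("chrom", "start", "end")], counts,
                          trc, gc, mapp)

  # synthetic gene set: non-overlapping, uniform
  genes <- local({
    gl <- round(runif(config$n_genes, 5e3, 5e4))
    gchrom <- sample(sprintf("chr%d", seq_len(config$n_chrom)),
                     config$n_genes, replace = TRUE)
    gs <- floor(runif(config$n_genes, 1, config$chrom_length - gl))
    df <- data.frame(chrom = gchrom, start = as.integer(gs),
                     end = as.integer(gs + gl),
                     name = sprintf("GENE%04d", seq_len(config$n_genes)),
                     stringsAsFactors = FALSE)
    gr <- granges_from_intervals(df)
    df <- df[GenomicRanges::countOverlaps(gr, gr) == 1, ]  # drop mutual overlaps
    df[order(df$chrom, df$start), ]
  })
  rownames(genes) <- NULL

  bundle <- list(records_a = records$A, records_b = records$B,
                 sample_map = smap, read_counts = rct, genes = genes,
                 truth = list(loci = loci, copy_number = cn,
                              cnv = truth_cnv,
                              differentiated_loci = loci$locus_id[diff_idx],
                              differentiated_pop = diff_pop),
                 config = config)
  if (!is.null(dir)) write_cohort(bundle, dir)
  bundle
}

vcf_header <- function(cfg, sample_id) {
  c("##fileformat=VCFv4.2",
    "##source=cnvpop-simulator",
    sprintf("##contig=<ID=chr%d,length=%d>", seq_len(cfg$n_chrom),
            as.integer(cfg$chrom_length)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Paired-end support\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split-read support\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id))
}

gt_to_vcf <- function(g) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[g]
}

#' Write a simulated cohort bundle to disk
#'
#' @param bundle result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in c("a", "b")) {
    sub <- file.path(dir, paste0("vcf_", cl))
    dir.create(sub, showWarnings = FALSE)
    rec <- bundle[[paste0("records_", cl)]]
    for (s in unique(bundle$sample_map$sample_id)) {
      r <- rec[rec$sample_id == s, , drop = FALSE]
      info <- sprintf("SVTYPE=%s;END=%d;PE=%d;SR=%d%s",
                      r$sv_type, r$end, r$pe, r$sr,
                      ifelse(r$imprecise, ";IMPRECISE", ""))
      lines <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s\tGT\t%s",
                       r$chrom, r$start, paste0("sv", seq_len(nrow(r))),
                       r$sv_type, info, gt_to_vcf(r$genotype))
      writeLines(c(vcf_header(bundle$config, s), lines),
                 file.path(sub, paste0(s, ".vcf")))
    }
  }
  write.table(bundle$sample_map, file.path(dir, "sample_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_read_counts(bundle$read_counts, file.path(dir, "read_counts.tsv"))
  write_bed(bundle$genes, file.path(dir, "genes.bed"))
  write_bed(bundle$truth$cnv[, c("chrom", "start", "end", "state", "sample_id")],
            file.path(dir, "truth_cnv.bed"))
  invisible(dir)
}

# >=50% reciprocal overlap matching between two interval sets of one sample
match_reciprocal <- function(calls, truth, min_frac = 0.5) {
  if (nrow(calls) == 0 || nrow(truth) == 0)
    return(list(call_matched = logical(nrow(calls)),
                truth_matched = logical(nrow(truth))))
  gg <- align_seqlevels(granges_from_intervals(calls),
                        granges_from_intervals(truth))
  grc <- gg$x; grt <- gg$y
  hits <- GenomicRanges::findOverlaps(grc, grt)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(grc[qi], grt[si]))
  good <- ow >= min_frac * GenomicRanges::width(grc)[qi] &
    ow >= min_frac * GenomicRanges::width(grt)[si] &
    calls$state[qi] == truth$state[si]
  list(call_matched = seq_len(nrow(calls)) %in% qi[good],
       truth_matched = seq_len(nrow(truth)) %in% si[good])
}

#' Precision/recall of pipeline output against ground truth
#'
#' Call-level precision and recall with at-least-50% reciprocal-overlap,
#' state-matched pairing per sample, and (when a scan result is given)
#' differentiation recall: the fraction of planted differentiated loci
#' flagged by the across-all V_ST scan.
#'
#' @param cnv consensus CNV calls (pipeline output).
#' @param truth the `truth` element of a [simulate_cohort()] bundle.
#' @param vst_result optional [vst_scan()] result whose rows are the
#'   truth loci.
#' @param min_frac reciprocal-overlap fraction (default 0.5).
#' @return a named list with `precision`, `recall`, counts, and
#'   (optionally) `differentiation_recall`.
#' @export
truth_metrics <- function(cnv, truth, vst_result = NULL, min_frac = 0.5) {
  samples <- unique(c(cnv$sample_id, truth$cnv$sample_id))
  n_call <- n_truth <- n_call_m <- n_truth_m <- 0L
  for (s in samples) {
    cc <- cnv[cnv$sample_id == s, , drop = FALSE]
    tt <- truth$cnv[truth$cnv$sample_id == s, , drop = FALSE]
    m <- match_reciprocal(cc, tt, min_frac)
    n_call <- n_call + nrow(cc); n_truth <- n_truth + nrow(tt)
    n_call_m <- n_call_m + sum(m$call_matched)
    n_truth_m <- n_truth_m + sum(m$truth_matched)
  }
  out <- list(precision = if (n_call > 0) n_call_m / n_call else NA_real_,
              recall = if (n_truth > 0) n_truth_m / n_truth else NA_real_,
              n_calls = n_call, n_truth = n_truth,
              n_calls_matched = n_call_m, n_truth_matched = n_truth_m)
  if (!is.null(vst_result)) {
    allr <- vst_result[vst_result$comparison == "all", , drop = FALSE]
    planted <- truth$differentiated_loci
    key <- paste0(truth$loci$chrom, ":", truth$loci$start, "-", truth$loci$end)
    planted_key <- key[truth$loci$locus_id %in% planted]
    flagged <- allr$locus[allr$is_differentiated]
    out$differentiation_recall <- if (length(planted_key) > 0)
      mean(planted_key %in% flagged) else NA_real_
  }
  out
}
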