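#' @importFrom stats median quantile rbinom rlnorm rnbinom rnorm rpois runif var setNames
#' @importFrom utils read.table write.table
#' @importFrom methods as
NULL

# Internal coordinate convention: 0-based half-open [start, end), the BED
# convention. VCF symbolic DEL/DUP records place POS on the base before the
# event, so internal start = POS and length = END - POS.

SV_GENOTYPES <- c("hom_ref", "het", "hom_alt", "missing")

gt_from_vcf <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% "1/1"] <- "hom_alt"
  out
}

#' Construct a table of SV records
#'
#' Builds the canonical per-caller SV call table used throughout the
#' pipeline. Intervals are 0-based half-open.
#'
#' @param sample_id,caller,chrom,start,end,sv_type,pe,sr,imprecise,genotype
#'   vectors (recycled to a common length) with the per-record fields;
#'   `sv_type` is `"DEL"` or `"DUP"`, `genotype` one of `"hom_ref"`, `"het"`,
#'   `"hom_alt"`, `"missing"`.
#' @return a `data.frame` with one row per SV record.
#' @export
sv_records <- function(sample_id, caller, chrom, start, end, sv_type,
                       pe = 0L, sr = 0L, imprecise = FALSE,
                       genotype = "missing") {
  df <- data.frame(sample_id = as.character(sample_id),
                   caller = as.character(caller),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   sv_type = as.character(sv_type),
                   pe = as.integer(pe), sr = as.integer(sr),
                   imprecise = as.logical(imprecise),
                   genotype = as.character(genotype),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$end > df$start), all(df$pe >= 0), all(df$sr >= 0),
            all(df$sv_type %in% c("DEL", "DUP")),
            all(df$genotype %in% SV_GENOTYPES))
  df
}

vcf_info_field <- function(info, key) {
  # scalar INFO lookup; NA when absent
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

vcf_info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)
}

#' Parse an SV-flavoured VCF into SV records
#'
#' Reads a single-sample VCF carrying symbolic structural-variant records
#' (INFO keys `SVTYPE` and `END`) and returns the DEL/DUP records as a
#' 0-based half-open table. Evidence counts are looked up as INFO keys
#' `PE`/`SR` first, then as per-sample FORMAT fields; absent evidence is 0.
#' Records with other SVTYPEs (INV, BND, INS, ...) are skipped and counted;
#' records with `END < POS` are rejected with a message.
#'
#' @param path path to a VCF (4.x) file.
#' @param sample_id sample identifier to attach to the records. For
#'   multi-sample VCFs the FORMAT columns of this sample are used; it must
#'   then match a sample column name.
#' @param caller caller label (conventionally `"A"` or `"B"`).
#' @param verbose print a line for skipped/rejected records.
#' @return a `data.frame` of SV records (see [sv_records()]), with
#'   attribute `"n_skipped"` = number of non-DEL/DUP records skipped.
#' @export
parse_sv_vcf <- function(path, sample_id, caller, verbose = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  # pre-scan for malformed data lines so errors carry a line number
  lines <- readLines(path)
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[is_data], "\t", fixed = TRUE))
  if (any(nf < 8)) {
    bad <- which(is_data)[which(nf < 8)[1]]
    stop("malformed VCF line ", bad, " in ", path, ": fewer than 8 fields")
  }
  if (!any(is_data)) {
    return(structure(sv_records(character(0), character(0), character(0),
                                integer(0), integer(0), character(0)),
                     n_skipped = 0L))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- unname(vcfR::getINFO(v))
  pos <- as.integer(fix[, "POS"])
  chrom <- as.character(fix[, "CHROM"])

  svtype <- vcf_info_field(info, "SVTYPE")
  endpos <- suppressWarnings(as.integer(vcf_info_field(info, "END")))

  keep <- svtype %in% c("DEL", "DUP")
  n_skipped <- sum(!keep)
  if (verbose && n_skipped > 0)
    message("parse_sv_vcf: skipped ", n_skipped, " non-DEL/DUP record(s) in ", path)

  bad_end <- keep & (is.na(endpos) | endpos < pos)
  if (any(bad_end)) {
    if (verbose)
      message("parse_sv_vcf: rejected ", sum(bad_end),
              " record(s) with END < POS or missing END in ", path)
    keep <- keep & !bad_end
  }

  pe <- suppressWarnings(as.integer(vcf_info_field(info, "PE")))
  sr <- suppressWarnings(as.integer(vcf_info_field(info, "SR")))

  gt_chr <- rep("missing", length(pos))
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    samples <- colnames(v@gt)[-1]
    col <- if (sample_id %in% samples) sample_id else if (length(samples) == 1) samples else
      stop("sample '", sample_id, "' not found in VCF ", path)
    fmt_pe <- function(key) {
      x <- tryCatch(vcfR::extract.gt(v, element = key, as.numeric = TRUE)[, col],
                    error = function(e) rep(NA_real_, length(pos)))
      suppressWarnings(as.integer(x))
    }
    # FORMAT fallback for evidence only where INFO lacked the key
    if (any(is.na(pe))) { f <- fmt_pe("PE"); pe[is.na(pe)] <- f[is.na(pe)] }
    if (any(is.na(sr))) { f <- fmt_pe("SR"); sr[is.na(sr)] <- f[is.na(sr)] }
    gt <- tryCatch(vcfR::extract.gt(v, element = "GT")[, col],
                   error = function(e) rep(NA_character_, length(pos)))
    gt_chr <- gt_from_vcf(ifelse(is.na(gt), "./.", gt))
  }
  pe[is.na(pe)] <- 0L
  sr[is.na(sr)] <- 0L

  out <- sv_records(sample_id = sample_id, caller = caller,
                    chrom = chrom[keep],
                    start = pos[keep],          # POS = base before the event
                    end = endpos[keep],
                    sv_type = svtype[keep],
                    pe = pe[keep], sr = sr[keep],
                    imprecise = vcf_info_flag(info, "IMPRECISE")[keep],
                    genotype = gt_chr[keep])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write intervals with attributes to BED
#'
#' Writes a BED3+ file (0-based half-open, tab-separated, no header), with
#' any extra columns appended after chrom/start/end, sorted by
#' (chrom, start, end).
#'
#' @param records a `data.frame` with at least `chrom`, `start`, `end`.
#' @param path output path.
#' @param extra_cols character vector of additional column names to emit
#'   (defaults to every other column present).
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path,
                      extra_cols = setdiff(names(records), c("chrom", "start", "end"))) {
  stopifnot(all(c("chrom", "start", "end") %in% names(records)))
  df <- records[order(records$chrom, records$start, records$end),
                c("chrom", "start", "end", extra_cols), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file
#'
#' @param path BED file (0-based half-open, no header).
#' @param extra_cols names for columns after the first three, if present.
#' @return a `data.frame` with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- tryCatch(read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "integer", "integer",
                                           rep(NA, length(extra_cols)))),
                 error = function(e) {
                   data.frame(chrom = character(0), start = integer(0),
                              end = integer(0))
                 })
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols) && ncol(df) >= 3 + length(extra_cols))
    names(df)[4:(3 + length(extra_cols))] <- extra_cols
  df
}

#' Read and validate a sample -> breed -> population map
#'
#' Accepts a tab- or comma-separated file with header columns
#' `sample_id`, `breed_code`, `population_code`. Each sample must appear
#' once and each breed must map to exactly one population.
#'
#' @param path path to the mapping table.
#' @return a validated `data.frame`.
#' @export
read_sample_map <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  validate_sample_map(df)
}

#' @rdname read_sample_map
#' @param sample_map a data.frame with the three mapping columns.
#' @export
validate_sample_map <- function(sample_map) {
  need <- c("sample_id", "breed_code", "population_code")
  if (!all(need %in% names(sample_map)))
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  df <- sample_map[, need]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0)
    stop("duplicate sample id(s) in sample map: ",
         paste(unique(dup), collapse = ", "))
  bp <- unique(df[, c("breed_code", "population_code")])
  multi <- bp$breed_code[duplicated(bp$breed_code)]
  if (length(multi) > 0)
    stop("breed(s) mapped to more than one population: ",
         paste(unique(multi), collapse = ", "))
  df
}

# GRanges helpers: internal [start, end) <-> 1-based closed IRanges
granges_from_intervals <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# put two GRanges on a shared seqlevel set so overlap ops stay quiet
align_seqlevels <- function(x, y) {
  lv <- union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(y))
  GenomeInfoDb::seqlevels(x) <- lv
  GenomeInfoDb::seqlevels(y) <- lv
  list(x = x, y = y)
}

intervals_from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
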