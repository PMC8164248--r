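# small, fast configuration used by most simulator tests
small_config <- function(seed = 5, ...) {
  sim_config(seed = seed,
             populations = list(P1 = c(X = 5L), P2 = c(Y = 5L)),
             n_cnv_loci = 300L, n_chrom = 2L, chrom_length = 1e7,
             n_differentiated_loci = 4L, n_genes = 50L, ...)
}

zero_noise_config <- function(seed = 5, ...) {
  small_config(seed = seed, detection_prob = 1, jitter_sd = 0,
               false_call_rate = 0, imprecise_prob = 0, ...)
}

# evidence/precision-agnostic filter for identity checks
permissive <- filter_params(t_override = 0, use_imprecise = TRUE,
                            min_len = 50, max_len = 1e7)

test_that("the generator is byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(small_config(), dir = d1)
  simulate_cohort(small_config(), dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_true(length(f1) > 10)
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_cohort(small_config(seed = 6), dir = d3)
  expect_false(identical(readLines(file.path(d1, "truth_cnv.bed")),
                         readLines(file.path(d3, "truth_cnv.bed"))))
})

test_that("deletion_fraction = 1 yields no duplication records", {
  b <- simulate_cohort(small_config(deletion_fraction = 1))
  expect_equal(sum(b$records_a$sv_type == "DUP"), 0)
  expect_equal(sum(b$records_b$sv_type == "DUP"), 0)
  expect_true(all(b$truth$loci$sv_type == "DEL"))
})

test_that("emitted VCFs re-parse to the in-memory record tables", {
  d <- withr::local_tempdir()
  b <- simulate_cohort(small_config(), dir = d)
  s <- b$sample_map$sample_id[1]
  rec <- parse_sv_vcf(file.path(d, "vcf_a", paste0(s, ".vcf")), s, "A")
  mem <- b$records_a[b$records_a$sample_id == s, ]
  mem <- mem[order(mem$chrom, mem$start, mem$end), ]
  rec <- rec[order(rec$chrom, rec$start, rec$end), ]
  rownames(mem) <- rownames(rec) <- NULL
  expect_equal(rec[, c("chrom", "start", "end", "sv_type", "pe", "sr",
                       "imprecise", "genotype")],
               mem[, c("chrom", "start", "end", "sv_type", "pe", "sr",
                       "imprecise", "genotype")])
})

test_that("zero-noise cohorts are recovered exactly by the consensus pipeline", {
  b <- simulate_cohort(zero_noise_config())
  cnv <- consensus_cnv(b$records_a, b$records_b, permissive)
  m <- truth_metrics(cnv, b$truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  # exact interval identity, not just 50% reciprocal overlap
  got <- cnv[order(cnv$sample_id, cnv$chrom, cnv$start),
             c("sample_id", "chrom", "start", "end", "state")]
  want <- b$truth$cnv[order(b$truth$cnv$sample_id, b$truth$cnv$chrom,
                            b$truth$cnv$start),
                      c("sample_id", "chrom", "start", "end", "state")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("one-sided false calls are vetoed by the missing partner", {
  b <- simulate_cohort(small_config(false_call_rate = c(0.3, 0)))
  cnv <- consensus_cnv(b$records_a, b$records_b, permissive)
  m <- truth_metrics(cnv, b$truth)
  expect_gte(m$precision, 0.99)
})

test_that("shuffled population labels drop differentiation recall to baseline", {
  # 5 planted loci in 500 = 1%, exactly the outlier budget of the flag rule
  cfg <- sim_config(seed = 9,
                    populations = list(P1 = c(X = 12L), P2 = c(Y = 12L)),
                    n_cnv_loci = 500L, n_chrom = 2L, chrom_length = 1e7,
                    n_differentiated_loci = 5L)
  b <- simulate_cohort(cfg)
  norm <- gc_adjust(b$read_counts)
  scan <- vst_scan(norm, b$sample_map, comparisons = list("all"))
  m <- truth_metrics(b$truth$cnv, b$truth, scan)
  expect_gte(m$differentiation_recall, 0.9)
  withr::with_seed(99, {
    perm <- b$sample_map
    perm$population_code <- sample(perm$population_code)
  })
  scan_p <- vst_scan(norm, perm, comparisons = list("all"))
  m_p <- truth_metrics(b$truth$cnv, b$truth, scan_p)
  expect_lte(m_p$differentiation_recall, 0.2)
})

test_that("infeasible locus placement raises a generation error", {
  expect_error(simulate_cohort(
    sim_config(seed = 1, populations = list(P1 = c(X = 2L)),
               n_cnv_loci = 400L, n_chrom = 1L, chrom_length = 3e6,
               del_meanlog = log(2e4), dup_meanlog = log(2e4),
               n_differentiated_loci = 0L)),
    "placed")
})

test_that("consensus count is at least the zero-jitter per-locus pair count", {
  b <- simulate_cohort(zero_noise_config(seed = 8))
  cnv <- consensus_cnv(b$records_a, b$records_b, permissive)
  pairs <- oracle_intersect(b$records_a[b$records_a$sample_id == "S001", ],
                            b$records_b[b$records_b$sample_id == "S001", ])
  expect_gte(nrow(cnv[cnv$sample_id == "S001", ]), nrow(pairs))
})
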