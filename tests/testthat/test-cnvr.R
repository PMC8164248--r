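smap3 <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    breed_code = c("X", "X", "Y", "Z"),
                    population_code = c("P1", "P1", "P2", "P2"),
                    stringsAsFactors = FALSE)

test_that("merging produces maximal regions with union state and carriers", {
  calls <- rbind(calls_df("chr1", 0, 100, "loss", "s1"),
                 calls_df("chr1", 50, 150, "loss", "s2"),
                 calls_df("chr1", 200, 300, "gain", "s1"))
  reg <- merge_cnv(calls, "global", smap3, n_cohort_samples = 4)
  expect_equal(reg$start, c(0L, 200L))
  expect_equal(reg$end, c(150L, 300L))
  expect_equal(reg$state, c("loss", "gain"))
  expect_equal(reg$n_carrier_samples, c(2L, 1L))
  expect_equal(reg$frequency, c(0.5, 0.25))

  both <- merge_cnv(rbind(calls_df("chr1", 0, 100, "loss"),
                          calls_df("chr1", 90, 200, "gain")), "global")
  expect_equal(both$state, "both")
  expect_equal(c(both$start, both$end), c(0L, 200L))

  expect_equal(nrow(merge_cnv(calls[0, ], "global")), 0)
})

test_that("merged regions match the boolean-mask union oracle", {
  withr::local_seed(21)
  for (rep in 1:5) {
    n <- 500
    start <- sample.int(9500, n, replace = TRUE)
    end <- pmin(start + sample(1:400, n, replace = TRUE), 10000L)
    calls <- calls_df("toy", start, end,
                      sample(c("loss", "gain"), n, replace = TRUE),
                      sample(c("s1", "s2", "s3"), n, replace = TRUE))
    reg <- merge_cnv(calls, "global")
    want <- oracle_union_mask(start, end, 10000L)
    expect_equal(reg$start, as.integer(want$start))
    expect_equal(reg$end, as.integer(want$end))
  }
})

test_that("merging is idempotent and per-population scope partitions samples", {
  withr::local_seed(22)
  start <- sample.int(9000, 200, replace = TRUE)
  calls <- calls_df("chr1", start, start + sample(10:200, 200, replace = TRUE),
                    "loss", sample(smap3$sample_id, 200, replace = TRUE))
  reg <- merge_cnv(calls, "global", smap3, 4)
  again <- merge_cnv(data.frame(sample_id = "m", reg[, c("chrom", "start", "end", "state")]),
                     "global")
  expect_equal(again[, c("chrom", "start", "end")],
               reg[, c("chrom", "start", "end")])

  per_pop <- merge_cnv(calls, "per_population", smap3)
  expect_setequal(unique(per_pop$scope_group), c("P1", "P2"))
  # a population's regions only carry that population's samples
  for (g in c("P1", "P2")) {
    carriers <- unlist(strsplit(per_pop$carrier_samples[per_pop$scope_group == g], ";"))
    expect_true(all(carriers %in% smap3$sample_id[smap3$population_code == g]))
  }
  expect_error(merge_cnv(calls_df("chr1", 1, 10, "loss", "ghost"),
                         "per_population", smap3), "ghost")
})

test_that("state partition conserves counts and coverage in the summary", {
  lens <- list(loss = c(100L, 200L, 300L), gain = 1000L, both = c(50L, 70L))
  regions <- do.call(rbind, lapply(names(lens), function(st) {
    start <- cumsum(c(0L, utils::head(lens[[st]], -1) + 10L))
    data.frame(chrom = paste0("chr_", st), start = start,
               end = start + lens[[st]], state = st, stringsAsFactors = FALSE)
  }))
  s <- summarize_cnvr(regions)
  expect_equal(s$n[s$state == "overall"], sum(s$n[s$state != "overall"]))
  expect_equal(s$coverage_bp[s$state == "overall"],
               sum(s$coverage_bp[s$state != "overall"]))
  expect_equal(s$mean_len[s$state == "loss"], 200)
  expect_equal(s$median_len[s$state == "loss"], 200)
  expect_equal(s$coverage_bp[s$state == "loss"], 600)
  expect_equal(s$mean_len, s$coverage_bp / s$n)
})

test_that("sharing flags all-breed, all-population and private regions", {
  reg <- merge_cnv(rbind(
    calls_df("chr1", 0, 100, "loss", "s1"),
    calls_df("chr1", 10, 90, "loss", "s3"),
    calls_df("chr1", 20, 80, "loss", "s4"),     # region 1: breeds X,Y,Z
    calls_df("chr2", 0, 50, "loss", "s1"),
    calls_df("chr2", 10, 60, "loss", "s2"),     # region 2: breed X only
    calls_df("chr3", 0, 50, "gain", "s3")),     # region 3: breed Y only
    "global", smap3, 4)
  sh <- cnvr_sharing(reg, smap3)
  r1 <- sh[sh$chrom == "chr1", ]
  expect_true(r1$present_in_all_breeds)
  expect_true(r1$present_in_all_populations)
  expect_false(r1$private_to_breed)
  expect_equal(r1$frequency, 0.75)              # 3 carriers of 4 samples
  r2 <- sh[sh$chrom == "chr2", ]
  expect_true(r2$private_to_breed)
  expect_true(r2$private_to_population)
  expect_false(r2$present_in_all_populations)
  expect_equal(attr(sh, "summary")[["n_private_to_breed"]], 2)
  expect_error(cnvr_sharing(reg, smap3[-1, ]), "s1")
})

test_that("frequency never exceeds one and shrinks as the cohort grows", {
  calls <- rbind(calls_df("chr1", 0, 100, "loss", "s1"),
                 calls_df("chr1", 50, 150, "loss", "s2"))
  f4 <- merge_cnv(calls, "global", n_cohort_samples = 4)$frequency
  f8 <- merge_cnv(calls, "global", n_cohort_samples = 8)$frequency
  expect_lte(f4, 1)
  expect_lt(f8, f4)
})

test_that("catalogue comparison reports overlap in both directions", {
  x <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  y <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  rep1 <- compare_cnvr_sets(x, y)
  expect_equal(rep1$intersection_bp, 50)
  expect_equal(rep1$frac_x_in_intersection, 0.5)
  expect_equal(rep1$frac_y_in_intersection, 0.5)
  expect_equal(rep1$union_of_overlapping_pairs_bp, 150)

  far <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  rep2 <- compare_cnvr_sets(x, far)
  expect_equal(rep2$intersection_bp, 0)
  expect_equal(rep2$n_x_overlapping, 0)

  bad <- data.frame(chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L))
  expect_error(compare_cnvr_sets(bad, y), "internally overlapping")
})

test_that("comparison intersection equals the mask oracle and is symmetric", {
  withr::local_seed(23)
  for (rep in 1:5) {
    mk_set <- function() {
      start <- sort(sample.int(9000, 30))
      end <- pmin(start + sample(10:200, 30, replace = TRUE), 10000L)
      df <- data.frame(chrom = "toy", start = start, end = end)
      keep <- c(TRUE, start[-1] >= cummax(end[-30]))  # enforce disjointness
      df[keep, ]
    }
    x <- mk_set(); y <- mk_set()
    want <- oracle_intersection_bp(x, y, 10000L)
    expect_equal(compare_cnvr_sets(x, y)$intersection_bp, want)
    expect_equal(compare_cnvr_sets(y, x)$intersection_bp, want)
  }
})
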