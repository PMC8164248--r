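mk <- function(start, end, sv_type = "DEL", pe = 4L, sr = 3L,
               imprecise = FALSE, caller = "A", sample_id = "s1",
               chrom = "chr1") {
  sv_records(sample_id, caller, chrom, start, end, sv_type,
             pe = pe, sr = sr, imprecise = imprecise)
}

test_that("evidence, precision and length filters follow the operating point", {
  p <- filter_params(stringency = "medium")
  expect_equal(p$t, 5L)
  expect_equal(filter_params(stringency = "low")$t, 3L)
  expect_equal(filter_params(stringency = "stringent")$t, 8L)
  expect_equal(filter_params(t_override = 7)$t, 7L)

  recs <- rbind(mk(1000, 2000, pe = 4L, sr = 3L),             # 7 >= 5: kept
                mk(3000, 4000, pe = 2L, sr = 2L),             # 4 < 5: dropped
                mk(5000, 3505000, pe = 9L, sr = 9L),          # 3.5 Mb: dropped
                mk(6e6, 7e6, pe = 9L, sr = 9L, imprecise = TRUE))
  kept <- filter_sv(recs, p)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 1000L)
  # imprecise retained when allowed
  expect_equal(nrow(filter_sv(recs, filter_params(use_imprecise = TRUE))), 2)
  # 10 Mb alternative cut-off readmits the 3.5 Mb record
  expect_equal(nrow(filter_sv(recs, filter_params(max_len = 1e7))), 2)
  # min_len applies pre-intersection only when asked
  short <- mk(100, 130, pe = 9L, sr = 9L)
  expect_equal(nrow(filter_sv(short, filter_params())), 1)
  expect_equal(nrow(filter_sv(short,
    filter_params(min_len_stage = "before_intersect"))), 0)
})

test_that("intersection emits the overlap segment per matching pair", {
  a <- mk(50, 450)
  b <- rbind(mk(100, 200, caller = "B"), mk(300, 400, caller = "B"))
  out <- intersect_callsets(a, b)
  expect_equal(nrow(out), 2)   # one long A record, two short B records
  expect_equal(out$start, c(100L, 300L))
  expect_equal(out$end, c(200L, 400L))
  expect_equal(out$state, c("loss", "loss"))

  # type mismatch yields nothing
  expect_equal(nrow(intersect_callsets(mk(0, 100, "DEL"),
                                       mk(0, 100, "DUP", caller = "B"))), 0)
  # half-open touch is not an overlap
  expect_equal(nrow(intersect_callsets(mk(0, 100),
                                       mk(100, 200, caller = "B"))), 0)
  # different samples violate the contract
  expect_error(intersect_callsets(mk(0, 100),
                                  mk(0, 100, caller = "B", sample_id = "s2")),
               "one sample")
})

test_that("intersection matches the all-pairs oracle and is symmetric", {
  withr::local_seed(11)
  for (rep in 1:5) {
    a <- random_records(200, caller = "A")
    b <- random_records(200, caller = "B")
    got <- intersect_callsets(a, b)
    got <- got[order(got$chrom, got$start, got$end, got$state),
               c("chrom", "start", "end", "state")]
    rownames(got) <- NULL
    want <- oracle_intersect(a, b)
    rownames(want) <- NULL
    expect_equal(got, want)
    swapped <- intersect_callsets(b, a)
    expect_equal(got,
                 {s <- swapped[order(swapped$chrom, swapped$start,
                                     swapped$end, swapped$state),
                               c("chrom", "start", "end", "state")]
                  rownames(s) <- NULL; s})
  }
})

test_that("consensus segments are contained in one source record per caller", {
  withr::local_seed(12)
  a <- random_records(150, caller = "A")
  b <- random_records(150, caller = "B")
  out <- intersect_callsets(a, b)
  for (i in seq_len(nrow(out))) {
    expect_true(out$start[i] >= out$a_start[i] && out$end[i] <= out$a_end[i])
    expect_true(out$start[i] >= out$b_start[i] && out$end[i] <= out$b_end[i])
  }
})

test_that("length cut-offs at the consensus stage respect the boundaries", {
  seg <- function(len) calls_df("chr1", 1000, 1000 + len)
  base <- cbind(seg(40), a_start = 0L, a_end = 1L, b_start = 0L, b_end = 1L)
  p <- filter_params()
  expect_equal(nrow(derive_cnv(base, p)), 0)                    # 40 < 50
  b50 <- base; b50$end <- 1050L
  expect_equal(nrow(derive_cnv(b50, p)), 1)                     # exactly 50 kept
  big <- base; big$end <- base$start + 3000001L
  expect_equal(nrow(derive_cnv(big, p)), 0)                     # > 3 Mb dropped
  exact <- base; exact$end <- base$start + 3000000L
  expect_equal(nrow(derive_cnv(exact, p)), 1)
})

test_that("tightening filters never increases the consensus call count", {
  withr::local_seed(13)
  a <- random_records(300, caller = "A")
  a$pe <- rpois(300, 4); a$sr <- rpois(300, 3)
  b <- random_records(300, caller = "B")
  b$pe <- rpois(300, 4); b$sr <- rpois(300, 3)
  counts <- vapply(c(0, 3, 5, 8, 12), function(t) {
    nrow(consensus_cnv(a, b, filter_params(t_override = t, min_len = 1)))
  }, 0)
  expect_true(all(diff(counts) <= 0))
  wide <- nrow(consensus_cnv(a, b, filter_params(t_override = 0, min_len = 1,
                                                 max_len = 1e6)))
  narrow <- nrow(consensus_cnv(a, b, filter_params(t_override = 0, min_len = 20,
                                                   max_len = 200)))
  expect_lte(narrow, wide)
})
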