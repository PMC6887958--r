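test_that("segment-mean to CCN conversion is exact and strictly monotone", {
  expect_identical(segmean_to_ccn(0), 2)
  expect_identical(segmean_to_ccn(1), 4)
  expect_identical(segmean_to_ccn(-1), 1)
  expect_error(segmean_to_ccn(NaN), "finite")
  s <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(segmean_to_ccn(s)) > 0))
  # AM-GM: ccn(s) + ccn(-s) >= 4, equality at 0
  expect_true(all(segmean_to_ccn(s) + segmean_to_ccn(-s) >= 4))
  expect_equal(segmean_to_ccn(0) + segmean_to_ccn(0), 4)
})

test_that("ccn_to_segmean inverts the conversion to machine precision", {
  expect_equal(ccn_to_segmean(2), 0)
  expect_equal(ccn_to_segmean(4), 1)
  s <- seq(-3, 3, by = 0.05)
  expect_equal(ccn_to_segmean(segmean_to_ccn(s)), s, tolerance = 1e-12)
  expect_error(ccn_to_segmean(0), "> 0")
  expect_error(ccn_to_segmean(-1), "> 0")
})

test_that("segment filter applies the length percentile then the probe floor", {
  seg <- data.frame(sample_id = "S1", chrom = 1L,
                    start = c(0, 100, 300, 600),
                    end = c(10, 120, 330, 640),   # lengths 10, 20, 30, 40
                    num_probes = 12L, segment_mean = 0)
  fl <- filter_segments(seg)
  # 25th percentile of (10,20,30,40) by linear interpolation is 17.5
  expect_equal(fl$report$length_threshold_bp, 17.5)
  expect_equal(fl$segments$end - fl$segments$start, c(20, 30, 40))
  # probe floor removes regardless of length
  seg$num_probes <- c(12L, 12L, 9L, 12L)
  fl2 <- filter_segments(seg)
  expect_false(30 %in% (fl2$segments$end - fl2$segments$start))
  expect_equal(fl2$report$n_removed_probes, 1L)
  # degenerate: all lengths equal, removal is strict-below so all retained
  seg3 <- data.frame(sample_id = "S1", chrom = 1L, start = 0, end = 50,
                     num_probes = 12L, segment_mean = 0)[rep(1, 4), ]
  expect_equal(nrow(filter_segments(seg3)$segments), 4L)
  # report arithmetic
  expect_equal(fl2$report$n_input,
               fl2$report$n_retained + fl2$report$n_removed_length +
                 fl2$report$n_removed_probes)
  expect_error(filter_segments(seg[0, ]), "non-empty")
})

test_that("per-patient summaries are length-weighted means", {
  seg1 <- data.frame(sample_id = "P1", chrom = 1L, start = 0, end = 100,
                     num_probes = 10L, segment_mean = 0)
  expect_equal(patient_mean_ccn(seg1), 2)
  seg2 <- data.frame(sample_id = "P1", chrom = 1L,
                     start = c(0, 100), end = c(100, 200), num_probes = 10L,
                     segment_mean = ccn_to_segmean(c(1, 3)))
  expect_equal(patient_mean_ccn(seg2), 2)
  seg3 <- data.frame(sample_id = "P1", chrom = 1L,
                     start = c(0, 100), end = c(100, 400), num_probes = 10L,
                     segment_mean = ccn_to_segmean(c(2, 4)))
  expect_equal(patient_mean_ccn(seg3), (100 * 2 + 300 * 4) / 400)
  # uniform weighting as the alternative
  expect_equal(patient_mean_ccn(seg3, weighting = "uniform"), 3)
  # absolute segment mean
  seg4 <- data.frame(sample_id = "P1", chrom = 1L,
                     start = c(0, 100), end = c(100, 200), num_probes = 10L,
                     segment_mean = c(0.5, -0.5))
  expect_equal(patient_abs_segmean(seg4), 0.5)
  seg5 <- data.frame(sample_id = "P1", chrom = 1L,
                     start = c(0, 100), end = c(100, 400), num_probes = 10L,
                     segment_mean = c(0.2, -0.6))
  expect_equal(patient_abs_segmean(seg5), (1 * 0.2 + 3 * 0.6) / 4)
  expect_true(is.na(suppressWarnings(patient_mean_ccn(seg5[0, ]))))
})

test_that("arm projection splits at the centromere and imputes neutral", {
  at <- make_arm_table(centromere = rep(100, 22), chrom_length = rep(200, 22))
  seg <- data.frame(sample_id = "P1", chrom = 1L,
                    start = c(0, 50), end = c(50, 100), num_probes = 10L,
                    segment_mean = ccn_to_segmean(c(2, 4)))
  pr <- project_to_arms(seg, at)
  expect_equal(unname(pr$arm_values["1p"]), 3)
  # segment spanning the centromere is split 10/10
  seg2 <- data.frame(sample_id = "P1", chrom = 2L, start = 90, end = 110,
                     num_probes = 10L, segment_mean = 1)
  pr2 <- project_to_arms(seg2, at)
  expect_equal(unname(pr2$arm_covered_bp[c("2p", "2q")]), c(10, 10))
  expect_equal(unname(pr2$arm_values["2p"]), 4)
  expect_equal(unname(pr2$arm_values["2q"]), 4)
  # uncovered arms are neutral and flagged
  expect_equal(unname(pr$arm_values["3p"]), 2)
  expect_true("3p" %in% pr$missing_arms)
  # segment past the chromosome end is clipped with a warning
  seg3 <- data.frame(sample_id = "P1", chrom = 1L, start = 150, end = 250,
                     num_probes = 10L, segment_mean = 0)
  expect_warning(pr3 <- project_to_arms(seg3, at), "clipped")
  expect_equal(unname(pr3$arm_covered_bp["1q"]), 50)
})

test_that("uniform tiling at segment mean s yields arm CCN exactly 2^s * 2", {
  at <- synthetic_arm_table()
  arms <- at[!at$zero_length, ]
  s <- 0.37
  seg <- data.frame(sample_id = "P1", chrom = arms$chrom,
                    start = arms$start, end = arms$end,
                    num_probes = 50L, segment_mean = s)
  pr <- project_to_arms(seg, at)
  expect_equal(unname(pr$arm_values), rep(segmean_to_ccn(s), nrow(arms)))
  expect_length(pr$missing_arms, 0)
})

test_that("arm matrices stack profiles with fixed ordering and flag gaps", {
  at <- make_arm_table(centromere = rep(100, 22), chrom_length = rep(200, 22))
  seg <- data.frame(sample_id = "P1", chrom = 1L, start = 0, end = 200,
                    num_probes = 10L, segment_mean = 1)
  p1 <- project_to_arms(seg, at)
  p_empty <- project_to_arms(seg[0, ], at)
  m <- build_arm_matrix(list(P1 = p1, P2 = p_empty))
  expect_equal(dim(m), c(2L, 44L))
  expect_equal(unname(m["P1", "1p"]), 4)
  expect_true(all(m["P2", ] == 2))
  expect_true(all(attr(m, "missing")["P2", ]))
  expect_error(build_arm_matrix(list(P1 = p1, P1 = p1)), "uniquely named")
  # values are bounded by the min/max CCN of overlapping segments
  sc <- get_small_cohort()
  expect_true(all(sc$am >= 0))
  expect_true(all(is.finite(sc$am)))
  expect_equal(ncol(sc$am), 39L)
})
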