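test_that("background-median shifting reproduces hand-shifted values", {
  # probes: background {1, 2, 3} on each flank, region values {5, 6}
  tr <- signal_track(tibble::tibble(
    contig = "c",
    pos = c(0L, 10L, 20L, 100L, 110L, 200L, 210L, 220L),
    value = c(1, 2, 3, 5, 6, 1, 2, 3)), "probe_log2_ratio")
  peak <- tibble::tibble(contig = "c", start = 95L, end = 120L)
  norm <- normalize_peak_region(tr, peak, flank = 120L)
  expect_equal(norm$background_median, 2)
  expect_equal(norm$region$shifted, c(3, 4))

  # background median already zero leaves values unchanged
  tr0 <- signal_track(tibble::tibble(
    contig = "c", pos = c(0L, 10L, 20L, 100L, 110L, 200L, 210L),
    value = c(-1, 0, 1, 5, 6, -1, 1)), "probe_log2_ratio")
  norm0 <- normalize_peak_region(tr0, peak, flank = 120L)
  expect_equal(norm0$region$shifted, c(5, 6))

  expect_error(
    normalize_peak_region(tr, tibble::tibble(contig = "c", start = 0L,
                                             end = 300L), flank = 10L),
    "no background")
})

test_that("normalization is idempotent and peak averages are shift-invariant", {
  tr <- fx_site_probe_track(6000, 3000, 2, noise_sd = 0.1, seed = 51)
  peak <- tibble::tibble(contig = "c", start = 2800L, end = 3200L)
  n1 <- normalize_peak_region(tr, peak)
  shifted <- tr
  shifted$value <- n1$region$shifted[match(shifted$pos, n1$region$pos)]
  sel <- !is.na(shifted$value)
  # re-normalizing the already-shifted region reproduces the same averages
  tr2 <- tr
  tr2$value <- tr$value - n1$background_median
  n2 <- normalize_peak_region(tr2, peak)
  expect_equal(n2$peak_average, n1$peak_average, tolerance = 1e-12)
  # adding a constant to the whole track cancels in the peak average
  tr3 <- tr
  tr3$value <- tr$value + 7.5
  n3 <- normalize_peak_region(tr3, peak)
  expect_equal(n3$peak_average, n1$peak_average, tolerance = 1e-9)
})

test_that("background probes inside neighbouring peaks are excluded", {
  tr <- signal_track(tibble::tibble(
    contig = "c", pos = c(0L, 10L, 20L, 100L, 200L, 210L, 220L),
    value = c(10, 10, 10, 5, 1, 2, 3)), "probe_log2_ratio")
  peak <- tibble::tibble(contig = "c", start = 95L, end = 120L)
  other <- tibble::tibble(contig = "c", start = 0L, end = 30L)
  norm <- normalize_peak_region(tr, peak, flank = 120L,
                                exclude_peaks = other)
  expect_equal(norm$background_median, 2)  # left-flank 10s dropped
  expect_identical(norm$n_background, 3L)
})

test_that("titration flags saturated and unsaturated Langmuir sites correctly", {
  concs <- c(0.45, 0.7, 1.9, 2.5)
  mk_tracks <- function(kd) {
    out <- lapply(concs, function(cc) {
      fx_site_probe_track(5000, 2500, langmuir_occupancy(cc, kd))
    })
    names(out) <- concs
    out
  }
  region <- tibble::tibble(contig = "c", start = 2300L, end = 2700L)
  # Kd 0.2: theta(2.5)/theta(1.9) ~ 1.02, inside the 5% band
  tt <- titration_analysis(mk_tracks(0.2), region)
  expect_true(all(tt$saturated))
  expect_true(all(diff(tt$peak_average) >= -1e-12))
  # Kd 2: the top step is a 14% increase
  tt2 <- titration_analysis(mk_tracks(2), region)
  expect_false(any(tt2$saturated))
  # identical tracks at all concentrations: no significant pairs, saturated
  same <- lapply(concs, function(cc) fx_site_probe_track(5000, 2500, 1))
  names(same) <- concs
  tt3 <- titration_analysis(same, region)
  expect_true(all(tt3$saturated))
  expect_true(all(is.na(tt3$p_step[tt3$concentration == concs[1]])))
  later <- tt3$p_step[tt3$concentration != concs[1]]
  expect_true(all(is.na(later) | later >= 0.05))
})

test_that("non-specific regions show no concentration dependence", {
  concs <- c(0.45, 0.7, 1.9, 2.5)
  tracks <- lapply(seq_along(concs), function(i) {
    fx_site_probe_track(5000, 2500, 0, noise_sd = 0.05, seed = 60 + i)
  })
  names(tracks) <- concs
  region <- tibble::tibble(contig = "c", start = 2300L, end = 2700L)
  tt <- titration_analysis(tracks, region)
  steps <- tt$p_step[!is.na(tt$p_step)]
  expect_true(all(steps > 0.01))
  expect_true(max(abs(tt$peak_average)) < 0.05)
})

test_that("strain comparison classifies shared, increased, and unmasked peaks", {
  wt <- fx_site_probe_track(8000, 2000, 2, noise_sd = 0.05, seed = 71)
  peaks <- tibble::tibble(contig = "c", start = c(1800L, 5800L),
                          end = c(2200L, 6200L))
  # identical tracks: everything shared and unchanged, never increased
  cs_same <- compare_strains(peaks, peaks, wt, wt)
  expect_true(all(cs_same$verdict == "shared_unchanged"))

  # mutant gains a new peak at 6000 and triples the shared one
  mut <- wt
  bump2 <- 2 * pmax(0, 1 - abs(mut$pos - 6000) / 200)
  bump1 <- 4 * pmax(0, 1 - abs(mut$pos - 2000) / 200)
  mut$value <- mut$value + bump1 + bump2
  peaks_mut <- peaks
  cs <- compare_strains(peaks[1, ], peaks_mut, wt, mut)
  expect_identical(cs$verdict[1], "shared_increased")
  expect_identical(cs$verdict[2], "mut_only")

  # swapping strain labels swaps the only-verdicts
  cs_rev <- compare_strains(peaks_mut, peaks[1, ], mut, wt)
  expect_identical(sort(unique(cs_rev$verdict[2])), "wt_only")
})

test_that("sigma70 differential occupancy flags direction and handles degeneracy", {
  withr::local_seed(72)
  pos <- 0:5999
  base <- 1 + stats::rnorm(6000, 0, 0.05)
  bump <- 2 * pmax(0, 1 - abs(pos - 3000) / 200)
  t_minus <- fx_track(base + 2 * bump)
  t_plus <- fx_track(base + bump)
  pk <- tibble::tibble(contig = "c", start = 2800L, end = 3200L,
                       summit = 3000L)
  res <- sigma70_differential(pk, t_minus, t_plus)
  expect_identical(res$verdict, "+")
  # equal tracks give no verdict
  res_eq <- sigma70_differential(pk, t_minus, t_minus)
  expect_identical(res_eq$verdict, "none")
  # zero-variance positive difference (after background shifting) is
  # significant by the degenerate rule
  inside <- pos >= 2800 & pos < 3200
  t_lo <- fx_track(ifelse(inside, 2, 1))
  t_hi <- fx_track(ifelse(inside, 3, 1))
  res_deg <- sigma70_differential(pk, t_hi, t_lo)
  expect_identical(res_deg$verdict, "+")
})

test_that("the simple peak caller finds, merges and summits runs", {
  expect_identical(nrow(simple_peak_caller(fx_track(rep(0, 500)), 0.5)), 0L)

  pos <- 0:999
  bump <- 3 * pmax(0, 1 - abs(pos - 500) / 100)
  pk <- simple_peak_caller(fx_track(bump), 0.5, min_len = 20, merge_gap = 10)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$summit, 500L)

  two <- 3 * pmax(0, 1 - abs(pos - 300) / 80) +
    3 * pmax(0, 1 - abs(pos - 460) / 80)
  merged <- simple_peak_caller(fx_track(two), 1, min_len = 20,
                               merge_gap = 100)
  expect_identical(nrow(merged), 1L)
  split2 <- simple_peak_caller(fx_track(two), 1, min_len = 20,
                               merge_gap = 5)
  expect_identical(nrow(split2), 2L)
})
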