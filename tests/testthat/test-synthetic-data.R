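test_that("genome generation is seeded, GC-calibrated, and validated", {
  g1 <- make_genome(100, seed = 101)
  g2 <- make_genome(100, seed = 101)
  expect_identical(g1, g2)
  g <- make_genome(1e5, gc = 0.5, seed = 102)
  gc_frac <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc_frac - 0.5), 0.01)
  expect_error(make_genome(100, gc = 0), "strictly between")
  expect_error(make_genome(100, gc = 1.2), "strictly between")
})

test_that("Langmuir occupancy is monotone with the half-saturation anchor", {
  expect_equal(langmuir_occupancy(0.3, 0.3), 0.5)
  conc <- seq(0, 5, 0.1)
  th <- langmuir_occupancy(conc, 0.2)
  expect_true(all(diff(th) > 0))
  expect_true(all(th >= 0 & th <= 1))
})

test_that("site planting respects score range, spacing, and the seed", {
  g <- make_genome(30000, seed = 103)
  p1 <- plant_sites(g, fx_pwm, 8, min_gap = 1500, seed = 104)
  p2 <- plant_sites(g, fx_pwm, 8, min_gap = 1500, seed = 104)
  expect_identical(p1$sites, p2$sites)
  expect_true(all(p1$sites$score >= fx_max_score - 1.5))
  expect_true(all(diff(p1$sites$start) >= 1500))
  # planted sequences really are in the genome on the stated strand
  for (i in seq_len(nrow(p1$sites))) {
    s <- p1$sites[i, ]
    written <- substr(p1$genome[[1]], s$start + 1, s$end)
    expect_identical(written,
                     if (s$strand == "+") s$sequence else
                       reverse_complement(s$sequence))
  }
})

test_that("a zero slope makes all planted affinities equal", {
  g <- make_genome(30000, seed = 105)
  p <- plant_sites(g, fx_pwm, 6, min_gap = 1500,
                   model = binding_model(beta = 0), seed = 106)
  expect_equal(p$sites$kd, rep(p$sites$kd[1], 6))
})

test_that("impossible placements fail with the achievable count", {
  g <- make_genome(10000, seed = 107)
  expect_error(plant_sites(g, fx_pwm, 20, min_gap = 1000, seed = 108),
               "at most")
})

test_that("planted consensus sites are recovered by a permissive scan", {
  g <- make_genome(20000, seed = 109)
  p <- plant_sites(g, fx_pwm, 5, min_gap = 1500, seed = 110)
  hits <- scan_pwm(p$genome, fx_pwm, -10, dist = fx_dist)
  expect_true(all(p$sites$start %in% hits$start))
})

test_that("the synthetic truth keeps occluded sites inside their NAP regions", {
  truth <- simulate_regulon_truth(genome_length = 1e5, n_sites = 15,
                                  seed = 111)
  expect_identical(sum(truth$sites$occluded), 3L)  # 20% of 15
  occ <- truth$sites[truth$sites$occluded, ]
  for (i in seq_len(nrow(occ))) {
    regs <- truth$nap_regions[[occ$occluding_nap[i]]]
    expect_true(any(regs$start <= occ$start[i] & regs$end >= occ$end[i]))
  }
  # reproducibility from the seed
  truth2 <- simulate_regulon_truth(genome_length = 1e5, n_sites = 15,
                                   seed = 111)
  expect_identical(truth$sites, truth2$sites)
  expect_identical(truth$genome, truth2$genome)
})

test_that("noiseless ChIP readouts peak at planted site centers", {
  truth <- simulate_regulon_truth(genome_length = 5e4, n_sites = 6,
                                  seed = 112)
  chip <- simulate_chip(truth, noise_sd = 0, seed = 113)
  acc <- truth$sites[!truth$sites$occluded, ]
  centers <- (acc$start + acc$end) %/% 2
  for (ctr in centers) {
    win <- chip$track$value[chip$track$pos >= ctr - 200 &
                              chip$track$pos <= ctr + 200]
    expect_identical(which.max(win), 201L)  # local maximum at the center
  }
  # occluded sites contribute nothing
  occ <- truth$sites[truth$sites$occluded, ]
  expect_true(all(chip$expected[truth$sites$occluded] == 0))
  expect_false(any(occ$start %in% (chip$peaks$summit - 7L)))
  expect_error(simulate_chip(truth, noise_sd = -1), "non-negative")
  # determinism
  c1 <- simulate_chip(truth, seed = 114)
  c2 <- simulate_chip(truth, seed = 114)
  expect_identical(c1$track$value, c2$track$value)
})

test_that("dropping H-NS from the occlusion set unmasks its silent sites", {
  truth <- simulate_regulon_truth(genome_length = 2e5, n_sites = 30,
                                  seed = 115)
  hns_occ <- which(truth$sites$occluded &
                     truth$sites$occluding_nap == "hns")
  expect_gt(length(hns_occ), 0L)
  wt <- simulate_chip(truth, noise_sd = 0)
  mut <- simulate_chip(truth, noise_sd = 0,
                       occlusion_naps = c("ihf", "fis"))
  expect_true(all(!hns_occ %in% wt$peaks$site_index))
  expect_true(all(hns_occ %in% mut$peaks$site_index))
})

test_that("expression simulation is seeded and validates the fold effect", {
  ops <- tibble::tibble(operon_id = c("opA", "opB"),
                        genes = list(c("a1", "a2"), "b1"),
                        strand = "+", first_gene_start = c(100L, 5000L),
                        contig = "c", tss = NA_integer_,
                        tss_status = "unknown")
  eff <- tibble::tibble(operon_id = "opA", direction = "up", fold = 4)
  e1 <- simulate_expression(ops, eff, seed = 116)
  e2 <- simulate_expression(ops, eff, seed = 116)
  expect_identical(e1$wt_minusO2, e2$wt_minusO2)
  expect_equal(unname(e1$gene_effects), c(2, 2, 0))
  expect_error(simulate_expression(ops, dplyr::mutate(eff, fold = -1)),
               "positive")
  # a fold of 1 plants no shift and the DE caller finds nothing
  null_eff <- dplyr::mutate(eff, fold = 1)
  en <- simulate_expression(ops, null_eff, seed = 117)
  mat <- cbind(en$wt_minusO2, en$dfnr_minusO2)
  colnames(mat) <- c(paste0("w", 1:3), paste0("m", 1:3))
  v <- de_genes(mat, paste0("w", 1:3), paste0("m", 1:3))
  expect_true(all(v$direction == "none"))
  # seq-like output is integer counts
  es <- simulate_expression(ops, eff, kind = "seq", seed = 118)
  expect_true(all(es$wt_minusO2 >= 0))
  expect_true(all(es$wt_minusO2 == round(es$wt_minusO2)))
})

test_that("heavy capture noise decouples summit height from site score", {
  truth <- simulate_regulon_truth(
    genome_length = 5e5, n_sites = 60,
    model = binding_model(capture_sd = 1.0), seed = 119)
  chip <- simulate_chip(truth, noise_sd = 0.02, seed = 120)
  acc <- chip$peaks
  r <- stats::cor(acc$summit_height, truth$sites$score[acc$site_index])
  expect_lt(abs(r), 0.3)
  expect_gte(nrow(acc), 45L)
})

test_that("upstream screen sets carry exactly the planted sites", {
  us <- make_upstream_set(fx_pwm, n = 20, n_planted = 2,
                          ln_p_threshold = -12, seed = 121)
  hits_per_seq <- vapply(us$sequences, function(s) {
    nrow(scan_pwm(c(u = s), fx_pwm, -12, dist = fx_dist))
  }, integer(1))
  expect_identical(names(which(hits_per_seq > 0)), us$planted)
  expect_identical(length(us$sequences), 20L)
  expect_true(all(nchar(us$sequences) == 500L))
})
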