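test_that("peak-operon association is window-bounded and strand-aware", {
  peaks <- tibble::tibble(contig = "c", start = 1000L, end = 1200L,
                          summit = 1100L)
  op <- function(start, strand = "+", id = "op") {
    tibble::tibble(operon_id = id, genes = list("g"), strand = strand,
                   first_gene_start = start, contig = "c",
                   tss = NA_integer_, tss_status = "unknown")
  }
  # peak edge 300 nt upstream: associated
  expect_identical(nrow(associate_peaks(peaks, op(1499L))), 1L)
  # peak edge 501 nt upstream: outside the window
  expect_identical(nrow(associate_peaks(peaks, op(1700L))), 0L)
  expect_identical(nrow(associate_peaks(peaks, op(1699L))), 1L)
  # start inside the peak counts as distance zero
  a <- associate_peaks(peaks, op(1100L))
  expect_identical(a$distance, 0L)
  # a downstream peak on the plus strand is not upstream evidence
  expect_identical(nrow(associate_peaks(peaks, op(500L))), 0L)
  # ... but it is for a minus-strand operon (upstream is rightward)
  expect_identical(nrow(associate_peaks(peaks, op(500L, "-"))), 1L)
})

test_that("one peak between divergent operons serves both", {
  peaks <- tibble::tibble(contig = "c", start = 900L, end = 1100L,
                          summit = 1000L)
  ops <- tibble::tibble(
    operon_id = c("right_op", "left_op"),
    genes = list("r1", "l1"),
    strand = c("+", "-"),
    first_gene_start = c(1300L, 700L),
    contig = "c", tss = NA_integer_, tss_status = "unknown")
  a <- associate_peaks(peaks, ops)
  expect_setequal(a$operon_id, c("right_op", "left_op"))
})

test_that("single-operon category decisions follow the evidence order", {
  genome <- make_genome(4000, seed = 131)
  pwm <- fx_pwm
  op <- tibble::tibble(operon_id = "op1", genes = list("g1"), strand = "+",
                       first_gene_start = 2000L, contig = "chr",
                       tss = NA_integer_, tss_status = "unknown")
  names(genome) <- "chr"
  pk_map <- tibble::tibble(operon_id = "op1", peak_index = 1L,
                           distance = 100L)
  no_map <- tibble::tibble(operon_id = character(), peak_index = integer(),
                           distance = integer())
  cons_up <- tibble::tibble(operon_id = "op1", direction = "up")
  cons_down <- tibble::tibble(operon_id = "op1", direction = "down")
  cons_none <- tibble::tibble(operon_id = character(),
                              direction = character())
  cat_of <- function(...) assign_categories(op, ..., genome = genome,
                                            pwm = pwm,
                                            dist = fx_dist)$category
  # peak + consensus up: direct activation (dmsABC pattern)
  expect_identical(cat_of(pk_map, cons_up), "1")
  # peak + consensus down: direct repression (ndh pattern)
  expect_identical(cat_of(pk_map, cons_down), "2")
  # peak, no DE, Fur repressor tag: masked activation (feoA pattern),
  # repressor precedence beating a coactivator tag
  ann <- tibble::tibble(operon_id = "op1", tag = c("Fur", "NarL"),
                        role = c("repressor", "coactivator"))
  expect_identical(cat_of(pk_map, cons_none, annotations = ann), "4")
  ann_co <- ann[2, ]
  expect_identical(cat_of(pk_map, cons_none, annotations = ann_co), "3")
  # peak, no DE, no annotation: other mechanisms
  expect_identical(cat_of(pk_map, cons_none), "5")
  # no peak, no DE, no mutant evidence: unclassified
  expect_identical(cat_of(no_map, cons_none), "unclassified")
})

test_that("the category-7 branch needs mutant-only peak and mutant-only DE", {
  genome <- c(chr = make_genome(4000, seed = 132)[[1]])
  op <- tibble::tibble(operon_id = "op1", genes = list("g1"), strand = "+",
                       first_gene_start = 2000L, contig = "chr",
                       tss = NA_integer_, tss_status = "unknown")
  no_map <- tibble::tibble(operon_id = character(), peak_index = integer(),
                           distance = integer())
  mut_map <- tibble::tibble(operon_id = "op1", peak_index = 1L,
                            distance = 100L)
  cons_none <- tibble::tibble(operon_id = character(),
                              direction = character())
  mut_de <- tibble::tibble(operon_id = "op1", direction = "up")
  asg <- assign_categories(op, no_map, cons_none, genome, fx_pwm,
                           mut_peak_map = mut_map, mut_o2_de = mut_de,
                           wt_o2_de = NULL, dist = fx_dist)
  expect_identical(asg$category, "7")
  # the same change in the WT background disqualifies it
  asg2 <- assign_categories(op, no_map, cons_none, genome, fx_pwm,
                            mut_peak_map = mut_map, mut_o2_de = mut_de,
                            wt_o2_de = mut_de, dist = fx_dist)
  expect_identical(asg2$category, "unclassified")
})

test_that("the printed-table fixture reproduces the regulon category counts", {
  fx <- fnr_category_fixture(seed = 1)
  peak_map <- associate_peaks(fx$peaks, fx$operons)
  mut_map <- associate_peaks(fx$mut_peaks, fx$operons)
  asg <- assign_categories(fx$operons, peak_map, fx$consensus, fx$genome,
                           fx$pwm, annotations = fx$annotations,
                           mut_peak_map = mut_map,
                           mut_o2_de = fx$mut_o2_de,
                           wt_o2_de = fx$wt_o2_de)
  counts <- category_counts(asg)
  merged <- dplyr::left_join(fx$expected_counts, counts, by = "category")
  expect_identical(merged$n.y, merged$n.x)
  # partition: every operon gets exactly one category
  expect_identical(sum(counts$n), nrow(fx$operons))
  # the single screened-out indirect candidate is the hmp analogue
  expect_identical(asg$operon_id[asg$category == "direct_candidate"], "hmp")
})

test_that("removing all peaks empties categories 1 through 5", {
  fx <- fnr_category_fixture(seed = 1)
  no_peaks <- tibble::tibble(operon_id = character(),
                             peak_index = integer(), distance = integer())
  asg <- assign_categories(fx$operons, no_peaks, fx$consensus, fx$genome,
                           fx$pwm, annotations = fx$annotations)
  expect_false(any(asg$category %in% c("1", "2", "3", "4", "5")))
})

test_that("report tables carry 1-based summits, offsets and sentinels", {
  ops <- tibble::tibble(
    operon_id = c("opA", "opB"),
    genes = list("a1", "b1"),
    strand = "+", first_gene_start = c(2000L, 4000L), contig = "c",
    tss = c(2000L, NA), tss_status = c("known", "unknown"))
  asg <- tibble::tibble(operon_id = c("opA", "opB"),
                        category = c("1", "1"), direction = "up",
                        has_peak = TRUE, n_peaks = 1L,
                        annotation_role = NA_character_,
                        upstream_site = NA, conflict = FALSE)
  calls <- tibble::tibble(operon_id = c("opA", "opB"),
                          summit = c(1899L, 3899L), n_sites = c(1L, 2L),
                          site_start = c(1951L, 3951L),
                          site_end = c(1965L, 3965L))
  sig <- tibble::tibble(operon_id = "opA", verdict = "+")
  wt <- tibble::tibble(operon_id = "opA", direction = "up")
  tab <- report_table(asg, ops, calls, sig, wt)
  rowA <- tab[tab$operon_id == "opA", ]
  expect_identical(rowA$peak_center_nt, 1900L)
  expect_identical(rowA$location, "-41.5")
  expect_identical(rowA$sigma70, "+")
  expect_identical(rowA$wt_expression, "+")
  rowB <- tab[tab$operon_id == "opB", ]
  expect_identical(rowB$location, "TSS not known")
  expect_identical(rowB$wt_expression, "o")
  # empty assignments give an empty table
  expect_identical(nrow(report_table(asg[0, ], ops)), 0L)
})

test_that("the printed tables carry the published row structure", {
  direct <- fnr_table_direct()
  expect_identical(sum(direct$category == "1"), 32L)
  expect_identical(sum(direct$category == "2"), 21L)
  expect_identical(nrow(fnr_table_narlp()), 9L)
  expect_identical(nrow(fnr_table_crp()), 11L)
  expect_identical(sum(fnr_table_crp()$divergent_pair), 1L)
  expect_identical(nrow(fnr_table_fur()), 10L)
  expect_identical(nrow(fnr_table_fnrs()), 11L)
  expect_true(all(fnr_table_fnrs()$regulation == "Repressed"))
  # feoA sits in both the nitrate and the Fur tables
  expect_true("feoA" %in% fnr_table_narlp()$operon)
  expect_true("feoA" %in% fnr_table_fur()$operon)
})
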