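#' Reference alignment of FNR binding-site sequences
#'
#' Twenty aligned 14-mers around the TTGATnnnnATCAA gapped-palindome
#' consensus, including the well-known strong (ydfZ-like,
#' TTGATaaaaAACAA) and weak (frdA-like, TCGATctcgTCAAA) site variants.
#' Used to build the default PWM; the central four positions are
#' unconstrained, the flanking half-sites nearly conserved.
#'
#' @return Character vector of aligned site sequences.
#' @export
fnr_reference_alignment <- function() {
  c("TTGATCCGGATCAA", "TTGATAAAAATCAA", "TTGATGTCAATCAA", "TTGATTTACATCAA",
    "TTGATCGTCATCAA", "TTGATGGATATCAA", "TTGATACCTATCAA", "TTGATTCAGATCAA",
    "TTGATCTTGATCAA", "TTGATGACCATCAA", "TTGATATGTATCAA", "TTGATTGCAATCAA",
    "TCGATCTCGTCAAA", "TTGATAAAAAACAA", "TTGCTAGTCATCAA", "TTGATCATGATCAT",
    "ATGATTCGCATCAA", "TTGATGCTAATCGA", "TTGATTAGCGTCAA", "TTAATCCGCATCAA")
}

#' Default FNR position weight matrix
#'
#' Built from [fnr_reference_alignment()] with a uniform background and
#' unit total pseudocount.
#'
#' @return An `fnr_pwm`.
#' @export
fnr_pwm_default <- function() {
  build_pwm(fnr_reference_alignment())
}

#' Printed summary of the directly activated / repressed operons
#'
#' The direct-regulon report: per operon the 1-based peak center, number
#' of called binding sites, location of the top-scoring site relative to
#' the TSS (sentinels `"TSS not known"` / `"TSS not in peak region"`),
#' the differential sigma-70 occupancy verdict, the WT anaerobic vs
#' aerobic expression verdict, and the category (`1` direct activation,
#' `2` direct repression).
#'
#' @return Tibble with one row per directly regulated operon.
#' @export
fnr_table_direct <- function() {
  act <- tibble::tribble(
    ~peak_center, ~operon, ~n_sites, ~location, ~sigma70, ~wt_expr,
    1003976L, "pyrD", 1L, "-38.5", "+", "o",
    1656036L, "ynfEFGH-dmsD", 1L, "-40.5", "+", "+",
    1935550L, "pykA", 1L, "-40.5", "+", "+",
    3611605L, "nikABCDE", 1L, "-40.5", "+", "+",
    953741L, "focA-pflB", 2L, "-40.5", "+", "+",
    2714605L, "yfiD", 1L, "-40.5", "+", "+",
    940035L, "dmsABC", 1L, "-41.5", "+", "+",
    1279003L, "narGHJI", 1L, "-41.5", "+", "+",
    1627208L, "ydfZ", 2L, "-41.5", "+", "+",
    1837412L, "ynjE", 1L, "-41.5", "+", "+",
    3491947L, "nirBDC-cysG", 1L, "-41.5", "+", "+",
    4285670L, "nrfABCDEFG", 1L, "-41.5", "+", "+",
    34059L, "caiF", 1L, "-41.5", "+", "o",
    1277082L, "narK", 1L, "-41.5", "+", "+",
    877441L, "bssR", 1L, "-41.5", "+", "+",
    1752688L, "ydhYVWXUT", 1L, "-42.5", "+", "+",
    1407150L, "fnrS", 1L, "-42.5", "+", NA,
    4380446L, "frdABCD", 1L, "-45.5", "+", "+",
    3635591L, "pitA", 1L, "-56.5", "+", "o",
    1831403L, "ydjXYZ-ynjABCD", 1L, "-60.5", "+", "+",
    913151L, "hcp-hcr", 1L, "-72.5", "no_sigma70_peak", "+",
    2411410L, "ackA-pta", 1L, "-74.5", "+", "+",
    4347259L, "dcuB-fumB", 1L, "-132.5", "+", "+",
    1665279L, "ynfK", 1L, "TSS not known", "+", "+",
    2415052L, "yfcC", 1L, "TSS not known", "+", "+",
    3299421L, "yhbUV", 1L, "TSS not known", "+", "+",
    3352152L, "yhcC", 1L, "TSS not known", "+", "+",
    3654199L, "yhiD", 1L, "TSS not in peak region", "+", "+",
    3463910L, "yjiML", 1L, "TSS not in peak region", "+", "+",
    4615181L, "yjjI", 1L, "TSS not known", "+", "+",
    655298L, "dcuC", 1L, "TSS not in peak region", "+", "+",
    4228181L, "pepE", 1L, "TSS not known", "+", "+"
  )
  rep1 <- tibble::tribble(
    ~peak_center, ~operon, ~n_sites, ~location, ~sigma70, ~wt_expr,
    1397604L, "fnr", 1L, "-0.5", "-", "o",
    142604L, "can", 2L, "-11.5", "-", "-",
    2088088L, "hisLGDC", 1L, "-11.5", "+", "o",
    1165151L, "ndh", 1L, "-50.5", "-", "o",
    2176686L, "fbaB", 1L, "-59.5", "no_sigma70_peak", "o",
    1030741L, "yccA", 1L, "-71.5", "-", "o",
    3217259L, "ygjG", 1L, "-96.5", "-", "-",
    1014801L, "rmf", 1L, "-98.5", "+", "o",
    4231491L, "lysC", 2L, "-115.5", "+", "o",
    1986025L, "yecR", 1L, "+30", "-", "o",
    400328L, "iraP", 2L, "TSS not in peak region", "-", "-",
    1860717L, "msrB", 1L, "TSS not in peak region", "+", "-",
    2342585L, "nrdAB", 1L, "TSS not in peak region", "-", "-"
  )
  rep2 <- tibble::tribble(
    ~peak_center, ~operon, ~n_sites, ~location, ~sigma70, ~wt_expr,
    3656030L, "gadE", 2L, "-22.5", "+", "+",
    3654924L, "hdeD", 1L, "-43.5", "+", "+",
    121987L, "pdhR-aceEF-lpdA", 1L, "-50.5", "-", "+",
    770404L, "cydAB", 1L, "-53.5", "+", "+",
    3654924L, "hdeAB-yhiD", 1L, "-126.5", "+", "+",
    1311935L, "ompW", 1L, "-126.5", "+", "+",
    2310730L, "ompC", 1L, "TSS not in peak region", "+", "+",
    2848688L, "hycABCDEFGHI", 1L, "TSS not in peak region",
    "no_sigma70_peak", "+"
  )
  dplyr::bind_rows(
    dplyr::mutate(act, category = "1"),
    dplyr::mutate(rep1, category = "2"),
    dplyr::mutate(rep2, category = "2")
  )
}

#' Printed co-activation candidates (nitrate/nitrite-responsive)
#'
#' Operons with an FNR peak but no FNR-dependent expression change under
#' glucose fermentation, activated by FNR together with NarL/NarP when
#' nitrate or nitrite is present (Category 3).
#'
#' @return Tibble `peak_center, operon`.
#' @export
fnr_table_narlp <- function() {
  tibble::tribble(
    ~peak_center, ~operon,
    816075L, "moaA", 1185000L, "pepT", 1545300L, "fdnG", 2301675L, "napF",
    2619000L, "upp", 3538050L, "feoA", 4131675L, "katG", 4360558L, "cadC",
    4460925L, "nrdD"
  )
}

#' Printed co-activation candidates (CRP)
#'
#' Operons with an FNR peak, no expression change under glucose
#' fermentation, and evidence for CRP co-activation in other carbon
#' sources (Category 3). The `uxaC/exuT` row is a divergent pair served
#' by one peak; `divergent_pair` marks it.
#'
#' @return Tibble `peak_center, operon, divergent_pair`.
#' @export
fnr_table_crp <- function() {
  tibble::tribble(
    ~peak_center, ~operon, ~divergent_pair,
    1019175L, "ompA", FALSE, 1157025L, "ptsG", FALSE,
    1608750L, "uxaB", FALSE, 2531550L, "ptsH", FALSE,
    2632200L, "guaB", FALSE, 3229415L, "fadH", FALSE,
    3242850L, "uxaC/exuT", TRUE, 3408300L, "dusB", FALSE,
    3490500L, "ppiA", FALSE, 3544500L, "gntT", FALSE,
    4366425L, "aspA", FALSE
  )
}

#' Printed Fur-repressed candidates
#'
#' Operons with an FNR peak, no expression change, and known Fur
#' repression under iron-replete conditions (Category 4).
#'
#' @return Tibble `peak_center, operon`.
#' @export
fnr_table_fur <- function() {
  tibble::tribble(
    ~peak_center, ~operon,
    611865L, "fes", 621417L, "fepD/entS", 623975L, "fepB/entC",
    1298775L, "oppA", 1308975L, "tonB", 1634625L, "nohA",
    1735575L, "purR", 3150150L, "exbB", 3273150L, "garP",
    3538050L, "feoA"
  )
}

#' Printed FnrS-target operons in the indirect regulon
#'
#' Peakless operons with an FNR-dependent expression change explained by
#' the FNR-activated small RNA FnrS (Category 6).
#'
#' @return Tibble `operon, regulation`.
#' @export
fnr_table_fnrs <- function() {
  tibble::tibble(
    operon = c("gpmA", "cydDC", "chaA", "adhP", "sodB", "yobA-yebZY",
               "dld", "folE-yeiB", "eco", "folX-yfcH", "yggG"),
    regulation = "Repressed"
  )
}

# sample a block that is free of above-threshold motif matches in the
# upstream window [upstream_lo, upstream_hi) of the block
clean_block <- function(block_len, pwm, dist, ln_p, upstream_lo,
                        upstream_hi) {
  repeat {
    s <- make_genome(block_len, 0.5)[[1]]
    win <- substr(s, upstream_lo + 1L, upstream_hi)
    hits <- scan_pwm(c(b = win), pwm, ln_p, dist = dist)
    if (nrow(hits) == 0L) return(s)
  }
}

#' Synthetic evidence fixture reproducing the printed category structure
#'
#' Builds an operon universe mirroring the published regulon layout (32
#' directly activated, 21 directly repressed, 9 + 12 co-activation
#' candidates, 10 Fur-masked, a configurable Category-5 remainder, 70
#' peakless DE operons of which exactly one — the hmp analogue — carries
#' a planted upstream site, plus mutant-only-peak and unclassified
#' operons), with peaks, consensus verdicts, annotations and a genome laid
#' out so [assign_categories()] reproduces the printed counts.
#'
#' Each operon occupies a 2-kb genome block with the translation start at
#' block offset 1500 and, where applicable, a peak at offsets 1150-1350.
#' Upstream windows of the peakless DE operons are guaranteed free of
#' above-threshold motif matches except for the planted one.
#'
#' @param pwm PWM used for the planted site and the upstream screen
#'   (default [fnr_pwm_default()]).
#' @param n_category5 Category-5 filler operons (default 5).
#' @param n_category7 Mutant-only-peak operons (default 3).
#' @param n_unclassified Operons with no evidence (default 3).
#' @param ln_p_threshold Threshold the clean upstream windows must respect
#'   (default [fnr_default_ln_p()]).
#' @param seed RNG seed (default 1).
#' @return List: `genome, operons, peaks, mut_peaks, consensus,
#'   annotations, mut_o2_de, wt_o2_de, expected_counts, pwm`.
#' @export
fnr_category_fixture <- function(pwm = fnr_pwm_default(), n_category5 = 5L,
                                 n_category7 = 3L, n_unclassified = 3L,
                                 ln_p_threshold = fnr_default_ln_p(),
                                 seed = 1L) {
  dist <- score_distribution(pwm)
  direct <- fnr_table_direct()
  ops <- tibble::tibble(
    operon_id = c(direct$operon,
                  fnr_table_narlp()$operon,
                  fnr_table_crp()$operon,
                  fnr_table_fur()$operon,
                  sprintf("cat5_op%02d", seq_len(n_category5)),
                  c(fnr_table_fnrs()$operon, "hmp",
                    sprintf("indirect_op%02d", seq_len(58L))),
                  sprintf("cat7_op%02d", seq_len(n_category7)),
                  sprintf("bg_op%02d", seq_len(n_unclassified))),
    kind = c(rep("direct", nrow(direct)),
             rep("narlp", 9L), rep("crp", 11L), rep("fur", 10L),
             rep("cat5", n_category5),
             rep("indirect", 70L),
             rep("cat7", n_category7),
             rep("bg", n_unclassified))
  )
  # feoA appears in both the NarL/NarP and the Fur tables; keep one operon
  ops <- ops[!duplicated(ops$operon_id), ]
  n <- nrow(ops)
  block <- 2000L
  withr::with_seed(as.integer(seed), {
    blocks <- character(n)
    for (i in seq_len(n)) {
      blocks[i] <- if (ops$kind[i] == "indirect") {
        clean_block(block, pwm, dist, ln_p_threshold, 1000L, 1500L)
      } else {
        make_genome(block, 0.5)[[1]]
      }
    }
    hmp_i <- which(ops$operon_id == "hmp")
    at <- 1200L
    substr(blocks[hmp_i], at + 1L, at + pwm$width) <- consensus_sequence(pwm)
    genome <- stats::setNames(paste(blocks, collapse = ""), "chr")
    operons <- tibble::tibble(
      operon_id = ops$operon_id,
      genes = purrr::map(ops$operon_id, ~ paste0(.x, "_g1")),
      strand = "+",
      first_gene_start = (seq_len(n) - 1L) * block + 1500L,
      contig = "chr",
      tss = NA_integer_,
      tss_status = "unknown"
    )
    peaked <- ops$kind %in% c("direct", "narlp", "crp", "fur", "cat5")
    peaks <- tibble::tibble(
      contig = "chr",
      start = operons$first_gene_start[peaked] - 350L,
      end = operons$first_gene_start[peaked] - 150L,
      summit = operons$first_gene_start[peaked] - 250L
    )
    cat7 <- ops$kind == "cat7"
    mut_peaks <- dplyr::bind_rows(
      peaks,
      tibble::tibble(contig = "chr",
                     start = operons$first_gene_start[cat7] - 350L,
                     end = operons$first_gene_start[cat7] - 150L,
                     summit = operons$first_gene_start[cat7] - 250L))
    consensus <- dplyr::bind_rows(
      tibble::tibble(operon_id = direct$operon,
                     direction = ifelse(direct$category == "1", "up",
                                        "down")),
      tibble::tibble(operon_id = ops$operon_id[ops$kind == "indirect"],
                     direction = rep(c("down", "up"), length.out = 70L))
    )
    annotations <- dplyr::bind_rows(
      tibble::tibble(operon_id = fnr_table_narlp()$operon, tag = "NarL",
                     role = "coactivator"),
      tibble::tibble(operon_id = fnr_table_crp()$operon, tag = "CRP",
                     role = "coactivator"),
      tibble::tibble(operon_id = fnr_table_fur()$operon, tag = "Fur",
                     role = "repressor")
    )
    mut_o2_de <- tibble::tibble(operon_id = ops$operon_id[cat7],
                                direction = "up")
    wt_o2_de <- tibble::tibble(operon_id = character(),
                               direction = character())
    expected <- tibble::tibble(
      category = c("1", "2", "3", "4", "5", "6", "direct_candidate", "7",
                   "unclassified"),
      # feoA carries both a NarL coactivator and a Fur repressor tag and
      # resolves to Category 4 by repressor precedence, so Category 3
      # holds 8 nitrate/nitrite rows plus the 11 CRP rows
      n = c(32L, 21L, 19L, 10L, n_category5, 69L, 1L, n_category7,
            n_unclassified)
    )
    list(genome = genome, operons = operons, peaks = peaks,
         mut_peaks = mut_peaks, consensus = consensus,
         annotations = annotations, mut_o2_de = mut_o2_de,
         wt_o2_de = wt_o2_de, expected_counts = expected, pwm = pwm)
  })
}
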