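#' Flag overlap of binding sites with NAP-enriched regions
#'
#' A site overlaps a NAP (nucleoid-associated protein) region on any
#' intersection of at least 1 bp. One logical column per NAP set plus an
#' `any_nap` column (logical OR) is added.
#'
#' @param sites Interval tibble of predicted binding sites.
#' @param nap_region_sets Named list of interval tibbles, one per NAP
#'   (e.g. `list(hns = ..., ihf = ..., fis = ...)`).
#' @return `sites` with one logical overlap column per NAP and `any_nap`.
#' @export
nap_overlap <- function(sites, nap_region_sets) {
  stopifnot(length(nap_region_sets) >= 1L, !is.null(names(nap_region_sets)))
  out <- sites
  for (nm in names(nap_region_sets)) {
    flag <- rep(FALSE, nrow(sites))
    flag[unique(overlap_pairs(sites, nap_region_sets[[nm]])$a)] <- TRUE
    out[[nm]] <- flag
  }
  out$any_nap <- Reduce(`|`, out[names(nap_region_sets)])
  out
}

#' Pooled two-proportion z-test
#'
#' The classic pooled-variance two-proportion z statistic without
#' continuity correction:
#' `z = (k1/n1 - k2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with
#' `p = (k1 + k2)/(n1 + n2)`. Both one- and two-sided p-values are from the
#' normal tail.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param sided `"two"` (default), `"greater"` (p1 > p2) or `"less"`.
#' @return Tibble: `p1, p2, z, p_value, sided`.
#' @export
proportion_ztest <- function(k1, n1, k2, n2,
                             sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  stopifnot(n1 >= 1L, n2 >= 1L, k1 >= 0L, k2 >= 0L)
  if (k1 > n1 || k2 > n2) stop("successes exceed trials")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- switch(sided,
              two = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  tibble::tibble(p1 = p1, p2 = p2, z = z, p_value = min(p, 1), sided = sided)
}

#' Classify H-NS enriched regions as extended or short
#'
#' Extended regions (length strictly greater than the cutoff, default
#' 1 kb) are taken as a proxy for H-NS filaments; a 1000-bp region is
#' "short" under the strict rule.
#'
#' @param regions Interval tibble.
#' @param cutoff Length cutoff in bp (default 1000).
#' @return `regions` with columns `length` and `class`
#'   (`"extended"`/`"short"`).
#' @export
classify_hns_regions <- function(regions, cutoff = 1000L) {
  regions$length <- regions$end - regions$start
  regions$class <- ifelse(regions$length > cutoff, "extended", "short")
  regions
}

#' Silent-site / NAP occlusion report
#'
#' Splits predicted sites into peak-confirmed and silent (no ChIP peak)
#' sets, flags NAP overlap for each, and tests whether NAP co-occupancy at
#' silent sites exceeds that at confirmed sites with the pooled
#' two-proportion z-test (both sidednesses are reported; the occlusion
#' hypothesis predicts silent > confirmed).
#'
#' @param predictions Motif-hit tibble of predicted sites.
#' @param peaks Peak tibble.
#' @param nap_region_sets Named list of NAP interval tibbles.
#' @return List of class `fnr_occlusion_report`: `sites` (per-site flags
#'   with a `status` column), `proportions` (per-NAP and any-NAP counts for
#'   both groups), `tests` (z-tests per NAP and any-NAP, one- and
#'   two-sided).
#' @export
occlusion_report <- function(predictions, peaks, nap_region_sets) {
  flagged <- nap_overlap(predictions, nap_region_sets)
  silent_flag <- !overlaps_any(predictions, peaks)
  flagged$status <- ifelse(silent_flag, "silent", "confirmed")
  nap_cols <- c(names(nap_region_sets), "any_nap")
  props <- purrr::map(nap_cols, function(col) {
    tibble::tibble(
      nap = col,
      silent_k = sum(flagged[[col]][flagged$status == "silent"]),
      silent_n = sum(flagged$status == "silent"),
      confirmed_k = sum(flagged[[col]][flagged$status == "confirmed"]),
      confirmed_n = sum(flagged$status == "confirmed")
    )
  }) |> dplyr::bind_rows()
  tests <- purrr::pmap(props, function(nap, silent_k, silent_n,
                                       confirmed_k, confirmed_n) {
    if (silent_n == 0L || confirmed_n == 0L) return(NULL)
    dplyr::bind_rows(
      dplyr::mutate(proportion_ztest(silent_k, silent_n, confirmed_k,
                                     confirmed_n, "greater"), nap = nap),
      dplyr::mutate(proportion_ztest(silent_k, silent_n, confirmed_k,
                                     confirmed_n, "two"), nap = nap)
    )
  }) |> dplyr::bind_rows()
  structure(list(sites = flagged, proportions = props, tests = tests),
            class = "fnr_occlusion_report")
}

overlaps_any <- function(a, b) {
  flag <- rep(FALSE, nrow(a))
  flag[unique(overlap_pairs(a, b)$a)] <- TRUE
  flag
}

#' @export
print.fnr_occlusion_report <- function(x, ...) {
  p <- x$proportions[x$proportions$nap == "any_nap", ]
  cat("<fnr_occlusion_report>", p$silent_k, "of", p$silent_n,
      "silent sites NAP-occupied vs", p$confirmed_k, "of", p$confirmed_n,
      "confirmed\n")
  invisible(x)
}

#' Venn partition counts over three NAP overlap flags
#'
#' @param flags Tibble with logical columns for each NAP (as produced by
#'   [nap_overlap()]).
#' @param naps Character vector of the flag columns to partition on.
#' @return Tibble of the 2^k overlap classes with counts; counts sum to
#'   `nrow(flags)`.
#' @export
nap_venn_counts <- function(flags, naps = c("hns", "ihf", "fis")) {
  stopifnot(all(naps %in% names(flags)))
  dplyr::count(flags, dplyr::across(dplyr::all_of(naps)), name = "n")
}

#' Contrast H-NS and RNAP signal within extended H-NS regions
#'
#' Collects the per-bp values of both tracks inside the extended (filament)
#' regions and tests one-sidedly whether the H-NS mean exceeds the RNAP
#' mean (Welch t), the transcription-silencing signature of H-NS
#' filaments.
#'
#' @param hns_regions_extended Interval tibble of extended H-NS regions.
#' @param rnap_track,hns_track Track tibbles covering the regions.
#' @return List: `summary` tibble (per-track n, mean, sd), `p_value` of the
#'   one-sided test, `t` statistic.
#' @export
rnap_hns_contrast <- function(hns_regions_extended, rnap_track, hns_track) {
  if (nrow(hns_regions_extended) == 0L) stop("empty extended-region set")
  pull_values <- function(track) {
    iv <- tibble::tibble(contig = track$contig, start = track$pos,
                         end = track$pos + 1L)
    track$value[unique(overlap_pairs(iv, hns_regions_extended)$a)]
  }
  v_hns <- pull_values(hns_track)
  v_rnap <- pull_values(rnap_track)
  stopifnot(length(v_hns) >= 2L, length(v_rnap) >= 2L)
  tt <- stats::t.test(v_hns, v_rnap, alternative = "greater")
  list(summary = tibble::tibble(
    track = c("hns", "rnap"),
    n = c(length(v_hns), length(v_rnap)),
    mean = c(mean(v_hns), mean(v_rnap)),
    sd = c(stats::sd(v_hns), stats::sd(v_rnap))),
    t = unname(tt$statistic), p_value = tt$p.value)
}
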