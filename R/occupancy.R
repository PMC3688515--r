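# one-sided paired t with the degenerate zero-variance convention:
# if all differences are equal, significant (p = 0) iff the common
# difference lies strictly in the tested direction, else p = 1.
paired_onesided_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2L) return(NA_real_)
  if (stats::sd(d) == 0) {
    hit <- if (alternative == "greater") d[1] > 0 else d[1] < 0
    return(if (hit) 0 else 1)
  }
  stats::t.test(d, alternative = alternative)$p.value
}

track_values_in <- function(track, contig, lo, hi) {
  sel <- track$contig == contig & track$pos >= lo & track$pos < hi
  track[sel, , drop = FALSE]
}

#' Background-median normalization of a peak region
#'
#' Probes in flanking regions beyond the peak boundary (default ~1500 bp on
#' each side, clipped at contig ends) define the background; probes falling
#' inside any other called peak are excluded from it. All probe values in
#' the peak region are shifted by the negative background median, so the
#' background median after shifting is 0. The peak average is the mean of
#' shifted values over the central fraction of the region (default the
#' center 50% by coordinate span).
#'
#' @param track Probe or read-density track tibble (`contig, pos, value`).
#' @param peak Single-row peak tibble (`contig, start, end`).
#' @param trim_fraction Central fraction of the region kept for the peak
#'   average (default 0.5).
#' @param flank Flank width in bp on each side (default 1500).
#' @param exclude_peaks Optional peak tibble; background probes inside any
#'   of these regions are dropped.
#' @param contig_length Optional contig length for clipping (warned when
#'   flanks are clipped and supplied).
#' @return List of class `fnr_norm_region`: `region` (probe tibble with a
#'   `shifted` column), `trimmed_region` interval, `background_median`,
#'   `peak_average`, `peak_sd`, `n_background`.
#' @export
normalize_peak_region <- function(track, peak, trim_fraction = 0.5,
                                  flank = 1500L, exclude_peaks = NULL,
                                  contig_length = NULL) {
  lo <- peak$start - flank
  hi <- peak$end + flank
  if (!is.null(contig_length)) {
    if (lo < 0L || hi > contig_length) {
      warning("flank clipped at contig end")
    }
    hi <- min(hi, contig_length)
  }
  lo <- max(0L, lo)
  bg <- dplyr::bind_rows(
    track_values_in(track, peak$contig, lo, peak$start),
    track_values_in(track, peak$contig, peak$end, hi)
  )
  if (!is.null(exclude_peaks) && nrow(bg) > 0L && nrow(exclude_peaks) > 0L) {
    bg_iv <- tibble::tibble(contig = bg$contig, start = bg$pos,
                            end = bg$pos + 1L)
    inside <- unique(overlap_pairs(bg_iv, exclude_peaks)$a)
    if (length(inside)) bg <- bg[-inside, , drop = FALSE]
  }
  if (nrow(bg) == 0L) stop("no background probes for peak region")
  bg_median <- stats::median(bg$value)
  region <- track_values_in(track, peak$contig, peak$start, peak$end)
  region$shifted <- region$value - bg_median
  center <- (peak$start + peak$end) / 2
  half_span <- (peak$end - peak$start) * trim_fraction / 2
  trim_lo <- floor(center - half_span)
  trim_hi <- ceiling(center + half_span)
  in_trim <- region$pos >= trim_lo & region$pos < trim_hi
  structure(list(region = region,
                 trimmed_region = tibble::tibble(contig = peak$contig,
                                                 start = as.integer(trim_lo),
                                                 end = as.integer(trim_hi)),
                 background_median = bg_median,
                 peak_average = mean(region$shifted[in_trim]),
                 peak_sd = stats::sd(region$shifted[in_trim]),
                 n_background = nrow(bg),
                 n_trimmed = sum(in_trim)),
            class = "fnr_norm_region")
}

#' @export
print.fnr_norm_region <- function(x, ...) {
  cat("<fnr_norm_region> peak average", round(x$peak_average, 4),
      "(sd", paste0(round(x$peak_sd, 4), ")"), "over", x$n_trimmed,
      "probes; background median", round(x$background_median, 4),
      "from", x$n_background, "probes\n")
  invisible(x)
}

# one-sided paired t against a shifted null: H0 mean(x - y) <= mu0,
# H1 greater. Degenerate zero-variance differences: p = 0 iff the common
# difference exceeds mu0, else 1.
paired_excess_p <- function(x, y, mu0) {
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2L) return(NA_real_)
  if (stats::sd(d) == 0) return(if (d[1] > mu0) 0 else 1)
  stats::t.test(d, mu = mu0, alternative = "greater")$p.value
}

#' Saturation analysis of peak occupancy across a TF titration
#'
#' For each tracked region, computes the background-shifted peak average at
#' every concentration and one-sided paired t-tests (pairing on probes,
#' alternative: higher concentration greater) between consecutive
#' concentrations. Saturation is decided on the top two concentrations: the
#' region is saturated when the relative increase between them is below
#' `tolerance` AND the increase is not significantly in excess of the
#' tolerance band (one-sided paired t of H0 `mean step <= tolerance x
#' |lower peak average|`). Testing excess over the band rather than any
#' difference keeps genuinely flat-but-nonzero saturation curves (e.g. a
#' Kd far below the lowest concentration, where the residual step is ~1%)
#' classified as saturated even at very low noise.
#'
#' @param tracks Named list of probe tracks; names are concentrations in uM
#'   and must be strictly increasing when parsed as numbers.
#' @param regions Peak tibble of regions to follow.
#' @param alpha Test level (default 0.05).
#' @param tolerance Maximum relative increase between the top two
#'   concentrations for a saturated call (default 0.05).
#' @param ... Passed to [normalize_peak_region()].
#' @return Tibble of class `fnr_titration`: one row per region x
#'   concentration with `peak_average`, `peak_sd`, `p_step` (one-sided
#'   paired p of the step up from the previous concentration), and
#'   per-region `rel_increase`, `p_excess`, `saturated`.
#' @export
titration_analysis <- function(tracks, regions, alpha = 0.05,
                               tolerance = 0.05, ...) {
  conc <- as.numeric(names(tracks))
  stopifnot(length(conc) >= 2L, !is.unsorted(conc, strictly = TRUE))
  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    peak <- regions[i, ]
    probes <- purrr::map(tracks, function(tr) {
      normalize_peak_region(tr, peak, ...)
    })
    n_probes <- nrow(probes[[1]]$region)
    if (n_probes < 2L) {
      warning("region ", i, " has fewer than 2 probes; skipped")
      return(NULL)
    }
    avg <- vapply(probes, function(p) p$peak_average, numeric(1))
    sds <- vapply(probes, function(p) p$peak_sd, numeric(1))
    step_p <- c(NA_real_, vapply(seq_along(conc)[-1], function(k) {
      paired_onesided_p(probes[[k]]$region$shifted,
                        probes[[k - 1]]$region$shifted, "greater")
    }, numeric(1)))
    k <- length(conc)
    rel_inc <- (avg[k] - avg[k - 1]) / abs(avg[k - 1])
    p_excess <- paired_excess_p(probes[[k]]$region$shifted,
                                probes[[k - 1]]$region$shifted,
                                tolerance * abs(avg[k - 1]))
    saturated <- !is.na(rel_inc) && rel_inc < tolerance &&
      (is.na(p_excess) || p_excess >= alpha)
    tibble::tibble(region_index = i, concentration = conc,
                   peak_average = unname(avg), peak_sd = unname(sds),
                   p_step = step_p, rel_increase = rel_inc,
                   p_excess = p_excess, saturated = saturated)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("fnr_titration", class(out)))
  out
}

#' Compare per-peak FNR occupancy between two strains
#'
#' Classifies the union of peaks from two strains (e.g. WT vs a
#' H-NS/StpA-deficient mutant) as `wt_only`, `mut_only` ("unmasked"),
#' `shared_unchanged`, or `shared_increased`. Shared peaks are labelled
#' increased only when the Bonferroni-corrected one-sided paired t-test
#' (pairing on probes, mutant greater) passes at `alpha` AND the mutant
#' peak average exceeds the WT peak average by more than the WT peak SD.
#' The Bonferroni family is all peaks tested in the current run.
#'
#' @param peaks_wt,peaks_mut Peak tibbles for the two strains.
#' @param track_wt,track_mut Probe tracks for the two strains (will be
#'   background-median shifted per peak via [normalize_peak_region()]).
#' @param alpha Test level (default 0.05).
#' @param ... Passed to [normalize_peak_region()].
#' @return Tibble: one row per peak in the union with `contig, start, end,
#'   verdict, wt_average, wt_sd, mut_average, p_raw, p_bonferroni`.
#' @export
compare_strains <- function(peaks_wt, peaks_mut, track_wt, track_mut,
                            alpha = 0.05, ...) {
  pairs <- overlap_pairs(peaks_wt, peaks_mut)
  shared_wt <- unique(pairs$a)
  rows <- list()
  for (i in seq_len(nrow(peaks_wt))) {
    peak <- peaks_wt[i, ]
    if (i %in% shared_wt) {
      nw <- normalize_peak_region(track_wt, peak, ...)
      nm <- normalize_peak_region(track_mut, peak, ...)
      p_raw <- paired_onesided_p(nm$region$shifted, nw$region$shifted,
                                 "greater")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contig = peak$contig, start = peak$start, end = peak$end,
        verdict = NA_character_, wt_average = nw$peak_average,
        wt_sd = nw$peak_sd, mut_average = nm$peak_average, p_raw = p_raw)
    } else {
      nw <- normalize_peak_region(track_wt, peak, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contig = peak$contig, start = peak$start, end = peak$end,
        verdict = "wt_only", wt_average = nw$peak_average, wt_sd = nw$peak_sd,
        mut_average = NA_real_, p_raw = NA_real_)
    }
  }
  mut_only_idx <- setdiff(seq_len(nrow(peaks_mut)), pairs$b)
  for (i in mut_only_idx) {
    peak <- peaks_mut[i, ]
    nm <- normalize_peak_region(track_mut, peak, ...)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      contig = peak$contig, start = peak$start, end = peak$end,
      verdict = "mut_only", wt_average = NA_real_, wt_sd = NA_real_,
      mut_average = nm$peak_average, p_raw = NA_real_)
  }
  out <- dplyr::bind_rows(rows)
  shared <- is.na(out$verdict)
  out$p_bonferroni <- NA_real_
  if (any(shared)) {
    out$p_bonferroni[shared] <- pmin(out$p_raw[shared] * sum(shared), 1)
    increased <- shared & !is.na(out$p_bonferroni) &
      out$p_bonferroni < alpha &
      out$mut_average > out$wt_average + out$wt_sd
    out$verdict[shared] <- ifelse(increased[shared], "shared_increased",
                                  "shared_unchanged")
  }
  out
}

#' Differential sigma-70 occupancy between anaerobic and aerobic tracks
#'
#' Both read-density tracks are shifted by their background medians
#' (background = positions outside all peaks), then a one-sided paired
#' t-test over the 100 bp surrounding each peak summit is performed in the
#' direction of the observed mean difference, Bonferroni-corrected over the
#' peaks tested.
#'
#' @param peaks Peak tibble with `summit`.
#' @param track_minusO2,track_plusO2 Dense read-density tracks.
#' @param window Window size in bp centered on the summit (default 100).
#' @param alpha Test level applied to the corrected p-value (default 0.01).
#' @return Tibble: per peak `verdict` (`"+"` anaerobic higher, `"-"` lower,
#'   `"none"`), `mean_diff`, `p_raw`, `p_bonferroni`.
#' @export
sigma70_differential <- function(peaks, track_minusO2, track_plusO2,
                                 window = 100L, alpha = 0.01) {
  shift_track <- function(track) {
    iv <- tibble::tibble(contig = track$contig, start = track$pos,
                         end = track$pos + 1L)
    inside <- unique(overlap_pairs(iv, peaks)$a)
    bg <- if (length(inside)) track$value[-inside] else track$value
    track$value <- track$value - stats::median(bg)
    track
  }
  tm <- shift_track(track_minusO2)
  tp <- shift_track(track_plusO2)
  rows <- purrr::map(seq_len(nrow(peaks)), function(i) {
    peak <- peaks[i, ]
    lo <- max(0L, peak$summit - window %/% 2L)
    hi <- peak$summit + window %/% 2L
    vm <- track_values_in(tm, peak$contig, lo, hi)
    vp <- track_values_in(tp, peak$contig, lo, hi)
    joined <- dplyr::inner_join(vm, vp, by = c("contig", "pos"),
                                suffix = c("_m", "_p"))
    if (nrow(joined) < 2L) {
      return(tibble::tibble(peak_index = i, mean_diff = NA_real_,
                            p_raw = NA_real_))
    }
    md <- mean(joined$value_m - joined$value_p)
    dir <- if (md >= 0) "greater" else "less"
    tibble::tibble(peak_index = i, mean_diff = md,
                   p_raw = paired_onesided_p(joined$value_m, joined$value_p,
                                             dir))
  })
  out <- dplyr::bind_rows(rows)
  tested <- !is.na(out$p_raw)
  out$p_bonferroni <- NA_real_
  out$p_bonferroni[tested] <- pmin(out$p_raw[tested] * sum(tested), 1)
  out$verdict <- dplyr::case_when(
    !tested | out$p_bonferroni >= alpha ~ "none",
    out$mean_diff > 0 ~ "+",
    .default = "-"
  )
  dplyr::bind_cols(peaks[out$peak_index, c("contig", "start", "end")], out)
}

#' Threshold-based peak caller for synthetic tracks
#'
#' Plumbing for simulated data: maximal runs of track positions with value
#' above `threshold`, merged across gaps of at most `merge_gap` bp, kept
#' when at least `min_len` bp long. The summit is the position of maximum
#' value within the run.
#'
#' @param track Track tibble.
#' @param threshold Signal threshold (exclusive).
#' @param min_len Minimum peak length in bp (default 20).
#' @param merge_gap Merge runs separated by gaps `<=` this many bp
#'   (default 50).
#' @return Peak tibble: `contig, start, end, summit, summit_height`.
#' @export
simple_peak_caller <- function(track, threshold, min_len = 20L,
                               merge_gap = 50L) {
  out <- purrr::map(split(track, track$contig), function(tr) {
    above <- tr$pos[tr$value > threshold]
    if (!length(above)) return(NULL)
    brk <- c(0L, which(diff(above) > merge_gap + 1L), length(above))
    runs <- purrr::map(seq_len(length(brk) - 1L), function(k) {
      seg <- above[(brk[k] + 1L):brk[k + 1L]]
      lo <- seg[1]
      hi <- seg[length(seg)] + 1L
      if (hi - lo < min_len) return(NULL)
      sel <- tr$pos >= lo & tr$pos < hi
      summit <- tr$pos[sel][which.max(tr$value[sel])]
      tibble::tibble(contig = tr$contig[1], start = lo, end = hi,
                     summit = summit,
                     summit_height = max(tr$value[sel]))
    })
    dplyr::bind_rows(runs)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), summit = integer(),
                          summit_height = double()))
  }
  dplyr::arrange(out, .data$contig, .data$start)
}
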