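#' Precision-recall curve for motif predictions against ChIP peaks
#'
#' At each threshold, predictions are the scan hits with
#' `ln_pvalue <= threshold`. True positives are peaks containing at least
#' one prediction; false positives are predictions overlapping no peak;
#' false negatives are peaks containing no prediction. Precision is defined
#' as 0 when no predictions exist at a threshold (avoids 0/0).
#'
#' @param hits Motif-hit tibble from [scan_pwm()] run at a permissive
#'   threshold (must carry `ln_pvalue`).
#' @param peaks Peak tibble (`contig, start, end`).
#' @param thresholds Numeric vector of ln p thresholds to evaluate; default
#'   is the set of observed hit `ln_pvalue` values.
#' @return Tibble of class `fnr_pr_curve`: one row per threshold with
#'   `ln_p_threshold, tp, fp, fn, precision, recall, f1`, ordered
#'   permissive to strict.
#' @export
pr_curve <- function(hits, peaks, thresholds = NULL) {
  if (nrow(peaks) == 0L) stop("no peaks supplied; recall is undefined")
  if (is.null(thresholds)) thresholds <- unique(hits$ln_pvalue)
  thresholds <- sort(thresholds, decreasing = TRUE)  # permissive -> strict
  pairs <- overlap_pairs(hits, peaks)
  hit_matched_peak <- split(pairs$b, factor(pairs$a, levels = seq_len(nrow(hits))))
  n_peaks <- nrow(peaks)
  rows <- purrr::map(thresholds, function(thr) {
    sel <- which(hits$ln_pvalue <= thr)
    matched_peaks <- unique(unlist(hit_matched_peak[sel], use.names = FALSE))
    in_peak <- lengths(hit_matched_peak[sel]) > 0L
    tp <- length(matched_peaks)
    fp <- sum(!in_peak)
    fn <- n_peaks - tp
    precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    recall <- tp / (tp + fn)
    tibble::tibble(ln_p_threshold = thr, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall)
  })
  out <- dplyr::bind_rows(rows)
  out$f1 <- ifelse(out$precision + out$recall == 0, 0,
                   2 * out$precision * out$recall /
                     (out$precision + out$recall))
  class(out) <- unique(c("fnr_pr_curve", class(out)))
  out
}

#' Select an operating threshold from a precision-recall curve
#'
#' Maximizes the configured criterion (default F1); ties are broken toward
#' the stricter (more negative) threshold.
#'
#' @param pr Tibble from [pr_curve()].
#' @param criterion `"f1"` or a function of `(precision, recall)` returning
#'   a numeric to maximize.
#' @return The selected `ln_p_threshold` (scalar).
#' @export
select_threshold <- function(pr, criterion = "f1") {
  stopifnot(nrow(pr) >= 1L)
  if (all(pr$precision == 0)) stop("precision is zero at every threshold")
  score <- if (identical(criterion, "f1")) {
    pr$f1
  } else {
    criterion(pr$precision, pr$recall)
  }
  best <- which(score == max(score))
  min(pr$ln_p_threshold[best])
}

#' Match predicted sites to ChIP peaks
#'
#' A prediction matches a peak iff its interval intersects the peak region
#' (half-open). Unmatched predictions are the "silent" sites; unmatched
#' peaks have no predicted site at the scanning threshold.
#'
#' @param predictions Motif-hit tibble.
#' @param peaks Peak tibble.
#' @return List with tibbles `confirmed` (predictions inside a peak, with a
#'   `peak_index` column of the first matching peak), `silent` (predictions
#'   in no peak), and integer vectors `matched_peaks` / `unmatched_peaks`
#'   (peak row indices).
#' @export
match_predictions <- function(predictions, peaks) {
  pairs <- overlap_pairs(predictions, peaks)
  matched <- sort(unique(pairs$a))
  confirmed <- predictions[matched, , drop = FALSE]
  confirmed$peak_index <- vapply(matched, function(i) {
    min(pairs$b[pairs$a == i])
  }, integer(1))
  silent <- predictions[setdiff(seq_len(nrow(predictions)), matched), ,
                        drop = FALSE]
  list(confirmed = confirmed,
       silent = silent,
       matched_peaks = sort(unique(pairs$b)),
       unmatched_peaks = setdiff(seq_len(nrow(peaks)), pairs$b))
}

grubbs_statistic <- function(x) {
  max(abs(x - mean(x))) / stats::sd(x)
}

#' Call the number of binding sites within one ChIP peak
#'
#' Implements the top-4 / SD-gap / single-Grubbs procedure: a 200-bp window
#' around the peak summit is scanned and the top four window scores
#' `s1 >= s2 >= s3 >= s4` recorded. If `s1 - s2` exceeds the sample standard
#' deviation of the four, the peak carries one site. Otherwise a Grubbs
#' outlier test is applied once (fixed critical Z, default 1.04 at alpha
#' 0.15); if an outlier is found it is removed, the SD recomputed over the
#' remaining three, and the gap re-tested. Peaks still not separated carry
#' two sites. Equal top scores (sd 0, gap 0) fall in the "not separated"
#' branch and yield two sites, flagged.
#'
#' @param peak Single-row peak tibble with a `summit` column.
#' @param genome Named character vector of sequences.
#' @param pwm An `fnr_pwm`.
#' @param dist Optional precomputed [score_distribution()].
#' @param window_bp Window size around the summit (default 200, i.e.
#'   summit +/- 100 clipped to the contig).
#' @param alpha,z_crit Grubbs screen constants (alpha is recorded; the
#'   critical Z is used verbatim, not recomputed from t quantiles).
#' @return List of class `fnr_peak_sites`: `n_sites` (1 or 2), `hits`
#'   (candidate windows ranked by score), `removed` (Grubbs-removed rows),
#'   `degenerate` flag, `window` interval.
#' @export
call_peak_sites <- function(peak, genome, pwm, dist = NULL, window_bp = 200L,
                            alpha = 0.15, z_crit = 1.04) {
  stopifnot(!is.null(peak$summit), !is.na(peak$summit))
  if (is.null(dist)) dist <- score_distribution(pwm)
  ctg_len <- nchar(genome[[peak$contig]])
  lo <- max(0L, peak$summit - window_bp %/% 2L)
  hi <- min(ctg_len, peak$summit + window_bp %/% 2L)
  win_seq <- substr(genome[[peak$contig]], lo + 1L, hi)
  hits <- scan_pwm(stats::setNames(win_seq, peak$contig), pwm,
                   ln_p_threshold = 0, dist = dist)
  hits$start <- hits$start + lo
  hits$end <- hits$end + lo
  hits <- dplyr::slice_max(hits, .data$score, n = 4L, with_ties = FALSE)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score))
  call <- decide_n_sites(hits$score, z_crit = z_crit)
  structure(list(n_sites = call$n_sites,
                 hits = hits,
                 removed = hits[call$removed, , drop = FALSE],
                 degenerate = call$degenerate,
                 alpha = alpha, z_crit = z_crit,
                 window = tibble::tibble(contig = peak$contig, start = lo,
                                         end = hi)),
            class = "fnr_peak_sites")
}

#' @export
print.fnr_peak_sites <- function(x, ...) {
  cat("<fnr_peak_sites>", x$n_sites, "site(s);", nrow(x$hits),
      "candidate windows;", nrow(x$removed), "removed by Grubbs\n")
  invisible(x)
}

#' Decide 1 vs 2 sites from ranked candidate scores
#'
#' The decision core of [call_peak_sites()], exposed for testing on bare
#' score vectors. Scores are sorted descending internally, so the result is
#' invariant to input order.
#'
#' @param scores Numeric vector of candidate scores (ideally 4).
#' @param z_crit Grubbs critical Z (default 1.04).
#' @return List: `n_sites`, `removed` (index into the sorted scores of the
#'   Grubbs-removed value, if any), `degenerate` flag.
#' @export
decide_n_sites <- function(scores, z_crit = 1.04) {
  scores <- sort(scores, decreasing = TRUE)
  if (length(scores) < 2L) {
    return(list(n_sites = 1L, removed = integer(), degenerate = TRUE))
  }
  s <- stats::sd(scores)
  if (is.na(s)) s <- 0
  if (s > 0 && (scores[1] - scores[2]) > s) {
    return(list(n_sites = 1L, removed = integer(), degenerate = FALSE))
  }
  removed <- integer()
  if (length(scores) >= 3L && s > 0) {
    g <- grubbs_statistic(scores)
    if (g > z_crit) {
      removed <- which.max(abs(scores - mean(scores)))
      kept <- scores[-removed]
      s2 <- stats::sd(kept)
      if (!is.na(s2) && s2 > 0 && (kept[1] - kept[2]) > s2) {
        return(list(n_sites = 1L, removed = removed, degenerate = FALSE))
      }
    }
  }
  list(n_sites = 2L, removed = removed, degenerate = s == 0)
}

#' Position of a binding site relative to an operon's TSS
#'
#' Reports the half-integer offset of the site center from the transcription
#' start (position +1), negative upstream, mirrored for minus-strand
#' operons. A 14-mer centered 41.5 bases upstream of the TSS reports -41.5.
#'
#' @param hit Single-row motif hit (`start`, `end`, 0-based half-open).
#' @param operon Single-row operon record with numeric `tss` (1-based) and
#'   `strand`; `tss_status` sentinels are passed through.
#' @return Numeric offset, or `NA` with attribute `status` when the TSS is
#'   unknown / not in the peak region.
#' @export
relative_position <- function(hit, operon) {
  status <- if (!is.null(operon$tss_status)) operon$tss_status else "known"
  if (status != "known" || is.na(operon$tss)) {
    out <- NA_real_
    attr(out, "status") <- if (status == "known") "unknown" else status
    return(out)
  }
  center_1based <- (hit$start + hit$end + 1) / 2  # half-integer for even width
  if (identical(operon$strand, "-")) {
    operon$tss - center_1based
  } else {
    center_1based - operon$tss
  }
}

#' Tally site positions of activated promoters around the Class II anchor
#'
#' Counts promoter sites whose center falls within a window of the Class II
#' activation position (-41.5). Because the window convention (+/- 4 vs
#' +/- 4.5 nt, inclusive vs exclusive) is ambiguous in the field, both the
#' strict and the half-open tallies are reported rather than asserted.
#'
#' @param positions Numeric vector of site centers relative to the TSS
#'   (NA for unknown TSS, dropped).
#' @param anchor Center of the window (default -41.5).
#' @param halfwidth Window half-width in nt (default 4).
#' @return Tibble with `n_known`, `n_in_window` (closed `anchor +/-
#'   halfwidth`) and `n_in_window_half` (closed `anchor +/- (halfwidth +
#'   0.5)`).
#' @export
summarise_site_positions <- function(positions, anchor = -41.5,
                                     halfwidth = 4) {
  p <- positions[!is.na(positions)]
  tibble::tibble(
    n_known = length(p),
    n_in_window = sum(p >= anchor - halfwidth & p <= anchor + halfwidth),
    n_in_window_half = sum(p >= anchor - halfwidth - 0.5 &
                             p <= anchor + halfwidth + 0.5)
  )
}
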