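BASES <- c("A", "C", "G", "T")

# utf8 code -> base index lookup (A=1, C=2, G=3, T=4, everything else NA)
.code_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut
})

seq_to_codes <- function(seq) {
  .code_lut[utf8ToInt(seq)]
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Build a position weight matrix from aligned binding sites
#'
#' Column frequencies use a Hertz/Stormo-style small-sample correction: a
#' total pseudocount distributed according to the background,
#' `f(b,i) = (c(b,i) + pseudo * p_b) / (N + pseudo)`, and weights are
#' natural-log odds `w(b,i) = ln(f(b,i) / p_b)`.
#'
#' @param aligned_sites Character vector of equal-length A/C/G/T sequences
#'   (at least 2).
#' @param background Named numeric vector of base probabilities summing to 1
#'   (default uniform).
#' @param pseudocount_total Total pseudocount added per column (default 1).
#' @return An object of class `fnr_pwm`: list with `counts`, `probs`,
#'   `weights` (all 4 x width matrices, rows A/C/G/T), `background`,
#'   `width`, `n_sites`, `pseudocount_total`.
#' @examples
#' pwm <- build_pwm(c("TTGATCCGGATCAA", "TTGATAAAAATCAA"))
#' information_content(pwm)
#' @export
build_pwm <- function(aligned_sites,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount_total = 1) {
  stopifnot(length(aligned_sites) >= 2L)
  w <- unique(nchar(aligned_sites))
  if (length(w) != 1L) stop("aligned sites must have equal length")
  if (any(grepl("[^ACGT]", aligned_sites))) {
    stop("aligned sites must contain only A/C/G/T")
  }
  background <- background[BASES]
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-8)
  mat <- do.call(rbind, strsplit(aligned_sites, ""))
  counts <- vapply(seq_len(w), function(i) {
    tabulate(match(mat[, i], BASES), nbins = 4L)
  }, integer(4))
  rownames(counts) <- BASES
  n <- length(aligned_sites)
  probs <- (counts + pseudocount_total * background) / (n + pseudocount_total)
  weights <- log(probs / background)
  structure(list(counts = counts, probs = probs, weights = weights,
                 background = background, width = w, n_sites = n,
                 pseudocount_total = pseudocount_total),
            class = "fnr_pwm")
}

#' @export
print.fnr_pwm <- function(x, ...) {
  cat("<fnr_pwm> width", x$width, "| built from", x$n_sites, "sites |",
      "total IC", round(sum(information_content(x)), 2), "bits\n")
  cat("consensus:", consensus_sequence(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (best-scoring base per position)
#'
#' @param pwm An `fnr_pwm`.
#' @return Single string of length `pwm$width`.
#' @export
consensus_sequence <- function(pwm) {
  paste(BASES[apply(pwm$weights, 2, which.max)], collapse = "")
}

#' Per-position information content of a PWM, in bits
#'
#' `IC_i = sum_b f(b,i) * log2(f(b,i)/p_b)`; a perfectly conserved position
#' under a uniform background carries 2 bits.
#'
#' @param pwm An `fnr_pwm`.
#' @return Numeric vector, one value per motif position.
#' @export
information_content <- function(pwm) {
  f <- pwm$probs
  p <- pwm$background
  term <- f * log2(f / p)
  term[f == 0] <- 0
  colSums(term)
}

#' Exact score distribution of a PWM under the background model
#'
#' Discretizes the log-odds weights on a grid of step `resolution` and
#' convolves positionwise, giving the exact distribution of the window score
#' for i.i.d. background sequence (within one grid step). Tail probabilities
#' `P(score >= s)` are non-increasing, equal 1 at the minimum score, and
#' support natural-log p-values matching PatSer semantics.
#'
#' @param pwm An `fnr_pwm`.
#' @param resolution Grid step in natural-log units (default 0.01).
#' @param max_grid Safety cap on grid size.
#' @return Object of class `fnr_score_dist` with `grid` (scores), `prob`,
#'   `tail_prob`, `ln_tail`, `resolution`, and the integer weight matrices
#'   used for exact window lookup.
#' @export
score_distribution <- function(pwm, resolution = 0.01, max_grid = 5e6) {
  stopifnot(resolution > 0)
  kw <- round(pwm$weights / resolution)
  mode(kw) <- "integer"
  min_int <- sum(apply(kw, 2, min))
  max_int <- sum(apply(kw, 2, max))
  span <- max_int - min_int
  if (span + 1 > max_grid) {
    stop("score grid too large (", span + 1, " cells); increase resolution to ~",
         signif(resolution * (span + 1) / max_grid, 2))
  }
  p <- 1
  bg <- pwm$background
  for (j in seq_len(pwm$width)) {
    sj <- kw[, j] - min(kw[, j])
    newp <- numeric(length(p) + max(sj))
    for (b in 1:4) {
      idx <- seq_along(p) + sj[b]
      newp[idx] <- newp[idx] + p * bg[b]
    }
    p <- newp
  }
  tail_prob <- rev(cumsum(rev(p)))
  tail_prob <- pmin(tail_prob, 1)
  structure(list(grid = (min_int + seq_along(p) - 1L) * resolution,
                 prob = p,
                 tail_prob = tail_prob,
                 ln_tail = log(tail_prob),
                 resolution = resolution,
                 kw = kw, min_int = min_int, max_int = max_int),
            class = "fnr_score_dist")
}

#' @export
print.fnr_score_dist <- function(x, ...) {
  cat("<fnr_score_dist> grid", length(x$grid), "cells, step", x$resolution,
      "| score range [", round(min(x$grid), 2), ",", round(max(x$grid), 2),
      "]\n")
  invisible(x)
}

#' Natural-log p-value of a PWM score
#'
#' @param dist An `fnr_score_dist`.
#' @param score Numeric score(s) on the weight scale.
#' @return `ln P(score' >= score)` under the background model.
#' @export
ln_pvalue <- function(dist, score) {
  idx <- round(score / dist$resolution) - dist$min_int + 1L
  idx <- pmax(pmin(idx, length(dist$ln_tail)), 1L)
  out <- dist$ln_tail[idx]
  out[score > max(dist$grid) + dist$resolution / 2] <- -Inf
  out
}

# integer window scores for one strand; codes NA (N bases) propagate
.window_scores <- function(codes, kw) {
  w <- ncol(kw)
  n <- length(codes)
  if (n < w) return(numeric(0))
  s <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    s <- s + unname(kw[, j][codes[j:(n - w + j)]])
  }
  s
}

#' Scan sequences with a PWM, reporting hits below a log p-value threshold
#'
#' Both strands are scanned; when both strands of the same window pass the
#' threshold only the better-scoring strand is kept (one site per locus, the
#' sensible convention for quasi-palindromic motifs). Hits are sorted by
#' coordinate.
#'
#' @param genome Named character vector of sequences (a genome from
#'   [read_fasta()] or any sequence set).
#' @param pwm An `fnr_pwm`.
#' @param ln_p_threshold Report windows with `ln p <= ln_p_threshold`
#'   (must be `<= 0`); default is [fnr_default_ln_p()].
#' @param dist Optional precomputed [score_distribution()]; built on the fly
#'   otherwise.
#' @param resolution Grid step forwarded to [score_distribution()].
#' @return Tibble of motif hits: `contig, start, end, strand, score,
#'   ln_pvalue`, 0-based half-open windows of width `pwm$width`.
#' @export
scan_pwm <- function(genome, pwm, ln_p_threshold = fnr_default_ln_p(),
                     dist = NULL, resolution = 0.01) {
  stopifnot(ln_p_threshold <= 0)
  if (is.null(dist)) dist <- score_distribution(pwm, resolution)
  kw <- dist$kw
  w <- pwm$width
  # reverse-complement weight matrix scores the minus strand on the forward
  # sequence: column j reads the complement of motif position w + 1 - j
  kw_rc <- kw[c(4L, 3L, 2L, 1L), rev(seq_len(w)), drop = FALSE]
  rownames(kw_rc) <- BASES
  hits <- purrr::imap(genome, function(seq, ctg) {
    codes <- seq_to_codes(seq)
    if (length(codes) < w) return(NULL)
    s_fwd <- .window_scores(codes, kw)
    s_rev <- .window_scores(codes, kw_rc)
    strand <- ifelse(!is.na(s_rev) & (is.na(s_fwd) | s_rev > s_fwd), "-", "+")
    best <- pmax(s_fwd, s_rev, na.rm = FALSE)
    best[is.na(s_fwd) | is.na(s_rev)] <- NA
    lp <- dist$ln_tail[as.integer(best) - dist$min_int + 1L]
    keep <- which(!is.na(lp) & lp <= ln_p_threshold)
    if (!length(keep)) return(NULL)
    tibble::tibble(contig = ctg,
                   start = keep - 1L,
                   end = keep - 1L + w,
                   strand = strand[keep],
                   score = best[keep] * dist$resolution,
                   ln_pvalue = lp[keep])
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), strand = character(),
                          score = double(), ln_pvalue = double()))
  }
  dplyr::arrange(out, .data$contig, .data$start)
}

#' Default scan threshold
#'
#' The natural-log p-value operating point selected by the original FNR
#' precision-recall analysis, shipped as a constant for reproduction mode.
#'
#' @return `-10.75`.
#' @export
fnr_default_ln_p <- function() -10.75

#' Serialize a PWM to a 4 x width TSV
#'
#' The header line names the background composition.
#'
#' @param pwm An `fnr_pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# background\t",
                    paste(sprintf("%s=%.6f", BASES, pwm$background),
                          collapse = "\t"),
                    "\t# pseudocount_total=", pwm$pseudocount_total,
                    "\t# n_sites=", pwm$n_sites), con)
  utils::write.table(cbind(base = BASES, as.data.frame(pwm$counts)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PWM serialized by [write_pwm()]
#'
#' @param path Path to the TSV.
#' @return An `fnr_pwm` rebuilt from the stored counts and background.
#' @export
read_pwm <- function(path) {
  header <- readr::read_lines(path, n_max = 1)
  bg <- as.numeric(sub(".*=", "", regmatches(
    header, gregexpr("[ACGT]=[0-9.]+", header))[[1]]))
  names(bg) <- BASES
  pseudo <- as.numeric(sub(".*pseudocount_total=([0-9.]+).*", "\\1", header))
  n <- as.integer(sub(".*n_sites=([0-9]+).*", "\\1", header))
  counts <- utils::read.delim(path, skip = 1)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$base
  m <- m[BASES, , drop = FALSE]
  probs <- sweep(m, 1, pseudo * bg, "+") / (n + pseudo)
  weights <- log(probs / bg)
  structure(list(counts = m, probs = probs, weights = weights,
                 background = bg, width = ncol(m), n_sites = n,
                 pseudocount_total = pseudo),
            class = "fnr_pwm")
}

#' Mononucleotide background composition of a genome
#'
#' @param genome Named character vector of sequences; `N` bases are ignored.
#' @param uniform If `TRUE`, return the uniform composition instead.
#' @return Named numeric vector over A/C/G/T summing to 1.
#' @export
genome_background <- function(genome, uniform = FALSE) {
  if (uniform) return(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  counts <- numeric(4)
  for (seq in genome) {
    codes <- seq_to_codes(seq)
    counts <- counts + tabulate(codes, nbins = 4L)
  }
  stats::setNames(counts / sum(counts), BASES)
}
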