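#' Quantile-normalize an expression matrix
#'
#' All columns are forced onto the identical sorted value vector (the mean
#' of order statistics across columns); within-column ranks are preserved
#' and ties receive the average of the values they span. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param mat Numeric matrix, genes x samples (at least 2 columns).
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 2L || nrow(mat) == 0L) {
    stop("quantile normalization needs a matrix with >= 2 columns")
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Sequencing tag density per gene
#'
#' Density = aligned tag count divided by gene length in kb.
#'
#' @param counts Numeric vector of aligned tag counts per gene.
#' @param lengths_bp Gene lengths in bp (strictly positive).
#' @return Numeric vector of tags per kb.
#' @export
tag_density <- function(counts, lengths_bp) {
  if (any(lengths_bp <= 0)) stop("gene lengths must be positive")
  counts / (lengths_bp / 1000)
}

moderated_t_stats <- function(xa, xb, prior_df = 4) {
  na <- ncol(xa)
  nb <- ncol(xb)
  df_g <- na + nb - 2L
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var)
  vb <- apply(xb, 1, stats::var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df_g
  s2_prior <- mean(s2)  # shrink toward the global mean variance
  s2_mod <- (prior_df * s2_prior + df_g * s2) / (prior_df + df_g)
  tstat <- (ma - mb) / sqrt(s2_mod * (1 / na + 1 / nb))
  list(diff = ma - mb, t = tstat, df = df_g + prior_df)
}

#' Per-gene differential expression between two groups
#'
#' A gene is called DE when BOTH the absolute log2 fold change reaches
#' `log2(fold)` AND the test p-value is below `alpha`. The matrix must be
#' on the log2 scale. `method = "moderated_t"` shrinks per-gene pooled
#' variances toward the global mean variance with a fixed prior degree of
#' freedom (a simple empirical-Bayes moderation); `"welch_t"` uses
#' per-gene Welch tests.
#'
#' @param mat Numeric gene x sample matrix of log2 expression values with
#'   rownames.
#' @param group_a,group_b Column names or indices of the two groups (>= 2
#'   replicates each). The reported direction is `up` when group A exceeds
#'   group B.
#' @param fold Fold-change cutoff on the linear scale (default 2).
#' @param alpha p-value cutoff (default 0.01).
#' @param method `"moderated_t"` (default) or `"welch_t"`.
#' @param prior_df Prior degrees of freedom for the moderated test
#'   (default 4).
#' @return Tibble: `gene, log2_fc, p_value, direction`
#'   (`up`/`down`/`none`).
#' @export
de_genes <- function(mat, group_a, group_b, fold = 2, alpha = 0.01,
                     method = c("moderated_t", "welch_t"), prior_df = 4) {
  method <- match.arg(method)
  xa <- mat[, group_a, drop = FALSE]
  xb <- mat[, group_b, drop = FALSE]
  stopifnot(ncol(xa) >= 2L, ncol(xb) >= 2L)
  if (method == "moderated_t") {
    st <- moderated_t_stats(xa, xb, prior_df)
    pv <- 2 * stats::pt(-abs(st$t), df = st$df)
    lfc <- st$diff
  } else {
    res <- purrr::map(seq_len(nrow(mat)), function(g) {
      a <- xa[g, ]
      b <- xb[g, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        # zero variance in both groups: p is 0/1 by whether means differ
        return(c(mean(a) - mean(b), if (mean(a) == mean(b)) 1 else 0))
      }
      tt <- stats::t.test(a, b)
      c(tt$estimate[1] - tt$estimate[2], tt$p.value)
    })
    lfc <- vapply(res, `[`, numeric(1), 1)
    pv <- vapply(res, `[`, numeric(1), 2)
  }
  de <- abs(lfc) >= log2(fold) & pv < alpha
  tibble::tibble(
    gene = rownames(mat),
    log2_fc = unname(lfc),
    p_value = unname(pv),
    direction = dplyr::case_when(!de ~ "none", lfc > 0 ~ "up",
                                 .default = "down")
  )
}

#' Aggregate gene DE verdicts to operons
#'
#' An operon is DE if at least one member gene is DE (the "even if only one
#' gene" reading); its direction is that of its DE members, and when
#' members disagree, the direction of the member with the smallest p-value
#' wins and the operon is conflict-flagged.
#'
#' @param gene_verdicts Tibble from [de_genes()].
#' @param operon_map Tibble `gene, operon_id` (each gene in at most one
#'   operon).
#' @param require_single If `TRUE`, the alternative strict reading: an
#'   operon is DE only when exactly one gene is DE.
#' @return Tibble: `operon_id, direction, n_de, p_min, conflict`.
#' @export
operon_de <- function(gene_verdicts, operon_map, require_single = FALSE) {
  stopifnot(!anyDuplicated(operon_map$gene))
  joined <- dplyr::inner_join(gene_verdicts, operon_map, by = "gene")
  summarise_one <- function(df) {
    de <- df$direction != "none"
    n_de <- sum(de)
    called <- if (require_single) n_de == 1L else n_de >= 1L
    tibble::tibble(
      direction = if (!called) "none" else {
        df$direction[de][which.min(df$p_value[de])]
      },
      n_de = n_de,
      p_min = if (n_de > 0L) min(df$p_value[de]) else NA_real_,
      conflict = dplyr::n_distinct(df$direction[de]) > 1L
    )
  }
  joined |>
    dplyr::group_by(.data$operon_id) |>
    dplyr::group_modify(~ summarise_one(.x)) |>
    dplyr::ungroup()
}

#' Consensus DE call across datasets
#'
#' An operon enters the consensus when it is DE with a consistent direction
#' in at least `k` of the supplied datasets.
#'
#' @param verdict_list Named list of operon-verdict tibbles (from
#'   [operon_de()]), one per dataset.
#' @param k Minimum number of agreeing datasets (default 2).
#' @return Tibble: `operon_id, direction, n_support` for consensus members.
#' @export
consensus_de <- function(verdict_list, k = 2L) {
  stopifnot(length(verdict_list) >= k)
  all_v <- purrr::imap(verdict_list, function(v, nm) {
    dplyr::mutate(v[v$direction != "none", c("operon_id", "direction")],
                  dataset = nm)
  }) |> dplyr::bind_rows()
  if (nrow(all_v) == 0L) {
    return(tibble::tibble(operon_id = character(), direction = character(),
                          n_support = integer()))
  }
  all_v |>
    dplyr::count(.data$operon_id, .data$direction, name = "n_support") |>
    dplyr::group_by(.data$operon_id) |>
    dplyr::slice_max(.data$n_support, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_support >= k)
}
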