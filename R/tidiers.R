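#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PWM into long format
#'
#' @param x An `fnr_pwm`.
#' @param ... Unused.
#' @return Tibble `position, base, count, prob, weight`.
#' @export
tidy.fnr_pwm <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$width), each = 4L),
    base = rep(BASES, x$width),
    count = as.vector(x$counts),
    prob = as.vector(x$probs),
    weight = as.vector(x$weights)
  )
}

#' One-row PWM summary
#'
#' @param x An `fnr_pwm`.
#' @param ... Unused.
#' @return Tibble `width, n_sites, total_ic_bits, max_score, consensus`.
#' @export
glance.fnr_pwm <- function(x, ...) {
  tibble::tibble(
    width = x$width,
    n_sites = x$n_sites,
    total_ic_bits = sum(information_content(x)),
    max_score = sum(apply(x$weights, 2, max)),
    consensus = consensus_sequence(x)
  )
}

#' Tidy a precision-recall curve
#'
#' @param x An `fnr_pr_curve`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.fnr_pr_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a precision-recall curve at its F1 optimum
#'
#' @param x An `fnr_pr_curve`.
#' @param ... Unused.
#' @return Tibble `ln_p_threshold, precision, recall, f1` at the selected
#'   operating point.
#' @export
glance.fnr_pr_curve <- function(x, ...) {
  thr <- select_threshold(x)
  at <- x[x$ln_p_threshold == thr, ][1, ]
  tibble::tibble(ln_p_threshold = thr, precision = at$precision,
                 recall = at$recall, f1 = at$f1)
}

#' Tidy an exact score distribution
#'
#' @param x An `fnr_score_dist`.
#' @param ... Unused.
#' @return Tibble `score, prob, tail_prob, ln_tail`.
#' @export
tidy.fnr_score_dist <- function(x, ...) {
  tibble::tibble(score = x$grid, prob = x$prob, tail_prob = x$tail_prob,
                 ln_tail = x$ln_tail)
}

#' Plot a precision-recall curve with its operating point
#'
#' @param object An `fnr_pr_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fnr_pr_curve <- function(object, ...) {
  best <- glance.fnr_pr_curve(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path(linewidth = 0.5) +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = "Precision-recall threshold selection",
      subtitle = sprintf("operating point: ln p <= %.2f (F1 = %.2f)",
                         best$ln_p_threshold, best$f1)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot per-position information content of a PWM
#'
#' @param object An `fnr_pwm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fnr_pwm <- function(object, ...) {
  df <- tibble::tibble(position = seq_len(object$width),
                       bits = information_content(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = df$position) +
    ggplot2::labs(x = "Motif position", y = "Information content (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot peak averages across a TF titration
#'
#' One line per tracked region; saturating regions flatten toward the
#' highest concentrations.
#'
#' @param object An `fnr_titration` from [titration_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fnr_titration <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$concentration,
                               y = .data$peak_average,
                               group = .data$region_index,
                               colour = factor(.data$region_index))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TF dimer concentration (uM)",
                  y = "Peak average (background-shifted)",
                  colour = "Region") +
    ggplot2::theme_minimal()
}
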