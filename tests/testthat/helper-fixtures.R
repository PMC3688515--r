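# shared objects built once per test run
fx_pwm <- fnr_pwm_default()
fx_dist <- score_distribution(fx_pwm)
fx_max_score <- sum(apply(fx_pwm$weights, 2, max))

# dense or probe track from a value vector starting at position 0
fx_track <- function(values, contig = "c", by = 1L,
                     kind = "read_density") {
  signal_track(
    tibble::tibble(contig = contig,
                   pos = as.integer(seq(0L, by = by,
                                        length.out = length(values))),
                   value = values),
    kind)
}

# a probe track holding a triangular site of amplitude `amp` centered at
# `center` over background 0, probe spacing 12 bp
fx_site_probe_track <- function(len, center, amp, halfwidth = 200,
                                noise_sd = 0, spacing = 12L, seed = NULL) {
  make <- function() {
    pos <- seq(0L, len - 1L, by = spacing)
    val <- amp * pmax(0, 1 - abs(pos - center) / halfwidth) +
      stats::rnorm(length(pos), 0, noise_sd)
    signal_track(tibble::tibble(contig = "c", pos = as.integer(pos),
                                value = val), "probe_log2_ratio")
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

# random PWM of a given width from a random alignment (for oracle tests)
fx_random_pwm <- function(width, n_sites = 8L) {
  sites <- vapply(seq_len(n_sites), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, character(1))
  build_pwm(sites)
}
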