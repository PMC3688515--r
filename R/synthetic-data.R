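with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Langmuir (single-site hyperbolic) occupancy
#'
#' `theta([TF], Kd) = [TF] / ([TF] + Kd)`: the simplest saturating binding
#' law, with no cooperativity. The dimer concentration is the input
#' variable. `theta(Kd, Kd) = 0.5` exactly.
#'
#' @param conc TF dimer concentration in uM (>= 0).
#' @param kd Dissociation constant in uM (> 0).
#' @return Fractional occupancy in `[0, 1]`.
#' @export
langmuir_occupancy <- function(conc, kd) {
  stopifnot(all(conc >= 0), all(kd > 0))
  conc / (conc + kd)
}

#' Score-to-affinity binding model for synthetic sites
#'
#' Maps a PWM score onto a dissociation constant,
#' `Kd = Kd_ref * exp(-beta * (score - score_ref))`, and carries the
#' lognormal capture-efficiency dispersion that decouples ChIP peak height
#' from affinity. With the defaults, sites planted near the consensus have
#' `Kd <= ~0.11 uM` and are more than 95% occupied at the 2.5 uM cellular
#' dimer level.
#'
#' @param kd_ref Kd at the reference (maximal) score, uM.
#' @param beta Score-to-affinity slope (0 makes all sites equal-affinity).
#' @param capture_sd SD of log capture efficiency (lognormal, median 1).
#' @return List of class `fnr_binding_model`.
#' @export
binding_model <- function(kd_ref = 0.05, beta = 0.5, capture_sd = 0.5) {
  stopifnot(kd_ref > 0, beta >= 0, capture_sd >= 0)
  structure(list(kd_ref = kd_ref, beta = beta, capture_sd = capture_sd),
            class = "fnr_binding_model")
}

#' Generate a random genome
#'
#' I.i.d. bases at the stated GC fraction; deterministic given `seed`.
#'
#' @param length_bp Genome length in bp.
#' @param gc GC fraction, strictly inside (0, 1).
#' @param contig Contig name.
#' @param seed Optional RNG seed.
#' @return Named character vector of length 1.
#' @export
make_genome <- function(length_bp, gc = 0.5, contig = "chr", seed = NULL) {
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  stopifnot(length_bp >= 1)
  with_optional_seed(seed, {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    bases <- sample(BASES, length_bp, replace = TRUE, prob = probs)
    stats::setNames(paste(bases, collapse = ""), contig)
  })
}

# sample one site sequence from PWM column probabilities whose score falls
# in [score_range[1], score_range[2]]
sample_site_sequence <- function(pwm, score_range, max_tries = 5000L) {
  w <- pwm$width
  for (i in seq_len(max_tries)) {
    idx <- vapply(seq_len(w), function(j) {
      sample.int(4L, 1L, prob = pwm$probs[, j])
    }, integer(1))
    score <- sum(pwm$weights[cbind(idx, seq_len(w))])
    if (score >= score_range[1] && score <= score_range[2]) {
      return(list(seq = paste(BASES[idx], collapse = ""), score = score))
    }
  }
  stop("could not sample a site in the requested score range")
}

#' Plant motif sites into a genome
#'
#' Samples `n_sites` sequences from the PWM whose scores fall in
#' `score_range` (default: within 1.5 natural-log units of the maximum
#' score, i.e. near-consensus sites) and writes them into the genome at
#' non-overlapping positions at least `min_gap` apart, on random strands.
#' Per-site affinity follows the binding model's score-to-Kd map and
#' capture efficiency is lognormal.
#'
#' @param genome Named character vector (single or multiple contigs; sites
#'   are planted on the first contig).
#' @param pwm An `fnr_pwm`.
#' @param n_sites Number of sites to plant.
#' @param score_range Numeric length-2 score window; `NULL` for the
#'   near-consensus default.
#' @param min_gap Minimum start-to-start distance between planted sites
#'   (default 2000 bp) and to the contig ends.
#' @param model A [binding_model()].
#' @param seed Optional RNG seed.
#' @return List: `genome` (with sites written in) and `sites`, a tibble
#'   `contig, start, end, strand, sequence, score, kd, capture`.
#' @export
plant_sites <- function(genome, pwm, n_sites, score_range = NULL,
                        min_gap = 2000L, model = binding_model(),
                        seed = NULL) {
  ctg <- names(genome)[1]
  len <- nchar(genome[[ctg]])
  w <- pwm$width
  if (w > len) stop("motif wider than genome")
  max_score <- sum(apply(pwm$weights, 2, max))
  if (is.null(score_range)) score_range <- c(max_score - 1.5, max_score)
  capacity <- (len - 2L * min_gap) %/% min_gap + 1L
  if (n_sites > capacity) {
    stop("cannot place ", n_sites, " sites with min_gap ", min_gap,
         " in ", len, " bp; at most ", max(capacity, 0L), " fit")
  }
  with_optional_seed(seed, {
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_sites) {
      tries <- tries + 1L
      if (tries > 200L * n_sites) {
        stop("cannot place ", n_sites, " sites with min_gap ", min_gap,
             "; placed ", length(starts))
      }
      cand <- sample.int(len - 2L * min_gap, 1L) + min_gap
      if (all(abs(cand - starts) >= min_gap)) starts <- c(starts, cand)
    }
    starts <- sort(starts)
    seq_chars <- genome[[ctg]]
    rows <- purrr::map(starts, function(s) {
      site <- sample_site_sequence(pwm, score_range)
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "+") site$seq else reverse_complement(site$seq)
      substr(seq_chars, s + 1L, s + w) <<- written
      tibble::tibble(contig = ctg, start = s, end = s + w, strand = strand,
                     sequence = site$seq, score = site$score)
    })
    sites <- dplyr::bind_rows(rows)
    sites$kd <- model$kd_ref * exp(-model$beta * (sites$score - max_score))
    sites$capture <- stats::rlnorm(n_sites, 0, model$capture_sd)
    genome[[ctg]] <- seq_chars
    list(genome = genome, sites = sites)
  })
}

draw_nap_region_around <- function(center, len, contig, contig_len) {
  # keep the site (motif width << 40 bp) fully inside the region
  offset <- sample(seq(20L, len - 20L), 1L)
  start <- max(0L, center - offset)
  end <- min(contig_len, start + len)
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end))
}

#' Generate a full synthetic regulon benchmark with known ground truth
#'
#' Builds a genome with planted near-consensus binding sites, marks a
#' fraction of them as occluded, and constructs NAP-enriched regions so
#' every occluded site lies inside a region of its occluding NAP. H-NS
#' region lengths mix the short (<= 1 kb) and extended (> 1 kb, filament)
#' classes; background regions not touching any accessible site are added
#' per NAP. Everything is reproducible from the seed.
#'
#' @param genome_length Genome size in bp (default 5e5).
#' @param gc GC fraction.
#' @param pwm PWM used for planting; default [fnr_pwm_default()].
#' @param n_sites Planted sites (default 60).
#' @param occluded_fraction Fraction of sites occluded by a NAP
#'   (default 0.2).
#' @param n_background_regions Background (non-occluding) regions per NAP.
#' @param model A [binding_model()].
#' @param seed RNG seed (required for reproducibility, default 1).
#' @return List of class `fnr_truth`: `genome`, `sites` (with `occluded`
#'   and `occluding_nap`), `nap_regions` (named list: hns, ihf, fis),
#'   `pwm`, `model`, `seed`.
#' @export
simulate_regulon_truth <- function(genome_length = 5e5, gc = 0.5,
                                   pwm = fnr_pwm_default(), n_sites = 60L,
                                   occluded_fraction = 0.2,
                                   n_background_regions = 12L,
                                   model = binding_model(), seed = 1L) {
  with_optional_seed(seed, {
    genome <- make_genome(genome_length, gc)
    planted <- plant_sites(genome, pwm, n_sites, model = model)
    sites <- planted$sites
    ctg <- names(planted$genome)[1]
    n_occ <- round(n_sites * occluded_fraction)
    occ_idx <- sort(sample.int(n_sites, n_occ))
    sites$occluded <- seq_len(n_sites) %in% occ_idx
    naps <- c("hns", "ihf", "fis")
    sites$occluding_nap <- NA_character_
    sites$occluding_nap[occ_idx] <- sample(naps, n_occ, replace = TRUE,
                                           prob = c(0.5, 0.25, 0.25))
    nap_regions <- stats::setNames(vector("list", 3L), naps)
    for (nap in naps) {
      covering <- purrr::map(which(sites$occluding_nap %in% nap), function(i) {
        extended <- stats::runif(1) < 0.5
        len <- if (extended) sample(1200:3000, 1L) else sample(300:900, 1L)
        draw_nap_region_around((sites$start[i] + sites$end[i]) %/% 2L, len,
                               ctg, genome_length)
      })
      background <- purrr::map(seq_len(n_background_regions), function(i) {
        len <- if (stats::runif(1) < 0.5) sample(1200:3000, 1L) else
          sample(300:900, 1L)
        start <- sample.int(genome_length - len, 1L)
        tibble::tibble(contig = ctg, start = start, end = start + len)
      })
      regs <- dplyr::bind_rows(c(covering, background))
      # background regions must not mask accessible sites
      acc <- sites[!sites$occluded, c("contig", "start", "end")]
      keep_bg <- !overlaps_any(regs, acc)
      keep_bg[seq_along(covering)] <- TRUE
      nap_regions[[nap]] <- dplyr::arrange(regs[keep_bg, ], .data$start)
    }
    structure(list(genome = planted$genome, sites = sites,
                   nap_regions = nap_regions, pwm = pwm, model = model,
                   seed = seed),
              class = "fnr_truth")
  })
}

#' @export
print.fnr_truth <- function(x, ...) {
  cat("<fnr_truth>", nchar(x$genome[[1]]), "bp genome,", nrow(x$sites),
      "planted sites (", sum(x$sites$occluded), "occluded ), NAP regions:",
      paste(names(x$nap_regions), vapply(x$nap_regions, nrow, integer(1)),
            collapse = ", "), "\n")
  invisible(x)
}

triangular_kernel <- function(offsets, halfwidth) {
  pmax(0, 1 - abs(offsets) / halfwidth)
}

#' Simulate a ChIP readout from a synthetic truth
#'
#' Per-site expected enrichment is
#' `E_i = theta(tf_conc, Kd_i) * capture_i`, zeroed when the site is
#' occluded by a NAP in `occlusion_naps` (binary occlusion). The signal is
#' `baseline + sum_i E_i * kernel(pos - center_i) + N(0, noise_sd)` with a
#' symmetric triangular kernel. Read-density tracks are dense per-bp;
#' probe-array tracks are sampled every `probe_spacing` bp (~12 bp for the
#' tiled arrays). The true peak list contains every accessible site whose
#' expected enrichment clears the detection floor.
#'
#' Dropping `"hns"` from `occlusion_naps` emulates the H-NS/StpA deletion
#' strain: previously H-NS-occluded sites produce peaks.
#'
#' @param truth An `fnr_truth` from [simulate_regulon_truth()].
#' @param tf_conc TF dimer concentration in uM (default 2.5, the cellular
#'   level).
#' @param readout `"read_density"` or `"probe_array"`.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param probe_spacing Probe spacing in bp for probe arrays (default 12).
#' @param kernel_halfwidth Enrichment kernel half-width in bp
#'   (default 200).
#' @param baseline Additive background level.
#' @param detection_floor Minimum expected enrichment for a site to appear
#'   in the true peak list (default 0.1).
#' @param occlusion_naps NAPs whose regions occlude (default all).
#' @param seed Optional RNG seed.
#' @return List: `track` (an `fnr_track`), `peaks` (true peak tibble with
#'   `site_index`, `summit`, `summit_height`), `expected` (per-site E_i).
#' @export
simulate_chip <- function(truth, tf_conc = 2.5,
                          readout = c("read_density", "probe_array"),
                          noise_sd = 0.05, probe_spacing = 12L,
                          kernel_halfwidth = 200L, baseline = 0,
                          detection_floor = 0.1,
                          occlusion_naps = names(truth$nap_regions),
                          seed = NULL) {
  readout <- match.arg(readout)
  stopifnot(tf_conc >= 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  sites <- truth$sites
  masked <- sites$occluded & sites$occluding_nap %in% occlusion_naps
  e <- langmuir_occupancy(tf_conc, sites$kd) * sites$capture *
    ifelse(masked, 0, 1)
  ctg <- names(truth$genome)[1]
  len <- nchar(truth$genome[[ctg]])
  centers <- (sites$start + sites$end) %/% 2L
  expected <- numeric(len)
  for (i in seq_len(nrow(sites))) {
    if (e[i] == 0) next
    lo <- max(0L, centers[i] - kernel_halfwidth)
    hi <- min(len - 1L, centers[i] + kernel_halfwidth)
    idx <- lo:hi
    expected[idx + 1L] <- expected[idx + 1L] +
      e[i] * triangular_kernel(idx - centers[i], kernel_halfwidth)
  }
  with_optional_seed(seed, {
    pos <- if (readout == "read_density") {
      0:(len - 1L)
    } else {
      seq(0L, len - 1L, by = probe_spacing)
    }
    values <- baseline + expected[pos + 1L] +
      stats::rnorm(length(pos), 0, noise_sd)
    track <- signal_track(
      tibble::tibble(contig = ctg, pos = as.integer(pos), value = values),
      if (readout == "read_density") "read_density" else "probe_log2_ratio")
    detected <- which(e > detection_floor)
    peaks <- tibble::tibble(
      contig = ctg,
      start = pmax(0L, centers[detected] - kernel_halfwidth %/% 2L),
      end = pmin(len, centers[detected] + kernel_halfwidth %/% 2L),
      summit = centers[detected],
      summit_height = baseline + e[detected],
      site_index = detected
    )
    list(track = track, peaks = peaks, expected = e)
  })
}

#' Simulate replicated expression matrices with planted FNR effects
#'
#' Gene baselines are uniform between 6 and 12 on the log2 scale; genes in
#' regulated operons
#' share the operon effect. In the fnr-deletion strain, FNR-activated
#' operons drop by log2(fold) and FNR-repressed operons rise; the aerobic
#' WT condition behaves like the deletion strain (FNR inactive with O2).
#' Array-like output is Gaussian on the log2 scale; seq-like output is
#' negative-binomial counts with mean `2^log2_level` and the given
#' dispersion.
#'
#' @param operons Operon tibble with list-column `genes`.
#' @param effects Tibble `operon_id, direction ("up"/"down"), fold` of
#'   FNR-regulated operons (direction is the WT-anaerobic vs deletion
#'   effect; fold > 0).
#' @param n_replicates Replicates per condition (default 3).
#' @param noise_sd Log2-scale replicate SD for array-like data
#'   (default 0.15).
#' @param dispersion Negative-binomial dispersion for seq-like counts
#'   (default 0.05).
#' @param kind `"array"` (log2 matrices) or `"seq"` (count matrices).
#' @param seed Optional RNG seed.
#' @return List of matrices `wt_minusO2, wt_plusO2, dfnr_minusO2` (genes x
#'   replicates), plus `gene_effects` (per-gene planted log2 shift).
#' @export
simulate_expression <- function(operons, effects, n_replicates = 3L,
                                noise_sd = 0.15, dispersion = 0.05,
                                kind = c("array", "seq"), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_replicates >= 2L)
  if (any(effects$fold <= 0)) stop("fold effects must be positive")
  genes <- unlist(operons$genes, use.names = FALSE)
  gene_operon <- rep(operons$operon_id, lengths(operons$genes))
  with_optional_seed(seed, {
    base <- stats::runif(length(genes), 6, 12)
    shift <- rep(0, length(genes))
    for (k in seq_len(nrow(effects))) {
      sel <- gene_operon == effects$operon_id[k]
      delta <- log2(effects$fold[k])
      shift[sel] <- if (effects$direction[k] == "up") delta else -delta
    }
    # WT anaerobic = base + shift; FNR inactive (deletion, or +O2) = base
    draw <- function(level) {
      m <- if (kind == "array") {
        matrix(stats::rnorm(length(level) * n_replicates, level, noise_sd),
               ncol = n_replicates)
      } else {
        matrix(stats::rnbinom(length(level) * n_replicates,
                              mu = rep(2^level, n_replicates),
                              size = 1 / dispersion),
               ncol = n_replicates)
      }
      rownames(m) <- genes
      colnames(m) <- paste0("rep", seq_len(n_replicates))
      m
    }
    list(wt_minusO2 = draw(base + shift),
         wt_plusO2 = draw(base),
         dfnr_minusO2 = draw(base),
         gene_effects = stats::setNames(shift, genes))
  })
}

#' Synthetic upstream-sequence set for the indirect-regulon screen
#'
#' Builds `n` upstream sequences of `length_bp` for peakless DE operons,
#' plants the PWM consensus centrally in exactly `n_planted` of them, and
#' guarantees by rejection sampling that no unplanted sequence carries an
#' above-threshold match on either strand (the fixture's defining
#' property).
#'
#' @param pwm An `fnr_pwm`.
#' @param n Number of operon upstream sequences (default 70).
#' @param n_planted How many carry a planted site (default 1, the first).
#' @param length_bp Upstream window length (default 500 nt).
#' @param ln_p_threshold Screen threshold the clean sequences must stay
#'   above (default [fnr_default_ln_p()]).
#' @param gc Background GC fraction.
#' @param dist Optional precomputed [score_distribution()].
#' @param seed Optional RNG seed.
#' @return List: `sequences` (named character vector `operon_001`...),
#'   `planted` (names of sequences carrying a site).
#' @export
make_upstream_set <- function(pwm, n = 70L, n_planted = 1L, length_bp = 500L,
                              ln_p_threshold = fnr_default_ln_p(), gc = 0.5,
                              dist = NULL, seed = NULL) {
  stopifnot(n_planted <= n)
  if (is.null(dist)) dist <- score_distribution(pwm)
  with_optional_seed(seed, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      repeat {
        s <- make_genome(length_bp, gc)[[1]]
        hits <- scan_pwm(c(u = s), pwm, ln_p_threshold, dist = dist)
        if (nrow(hits) == 0L) break
      }
      seqs[i] <- s
    }
    cons <- consensus_sequence(pwm)
    for (i in seq_len(n_planted)) {
      at <- (length_bp - pwm$width) %/% 2L
      substr(seqs[i], at + 1L, at + pwm$width) <- cons
    }
    names(seqs) <- sprintf("operon_%03d", seq_len(n))
    list(sequences = seqs,
         planted = names(seqs)[seq_len(n_planted)])
  })
}
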