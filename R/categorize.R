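#' Associate ChIP peaks with downstream operons
#'
#' An operon is linked to every peak whose region overlaps the first-gene
#' translation start or comes within `window` nt of it on the operon's
#' upstream side. A single peak between divergent operons can serve both.
#'
#' @param peaks Peak tibble.
#' @param operons Operon tibble (`operon_id, strand, first_gene_start`,
#'   optional `contig`).
#' @param window Association window in nt (default 500).
#' @return Tibble `operon_id, peak_index, distance` (0 when the start lies
#'   inside the peak).
#' @export
associate_peaks <- function(peaks, operons, window = 500L) {
  rows <- purrr::map(seq_len(nrow(operons)), function(i) {
    op <- operons[i, ]
    cand <- if (!is.null(op$contig) && !is.na(op$contig)) {
      which(peaks$contig == op$contig)
    } else {
      seq_len(nrow(peaks))
    }
    if (!length(cand)) return(NULL)
    s <- op$first_gene_start
    res <- purrr::map(cand, function(j) {
      pk <- peaks[j, ]
      if (s >= pk$start && s < pk$end) {
        return(tibble::tibble(operon_id = op$operon_id, peak_index = j,
                              distance = 0L))
      }
      upstream <- if (identical(op$strand, "-")) pk$start > s else pk$end <= s
      if (!upstream) return(NULL)
      d <- min(abs(s - pk$start), abs(s - (pk$end - 1L)))
      if (d <= window) {
        tibble::tibble(operon_id = op$operon_id, peak_index = j,
                       distance = as.integer(d))
      } else NULL
    })
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(operon_id = character(), peak_index = integer(),
                          distance = integer()))
  }
  out
}

upstream_window_sequence <- function(genome, operon, window = 500L) {
  ctg <- if (!is.null(operon$contig) && !is.na(operon$contig)) {
    operon$contig
  } else {
    names(genome)[1]
  }
  len <- nchar(genome[[ctg]])
  s <- operon$first_gene_start
  if (identical(operon$strand, "-")) {
    lo <- min(s + 1L, len)
    hi <- min(s + 1L + window, len)
  } else {
    lo <- max(0L, s - window)
    hi <- s
  }
  if (hi <= lo) return("")
  substr(genome[[ctg]], lo + 1L, hi)
}

#' Classify operons into the seven regulatory categories
#'
#' Combines WT ChIP peaks, consensus differential-expression verdicts,
#' curated TF annotations, and the H-NS/StpA-deletion comparison:
#' \enumerate{
#'   \item peak + consensus DE up: direct activation;
#'   \item peak + consensus DE down: direct repression;
#'   \item peak, no DE, co-activator annotation (e.g. NarL/NarP/CRP);
#'   \item peak, no DE, repressor annotation (e.g. Fur) masking FNR;
#'   \item peak, no DE, otherwise: other mechanisms;
#'   \item DE, no peak: indirect regulation — unless the 500-nt upstream
#'     scan at the operating threshold finds a site, in which case the
#'     operon is flagged `direct_candidate` instead;
#'   \item no WT peak, mutant-only peak, and an O2-dependent expression
#'     change only in the deletion strain.
#' }
#' Annotation roles are resolved by `role_precedence` (repressor beats
#' co-activator by default, the feoA convention).
#'
#' @param operons Operon tibble.
#' @param peak_map Tibble from [associate_peaks()] for the WT peaks.
#' @param consensus Tibble `operon_id, direction` of consensus-DE operons.
#' @param genome,pwm Genome and PWM for the Category-6 upstream scan.
#' @param annotations Tibble `operon_id, tag, role` with roles in
#'   `c("coactivator", "repressor", "other")`; data, not code.
#' @param mut_peak_map Optional [associate_peaks()] tibble for
#'   mutant-strain peaks.
#' @param mut_o2_de,wt_o2_de Optional tibbles `operon_id, direction` of
#'   O2-dependent DE in the mutant / WT backgrounds.
#' @param ln_p_threshold Upstream-scan threshold (default
#'   [fnr_default_ln_p()]).
#' @param dist Optional precomputed [score_distribution()].
#' @param upstream_window Upstream scan window in nt (default 500).
#' @param role_precedence Order in which annotation roles decide
#'   Categories 3/4.
#' @return Tibble of class `fnr_categories`: `operon_id, category`
#'   (`"1"`..`"7"`, `"direct_candidate"`, `"unclassified"`), `direction`,
#'   `has_peak`, `n_peaks`, `annotation_role`, `upstream_site`, `conflict`.
#' @export
assign_categories <- function(operons, peak_map, consensus, genome, pwm,
                              annotations = NULL, mut_peak_map = NULL,
                              mut_o2_de = NULL, wt_o2_de = NULL,
                              ln_p_threshold = fnr_default_ln_p(),
                              dist = NULL, upstream_window = 500L,
                              role_precedence = c("repressor",
                                                  "coactivator")) {
  if (is.null(dist)) dist <- score_distribution(pwm)
  cons_dir <- stats::setNames(consensus$direction, consensus$operon_id)
  mut_ops <- if (!is.null(mut_peak_map)) unique(mut_peak_map$operon_id) else
    character()
  mut_de_ops <- if (!is.null(mut_o2_de)) {
    mut_o2_de$operon_id[mut_o2_de$direction != "none"]
  } else character()
  wt_de_ops <- if (!is.null(wt_o2_de)) {
    wt_o2_de$operon_id[wt_o2_de$direction != "none"]
  } else character()
  rows <- purrr::map(seq_len(nrow(operons)), function(i) {
    op <- operons[i, ]
    id <- op$operon_id
    pk_idx <- peak_map$peak_index[peak_map$operon_id == id]
    has_peak <- length(pk_idx) > 0L
    direction <- if (id %in% names(cons_dir)) cons_dir[[id]] else "none"
    role <- NA_character_
    upstream_site <- NA
    category <- if (has_peak && direction == "up") {
      "1"
    } else if (has_peak && direction == "down") {
      "2"
    } else if (has_peak) {
      roles <- if (!is.null(annotations)) {
        annotations$role[annotations$operon_id == id]
      } else character()
      hit <- role_precedence[role_precedence %in% roles]
      if (length(hit)) {
        role <- hit[1]
        if (hit[1] == "repressor") "4" else "3"
      } else {
        "5"
      }
    } else if (direction != "none") {
      useq <- upstream_window_sequence(genome, op, upstream_window)
      hits <- if (nchar(useq) >= pwm$width) {
        scan_pwm(stats::setNames(useq, id), pwm, ln_p_threshold, dist = dist)
      } else {
        tibble::tibble()
      }
      upstream_site <- nrow(hits) > 0L
      if (upstream_site) "direct_candidate" else "6"
    } else if (id %in% mut_ops && id %in% mut_de_ops &&
               !(id %in% wt_de_ops)) {
      "7"
    } else {
      "unclassified"
    }
    tibble::tibble(operon_id = id, category = category,
                   direction = direction, has_peak = has_peak,
                   n_peaks = length(pk_idx), annotation_role = role,
                   upstream_site = upstream_site)
  })
  out <- dplyr::bind_rows(rows)
  out$conflict <- FALSE
  class(out) <- unique(c("fnr_categories", class(out)))
  out
}

#' Summarize category assignments
#'
#' @param assignments Tibble from [assign_categories()].
#' @return Tibble of category counts (all operons accounted for exactly
#'   once).
#' @export
category_counts <- function(assignments) {
  dplyr::count(assignments, .data$category, name = "n")
}

#' Build a per-operon report table in the style of a regulon summary
#'
#' One row per categorized operon: 1-based peak summit, number of binding
#' sites called in the peak, the top site's position relative to the TSS
#' (or a sentinel when the TSS is unknown or outside the peak region), the
#' differential sigma-70 occupancy verdict, and the WT anaerobic/aerobic
#' expression verdict.
#'
#' @param assignments Tibble from [assign_categories()].
#' @param operons Operon tibble (for TSS lookups).
#' @param site_calls Optional tibble `operon_id, summit, n_sites,
#'   site_start, site_end` (0-based site interval of the top-scoring
#'   site).
#' @param sigma70_verdicts Optional tibble `operon_id, verdict` from
#'   [sigma70_differential()].
#' @param wt_expression Optional tibble `operon_id, direction` of WT
#'   -O2 vs +O2 expression (`up`/`down`/`none`).
#' @return Tibble: `peak_center_nt` (1-based), `operon_id, category,
#'   n_sites, location, sigma70, wt_expression`.
#' @export
report_table <- function(assignments, operons, site_calls = NULL,
                         sigma70_verdicts = NULL, wt_expression = NULL) {
  kept <- assignments[assignments$category != "unclassified", ]
  rows <- purrr::map(kept$operon_id, function(id) {
    op <- operons[operons$operon_id == id, ]
    sc <- if (!is.null(site_calls)) {
      site_calls[site_calls$operon_id == id, ]
    } else NULL
    location <- "TSS not known"
    peak_center <- NA_integer_
    n_sites <- NA_integer_
    if (!is.null(sc) && nrow(sc) == 1L) {
      peak_center <- sc$summit + 1L  # display layer is 1-based
      n_sites <- sc$n_sites
      if (op$tss_status == "known") {
        pos <- relative_position(
          tibble::tibble(start = sc$site_start, end = sc$site_end), op)
        location <- format(pos)
      } else if (op$tss_status == "not_in_peak") {
        location <- "TSS not in peak region"
      }
    } else if (nrow(op) == 1L && op$tss_status == "not_in_peak") {
      location <- "TSS not in peak region"
    }
    sig <- if (!is.null(sigma70_verdicts) &&
               id %in% sigma70_verdicts$operon_id) {
      sigma70_verdicts$verdict[sigma70_verdicts$operon_id == id][1]
    } else "none"
    wt <- if (!is.null(wt_expression) && id %in% wt_expression$operon_id) {
      d <- wt_expression$direction[wt_expression$operon_id == id][1]
      dplyr::case_when(d == "up" ~ "+", d == "down" ~ "-", .default = "o")
    } else "o"
    tibble::tibble(peak_center_nt = peak_center, operon_id = id,
                   category = kept$category[kept$operon_id == id][1],
                   n_sites = n_sites, location = location, sigma70 = sig,
                   wt_expression = wt)
  })
  dplyr::bind_rows(rows)
}
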