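#' Default end-to-end pipeline configuration
#'
#' All tunables of the synthetic-benchmark pipeline in one list: the
#' genome/planting parameters, the ChIP readout, the scan and
#' precision-recall settings, the occupancy and expression test levels,
#' and the category engine constants. The configuration round-trips
#' through JSON.
#'
#' @param seed RNG seed for the whole run (per-stage substreams are
#'   derived from it).
#' @param outdir Output directory for stage files.
#' @return Named list of class `fnr_config`.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = tempfile("fnr_run_")) {
  structure(list(
    mode = "synthetic",
    seed = as.integer(seed),
    outdir = outdir,
    genome_length = 1e5,
    gc = 0.5,
    n_sites = 20L,
    occluded_fraction = 0.2,
    tf_conc = 2.5,
    noise_sd = 0.05,
    kernel_halfwidth = 200L,
    peak_threshold = 0.25,
    scan_base_ln_p = -5,
    window_nt = 500L,
    peak_window_bp = 200L,
    trim_fraction = 0.5,
    flank_bp = 1500L,
    alpha_occupancy = 0.05,
    alpha_de = 0.01,
    fold = 2,
    sim_fold = 4,
    n_replicates = 3L,
    consensus_k = 2L,
    hns_cutoff_bp = 1000L,
    grubbs_alpha = 0.15,
    grubbs_z = 1.04,
    reproduction_ln_p = fnr_default_ln_p()
  ), class = c("fnr_config", "list"))
}

write_stage <- function(obj, path) {
  utils::write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the synthetic benchmark pipeline end to end
#'
#' Chains simulate -> ChIP readout -> peak calling -> scan ->
#' precision-recall threshold -> per-peak site calls -> occlusion report
#' -> expression simulation -> operon consensus -> category assignment,
#' writing every stage output as TSV/FASTA/BED under `config$outdir`
#' together with a JSON manifest recording the seed, the configuration,
#' and a content hash per output. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config List from [default_pipeline_config()].
#' @return List of in-memory stage results (invisibly also written to
#'   disk); `$manifest` names every output file.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stopifnot(config$mode == "synthetic")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$outdir, name)
  seed <- config$seed
  pwm <- fnr_pwm_default()
  dist <- score_distribution(pwm)

  truth <- simulate_regulon_truth(
    genome_length = config$genome_length, gc = config$gc, pwm = pwm,
    n_sites = config$n_sites, occluded_fraction = config$occluded_fraction,
    seed = seed)
  write_fasta(truth$genome, out("genome.fa"))
  write_bed(truth$sites, out("truth_sites.bed"))
  for (nap in names(truth$nap_regions)) {
    write_bed(truth$nap_regions[[nap]], out(paste0("nap_", nap, ".bed")))
  }

  chip <- simulate_chip(truth, tf_conc = config$tf_conc,
                        noise_sd = config$noise_sd,
                        kernel_halfwidth = config$kernel_halfwidth,
                        seed = seed + 1L)
  write_bedgraph(chip$track, out("chip_track.bedgraph"))

  peaks <- simple_peak_caller(chip$track, threshold = config$peak_threshold,
                              min_len = 50L, merge_gap = 100L)
  write_bed(peaks, out("peaks.bed"))

  hits <- scan_pwm(truth$genome, pwm, config$scan_base_ln_p, dist = dist)
  write_stage(hits, out("scan_hits.tsv"))

  pr <- pr_curve(hits, peaks)
  write_stage(pr, out("pr_curve.tsv"))
  threshold <- select_threshold(pr)

  predictions <- hits[hits$ln_pvalue <= threshold, , drop = FALSE]
  write_stage(predictions, out("predicted_sites.tsv"))

  site_calls <- purrr::map(seq_len(nrow(peaks)), function(i) {
    call <- call_peak_sites(peaks[i, ], truth$genome, pwm, dist = dist,
                            window_bp = config$peak_window_bp,
                            alpha = config$grubbs_alpha,
                            z_crit = config$grubbs_z)
    tibble::tibble(peak_index = i, summit = peaks$summit[i],
                   n_sites = call$n_sites,
                   top_score = call$hits$score[1])
  }) |> dplyr::bind_rows()
  write_stage(site_calls, out("peak_site_calls.tsv"))

  occl <- occlusion_report(predictions, peaks, truth$nap_regions)
  write_stage(occl$sites, out("occlusion_sites.tsv"))
  write_stage(occl$tests, out("occlusion_tests.tsv"))

  # one operon downstream of each planted site (accessible ones are
  # FNR-activated) plus three unregulated decoys per site, so regulated
  # genes stay a minority and quantile normalization keeps its footing
  n_sites <- nrow(truth$sites)
  site_ops <- tibble::tibble(
    operon_id = sprintf("op%03d", seq_len(n_sites)),
    first_gene_start = truth$sites$end + 150L)
  gaps <- round(seq(1000L, config$genome_length - 1000L,
                    length.out = 3L * n_sites))
  gaps <- gaps[!overlaps_any(
    tibble::tibble(contig = truth$sites$contig[1], start = gaps,
                   end = gaps + 1L),
    tibble::tibble(contig = truth$sites$contig,
                   start = truth$sites$start - 800L,
                   end = truth$sites$end + 800L))]
  decoy_ops <- tibble::tibble(
    operon_id = sprintf("decoy%03d", seq_along(gaps)),
    first_gene_start = as.integer(gaps))
  operons <- dplyr::bind_rows(site_ops, decoy_ops)
  operons <- tibble::tibble(
    operon_id = operons$operon_id,
    genes = purrr::map(operons$operon_id, ~ paste0(.x, "_g", 1:2)),
    strand = "+",
    first_gene_start = operons$first_gene_start,
    contig = truth$sites$contig[1],
    tss = NA_integer_,
    tss_status = "unknown"
  )
  regulated <- site_ops$operon_id[!truth$sites$occluded]
  effects <- tibble::tibble(operon_id = regulated, direction = "up",
                            fold = config$sim_fold)
  verdicts <- purrr::map(1:3, function(d) {
    expr <- simulate_expression(operons, effects,
                                n_replicates = config$n_replicates,
                                seed = seed + 10L + d)
    mat <- cbind(expr$wt_minusO2, expr$dfnr_minusO2)
    colnames(mat) <- c(paste0("wt", seq_len(config$n_replicates)),
                       paste0("dfnr", seq_len(config$n_replicates)))
    gv <- de_genes(quantile_normalize(mat),
                   paste0("wt", seq_len(config$n_replicates)),
                   paste0("dfnr", seq_len(config$n_replicates)),
                   fold = config$fold, alpha = config$alpha_de)
    operon_de(gv, tibble::tibble(
      gene = unlist(operons$genes),
      operon_id = rep(operons$operon_id, lengths(operons$genes))))
  })
  consensus <- consensus_de(stats::setNames(verdicts, paste0("ds", 1:3)),
                            k = config$consensus_k)
  write_stage(consensus, out("consensus_de.tsv"))

  peak_map <- associate_peaks(peaks, operons, window = config$window_nt)
  categories <- assign_categories(operons, peak_map, consensus,
                                  truth$genome, pwm,
                                  ln_p_threshold = threshold, dist = dist,
                                  upstream_window = config$window_nt)
  write_stage(categories, out("categories.tsv"))

  files <- list.files(config$outdir, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    seed = seed,
    threshold = threshold,
    config = config[setdiff(names(config), "outdir")],
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    outputs = lapply(stats::setNames(files, files), function(f) {
      rlang::hash(readr::read_file(file.path(config$outdir, f)))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(truth = truth, chip = chip, peaks = peaks, hits = hits,
                 pr = pr, threshold = threshold, predictions = predictions,
                 site_calls = site_calls, occlusion = occl,
                 consensus = consensus, categories = categories,
                 manifest = manifest))
}
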