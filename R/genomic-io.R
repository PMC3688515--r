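#' Read a genome from a FASTA file
#'
#' Parses a (multi-)FASTA file into a named character vector, one element per
#' record. Sequences are uppercased and any character outside A/C/G/T is
#' replaced by `N` (with a warning), so downstream scanning can rely on a
#' five-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are record identifiers
#'   (first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("non-ACGT characters in record(s) ",
            paste(nm[bad], collapse = ", "), " mapped to N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA record")
  stats::setNames(seqs, nm)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Lengths of genome contigs
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @return Named integer vector of contig lengths in bp.
#' @export
genome_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Construct an interval tibble
#'
#' Intervals are 0-based, half-open `[start, end)` — the native BED
#' convention used throughout the package. Display-layer outputs (report
#' tables) convert to 1-based positions.
#'
#' @param contig Contig name(s).
#' @param start,end Integer bounds, 0-based half-open.
#' @param strand One of `"+"`, `"-"`, `"."` (recycled).
#' @param ... Further columns (e.g. `name`, `summit`).
#' @return A tibble with class `fnr_intervals`.
#' @export
intervals <- function(contig, start, end, strand = ".", ...) {
  out <- tibble::tibble(contig = as.character(contig),
                        start = as.integer(start),
                        end = as.integer(end),
                        strand = strand, ...)
  validate_intervals(out)
  out
}

validate_intervals <- function(x, lengths = NULL) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  if (any(x$start < 0L)) stop("interval start < 0")
  if (any(x$start >= x$end)) stop("interval with start >= end")
  if (!is.null(lengths)) {
    bad <- x$end > lengths[x$contig]
    if (any(bad)) stop("interval extends past contig end")
  }
  invisible(x)
}

#' Read intervals or peaks from a BED file
#'
#' Accepts BED3 and BED6; a seventh column, when present, is interpreted as
#' the peak summit (0-based position of maximum signal) and an eighth as the
#' summit height. Lines violating `0 <= start < end` are rejected with an
#' error naming the line. Missing strand is stored as `"."`.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `contig, start, end, name, score, strand` and,
#'   when present in the file, `summit` and `summit_height`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), name = character(),
                          score = double(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED line ", which(ncol < 3L)[1], " has fewer than 3 fields")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  }
  out <- tibble::tibble(
    contig = get(1L, NA_character_),
    start = as.integer(get(2L, NA_character_)),
    end = as.integer(get(3L, NA_character_)),
    name = get(4L, NA_character_),
    score = suppressWarnings(as.numeric(get(5L, NA_character_))),
    strand = dplyr::if_else(get(6L, ".") %in% c("+", "-"), get(6L, "."), ".")
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0L |
                 out$start >= out$end)
  if (length(bad)) {
    stop("invalid BED interval at line ", bad[1], ": start >= end or not numeric")
  }
  if (max(ncol) >= 7L) {
    out$summit <- suppressWarnings(as.integer(get(7L, NA_character_)))
    in_range <- is.na(out$summit) |
      (out$summit >= out$start & out$summit < out$end)
    if (!all(in_range)) {
      stop("summit outside peak region at line ", which(!in_range)[1])
    }
  }
  if (max(ncol) >= 8L) {
    out$summit_height <- suppressWarnings(as.numeric(get(8L, NA_character_)))
  }
  out
}

#' Write intervals/peaks as BED
#'
#' Emits BED6, appending `summit` (and `summit_height`) columns when present.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(
    contig = x$contig, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else ".",
    score = if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  if ("summit" %in% names(x)) df$summit <- x$summit
  if ("summit_height" %in% names(x)) df$summit_height <- x$summit_height
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a signal track from a bedGraph file
#'
#' A track is a tibble of `(contig, pos, value)` with strictly increasing
#' positions per contig and a `kind` attribute. For `kind = "read_density"`
#' each bedGraph span is expanded to one entry per base; for
#' `kind = "probe_log2_ratio"` (sparse microarray probes, ~12 bp spacing)
#' each span contributes a single entry at its midpoint. Overlapping spans
#' are rejected.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param kind `"read_density"` or `"probe_log2_ratio"`.
#' @return A track tibble (`contig, pos, value`) with attribute `kind`.
#' @export
read_bedgraph <- function(path, kind = c("read_density", "probe_log2_ratio")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(signal_track(tibble::tibble(contig = character(), pos = integer(),
                                       value = double()), kind))
  }
  f <- readr::read_tsv(I(lines),
                       col_names = c("contig", "start", "end", "value"),
                       col_types = "ciid", progress = FALSE)
  if (any(f$start >= f$end)) stop("bedGraph span with start >= end")
  f <- dplyr::arrange(f, .data$contig, .data$start)
  ov <- f |>
    dplyr::group_by(.data$contig) |>
    dplyr::filter(dplyr::row_number() > 1L,
                  .data$start < dplyr::lag(.data$end)) |>
    nrow()
  if (ov > 0L) stop("overlapping bedGraph spans")
  out <- if (kind == "read_density") {
    f |>
      dplyr::reframe(pos = seq(.data$start, .data$end - 1L),
                     value = rep(.data$value, .data$end - .data$start),
                     .by = c("contig", "start")) |>
      dplyr::select("contig", "pos", "value")
  } else {
    tibble::tibble(contig = f$contig,
                   pos = as.integer((f$start + f$end - 1L) %/% 2L),
                   value = f$value)
  }
  signal_track(dplyr::arrange(out, .data$contig, .data$pos), kind)
}

#' Write a signal track as bedGraph
#'
#' Each entry is written as a single-bp span; values keep 6 decimals so a
#' write-then-read round trip preserves them.
#'
#' @param track Track tibble from [read_bedgraph()] or [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(contig = track$contig, start = track$pos,
                   end = track$pos + 1L,
                   value = formatC(track$value, format = "f", digits = 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a signal track
#'
#' @param x Tibble with columns `contig, pos, value`.
#' @param kind `"read_density"` (dense per-base) or `"probe_log2_ratio"`
#'   (sparse probe positions).
#' @return `x` with class `fnr_track` and attribute `kind`.
#' @export
signal_track <- function(x, kind = c("read_density", "probe_log2_ratio")) {
  kind <- match.arg(kind)
  stopifnot(all(c("contig", "pos", "value") %in% names(x)))
  dup <- x |>
    dplyr::group_by(.data$contig) |>
    dplyr::filter(dplyr::row_number() > 1L, .data$pos <= dplyr::lag(.data$pos))
  if (nrow(dup) > 0L) stop("track positions must be strictly increasing")
  attr(x, "kind") <- kind
  class(x) <- unique(c("fnr_track", class(x)))
  x
}

#' Test pairwise overlap of two intervals
#'
#' Half-open intersection: `[0,10)` and `[10,20)` do not overlap. Intervals
#' on different contigs never overlap.
#'
#' @param a,b Single-row interval tibbles (or tibbles recycled rowwise).
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  a$contig == b$contig & a$start < b$end & b$start < a$end
}

#' Match intervals in `a` to overlapping intervals in `b`
#'
#' @param a,b Interval tibbles.
#' @return Tibble with columns `a` and `b`: row indices of overlapping pairs.
#' @keywords internal
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble::tibble(a = integer(), b = integer()))
  }
  hits <- purrr::map(unique(a$contig), function(ctg) {
    ia <- which(a$contig == ctg)
    ib <- which(b$contig == ctg)
    if (!length(ia) || !length(ib)) return(NULL)
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    tibble::tibble(a = ia[S4Vectors::queryHits(ov)],
                   b = ib[S4Vectors::subjectHits(ov)])
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) tibble::tibble(a = integer(), b = integer()) else out
}

#' Distance from a peak region to an operon's first-gene translation start
#'
#' The distance is the minimum over positions inside the peak region of the
#' absolute offset to the translation start, 0 when the start lies inside the
#' region. The region anchor (not the summit) is used, so "within 500 nt"
#' means any base of the peak comes within 500 nt of the start.
#'
#' @param peak Single-row peak tibble (`contig, start, end`).
#' @param operon Single-row operon record with `contig` (optional if single
#'   contig) and `first_gene_start` (0-based position of the first coding
#'   base; for minus-strand operons the rightmost coding base).
#' @return Integer distance in bp, or `NA` with a warning if contigs differ.
#' @export
distance_to_start <- function(peak, operon) {
  if (!is.null(operon$contig) && !is.na(operon$contig) &&
      operon$contig != peak$contig) {
    warning("peak and operon on different contigs; distance undefined")
    return(NA_integer_)
  }
  s <- operon$first_gene_start
  if (s >= peak$start && s < peak$end) return(0L)
  as.integer(min(abs(s - peak$start), abs(s - (peak$end - 1L))))
}

#' Read an operon annotation table
#'
#' Tab-separated with header: `operon_id`, `genes` (semicolon-joined, in
#' transcription order), `strand`, `first_gene_start` (0-based translation
#' start of the first gene; rightmost coding start for minus-strand operons),
#' `tss` (1-based TSS position, or `unknown` / `not_in_peak`), and optionally
#' `contig`.
#'
#' @param path Path to the TSV.
#' @return Tibble with list-column `genes` and parsed `tss` (`NA` for the
#'   sentinel values, kept verbatim in `tss_status`).
#' @export
read_operons <- function(path) {
  f <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  stopifnot(all(c("operon_id", "genes", "strand", "first_gene_start") %in%
                  names(f)))
  tss_chr <- if ("tss" %in% names(f)) f$tss else rep("unknown", nrow(f))
  tibble::tibble(
    operon_id = f$operon_id,
    genes = strsplit(f$genes, ";", fixed = TRUE),
    strand = f$strand,
    first_gene_start = as.integer(f$first_gene_start),
    contig = if ("contig" %in% names(f)) f$contig else NA_character_,
    tss = suppressWarnings(as.integer(tss_chr)),
    tss_status = dplyr::case_when(
      !is.na(suppressWarnings(as.integer(tss_chr))) ~ "known",
      tss_chr == "not_in_peak" ~ "not_in_peak",
      .default = "unknown"
    )
  )
}

#' Write an operon annotation table
#'
#' @param operons Operon tibble as from [read_operons()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_operons <- function(operons, path) {
  tss_chr <- ifelse(operons$tss_status == "known", as.character(operons$tss),
                    operons$tss_status)
  df <- data.frame(
    operon_id = operons$operon_id,
    genes = vapply(operons$genes, paste, character(1), collapse = ";"),
    strand = operons$strand,
    first_gene_start = operons$first_gene_start,
    tss = tss_chr,
    contig = operons$contig
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
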