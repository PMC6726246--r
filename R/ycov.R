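#' Parameters for Y-specific window calls
#'
#' Two signatures are searched on a male-read assembly: male-only 1-kb
#' windows (male mean depth strictly above \code{mr_min_male_depth} and no
#' female coverage at all, "MR1k"), and hemizygous half-coverage segments
#' (male relative coverage in [\code{half_rel_low}, \code{half_rel_high}],
#' closed interval, with female absolute coverage below
#' \code{half_max_female_abs}).
#'
#' @param mr_min_male_depth male mean depth must exceed this (strict).
#' @param mr_max_female_depth maximum total female depth in the window
#'   (default 0: "no aligned reads in females").
#' @param half_rel_low,half_rel_high male relative-coverage window for the
#'   hemizygous signature.
#' @param half_max_female_abs female mean depth must be below this.
#' @return list of class \code{ycall_params}.
#' @export
ycall_params <- function(mr_min_male_depth = 10, mr_max_female_depth = 0,
                         half_rel_low = 0.3, half_rel_high = 0.7,
                         half_max_female_abs = 1) {
  stopifnot(half_rel_low < half_rel_high)
  structure(list(mr_min_male_depth = mr_min_male_depth,
                 mr_max_female_depth = mr_max_female_depth,
                 half_rel_low = half_rel_low, half_rel_high = half_rel_high,
                 half_max_female_abs = half_max_female_abs),
            class = "ycall_params")
}

#' Per-sex coverage in non-overlapping windows
#'
#' Mean absolute depth per sex in fixed-width windows tiling each contig
#' over its full declared length: positions absent from the input
#' contribute depth 0, and the window mean divides by the window width
#' (the last window of a contig may be shorter). Relative coverage divides
#' each pool's window mean by that pool's genome-wide mean depth over all
#' tiled positions, zero-depth positions included.
#'
#' @param sites a \code{pool_sites} table, sorted by (contig, pos).
#' @param contig_lengths named vector of contig lengths covering every
#'   contig present in \code{sites}.
#' @param window_size window width in bp (1000 in the Y-detection scan).
#' @return \code{data.table}: contig, start, end, width, male_abs,
#'   female_abs, male_sum, female_sum, male_rel, female_rel.
#' @export
coverage_windows <- function(sites, contig_lengths, window_size = 1000) {
  missing <- setdiff(unique(sites$contig), names(contig_lengths))
  if (length(missing))
    stop("no declared length for contig(s): ", paste(missing, collapse = ", "))
  md <- pool_depth(sites, "male")
  fd <- pool_depth(sites, "female")
  total_len <- sum(as.numeric(contig_lengths))
  mean_m <- sum(as.numeric(md)) / total_len
  mean_f <- sum(as.numeric(fd)) / total_len
  out <- vector("list", length(contig_lengths))
  for (ci in seq_along(contig_lengths)) {
    ctg <- names(contig_lengths)[ci]
    L <- as.integer(contig_lengths[[ci]])
    nwin <- as.integer((L - 1L) %/% window_size) + 1L
    sel <- sites$contig == ctg
    bin <- (sites$pos[sel] - 1L) %/% window_size + 1L
    sum_in <- function(x) {
      v <- numeric(nwin)
      if (length(x)) {
        s <- tapply(x, factor(bin, levels = seq_len(nwin)), sum, default = 0)
        v <- as.numeric(s)
      }
      v
    }
    msum <- sum_in(md[sel]); fsum <- sum_in(fd[sel])
    starts <- (seq_len(nwin) - 1L) * as.integer(window_size) + 1L
    ends <- pmin(starts + as.integer(window_size) - 1L, L)
    width <- ends - starts + 1L
    out[[ci]] <- data.table::data.table(
      contig = ctg, start = starts, end = ends, width = width,
      male_abs = msum / width, female_abs = fsum / width,
      male_sum = msum, female_sum = fsum,
      male_rel = if (mean_m > 0) (msum / width) / mean_m else 0,
      female_rel = if (mean_f > 0) (fsum / width) / mean_f else 0)
  }
  data.table::rbindlist(out)
}

#' Male-only windows (MR1k)
#'
#' Windows with male mean depth strictly above the threshold and no female
#' coverage at all. With pooled count input, "no aligned reads" is
#' evaluated as zero female depth summed over the window, which is
#' equivalent to no female read overlapping it.
#'
#' @param windows output of [coverage_windows()].
#' @param params a [ycall_params()].
#' @return the flagged subset of \code{windows}.
#' @export
detect_mr1k <- function(windows, params = ycall_params()) {
  windows[windows$male_abs > params$mr_min_male_depth &
            windows$female_sum <= params$mr_max_female_depth]
}

#' Hemizygous half-coverage windows
#'
#' Windows with male relative coverage inside the closed interval
#' [\code{half_rel_low}, \code{half_rel_high}] — the expectation for
#' sequence present on the Y haplotype only, at half the diploid genome
#' average — and female mean depth below \code{half_max_female_abs}.
#'
#' @inheritParams detect_mr1k
#' @return the flagged subset of \code{windows}.
#' @export
detect_half_coverage <- function(windows, params = ycall_params()) {
  windows[windows$male_rel >= params$half_rel_low &
            windows$male_rel <= params$half_rel_high &
            windows$female_abs < params$half_max_female_abs]
}

#' Total length of Y-specific sequence
#'
#' Merges flagged windows separated by at most \code{max_gap} bp into
#' segments and totals the merged length.
#'
#' @param flagged flagged windows (union of [detect_mr1k()] and
#'   [detect_half_coverage()] output), sorted by (contig, start).
#' @param max_gap maximum bp between consecutive flagged windows to merge.
#' @return list with \code{segments} (data.table contig, start, end,
#'   length) and \code{total} (bp).
#' @export
total_y_length <- function(flagged, max_gap = 0L) {
  if (nrow(flagged) == 0L)
    return(list(segments = data.table::data.table(
      contig = character(), start = integer(), end = integer(),
      length = integer()), total = 0L))
  f <- unique(flagged[, c("contig", "start", "end"), with = FALSE])
  data.table::setorder(f, contig, start)
  new_seg <- c(TRUE, f$contig[-1L] != f$contig[-nrow(f)] |
                 f$start[-1L] - f$end[-nrow(f)] - 1L > max_gap)
  f$seg_id <- cumsum(new_seg)
  segs <- f[, list(contig = contig[1L], start = min(start), end = max(end)),
            by = "seg_id"]
  segs$seg_id <- NULL
  segs$length <- segs$end - segs$start + 1L
  list(segments = segs[], total = sum(segs$length))
}

#' Export windows or segments as BED
#'
#' Converts 1-based inclusive intervals to the 0-based half-open BED
#' convention.
#'
#' @param intervals data frame with contig, start, end (1-based inclusive).
#' @param file output path.
#' @param header optional '#'-prefixed header lines.
#' @export
write_bed <- function(intervals, file, header = NULL) {
  lines <- paste(intervals$contig, intervals$start - 1L, intervals$end,
                 sep = "\t")
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, file)
  invisible(file)
}
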