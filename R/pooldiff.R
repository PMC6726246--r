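#' Classifier parameters for sex-specific SNP detection
#'
#' Defaults follow the standard pool-seq scanning configuration: minimum
#' depth 10 in each pool, heterozygous allele-frequency window 0.5 +/- 0.15,
#' homozygous window 1 +/- 0.05 (truncated at 1, since frequencies cannot
#' exceed 1).
#'
#' @param min_depth minimum per-pool depth for a site to be classified.
#' @param freq_het,range_het centre and half-width of the heterozygous
#'   allele-frequency window.
#' @param freq_hom,range_hom centre and half-width of the homozygous window.
#' @return a list of class \code{classifier_params}.
#' @export
classifier_params <- function(min_depth = 10, freq_het = 0.5, range_het = 0.15,
                              freq_hom = 1, range_hom = 0.05) {
  stopifnot(min_depth >= 1,
            freq_het - range_het > 0, freq_het + range_het < 1,
            freq_hom - range_hom >= 0, freq_hom <= 1)
  structure(list(min_depth = min_depth, freq_het = freq_het,
                 range_het = range_het, freq_hom = freq_hom,
                 range_hom = range_hom),
            class = "classifier_params")
}

# Allele-frequency matrix (A,T,C,G) for one pool; rows with zero depth get NA.
pool_freqs <- function(sites, sex) {
  cols <- if (sex == "male") male_cols(DEPTH_NUCS) else female_cols(DEPTH_NUCS)
  cnt <- as.matrix(sites[, cols, with = FALSE])
  d <- rowSums(cnt)
  f <- cnt / ifelse(d > 0, d, NA_real_)
  colnames(f) <- DEPTH_NUCS
  f
}

# het: exactly two alleles with counts > 0, both frequencies inside the window.
# Any third allele with a single read disqualifies (strict rule).
is_het_pool <- function(cnt, freqs, p) {
  nall <- rowSums(cnt > 0)
  lo <- p$freq_het - p$range_het
  hi <- p$freq_het + p$range_het
  inwin <- (freqs >= lo & freqs <= hi) | cnt == 0
  nall == 2L & rowSums(inwin) == 4L
}

# hom: majority allele frequency inside [freq_hom - range_hom, freq_hom].
is_hom_pool <- function(freqs, p) {
  fmax <- do.call(pmax, c(as.data.frame(freqs), na.rm = FALSE))
  fmax >= p$freq_hom - p$range_hom & fmax <= p$freq_hom
}

#' Classify sites as sex-specific SNPs and compute per-base FST
#'
#' A position is a male-specific SNP (MSS) when the male pool is
#' heterozygous — exactly two alleles, both with frequency inside the
#' heterozygous window — while the female pool is homozygous (majority
#' allele frequency inside the homozygous window); a female-specific SNP
#' (FSS) is the mirror image. Sites where either pool is below
#' \code{min_depth} are \code{"low_depth"} and get no FST.
#'
#' @param sites a \code{pool_sites} table.
#' @param params a [classifier_params()] object.
#' @param fst_fun per-site FST estimator; defaults to [fst_nei()]. Any
#'   function mapping two 4-column frequency matrices to a numeric vector
#'   can be plugged in (e.g. a pool-size-corrected estimator).
#' @return a \code{data.table} with columns contig, pos, call
#'   (male_specific / female_specific / none / low_depth), fst, and the
#'   per-pool depths (male_depth, female_depth).
#' @export
classify_sites <- function(sites, params = classifier_params(),
                           fst_fun = fst_nei) {
  md <- pool_depth(sites, "male")
  fd <- pool_depth(sites, "female")
  mf <- pool_freqs(sites, "male")
  ff <- pool_freqs(sites, "female")
  mc <- as.matrix(sites[, male_cols(DEPTH_NUCS), with = FALSE])
  fc <- as.matrix(sites[, female_cols(DEPTH_NUCS), with = FALSE])
  ok <- md >= params$min_depth & fd >= params$min_depth
  call <- rep("low_depth", nrow(sites))
  mss <- ok & is_het_pool(mc, mf, params) & is_hom_pool(ff, params)
  fss <- ok & is_het_pool(fc, ff, params) & is_hom_pool(mf, params)
  call[ok] <- "none"
  call[mss] <- "male_specific"
  call[fss] <- "female_specific"
  fst <- rep(NA_real_, nrow(sites))
  fst[ok] <- fst_fun(mf[ok, , drop = FALSE], ff[ok, , drop = FALSE])
  data.table::data.table(contig = sites$contig, pos = sites$pos,
                         call = call, fst = fst,
                         male_depth = md, female_depth = fd)
}

#' Classify a single site
#'
#' Scalar convenience wrapper around [classify_sites()].
#'
#' @param male,female named counts (any of A, T, C, G, N, del).
#' @inheritParams classify_sites
#' @return list with elements \code{call} and \code{fst}.
#' @export
classify_site <- function(male, female, params = classifier_params()) {
  s <- pool_sites("x", 1L, "N",
                  as.data.frame(as.list(male)), as.data.frame(as.list(female)))
  r <- classify_sites(s, params)
  list(call = r$call, fst = r$fst)
}

#' Nei-type per-site FST from pool allele frequencies
#'
#' \eqn{H_s} is the mean over the two pools of \eqn{1 - \sum_i p_i^2};
#' \eqn{H_t = 1 - \sum_i \bar p_i^2} with \eqn{\bar p} the unweighted mean
#' of the two pools' frequencies; \eqn{F_{ST} = (H_t - H_s)/H_t}, defined
#' as 0 when \eqn{H_t = 0}, clamped to [0, 1]. No pool-size correction is
#' applied: in this pipeline FST is a ranking diagnostic, not a
#' demographic estimate.
#'
#' @param p1,p2 numeric matrices of allele frequencies (columns A,T,C,G).
#' @return numeric vector of FST values in [0, 1].
#' @export
fst_nei <- function(p1, p2) {
  hs <- ((1 - rowSums(p1^2)) + (1 - rowSums(p2^2))) / 2
  pbar <- (p1 + p2) / 2
  ht <- 1 - rowSums(pbar^2)
  fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
  pmin(pmax(fst, 0), 1)
}

#' Per-site FST for one pair of count vectors
#'
#' @inheritParams classify_site
#' @param params a [classifier_params()]; below \code{min_depth} the value
#'   is undefined (NA).
#' @return scalar FST or NA.
#' @export
fst_site <- function(male, female, params = classifier_params()) {
  classify_site(male, female, params)$fst
}

#' Window configuration
#'
#' @param window_size window width in bp (50000 for the genome-wide
#'   sex-specific SNP scan, 2500 for fine delimitation, 1000 for coverage).
#' @param step distance between window starts; defaults to
#'   \code{window_size} (non-overlapping tiling). Must divide
#'   \code{window_size} when smaller.
#' @return list of class \code{window_config}.
#' @export
window_config <- function(window_size = 50000, step = window_size) {
  stopifnot(window_size > 0, step > 0, step <= window_size)
  if (window_size %% step != 0)
    stop("step must divide window_size")
  structure(list(window_size = as.integer(window_size), step = as.integer(step)),
            class = "window_config")
}

#' Aggregate site calls over genomic windows
#'
#' Windows tile each contig from position 1. Per window the number of
#' male- and female-specific SNPs is counted, per-base FST values are
#' averaged over sites where FST is defined, and mean absolute coverage
#' per sex is computed over the positions present in the input. Relative
#' coverage divides by the genome-wide mean depth of that pool over all
#' sites passing the depth filter (precomputed or supplied).
#'
#' @param calls output of [classify_sites()], sorted by (contig, pos).
#' @param cfg a [window_config()].
#' @param contig_lengths optional named vector; when given, windows cover
#'   each contig's full declared length (else up to the last observed
#'   position).
#' @param genome_mean_depth optional list(male=, female=) overriding the
#'   genome-wide mean depths used for relative coverage.
#' @return \code{data.table}: contig, start, end (1-based inclusive),
#'   width, n_mss, n_fss, n_sites, mean_fst, male_abs_cov, female_abs_cov,
#'   male_rel_cov, female_rel_cov.
#' @export
window_scan <- function(calls, cfg = window_config(), contig_lengths = NULL,
                        genome_mean_depth = NULL) {
  o <- order(calls$contig, calls$pos)
  if (!identical(o, seq_len(nrow(calls)))) stop("calls must be sorted by (contig, pos)")
  if (is.null(genome_mean_depth)) {
    ok <- calls$call != "low_depth"
    genome_mean_depth <- list(male = mean(calls$male_depth[ok]),
                              female = mean(calls$female_depth[ok]))
  }
  w <- cfg$window_size; stp <- cfg$step; nb <- w %/% stp
  contigs <- if (is.null(contig_lengths)) unique(calls$contig) else names(contig_lengths)
  out <- vector("list", length(contigs))
  dt <- data.table::as.data.table(calls)
  for (ci in seq_along(contigs)) {
    ctg <- contigs[ci]
    sub <- dt[dt$contig == ctg]
    L <- if (is.null(contig_lengths)) {
      if (nrow(sub)) max(sub$pos) else 0L
    } else as.integer(contig_lengths[[ctg]])
    if (L == 0L) next
    nbin <- as.integer((L - 1L) %/% stp) + 1L
    bin <- (sub$pos - 1L) %/% stp + 1L
    agg <- function(x) {
      v <- numeric(nbin)
      if (length(x)) {
        s <- tapply(x, factor(bin, levels = seq_len(nbin)), sum, default = 0)
        v <- as.numeric(s)
      }
      v
    }
    b_mss <- agg(sub$call == "male_specific")
    b_fss <- agg(sub$call == "female_specific")
    b_n   <- agg(rep(1, nrow(sub)))
    b_fstS <- agg(ifelse(is.na(sub$fst), 0, sub$fst))
    b_fstN <- agg(!is.na(sub$fst))
    b_md  <- agg(sub$male_depth)
    b_fd  <- agg(sub$female_depth)
    roll <- function(v) {
      if (nb == 1L) return(v)
      cs <- c(0, cumsum(v))
      i <- seq_len(nbin)
      cs[pmin(i + nb, nbin + 1L)] - cs[i]
    }
    starts <- (seq_len(nbin) - 1L) * stp + 1L
    ends <- pmin(starts + w - 1L, L)
    n_sites <- roll(b_n)
    fst_n <- roll(b_fstN)
    res <- data.table::data.table(
      contig = ctg, start = starts, end = ends, width = ends - starts + 1L,
      n_mss = as.integer(roll(b_mss)), n_fss = as.integer(roll(b_fss)),
      n_sites = as.integer(n_sites),
      mean_fst = ifelse(fst_n > 0, roll(b_fstS) / fst_n, NA_real_),
      male_abs_cov = ifelse(n_sites > 0, roll(b_md) / n_sites, 0),
      female_abs_cov = ifelse(n_sites > 0, roll(b_fd) / n_sites, 0))
    out[[ci]] <- res
  }
  res <- data.table::rbindlist(out)
  res$male_rel_cov <- res$male_abs_cov / genome_mean_depth$male
  res$female_rel_cov <- res$female_abs_cov / genome_mean_depth$female
  res[]
}

#' Delimit regions enriched in sex-specific SNPs
#'
#' Merges runs of windows whose chosen metric reaches \code{threshold},
#' tolerating up to \code{max_gap} consecutive sub-threshold windows
#' inside a run. Region bounds span from the first to the last
#' above-threshold window of the run; the metric is summed over the whole
#' span.
#'
#' @param windows output of [window_scan()].
#' @param metric \code{"n_mss"} or \code{"n_fss"}.
#' @param threshold minimum per-window metric to seed/extend a region.
#' @param max_gap number of consecutive sub-threshold windows allowed
#'   inside a region.
#' @return \code{data.table}: contig, start, end, n_windows, total.
#' @export
delimit_enriched_region <- function(windows, metric = c("n_mss", "n_fss"),
                                    threshold, max_gap = 0L) {
  metric <- match.arg(metric)
  if (threshold < 1) stop("threshold must be >= 1")
  vals <- windows[[metric]]
  res <- list()
  for (ctg in unique(windows$contig)) {
    idx <- which(windows$contig == ctg)
    above <- which(vals[idx] >= threshold)
    if (!length(above)) next
    # split above-threshold windows into runs separated by > max_gap gaps
    grp <- cumsum(c(1L, diff(above) > max_gap + 1L))
    for (g in unique(grp)) {
      ii <- above[grp == g]
      lo <- idx[min(ii)]; hi <- idx[max(ii)]
      res[[length(res) + 1L]] <- data.table::data.table(
        contig = ctg,
        start = windows$start[lo], end = windows$end[hi],
        n_windows = max(ii) - min(ii) + 1L,
        total = sum(vals[idx[min(ii):max(ii)]]))
    }
  }
  if (!length(res))
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), n_windows = integer(),
                                  total = numeric()))
  data.table::rbindlist(res)
}
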