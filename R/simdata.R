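#' Simulation configuration for a synthetic XY population
#'
#' The generator emulates the data structures consumed by the detection
#' modules: pooled nucleotide counts from an XY male pool and an XX
#' female pool over a multi-contig reference, with a planted
#' X/Y-differentiated region (elevated density of sites heterozygous only
#' in males, the Y-divergent allele at expected frequency 0.5 in the male
#' pool), a planted Y-specific insertion (male coverage about half the
#' genome mean, female coverage zero), and a RAD family panel (XY sire,
#' XX dam, sexed offspring) in which Y-linked markers leak into the
#' opposite sex by recombination.
#'
#' Defaults mirror the study conditions this package targets: a 10-Mb
#' genome with a 300-kb differentiated region (per-bp divergent-site
#' probability 0.005) on the sex contig, pools of 30 males and 30 females
#' at 50x depth each, a 180-kb Y insertion for the coverage scan at 40x,
#' and a family panel of 37 male and 41 female offspring (78 total).
#'
#' @param genome named integer vector of contig lengths.
#' @param sex_contig name of the contig carrying the sex locus.
#' @param locus differentiated interval c(start, end), 1-based inclusive.
#' @param divergence per-bp probability of an X/Y-divergent site inside
#'   the locus.
#' @param y_insertion optional c(start, end) on \code{y_contig}: interval
#'   present only on the Y haplotype.
#' @param y_contig contig carrying the insertion.
#' @param snp_density per-bp probability of an ordinary shared SNP.
#' @param depth_mean mean per-pool sequencing depth (reads are Poisson).
#' @param error_rate per-read-base sequencing error probability.
#' @param pool_n c(male, female) pool sizes.
#' @param finite_pool if TRUE, pool allele frequencies are binomially
#'   resampled from 2n chromosomes instead of being exact.
#' @param family list: n_male, n_female (offspring), distances
#'   (recombination fractions of Y-linked paternal markers from the sex
#'   locus), n_paternal_per_distance, n_maternal, n_nonspecific,
#'   marker_depth_mean, read_length.
#' @param map list: n_offspring, n_per_class (loci per segregation class).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(genome = c(LG01 = 4e6, LG02 = 4e6, LG24 = 2e6),
                       sex_contig = "LG24",
                       locus = c(720001, 1020000),
                       divergence = 0.005,
                       y_insertion = NULL,
                       y_contig = sex_contig,
                       snp_density = 0.002,
                       depth_mean = 50,
                       error_rate = 0.002,
                       pool_n = c(male = 30, female = 30),
                       finite_pool = FALSE,
                       family = list(),
                       map = list()) {
  genome <- setNames(as.integer(genome), names(genome))
  stopifnot(length(names(genome)) == length(genome),
            sex_contig %in% names(genome),
            locus[1] >= 1, locus[2] <= genome[[sex_contig]],
            divergence >= 0, divergence <= 1,
            snp_density >= 0, snp_density <= 1,
            error_rate >= 0, error_rate <= 1,
            depth_mean > 0)
  if (!is.null(y_insertion)) {
    stopifnot(y_contig %in% names(genome),
              y_insertion[1] >= 1, y_insertion[2] <= genome[[y_contig]])
    if (y_contig == sex_contig &&
        y_insertion[1] <= locus[2] && locus[1] <= y_insertion[2])
      stop("y_insertion must not overlap the differentiated locus")
  }
  fam_defaults <- list(n_male = 37, n_female = 41,
                       distances = c(0, 0.05, 0.1, 0.2, 0.3, 0.5),
                       n_paternal_per_distance = 200,
                       n_maternal = 300, n_nonspecific = 200,
                       marker_depth_mean = 10, read_length = 80)
  map_defaults <- list(n_offspring = 78, n_per_class = 40)
  structure(list(genome = genome, sex_contig = sex_contig, locus = locus,
                 divergence = divergence, y_insertion = y_insertion,
                 y_contig = y_contig, snp_density = snp_density,
                 depth_mean = depth_mean, error_rate = error_rate,
                 pool_n = pool_n, finite_pool = finite_pool,
                 family = utils::modifyList(fam_defaults, family),
                 map = utils::modifyList(map_defaults, map)),
            class = "sim_config")
}

# Derived per-stream seeds so each generator can be re-run independently
# from one root seed. Offsets are fixed and documented: pools 0, family 1,
# map loci 2.
stream_seed <- function(seed, stream) {
  offset <- c(pools = 0L, family = 1L, maploci = 2L)[[stream]]
  (as.integer(seed) * 7L + offset) %% 2147483629L
}

# Distribute per-row error counts uniformly over the three bases other
# than `from_idx`, accumulating into the n x 4 count matrix `cnt`.
spread_errors <- function(cnt, n_err, from_idx) {
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  has <- which(n_err > 0L)
  if (!length(has)) return(cnt)
  e <- n_err[has]
  x1 <- rbinom(length(e), e, 1 / 3)
  x2 <- rbinom(length(e), e - x1, 1 / 2)
  x3 <- e - x1 - x2
  o <- others[from_idx[has], , drop = FALSE]
  cnt[cbind(has, o[, 1])] <- cnt[cbind(has, o[, 1])] + x1
  cnt[cbind(has, o[, 2])] <- cnt[cbind(has, o[, 2])] + x2
  cnt[cbind(has, o[, 3])] <- cnt[cbind(has, o[, 3])] + x3
  cnt
}

# Observed A/T/C/G counts for one pool at n positions given total depth,
# ref/alt allele indices and the true alt-allele count per position.
pool_counts <- function(depth, ref_idx, alt_idx, alt_true, error_rate) {
  n <- length(depth)
  ref_true <- depth - alt_true
  err_ref <- rbinom(n, ref_true, error_rate)
  err_alt <- rbinom(n, alt_true, error_rate)
  cnt <- matrix(0L, n, 4L)
  cnt[cbind(seq_len(n), ref_idx)] <- ref_true - err_ref
  ha <- alt_true > 0L
  if (any(ha))
    cnt[cbind(which(ha), alt_idx[ha])] <-
      cnt[cbind(which(ha), alt_idx[ha])] + (alt_true - err_alt)[ha]
  cnt <- spread_errors(cnt, err_ref, ref_idx)
  safe_alt <- ifelse(is.na(alt_idx), ref_idx, alt_idx)
  cnt <- spread_errors(cnt, err_alt, safe_alt)
  storage.mode(cnt) <- "integer"
  cnt
}

#' Simulate pooled sequencing of an XY population
#'
#' Every position of every contig receives Poisson read depth per pool.
#' The female (XX) pool draws from the XX allele frequencies; the male
#' (XY) pool draws from an X+Y mixture, so at planted divergent sites
#' inside the locus the Y allele has expected frequency 0.5 in the male
#' pool while the female pool stays fixed for the reference. Inside the
#' Y insertion female depth is 0 and male depth is Poisson at half the
#' configured mean. Shared SNPs occur genome-wide at
#' \code{snp_density} with a uniform population frequency. Sequencing
#' errors hit each read base independently at \code{error_rate} and land
#' uniformly on the other three nucleotides. Identical seeds give
#' identical output.
#'
#' @param cfg a [sim_config()].
#' @param seed integer root seed.
#' @param out_dir optional directory; when given, writes
#'   \code{pools.sync}, \code{contigs.fai} and \code{truth_sites.tsv}.
#' @return list: \code{sites} (a \code{pool_sites} table),
#'   \code{contig_lengths}, \code{truth} (list with locus, divergent_pos,
#'   y_insertion, insertion_length, snp_pos).
#' @export
simulate_pools <- function(cfg, seed = 1L, out_dir = NULL) {
  set.seed(stream_seed(seed, "pools"))
  nucs <- DEPTH_NUCS
  per_contig <- vector("list", length(cfg$genome))
  truth <- list(locus = cfg$locus, sex_contig = cfg$sex_contig,
                y_contig = if (is.null(cfg$y_insertion)) NA_character_ else cfg$y_contig,
                y_insertion = cfg$y_insertion,
                insertion_length = if (is.null(cfg$y_insertion)) 0L
                                   else cfg$y_insertion[2] - cfg$y_insertion[1] + 1L,
                divergent_pos = integer(), snp = list())
  for (ci in seq_along(cfg$genome)) {
    ctg <- names(cfg$genome)[ci]
    L <- cfg$genome[[ci]]
    pos <- seq_len(L)
    in_locus <- ctg == cfg$sex_contig & pos >= cfg$locus[1] & pos <= cfg$locus[2]
    in_ins <- if (!is.null(cfg$y_insertion) && ctg == cfg$y_contig)
      pos >= cfg$y_insertion[1] & pos <= cfg$y_insertion[2] else rep(FALSE, L)
    ref_idx <- sample.int(4L, L, replace = TRUE)
    divergent <- in_locus & runif(L) < cfg$divergence
    snp <- !divergent & runif(L) < cfg$snp_density
    alt_idx <- rep(NA_integer_, L)
    k <- divergent | snp
    # alt is a uniformly drawn base different from ref
    alt_idx[k] <- ((ref_idx[k] - 1L + sample.int(3L, sum(k), replace = TRUE)) %% 4L) + 1L
    md <- rpois(L, ifelse(in_ins, cfg$depth_mean / 2, cfg$depth_mean))
    fd <- ifelse(in_ins, 0L, rpois(L, cfg$depth_mean))
    # population alt frequency: shared SNPs uniform in (0.05, 0.95);
    # divergent sites: 0 in XX females, 0.5 in the XY male pool
    q <- numeric(L)
    q[snp] <- runif(sum(snp), 0.05, 0.95)
    qm <- q; qf <- q
    qm[divergent] <- 0.5
    if (cfg$finite_pool) {
      nm <- 2L * cfg$pool_n[["male"]]; nf <- 2L * cfg$pool_n[["female"]]
      qm[k] <- rbinom(sum(k), nm, qm[k]) / nm
      qf[k] <- rbinom(sum(k), nf, qf[k]) / nf
    }
    alt_m <- integer(L); alt_f <- integer(L)
    alt_m[k] <- rbinom(sum(k), md[k], qm[k])
    alt_f[k] <- rbinom(sum(k), fd[k], qf[k])
    mc <- pool_counts(md, ref_idx, alt_idx, alt_m, cfg$error_rate)
    fc <- pool_counts(fd, ref_idx, alt_idx, alt_f, cfg$error_rate)
    keep <- md + fd > 0L
    dt <- data.table::data.table(contig = ctg, pos = pos[keep],
                                 ref = nucs[ref_idx[keep]])
    for (j in 1:4) dt[[male_cols()[j]]] <- mc[keep, match(SYNC_NUCS[j], nucs)]
    dt[["m_N"]] <- 0L; dt[["m_del"]] <- 0L
    for (j in 1:4) dt[[female_cols()[j]]] <- fc[keep, match(SYNC_NUCS[j], nucs)]
    dt[["f_N"]] <- 0L; dt[["f_del"]] <- 0L
    per_contig[[ci]] <- dt
    if (any(divergent))
      truth$divergent_pos <- pos[divergent]  # only the sex contig has any
    truth$snp[[ctg]] <- pos[snp]
  }
  sites <- data.table::rbindlist(per_contig)
  data.table::setattr(sites, "class", c("pool_sites", class(sites)))
  out <- list(sites = sites, contig_lengths = cfg$genome, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sync(sites, file.path(out_dir, "pools.sync"))
    writeLines(paste(names(cfg$genome), cfg$genome, sep = "\t"),
               file.path(out_dir, "contigs.fai"))
    tr <- data.table::data.table(contig = cfg$sex_contig,
                                 pos = truth$divergent_pos,
                                 kind = "divergent")
    utils::write.table(tr, file.path(out_dir, "truth_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# Deterministic unique marker sequence: a base-4 encoding of the marker
# index in the first 12 positions, random tail.
marker_sequences <- function(n, read_length) {
  nucs <- DEPTH_NUCS
  idx <- vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(12L)
    for (j in 1:12) { digits[j] <- i %% 4L; i <- i %/% 4L }
    paste(nucs[digits + 1L], collapse = "")
  }, character(1))
  tails <- vapply(seq_len(n), function(i)
    paste(sample(nucs, read_length - 12L, replace = TRUE), collapse = ""),
    character(1))
  paste0(idx, tails)
}

#' Simulate a RAD family panel with Y-linked markers
#'
#' Generates an XY sire, an XX dam and sexed offspring. Paternal markers
#' sit on the sire's Y haplotype at configurable recombination fractions
#' from the sex-determining locus: a male offspring carries such a marker
#' with probability 1 - r, a female with probability r. Maternal markers
#' are heterozygous in the dam (each offspring inherits with probability
#' 1/2, sex-independent); nonspecific markers are heterozygous in both
#' parents (offspring carry with probability 3/4). Carrier read depth is
#' Poisson(\code{marker_depth_mean}); non-carriers have depth 0. Marker
#' sequences are distinct fixed-length reads, so exact-sequence grouping
#' reconstructs the depth matrix.
#'
#' @inheritParams simulate_pools
#' @param out_dir optional; when given, writes one FASTA per individual,
#'   \code{metadata.tsv} and \code{truth_markers.tsv}.
#' @return list: \code{table} (a [marker_table()]), \code{truth}
#'   (data.table marker_id, class, distance, contig, pos),
#'   \code{metadata}; with \code{out_dir}, also \code{files}.
#' @export
simulate_family <- function(cfg, seed = 1L, out_dir = NULL) {
  set.seed(stream_seed(seed, "family"))
  fam <- cfg$family
  n_off <- fam$n_male + fam$n_female
  if (n_off < 2L) stop("family must have at least 2 offspring")
  ids <- c("sire", "dam", sprintf("O%03d", seq_len(n_off)))
  sex <- c("male", "female",
           sample(rep(c("male", "female"), c(fam$n_male, fam$n_female))))
  role <- c("sire", "dam", rep("offspring", n_off))
  has_y <- sex == "male" & role != "dam"; has_y[2] <- FALSE
  n_pat <- length(fam$distances) * fam$n_paternal_per_distance
  n_mark <- n_pat + fam$n_maternal + fam$n_nonspecific
  cls <- c(rep("paternal", n_pat), rep("maternal", fam$n_maternal),
           rep("nonspecific", fam$n_nonspecific))
  dist <- c(rep(fam$distances, each = fam$n_paternal_per_distance),
            rep(NA_real_, fam$n_maternal + fam$n_nonspecific))
  carrier <- matrix(FALSE, n_mark, length(ids), dimnames = list(NULL, ids))
  off <- which(role == "offspring")
  off_male <- sex[off] == "male"
  for (m in seq_len(n_mark)) {
    if (cls[m] == "paternal") {
      carrier[m, "sire"] <- TRUE
      r <- dist[m]
      # recombinant gametes carry the Y-marker without the Y (or vice versa)
      rec <- runif(n_off) < r
      carrier[m, off] <- ifelse(off_male, !rec, rec)
    } else if (cls[m] == "maternal") {
      carrier[m, "dam"] <- TRUE
      carrier[m, off] <- runif(n_off) < 0.5
    } else {
      carrier[m, "sire"] <- TRUE; carrier[m, "dam"] <- TRUE
      carrier[m, off] <- runif(n_off) < 0.75
    }
  }
  depth <- matrix(0L, n_mark, length(ids), dimnames = list(NULL, ids))
  nc <- sum(carrier)
  depth[carrier] <- rpois(nc, fam$marker_depth_mean)
  seqs <- marker_sequences(n_mark, fam$read_length)
  meta <- data.frame(id = ids, file = NA_character_, sex = sex, role = role,
                     stringsAsFactors = FALSE)
  tab <- marker_table(seqs, depth, meta)
  # truth positions: paternal markers along the sex contig, proportional to
  # recombination distance from the locus; others on autosomes
  pos <- integer(n_mark); ctg <- character(n_mark)
  pat <- cls == "paternal"
  ctg[pat] <- cfg$sex_contig
  pos[pat] <- as.integer(cfg$locus[1] + dist[pat] * 2e6)
  auto <- names(cfg$genome)[names(cfg$genome) != cfg$sex_contig]
  if (!length(auto)) auto <- cfg$sex_contig
  ctg[!pat] <- sample(auto, sum(!pat), replace = TRUE)
  pos[!pat] <- sapply(ctg[!pat], function(cc) sample.int(cfg$genome[[cc]], 1L))
  truth <- data.table::data.table(marker_id = tab$markers$marker_id,
                                  class = cls, distance = dist,
                                  contig = ctg, pos = pos)
  out <- list(table = tab, truth = truth, metadata = meta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(length(ids))
    for (i in seq_along(ids)) {
      f <- file.path(out_dir, paste0(ids[i], ".fasta"))
      reads <- rep(seqs, depth[, i])
      if (length(reads)) reads <- sample(reads)
      writeLines(paste0(">", ids[i], "_r", seq_along(reads), "\n", reads), f)
      files[i] <- f
    }
    meta$file <- files
    utils::write.table(meta, file.path(out_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$metadata <- meta
    out$files <- files
  }
  out
}

#' Simulate genotype tables for the map-locus filter
#'
#' Generates loci in tagged segregation classes so that every rule of
#' [filter_map_loci()] fires on a known subset. Genotype class counts are
#' fixed deterministically per tag (only the assignment of genotypes to
#' individuals is randomised), so each locus's fate under the filter is
#' exact, not merely probable:
#' \describe{
#'   \item{pass_1to1}{two genotypes split as evenly as n allows; kept by
#'     rule 4.}
#'   \item{pass_1to2to1}{three genotypes, heterozygosity 1/2, homozygote
#'     ratio 20:19-like; kept by rule 5.}
#'   \item{sparse}{genotyped in fewer than half the offspring; rule 1.}
#'   \item{anomalous}{three triploid calls; rule 2.}
#'   \item{high_het}{heterozygosity above 0.66; rule 3.}
#'   \item{low_het}{heterozygosity below 0.33; rule 3.}
#'   \item{distorted_121}{three genotypes with homozygote ratio far
#'     outside [0.8, 1.2]; dropped after rules 4-5.}
#' }
#'
#' @inheritParams simulate_pools
#' @param out_dir optional; writes \code{genotypes.tsv} and
#'   \code{truth_loci.tsv}.
#' @return list: \code{genotypes} (long table locus_id, individual,
#'   genotype), \code{offspring} (ids), \code{truth} (locus_id, tag,
#'   expected_fate).
#' @export
simulate_map_loci <- function(cfg, seed = 1L, out_dir = NULL) {
  set.seed(stream_seed(seed, "maploci"))
  n <- cfg$map$n_offspring
  npc <- cfg$map$n_per_class
  ids <- sprintf("O%03d", seq_len(n))
  h <- n %/% 2L
  q1 <- n %/% 4L
  classes <- list(
    pass_1to1     = list(g = c("0/1", "0/0"), k = c(h, n - h),
                         fate = "kept_rule4"),
    pass_1to2to1  = list(g = c("0/0", "0/1", "1/1"), k = c(q1 + 1L, h, n - h - q1 - 1L),
                         fate = "kept_rule5"),
    sparse        = list(g = c("0/1", "0/0", NA), k = c(h %/% 2L, h %/% 2L - 1L,
                                                        n - 2L * (h %/% 2L) + 1L),
                         fate = "removed_rule1"),
    anomalous     = list(g = c("0/1", "0/0", "0/0/1"), k = c(h - 1L, n - h - 2L, 3L),
                         fate = "removed_rule2"),
    high_het      = list(g = c("0/1", "0/0"), k = c(ceiling(0.77 * n), n - ceiling(0.77 * n)),
                         fate = "removed_rule3"),
    low_het       = list(g = c("0/1", "0/0"), k = c(floor(0.25 * n), n - floor(0.25 * n)),
                         fate = "removed_rule3"),
    distorted_121 = list(g = c("0/0", "0/1", "1/1"), k = c(n - h - 9L, h, 9L),
                         fate = "removed_rule45"))
  rows <- list(); truth <- list()
  for (cn in names(classes)) {
    cl <- classes[[cn]]
    for (i in seq_len(npc)) {
      loc <- sprintf("%s_%03d", cn, i)
      geno <- sample(rep(cl$g, cl$k))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        locus_id = loc, individual = ids, genotype = geno)
      truth[[length(truth) + 1L]] <- data.table::data.table(
        locus_id = loc, tag = cn, expected_fate = cl$fate)
    }
  }
  genotypes <- data.table::rbindlist(rows)
  truth <- data.table::rbindlist(truth)
  out <- list(genotypes = genotypes, offspring = ids, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(genotypes, file.path(out_dir, "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
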