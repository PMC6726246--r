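#' Build a RAD marker table from per-individual read files
#'
#' Groups reads sharing the exact same sequence into markers (no
#' clustering, no canonicalisation: reverse complements are distinct
#' markers), so markers are non-polymorphic by construction and reads from
#' one polymorphic locus split into several markers. The result is a depth
#' matrix marker x individual.
#'
#' @param metadata data frame with columns \code{id}, \code{file},
#'   \code{sex} ("male"/"female") and \code{role} ("sire"/"dam"/
#'   "offspring"); one row per individual. Files may be FASTA or FASTQ,
#'   optionally gzipped (format detected from the extension).
#' @param trim_to optional length to which all reads are truncated before
#'   grouping; by default reads must already share one length.
#' @return a \code{marker_table}: list with \code{markers} (data.frame
#'   marker_id, sequence), \code{depth} (integer matrix marker x
#'   individual) and \code{individuals} (the metadata).
#' @export
build_marker_table <- function(metadata, trim_to = NULL) {
  metadata <- as.data.frame(metadata)
  stopifnot(all(c("id", "file", "sex", "role") %in% names(metadata)))
  if (anyDuplicated(metadata$id)) stop("individual ids must be unique")
  counts <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", metadata$file[i])) "fastq" else "fasta"
    seqs <- as.character(Biostrings::readDNAStringSet(metadata$file[i], format = fmt))
    if (!is.null(trim_to)) seqs <- substr(seqs, 1L, trim_to)
    if (length(seqs) && length(unique(nchar(seqs))) > 1L)
      stop(sprintf("reads of unequal length in '%s'; use trim_to", metadata$file[i]))
    counts[[i]] <- table(seqs)
  }
  lens <- unlist(lapply(counts, function(tb) nchar(names(tb))))
  if (length(lens) && length(unique(lens)) > 1L)
    stop("read length differs between individuals; use trim_to")
  all_seqs <- sort(unique(unlist(lapply(counts, names))))
  depth <- matrix(0L, nrow = length(all_seqs), ncol = nrow(metadata),
                  dimnames = list(NULL, metadata$id))
  for (i in seq_len(nrow(metadata))) {
    tb <- counts[[i]]
    depth[match(names(tb), all_seqs), i] <- as.integer(tb)
  }
  marker_table(sequences = all_seqs, depth = depth, individuals = metadata)
}

#' Construct a marker table directly
#'
#' @param sequences character vector of marker sequences (same length).
#' @param depth integer matrix, rows = markers, columns = individuals.
#' @param individuals data frame with id, sex, role.
#' @param marker_id optional ids; default M000001...
#' @return object of class \code{marker_table}.
#' @export
marker_table <- function(sequences, depth, individuals, marker_id = NULL) {
  individuals <- as.data.frame(individuals)
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (nrow(depth) != length(sequences))
    stop("depth must have one row per marker")
  if (ncol(depth) != nrow(individuals))
    stop("depth must have one column per individual")
  if (any(depth < 0)) stop("depths must be non-negative")
  if (anyDuplicated(individuals$id)) stop("individual ids must be unique")
  if (is.null(marker_id))
    marker_id <- sprintf("M%06d", seq_along(sequences))
  colnames(depth) <- individuals$id
  structure(list(markers = data.frame(marker_id = marker_id,
                                      sequence = as.character(sequences),
                                      stringsAsFactors = FALSE),
                 depth = depth, individuals = individuals),
            class = "marker_table")
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("marker_table: %d markers x %d individuals (%d male, %d female)\n",
              nrow(x$depth), ncol(x$depth),
              sum(x$individuals$sex == "male"),
              sum(x$individuals$sex == "female")))
  invisible(x)
}

#' Marker presence calls
#'
#' A marker is present in an individual when its depth reaches
#' \code{min_depth} (inclusive threshold, default 5).
#'
#' @param depth integer vector or matrix of read depths.
#' @param min_depth minimum depth to call a marker present.
#' @return logical vector/matrix of the same shape.
#' @export
presence <- function(depth, min_depth = 5) {
  depth >= min_depth
}

#' Sex-bias and per-marker association with sex
#'
#' For every marker, the sex-bias statistic
#' \eqn{S = M/M_{TOTAL} - F/F_{TOTAL}} is the difference between the
#' proportion of males and the proportion of females in which the marker
#' is present (S = 1: present in all males and no females, i.e. fully
#' Y-linked; S = -1 the mirror). When the metadata declares a sire and a
#' dam (family design), M_TOTAL and F_TOTAL count offspring only, so S
#' measures segregation between male and female offspring. A two-sided
#' Fisher's exact test on the 2x2 presence-by-sex table gives p_fisher;
#' a Bonferroni-adjusted column is emitted alongside the raw p.
#'
#' @param table a \code{marker_table}.
#' @param min_depth presence threshold, see [presence()].
#' @return \code{data.table}: marker_id, M, F, M_TOTAL, F_TOTAL, S,
#'   p_fisher, p_bonferroni, origin (see [parental_origin()];
#'   "unassigned" when no parents are declared).
#' @export
sex_bias <- function(table, min_depth = 5) {
  ind <- table$individuals
  family <- any(ind$role %in% c("sire", "dam"))
  use <- if (family) ind$role == "offspring" else rep(TRUE, nrow(ind))
  males <- use & ind$sex == "male"
  females <- use & ind$sex == "female"
  m_total <- sum(males); f_total <- sum(females)
  if (m_total == 0L || f_total == 0L)
    stop("need at least one male and one female (offspring in a family design)")
  pres <- presence(table$depth, min_depth)
  M <- as.integer(rowSums(pres[, males, drop = FALSE]))
  F_ <- as.integer(rowSums(pres[, females, drop = FALSE]))
  S <- M / m_total - F_ / f_total
  p <- fisher_exact(cbind(M, m_total - M, F_, f_total - F_))
  origin <- if (family) parental_origin(table, min_depth = min_depth)$origin
            else rep("unassigned", nrow(pres))
  data.table::data.table(marker_id = table$markers$marker_id,
                         M = M, F = F_,
                         M_TOTAL = m_total, F_TOTAL = f_total, S = S,
                         p_fisher = p,
                         p_bonferroni = pmin(p * nrow(pres), 1),
                         origin = origin)
}

#' Parental origin of markers in a family panel
#'
#' Markers present in the dam but not the sire are maternal; present in
#' the sire but not the dam, paternal; present in both, nonspecific;
#' present in neither parent, unassigned. Markers present (at
#' \code{min_depth}) in fewer than \code{min_individuals} individuals
#' overall are set aside as \code{below_min_individuals} before the rule
#' is applied. The same depth threshold applies to parents and offspring.
#'
#' @param table a \code{marker_table} whose metadata declares exactly one
#'   sire and one dam.
#' @param min_individuals minimum number of individuals (parents
#'   included) in which the marker must be present.
#' @param min_depth presence threshold.
#' @return \code{data.table}: marker_id, origin, n_present.
#' @export
parental_origin <- function(table, min_individuals = 10, min_depth = 5) {
  ind <- table$individuals
  sire <- which(ind$role == "sire"); dam <- which(ind$role == "dam")
  if (length(sire) != 1L || length(dam) != 1L)
    stop("metadata must declare exactly one sire and one dam")
  pres <- presence(table$depth, min_depth)
  n_present <- as.integer(rowSums(pres))
  in_sire <- pres[, sire]; in_dam <- pres[, dam]
  origin <- ifelse(n_present < min_individuals, "below_min_individuals",
            ifelse(in_sire & in_dam, "nonspecific",
            ifelse(in_sire, "paternal",
            ifelse(in_dam, "maternal", "unassigned"))))
  data.table::data.table(marker_id = table$markers$marker_id,
                         origin = origin, n_present = n_present)
}

#' Sex-bias segregation profile along the genome
#'
#' Joins sex-bias results to externally supplied marker positions
#' (alignment itself is upstream of this package; a simulator supplies
#' truth positions) and returns rows ready to plot S against position by
#' origin class. Markers without a position are dropped, with a message
#' stating how many.
#'
#' @param results output of [sex_bias()].
#' @param positions data frame marker_id, contig, pos.
#' @return \code{data.table}: contig, pos, marker_id, origin, S,
#'   p_fisher, sorted by (contig, pos).
#' @export
segregation_profile <- function(results, positions) {
  positions <- data.table::as.data.table(positions)
  m <- merge(data.table::as.data.table(results), positions,
             by = "marker_id")
  dropped <- nrow(results) - nrow(m)
  if (dropped > 0)
    message(sprintf("segregation_profile: dropped %d marker(s) without a position", dropped))
  out <- m[, c("contig", "pos", "marker_id", "origin", "S", "p_fisher"), with = FALSE]
  data.table::setorder(out, contig, pos)
  out[]
}
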