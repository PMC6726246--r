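# Parse "a/b"-style genotype strings. Missing: NA, "", "-", "./.".
# Three or more allele fields mark a higher-ploidy anomaly.
parse_genotypes <- function(g) {
  g <- as.character(g)
  miss <- is.na(g) | g %in% c("", "-", "./.", "NA")
  parts <- strsplit(g, "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  anom <- !miss & n_alleles >= 3L
  a1 <- rep(NA_integer_, length(g)); a2 <- a1
  norm <- !miss & !anom
  if (any(norm)) {
    p2 <- parts[norm]
    one <- lengths(p2) == 1L  # haploid-coded call treated as homozygote
    a <- suppressWarnings(vapply(p2, function(x) as.integer(x[1L]), integer(1)))
    b <- suppressWarnings(vapply(p2, function(x) as.integer(x[min(2L, length(x))]), integer(1)))
    if (anyNA(a) || anyNA(b)) stop("genotype allele indices must be integers")
    a1[norm] <- pmin(a, b); a2[norm] <- pmax(a, b)
  }
  data.frame(missing = miss, anomalous = anom, a1 = a1, a2 = a2)
}

#' Filter polymorphic RAD loci for linkage-map construction
#'
#' Applies, in order, the six-rule marker filter used ahead of map
#' building:
#' \enumerate{
#'   \item drop loci genotyped in fewer than half of the declared
#'     offspring (strict inequality);
#'   \item drop loci with more than two triploid-or-higher genotypes;
#'     at surviving loci such anomalous calls become missing;
#'   \item drop loci with offspring heterozygosity above 0.66 or below
#'     0.33 (boundary values kept), heterozygosity being the fraction of
#'     non-missing offspring calls that are heterozygous;
#'   \item keep loci with two alleles and two genotype classes;
#'   \item keep loci with two alleles and three genotype classes whose
#'     heterozygosity lies in [0.47, 0.53] and whose homozygote-class
#'     ratio hom1/hom2 (allele order as defined at the locus) lies in
#'     [0.8, 1.2];
#'   \item export survivors in a mapping-software-ready layout (see
#'     [export_mapping_table()]).
#' }
#' Loci passing neither rule 4 nor rule 5 are dropped. Heterozygosity and
#' class counts use offspring only; parents never enter the filter.
#'
#' @param genotypes long data frame: locus_id, individual, genotype.
#'   Genotypes are unordered allele-index pairs "a/b"; three or more
#'   indices flag a higher-ploidy anomaly; NA, "", "-" and "./." are
#'   missing.
#' @param offspring character vector of offspring ids; its length is the
#'   declared offspring count against which rule 1 is assessed.
#' @return list with \code{kept} (long table of surviving loci with
#'   anomalies blanked and a \code{rule} column saying which rule kept
#'   each locus), \code{report} (per-rule removal counts) and
#'   \code{fate} (per-locus outcome).
#' @export
filter_map_loci <- function(genotypes, offspring) {
  if (length(offspring) == 0L) stop("offspring set must be declared")
  g <- data.table::as.data.table(genotypes)[individual %in% offspring]
  loci <- unique(data.table::as.data.table(genotypes)$locus_id)
  pg <- parse_genotypes(g$genotype)
  g <- cbind(g, pg)
  half <- length(offspring) / 2
  fate <- character(length(loci)); names(fate) <- loci
  kept_rows <- list()
  for (loc in loci) {
    sub <- g[g$locus_id == loc]
    n_typed <- sum(!sub$missing)
    if (n_typed < half) { fate[loc] <- "removed_rule1"; next }
    if (sum(sub$anomalous) > 2L) { fate[loc] <- "removed_rule2"; next }
    sub$missing[sub$anomalous] <- TRUE
    sub$a1[sub$anomalous] <- NA_integer_; sub$a2[sub$anomalous] <- NA_integer_
    sub$anomalous <- FALSE
    ok <- !sub$missing
    if (!any(ok)) { fate[loc] <- "removed_rule1"; next }
    het <- mean(sub$a1[ok] != sub$a2[ok])
    if (het > 0.66 || het < 0.33) { fate[loc] <- "removed_rule3"; next }
    alleles <- sort(unique(c(sub$a1[ok], sub$a2[ok])))
    geno_class <- paste(sub$a1[ok], sub$a2[ok], sep = "/")
    n_geno <- length(unique(geno_class))
    if (length(alleles) == 2L && n_geno == 2L) {
      fate[loc] <- "kept_rule4"
    } else if (length(alleles) == 2L && n_geno == 3L) {
      hom1 <- sum(geno_class == paste(alleles[1L], alleles[1L], sep = "/"))
      hom2 <- sum(geno_class == paste(alleles[2L], alleles[2L], sep = "/"))
      ratio <- if (hom2 > 0) hom1 / hom2 else Inf
      if (het >= 0.47 && het <= 0.53 && hom1 > 0 && ratio >= 0.8 && ratio <= 1.2)
        fate[loc] <- "kept_rule5"
      else { fate[loc] <- "removed_rule45"; next }
    } else { fate[loc] <- "removed_rule45"; next }
    out <- sub[, c("locus_id", "individual"), with = FALSE]
    out$genotype <- ifelse(sub$missing, NA_character_,
                           paste(sub$a1, sub$a2, sep = "/"))
    out$rule <- fate[loc]
    kept_rows[[length(kept_rows) + 1L]] <- out
  }
  report <- data.table::data.table(
    rule = c("input", "removed_rule1", "removed_rule2", "removed_rule3",
             "removed_rule45", "kept_rule4", "kept_rule5"),
    n = c(length(loci),
          sum(fate == "removed_rule1"), sum(fate == "removed_rule2"),
          sum(fate == "removed_rule3"), sum(fate == "removed_rule45"),
          sum(fate == "kept_rule4"), sum(fate == "kept_rule5")))
  list(kept = if (length(kept_rows)) data.table::rbindlist(kept_rows)
       else data.table::data.table(locus_id = character(),
                                   individual = character(),
                                   genotype = character(), rule = character()),
       report = report,
       fate = data.table::data.table(locus_id = names(fate), fate = unname(fate)))
}

#' Export filtered loci as a wide genotype table
#'
#' One row per locus, one column per individual (sorted by id for a
#' deterministic layout), missing calls coded by a single configurable
#' token, no timestamps — the export is byte-identical across runs on
#' identical input. This wide TSV is the hand-off point to map-ordering
#' software; linkage-group clustering and marker ordering are outside
#' this package.
#'
#' @param kept long table from [filter_map_loci()]\code{$kept}.
#' @param file output path.
#' @param missing token for missing genotypes.
#' @param header optional '#'-prefixed header lines.
#' @export
export_mapping_table <- function(kept, file, missing = "-", header = NULL) {
  if (nrow(kept) == 0L)
    stop("no loci passed the filter; review the thresholds before exporting")
  ids <- sort(unique(kept$individual))
  loci <- unique(kept$locus_id)
  wide <- matrix(missing, nrow = length(loci), ncol = length(ids),
                 dimnames = list(loci, ids))
  idx <- cbind(match(kept$locus_id, loci), match(kept$individual, ids))
  val <- ifelse(is.na(kept$genotype), missing, kept$genotype)
  wide[idx] <- val
  lines <- c(header,
             paste(c("locus_id", ids), collapse = "\t"),
             vapply(seq_along(loci), function(i)
               paste(c(loci[i], wide[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' Read back a wide mapping-table export
#'
#' @param file path written by [export_mapping_table()].
#' @param missing token used for missing genotypes.
#' @return long \code{data.table}: locus_id, individual, genotype.
#' @export
read_mapping_table <- function(file, missing = "-") {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ids <- hdr[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  long <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(locus_id = r[1L], individual = ids,
                           genotype = r[-1L])))
  long$genotype[long$genotype == missing] <- NA_character_
  long[]
}
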