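# Column layout shared by all modules working on pooled count tables.
# Nucleotide order follows the sync dialect: A:T:C:G:N:del.
SYNC_NUCS <- c("A", "T", "C", "G", "N", "del")
DEPTH_NUCS <- c("A", "T", "C", "G")

male_cols <- function(nucs = SYNC_NUCS) paste0("m_", nucs)
female_cols <- function(nucs = SYNC_NUCS) paste0("f_", nucs)

#' Construct a pooled-count site table
#'
#' A pool-site table holds, for every genomic position, the nucleotide
#' read counts of a male pool and a female pool (the record stored per
#' line of a popoolation2 sync file). It is the common currency of the
#' pooled-sequencing modules: one row per position, with columns
#' \code{contig}, \code{pos} (1-based), \code{ref} and twelve count
#' columns \code{m_A, m_T, m_C, m_G, m_N, m_del, f_A, ..., f_del}.
#'
#' @param contig character vector of sequence identifiers.
#' @param pos integer vector of 1-based positions.
#' @param ref reference nucleotide per position (A/C/G/T/N).
#' @param male,female numeric matrices (or data frames) with one row per
#'   position and columns A, T, C, G and optionally N, del.
#' @return a \code{data.table} with class \code{pool_sites}.
#' @export
pool_sites <- function(contig, pos, ref, male, female) {
  n <- length(pos)
  fill6 <- function(m) {
    m <- as.data.frame(m)
    out <- matrix(0L, n, 6L, dimnames = list(NULL, SYNC_NUCS))
    for (nm in intersect(colnames(m), SYNC_NUCS))
      out[, nm] <- as.integer(m[[nm]])
    as.data.frame(out)
  }
  male <- fill6(male); female <- fill6(female)
  dt <- data.table::data.table(contig = as.character(contig),
                               pos = as.integer(pos),
                               ref = toupper(as.character(ref)))
  for (i in seq_along(SYNC_NUCS)) dt[[male_cols()[i]]] <- as.integer(male[[i]])
  for (i in seq_along(SYNC_NUCS)) dt[[female_cols()[i]]] <- as.integer(female[[i]])
  validate_pool_sites(dt)
  data.table::setattr(dt, "class", c("pool_sites", class(dt)))
  dt[]
}

validate_pool_sites <- function(dt) {
  cnt <- as.matrix(dt[, c(male_cols(), female_cols()), with = FALSE])
  if (anyNA(cnt) || any(cnt < 0)) stop("pool counts must be non-negative integers")
  if (any(dt$pos < 1L)) stop("positions are 1-based: pos >= 1 required")
  invisible(dt)
}

#' Read a popoolation2 sync file
#'
#' Parses the tab-separated sync dialect: \code{contig  pos  ref} followed
#' by one colon-separated count field \code{A:T:C:G:N:del} per pool.
#' Exactly two pools are expected. Reading is gzip-transparent.
#'
#' @param file path to a sync file (optionally gzip-compressed) or a
#'   connection.
#' @param pool_order which pool comes first in the file; the default
#'   \code{c("male", "female")} matches the convention used throughout
#'   this package.
#' @return a \code{pool_sites} table in input row order.
#' @export
read_sync <- function(file, pool_order = c("male", "female")) {
  pool_order <- match.arg(pool_order, several.ok = TRUE)
  if (!setequal(pool_order, c("male", "female")) || length(pool_order) != 2L)
    stop("pool_order must be a permutation of c('male', 'female')")
  con <- if (inherits(file, "connection")) file else gzfile(file, "rt")
  if (!inherits(file, "connection")) on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(pool_sites(character(), integer(), character(),
                      matrix(0L, 0, 6, dimnames = list(NULL, SYNC_NUCS)),
                      matrix(0L, 0, 6, dimnames = list(NULL, SYNC_NUCS))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    bad <- which(nf < 5L)[1L]
    stop(sprintf("sync line %d: expected >= 5 tab-separated fields (contig, pos, ref, 2 pools), got %d",
                 bad, nf[bad]))
  }
  parse_counts <- function(idx) {
    raw <- vapply(fields, `[[`, character(1), idx)
    parts <- strsplit(raw, ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      bad <- which(lengths(parts) != 6L)[1L]
      stop(sprintf("sync line %d: count field '%s' is not 6 colon-separated integers",
                   bad, raw[bad]))
    }
    m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 6L, byrow = TRUE)
    if (anyNA(m)) {
      bad <- which(apply(is.na(m), 1, any))[1L]
      stop(sprintf("sync line %d: count field '%s' contains a non-integer",
                   bad, raw[bad]))
    }
    colnames(m) <- SYNC_NUCS
    m
  }
  p1 <- parse_counts(4L)
  p2 <- parse_counts(5L)
  pools <- list(p1, p2)
  names(pools) <- pool_order
  pool_sites(contig = vapply(fields, `[[`, character(1), 1L),
             pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
             ref = vapply(fields, `[[`, character(1), 3L),
             male = pools$male, female = pools$female)
}

#' Write a pooled-count table as a sync file
#'
#' Emits exactly the dialect accepted by [read_sync()]: tab-separated
#' contig, 1-based position, upper-case reference base, then one
#' 6-part colon-separated count field per pool (male pool first unless
#' \code{pool_order} says otherwise).
#'
#' @param sites a \code{pool_sites} table sorted by (contig, pos).
#' @param file output path ('.gz' suffix compresses) or connection.
#' @inheritParams read_sync
#' @param header optional character vector of '#'-prefixed header lines.
#' @export
write_sync <- function(sites, file, pool_order = c("male", "female"), header = NULL) {
  stopifnot(inherits(sites, "pool_sites") || is.data.frame(sites))
  o <- order(sites$contig, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) stop("sites must be sorted by (contig, pos) before writing")
  glue6 <- function(cols) {
    do.call(paste, c(unname(as.list(sites[, cols, with = FALSE])), sep = ":"))
  }
  m <- glue6(male_cols()); f <- glue6(female_cols())
  pools <- if (identical(pool_order, c("male", "female"))) list(m, f) else list(f, m)
  lines <- paste(sites$contig, sites$pos, toupper(sites$ref),
                 pools[[1L]], pools[[2L]], sep = "\t")
  if (!is.null(header)) lines <- c(header, lines)
  con <- if (inherits(file, "connection")) file else {
    if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  }
  if (!inherits(file, "connection")) on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' Per-pool sequencing depth
#'
#' Depth is the sum of the A, T, C and G counts; N and deletion counts are
#' carried through the table but never enter depth or allele-frequency
#' arithmetic.
#'
#' @param sites a \code{pool_sites} table.
#' @param sex \code{"male"} or \code{"female"}.
#' @return integer vector of depths, one per row of \code{sites}.
#' @export
pool_depth <- function(sites, sex = c("male", "female")) {
  sex <- match.arg(sex)
  cols <- if (sex == "male") male_cols(DEPTH_NUCS) else female_cols(DEPTH_NUCS)
  as.integer(rowSums(sites[, cols, with = FALSE]))
}

#' Read a contig-length index
#'
#' Accepts a two-column TSV (contig, length) or a samtools '.fai' index,
#' of which only the first two columns are used.
#'
#' @param file path to the index file.
#' @return named integer vector of contig lengths.
#' @export
read_contig_index <- function(file) {
  dt <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(as.integer(dt[[2L]]), as.character(dt[[1L]]))
}
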