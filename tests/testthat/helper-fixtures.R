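# Small builders used across test files; all fixtures are constructed in
# code, nothing is read from disk unless the test itself writes it first.

# Uniform-coverage pooled sites: every position of a contig covered at the
# given per-pool depth, all reads matching the reference base.
sites_uniform <- function(contig, len, male_depth, female_depth, ref = "A") {
  pool_sites(rep(contig, len), seq_len(len), rep(ref, len),
             data.frame(A = rep(male_depth, len)),
             data.frame(A = rep(female_depth, len)))
}

# One-row site table from named count vectors.
site1 <- function(male, female, contig = "c1", pos = 1L, ref = "A") {
  pool_sites(contig, pos, ref,
             as.data.frame(as.list(male)), as.data.frame(as.list(female)))
}

# Write reads (character vector) as a FASTA file, one record per read.
write_reads_fasta <- function(reads, file) {
  if (length(reads))
    writeLines(paste0(">r", seq_along(reads), "\n", reads), file)
  else
    writeLines(character(), file)
  file
}

# Independent two-sided Fisher oracle: exhaustive enumeration of the
# hypergeometric support using dhyper (a different code path from the
# package's lchoose-based log-space sum).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(k, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Small family marker table built directly (no files): presence patterns
# given as a logical matrix markers x individuals.
family_table <- function(pattern, sexes, roles, depth_present = 10L) {
  n <- nrow(pattern)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  depth <- matrix(0L, n, ncol(pattern))
  depth[pattern] <- depth_present
  marker_table(seqs, depth,
               data.frame(id = colnames(pattern), sex = sexes, role = roles,
                          stringsAsFactors = FALSE))
}
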