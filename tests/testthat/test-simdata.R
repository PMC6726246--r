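# Small genomes keep the unit tests fast; the full study-scale conditions
# are exercised in test-acceptance.R.
small_cfg <- function(...) {
  sim_config(genome = c(LG01 = 50000, LG24 = 50000), sex_contig = "LG24",
             locus = c(10001, 20000), ...)
}

test_that("identical seeds reproduce every generator byte for byte", {
  cfg <- small_cfg()
  a <- simulate_pools(cfg, seed = 5)
  b <- simulate_pools(cfg, seed = 5)
  expect_identical(as.data.frame(a$sites), as.data.frame(b$sites))
  expect_identical(a$truth$divergent_pos, b$truth$divergent_pos)
  c_ <- simulate_pools(cfg, seed = 6)
  expect_false(identical(as.data.frame(a$sites), as.data.frame(c_$sites)))
  d1 <- tempfile(); d2 <- tempfile()
  fam_cfg <- small_cfg(family = list(n_male = 5, n_female = 5,
                                     distances = 0, n_paternal_per_distance = 4,
                                     n_maternal = 4, n_nonspecific = 2))
  f1 <- simulate_family(fam_cfg, seed = 5, out_dir = d1)
  f2 <- simulate_family(fam_cfg, seed = 5, out_dir = d2)
  for (i in seq_along(f1$files))
    expect_identical(readLines(f1$files[i]), readLines(f2$files[i]))
  m1 <- simulate_map_loci(cfg, seed = 5)
  m2 <- simulate_map_loci(cfg, seed = 5)
  expect_identical(as.data.frame(m1$genotypes), as.data.frame(m2$genotypes))
})

test_that("truth is consistent with the configuration and the data", {
  cfg <- small_cfg(y_insertion = c(30001, 35000), y_contig = "LG01")
  sim <- simulate_pools(cfg, seed = 7)
  tr <- sim$truth
  expect_true(all(tr$divergent_pos >= cfg$locus[1] & tr$divergent_pos <= cfg$locus[2]))
  expect_equal(tr$insertion_length, 5000L)
  # inside the insertion the female pool has no reads at all
  ins <- sim$sites[sim$sites$contig == "LG01" &
                     sim$sites$pos >= 30001 & sim$sites$pos <= 35000]
  expect_equal(sum(pool_depth(ins, "female")), 0L)
  # male depth inside the insertion is about half the configured mean
  expect_equal(mean(pool_depth(ins, "male")), cfg$depth_mean / 2, tolerance = 0.1)
})

test_that("a signal-free simulation yields no downstream findings", {
  cfg <- small_cfg(divergence = 0, snp_density = 0, error_rate = 0)
  sim <- simulate_pools(cfg, seed = 8)
  calls <- classify_sites(sim$sites)
  expect_equal(sum(calls$call %in% c("male_specific", "female_specific")), 0L)
  # no Y insertion: no male-only windows on either contig
  cw <- coverage_windows(sim$sites, sim$contig_lengths, 1000)
  expect_equal(nrow(detect_mr1k(cw)), 0L)
  expect_equal(nrow(detect_half_coverage(cw)), 0L)
})

test_that("detected MSS counts match an exact enumeration of the classifier", {
  # error-free, SNP-free conditions make the detection probability exactly
  # enumerable: male depth ~ Poisson(50), Y allele at frequency 0.5, both
  # pool depths must reach 10 and the alt fraction must fall in [0.35, 0.65]
  cfg <- sim_config(genome = c(LG24 = 500000), sex_contig = "LG24",
                    locus = c(100001, 400000), divergence = 0.005,
                    snp_density = 0, error_rate = 0, depth_mean = 50)
  sim <- simulate_pools(cfg, seed = 10)
  calls <- classify_sites(sim$sites)
  n_mss <- sum(calls$call == "male_specific")
  n_true <- length(sim$truth$divergent_pos)
  dm <- 10:200
  p_het <- sum(vapply(dm, function(dd) {
    lo <- ceiling(0.35 * dd); hi <- floor(0.65 * dd)
    lo <- max(lo, 1); hi <- min(hi, dd - 1)
    if (lo > hi) return(0)
    stats::dpois(dd, 50) * sum(stats::dbinom(lo:hi, dd, 0.5))
  }, numeric(1)))
  p_detect <- p_het * (1 - stats::ppois(9, 50))
  expected <- n_true * p_detect
  sd3 <- 3 * sqrt(n_true * p_detect * (1 - p_detect))
  expect_gt(n_mss, expected - sd3)
  expect_lt(n_mss, expected + sd3)
})

test_that("perfect linkage puts paternal markers in sire and male offspring only", {
  cfg <- small_cfg(family = list(n_male = 10, n_female = 10, distances = 0,
                                 n_paternal_per_distance = 20, n_maternal = 0,
                                 n_nonspecific = 0, marker_depth_mean = 500))
  fam <- simulate_family(cfg, seed = 11)
  pres <- presence(fam$table$depth)
  ind <- fam$table$individuals
  carriers_expected <- ind$role == "sire" |
    (ind$role == "offspring" & ind$sex == "male")
  for (m in seq_len(nrow(pres)))
    expect_equal(unname(pres[m, ]), carriers_expected)
})

test_that("free recombination erases the sex bias of paternal markers", {
  cfg <- small_cfg(family = list(n_male = 30, n_female = 30, distances = 0.5,
                                 n_paternal_per_distance = 300, n_maternal = 0,
                                 n_nonspecific = 0, marker_depth_mean = 500))
  fam <- simulate_family(cfg, seed = 12)
  sb <- sex_bias(fam$table)
  se <- sd(sb$S) / sqrt(nrow(sb))
  expect_lt(abs(mean(sb$S)), 3 * se)
})

test_that("family output written to disk rebuilds the in-memory marker table", {
  d <- tempfile()
  cfg <- small_cfg(family = list(n_male = 4, n_female = 4, distances = 0,
                                 n_paternal_per_distance = 5, n_maternal = 5,
                                 n_nonspecific = 3, marker_depth_mean = 8))
  fam <- simulate_family(cfg, seed = 13, out_dir = d)
  rebuilt <- build_marker_table(fam$metadata)
  # markers with zero reads everywhere cannot appear in the files
  seen <- rowSums(fam$table$depth) > 0
  ord <- match(fam$table$markers$sequence[seen], rebuilt$markers$sequence)
  expect_false(anyNA(ord))
  expect_equal(rebuilt$depth[ord, colnames(fam$table$depth)],
               fam$table$depth[seen, ], ignore_attr = TRUE)
})

test_that("tagged map loci are removed by exactly the predicted rule", {
  sim <- simulate_map_loci(sim_config(map = list(n_per_class = 10)), seed = 14)
  res <- filter_map_loci(sim$genotypes, sim$offspring)
  ft <- merge(res$fate, sim$truth, by = "locus_id")
  expect_equal(ft$fate, ft$expected_fate)
})

test_that("overlapping locus and insertion intervals are rejected", {
  expect_error(sim_config(genome = c(LG24 = 50000), sex_contig = "LG24",
                          locus = c(10001, 20000),
                          y_insertion = c(15000, 25000), y_contig = "LG24"),
               "overlap")
})
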