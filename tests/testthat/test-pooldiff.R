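test_that("sex-specific SNP classification follows the frequency windows", {
  # male 10/18 = 0.556 and 8/18 = 0.444 both in [0.35, 0.65]; female fixed
  r <- classify_site(c(A = 10, C = 8), c(A = 20))
  expect_equal(r$call, "male_specific")
  # below min depth in one pool
  expect_equal(classify_site(c(A = 5, C = 4), c(A = 20))$call, "low_depth")
  # heterozygous in both pools: no sex specificity
  expect_equal(classify_site(c(A = 10, C = 10), c(A = 10, C = 10))$call, "none")
  # mirror image is female-specific
  expect_equal(classify_site(c(A = 20), c(A = 10, C = 8))$call, "female_specific")
  # a single third-allele read disqualifies the heterozygous pool
  expect_equal(classify_site(c(A = 10, C = 9, G = 1), c(A = 20))$call, "none")
  # boundary: female max frequency exactly 0.95 still homozygous
  expect_equal(classify_site(c(A = 10, C = 10), c(A = 19, C = 1))$call,
               "male_specific")
})

test_that("classification is symmetric under swapping the pools", {
  set.seed(42)
  flip <- c(male_specific = "female_specific", female_specific = "male_specific",
            none = "none", low_depth = "low_depth")
  for (i in 1:50) {
    m <- c(A = rpois(1, 8), C = rpois(1, 8), G = rpois(1, 1), T = 0)
    f <- c(A = rpois(1, 15), C = rpois(1, 2), G = 0, T = 0)
    a <- classify_site(m, f)
    b <- classify_site(f, m)
    expect_equal(b$call, unname(flip[a$call]))
    expect_equal(b$fst, a$fst)
  }
})

test_that("per-site FST matches its closed forms and stays in [0,1]", {
  expect_equal(fst_site(c(A = 5, C = 5), c(A = 10)), 1 / 3)
  expect_equal(fst_site(c(A = 10, C = 10), c(A = 10, C = 10)), 0)
  expect_equal(fst_site(c(A = 10), c(C = 10)), 1)
  # undefined below min depth
  expect_true(is.na(fst_site(c(A = 5), c(A = 50))))
})

test_that("FST agrees with a brute-force evaluation of the estimator", {
  set.seed(7)
  for (i in 1:200) {
    mc <- rpois(4, 5); fc <- rpois(4, 5)
    if (sum(mc) < 10 || sum(fc) < 10) next
    got <- fst_site(setNames(mc, c("A", "T", "C", "G")),
                    setNames(fc, c("A", "T", "C", "G")))
    p1 <- mc / sum(mc); p2 <- fc / sum(fc)
    hs <- ((1 - sum(p1^2)) + (1 - sum(p2^2))) / 2
    ht <- 1 - sum(((p1 + p2) / 2)^2)
    want <- if (ht > 0) (ht - hs) / ht else 0
    expect_equal(got, min(max(want, 0), 1), tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

make_calls <- function(pos, call, contig = "c1") {
  data.table::data.table(contig = contig, pos = as.integer(pos), call = call,
                         fst = 0.1, male_depth = 20L, female_depth = 20L)
}

test_that("window counts are exact and tile the contig", {
  calls <- make_calls(seq(100, 900, by = 200), "male_specific")
  w <- window_scan(calls, window_config(1000),
                   genome_mean_depth = list(male = 20, female = 20))
  expect_equal(w$n_mss[1], 5L)
  expect_equal(sum(w$n_mss), 5L)
})

test_that("empty windows report zero counts and undefined FST", {
  calls <- make_calls(c(100, 2500), "male_specific")
  w <- window_scan(calls, window_config(1000), contig_lengths = c(c1 = 3000L),
                   genome_mean_depth = list(male = 20, female = 20))
  expect_equal(nrow(w), 3L)
  expect_equal(w$n_mss, c(1L, 0L, 1L))
  expect_equal(w$male_abs_cov[2], 0)
  expect_true(is.na(w$mean_fst[2]))
})

test_that("non-overlapping window counts sum to the total call count", {
  set.seed(11)
  pos <- sort(sample.int(100000, 400))
  call <- sample(c("male_specific", "female_specific", "none"), 400, replace = TRUE)
  calls <- make_calls(pos, call)
  w <- window_scan(calls, window_config(7000),
                   genome_mean_depth = list(male = 20, female = 20))
  expect_equal(sum(w$n_mss), sum(call == "male_specific"))
  expect_equal(sum(w$n_fss), sum(call == "female_specific"))
  # last window is partial, with its true width
  expect_lte(w$width[nrow(w)], 7000L)
})

test_that("overlapping windows see every call window_size/step times", {
  calls <- make_calls(5000, "male_specific")
  w <- window_scan(calls, window_config(2000, 500), contig_lengths = c(c1 = 10000L),
                   genome_mean_depth = list(male = 20, female = 20))
  expect_equal(sum(w$n_mss), 4L)
})

test_that("unsorted calls are refused", {
  calls <- make_calls(c(500, 100), "male_specific")
  expect_error(window_scan(calls, window_config(1000)), "sorted")
})

test_that("enriched-region delimitation merges runs with bounded gaps", {
  win <- data.table::data.table(contig = "c1",
                                start = seq(1, by = 1000, length.out = 5),
                                end = seq(1000, by = 1000, length.out = 5),
                                n_mss = c(0L, 12L, 30L, 9L, 0L))
  r <- delimit_enriched_region(win, "n_mss", threshold = 5)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 1001L)
  expect_equal(r$end, 4000L)
  expect_equal(r$total, 51L)
  # nothing above threshold
  expect_equal(nrow(delimit_enriched_region(win, "n_mss", threshold = 100)), 0L)
  # gap bridging
  win2 <- data.table::data.table(contig = "c1",
                                 start = c(1L, 1001L, 2001L),
                                 end = c(1000L, 2000L, 3000L),
                                 n_mss = c(8L, 0L, 8L))
  r1 <- delimit_enriched_region(win2, "n_mss", threshold = 5, max_gap = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$total, 16L)
  r0 <- delimit_enriched_region(win2, "n_mss", threshold = 5, max_gap = 0)
  expect_equal(nrow(r0), 2L)
  expect_error(delimit_enriched_region(win2, "n_mss", threshold = 0), "threshold")
})

test_that("regions never span contig boundaries", {
  win <- data.table::data.table(contig = c("c1", "c2"),
                                start = c(1L, 1L), end = c(1000L, 1000L),
                                n_mss = c(9L, 9L))
  r <- delimit_enriched_region(win, "n_mss", threshold = 5, max_gap = 3)
  expect_equal(nrow(r), 2L)
})
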