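test_that("mononucleosome gate is inclusive on both bounds", {
  fr <- frag_df(start = c(0L, 0L, 0L, 0L, 0L),
                end = c(150L, 124L, 176L, 125L, 175L))
  fr$properly_paired[1] <- TRUE
  kept <- select_mononucleosomal(fr)
  expect_equal(sort(kept$outer_distance), c(125L, 150L, 175L))
  expect_equal(attr(kept, "dropped"), 2L)

  improper <- frag_df(0L, 150L, properly_paired = FALSE)
  expect_equal(nrow(select_mononucleosomal(improper)), 0L)
})

test_that("overlap counting enforces the minimum overlap and ambiguity rule", {
  iv <- build_interval_set(data.frame(contig_id = "contig_01",
                                      start = c(240L, 500L), end = c(300L, 530L),
                                      ies_id = c("a", "b")))
  oc <- count_fragment_overlaps(frag_df(100L, 250L), iv)   # overlap 10
  expect_equal(oc$counts$count, c(1L, 0L))
  oc <- count_fragment_overlaps(frag_df(100L, 248L), iv)   # overlap 8
  expect_equal(oc$counts$count, c(0L, 0L))
  expect_equal(oc$total_mapped, 1L)

  # >= 9 bp with both IESs: ambiguous, counted for neither
  amb <- frag_df(280L, 520L)
  oc <- count_fragment_overlaps(amb, iv)
  expect_equal(oc$counts$count, c(0L, 0L))
  expect_equal(oc$ambiguous, 1L)

  expect_error(count_fragment_overlaps(frag_df(1L, 100L), iv[0, ]), "empty")
})

test_that("downsampling is Bernoulli, deterministic, and thins counts", {
  fr <- frag_df(seq_len(10000L), seq_len(10000L) + 150L)
  expect_equal(nrow(downsample_fragments(fr, 1)), 10000L)
  expect_equal(nrow(downsample_fragments(fr, 0)), 0L)
  k <- nrow(downsample_fragments(fr, 0.5, seed = 5L))
  expect_lt(abs(k - 5000), 3 * sqrt(10000 * 0.25))
  expect_identical(downsample_fragments(fr, 0.5, seed = 5L),
                   downsample_fragments(fr, 0.5, seed = 5L))
  cnt <- downsample_fragments(c(a = 1000L, b = 0L), 0.5, seed = 1L)
  expect_equal(cnt[["b"]], 0L)
  expect_lt(abs(cnt[["a"]] - 500), 3 * sqrt(250))
})

test_that("library-matching fraction truncates to four decimals", {
  expect_equal(library_match_fraction(10195480, 11930456), 0.8545)
  expect_equal(library_match_fraction(500, 1000), 0.5)
  expect_equal(library_match_fraction(999999, 1000000), 0.9999)
  expect_error(library_match_fraction(1000, 500), "larger library")
})

test_that("DNA-seq-normalized density formula and sentinels", {
  expect_equal(compute_density(10, 100, 20, 200), 1)
  expect_equal(compute_density(6, 100, 3, 200), 4)
  expect_equal(compute_density(0, 100, 5, 200), 0)
  expect_true(is.na(compute_density(5, 100, 0, 200)))
  expect_error(compute_density(5, 0, 5, 200), ">= 1")
})

test_that("stratification partitions defined scores and bounds are inclusive", {
  dens <- data.frame(ies_id = sprintf("i%d", 1:6), n = 5L, d = c(10L, 10L, 10L, 10L, 10L, 0L),
                     r = c(0.5, 1, 1.5, 2, 2.5, NA), condition_label = "EV_control")
  scores <- data.frame(ies_id = sprintf("i%d", 1:6),
                       irs = c(0.05, 0.5, NA, 0.09, 0.95, 0.5))
  lens <- data.frame(ies_id = sprintf("i%d", 1:6),
                     length = c(26L, 31L, 28L, 25L, 32L, 28L))
  below <- stratify_densities(dens, scores, stratum_spec(0.1, "below"), lens)
  above <- stratify_densities(dens, scores, stratum_spec(0.1, "at_or_above"), lens)
  # i3 (undefined IRS) and i6 (undefined r) excluded; partition of the rest
  expect_equal(sort(c(below, above)), c(0.5, 1, 2, 2.5))

  peak <- stratify_densities(dens, scores,
                             stratum_spec(0, "at_or_above", c(26L, 31L)), lens)
  # lengths 26 and 31 included, 25 and 32 excluded
  expect_equal(sort(peak), c(0.5, 1))
  expect_error(
    stratify_densities(dens, scores,
                       stratum_spec(0.99, "at_or_above", c(26L, 31L)), lens),
    "empty stratum")
})

test_that("density histograms integrate to one and pool overflow", {
  h <- histogram_densities(2.05)
  expect_equal(sum(h$density * (h$bin_hi - h$bin_lo)), 1)
  expect_equal(sum(h$count), 1L)

  set.seed(3)
  h <- histogram_densities(rexp(500, 1))
  expect_equal(sum(h$density * (h$bin_hi - h$bin_lo)), 1, tolerance = 1e-9)

  h <- histogram_densities(c(0.5, 10), bin_edges = c(0, 1, 2))
  expect_equal(h$count, c(1L, 1L))   # 10 pooled into the last bin

  set.seed(4)
  h <- histogram_densities(runif(10000, 0, 2), bin_edges = c(0, 1, 2))
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(h$density[1] - 0.5), 3 * se)
  expect_lt(abs(h$density[2] - 0.5), 3 * se)

  expect_error(histogram_densities(numeric(0)), "empty")
  expect_error(histogram_densities(1, bin_edges = c(0, 0, 1)), "increasing")
})

test_that("KS statistic matches hand cases and the brute-force oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, x)$p_value, 1)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  expect_equal(ks_two_sample(x, c(2, 3, 4, 5))$statistic, 0.25)

  set.seed(6)
  for (i in 1:30) {
    a <- sample(0:6, sample(2:9, 1), replace = TRUE)
    b <- sample(0:6, sample(2:9, 1), replace = TRUE)
    expect_equal(ks_two_sample(a, b)$statistic, ks_brute_stat(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS asymptotic p agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(30 + i); b <- rnorm(45, 0.4)
    got <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    # both are the asymptotic Kolmogorov distribution; the reference
    # truncates its series differently, so agreement is to ~1e-5
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-3)
  }
})
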