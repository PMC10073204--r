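# Retention counting geometry: one IES spanning [1000, 1060) on the MAC+IES
# contig, first on its contig, so its MAC excision point is 1000.
.one_ies <- function() {
  build_interval_set(data.frame(contig_id = "contig_01", start = 1000L,
                                end = 1060L, ies_id = "ies_0001"))
}
.no_frags <- function() frag_df(integer(0), integer(0))

test_that("boundary-anchored counting classifies fragments correctly", {
  iv <- .one_ies()
  plus <- frag_df(start = c(990L, 995L, 1010L, 1002L, 990L),
                  end = c(1010L, 1065L, 1050L, 1062L, 1004L))
  # 990-1010: crosses left boundary with 10/10            -> +1
  # 995-1065: crosses left (5/65) and right (65/5)        -> +2
  # 1010-1050: fully inside the IES                       -> uninformative
  # 1002-1062: right boundary anchored 58/2 (< 5)         -> uninformative
  # 990-1004: left boundary 10/4 (< 5)                    -> uninformative
  counts <- count_retention_reads(plus, .no_frags(), iv, min_anchor = 5L)
  expect_equal(counts$n_plus, 3L)
  expect_equal(counts$n_minus, 0L)

  minus <- frag_df(start = c(990L, 997L), end = c(1040L, 1050L))
  # junction at MAC offset 1000: 990-1040 crosses 10/40 -> 2 units;
  # 997-1050 has only 3 bases left of the junction -> uninformative
  counts <- count_retention_reads(.no_frags(), minus, iv, min_anchor = 5L)
  expect_equal(counts$n_plus, 0L)
  expect_equal(counts$n_minus, 2L)
})

test_that("MAC junction offsets subtract preceding IES lengths", {
  iv <- build_interval_set(data.frame(
    contig_id = "contig_01", start = c(1000L, 2000L), end = c(1060L, 2030L),
    ies_id = c("a", "b")))
  # second IES: MAC junction at 2000 - 60 = 1940
  minus <- frag_df(start = 1920L, end = 1980L)
  counts <- count_retention_reads(.no_frags(), minus, iv)
  expect_equal(counts$n_minus, c(0L, 2L))
})

test_that("IRS formula and sentinels", {
  x <- compute_irs(data.frame(ies_id = c("a", "b", "c", "d"),
                              n_plus = c(5L, 0L, 7L, 0L),
                              n_minus = c(15L, 10L, 0L, 0L)))
  expect_equal(x$irs, c(0.25, 0, 1, NA_real_))
  expect_error(compute_irs(data.frame(ies_id = "a", n_plus = -1L,
                                      n_minus = 0L)), "non-negative")
})

test_that("IRS is monotone in the evidence counts", {
  set.seed(1)
  for (i in 1:50) {
    np <- rpois(1, 20); nm <- rpois(1, 20)
    base <- compute_irs(data.frame(ies_id = "x", n_plus = np, n_minus = nm))$irs
    up <- compute_irs(data.frame(ies_id = "x", n_plus = np + 1L,
                                 n_minus = nm))$irs
    dn <- compute_irs(data.frame(ies_id = "x", n_plus = np,
                                 n_minus = nm + 1L))$irs
    if (!is.na(base)) {
      expect_gte(up, base)
      expect_lte(dn, base)
    }
  }
})

test_that("retention summary applies the cutoff over defined scores only", {
  sc <- data.frame(ies_id = letters[1:5], n_plus = 1L, n_minus = 1L,
                   irs = c(0, 0.05, 0.2, 1.0, NA))
  s <- summarize_retention(sc, cutoff = 0.1)
  expect_equal(s$count, 2L)
  expect_equal(s$percentage, 50)
  expect_equal(s$n_defined, 4L)

  sc$irs <- c(0, 0, 0, 0, 0)
  s <- summarize_retention(sc, cutoff = 0.1)
  expect_equal(s$count, 0L)
  expect_equal(s$percentage, 0)

  sc$irs <- NA_real_
  expect_error(summarize_retention(sc), "no IES with a defined IRS")
})

test_that("IRS correlation: identity, anti-identity and closed-form OLS", {
  a <- data.frame(ies_id = sprintf("i%02d", 1:10), irs = seq(0, 1, length.out = 10))
  same <- correlate_irs(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$ols_slope, 1)
  expect_equal(same$ols_intercept, 0)
  expect_equal(same$n_pairs, 10L)
  expect_equal(sum(same$hexbin_counts$count), same$n_pairs)

  b <- a; b$irs <- 1 - a$irs
  expect_equal(correlate_irs(a, b)$pearson_r, -1)

  # hand-computed least squares for {(0,0),(0.5,0.25),(1,0.75)}
  x <- c(0, 0.5, 1); y <- c(0, 0.25, 0.75)
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(x)
  expect_equal(slope_oracle, 0.75)
  expect_equal(intercept_oracle, -1 / 24)
  got <- correlate_irs(data.frame(ies_id = c("a", "b", "c"), irs = x),
                       data.frame(ies_id = c("a", "b", "c"), irs = y))
  expect_equal(got$ols_slope, slope_oracle)
  expect_equal(got$ols_intercept, intercept_oracle)

  # symmetry of Pearson's r
  set.seed(2)
  u <- data.frame(ies_id = sprintf("i%02d", 1:20), irs = runif(20))
  v <- data.frame(ies_id = sprintf("i%02d", 1:20), irs = runif(20))
  expect_equal(correlate_irs(u, v)$pearson_r, correlate_irs(v, u)$pearson_r)
})

test_that("degenerate correlation inputs are handled", {
  a <- data.frame(ies_id = c("a", "b"), irs = c(0.1, 0.2))
  expect_error(correlate_irs(a, a), "at least 3")
  flat <- data.frame(ies_id = c("a", "b", "c"), irs = c(0.5, 0.5, 0.5))
  vary <- data.frame(ies_id = c("a", "b", "c"), irs = c(0.1, 0.5, 0.9))
  out <- correlate_irs(flat, vary)
  expect_true(is.na(out$pearson_r))
  expect_true(is.na(out$ols_slope))
})

test_that("fully retained simulation yields no excision evidence", {
  cfg <- tiny_config(strong_fraction = 1, retention_kd_strong = c(1, 1))
  built <- build_genome(cfg)
  lib <- simulate_dna_fragments(built$genome, built$truth, cfg, "KD")
  iv <- build_interval_set(built$genome$ies)
  counts <- count_retention_reads(lib$mac_ies, lib$mac, iv)
  expect_true(all(counts$n_minus == 0L))
  expect_true(sum(counts$n_plus) > 0L)
})
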