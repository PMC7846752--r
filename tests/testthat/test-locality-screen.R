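test_that("the sample-size gate opens at nine individuals", {
  expect_true(sample_size_gate(9))
  expect_false(sample_size_gate(8))
  expect_true(sample_size_gate(50))
  expect_false(sample_size_gate(0))
  expect_true(sample_size_gate(8, min_n = 5))
})

test_that("the MAD variant follows the normality verdict", {
  expect_equal(select_mad_variant(tibble::tibble(p = 0.47)),
               "three_mad_norm")
  expect_equal(select_mad_variant(tibble::tibble(p = 0.02)),
               "three_mad_q3")
  # boundary p = alpha counts as non-normal
  expect_equal(select_mad_variant(tibble::tibble(p = 0.05)),
               "three_mad_q3")
})

test_that("window bounds reproduce the published community windows", {
  # FR-like: median 24.4, mad_norm 0.7 -> [22.3, 26.5], width 4.2
  stats <- tibble::tibble(n = 18, min = 21.6, max = 26.3, mean = 24.4,
                          sd = 1.2, median = 24.4, q1 = 23.9, q3 = 24.8,
                          range = 4.7)
  spread <- tibble::tibble(mad_raw = 0.5, mad_norm = 0.7, mad_q3 = 0.6,
                           iqr = 0.9)
  w <- locality_window(stats, spread, "three_mad_norm")
  expect_equal(c(w$lower, w$upper), c(22.3, 26.5))
  expect_equal(w$upper - w$lower, 4.2)

  # Rome-like pool: q1 26.0, q3 26.4, iqr 0.4 -> [25.4, 27.0], width 1.6
  stats_rome <- tibble::tibble(n = 30, min = 23.8, max = 27.6, mean = 26.1,
                               sd = 0.8, median = 26.2, q1 = 26.0,
                               q3 = 26.4, range = 3.8)
  spread_rome <- tibble::tibble(mad_raw = 0.2, mad_norm = NA, mad_q3 = 0.3,
                                iqr = 0.4)
  w2 <- locality_window(stats_rome, spread_rome, "tukey_iqr")
  expect_equal(c(w2$lower, w2$upper), c(25.4, 27.0))
  expect_equal(w2$upper - w2$lower, 1.6)

  w3 <- locality_window(tibble::tibble(mean = 26.0, sd = 1), NULL,
                        "two_permil")
  expect_equal(c(w3$lower, w3$upper), c(24.0, 28.0))

  expect_error(locality_window(stats, NULL, "tukey_iqr"), "spread")
})

test_that("window width identities hold on random data", {
  set.seed(19)
  for (i in 1:50) {
    x <- rnorm(sample(9:60, 1), 26, runif(1, 0.2, 1.5))
    stats <- descriptive_stats(x)
    spread <- robust_spread(x)
    width <- function(m) {
      w <- locality_window(stats, spread, m)
      w$upper - w$lower
    }
    expect_equal(width("two_sd"), 4 * stats$sd)
    expect_equal(width("three_mad_norm"), 6 * spread$mad_norm)
    expect_equal(width("three_mad_q3"), 6 * spread$mad_q3)
    expect_equal(width("tukey_iqr"), 4 * spread$iqr)
    expect_equal(width("two_permil"), 4.0)
  }
})

test_that("classification is strict at bounds and counts consensus", {
  windows <- tibble::tibble(method = c("two_sd", "two_permil"),
                            center = c(26, 26),
                            lower = c(25, 24), upper = c(27, 28))
  samples <- tibble::tibble(sample_id = c("on_bound", "inside", "low",
                                          "very_low"),
                            value = c(27, 26, 24.5, 23))
  rep <- classify_outliers(samples, windows)
  expect_false(rep$out_two_sd[rep$sample_id == "on_bound"])
  expect_true(rep$boundary[rep$sample_id == "on_bound"])
  expect_equal(rep$consensus_count, c(0L, 0L, 1L, 2L))
  expect_equal(rep$is_consensus_outlier, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("a planted newcomer is flagged by all four criteria", {
  cfg <- synth_site_config("SS", n = 50, mu = 26.9, sigma = 0.55,
                           seed = 101)
  tab <- generate_site(cfg)
  # plant one individual at exactly 24.7 permil V-SMOW, 2.2 below the mean
  tab$d18O_ca_vpdb[1] <- vsmow_to_vpdb(24.7)
  tab$true_status[1] <- "migrant"
  v <- vpdb_to_vsmow(tab$d18O_ca_vpdb)
  windows <- locality_windows(v)
  rep <- classify_outliers(
    tibble::tibble(sample_id = tab$sample_id, value = v), windows)
  migrant <- tab$sample_id[tab$true_status == "migrant"]
  expect_true(rep$is_consensus_outlier[rep$sample_id == migrant])
  expect_equal(rep$consensus_count[rep$sample_id == migrant], 4L)

  # cross-check all four windows against the brute-force oracle
  variant <- if (any(windows$method == "three_mad_q3")) "q3" else "norm"
  ow <- oracle_windows(v, variant)
  pick <- function(m) {
    w <- windows[windows$method == m, ]
    c(w$lower, w$upper)
  }
  expect_equal(pick("two_sd"), ow$two_sd, tolerance = 1e-12)
  expect_equal(pick(paste0("three_mad_", variant)), ow$three_mad,
               tolerance = 1e-12)
  expect_equal(pick("tukey_iqr"), ow$tukey_iqr, tolerance = 1e-12)
  expect_equal(pick("two_permil"), ow$two_permil, tolerance = 1e-12)
})

test_that("constant community values flag nobody", {
  windows <- locality_windows(rep(26, 12), mad_variant = "q3")
  rep <- classify_outliers(
    tibble::tibble(sample_id = as.character(1:12), value = rep(26, 12)),
    windows)
  expect_equal(sum(rep$consensus_count), 0L)
})

test_that("outlier sets are monotone in window nesting", {
  set.seed(23)
  x <- rnorm(40, 26, 0.6)
  samples <- tibble::tibble(sample_id = as.character(1:40), value = x)
  stats <- descriptive_stats(x)
  narrow <- tibble::tibble(method = "two_sd", center = stats$mean,
                           lower = stats$mean - 1, upper = stats$mean + 1)
  wide <- tibble::tibble(method = "two_permil", center = stats$mean,
                         lower = stats$mean - 2, upper = stats$mean + 2)
  flag_narrow <- classify_outliers(samples, narrow)$out_two_sd
  flag_wide <- classify_outliers(samples, wide)$out_two_permil
  expect_true(all(flag_narrow[flag_wide])) # wide-window outliers a subset
})

test_that("the statistical criteria are invariant to the working scale", {
  # the 2 permil band is a fixed width defined on the reporting (V-SMOW)
  # scale and is deliberately excluded: an affine change of scale rescales
  # every window statistic but not a fixed band
  stat_methods <- c("two_sd", "mad", "tukey_iqr")
  set.seed(31)
  for (i in 1:20) {
    x_vpdb <- rnorm(30, -4.5, 0.8)
    x_vsmow <- vpdb_to_vsmow(x_vpdb)
    ids <- as.character(1:30)
    rep1 <- classify_outliers(
      tibble::tibble(sample_id = ids, value = x_vpdb),
      locality_windows(x_vpdb, methods = stat_methods, mad_variant = "q3"))
    rep2 <- classify_outliers(
      tibble::tibble(sample_id = ids, value = x_vsmow),
      locality_windows(x_vsmow, methods = stat_methods, mad_variant = "q3"))
    expect_identical(rep1$consensus_count, rep2$consensus_count)
    expect_identical(rep1$is_consensus_outlier, rep2$is_consensus_outlier)
  }
})

test_that("consensus summaries order by consensus then extremity", {
  windows <- tibble::tibble(method = "two_sd", center = 26, lower = 25,
                            upper = 27)
  rep <- classify_outliers(
    tibble::tibble(sample_id = c("a", "b", "c"),
                   value = c(26.1, 24.0, 23.0)), windows)
  s <- consensus_summary(rep, windows)
  expect_equal(s$per_sample$sample_id, c("c", "b", "a"))
  expect_equal(s$per_method$n_flagged, 2L)

  empty <- classify_outliers(
    tibble::tibble(sample_id = character(), value = numeric()), windows)
  expect_equal(nrow(consensus_summary(empty, windows)$per_sample), 0)
})
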