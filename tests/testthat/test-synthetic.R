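test_that("site generation is seed-deterministic and hits its target mean", {
  cfg <- synth_site_config("SS", n = 50, mu = 26.8, sigma = 0.6, seed = 1)
  a <- generate_site(cfg)
  b <- generate_site(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 50)
  v <- vpdb_to_vsmow(a$d18O_ca_vpdb)
  expect_lt(abs(mean(v) - 26.8), 3 * 0.6 / sqrt(50))

  expect_equal(nrow(generate_site(synth_site_config("X", 0, 26, 0.5))), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_site_config("X", -1, 26, 0.5), "n must be")
  expect_error(synth_site_config("X", 5, 26, -0.5), "sigma")
  expect_error(synth_site_config("X", 5, 26, 0.5,
                                 deciduous_fraction = 1.5),
               "deciduous_fraction")
  cfg <- synth_site_config("X", 3, 26, 0.5,
                           migrants = list(list(5L, 2)))
  expect_error(generate_site(cfg), "more planted migrants")
})

test_that("planted migrants are labelled and count-limited", {
  cfg <- synth_site_config("SS", n = 50, mu = 26.8, sigma = 0.6, seed = 3)
  tab <- generate_site(cfg)
  planted <- plant_migrants(tab, count = 1, offset = -2.1, mu = 26.8,
                            sigma = 0.6, seed = 9)
  expect_equal(sum(planted$true_status == "migrant"), 1)
  expect_equal(unique(planted$true_offset[planted$true_status == "migrant"]),
               -2.1)

  expect_identical(plant_migrants(tab, 0, -2, 26.8, 0.6), tab)
  expect_error(plant_migrants(tab, 51, -2, 26.8, 0.6), "count exceeds")

  both <- generate_site(synth_site_config(
    "Y", n = 30, mu = 26, sigma = 0.5, seed = 4,
    migrants = list(list(1L, 3), list(1L, -3))))
  expect_equal(sort(both$true_offset[both$true_status == "migrant"]),
               c(-3, 3))
})

test_that("diagenetic mixing is exactly linear per axis", {
  cfg <- synth_site_config("MC", n = 9, mu = 25.9, sigma = 0.5, seed = 6,
                           d13C_mu = -12, d13C_sigma = 0.01)
  tab <- generate_site(cfg)
  em <- list(d13C = -2, d18O = 25.5)

  none <- apply_diagenetic_mixing(tab, em, c(0, 0.8), 0, seed = 1)
  expect_equal(none$d13C_ca_vpdb, tab$d13C_ca_vpdb)

  full <- apply_diagenetic_mixing(tab, em, c(1, 1), 1, seed = 1)
  expect_equal(full$d13C_ca_vpdb, rep(-2, 9))

  mixed <- apply_diagenetic_mixing(tab, em, c(0.2, 0.9), 0.6, seed = 2)
  aff <- mixed$true_f > 0
  f_recovered <- (mixed$d13C_ca_vpdb[aff] - tab$d13C_ca_vpdb[aff]) /
    (em$d13C - tab$d13C_ca_vpdb[aff])
  expect_equal(f_recovered, mixed$true_f[aff], tolerance = 1e-9)
  # half mixing of biogenic -12 with endmember -2 lands at -7
  expect_equal((1 - 0.5) * -12 + 0.5 * -2, -7)

  expect_error(apply_diagenetic_mixing(tab, em, c(0.9, 0.2), 0.5),
               "f_range")
})

test_that("benchmarking scores a report against the generator truth", {
  cfg <- synth_site_config("SS", n = 30, mu = 26.8, sigma = 0.5, seed = 12,
                           migrants = list(list(1L, 3)))
  tab <- generate_site(cfg)
  v <- vpdb_to_vsmow(tab$d18O_ca_vpdb)
  rep <- classify_outliers(
    tibble::tibble(sample_id = tab$sample_id, value = v),
    locality_windows(v))
  bench <- benchmark_detection(tab, rep)
  cons <- bench[bench$method == "consensus", ]
  expect_equal(cons$tp + cons$fn, 1)
  expect_equal(cons$tp + cons$fp + cons$fn + cons$tn, 30)

  # no migrants: sensitivity not applicable, specificity well defined
  tab0 <- generate_site(synth_site_config("SS", 30, 26.8, 0.5, seed = 13))
  v0 <- vpdb_to_vsmow(tab0$d18O_ca_vpdb)
  rep0 <- classify_outliers(
    tibble::tibble(sample_id = tab0$sample_id, value = v0),
    locality_windows(v0))
  bench0 <- benchmark_detection(tab0, rep0)
  expect_true(all(is.na(bench0$sensitivity)))
  expect_true(all(bench0$specificity >= 0 & bench0$specificity <= 1))

  expect_error(benchmark_detection(tab0[1:10, ], rep0), "different samples")
})

test_that("zero-offset 'migrants' are exchangeable with locals", {
  set.seed(21)
  flagged_m <- 0; n_m <- 0
  flagged_l <- 0; n_l <- 0
  for (r in 1:60) {
    cfg <- synth_site_config("Z", n = 30, mu = 26, sigma = 0.5,
                             seed = 3000 + r,
                             migrants = list(list(3L, 0)))
    tab <- generate_site(cfg)
    v <- vpdb_to_vsmow(tab$d18O_ca_vpdb)
    rep <- classify_outliers(
      tibble::tibble(sample_id = tab$sample_id, value = v),
      locality_windows(v, mad_variant = "q3"))
    mig <- tab$true_status == "migrant"
    flagged_m <- flagged_m + sum(rep$is_consensus_outlier[mig])
    n_m <- n_m + sum(mig)
    flagged_l <- flagged_l + sum(rep$is_consensus_outlier[!mig])
    n_l <- n_l + sum(!mig)
  }
  expect_lt(abs(flagged_m / n_m - flagged_l / n_l), 0.05)
})

test_that("the bundled scenario mirrors the published study structure", {
  sc <- generate_scenario(seed = 42)
  expect_equal(nrow(sc$samples), 126)
  expect_equal(length(unique(sc$samples$site_code)), 10)
  counts <- table(sc$samples$site_code)
  expect_equal(unname(counts[["SS"]]), 50)
  expect_equal(unname(counts[["FR"]]), 18)
  expect_equal(sum(sc$samples$true_status == "migrant"), 1)
  # round-trips through validation without blocking findings
  rep <- validate_dataset(sc$samples, sc$sites)
  expect_equal(sum(rep$severity == "error"), 0)
})
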