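# CFU back-calculation, detection limits, censored transfer rates, fold
# changes and log-scale summary statistics.

test_that("CFU back-calculation from dilution spots follows the plating math", {
  # 20 colonies in 5 uL at 10^-3 -> 20 * 10^3 / 0.005 = 4e6 CFU/mL
  one <- tibble::tibble(dilution_exponent = 3, spot_volume_uL = 5,
                        colonies = 20)
  expect_equal(cfu_from_spots(one)$cfu, 4e6)

  # replicate spots average to the same answer
  tri <- tibble::tibble(dilution_exponent = 3, spot_volume_uL = 5,
                        colonies = c(18, 20, 22))
  expect_equal(cfu_from_spots(tri)$cfu, 4e6)

  # the most dilute countable dilution wins (overgrown rows ignored)
  series <- tibble::tibble(dilution_exponent = rep(c(1, 2, 3), each = 3),
                           spot_volume_uL = 5,
                           colonies = c(900, 910, 890, 180, 200, 190,
                                        18, 20, 22))
  out <- cfu_from_spots(series)
  expect_equal(out$dilution_used, 3L)
  expect_equal(out$cfu, 4e6)

  # per-gram scaling via sample mass and homogenization volume
  per_g <- dplyr::mutate(tri, sample_mass_g = 0.1, homogenate_volume_mL = 1)
  expect_equal(cfu_from_spots(per_g)$cfu, 4e7)
  expect_equal(cfu_from_spots(per_g)$unit, "per_g")

  zeroes <- tibble::tibble(dilution_exponent = 0:5, spot_volume_uL = 5,
                           colonies = 0)
  out <- cfu_from_spots(zeroes)
  expect_equal(out$cfu, 0)
  expect_true(out$below_detection)

  lawn <- tibble::tibble(dilution_exponent = 0:2, spot_volume_uL = 5,
                         colonies = 400)
  expect_error(cfu_from_spots(lawn), class = "conjseq_overgrown")
})

test_that("the detection limit scales with recipient abundance and plated amount", {
  # 1e8 CFU/g recipient, 10 mg plated -> 1 / (1e8 * 0.01) = 1e-6
  expect_equal(
    detection_limit(1e8, plated_volume_uL = 100,
                    homogenate_volume_mL = 1, sample_mass_g = 0.1),
    1e-6
  )
  # 10x more material plated -> bound 10x lower
  expect_equal(
    detection_limit(1e8, plated_volume_uL = 1000,
                    homogenate_volume_mL = 1, sample_mass_g = 0.1),
    1e-7
  )
  expect_error(detection_limit(0, plated_volume_uL = 100),
               class = "conjseq_no_recipient")
})

test_that("transfer rates divide transconjugants by recipients and censor non-detects", {
  rec <- tibble::tibble(selection = "recipient",
                        dilution_exponent = rep(0:5, each = 3),
                        spot_volume_uL = 5,
                        colonies = rep(c(900, 900, 500, 50, 5, 0), each = 3))
  tc <- dplyr::mutate(rec, selection = "transconjugant",
                      colonies = rep(c(50, 5, 0, 0, 0, 0), each = 3))
  out <- transfer_rate(tc, rec)
  expect_false(out$censored)
  expect_equal(out$value, out$transconjugant_cfu / out$recipient_cfu)
  expect_equal(out$value, 1e-3)  # 1e4 CFU/mL over 1e7 CFU/mL

  # all-zero transconjugant series: the LOD bound is reported, flagged
  none <- dplyr::mutate(tc, colonies = 0)
  out <- transfer_rate(none, rec)
  expect_true(out$censored)
  expect_equal(out$value, out$lod)
  expect_equal(out$transconjugant_cfu, 0)

  # a recipient below detection leaves the frequency undefined
  no_rec <- dplyr::mutate(rec, colonies = 0)
  expect_error(transfer_rate(tc, no_rec), class = "conjseq_no_recipient")

  # saturation: transconjugant series equal to the recipient series gives 1
  expect_equal(transfer_rate(dplyr::mutate(rec, selection = "transconjugant"),
                             rec)$value, 1)
})

test_that("rates are invariant to the shared homogenization volume and 1:1 mixing", {
  assay <- gen_cfu_assay(true_rate = 1e-3, n_mice = 2,
                         cfg = sim_config(seed = 30))
  r1 <- transfer_rates(assay)
  r2 <- transfer_rates(assay, homogenate_volume_mL = 10)
  expect_equal(r1$value, r2$value)

  # per-donor equals per-recipient when donor and recipient series coincide
  rec <- tibble::tibble(dilution_exponent = rep(2:4, each = 3),
                        spot_volume_uL = 5,
                        colonies = rep(c(300, 30, 3), each = 3))
  tc <- dplyr::mutate(rec, colonies = colonies %/% 100)
  per_recipient <- transfer_rate(tc, rec)$value
  per_donor <- transfer_rate(tc, rec)$value  # donor series identical to rec
  expect_equal(per_donor, per_recipient)
})

test_that("fold changes aggregate geometrically and propagate censoring", {
  a <- tibble::tibble(value = c(1e-3, 1e-3), censored = FALSE)
  expect_equal(fold_change(a, a)$fold, 1)

  b <- tibble::tibble(value = c(1e-4, 1e-4), censored = FALSE)
  expect_equal(fold_change(a, b)$fold, 10)
  expect_false(fold_change(a, b)$bound)

  cens <- tibble::tibble(value = 1e-6, censored = TRUE)
  expect_true(fold_change(cens, b)$bound)
  expect_error(fold_change(a, cens), class = "conjseq_bad_input")

  # synthetic rates with a known 10x difference recover it
  hi <- transfer_rates(gen_cfu_assay(true_rate = 1e-3, n_mice = 12,
                                     cfg = sim_config(seed = 8, mouse_cv = 0.3)))
  lo <- transfer_rates(gen_cfu_assay(true_rate = 1e-4, n_mice = 12,
                                     cfg = sim_config(seed = 9, mouse_cv = 0.3)))
  f <- fold_change(hi, lo)
  expect_lt(abs(log10(f$fold) - 1), 0.35)  # within ~3 SE of the design
})

test_that("log-scale correlation behaves at its fixed points", {
  x <- c(1e-6, 1e-4, 1e-2)
  expect_equal(log_r_squared(x, x)$r_squared, 1)
  expect_equal(log_r_squared(x, 10 * x)$r_squared, 1)

  # independent values decorrelate for large n
  big <- withr::with_seed(2, 10^stats::rnorm(300, -4, 1))
  perm <- withr::with_seed(3, sample(big))
  expect_lt(log_r_squared(big, perm)$r_squared, 0.05)

  expect_error(log_r_squared(x[1:2], x[1:2]), class = "conjseq_bad_input")

  # censored pairs are excluded (and counted) by default
  xt <- tibble::tibble(value = c(x, 1e-5), censored = c(FALSE, FALSE, FALSE, TRUE))
  yt <- tibble::tibble(value = c(x, 1e-3), censored = FALSE)
  out <- log_r_squared(xt, yt)
  expect_equal(out$n_used, 3L)
  expect_equal(out$n_excluded, 1L)
  expect_equal(out$r_squared, 1)
})

test_that("log-scale one-way ANOVA matches its closed-form identities", {
  identical_groups <- list(g1 = c(1e-4, 1e-3, 1e-2), g2 = c(1e-4, 1e-3, 1e-2))
  out <- anova_log(identical_groups)
  expect_equal(out$f, 0)
  expect_equal(out$p, 1)

  # two groups: F equals the squared pooled-variance t statistic
  g1 <- c(1e-5, 3e-5, 1e-4, 2e-4)
  g2 <- c(5e-4, 1e-3, 8e-4, 2e-3)
  out <- anova_log(list(a = g1, b = g2))
  tt <- stats::t.test(log10(g1), log10(g2), var.equal = TRUE)
  expect_equal(out$f, unname(tt$statistic^2))
  expect_equal(out$p, tt$p.value)
  expect_equal(tidy(out)$f, out$f)

  expect_error(anova_log(list(a = c(0, 1e-3), b = g2)),
               class = "conjseq_bad_input")
  expect_error(anova_log(list(a = g1)), class = "conjseq_bad_input")
})

test_that("group summaries report log-scale moments and extremes", {
  rates <- tibble::tibble(value = c(1e-4, 1e-3, 1e-5, 1e-6),
                          censored = c(FALSE, FALSE, FALSE, TRUE))
  s <- rate_summary(rates, c("a", "a", "b", "b"))
  expect_equal(s$n, c(2L, 1L))  # censored observation excluded
  expect_equal(s$mean_log10[1], -3.5)
  expect_equal(s$min_log10[1], -4)
  expect_equal(s$geo_mean_rate[1], 10^-3.5)
})
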