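test_that("noiseless power-law points are recovered exactly", {
  lg <- c(5, 20, 80, 320)
  fit <- loglog_fit(lg, 1e3 * lg^1)
  expect_equal(fit$m, 1, tolerance = 1e-12)
  expect_equal(fit$A, 3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n, 4)
})

test_that("loglog_fit matches the closed-form normal-equations oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    lg <- 10^runif(n, 0.5, 3.5)
    vc <- 10^(runif(1, 0, 4) + runif(1, 0.3, 2.5) * log10(lg) +
                rnorm(n, 0, runif(1, 0.05, 0.6)))
    fit <- loglog_fit(lg, vc)
    oracle <- ols_oracle(log10(lg), log10(vc))
    expect_equal(fit$m, oracle$m, tolerance = 1e-10)
    expect_equal(fit$A, oracle$A, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-10)
    expect_equal(fit$se_m, oracle$se_m, tolerance = 1e-10)
    expect_true(fit$ci_m[1] <= fit$m && fit$m <= fit$ci_m[2])
  }
})

test_that("degenerate inputs are refused", {
  expect_error(loglog_fit(c(1, 2), c(1, 2)), "3 points")
  expect_error(loglog_fit(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(loglog_fit(c(1, 2, 3), c(1, 0, 3)), "positive")
})

test_that("rescaling axes shifts A as predicted and leaves m, R^2, p alone", {
  set.seed(7)
  lg <- 10^runif(30, 1, 3)
  vc <- 10^(3.5 + 0.95 * log10(lg) + rnorm(30, 0, 0.3))
  base <- loglog_fit(lg, vc)
  c1 <- 42
  fv <- loglog_fit(lg, vc * c1)
  expect_equal(fv$m, base$m)
  expect_equal(fv$A, base$A + log10(c1))
  expect_equal(fv$r_squared, base$r_squared)
  expect_equal(fv$p_value, base$p_value)
  fl <- loglog_fit(lg * c1, vc)
  expect_equal(fl$m, base$m)
  expect_equal(fl$A, base$A - base$m * log10(c1))
})

test_that("predict_volume evaluates the law and refitting round-trips", {
  fit <- reference_fit("ncldv")
  expect_equal(predict_volume(fit, 330), 10^1.38 * 330^2)
  expect_equal(predict_volume(fit, 330), 2.613e6, tolerance = 1e-3)
  id <- structure(list(m = 1, A = 0, a = 1, genome_unit = "kb"),
                  class = "allofit")
  expect_equal(predict_volume(id, 7), 7)
  lg <- c(12, 60, 240, 960)
  refit <- loglog_fit(lg, predict_volume(fit, lg))
  expect_equal(refit$m, fit$m, tolerance = 1e-10)
  expect_equal(refit$A, fit$A, tolerance = 1e-10)
})

test_that("genome_length_from_radius inverts the fitted law", {
  fit <- reference_fit("ncldv")
  # plug-in value for a 100 nm inner radius
  expect_equal(genome_length_from_radius(100, fit),
               sqrt((4 * pi / 3) * 1e6 / 10^1.38))
  expect_equal(genome_length_from_radius(100, fit), 417.9, tolerance = 1e-3)
  # algebraic round trip Lg -> Vc -> rc -> Lg
  for (lg in c(50, 120, 417.9, 2400)) {
    vc <- predict_volume(fit, lg)
    rc <- (3 * vc / (4 * pi))^(1 / 3)
    expect_equal(genome_length_from_radius(rc, fit), lg, tolerance = 1e-10)
  }
  # constructed identity: m = 3, a = 4pi/3 makes Lg = rc
  ident <- structure(list(m = 3, a = 4 * pi / 3, A = log10(4 * pi / 3),
                          genome_unit = "kb"), class = "allofit")
  expect_equal(genome_length_from_radius(5, ident), 5)
})

test_that("group fits recover per-group exponents and skip small groups", {
  dp <- simulate_viruses(synthetic_config("phage", n = 40, m = 1.0, A = 3.0,
                                          sigma = 0, seed = 21))
  dn <- simulate_viruses(synthetic_config("ncldv", n = 40, m = 2.0, A = 1.38,
                                          sigma = 0, seed = 22))
  tiny <- make_record("lone", group_tag = "jumbo_phage")
  recs <- dplyr::bind_rows(dp$records, dn$records, tiny)
  fits <- fit_by_group(recs, group_by = "group_tag", volume = "inner")
  # bp rounding at generation perturbs x only at the ~1e-5 level
  expect_equal(fits$phage$m, 1.0, tolerance = 1e-3)
  expect_equal(fits$phage$A, 3.0, tolerance = 1e-3)
  expect_equal(fits$NCLDV$m, 2.0, tolerance = 1e-3)
  expect_equal(fits$NCLDV$A, 1.38, tolerance = 1e-2)
  skipped <- attr(fits, "skipped")
  expect_equal(skipped$group, "jumbo_phage")
  expect_match(skipped$reason, "fewer than 3")
})

test_that("a single-group table reproduces loglog_fit directly", {
  sim <- simulate_viruses(synthetic_config("phage", n = 30, seed = 5))
  fits <- fit_by_group(sim$records, "group_tag", volume = "inner")
  t <- 3
  direct <- loglog_fit(sim$records$genome_length_bp / 1000,
                       4 / 3 * pi * (sim$records$dim1_nm - t)^3,
                       volume_kind = "inner")
  expect_equal(fits$phage$m, direct$m)
  expect_equal(fits$phage$A, direct$A)
  expect_equal(fits$phage$p_value, direct$p_value)
})

test_that("unknown grouping column is a usage error", {
  sim <- simulate_viruses(synthetic_config("phage", n = 10, seed = 1))
  expect_error(fit_by_group(sim$records, group_by = "family"))
})

test_that("fits_to_table flattens a fit list", {
  sim <- simulate_viruses(synthetic_config("mixed", n = 40, seed = 9))
  tab <- fits_to_table(fit_by_group(sim$records, "group_tag"))
  expect_setequal(tab$group, c("phage", "NCLDV"))
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})
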