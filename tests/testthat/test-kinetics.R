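test_that("rate law reduces to its closed-form special cases", {
  p <- kinetic_parameters(100, 100, Ki = 5, Ki_prime = 5)
  # no inhibitor: Michaelis-Menten
  expect_equal(inhibition_velocity(p, 50, 0), 100 * 50 / 150)
  # pure non-competitive at I = Ki, S = Km: quarter of Vmax
  expect_equal(inhibition_velocity(p, 100, 5), 25)
  # linear mixed, S -> infinity limit: Vmax / (1 + I/Ki')
  pm <- kinetic_parameters(100, 100, Ki = 5, Ki_prime = 10)
  v_inf <- inhibition_velocity(pm, 1e6 * 100, 20)
  expect_equal(v_inf, 100 / (1 + 20 / 10), tolerance = 1e-3)
})

test_that("velocity is monotone in S and I and collapses when b=0, Ki=Ki'", {
  p <- kinetic_parameters(80, 120, Ki = 4, Ki_prime = 9, b = 0.25)
  S <- c(10, 30, 100, 300, 1000)
  for (s in S) {
    vI <- inhibition_velocity(p, s, c(0, 1, 5, 20, 50))
    expect_true(all(diff(vI) < 0))
  }
  vS <- inhibition_velocity(p, S, 10)
  expect_true(all(diff(vS) > 0))
  expect_true(all(vS < p$Vmax))
  pnc <- kinetic_parameters(80, 120, Ki = 4)
  grid <- expand.grid(S = S, I = c(0, 2, 4, 8, 40))
  v <- inhibition_velocity(pnc, grid$S, grid$I)
  v0 <- inhibition_velocity(pnc, grid$S, 0)
  expect_equal(v, v0 / (1 + grid$I / 4), tolerance = 1e-12)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(kinetic_parameters(0, 1, 1), "positive")
  expect_error(kinetic_parameters(1, 1, 1, b = 1), "\\[0, 1\\)")
  expect_error(inhibition_velocity(kinetic_parameters(1, 1, 1), -5, 0),
               "positive")
})

test_that("primary fits recover exact reciprocal-line parameters", {
  p <- kinetic_parameters(100, 100, Ki = 5, Ki_prime = 10)
  d <- noiseless_kinetics(p, I = c(0, 2.5, 5))
  lb <- lineweaver_burk(d)
  base <- lb$primary[lb$primary$I == 0, ]
  expect_equal(base$slope, p$Km / p$Vmax, tolerance = 1e-10)
  expect_equal(base$intercept, 1 / p$Vmax, tolerance = 1e-10)
  # slope ratio identity (1 + I/Ki) on noiseless linear-mixed data
  s5 <- lb$primary$slope[lb$primary$I == 5]
  expect_equal(s5 / base$slope, 2.0, tolerance = 1e-10)
  # secondary slope replot exactly linear
  fit <- lm(slope ~ I, data = lb$primary)
  expect_lt(sum(residuals(fit)^2), 1e-16)
})

test_that("replot assembly enforces its preconditions", {
  p <- kinetic_parameters(100, 100, Ki = 5)
  d <- noiseless_kinetics(p, I = c(1, 2, 4))  # no I = 0
  expect_error(lineweaver_burk(d), "I = 0")
  d2 <- noiseless_kinetics(p, I = c(0, 2))
  d2 <- rbind(d2, data.frame(S = c(10, 20), I = 4,
                             v = inhibition_velocity(p, c(10, 20), 4)))
  expect_warning(lb <- lineweaver_burk(d2), "< 3 substrate levels")
  expect_false(4 %in% lb$primary$I)
  expect_error(lineweaver_burk(data.frame(S = 1, I = 0, v = -1)),
               "positive")
})

test_that("secondary curvature test separates linear from partial inhibition", {
  lin <- kinetic_parameters(100, 100, Ki = 5, Ki_prime = 10)
  lb <- lineweaver_burk(noiseless_kinetics(lin, I = c(0, 2.5, 5, 10, 25)))
  cls <- classify_secondary(lb)
  expect_identical(cls$slope$verdict, "linear")
  expect_identical(cls$intercept$verdict, "linear")
  par <- kinetic_parameters(100, 100, Ki = 3.69, Ki_prime = 1.45, b = 0.4)
  lbp <- lineweaver_burk(noiseless_kinetics(par, I = c(0, 1, 2, 4, 8)))
  clsp <- classify_secondary(lbp)
  expect_identical(clsp$slope$verdict, "nonlinear")
  # too few inhibitor levels: inconclusive, not an error
  lb3 <- lineweaver_burk(noiseless_kinetics(lin, I = c(0, 5, 10)))
  expect_identical(classify_secondary(lb3)$slope$verdict, "inconclusive")
})

test_that("tertiary replot mapping round-trips the generating constants", {
  par <- kinetic_parameters(100, 100, Ki = 3.69, Ki_prime = 1.45, b = 0.3)
  lb <- lineweaver_burk(noiseless_kinetics(par, I = c(0, 1, 2, 4, 8, 16)))
  est <- tertiary_replot_fit(lb)
  expect_equal(est$Ki, 3.69, tolerance = 0.01)
  expect_equal(est$Ki_prime, 1.45, tolerance = 0.01)
  expect_equal(est$b, 0.3, tolerance = 0.01)
  # b = 0 limit recovers the linear-mixed constants
  lin <- kinetic_parameters(100, 100, Ki = 5, Ki_prime = 10)
  lbl <- lineweaver_burk(noiseless_kinetics(lin, I = c(0, 2.5, 5, 10)))
  estl <- tertiary_replot_fit(lbl)
  expect_equal(estl$Ki, 5, tolerance = 0.01)
  expect_equal(estl$Ki_prime, 10, tolerance = 0.01)
})

test_that("global fit is exact on noiseless data and matches replots", {
  p <- kinetic_parameters(100, 100, Ki = 9.55)
  d <- noiseless_kinetics(p)
  fit <- inhibition_fit(d, model = "pure_noncompetitive")
  expect_equal(unname(coef(fit)["Ki"]), 9.55, tolerance = 1e-7)
  expect_equal(unname(coef(fit)["Vmax"]), 100, tolerance = 1e-7)
  # replot chain and global fit agree exactly on noiseless linear data
  lm_p <- kinetic_parameters(100, 100, Ki = 3.67, Ki_prime = 4.97)
  d2 <- noiseless_kinetics(lm_p)
  fit2 <- inhibition_fit(d2, model = "linear_mixed")
  est3 <- tertiary_replot_fit(lineweaver_burk(d2))
  expect_equal(unname(coef(fit2)["Ki"]), est3$Ki, tolerance = 1e-6)
  expect_equal(unname(coef(fit2)["Ki_prime"]), est3$Ki_prime,
               tolerance = 1e-6)
})

test_that("auto model selection follows the replot diagnostics", {
  lin <- noiseless_kinetics(kinetic_parameters(100, 100, 3.67, 4.97))
  expect_identical(inhibition_fit(lin)$model, "linear_mixed")
  nc <- noiseless_kinetics(kinetic_parameters(100, 100, 9.55))
  expect_identical(inhibition_fit(nc)$model, "pure_noncompetitive")
  par <- noiseless_kinetics(
    kinetic_parameters(100, 100, 3.69, 1.45, b = 0.3),
    I = c(0, 1, 2, 4, 8))
  fitp <- inhibition_fit(par)
  expect_identical(fitp$model, "partial_mixed")
  expect_equal(unname(coef(fitp)["b"]), 0.3, tolerance = 1e-4)
})

test_that("degenerate inputs produce fit errors, not estimates", {
  d <- expand.grid(S = c(10, 20, 40), I = c(0, 5))
  d$v <- 1
  expect_error(inhibition_fit(d), "degenerate")
  one_level <- noiseless_kinetics(kinetic_parameters(100, 100, 5),
                                  I = 0)
  expect_error(inhibition_fit(one_level), "inhibitor levels")
})

test_that("fit methods expose prediction, residuals and simulation", {
  p <- kinetic_parameters(100, 100, 3.67, 4.97)
  d <- gen_kinetic_data(kinetic_generator_spec(p, cv = 0.02, seed = 5))
  fit <- inhibition_fit(d, model = "linear_mixed")
  expect_equal(length(predict(fit)), nrow(d))
  expect_equal(residuals(fit), d$v - predict(fit))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$v, sims[[2]]$v))
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients$std_error)))
})

test_that("percent inhibition and absorbance conversion follow their formulas", {
  expect_equal(percent_inhibition(2, 0), 100)
  expect_equal(percent_inhibition(2, 2), 0)
  expect_equal(percent_inhibition(2.0, 0.109), 94.55)
  expect_warning(pi_neg <- percent_inhibition(1, 1.5), "activation")
  expect_equal(pi_neg, -50)
  expect_equal(activity_from_absorbance(0.0096, 9600, 1, 1e-3), 0.001)
  expect_equal(activity_from_absorbance(0, volume = 1), 0)
  expect_equal(activity_from_absorbance(9.6, 9600, 1, 1), 1000)
  expect_error(activity_from_absorbance(0.1, volume = -1), "positive")
})
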