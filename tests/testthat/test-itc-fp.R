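test_that("ITC isotherm obeys its limits and the equilibrium oracle", {
  geom <- itcExperiment(28e-6, 0.30e-3)
  # KD -> infinity: all heats vanish
  h_inf <- itcIsotherm(1, 1e3, -10, geom)
  expect_lt(max(abs(h_inf)), 1e-4)

  # saturation limit conserves total enthalpy N Mt V0 dH; the residual
  # displaced-volume term is O(v/2V0), so the limit is taken with very
  # small injections of a very concentrated titrant
  geom_s <- itcExperiment(28e-6, 1e4, injectionVolumes = rep(2e-10, 30))
  h_s <- itcIsotherm(1, 1e-12, -10, geom_s)
  total <- sum(h_s) * 1e-6                     # cal
  expect_equal(total, 1 * 28e-6 * 200e-6 * (-10 * 1000),
               tolerance = 1e-6)

  # per-injection heats match a numeric root-finder on the binding
  # polynomial under identical dilution bookkeeping
  N <- 0.97; KD <- 67e-9; dH <- -10
  h <- itcIsotherm(N, KD, dH, geom)
  V0 <- 200e-6
  d <- cumsum(geom@injectionVolumes)
  phi <- 1 / (1 + d / (2 * V0))
  Mt <- 28e-6 * (1 - d / (2 * V0)) * phi
  Xt <- 0.30e-3 * (d / V0) * phi
  MX <- vapply(seq_along(d), function(i) {
    # solve KD = (Xt - MX)(N Mt - MX) / MX for MX in (0, min(Xt, N Mt))
    g <- function(mx) (Xt[i] - mx) * (N * Mt[i] - mx) - KD * mx
    upper <- min(Xt[i], N * Mt[i])
    uniroot(g, c(0, upper), tol = 1e-18)$root
  }, numeric(1))
  Q <- V0 * dH * 1000 * MX
  Qprev <- c(0, Q[-length(Q)])
  v <- geom@injectionVolumes
  dQ <- (Q - Qprev + (v / V0) * (Q + Qprev) / 2) * 1e6
  expect_lt(max(abs(dQ - h) / pmax(abs(h), 1e-9)), 1e-9)
})

test_that("one-set-of-sites fit recovers KD, N and dH", {
  geom <- itcExperiment(28e-6, 0.30e-3)
  h <- itcIsotherm(1, 67e-9, -10, geom)
  fit <- fitItc(itcExperiment(28e-6, 0.30e-3, heats = h))
  expect_equal(fit$KD, 67e-9, tolerance = 5e-3)
  expect_equal(fit$N, 1, tolerance = 5e-3)
  expect_equal(fit$dH, -10, tolerance = 5e-3)
  expect_true(fit$reliable)

  # N = 1 recovered from arbitrary noiseless N = 1 simulations
  set.seed(44)
  for (i in 1:10) {
    kd <- 10^runif(1, -8.5, -6)
    dh <- runif(1, -15, -3)
    hh <- itcIsotherm(1, kd, dh, geom)
    f <- fitItc(itcExperiment(28e-6, 0.30e-3, heats = hh))
    expect_equal(f$N, 1, tolerance = 1e-3)
    expect_equal(f$KD, kd, tolerance = 0.02)
  }

  # 2% heat noise: KD within 30%
  tit <- genTitrations(seed = 9, itcNoiseFrac = 0.02)
  fn <- fitItc(tit$itc)
  expect_lt(abs(fn$KD - tit$truth$itcKd) / tit$truth$itcKd, 0.30)

  # unreliable c-value warns but still returns
  weak <- itcIsotherm(1, 28e-6 / 0.05, -10, geom)
  expect_warning(fw <- fitItc(itcExperiment(28e-6, 0.30e-3, heats = weak)),
                 "c-value")
  expect_false(fw$reliable)
  expect_error(fitItc(geom), "no heats")
})

test_that("depletion-corrected bound fraction matches mass balance", {
  # Lt -> 0 reduces to the receptor hyperbola
  KD <- 2e-7
  Rt <- 10^seq(-9, -5, length.out = 9)
  fb0 <- fpBoundFraction(KD, Rt, 1e-15)
  expect_equal(fb0, Rt / (Rt + KD), tolerance = 1e-6)
  # saturation in receptor
  expect_equal(fpBoundFraction(KD, 1e3, 50e-9), 1, tolerance = 1e-9)
  # quadratic solution vs numeric mass-balance root across a grid
  for (kd in c(1e-8, 3e-7, 5e-6)) for (lt in c(5e-9, 5e-8, 1e-6))
    for (rt in c(1e-8, 1e-6, 1e-4)) {
      fb <- fpBoundFraction(kd, rt, lt)
      g <- function(b) (lt - b * lt) * (rt - b * lt) - kd * b * lt
      num <- uniroot(g, c(0, 1 - 1e-15), tol = 1e-16)$root
      expect_lt(abs(fb - num), 1e-10)
    }
})

test_that("direct FP fit recovers the apparent KD", {
  tit <- genTitrations(seed = 5, fpNoise = 0)
  f0 <- fpDirectFit(tit$fpDirect)
  expect_equal(f0$KD, tit$truth$fpKd, tolerance = 1e-3)
  fn <- fpDirectFit(genTitrations(seed = 5)$fpDirect)
  expect_lt(abs(fn$KD - tit$truth$fpKd) / tit$truth$fpKd, 0.2)
  expect_error(fpDirectFit(fpTitration(c(0, 1e-6), c(60, 200))), ">= 4")
})

test_that("competition cubic matches a numeric equilibrium solver", {
  set.seed(12)
  for (i in 1:25) {
    Rt <- 10^runif(1, -7.5, -5)
    Lt <- 10^runif(1, -8.5, -7)
    It <- 10^runif(1, -8, -4)
    KdT <- 10^runif(1, -8, -6)
    Ki <- 10^runif(1, -8, -5)
    exact <- competitionEquilibrium(Rt, Lt, It, KdT, Ki)$freeReceptor
    num <- 10^uniroot(function(lR) {
      R <- 10^lR
      R * (1 + Lt / (KdT + R) + It / (Ki + R)) - Rt
    }, c(-20, 0), tol = 1e-15)$root
    expect_lt(abs(exact - num) / num, 1e-9)
  }
  # zero competitor reduces to the two-component quadratic
  Rt <- 1e-6; Lt <- 5e-8; KdT <- 3e-7
  eq0 <- competitionEquilibrium(Rt, Lt, 0, KdT, 1e-6)$tracerBoundFraction
  expect_equal(eq0, fpBoundFraction(KdT, Rt, Lt), tolerance = 1e-9)
})

test_that("competitive FP fit recovers the planted KI", {
  tit <- genTitrations(seed = 13)
  fit <- fpCompetitionKi(tit$fpCompetition)
  expect_lt(abs(fit$KI - tit$truth$fpKi) / tit$truth$fpKi, 0.2)
  expect_false(fit$kiLowerBoundOnly)
  # tracer binding without competitor equals the direct-fit prediction
  cv <- tit$fpCompetition
  fb0 <- competitionEquilibrium(cv@receptorConc, cv@tracerConc, 0,
                                cv@tracerKd, fit$KI)$tracerBoundFraction
  expect_equal(fb0, fpBoundFraction(cv@tracerKd, cv@receptorConc,
                                    cv@tracerConc), tolerance = 1e-9)
  # monotonicity: an ever-weaker competitor converges to that signal
  fbs <- vapply(10^seq(-6, 2, by = 2), function(ki)
    competitionEquilibrium(cv@receptorConc, cv@tracerConc,
                           max(cv@competitorConc), cv@tracerKd,
                           ki)$tracerBoundFraction[1], numeric(1))
  expect_true(all(diff(fbs) > -1e-12))
  expect_equal(fbs[length(fbs)], fb0, tolerance = 1e-6)
})

test_that("pull-down Ki honours Cheng-Prusoff and recovers truth", {
  tit <- genTitrations(seed = 21)
  fit <- pulldownKi(tit$pulldown)
  expect_gt(fit$Ki, tit$truth$pdKi / 2)
  expect_lt(fit$Ki, tit$truth$pdKi * 2)
  # on the fitted model, [tracer] = KD_tracer doubles the midpoint
  cv <- tit$pulldown
  expect_equal(fit$IC50, fit$Ki * (1 + cv@tracerConc / cv@tracerKd))
  cv_eq <- competitionCurve(cv@competitorConc, cv@signal, cv@receptorConc,
                            cv@tracerKd, cv@tracerKd)  # tracer at its KD
  expect_equal(pulldownKi(cv_eq)$IC50 / pulldownKi(cv_eq)$Ki, 2)
  # vanishing tracer: IC50 -> Ki
  cv_lo <- competitionCurve(cv@competitorConc, cv@signal, cv@receptorConc,
                            cv@tracerKd * 1e-6, cv@tracerKd)
  expect_equal(pulldownKi(cv_lo)$IC50 / pulldownKi(cv_lo)$Ki, 1,
               tolerance = 1e-5)
  expect_error(pulldownKi(competitionCurve(c(0, 1e-9, 1e-8), c(100, 80, 50),
                                           1e-7, 1e-7, 1e-7)), ">= 4")
})
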