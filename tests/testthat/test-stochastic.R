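test_that("SSA reproduces Poisson birth and exponential death moments", {
  birth <- stochastic_model("X", c(X = 0),
                            list(list(rate = 2, reactants = character(0),
                                      change = c(X = 1))))
  set.seed(1)
  v <- replicate(3000, gillespie_direct(birth, 50, report_dt = 50)$X[2])
  expect_equal(mean(v), 100, tolerance = 0.05)   # Poisson mean = lambda t
  expect_equal(var(v), 100, tolerance = 0.05)    # Poisson variance = mean
  death <- stochastic_model("X", c(X = 200),
                            list(list(rate = 0.05, reactants = "X",
                                      change = c(X = -1))))
  set.seed(2)
  w <- replicate(2000, gillespie_direct(death, 20, report_dt = 20)$X[2])
  expect_equal(mean(w), 200 * exp(-0.05 * 20), tolerance = 0.05)
})

test_that("zero total propensity freezes the state", {
  frozen <- stochastic_model("X", c(X = 7),
                             list(list(rate = 0, reactants = "X",
                                       change = c(X = -1))))
  tr <- gillespie_direct(frozen, 100, report_dt = 10, seed = 1)
  expect_true(all(tr$X == 7))
})

test_that("birth-death stationary distribution is Poisson (chi-square, 1% level)", {
  lambda <- 10  # births/s; deaths at 1/s per molecule -> Poisson(10)
  bd <- stochastic_model("X", c(X = 10),
                         list(list(rate = lambda, reactants = character(0),
                                   change = c(X = 1)),
                              list(rate = 1, reactants = "X",
                                   change = c(X = -1))))
  set.seed(3)
  samples <- replicate(1e4, gillespie_direct(bd, 6, report_dt = 6)$X[2])
  breaks <- c(-0.5, seq(4.5, 15.5), Inf)
  obs <- table(cut(samples, breaks))
  p <- diff(c(0, ppois(c(4:15), lambda), 1))
  chi <- suppressWarnings(chisq.test(as.vector(obs), p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("ensembles are reproducible under a master seed", {
  m <- reporter_stochastic_model(5e-9)
  e1 <- run_ensemble(m, n = 3, t_end = 600, report_dt = 300, seed = 9)
  e2 <- run_ensemble(m, n = 3, t_end = 600, report_dt = 300, seed = 9)
  expect_identical(e1$counts, e2$counts)
  e3 <- run_ensemble(m, n = 3, t_end = 600, report_dt = 300, seed = 10)
  expect_false(identical(e1$counts, e3$counts))
})

test_that("Ste2 QSSA matches the deterministic receptor equilibrium", {
  expect_identical(ste2_qssa(0), 0)
  # saturation plateau: synthesis / bound-receptor degradation
  p <- default_parameters()
  plateau <- p$v_Ste2_production / p$k5 * 1.74638e10
  expect_equal(ste2_qssa(1e-4), plateau, tolerance = 0.01)
  # independent oracle: long integration of the deterministic receptor ODEs
  ss <- steady_state(reporter_cell(), list(alpha = 5e-9))
  count <- concentration_to_count(ss[["Ste2_Ph"]], 29)
  expect_equal(ste2_qssa(5e-9), count, tolerance = 0.001)
})

test_that("hybrid drive: derivative of the fitted count curve, clamped at zero", {
  # constant series -> zero drive
  flat <- structure(data.frame(time_s = seq(0, 3600, 60), Fus3ppn = 50),
                    class = c("trajectory", "data.frame"))
  d0 <- hybrid_drive(flat)
  expect_true(all(d0$v == 0))
  # linear count ramp a + b t -> constant propensity b
  b_counts <- 0.25  # molecules/s
  n_per_nM <- 4.06e-15 * 6.022e23 * 1e-9
  ramp <- structure(data.frame(time_s = seq(0, 3600, 60)),
                    class = c("trajectory", "data.frame"))
  ramp$Fus3ppn <- (5 + b_counts * ramp$time_s) / n_per_nM
  dr <- hybrid_drive(ramp)
  expect_equal(unname(range(dr$v)), c(b_counts, b_counts), tolerance = 1e-6)
  expect_lt(dr$fit_rel_error, 0.01)
})

test_that("IDENTITY-gate drive is silent before the deterministic onset", {
  res <- identity_hybrid()$reporter
  # first Fus3ppn molecules appear several minutes into the run
  expect_gt(res$drive$onset_s, 300)
  expect_lt(res$drive$onset_s, 600)
  expect_lt(res$drive$fit_rel_error, 0.01)
  ens <- res$ensemble
  before <- ens$times < res$drive$onset_s
  expect_true(all(ens$counts[, before, ] == 0))
})

test_that("hybrid ensemble mean GFP tracks the deterministic trajectory", {
  res <- identity_hybrid()$reporter
  ens <- res$ensemble
  det <- res$deterministic$trajectory
  det_counts <- det$reporter.mature_GFP * 1.74638e10 * 1e-9
  for (h in c(1, 2, 4)) {
    i <- which(ens$times == h * 3600)
    v <- ens$counts[, i, "mature_GFP"]
    sem <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - det_counts[det$time_s == h * 3600]), 3 * sem)
  }
})

test_that("hybrid Fus3ppn is a Poisson counting process (CV = 100/sqrt(mean))", {
  ens <- identity_hybrid()$reporter$ensemble
  for (h in c(1, 2, 4)) {
    i <- which(ens$times == h * 3600)
    m <- mean(ens$counts[, i, "Fus3ppn"])
    expect_equal(coefficient_of_variation(ens, "Fus3ppn", h),
                 100 / sqrt(m), tolerance = 0.1)
    # and the variance itself is Poisson
    expect_equal(var(ens$counts[, i, "Fus3ppn"]), m, tolerance = 0.25)
  }
})

test_that("GFP noise decreases over time for a rising-signal gate", {
  cv <- identity_hybrid()$reporter$cv_gfp
  expect_true(all(diff(cv) < 0))  # 1 h > 2 h > 4 h
})

test_that("coefficient of variation handles degenerate ensembles", {
  m <- stochastic_model("X", c(X = 5), list(list(rate = 0, reactants = "X",
                                                 change = c(X = -1))))
  ens <- run_ensemble(m, n = 5, t_end = 3600, report_dt = 3600, seed = 1)
  expect_identical(coefficient_of_variation(ens, "X", 1), 0)   # identical
  m0 <- stochastic_model("X", c(X = 0), list(list(rate = 0, reactants = "X",
                                                  change = c(X = -1))))
  e0 <- run_ensemble(m0, n = 5, t_end = 3600, report_dt = 3600, seed = 1)
  expect_identical(coefficient_of_variation(e0, "X", 1), 0)    # zero mean
  expect_error(coefficient_of_variation(ens, "X", 0.35), "report grid")
})

test_that("slow-species statistics are invariant to the fast-cycle rescaling", {
  # the Fus3 cycle is conditionally linear: uniform rescaling preserves its
  # stationary distribution; compare a 4x rate difference at the 1-h mark
  e1 <- run_ensemble(reporter_stochastic_model(0.5e-9, fast_scale = 500),
                     n = 40, t_end = 3600, seed = 21)
  e2 <- run_ensemble(reporter_stochastic_model(0.5e-9, fast_scale = 2000),
                     n = 40, t_end = 3600, seed = 22)
  i <- which(e1$times == 3600)
  m1 <- mean(e1$counts[, i, "Fus3ppn"]); m2 <- mean(e2$counts[, i, "Fus3ppn"])
  expect_equal(m1, m2, tolerance = 0.05)
  g1 <- mean(e1$counts[, i, "mature_GFP"]); g2 <- mean(e2$counts[, i, "mature_GFP"])
  expect_equal(g1, g2, tolerance = 0.15)  # ~3 sigma at this ensemble size
  r <- coefficient_of_variation(e1, "mature_GFP", 1) /
       coefficient_of_variation(e2, "mature_GFP", 1)
  expect_gt(r, 0.6)
  expect_lt(r, 1.6)
})
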