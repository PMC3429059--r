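test_that("osmostress is the clamped gain-weighted salt excess", {
  expect_equal(osmostress(0.4, 0, 2.39), 0.956)
  expect_identical(osmostress(0.4, 1.0, 2.39), 0)
  expect_identical(osmostress(0, 0, 2.39), 0)
  expect_error(osmostress(-0.1, 0, 2.39))
})

test_that("dilution law: coefficient, halving and density scaling", {
  cc <- culture_config()
  expect_identical(dilution_factor(0, cc), 13800)
  expect_equal(dilution_factor(4, cc), 13800 / 2)
  expect_equal(dilution_factor(8, cc), 13800 / 4)
  expect_equal(culture_config(doubling_h = 2)$dilution_rate, log(2) / 2)
  expect_error(dilution_factor(-1, cc), "negative")
  # coefficient scales inversely with the initial density
  expect_equal(dilution_factor(0, culture_config(density = 1e7)), 6900)
  expect_equal(dilution_factor(0, culture_config(density = 1e6)), 69000)
})

test_that("all-zero state with no stimulus is a fixed point of every cell", {
  inputs <- list(NaCl = 0, DOX = 0, Gal = 0, alpha = 0)
  for (model in list(salt_cell(), gal_cell(precultured = TRUE))) {
    zero <- stats::setNames(numeric(length(model$species)), model$species)
    d <- model$rhs(0, zero, inputs)
    expect_true(all(d == 0), label = model$name)
  }
  # the reporter keeps synthesising receptor even from an empty state
  rep <- reporter_cell()
  zero <- stats::setNames(numeric(length(rep$species)), rep$species)
  dr <- rep$rhs(0, zero, inputs)
  expect_gt(dr[["Ste2"]], 0)
  expect_true(all(dr[setdiff(rep$species, "Ste2")] == 0))
  # the dox-cell is constitutive: transcription fires even from zero
  dz <- dox_cell()$rhs(0, c(MFalpha1_mRNA = 0, prepro_Alpha = 0,
                            Alpha_in_medium = 0), inputs)
  expect_gt(dz[["MFalpha1_mRNA"]], 0)
})

test_that("kinase pools are conserved by the model equations at any state", {
  set.seed(42)
  geom <- cell_geometry()
  vc <- geom$v_cyt
  vn <- geom$v_nuc
  salt <- salt_cell()
  rep <- reporter_cell()
  for (i in 1:25) {
    s <- stats::setNames(stats::runif(10, 0, 1e-6), salt$species)
    d <- salt$rhs(0, s, list(NaCl = stats::runif(1, 0, 0.8), DOX = 0,
                             Gal = 0, alpha = 0))
    hog1 <- (d[["Hog1c"]] + d[["Hog1ppc"]]) * vc +
            (d[["Hog1n"]] + d[["Hog1ppn"]]) * vn
    expect_equal(hog1, 0, tolerance = 1e-12)
    expect_equal(d[["Pbs2"]] + d[["Pbs2pp"]], 0, tolerance = 1e-12)

    r <- stats::setNames(stats::runif(11, 0, 1e-6), rep$species)
    dr <- rep$rhs(0, r, list(alpha = stats::runif(1, 0, 1e-8)))
    fus3 <- (dr[["Fus3c"]] + dr[["Fus3ppc"]]) * vc +
            (dr[["Fus3n"]] + dr[["Fus3ppn"]]) * vn
    expect_equal(fus3, 0, tolerance = 1e-12)
    expect_equal(dr[["inactive_Ste5complex"]] + dr[["active_Ste5complex"]], 0,
                 tolerance = 1e-12)
  }
})

test_that("sender expression modules hit their closed-form steady states", {
  ref <- table4_reference()
  p <- default_parameters()
  # closed forms: mRNA_ss = transcription/k31_deg, prepro_ss = k32 mRNA/k33
  expect_equal(p$k38 / p$k31_deg * 1e9, ref$dox[["MFalpha1_mRNA"]],
               tolerance = 1e-3)
  expect_equal(p$k37 * gal_to_canonical(2) / p$k31_deg * 1e9,
               ref$gal[["MFalpha1_mRNA"]], tolerance = 1e-3)
  # and the 16-h integration reaches them
  tr <- simulate_cell(dox_cell(), list(DOX = 0), hours = 16)
  fin <- tr[nrow(tr), ]
  expect_equal(fin$MFalpha1_mRNA, ref$dox[["MFalpha1_mRNA"]],
               tolerance = 0.01)
  expect_equal(fin$prepro_Alpha, ref$dox[["prepro_Alpha"]], tolerance = 0.01)
})

test_that("doxycycline represses and galactose induction obeys the 3-h delay", {
  p <- default_parameters()
  # strong doxycycline shuts transcription down (limit of the Tet-Off term)
  rate0 <- p$k38
  rate10 <- p$k38 / (1 + p$Ki38 * dox_to_canonical(10))
  expect_lt(rate10 / rate0, 0.005)
  # no preculture: zero transcription before 3 h, active afterwards
  tr <- simulate_cell(gal_cell(precultured = FALSE),
                      list(Gal = gal_to_canonical(2)), hours = 5)
  expect_equal(tr$MFalpha1_mRNA[tr$time_s == 2 * 3600], 0)
  expect_gt(tr$MFalpha1_mRNA[tr$time_s == 4 * 3600], 0)
  # without galactose the mRNA pool decays at k31_deg
  g <- gal_cell(precultured = TRUE)
  g$initial["MFalpha1_mRNA"] <- 1e-9
  tr0 <- simulate_cell(g, list(Gal = 0), hours = 1)
  expect_equal(tr0$MFalpha1_mRNA[tr0$time_s == 3600],
               1 * exp(-p$k31_deg * 3600), tolerance = 1e-4)
})

test_that("unstimulated reporter rests at its documented basal state", {
  p <- default_parameters()
  # receptor balance: synthesis rate equals basal Ste2 times its turnover
  expect_equal(p$v_Ste2_production / p$k4 * 1e9, 378, tolerance = 0.001)
  ss <- steady_state(reporter_cell(), list(alpha = 0))
  expect_equal(ss[["Ste2"]], 378, tolerance = 0.001)
  # nuclear/cytoplasmic Fus3 partition
  expect_equal(ss[["Fus3n"]] / ss[["Fus3c"]], 1.4, tolerance = 0.001)
  # pure accumulators are excluded from the steady state
  expect_true(is.na(ss[["mature_GFP"]]))
})
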