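test_that("pre-culture conditioning reproduces the standard initial pools", {
  ref <- table4_reference()
  pc <- precondition(gate_spec("implies"))
  expect_equal(pc$gal[["MFalpha1_mRNA"]] * 1e9, ref$gal[["MFalpha1_mRNA"]],
               tolerance = 0.01)
  expect_equal(pc$gal[["prepro_Alpha"]] * 1e9, ref$gal[["prepro_Alpha"]],
               tolerance = 0.01)
  expect_equal(pc$dox[["MFalpha1_mRNA"]] * 1e9, ref$dox[["MFalpha1_mRNA"]],
               tolerance = 0.01)
  expect_equal(pc$dox[["prepro_Alpha"]] * 1e9, ref$dox[["prepro_Alpha"]],
               tolerance = 0.01)
  # media exchange always removes extracellular alpha
  expect_identical(pc$gal[["Alpha_in_medium"]], 0)
})

test_that("pre-culture modes: zero reset, handling decay, salt no-op", {
  g <- gate_spec("not")
  z <- precondition(g, mode = "zero")
  expect_identical(unname(z$dox[c("MFalpha1_mRNA", "prepro_Alpha")]), c(0, 0))
  p <- default_parameters()
  full <- precondition(g)
  delayed <- precondition(g, handling_delay_min = 15)
  expect_equal(delayed$dox[["MFalpha1_mRNA"]],
               full$dox[["MFalpha1_mRNA"]] * exp(-p$k31_deg * 900))
  expect_equal(delayed$dox[["prepro_Alpha"]],
               full$dox[["prepro_Alpha"]] * exp(-p$k33 * 900))
  expect_warning(precondition(gate_spec("identity")), "no-op")
})

test_that("IDENTITY gate: no stimulus means no GFP; dose response is monotone", {
  g <- gate_spec("identity")
  run0 <- run_gate(g, list(nacl_M = 0))
  expect_false(run0$verdict[["reporter"]])
  expect_lt(run0$gfp_uM[["reporter"]], 1e-12)
  gfp <- vapply(c(0, 0.1, 0.2, 0.4, 0.6), function(s)
    run_gate(g, list(nacl_M = s))$gfp_uM[["reporter"]], numeric(1))
  expect_true(all(diff(gfp) > 0))
})

test_that("NOT gate: pre-accumulated pools leak GFP, zero-reset removes it", {
  g <- gate_spec("not")
  hi <- run_gate(g, list(dox_ug_ml = 10))
  expect_gt(hi$gfp_uM[["reporter"]], 2)       # leaks over 2 uM GFP
  expect_false(hi$verdict[["reporter"]])      # but stays below threshold
  lo <- run_gate(g, list(dox_ug_ml = 0))
  expect_true(lo$verdict[["reporter"]])
  # NOT output is non-increasing in doxycycline
  gfp <- vapply(c(0, 0.1, 1, 10), function(d)
    run_gate(g, list(dox_ug_ml = d))$gfp_uM[["reporter"]], numeric(1))
  expect_true(all(diff(gfp) < 0))
  zero <- run_gate(g, list(dox_ug_ml = 10), preculture = list(mode = "zero"))
  expect_lt(zero$gfp_uM[["reporter"]], 0.1)
})

test_that("two-input truth tables match the gate logic", {
  tt_or <- truth_table(gate_spec("or"),
                       list(nacl_M = c(0, 0.4), gal_percent = c(0, 2)))
  expect_identical(tt_or$positive, c(FALSE, TRUE, TRUE, TRUE))
  tt_imp <- truth_table(gate_spec("implies"),
                        list(dox_ug_ml = c(0, 10), gal_percent = c(0, 2)))
  expect_identical(tt_imp$positive, c(TRUE, FALSE, TRUE, TRUE))
  # glucose relabeling turns the same assembly into NAND
  tt_nand <- truth_table(gate_spec("nand"),
                         list(dox_ug_ml = c(0, 10), glucose = c(0, 1)))
  expect_identical(tt_nand$positive, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("sender fluxes superpose in the shared medium", {
  or <- gate_spec("or")
  both <- run_gate(or, list(nacl_M = 0.4, gal_percent = 2))$trajectory
  salt_only <- run_gate(or, list(nacl_M = 0.4, gal_percent = 0))$trajectory
  gal_only <- run_gate(or, list(nacl_M = 0, gal_percent = 2))$trajectory
  expect_true(all(both$Alpha_in_medium >=
                  salt_only$Alpha_in_medium - 1e-12))
  expect_true(all(both$Alpha_in_medium >= gal_only$Alpha_in_medium - 1e-12))
})

test_that("halving the culture density halves the initial alpha export rate", {
  mk <- function(density) {
    gate_spec("not", culture = culture_config(density = density))
  }
  slope <- function(gate) {
    tr <- run_gate(gate, list(dox_ug_ml = 0), hours = 0.1)$trajectory
    tr$Alpha_in_medium[2] / tr$time_s[2]
  }
  s_half <- slope(mk(2.5e6))
  s_ref <- slope(mk(5e6))
  expect_equal(s_half / s_ref, 0.5, tolerance = 0.01)
})

test_that("doubling time only reshapes the dilution decay, not its start", {
  fast <- gate_spec("identity", culture = culture_config(doubling_h = 2))
  slow <- gate_spec("identity", culture = culture_config(doubling_h = 6))
  expect_identical(dilution_factor(0, fast$culture),
                   dilution_factor(0, slow$culture))
  expect_gt(dilution_factor(4, slow$culture), dilution_factor(4, fast$culture))
})

test_that("verdict is monotone in the GFP threshold", {
  run <- identity_run_6h()
  gfp <- run$gfp_uM[["reporter"]]
  for (thr in c(1, 4.5, 10)) {
    g <- gate_spec("identity", threshold_uM = thr)
    expect_identical(gfp >= thr, unname((gfp >= g$threshold_uM)))
  }
  lo <- run_gate(gate_spec("identity", threshold_uM = 0.5),
                 list(nacl_M = 0.4))
  hi <- run_gate(gate_spec("identity", threshold_uM = 20),
                 list(nacl_M = 0.4))
  expect_true(lo$verdict[["reporter"]])
  expect_false(hi$verdict[["reporter"]])
})

test_that("three-value gate separates low and high salt at the 5-h readout", {
  tv <- three_value_gate()
  expect_identical(tv$positive.reporter_wt, c(FALSE, TRUE, TRUE))
  expect_identical(tv$positive.reporter_mut, c(FALSE, FALSE, TRUE))
  # the mutant receptor responds strictly more slowly
  expect_true(all(tv$gfp_uM.reporter_mut[-1] < tv$gfp_uM.reporter_wt[-1]))
})

test_that("without pre-culture the gal-cell contributes only after 3 h", {
  g <- gate_spec("or")
  tr <- run_gate(g, list(nacl_M = 0, gal_percent = 2),
                 preculture = list(mode = "none"))$trajectory
  expect_true(all(tr$gal.MFalpha1_mRNA[tr$time_s < 3 * 3600] == 0))
  expect_gt(tr$gal.MFalpha1_mRNA[tr$time_s == 4 * 3600], 0)
  # one hour of induction produces far less GFP than an overnight pre-culture
  pre <- run_gate(g, list(nacl_M = 0, gal_percent = 2))
  expect_lt(tr$reporter.mature_GFP[tr$time_s == 14400] / 1000,
            0.2 * pre$gfp_uM[["reporter"]])
})

test_that("unknown gates and inputs are rejected", {
  expect_error(gate_spec("xor"))
  expect_error(run_gate(gate_spec("identity"), list(dox_ug_ml = 1)),
               "unknown input")
})
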