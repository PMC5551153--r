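test_that("theoretical volume applies the uL/cm2 x m2 unit bridge", {
  expect_equal(theoretical_volume(3.41, 129.72, 555.56, 0.8), 1966.1,
               tolerance = 1e-4)
  expect_equal(theoretical_volume(1.0, 100, 100, 1.0), 100)
  expect_error(theoretical_volume(0, 100, 100, 1), "positive")
  expect_error(theoretical_volume(1, 100, 100, 0), "positive")
})

test_that("recommended volume inflates by the application efficiency", {
  expect_equal(recommended_volume(1966.1, 0.6), 3276.8, tolerance = 1e-4)
  expect_equal(recommended_volume(100, 1.0), 100)
  expect_equal(recommended_volume(60, 0.6), 100)
  expect_error(recommended_volume(100, 0), "positive")
  expect_error(dose_constants(f_E = 1.5), "\\(0, 1\\]")
})

test_that("hedged rows give a single recommendation, gapped rows two", {
  rec <- recommend(p1_geometry(), "medium", "normal",
                   target = "California red scale", product = "chlorpyrifos")
  expect_null(rec$v_r2)
  expect_null(rec$sensor_savings_pct)
  expect_true("check_label" %in% rec$warnings)
  # full hand-chain: N = 555.56, VT1 = 17.527, S = 64.85, S_W = 129.70,
  # V = 3.41 * 129.70 * 0.01 * 0.8 * 555.56 = 1965.7, V_R = V / 0.6
  expect_equal(rec$v_r1, 3276, tolerance = 1e-3)

  g5 <- orchard_geometry(1.99, 2.93, 1.96, sp_tree = 2, sp_row = 6)
  r5 <- recommend(g5, "medium", "normal",
                  target = "California red scale", product = "chlorpyrifos")
  expect_false(is.null(r5$v_r2))
  expect_gte(r5$v_r2, r5$v_r1)
  expect_equal(r5$sensor_savings_pct, 100 * (1 - 1.96 / 2.0))

  # boundary d_along = sp_tree stays in case 1
  gb <- orchard_geometry(1.99, 2.93, 2.0, sp_tree = 2, sp_row = 6)
  rb <- recommend(gb, "medium", "normal",
                  target = "California red scale", product = "chlorpyrifos")
  expect_null(rb$v_r2)
})

test_that("target and product advisories propagate into the recommendation", {
  rec <- recommend(p1_geometry(), "medium", "normal",
                   target = "Foot rot and gummosis", product = "mineral oil")
  expect_true(all(c("check_label", "trunk_application") %in% rec$warnings))
  expect_equal(rec$trace$target$f_target, 0.75)
  expect_equal(rec$trace$product$deposit_ul_cm2, 4.72)
})

test_that("a cultivar name resolves to its density group in recommend()", {
  by_group <- recommend(p1_geometry(), "medium", "normal",
                        target = "Thrips", product = "abamectin")
  by_cultivar <- recommend(p1_geometry(), "Clemenules", "normal",
                           target = "Thrips", product = "abamectin")
  expect_equal(by_cultivar$v_r1, by_group$v_r1)
})

test_that("sensor savings equal the closed form 1 - d_along/sp_tree", {
  set.seed(7)
  n_checked <- 0
  for (i in 1:40) {
    g <- random_geometry()
    rec <- recommend(g, "medium", "normal",
                     target = "California red scale", product = "chlorpyrifos")
    if (!is.null(rec$v_r2)) {
      expect_equal(rec$sensor_savings_pct, 100 * (1 - g$d_along / g$sp_tree),
                   tolerance = 1e-9)
      n_checked <- n_checked + 1
    } else {
      expect_gte(g$d_along, g$sp_tree)
    }
  }
  expect_gt(n_checked, 5)
})

test_that("the recommendation is linear in deposit, LAD, f_target and density", {
  set.seed(11)
  for (i in 1:10) {
    g <- random_geometry()
    base <- recommend(g, target = "California red scale",
                      product = "contact", lad = 3.7)$v_r1
    # doubling the deposit: suffocating is 4.72/3.41 times contact
    expect_equal(
      recommend(g, target = "California red scale", product = "suffocating",
                lad = 3.7)$v_r1,
      base * 4.72 / 3.41)
    # doubling LAD
    expect_equal(
      recommend(g, target = "California red scale", product = "contact",
                lad = 7.4)$v_r1,
      2 * base)
    # f_target scales linearly: intermediate is 0.75 of internal
    expect_equal(
      recommend(g, target = "Thrips", product = "contact", lad = 3.7)$v_r1,
      0.75 * base)
    # halving both spacings quadruples density and the rate
    g2 <- orchard_geometry(g$h, g$d_across, g$d_along,
                           g$sp_tree / 2, g$sp_row / 2)
    expect_equal(
      recommend(g2, target = "California red scale", product = "contact",
                lad = 3.7)$v_r1,
      4 * base)
  }
})

test_that("the deposit is recoverable from the recommendation by inversion", {
  set.seed(23)
  for (i in 1:10) {
    g <- random_geometry()
    lad <- runif(1, 2.5, 5)
    rec <- recommend(g, target = "California red scale", product = "contact",
                     lad = lad)
    tr <- rec$trace
    d_back <- rec$v_r1 * tr$constants$f_E /
      (tr$s_w1 * 0.01 * tr$constants$f_lab_field * tr$n_trees)
    expect_equal(d_back, 3.41, tolerance = 1e-9)
  }
})
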