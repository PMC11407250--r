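# Absorption / scattering models and property assignment.

test_that("static absorption matches a term-by-term hand evaluation", {
  tab <- load_chromophores()
  row <- tab[tab$wavelength_nm == 800, ]
  fat <- default_tissue_params()$maternal_fat
  # independent evaluation of the five-term mixture, straight off the table
  byhand <- 12.2 * 0.75 * row$eps_HbO + 12.2 * 0.25 * row$eps_Hb +
    0.23 * row$mua_water + 0.72 * row$mua_fat + 0 * row$mua_melanin
  expect_equal(mua_static(fat, 800), byhand, tolerance = 1e-12)

  # degenerate limits
  none <- list(HbT = 0, StO2 = 0.5, Vwater = 0, Vfat = 0, Vmelanin = 0)
  expect_equal(mua_static(none, 780), 0)
  pure <- list(HbT = 10, StO2 = 1, Vwater = 0, Vfat = 0, Vmelanin = 0)
  expect_equal(mua_static(pure, 780),
               10 * chromophores_at(780)$eps_HbO, tolerance = 1e-12)
})

test_that("static absorption is linear in HbT with the saturation-mixed slope", {
  ch <- chromophores_at(810)
  slope <- 0.6 * ch$eps_HbO + 0.4 * ch$eps_Hb
  base <- list(HbT = 0, StO2 = 0.6, Vwater = 0.5, Vfat = 0, Vmelanin = 0)
  for (hbt in c(5, 20, 80)) {
    p <- base; p$HbT <- hbt
    expect_equal(mua_static(p, 810) - mua_static(base, 810), hbt * slope,
                 tolerance = 1e-12)
  }
})

test_that("pulsatile absorption: compartments, Vp limit and difference", {
  brain <- default_tissue_params()$fetal_brain
  # Vp = 0: systole == diastole exactly
  b0 <- brain; b0$Vp <- 0
  expect_identical(mua_pulsatile(b0, 770, "systole"),
                   mua_pulsatile(b0, 770, "diastole"))
  # difference equals Vp * (HbO_a*epsHbO + Hb_a*epsHb), brute recomputation
  ch <- chromophores_at(770)
  hbo_a <- brain$HbT * brain$Va * brain$SaO2
  hb_a <- brain$HbT * brain$Va * (1 - brain$SaO2)
  dmua <- mua_pulsatile(brain, 770, "systole") - mua_pulsatile(brain, 770, "diastole")
  expect_equal(dmua, brain$Vp * (hbo_a * ch$eps_HbO + hb_a * ch$eps_Hb),
               tolerance = 1e-12)
  expect_gt(dmua, 0)
  # Va = 0 reduces to venous + background
  bv <- brain; bv$Va <- 0; bv$Vv <- 1
  expect_equal(mua_pulsatile(bv, 770, "diastole"),
               brain$HbT * brain$SvO2 * ch$eps_HbO +
                 brain$HbT * (1 - brain$SvO2) * ch$eps_Hb +
                 brain$Vwater * ch$mua_water, tolerance = 1e-12)
  expect_error(mua_pulsatile(list(HbT = 10), 770), "missing fetal parameters")
})

test_that("reduced scattering follows the 500 nm power law", {
  expect_equal(musp_power_law(9.69, 0.81, 500), 9.69)
  expect_equal(musp_power_law(9.69, 0.81, 730), 9.69 * (730 / 500)^(-0.81),
               tolerance = 1e-12)
  expect_equal(musp_power_law(7, 0, 850), 7)
  expect_error(musp_power_law(-1, 0.8, 700), "positive")
  # spectral shape: decreasing in wavelength for every non-fluid tissue
  for (p in default_tissue_params()) {
    if (identical(p$kind, "fluid")) next
    expect_gt(musp_power_law(p$a, p$b, 730), musp_power_law(p$a, p$b, 850))
  }
})

test_that("property assignment: fluid rule, pulsation locality, positivity", {
  mesh <- tiny_phantom()
  lams <- seq(730, 850, by = 20)
  for (lam in c(730, 850)) {
    pf <- assign_properties(mesh, lam, "diastole")
    csf <- mesh$labels == "fetal_csf"
    expect_equal(unique(pf$mua[csf]), chromophores_at(lam)$mua_water)
    expect_equal(unique(pf$musp[csf]), 0.1)
    expect_equal(unique(pf$n[csf]), 1.33)
    expect_equal(unique(pf$n[mesh$labels == "maternal_fat"]), 1.4)
    expect_equal(unique(pf$n[mesh$labels == "fetal_brain"]), 1.3)
  }
  dia <- assign_properties(mesh, 770, "diastole")
  sys <- assign_properties(mesh, 770, "systole")
  changed <- dia$mua != sys$mua
  pulsed <- mesh$labels %in% c("fetal_brain", "fetal_muscle")
  expect_true(all(changed == pulsed))
  expect_true(all(sys$mua >= dia$mua))
  for (lam in lams) {
    pf <- assign_properties(mesh, lam)
    expect_true(all(pf$kappa > 0))
    # qualitative spectral ordering: fetal brain absorbs more than fat
    expect_gt(unique(pf$mua[mesh$labels == "fetal_brain"]),
              unique(pf$mua[mesh$labels == "maternal_fat"]))
  }
  expect_error(assign_properties(mesh, 650), "outside")
})
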