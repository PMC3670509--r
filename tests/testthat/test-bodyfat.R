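# Body-fat estimation battery ------------------------------------------------

test_that("Siri conversion matches its closed form and guards its domain", {
  expect_equal(siri_percent_fat(1.1), 0)
  expect_equal(siri_percent_fat(1.05), (4.95 / 1.05 - 4.5) * 100,
               tolerance = 1e-12)
  expect_equal(siri_percent_fat(0.99), 50) # 4.95/0.99 = 5 exactly
  expect_error(siri_percent_fat(0.9), "lower physiological bound",
               class = "adipoquant_domain_error")
  expect_error(siri_percent_fat(1.2), "upper physiological bound",
               class = "adipoquant_domain_error")
  # round trip density -> %BF -> density over the physiological range
  d <- seq(0.991, 1.19, by = 0.001)
  expect_equal(4.95 / (siri_percent_fat(d) / 100 + 4.5), d, tolerance = 1e-9)
})

test_that("four-fold densitometry selects age/sex coefficient sets", {
  m <- eq1_durnin(make_subject(age = 15.5, biceps = 5, triceps = 5,
                               suprailiac = 5, subscapular = 5))
  expect_equal(m$density, 1.1533 - 0.0643 * log10(20), tolerance = 1e-12)
  expect_equal(m$percent_fat, 12.7708899835, tolerance = 1e-8)

  f <- eq1_durnin(make_subject(sex = "female", age = 17.2, biceps = 5,
                               triceps = 5, suprailiac = 5, subscapular = 5))
  expect_equal(f$density, 1.1549 - 0.0678 * log10(20), tolerance = 1e-12)
  expect_equal(f$percent_fat, 14.0522765104, tolerance = 1e-8)

  # algebraic inversion: the fold sum at which density is exactly 1.0
  s4 <- 10^((1.1533 - 1.0) / 0.0643)
  inv <- eq1_durnin(make_subject(age = 15, biceps = s4 / 4, triceps = s4 / 4,
                                 suprailiac = s4 / 4, subscapular = s4 / 4))
  expect_equal(inv$density, 1.0, tolerance = 1e-12)
  expect_equal(inv$percent_fat, 45.0, tolerance = 1e-9)

  expect_error(eq1_durnin(make_subject(age = 14.2)), "unsupported age",
               class = "adipoquant_skip_error")
  expect_error(eq1_durnin(make_subject(triceps = NA)),
               "missing measurement: triceps",
               class = "adipoquant_skip_error")
})

test_that("triceps+subscapular quadratics keep their printed sex offsets", {
  expect_equal(eq2_boileau(make_subject(triceps = 10, subscapular = 10))$percent_fat,
               17.8, tolerance = 1e-12)
  expect_equal(eq2_boileau(make_subject(sex = "female", triceps = 10,
                                        subscapular = 10))$percent_fat,
               19.8, tolerance = 1e-12)
  # constant sex offset across the input range
  for (t in c(5, 12, 20)) {
    d <- eq2_boileau(make_subject(sex = "female", triceps = t))$percent_fat -
      eq2_boileau(make_subject(triceps = t))$percent_fat
    expect_equal(d, 2.0, tolerance = 1e-12)
  }
})

test_that("triceps+calf linear forms evaluate as printed", {
  expect_equal(eq3_slaughter_tc(make_subject(triceps = 10, calf = 10))$percent_fat,
               15.7, tolerance = 1e-12)
  expect_equal(eq3_slaughter_tc(make_subject(sex = "female", triceps = 10,
                                             calf = 10))$percent_fat,
               17.3, tolerance = 1e-12)
})

test_that("the 35 mm switch and maturation/race intercepts behave as documented", {
  expect_equal(eq4_slaughter_ts(make_subject(triceps = 10,
                                             subscapular = 10))$percent_fat,
               1.21 * 20 - 0.008 * 400 - 5.5, tolerance = 1e-12)
  expect_equal(eq4_slaughter_ts(make_subject(sex = "female", triceps = 20,
                                             subscapular = 20))$percent_fat,
               0.546 * 40 + 9.7, tolerance = 1e-12)
  # black vs white postpubescent male: intercept difference exactly -1.3
  d <- eq4_slaughter_ts(make_subject(race = "nonwhite"))$percent_fat -
    eq4_slaughter_ts(make_subject(race = "white"))$percent_fat
  expect_equal(d, -1.3, tolerance = 1e-12)
  # the switch is discontinuous; exactly 35 mm goes to the quadratic branch
  at35 <- eq4_slaughter_ts(make_subject(triceps = 17.5, subscapular = 17.5))
  expect_equal(at35$percent_fat, 1.21 * 35 - 0.008 * 35^2 - 5.5,
               tolerance = 1e-12)
  above <- eq4_slaughter_ts(make_subject(triceps = 17.6, subscapular = 17.5))
  expect_equal(above$percent_fat, 0.783 * 35.1 + 1.6, tolerance = 1e-12)
  expect_gt(abs(above$percent_fat - at35$percent_fat), 1) # documented jump
  # male low-sum branch needs maturation and race
  expect_error(eq4_slaughter_ts(make_subject(maturation = NA)),
               "missing covariate", class = "adipoquant_skip_error")
})

test_that("age-adjusted densitometry follows the reconstructed reading", {
  # at the male age anchor the age terms vanish
  s <- make_subject(age = 2, biceps = 5, triceps = 5, suprailiac = 5,
                    subscapular = 5)
  m <- suppressWarnings(eq5_weststrate(s)) # age-window soft warning expected
  d <- 1.1315 - 0.0719 * log10(20)
  expect_equal(m$density, d, tolerance = 1e-12)
  expect_equal(m$percent_fat, 562 / d - 525, tolerance = 1e-9)

  m17 <- eq5_weststrate(make_subject(age = 17, biceps = 5, triceps = 5,
                                     suprailiac = 5, subscapular = 5))
  expect_equal(m17$density, 1.07666521327, tolerance = 1e-8)
  expect_equal(m17$percent_fat, 8.96811789636, tolerance = 1e-8)

  # %BF strictly increases with the fold sum at fixed age
  pf <- vapply(seq(4, 40, by = 2), function(x) {
    eq5_weststrate(make_subject(age = 17, biceps = x, triceps = x,
                                suprailiac = x, subscapular = x))$percent_fat
  }, numeric(1))
  expect_true(all(diff(pf) > 0))

  # the female density footnote variants differ and are both available
  f <- make_subject(sex = "female", age = 17)
  printed <- eq5_weststrate(f)$percent_fat
  age10 <- eq5_weststrate(f, eq5_female_density_variant = "age10")$percent_fat
  expect_false(isTRUE(all.equal(printed, age10)))
})

test_that("fat-free-mass predictions derive percent fat by mass difference", {
  m <- eq6_guo(make_subject(weight = 60, calf = 10, midaxillary = 8,
                            brachial_perimeter = 25 + pi * 10 / 10,
                            triceps = 10, height = 170, resistance = 500))
  # arm muscle circumference = 25 cm by construction
  expect_equal(m$ffm, 52.5598, tolerance = 1e-9)
  expect_equal(m$percent_fat, 12.4003333333, tolerance = 1e-8)

  f <- eq6_guo(make_subject(sex = "female", weight = 55, calf = 12,
                            midaxillary = 10, triceps = 14, subscapular = 12,
                            height = 160, resistance = 600))
  expect_equal(f$ffm, 41.5533333333, tolerance = 1e-8)
  expect_equal(f$percent_fat, 24.4484848485, tolerance = 1e-8)

  h <- eq9_houtkooper(make_subject(weight = 60, height = 170, resistance = 500))
  expect_equal(h$ffm, 51.568, tolerance = 1e-12)
  expect_equal(h$percent_fat, 14.0533333333, tolerance = 1e-8)

  # at fixed height^2/R, heavier subjects carry proportionally more fat
  pf <- vapply(seq(50, 90, by = 5), function(w) {
    eq9_houtkooper(make_subject(weight = w))$percent_fat
  }, numeric(1))
  expect_true(all(diff(pf) > 0))

  expect_error(eq9_houtkooper(make_subject(resistance = NA)),
               "missing measurement: resistance",
               class = "adipoquant_skip_error")
})

test_that("log-sum and BMI regressions evaluate as printed", {
  expect_equal(eq7_deurenberg90(make_subject(biceps = 25, triceps = 25,
                                             suprailiac = 25,
                                             subscapular = 25))$percent_fat,
               22.18, tolerance = 1e-12)
  low <- eq7_deurenberg90(make_subject(sex = "female", biceps = 2.5,
                                       triceps = 2.5, suprailiac = 2.5,
                                       subscapular = 2.5))
  expect_equal(low$percent_fat, -4.47, tolerance = 1e-12)
  expect_true(low$out_of_range)
  s4 <- 10^(15.58 / 18.88)
  expect_equal(eq7_deurenberg90(make_subject(biceps = s4 / 4, triceps = s4 / 4,
                                             suprailiac = s4 / 4,
                                             subscapular = s4 / 4))$percent_fat,
               0, tolerance = 1e-9)

  # BMI 21.2 constructed from weight and height
  s <- make_subject(age = 17, height = 160, weight = 21.2 * 1.6^2)
  expect_equal(eq8_deurenberg91(s)$percent_fat, 13.15, tolerance = 1e-9)
  sf <- make_subject(sex = "female", age = 17, height = 160,
                     weight = 21.2 * 1.6^2)
  expect_equal(eq8_deurenberg91(sf)$percent_fat, 23.95, tolerance = 1e-9)
  expect_equal(eq8_deurenberg91(s)$percent_fat -
                 eq8_deurenberg91(sf)$percent_fat, -10.8, tolerance = 1e-12)
})

test_that("fat-mass regressions respect sex-by-race forms and identities", {
  wm <- eq10_ellis(make_subject(weight = 60, age = 17))
  expect_equal(wm$fat_mass, 8.04, tolerance = 1e-9)
  expect_equal(wm$percent_fat, 13.4, tolerance = 1e-9)
  wf <- eq10_ellis(make_subject(sex = "female", weight = 55, height = 160,
                                age = 17))
  expect_equal(wf$fat_mass, 14.788, tolerance = 1e-9)
  expect_equal(wf$percent_fat, 26.8872727273, tolerance = 1e-8)
  # %BF * weight / 100 recovers the fat mass exactly
  expect_equal(wf$percent_fat * 55 / 100, wf$fat_mass, tolerance = 1e-12)
  expect_error(eq10_ellis(make_subject(race = NA)), "missing covariate: race",
               class = "adipoquant_skip_error")
})

test_that("the horizontal-device estimate is a configurable FFM binding", {
  s <- make_subject()
  b <- bia1_percent_fat(s)
  expect_equal(b$percent_fat, eq9_houtkooper(s)$percent_fat)
  expect_equal(b$ffm, eq9_houtkooper(s)$ffm)
  b6 <- bia1_percent_fat(s, bia1_equation = "EQ6")
  expect_equal(b6$percent_fat, eq6_guo(s)$percent_fat)
})

test_that("the battery reports structured skips and stable ordering", {
  s <- make_subject()
  est <- evaluate_battery(s)
  expect_equal(nrow(est), 12)
  expect_equal(est$method, bf_methods())
  expect_true(all(is.na(est$skip_reason)))

  # a record lacking resistance skips exactly the resistance-based methods
  s2 <- make_subject(resistance = NA)
  est2 <- evaluate_battery(s2)
  skipped <- est2$method[!is.na(est2$skip_reason)]
  expect_setequal(skipped, c("EQ6", "EQ9", "BIA1"))
  expect_match(est2$skip_reason[est2$method == "EQ9"],
               "missing measurement: resistance")
  expect_error(evaluate_battery(s2, strict = TRUE),
               class = "adipoquant_skip_error")

  # determinism and usage errors
  expect_identical(evaluate_battery(s), evaluate_battery(s))
  expect_error(evaluate_battery(s, methods = character(0)),
               class = "adipoquant_usage_error")
  expect_error(evaluate_battery(s, methods = "EQ99"),
               class = "adipoquant_usage_error")
})

test_that("excess-fat classification uses inclusive sex-specific thresholds", {
  expect_false(classify_excess_fat(0, "male"))
  expect_true(classify_excess_fat(99, "male"))
  expect_true(classify_excess_fat(20, "male"))
  expect_false(classify_excess_fat(19.999, "male"))
  expect_true(classify_excess_fat(25, "female"))
  expect_false(classify_excess_fat(24.9, "female"))
  expect_true(classify_excess_fat(30, "female", c(male = 20, female = 30)))
})

test_that("mass conservation holds exactly for every FFM-based method", {
  subs <- random_subjects(200, seed = 42)
  est <- evaluate_battery(subs)
  ffm_rows <- est[!is.na(est$ffm), ]
  w <- subs$weight[match(ffm_rows$subject_id, subs$subject_id)]
  expect_equal(ffm_rows$ffm + ffm_rows$fat_mass, w, tolerance = 1e-12)
  expect_equal(ffm_rows$percent_fat, 100 * ffm_rows$fat_mass / w,
               tolerance = 1e-12)
})

test_that("skinfold estimates are monotone in each fold over its range", {
  # EQ2's printed quadratic peaks at a fold sum of 56.25 mm, so monotonicity
  # in a single fold holds only while the pair sum stays below the peak; the
  # other skinfold methods are monotone across the full caliper range.
  base <- make_subject(age = 16, biceps = 10, triceps = 10, subscapular = 10,
                       suprailiac = 10, midaxillary = 10, calf = 10)
  grid <- seq(5, 45, by = 5)
  for (m in c("EQ1", "EQ3", "EQ4", "EQ5", "EQ7")) {
    for (fold in c("triceps", "subscapular", "suprailiac", "calf")) {
      need <- switch(m, EQ3 = c("triceps", "calf"),
                     EQ4 = c("triceps", "subscapular"),
                     c("biceps", "triceps", "subscapular", "suprailiac"))
      if (!fold %in% need) next
      pf <- vapply(grid, function(v) {
        s <- base; s[[fold]] <- v
        evaluate_battery(s, methods = m)$percent_fat
      }, numeric(1))
      expect_true(all(diff(pf) >= 0), label = paste(m, fold, "monotone"))
    }
  }
  # EQ2 rises up to the quadratic peak and falls beyond it
  pf2 <- vapply(grid, function(v) {
    evaluate_battery(make_subject(triceps = v, subscapular = 15),
                     methods = "EQ2")$percent_fat
  }, numeric(1))
  sums <- grid + 15
  expect_true(all(diff(pf2[sums <= 55]) > 0))
  expect_true(pf2[length(pf2)] < max(pf2))
})

test_that("every equation matches the independent straight-line oracle", {
  subs <- random_subjects(300, seed = 7)
  est <- evaluate_battery(subs)
  orc <- oracle_battery(subs)
  key <- paste(est$subject_id, est$method)
  okey <- paste(orc$subject_id, orc$method)
  got <- est$percent_fat[match(okey, key)]
  comparable <- !is.na(orc$percent_fat)
  expect_gt(sum(comparable), 3000)
  expect_equal(got[comparable], orc$percent_fat[comparable], tolerance = 1e-9)
  # oracle NA (EQ1 outside its age window) must be a structured skip
  expect_true(all(!is.na(est$skip_reason[match(okey, key)][!comparable])))
})
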