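kb <- load_kb()
similac <- lookup_formula(kb, "Similac")
ketonex <- lookup_formula(kb, "Ketonex-1")
band3_5kg <- function() scale_allowance(lookup_allowance(kb, 3), 5)

test_that("allowance scaling is linear in weight with identity at 1 kg", {
  a <- band3_5kg()
  expect_equal(a$isoleucine_mg, 280)
  expect_equal(a$leucine_mg, 462.5)
  expect_equal(a$valine_mg, 322.5)
  expect_equal(a$protein_g, 15.8)
  expect_equal(a$energy_kcal, 600)
  expect_equal(a$fluid_ml, 500)
  expect_null(a$adjustment_applied)

  per_kg <- lookup_allowance(kb, 5)
  unit <- scale_allowance(per_kg, 1)
  expect_equal(unit$leucine_mg, per_kg$leucine_mg_per_kg)
  expect_equal(unit$protein_g, per_kg$protein_g_per_kg)

  w <- 3.7
  single <- scale_allowance(per_kg, w)
  doubled <- scale_allowance(per_kg, 2 * w)
  for (f in c("leucine_mg", "isoleucine_mg", "valine_mg", "protein_g",
              "energy_kcal", "fluid_ml")) {
    expect_equal(doubled[[f]], 2 * single[[f]])
  }
  expect_error(scale_allowance(per_kg, 0), "positive")
})

test_that("plasma adjustment fires only above the configured bands", {
  tree <- default_rdr_tree(kb$config)

  calm <- apply_plasma_adjustment(band3_5kg(), plasma_panel(80, 17, 55), tree)
  expect_equal(calm$leucine_mg, 462.5)
  expect_null(calm$adjustment_applied)
  expect_length(calm$flags, 0)

  hot <- apply_plasma_adjustment(band3_5kg(), plasma_panel(250, 17, 55), tree)
  expect_equal(hot$leucine_mg, 462.5 * 0.5)
  expect_equal(hot$isoleucine_mg, 280)  # untouched
  expect_equal(hot$adjustment_applied, "reduce_leucine")
  expect_true("consult_dietitian" %in% hot$flags)

  hot_val <- apply_plasma_adjustment(band3_5kg(), plasma_panel(80, 17, 500),
                                     tree)
  expect_equal(hot_val$valine_mg, 322.5 * 0.5)
  expect_equal(hot_val$adjustment_applied, "reduce_valine")

  # a factor of exactly 1 is the identity and raises nothing
  ident <- rdr_tree(rdr_conclusion("noop",
                                   payload = list(leucine_factor = 1.0)))
  same <- apply_plasma_adjustment(band3_5kg(), plasma_panel(80, 17, 55),
                                  ident)
  expect_equal(same$leucine_mg, 462.5)
  expect_null(same$adjustment_applied)

  # factors outside (0, 1] are a configuration error: rules may only tighten
  loose <- rdr_tree(rdr_conclusion("bad",
                                   payload = list(leucine_factor = 1.5)))
  expect_error(apply_plasma_adjustment(band3_5kg(), plasma_panel(80, 17, 55),
                                       loose),
               "leucine_factor must lie in \\(0, 1\\]")
})

test_that("allocation pushes commercial to the tightest BCAA and fills protein", {
  alloc <- allocate(band3_5kg(), similac, ketonex)
  expect_equal(alloc$commercial_grams, 462.5 / 10.79, tolerance = 1e-10)
  expect_equal(alloc$limiting_nutrient, "leucine")
  expect_equal(alloc$medical_grams,
               (15.8 - (462.5 / 10.79) * 0.1083) / 0.15, tolerance = 1e-10)

  # hypothetical BCAA-free commercial powder: capped by protein instead
  zero_bcaa <- data.frame(name = "ZeroBC", category = "commercial",
                          leucine_mg_per_100g = 0, isoleucine_mg_per_100g = 0,
                          valine_mg_per_100g = 0, protein_g_per_100g = 10,
                          energy_kcal_per_100g = 500)
  free <- allocate(band3_5kg(), zero_bcaa, ketonex)
  expect_equal(free$limiting_nutrient, "none")
  expect_equal(free$commercial_grams, 15.8 / 0.10)
  expect_equal(free$medical_grams, 0)

  # zero protein requirement floors the medical dose at 0
  sated <- band3_5kg()
  sated$protein_g <- 0
  expect_equal(allocate(sated, similac, ketonex)$medical_grams, 0)

  expect_error(allocate(band3_5kg(), ketonex, ketonex), "not a commercial")
  expect_error(allocate(band3_5kg(), similac, similac), "not a medical")
})

test_that("discretization rounds commercial down, medical to nearest scoop", {
  a <- band3_5kg()
  alloc <- allocate(a, similac, ketonex)
  plan <- discretize(alloc, a, similac, ketonex, kb$config)
  expect_identical(plan$commercial_scoops, 8L)   # floor(42.86 / 5)
  expect_identical(plan$medical_scoops, 15L)     # round(76.45 / 5 = 15.29)
  expect_equal(plan$water_ml, 500)
  expect_equal(plan$feeds_per_day, 8L)
  expect_equal(plan$delivered$leucine_mg, 431.6)
  expect_lte(plan$delivered$leucine_mg, a$leucine_mg)
  # energy 40*5.26 + 75*4.80 = 570.4 sits inside the 10% band [540, 660]
  expect_equal(plan$delivered$energy_kcal, 570.4)
  expect_false(any(grepl("energy", plan$flags)))
  # per-feed split conserves the daily totals
  expect_equal(sum(plan$per_feed$commercial_scoops), plan$commercial_scoops)
  expect_equal(sum(plan$per_feed$medical_scoops), plan$medical_scoops)
  expect_equal(sum(plan$per_feed$water_ml), plan$water_ml)
  expect_lte(max(plan$per_feed$medical_scoops) -
               min(plan$per_feed$medical_scoops), 1L)

  # an exact multiple of the scoop size loses nothing to rounding
  exact <- structure(list(commercial_grams = 40, medical_grams = 0,
                          limiting_nutrient = "leucine"),
                     class = "allocation_result")
  expect_identical(discretize(exact, a, similac, NULL,
                              kb$config)$commercial_scoops, 8L)
})

test_that("end-to-end recommendation reproduces the worked example", {
  rec <- recommend(patient_profile(3, 5), plasma_panel(80, 17, 55),
                   formula_selection("Similac", "Ketonex-1"), kb)
  expect_identical(rec$plan$commercial_scoops, 8L)
  expect_identical(rec$plan$medical_scoops, 15L)
  expect_equal(rec$plan$water_ml, 500)
  expect_equal(rec$allowance$leucine_mg, 462.5)

  # medical-only plans deliver exactly zero of every BCAA
  med_only <- recommend(patient_profile(3, 5), plasma_panel(80, 17, 55),
                        formula_selection(NULL, "Ketonex-1"), kb)
  expect_identical(med_only$plan$commercial_scoops, 0L)
  expect_equal(med_only$plan$delivered$leucine_mg, 0)
  expect_equal(med_only$plan$delivered$isoleucine_mg, 0)
  expect_equal(med_only$plan$delivered$valine_mg, 0)
  expect_equal(med_only$plan$delivered$protein_g,
               med_only$plan$medical_scoops * 5 * 0.15)

  # stage tagging on a guard violation (profile validation bypassed)
  broken <- structure(list(age_months = 8, weight_kg = 5, height_cm = NULL),
                      class = "patient_profile")
  err <- tryCatch(recommend(broken, plasma_panel(80, 17, 55),
                            formula_selection("Similac", "Ketonex-1"), kb),
                  error = function(e) e)
  expect_match(conditionMessage(err), "\\[allowance_lookup\\]")
})

test_that("safety, oracle agreement and structural properties hold at random", {
  set.seed(1234)
  commercials <- kb$formulas[kb$formulas$category == "commercial", ]
  medicals <- kb$formulas[kb$formulas$category == "medical", ]
  tree <- default_rdr_tree(kb$config)
  for (i in 1:40) {
    pt <- rand_patient()
    ci <- sample(nrow(commercials), 1)
    mi <- sample(nrow(medicals), 1)
    com <- commercials[ci, ]
    med <- medicals[mi, ]
    a <- apply_plasma_adjustment(
      scale_allowance(lookup_allowance(kb, pt$profile$age_months),
                      pt$profile$weight_kg),
      pt$panel, tree)
    plan <- discretize(allocate(a, com, med), a, com, med, kb$config)
    expect_lte(plan$delivered$leucine_mg, a$leucine_mg + 1e-9)
    expect_lte(plan$delivered$isoleucine_mg, a$isoleucine_mg + 1e-9)
    expect_lte(plan$delivered$valine_mg, a$valine_mg + 1e-9)
    want <- oracle_scoops(a, com, med, kb$config$scoop_grams)
    expect_identical(c(plan$commercial_scoops, plan$medical_scoops),
                     as.integer(unname(want)))
  }

  # monotonicity: more body weight never means less commercial formula
  weights <- seq(2, 10, by = 0.5)
  grams <- vapply(weights, function(w) {
    allocate(scale_allowance(lookup_allowance(kb, 3), w), similac,
             ketonex)$commercial_grams
  }, numeric(1))
  expect_true(all(diff(grams) >= -1e-12))

  # scale invariance of the rounding rule: (w, s) ~ (2w, 2s)
  set.seed(99)
  for (i in 1:10) {
    pt <- rand_patient()
    a1 <- scale_allowance(lookup_allowance(kb, pt$profile$age_months),
                          pt$profile$weight_kg)
    a2 <- scale_allowance(lookup_allowance(kb, pt$profile$age_months),
                          2 * pt$profile$weight_kg)
    cfg2 <- kb$config
    cfg2$scoop_grams <- 2 * kb$config$scoop_grams
    p1 <- discretize(allocate(a1, similac, ketonex), a1, similac, ketonex,
                     kb$config)
    p2 <- discretize(allocate(a2, similac, ketonex), a2, similac, ketonex,
                     cfg2)
    expect_identical(p1$commercial_scoops, p2$commercial_scoops)
    expect_identical(p1$medical_scoops, p2$medical_scoops)
  }
})
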