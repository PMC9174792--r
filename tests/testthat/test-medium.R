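glucose <- medium_component("glucose", "C6H12O6", "sugars", 875)
glycine <- medium_component("glycine", "C2H5NO2", "amino_acids", 175)

test_that("element mass concentrations follow count x weight x conc", {
  expect_equal(element_mass_concentration(glucose, "C"),
               6 * 12.011 * 0.875)
  expect_equal(element_mass_concentration(glycine, "N"),
               14.007 * 0.175)
  expect_equal(element_mass_concentration(glucose, "N"), 0)
})

test_that("stoichiometry table sums per group and in total", {
  med <- medium_definition("m", rbind(glucose, glycine))
  tab <- stoichiometry_table(med)
  sug <- tab[tab$group == "sugars", ]
  expect_equal(sug$uM_each, 875)
  expect_equal(sug$n_compounds, 1L)
  expect_equal(sug$C_mg_L, 63.06, tolerance = 1e-4)
  expect_equal(sug$N_mg_L, 0)
  tot <- tab[tab$group == "total", ]
  expect_equal(tot$C_mg_L,
               element_mass_concentration(glucose, "C") +
                 element_mass_concentration(glycine, "C"),
               tolerance = 1e-9)
  # empty medium collapses to an all-zero total row
  empty <- medium_definition("e", glucose[0, ])
  etab <- stoichiometry_table(empty)
  expect_equal(etab$C_mg_L, 0)
  expect_equal(etab$n_compounds, 0L)
})

test_that("stoichiometry totals are additive over components", {
  comps <- do.call(rbind, lapply(1:20, function(i) {
    medium_component(paste0("c", i), format_formula(random_tally(i + 500)),
                     sample(c("sugars", "organic_acids", "amino_acids",
                              "other"), 1),
                     runif(1, 1, 1000))
  }))
  med <- medium_definition("rand", comps)
  tab <- stoichiometry_table(med)
  for (el in c("C", "N")) {
    manual <- sum(vapply(seq_len(nrow(comps)), function(i)
      element_mass_concentration(comps[i, ], el), numeric(1)))
    expect_equal(tab[tab$group == "total", paste0(el, "_mg_L")], manual,
                 tolerance = 1e-9)
  }
})

test_that("doubling concentrations doubles masses, C:N unchanged", {
  comps <- rbind(glucose, glycine)
  med1 <- medium_definition("m1", comps)
  comps2 <- comps; comps2$conc_uM <- comps2$conc_uM * 2
  med2 <- medium_definition("m2", comps2)
  t1 <- stoichiometry_table(med1); t2 <- stoichiometry_table(med2)
  expect_equal(t2$C_mg_L, 2 * t1$C_mg_L, tolerance = 1e-12)
  expect_equal(t2$N_mg_L, 2 * t1$N_mg_L, tolerance = 1e-12)
  expect_equal(cn_ratio(med1, "molar"), cn_ratio(med2, "molar"),
               tolerance = 1e-12)
  expect_equal(cn_ratio(med1, "mass"), cn_ratio(med2, "mass"),
               tolerance = 1e-12)
})

test_that("C:N ratio handles bases and inorganic nitrogen", {
  # published-style totals: C 1042, N 123 mg/L plus 1 mM ammonium
  expect_equal(
    cn_ratio_from_totals(1042, 123, n_salt_mg_l = 1 * 14.007,
                         basis = "molar"),
    (1042 / 12.011) / ((123 + 14.007) / 14.007))
  # equal molar C and N (ethylenediamine C2H8N2) gives exactly 1
  eda <- medium_component("eda", "C2H8N2", "other", 100)
  expect_equal(cn_ratio(medium_definition("m", eda), "molar"), 1)
  # no nitrogen anywhere is a domain error
  expect_error(cn_ratio(medium_definition("m", glucose), "molar"),
               "nitrogen is zero")
  # ammonium enters only when requested
  med <- medium_definition("m", rbind(glucose, glycine),
                           salts = c(ammonium = 1))
  expect_gt(cn_ratio(med, "molar", include_inorganic_n = FALSE),
            cn_ratio(med, "molar", include_inorganic_n = TRUE))
})

test_that("tier-scale solver inverts the carbon computation", {
  expect_equal(solve_tier_scale(list("C6H12O6"), 1, 6 * 12.011 * 0.875),
               875, tolerance = 1e-9)
  expect_error(solve_tier_scale(list("H2O"), 1, 10), "no carbon")
  expect_error(solve_tier_scale(list("C6H12O6"), -1, 10),
               "multipliers must be > 0")
  # round-trip property over random component sets
  for (seed in 1:100) {
    withr::with_seed(seed, {
      k <- sample(2:6, 1)
      tallies <- lapply(seq_len(k) + seed * 17, random_tally)
      has_c <- any(vapply(tallies, function(t) "C" %in% names(t),
                          logical(1)))
      mult <- runif(k, 0.1, 60)
      target <- runif(1, 1, 2000)
      if (!has_c) {
        expect_error(solve_tier_scale(tallies, mult, target), "no carbon")
      } else {
        base <- solve_tier_scale(tallies, mult, target)
        achieved <- sum(vapply(seq_len(k), function(i)
          element_mass_concentration(
            list(formula = format_formula(tallies[[i]]),
                 conc_uM = base * mult[i]), "C"), numeric(1)))
        expect_equal(achieved, target, tolerance = 1e-9)
      }
    })
  }
})

test_that("recipe converts micromolar to weighable mass", {
  med <- medium_definition("m", glucose, salts = c(ammonium = 1),
                           supplements = data.frame(name = "vitamins",
                                                    fold = 1))
  r <- recipe(med)
  expect_equal(r$mg_per_L[r$name == "glucose"], 180.156 * 0.875)
  expect_equal(nrow(r), 3L)
  expect_setequal(r$type, c("metabolite", "salt", "supplement"))
  expect_error(medium_component("x", "C6H12O6", "sugars", 0),
               "must be a finite number > 0")
})

test_that("medium definitions round-trip through JSON and TSV", {
  med <- medium_definition(
    "demo", rbind(glucose, glycine),
    salts = c(ammonium = 1, phosphate = 5),
    supplements = data.frame(name = "vitamins", fold = 1,
                             stringsAsFactors = FALSE),
    ph = c(6.8, 7.2))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_medium(med, jf)
  back <- read_medium(jf)
  expect_equal(back$components$name, med$components$name)
  expect_equal(back$components$conc_uM, med$components$conc_uM)
  expect_equal(back$salts[sort(names(back$salts))],
               med$salts[sort(names(med$salts))])
  expect_equal(back$supplements, med$supplements)
  expect_equal(back$ph, med$ph)
  # TSV carries components only; both encodings agree on them
  write_medium(med, tf)
  back_tsv <- read_medium(tf)
  expect_equal(back_tsv$components[, c("name", "formula", "group",
                                       "conc_uM")],
               back$components[, c("name", "formula", "group", "conc_uM")])
})

test_that("malformed medium tables are rejected with row context", {
  bad_group <- rbind(glucose,
                     data.frame(name = "oleate", formula = "C18H34O2",
                                group = "lipid", conc_uM = 10,
                                source = NA, stringsAsFactors = FALSE))
  expect_error(medium_definition("m", bad_group), "row 2.*lipid")
  dup <- rbind(glucose, glucose)
  expect_error(medium_definition("m", dup), "duplicate component name")
  bad_formula <- glucose; bad_formula$formula <- "C6Zz"
  expect_error(medium_definition("m", bad_formula), "row 1")
})
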