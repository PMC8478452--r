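test_that("reaction parser extracts coefficients and rejects bad species", {
  r <- parse_reaction("4Fe+2 + O2 + 6H2O = 4FeOOH + 8H+")
  expect_equal(unname(r$reactants[c("Fe+2", "O2(aq)", "H2O")]), c(4, 1, 6))
  expect_equal(unname(r$products[c("ferrihydrite", "H+")]), c(4, 8))
  expect_equal(r$role, "iron-as-donor")

  expect_warning(parse_reaction("H2O = H2O"), "zero net stoichiometry")
  expect_error(parse_reaction("2XYZ + H2O = H2O + 2XYZ"),
               class = "ferroflux_unknown_species")
  expect_error(parse_reaction("H2O = H+ = OH-"),
               class = "ferroflux_parse_error")
})

test_that("library expansion yields 48 reactions with the footnote mapping", {
  lib <- reaction_library("rebalanced")
  expect_equal(nrow(lib), 48)
  expect_equal(lib$reaction_id, 1:48)
  # first FeOOH-acceptor row expands to ids 8, 9, 10 = fer, goe, lep
  expect_equal(lib$iron_species[8:10],
               c("ferrihydrite", "goethite", "lepidocrocite"))
  # donor-product FeOOH binds to ferrihydrite -> 7 planktonic donor reactions
  expect_equal(sum(lib$role == "iron-as-donor" & lib$lifestyle == "planktonic"),
               7)
  # pyrite and siderite groups contribute 3 + 3
  expect_equal(sum(lib$iron_species == "pyrite"), 3)
  expect_equal(sum(lib$iron_species == "siderite"), 3)
  # lifestyle rule: planktonic iff Fe2+ or ferrihydrite
  expect_identical(lib$lifestyle == "planktonic",
                   lib$iron_species %in% c("Fe+2", "ferrihydrite"))
})

test_that("balance validator flags exactly the four inconsistent printed rows", {
  lib <- reaction_library("as-printed")
  rep <- balance_report(lib)
  expect_equal(rep$reaction_id[!rep$balanced], c(6, 43, 44, 45))
  r43 <- check_balance(lib$reaction[[43]])
  expect_equal(r43$charge_imbalance, -6)
  expect_true(all(r43$element_imbalance == 0))
  r44 <- check_balance(lib$reaction[[44]])
  expect_equal(unname(r44$element_imbalance["Fe"]), -2)
  r7 <- check_balance(lib$reaction[[7]])
  expect_true(r7$balanced)
})

test_that("rebalanced library is fully balanced, counts preserved on sound rows", {
  printed <- reaction_library("as-printed")
  rebal <- reaction_library("rebalanced")
  rep <- balance_report(rebal)
  expect_true(all(rep$balanced))
  ne_p <- vapply(printed$reaction, function(r) {
    suppressWarnings(count_electrons(r))
  }, numeric(1))
  ne_r <- vapply(rebal$reaction, function(r) {
    suppressWarnings(count_electrons(r))
  }, numeric(1))
  sound <- setdiff(1:48, c(6, 43, 44, 45))
  expect_equal(ne_r[sound], ne_p[sound])
  expect_equal(ne_r[6], 2) # printed couple size survives correction for row 6
})

test_that("electron counter reproduces the printed column for all 48 rows", {
  lib <- reaction_library("as-printed")
  ne <- vapply(lib$reaction, function(r) {
    suppressWarnings(count_electrons(r))
  }, numeric(1))
  expect_equal(ne, lib$n_e_printed)
  # spot values from the printed table
  expect_equal(ne[c(1, 5, 7, 20, 21, 22, 29, 43)], c(8, 8, 4, 2, 2, 2, 8, 48))
})

test_that("a reaction without redox change counts zero electrons, warns", {
  diss <- parse_reaction("FeCO3 + H+ = Fe+2 + HCO3-",
                         role = "iron-as-donor")
  expect_warning(n <- count_electrons(diss), "no redox couple")
  expect_equal(n, 0)
})

test_that("reaction quotient: unit activities, antisymmetry, hand value at D1", {
  lib <- reaction_library()
  r7 <- lib$reaction[[7]]
  ones <- structure(
    tibble::tibble(
      species = c("Fe+2", "O2(aq)", "H+"),
      molality = 1, gamma = 1, activity = 1, flag = NA_character_,
      activity_floored = 1
    ),
    site_id = "unit", T_K = 298.15, class = c("ferro_activity_map", "tbl_df",
                                              "tbl", "data.frame")
  )
  expect_equal(as.numeric(reaction_quotient(r7, ones)), 0)

  r7_rev <- parse_reaction("4FeOOH + 8H+ = 4Fe+2 + O2 + 6H2O")
  am <- build_activity_map(demmo_sites()[1, ])
  expect_equal(as.numeric(reaction_quotient(r7_rev, am)),
               -as.numeric(reaction_quotient(r7, am)), tolerance = 1e-12)

  # independent log-sum from the activity map
  a <- function(s) am$activity_floored[am$species == s]
  hand <- 8 * log10(a("H+")) - (4 * log10(a("Fe+2")) + log10(a("O2(aq)")))
  expect_equal(as.numeric(reaction_quotient(r7, am)), hand, tolerance = 1e-12)
})

test_that("delta G: zero at equilibrium, antisymmetric, two-route consistent", {
  lib <- reaction_library()
  am <- build_activity_map(demmo_sites()[1, ])
  T_K <- attr(am, "T_K")
  r7 <- lib$reaction[[7]]
  dg <- delta_g(r7, am)
  # route 2: standard energy plus RT ln Q
  dg2 <- gibbs_standard(r7, T_K) +
    log(10) * 8.314 * T_K * as.numeric(reaction_quotient(r7, am)) / 1000
  expect_equal(dg$delta_g_kj_mol, dg2, tolerance = 1e-9 * abs(dg2))

  r7_rev <- parse_reaction("4FeOOH + 8H+ = 4Fe+2 + O2 + 6H2O")
  dg_rev <- delta_g(r7_rev, am)
  expect_equal(dg_rev$delta_g_kj_mol, -dg$delta_g_kj_mol, tolerance = 1e-9)

  # Q = K gives zero: build a map holding the reaction at equilibrium
  w <- parse_reaction("H2O = H+ + OH-")
  K <- 10^log_k(w, 298.15)
  eq_map <- structure(
    tibble::tibble(species = c("H+", "OH-"), molality = c(1e-7, K / 1e-7),
                   gamma = 1, activity = c(1e-7, K / 1e-7),
                   flag = NA_character_,
                   activity_floored = c(1e-7, K / 1e-7)),
    site_id = "eq", T_K = 298.15,
    class = c("ferro_activity_map", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(delta_g(w, eq_map)$delta_g_kj_mol, 0, tolerance = 1e-9)
})

test_that("ferrous iron oxidation with bicarbonate stays endergonic on fixture", {
  lib <- reaction_library()
  sites <- demmo_sites()
  for (i in seq_len(nrow(sites))) {
    am <- build_activity_map(sites[i, ])
    dg <- delta_g(lib$reaction[[3]], am)
    expect_true(dg$delta_g_kj_mol > 0)
  }
})
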