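test_that("site table loads with six sites and exact printed values", {
  sites <- demmo_sites()
  expect_equal(sites$site_id, paste0("D", 1:6))
  d1 <- sites[sites$site_id == "D1", ]
  expect_equal(d1$`Fe2+`, 2.32)
  expect_equal(d1$temperature_C, 10.5)
  expect_equal(d1$pH, 7.3)
  d6 <- sites[sites$site_id == "D6", ]
  expect_equal(d6$`SO4-2`, 4110)
  expect_equal(d6$DO, 0) # true zero preserved
})

test_that("site table loader rejects empty and malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a comment", f)
  expect_error(load_site_table(f), class = "ferroflux_input_error")

  writeLines(c("Parameter\tS1", "Temp_C\t20", "pH\t7"), f)
  err <- expect_error(load_site_table(f), class = "ferroflux_input_error")
  expect_match(conditionMessage(err), "DOC")

  src <- readLines(system.file("extdata", "demmo_geochem.tsv",
                               package = "ferroflux"))
  src[which(startsWith(src, "DOC"))] <- "DOC\toops\t0.393\t0.25\t0.244\t0.316\t0.286"
  writeLines(src, f)
  err <- expect_error(load_site_table(f), class = "ferroflux_input_error")
  expect_match(conditionMessage(err), "DOC")
  expect_match(conditionMessage(err), "D1")
})

test_that("molality conversion uses the right mass basis", {
  expect_equal(to_molality("Fe2+", 2.32), 2.32 / 55.845 / 1000,
               tolerance = 1e-12)
  expect_equal(to_molality("Fe2+", 2.32), 4.154e-5, tolerance = 1e-3)
  expect_equal(to_molality("DOC", 0.468), 0.468 / (2 * 12.011) / 1000,
               tolerance = 1e-12)
  expect_equal(to_molality("DOC", 0.468), 1.948e-5, tolerance = 1e-3)
  expect_equal(to_molality("SO4-2", 0), 0)
  expect_error(to_molality("unobtainium", 1), class = "ferroflux_input_error")
})

test_that("ionic strength follows the half-sum of m z^2", {
  expect_equal(ionic_strength(c("Na+" = 0.01, "Cl-" = 0.01)), 0.01)
  expect_equal(ionic_strength(c("Ca+2" = 0.005, "Cl-" = 0.01)), 0.015)
  expect_equal(ionic_strength(numeric(0)), 0)
  expect_equal(ionic_strength(c("CH4(aq)" = 0.1)), 0) # neutral contributes 0
})

test_that("activity coefficients: limits, symmetry, Davies spot value", {
  expect_equal(activity_coefficient(2, 0), 1)
  expect_equal(activity_coefficient(-1, 0, method = "davies"), 1)
  expect_equal(activity_coefficient(1, 0.05), activity_coefficient(-1, 0.05))
  # Davies with A ~ 0.509 at 25 C
  expect_equal(activity_coefficient(1, 0.1, 298.15, method = "davies"),
               0.78, tolerance = 0.01)
  expect_error(activity_coefficient(1, -0.01), class = "ferroflux_input_error")
  # gamma stays in (0, 1] for ions at I <= 1
  for (I in c(1e-4, 0.01, 0.3, 1)) {
    g <- activity_coefficient(c(-2, -1, 1, 2, 3), I)
    expect_true(all(g > 0 & g <= 1))
  }
})

test_that("perchlorate estimator is Nernstian in Eh and linear in chloride", {
  a1 <- estimate_perchlorate(1e-4, -0.1, 7, 298.15)
  a2 <- estimate_perchlorate(2e-4, -0.1, 7, 298.15)
  expect_equal(a2 / a1, 2, tolerance = 1e-9)
  # reducing potentials push perchlorate far below chloride
  expect_true(a1 < 1e-4 * 1e-50)
  # more oxidizing -> more perchlorate
  expect_true(estimate_perchlorate(1e-4, 0.5, 7) >
                estimate_perchlorate(1e-4, -0.5, 7))
  expect_error(estimate_perchlorate(1e-4, NA, 7),
               class = "ferroflux_input_error")

  # independent hand evaluation of the Nernst expression at the D1 inputs
  sites <- demmo_sites()
  am <- build_activity_map(sites[1, ])
  T_K <- 283.65
  tab <- thermo_table()
  g <- function(s) tab$dG_f_kJ_mol[tab$name == s]
  h <- function(s) tab$dH_f_kJ_mol[tab$name == s]
  dG0 <- g("Cl-") + 4 * g("H2O") - g("ClO4-")
  dH0 <- h("Cl-") + 4 * h("H2O") - h("ClO4-")
  dGT <- dG0 * T_K / 298.15 + dH0 * (1 - T_K / 298.15)
  logK <- -dGT * 1000 / (log(10) * 8.314 * T_K)
  pe <- -0.068 * 96485.33 / (log(10) * 8.314 * T_K)
  a_cl <- am$activity[am$species == "Cl-"]
  expected <- 10^(log10(a_cl) + 8 * 7.3 + 8 * pe - logK)
  got <- am$activity[am$species == "ClO4-"]
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("activity map obeys the special-species rules", {
  sites <- demmo_sites()
  am1 <- build_activity_map(sites[1, ])
  expect_equal(am1$activity[am1$species == "H+"], 10^(-7.3))
  # CO activity equals its molality (concentration substitution)
  expect_equal(am1$activity[am1$species == "CO(aq)"],
               am1$molality[am1$species == "CO(aq)"])
  # positive concentrations give positive activities
  expect_true(all(am1$activity[am1$molality > 0] > 0))

  am6 <- build_activity_map(sites[6, ])
  expect_equal(am6$flag[am6$species == "O2(aq)"], "below_floor")
  expect_equal(am6$molality[am6$species == "O2(aq)"], 0)
  expect_true(am6$activity_floored[am6$species == "O2(aq)"] > 0)
})

test_that("ionic strength is positive everywhere and largest at D6", {
  sites <- demmo_sites()
  I <- vapply(seq_len(nrow(sites)), function(i) {
    attr(build_activity_map(sites[i, ]), "ionic_strength")
  }, numeric(1))
  expect_true(all(I > 0))
  expect_equal(which.max(I), 6)
})

test_that("activity map round-trips through the site report file", {
  sites <- demmo_sites()
  am <- build_activity_map(sites[3, ])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_activity_map(am, f)
  back <- read_activity_map(f)
  expect_identical(back$species, am$species)
  for (col in c("molality", "gamma", "activity", "activity_floored")) {
    expect_rel_equal(back[[col]], am[[col]], tol = 1e-12)
  }
  expect_identical(attr(back, "site_id"), attr(am, "site_id"))
  expect_equal(attr(back, "ionic_strength"), attr(am, "ionic_strength"),
               tolerance = 1e-12)
})
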