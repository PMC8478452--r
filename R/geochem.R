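# Analyte -> species mapping and molar-mass basis (g/mol).
# DOC is measured as mg C/liter and converted on a carbon basis to the
# two-carbon acetate ion; S2- is measured as sulfide-S and carried as HS-,
# the dominant sulfide species at the circumneutral-to-alkaline site pH.
.analyte_basis <- tibble::tribble(
  ~analyte,   ~species,    ~mass_g_mol,
  "DOC",      "acetate",   2 * 12.011,
  "NO3-",     "NO3-",      62.004,
  "NH4+",     "NH4+",      18.039,
  "Fe2+",     "Fe+2",      55.845,
  "Total_Fe", NA,          55.845,
  "S2-",      "HS-",       32.06,
  "DO",       "O2(aq)",    31.998,
  "SO4-2",    "SO4-2",     96.06,
  "Cl-",      "Cl-",       35.453,
  "CH4",      "CH4(aq)",   16.043,
  "H2",       "H2(aq)",    2.016,
  "CO2",      "CO2(aq)",   44.009,
  "CO",       "CO(aq)",    28.010,
  "K+",       "K+",        39.098,
  "NO2-",     "NO2-",      46.005
)

.required_analytes <- c("DOC", "NO3-", "NH4+", "Fe2+", "S2-", "DO", "SO4-2",
                        "Cl-", "CH4", "H2", "CO2", "CO")
.meta_rows <- c("Depth_m", "Temp_C", "pH", "ORP_mV")

#' Load a site geochemistry table
#'
#' Reads a tab-separated table in the packaged layout (analytes as rows, sites
#' as columns) or transposed (sites as rows); orientation is auto-detected from
#' the header. Concentrations are mg/liter; metadata rows are depth (m),
#' temperature (degC), pH and ORP (mV). Zeros are preserved as true zeros.
#'
#' @param path Path to the table.
#' @return Tibble with one row per site: `site_id`, `depth_m`, `temperature_C`,
#'   `pH`, `orp_mV`, then one column per analyte (mg/liter).
#' @export
load_site_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 2) {
    abort(sprintf("site table '%s' is empty", path),
          class = "ferroflux_input_error")
  }
  raw <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, colClasses = "character")
  by_row <- "Parameter" %in% names(raw) || raw[[1]][1] %in% .meta_rows
  if (by_row) {
    params <- raw[[1]]
    sites <- names(raw)[-1]
    mat <- as.matrix(raw[, -1, drop = FALSE])
    rownames(mat) <- params
  } else {
    sites <- raw[[1]]
    params <- names(raw)[-1]
    mat <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(mat) <- sites
    rownames(mat) <- params
  }
  missing <- setdiff(c(.meta_rows[-1], .required_analytes), rownames(mat))
  if (length(missing)) {
    abort(sprintf("site table is missing required rows: %s",
                  paste(missing, collapse = ", ")),
          class = "ferroflux_input_error")
  }
  num <- suppressWarnings(apply(mat, c(1, 2), as.numeric))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at row '%s', site '%s': '%s'",
                  rownames(mat)[bad[1]], colnames(mat)[bad[2]],
                  mat[bad[1], bad[2]]),
          class = "ferroflux_input_error")
  }
  analytes <- setdiff(rownames(num), .meta_rows)
  out <- tibble(
    site_id = unname(sites),
    depth_m = if ("Depth_m" %in% rownames(num)) unname(num["Depth_m", ])
              else NA_real_,
    temperature_C = unname(num["Temp_C", ]),
    pH = unname(num["pH", ]),
    orp_mV = unname(num["ORP_mV", ])
  )
  for (a in analytes) out[[a]] <- unname(num[a, ])
  stopifnot(all(out$temperature_C > 0 & out$temperature_C < 100),
            all(out$pH > 0 & out$pH < 14),
            all(as.matrix(out[analytes]) >= 0))
  out
}

#' Packaged six-site fracture-fluid geochemistry fixture
#'
#' @return Site tibble as from [load_site_table()].
#' @export
demmo_sites <- function() {
  load_site_table(system.file("extdata", "demmo_geochem.tsv",
                              package = "ferroflux"))
}

#' Convert a concentration in mg/liter to molality
#'
#' Fluid density is taken as 1.0 kg/liter (dilute fluids). DOC uses a carbon
#' basis: mg C/liter divided by two carbons per acetate.
#'
#' @param analyte Analyte name (site-table vocabulary, e.g. `"Fe2+"`, `"DOC"`).
#' @param conc_mg_L Concentration in mg/liter.
#' @return Molality in mol/kg.
#' @examples
#' to_molality("Fe2+", 2.32)
#' @export
to_molality <- function(analyte, conc_mg_L) {
  i <- match(analyte, .analyte_basis$analyte)
  if (is.na(i)) {
    abort(sprintf("no molar-mass basis for analyte '%s'", analyte),
          class = "ferroflux_input_error")
  }
  conc_mg_L / (.analyte_basis$mass_g_mol[i] * 1000)
}

#' Ionic strength from species molalities
#'
#' \eqn{I = \frac{1}{2}\sum_i m_i z_i^2}; uncharged species contribute zero.
#'
#' @param molalities Named vector (names are species in the thermodynamic
#'   table), mol/kg.
#' @return Ionic strength, mol/kg.
#' @export
ionic_strength <- function(molalities) {
  if (length(molalities) == 0) return(0)
  tab <- thermo_table()
  z <- tab$charge[match(names(molalities), tab$name)]
  if (anyNA(z)) {
    abort(sprintf("unknown species in molality vector: %s",
                  paste(names(molalities)[is.na(z)], collapse = ", ")),
          class = "ferroflux_unknown_species")
  }
  0.5 * sum(molalities * z^2)
}

# Debye-Hueckel parameters vs temperature (degC); linear interpolation.
.dh_params <- tibble::tribble(
  ~T_C, ~A,     ~B,     ~bdot,
  0,    0.4913, 0.3247, 0.0374,
  25,   0.5092, 0.3283, 0.0410,
  60,   0.5450, 0.3343, 0.0438,
  100,  0.5998, 0.3422, 0.0460
)

#' Single-ion activity coefficient
#'
#' Extended Debye-Hueckel ("B-dot") model by default, with the Davies equation
#' as a configurable fallback. Neutral species get \eqn{\gamma = 1}, and
#' \eqn{\gamma \to 1} as \eqn{I \to 0}.
#'
#' @param charge Ion charge (integer, vectorized).
#' @param I Ionic strength, mol/kg (must be >= 0).
#' @param T_K Temperature, kelvin.
#' @param method `"bdot"` or `"davies"`.
#' @param ion_size_A Ion size parameter in angstroms (B-dot only; default 4).
#' @return Dimensionless activity coefficient(s).
#' @examples
#' activity_coefficient(1, 0.1, method = "davies")
#' @export
activity_coefficient <- function(charge, I, T_K = 298.15,
                                 method = c("bdot", "davies"),
                                 ion_size_A = 4) {
  method <- match.arg(method)
  if (I < 0) abort("ionic strength must be >= 0", class = "ferroflux_input_error")
  T_C <- T_K - 273.15
  A <- stats::approx(.dh_params$T_C, .dh_params$A, T_C, rule = 2)$y
  B <- stats::approx(.dh_params$T_C, .dh_params$B, T_C, rule = 2)$y
  bdot <- stats::approx(.dh_params$T_C, .dh_params$bdot, T_C, rule = 2)$y
  ion_size_A <- ifelse(is.na(ion_size_A), 4, ion_size_A)
  log_g <- if (method == "bdot") {
    -A * charge^2 * sqrt(I) / (1 + B * ion_size_A * sqrt(I)) + bdot * I
  } else {
    -A * charge^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I)
  }
  out <- 10^log_g
  out[charge == 0] <- 1
  out
}

#' Estimate perchlorate activity at equilibrium with chloride
#'
#' Nernstian equilibrium of the 8-electron ClO4-/Cl- couple at the measured
#' redox potential (vs SHE), unit water activity:
#' \deqn{\log a_{ClO_4^-} = \log a_{Cl^-} + 8\,\mathrm{pH} + 8\,\mathrm{pe}
#'   - \log K}
#' with pe = Eh F / (ln(10) R T) and log K computed from the packaged
#' thermodynamic table at T.
#'
#' @param a_cl Chloride activity (> 0).
#' @param Eh_V Redox potential in volts vs SHE.
#' @param pH Site pH.
#' @param T_K Temperature, kelvin.
#' @return Perchlorate activity (dimensionless).
#' @export
estimate_perchlorate <- function(a_cl, Eh_V, pH, T_K = 298.15) {
  stopifnot(a_cl > 0)
  if (is.na(Eh_V)) {
    abort("Eh is required to estimate perchlorate activity",
          class = "ferroflux_input_error")
  }
  tab <- thermo_table()
  g <- function(s) tab$dG_f_kJ_mol[match(s, tab$name)]
  h <- function(s) tab$dH_f_kJ_mol[match(s, tab$name)]
  dG0 <- g("Cl-") + 4 * g("H2O") - g("ClO4-")
  dH0 <- h("Cl-") + 4 * h("H2O") - h("ClO4-")
  dG_T <- dG0 * T_K / .T_REF + dH0 * (1 - T_K / .T_REF)
  logK <- -dG_T * 1000 / (log(10) * .R_GAS * T_K)
  pe <- Eh_V * .FARADAY / (log(10) * .R_GAS * T_K)
  10^(log10(a_cl) + 8 * pH + 8 * pe - logK)
}

#' Default activity-model configuration
#'
#' @param activity_model `"bdot"` or `"davies"`.
#' @param floor_molal Molality floor used only to keep logs finite in Gibbs
#'   energy terms (never in energy densities), mol/kg.
#' @param no2_default_molal Nitrite molality used when the analyte is absent.
#' @param electrode_offset_mV Offset added to ORP to convert to Eh vs SHE.
#' @return Named list of settings.
#' @export
geochem_config <- function(activity_model = "bdot", floor_molal = 1e-12,
                           no2_default_molal = 1e-7, electrode_offset_mV = 0) {
  list(activity_model = activity_model, floor_molal = floor_molal,
       no2_default_molal = no2_default_molal,
       electrode_offset_mV = electrode_offset_mV)
}

#' Build the per-site activity map
#'
#' Converts analyte concentrations to molalities, computes ionic strength and
#' activity coefficients, and applies the special rules: H+ activity is
#' 10^(-pH) exactly; dissolved gases are neutral with unit gamma, and CO
#' activity is set equal to its molal concentration; acetate comes from DOC on
#' a carbon basis; bicarbonate is derived from dissolved CO2 and pH through
#' the first carbonic-acid dissociation; perchlorate from the Nernstian
#' chloride estimator; nitrite defaults to a configurable molality when not
#' measured. Species with true zero concentration are flagged `below_floor`:
#' their floored activity keeps logarithms finite in Gibbs energy terms, while
#' the true zero molality is preserved for energy-density scaling.
#'
#' @param site One-row site tibble (a row of [load_site_table()] output).
#' @param config Settings from [geochem_config()].
#' @return Tibble of class `ferro_activity_map` with columns `species`,
#'   `molality`, `gamma`, `activity`, `activity_floored`, `flag`; attributes
#'   `site_id`, `T_K`, `pH`, `Eh_V`, `ionic_strength`.
#' @export
build_activity_map <- function(site, config = geochem_config()) {
  stopifnot(nrow(site) == 1)
  tab <- thermo_table()
  T_K <- site$temperature_C + 273.15
  pH <- site$pH
  Eh_V <- (site$orp_mV + config$electrode_offset_mV) / 1000
  basis <- .analyte_basis %>%
    filter(!is.na(.data$species), .data$analyte %in% names(site))
  mol <- stats::setNames(
    purrr::map2_dbl(basis$analyte, basis$mass_g_mol,
                    ~ site[[.x]] / (.y * 1000)),
    basis$species
  )
  if (!"NO2-" %in% names(mol)) mol["NO2-"] <- config$no2_default_molal
  I <- ionic_strength(mol)
  z <- tab$charge[match(names(mol), tab$name)]
  a0 <- tab$ion_size_A[match(names(mol), tab$name)]
  gamma <- purrr::map_dbl(seq_along(mol), function(i) {
    activity_coefficient(z[i], I, T_K, method = config$activity_model,
                         ion_size_A = a0[i])
  })
  activity <- gamma * mol
  # CO: activity substituted by concentration (no coefficient)
  activity["CO(aq)"] <- mol[["CO(aq)"]]
  res <- tibble(species = names(mol), molality = unname(mol),
                gamma = unname(gamma), activity = unname(activity),
                flag = NA_character_)

  # H+ exactly from pH
  g_h <- activity_coefficient(1, I, T_K, method = config$activity_model,
                              ion_size_A = tab$ion_size_A[match("H+", tab$name)])
  res <- bind_rows(res, tibble(species = "H+", molality = 10^(-pH) / g_h,
                               gamma = g_h, activity = 10^(-pH),
                               flag = NA_character_))

  # bicarbonate from CO2(aq) and pH via the first dissociation constant
  k1_rxn <- parse_reaction("CO2 + H2O = HCO3- + H+")
  logK1 <- log_k(k1_rxn, T_K)
  g_hco3 <- activity_coefficient(-1, I, T_K, method = config$activity_model,
                                 ion_size_A = tab$ion_size_A[match("HCO3-", tab$name)])
  a_hco3 <- 10^logK1 * activity[["CO2(aq)"]] / 10^(-pH)
  res <- bind_rows(res, tibble(species = "HCO3-", molality = a_hco3 / g_hco3,
                               gamma = g_hco3, activity = a_hco3,
                               flag = "derived"))

  # perchlorate from the chloride equilibrium estimator
  g_clo4 <- activity_coefficient(-1, I, T_K, method = config$activity_model,
                                 ion_size_A = tab$ion_size_A[match("ClO4-", tab$name)])
  a_clo4 <- estimate_perchlorate(res$activity[res$species == "Cl-"], Eh_V, pH, T_K)
  res <- bind_rows(res, tibble(species = "ClO4-", molality = a_clo4 / g_clo4,
                               gamma = g_clo4, activity = a_clo4,
                               flag = "estimated"))

  res <- res %>%
    mutate(
      flag = ifelse(.data$molality <= 0, "below_floor", .data$flag),
      activity_floored = ifelse(.data$molality <= 0,
                                .data$gamma * config$floor_molal,
                                .data$activity)
    )
  structure(res, site_id = site$site_id, T_K = T_K, pH = pH, Eh_V = Eh_V,
            ionic_strength = I,
            class = c("ferro_activity_map", class(res)))
}

#' Write / read an activity map as a tab-separated site report
#'
#' Values are written in full double precision so a round trip reproduces the
#' map exactly; site metadata travel in '#' header comments.
#'
#' @param amap Activity map from [build_activity_map()].
#' @param path Output path.
#' @return `path`, invisibly (writer); the reconstructed map (reader).
#' @export
write_activity_map <- function(amap, path) {
  meta <- sprintf("# %s=%.17g", c("T_K", "pH", "Eh_V", "ionic_strength"),
                  c(attr(amap, "T_K"), attr(amap, "pH"), attr(amap, "Eh_V"),
                    attr(amap, "ionic_strength")))
  header <- c(sprintf("# site_id=%s", attr(amap, "site_id")), meta)
  body <- vapply(seq_len(nrow(amap)), function(i) {
    paste(c(amap$species[i],
            sprintf("%.17g", c(amap$molality[i], amap$gamma[i],
                               amap$activity[i], amap$activity_floored[i])),
            ifelse(is.na(amap$flag[i]), "", amap$flag[i])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header,
               "species\tmolality\tgamma\tactivity\tactivity_floored\tflag",
               body), path)
  invisible(path)
}

#' @rdname write_activity_map
#' @export
read_activity_map <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  kv <- stringr::str_match(meta_lines, "^# *([^=]+)=(.*)$")
  meta <- stats::setNames(kv[, 3], kv[, 2])
  body <- utils::read.delim(text = paste(lines[!startsWith(lines, "#")],
                                         collapse = "\n"),
                            check.names = FALSE, colClasses = "character")
  res <- tibble(
    species = body$species,
    molality = as.numeric(body$molality),
    gamma = as.numeric(body$gamma),
    activity = as.numeric(body$activity),
    flag = ifelse(body$flag == "", NA_character_, body$flag),
    activity_floored = as.numeric(body$activity_floored)
  ) %>% select("species", "molality", "gamma", "activity", "flag",
               "activity_floored")
  structure(res, site_id = unname(meta[["site_id"]]),
            T_K = as.numeric(meta[["T_K"]]), pH = as.numeric(meta[["pH"]]),
            Eh_V = as.numeric(meta[["Eh_V"]]),
            ionic_strength = as.numeric(meta[["ionic_strength"]]),
            class = c("ferro_activity_map", class(res)))
}
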