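#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% filter mutate select arrange left_join group_by
#'   summarise ungroup bind_rows distinct rename count across all_of pull n
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats setNames
#' @importFrom utils head
NULL

# Gas constant, J/(mol K), and reference temperature, K
.R_GAS <- 8.314
.T_REF <- 298.15
.FARADAY <- 96485.33

#' Parse a chemical formula into element counts
#'
#' Understands simple `Element`/`ElementN` concatenations such as `"Fe2O3"`,
#' `"C2H3O2"` or `"FeOOH"`. Charge is not part of the formula string; it is a
#' separate field of the thermodynamic table.
#'
#' @param formula Formula string.
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("Fe2O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  tokens <- stringr::str_match_all(formula, "([A-Z][a-z]?)([0-9]*)")[[1]]
  if (paste0(tokens[, 1], collapse = "") != formula) {
    abort(sprintf("cannot parse formula '%s'", formula), class = "ferroflux_parse_error")
  }
  counts <- ifelse(tokens[, 3] == "", 1, as.numeric(tokens[, 3]))
  out <- tapply(counts, tokens[, 2], sum)
  stats::setNames(as.numeric(out), names(out))
}

.thermo_env <- new.env(parent = emptyenv())

#' Packaged standard-state thermodynamic table
#'
#' One record per chemical species: elemental formula, phase, charge, standard
#' Gibbs energy and enthalpy of formation at 298.15 K / 1 bar, ion size (for
#' the extended Debye-Hueckel model) and a source citation. Values are
#' transcribed from standard compilations; each row names its source.
#'
#' @param path Optional path to an alternative table in the same layout.
#' @return A tibble with columns `name`, `formula`, `phase`, `charge`,
#'   `dG_f_kJ_mol`, `dH_f_kJ_mol`, `ion_size_A`, `source`.
#' @export
thermo_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.thermo_env$table)) return(.thermo_env$table)
    path <- system.file("extdata", "thermo_table.tsv", package = "ferroflux")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = "NA", progress = FALSE)
  tab <- as_tibble(tab)
  # invariant: formulas parse and charges are integers
  purrr::walk(tab$formula, parse_formula)
  stopifnot(all(tab$charge == round(tab$charge)))
  if (anyDuplicated(tolower(tab$name))) {
    abort("duplicate species records in thermodynamic table")
  }
  if (cache) .thermo_env$table <- tab
  tab
}

# Alias map: Table-2 style and common tokens -> canonical record names.
.species_aliases <- c(
  "fe2+" = "Fe+2", "fe^2+" = "Fe+2", "fe+2" = "Fe+2", "fe(ii)" = "Fe+2",
  "o2" = "O2(aq)", "h2" = "H2(aq)", "ch4" = "CH4(aq)", "co" = "CO(aq)",
  "co2" = "CO2(aq)", "c2h3o2-" = "acetate", "ac-" = "acetate",
  "hco3-" = "HCO3-", "bicarbonate" = "HCO3-", "carbonate" = "CO3-2",
  "so42-" = "SO4-2", "so4--" = "SO4-2", "so4-2" = "SO4-2", "sulfate" = "SO4-2",
  "hs-" = "HS-", "sulfide" = "HS-", "s0" = "S0", "sulfur" = "S0",
  "clo4-" = "ClO4-", "perchlorate" = "ClO4-", "cl-" = "Cl-",
  "no3-" = "NO3-", "nitrate" = "NO3-", "no2-" = "NO2-", "nitrite" = "NO2-",
  "nh4+" = "NH4+", "ammonium" = "NH4+",
  "feooh_fer" = "ferrihydrite", "feooh_goe" = "goethite",
  "feooh_lep" = "lepidocrocite", "feooh" = "ferrihydrite",
  "fe2o3" = "hematite", "fe3o4" = "magnetite", "fes2" = "pyrite",
  "feco3" = "siderite", "water" = "H2O", "oh-" = "OH-",
  "na+" = "Na+", "k+" = "K+", "ca+2" = "Ca+2", "ca2+" = "Ca+2"
)

#' Resolve a species name to its canonical thermodynamic record name
#'
#' Case-insensitive; accepts reaction-table spellings such as `"FeOOH_fer"`,
#' `"C2H3O2-"` or `"SO42-"`.
#'
#' @param name Species name or alias.
#' @return Canonical record name (character scalar).
#' @export
resolve_species <- function(name) {
  tab <- thermo_table()
  key <- tolower(trimws(name))
  hit <- match(key, tolower(tab$name))
  if (!is.na(hit)) return(tab$name[hit])
  if (key %in% names(.species_aliases)) return(unname(.species_aliases[[key]]))
  near <- utils::adist(key, c(tolower(tab$name), names(.species_aliases)))
  cand <- c(tab$name, unname(.species_aliases))[order(near)][1:3]
  abort(sprintf("unknown species '%s'; nearest known names/aliases: %s",
                name, paste(unique(cand), collapse = ", ")),
        class = "ferroflux_unknown_species")
}

#' Look up the thermodynamic record for one species
#'
#' @param name Species name or alias (case-insensitive).
#' @return One-row tibble (the unique record).
#' @examples
#' lookup_species("Fe2+")
#' lookup_species("hematite")
#' @export
lookup_species <- function(name) {
  canon <- resolve_species(name)
  thermo_table() %>% filter(.data$name == canon)
}

# Sum a per-species property over a signed stoichiometry
# reaction: object from parse_reaction(); column: "dG_f_kJ_mol" or "dH_f_kJ_mol"
.reaction_sum <- function(reaction, column) {
  tab <- thermo_table()
  species <- c(names(reaction$reactants), names(reaction$products))
  nu <- c(-unname(reaction$reactants), unname(reaction$products))
  idx <- match(species, tab$name)
  if (anyNA(idx)) {
    abort(sprintf("species without thermodynamic record: %s",
                  paste(species[is.na(idx)], collapse = ", ")),
          class = "ferroflux_unknown_species")
  }
  sum(nu * tab[[column]][idx])
}

#' Standard Gibbs energy of reaction at temperature T
#'
#' \eqn{\Delta G^\circ_r} at 298.15 K is the stoichiometric sum of standard
#' Gibbs energies of formation; the value at other temperatures comes from the
#' integrated van't Hoff relation with \eqn{\Delta H^\circ_r} held constant
#' (adequate over the 10-32 degC range of the site data):
#' \deqn{\Delta G^\circ_r(T) = \frac{T}{T_0}\Delta G^\circ_r(T_0) +
#'   \Delta H^\circ_r\left(1 - \frac{T}{T_0}\right)}
#'
#' @param reaction A reaction from [parse_reaction()].
#' @param T_K Temperature in kelvin, within (273, 373).
#' @return \eqn{\Delta G^\circ_r(T)} in kJ/mol.
#' @export
gibbs_standard <- function(reaction, T_K = .T_REF) {
  stopifnot(T_K > 273, T_K < 373)
  dG0 <- .reaction_sum(reaction, "dG_f_kJ_mol")
  dH0 <- .reaction_sum(reaction, "dH_f_kJ_mol")
  dG0 * T_K / .T_REF + dH0 * (1 - T_K / .T_REF)
}

#' Equilibrium constant (log10) of a reaction at temperature T
#'
#' \eqn{\log K = -\Delta G^\circ_r(T) / (\ln 10 \cdot R T)}.
#'
#' @inheritParams gibbs_standard
#' @return log10 K (dimensionless).
#' @export
log_k <- function(reaction, T_K = .T_REF) {
  dG <- gibbs_standard(reaction, T_K) * 1000 # J/mol
  -dG / (log(10) * .R_GAS * T_K)
}
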