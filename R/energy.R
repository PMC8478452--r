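#' Limiting aqueous reactant of a reaction at given molalities
#'
#' Among aqueous reactants only — minerals, water and the ubiquitous medium
#' species H+/OH- are excluded — returns the species minimizing molality over
#' stoichiometric coefficient. A zero-concentration reactant is limiting with
#' molality 0.
#'
#' @param reaction A `ferro_reaction`.
#' @param molalities Named molality vector (mol/kg) or a
#'   `ferro_activity_map`.
#' @return One-row tibble: `species`, `molality`, `nu`, `m_over_nu`.
#' @export
limiting_reactant <- function(reaction, molalities) {
  if (inherits(molalities, "ferro_activity_map")) {
    molalities <- stats::setNames(molalities$molality, molalities$species)
  }
  tab <- thermo_table()
  sp <- names(reaction$reactants)
  phase <- tab$phase[match(sp, tab$name)]
  sp <- sp[phase == "aqueous" & !sp %in% c("H+", "OH-")]
  if (length(sp) == 0) {
    abort(sprintf("no aqueous reactant to scale in '%s'", reaction$equation),
          class = "ferroflux_no_aqueous_reactant")
  }
  m <- molalities[sp]
  if (anyNA(m)) {
    abort(sprintf("molalities missing for: %s",
                  paste(sp[is.na(m)], collapse = ", ")),
          class = "ferroflux_missing_activity")
  }
  nu <- unname(reaction$reactants[sp])
  ratio <- unname(m) / nu
  i <- which.min(ratio)
  tibble(species = sp[i], molality = unname(m)[i], nu = nu[i],
         m_over_nu = ratio[i])
}

#' Energy density of one reaction at one site
#'
#' The exergonic Gibbs energy is scaled to the availability of the limiting
#' aqueous reactant: \eqn{E = \max(0, -\Delta G_r) \cdot m_{lim}/\nu_{lim}}
#' in joules per kg of fluid. Endergonic reactions have zero energy density.
#' Gibbs energies use floored activities so logarithms stay finite; the
#' limiting molality is the true (unfloored) value, so a reactant measured at
#' zero gives zero density. Reactions consuming an iron mineral are flagged
#' `upper_limit`: mineral availability is never the limiter, so the density
#' assumes unlimited mineral substrate.
#'
#' @param reaction A `ferro_reaction`.
#' @param site Activity map from [build_activity_map()].
#' @param n_e Electron count (defaults to [count_electrons()]).
#' @return One-row tibble (an energy result): identifiers, `logK`, `logQ`,
#'   `delta_g_kj_mol`, `delta_g_kj_mol_e`, `limiting_species`,
#'   `limiting_molality`, `energy_density_J_kg`, `exergonic`, `flags`.
#' @export
energy_density <- function(reaction, site, n_e = NULL) {
  dg <- delta_g(reaction, site, n_e = n_e)
  lim <- limiting_reactant(reaction, site)
  tab <- thermo_table()
  mineral_reactant <- any(
    tab$phase[match(names(reaction$reactants), tab$name)] == "mineral"
  )
  exergonic <- dg$delta_g_kj_mol < 0
  E <- max(0, -dg$delta_g_kj_mol) * 1000 * lim$m_over_nu
  flags <- c(
    if (nzchar(dg$flags)) dg$flags,
    if (mineral_reactant) "upper_limit"
  )
  tibble(
    reaction_id = reaction$reaction_id,
    site_id = attr(site, "site_id"),
    iron_species = reaction$iron_species,
    role = reaction$role,
    lifestyle = reaction$lifestyle,
    logK = dg$logK, logQ = dg$logQ,
    delta_g_kj_mol = dg$delta_g_kj_mol,
    delta_g_kj_mol_e = dg$delta_g_kj_mol_e,
    limiting_species = lim$species,
    limiting_molality = lim$molality,
    energy_density_J_kg = E,
    exergonic = exergonic,
    flags = paste(flags, collapse = ";")
  )
}

#' Reaction-by-site energy matrix
#'
#' Runs the full energetics pipeline: one activity map per site, then Gibbs
#' energy, limiting reactant and energy density for every library reaction at
#' every site.
#'
#' @param library Library tibble from [reaction_library()].
#' @param sites Site tibble from [load_site_table()] / [demmo_sites()].
#' @param config Settings from [geochem_config()].
#' @param units `"J_per_kg"` (default) or `"cal_per_kg"` for the density
#'   column.
#' @return Long-format tibble of class `ferro_energy`, one row per
#'   reaction-site cell.
#' @export
site_energy_matrix <- function(library = reaction_library(),
                               sites = demmo_sites(),
                               config = geochem_config(),
                               units = c("J_per_kg", "cal_per_kg")) {
  units <- match.arg(units)
  maps <- purrr::map(seq_len(nrow(sites)),
                     ~ build_activity_map(sites[.x, ], config))
  cells <- purrr::map(maps, function(am) {
    purrr::map2(library$reaction, library$n_e_printed,
                ~ energy_density(.x, am, n_e = .y)) %>% bind_rows()
  }) %>% bind_rows()
  if (units == "cal_per_kg") {
    cells <- cells %>%
      rename(energy_density_cal_kg = "energy_density_J_kg") %>%
      mutate(energy_density_cal_kg = .data$energy_density_cal_kg / 4.184)
  }
  structure(arrange(cells, .data$site_id, .data$reaction_id),
            units = units,
            class = c("ferro_energy", class(cells)))
}

#' @export
tidy.ferro_energy <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.ferro_energy <- function(x, ...) {
  dens <- x[[grep("^energy_density", names(x), value = TRUE)[1]]]
  tibble(
    n_reactions = dplyr::n_distinct(x$reaction_id),
    n_sites = dplyr::n_distinct(x$site_id),
    n_cells = nrow(x),
    n_exergonic = sum(x$exergonic),
    max_energy_density = max(dens)
  )
}

#' Heat-map of a reaction-by-site energy matrix
#'
#' Exergonic energy densities on a log10 color scale, faceted by lifestyle;
#' endergonic cells are blank, mirroring the convention that only reactions
#' with positive energy supply are displayed.
#'
#' @param object A `ferro_energy` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ferro_energy <- function(object, ...) {
  dens_col <- grep("^energy_density", names(object), value = TRUE)[1]
  df <- as_tibble(object) %>%
    mutate(
      label = paste0(substr(.data$iron_species, 1, 3), "_", .data$reaction_id),
      density = .data[[dens_col]]
    ) %>%
    filter(.data$exergonic, .data$density > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$site_id,
                                   stats::reorder(.data$label, .data$density),
                                   fill = log10(.data$density))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lifestyle),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ E)) +
    ggplot2::labs(x = "site", y = "reaction (iron species_id)") +
    ggplot2::theme_minimal()
}

#' Property checks on a reaction-by-site energy matrix
#'
#' Evaluates the qualitative orderings expected of the packaged site fixture:
#' (a) zero energy density for aqueous-Fe2+-donor reactions wherever ferrous
#' iron is absent; (b) ferrihydrite reduction with acetate attains the maximal
#' planktonic energy density at every site; (c) ferrous iron oxidation with
#' bicarbonate is endergonic at every site; (d) ferrous iron oxidation with
#' perchlorate has strongly negative Gibbs energy per electron yet
#' bottom-quartile energy density. Checks (b)-(d) depend on the packaged
#' thermodynamic data; each row carries the full Gibbs decomposition (logK,
#' logQ, per-mole and per-electron energies) so a failed ordering is
#' reportable, not silent.
#'
#' @param em A `ferro_energy` matrix over the packaged library.
#' @param strong_kj_per_e Threshold (kJ/mol e-) below which a per-electron
#'   Gibbs energy counts as strongly negative.
#' @return Tibble: `check`, `site_id`, `pass`, `detail` plus decomposition
#'   columns.
#' @export
energy_ordering_checks <- function(em, strong_kj_per_e = -20) {
  df <- as_tibble(em)
  dens <- grep("^energy_density", names(df), value = TRUE)[1]
  by_site <- split(df, df$site_id)
  rows <- purrr::imap(by_site, function(d, site) {
    fe_don <- d %>% filter(.data$iron_species == "Fe+2")
    fe2_absent <- fe_don$limiting_species == "Fe+2" &
      fe_don$limiting_molality == 0
    a_pass <- if (any(fe2_absent)) all(fe_don[[dens]][fe2_absent] == 0) else NA
    pl <- d %>% filter(.data$lifestyle == "planktonic")
    top <- pl %>% dplyr::slice_max(.data[[dens]], n = 1, with_ties = TRUE)
    b_pass <- all(top$reaction_id == 8)
    r3 <- d %>% filter(.data$reaction_id == 3)
    c_pass <- !r3$exergonic
    r1 <- d %>% filter(.data$reaction_id == 1)
    d_dg <- r1$delta_g_kj_mol_e <= strong_kj_per_e
    d_E <- r1[[dens]] <= stats::quantile(pl[[dens]], 0.25)
    decomp <- function(r) {
      sprintf("logK=%.3f logQ=%.3f dG=%.2f kJ/mol dG/e-=%.2f kJ/mol e- E=%.3g",
              r$logK, r$logQ, r$delta_g_kj_mol, r$delta_g_kj_mol_e, r[[dens]])
    }
    tibble(
      check = c("fe2_donor_zero_density", "fer_acetate_max_planktonic",
                "fe2_bicarbonate_endergonic", "fe2_perchlorate_dg",
                "fe2_perchlorate_bottom_quartile_E"),
      site_id = site,
      pass = c(a_pass, b_pass, c_pass, d_dg, d_E),
      detail = c(
        sprintf("Fe2+-donor reactions with zero ferrous iron: %d",
                sum(fe_don$limiting_species == "Fe+2" &
                      fe_don$limiting_molality == 0)),
        sprintf("max planktonic density: reaction %d (%s)",
                top$reaction_id[1], decomp(top[1, ])),
        sprintf("reaction 3: %s", decomp(r3)),
        sprintf("reaction 1: %s", decomp(r1)),
        sprintf("reaction 1 E=%.3g vs planktonic 25th pct %.3g",
                r1[[dens]], stats::quantile(pl[[dens]], 0.25))
      )
    )
  })
  bind_rows(rows)
}
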