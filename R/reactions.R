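# Oxidation states per canonical species (per atom). Fixed lookup rather than
# a general solver: disulfide S is -1, sulfate S +6, acetate C 0, etc.
.ox_states <- list(
  "H2O"          = c(H = 1, O = -2),
  "H+"           = c(H = 1),
  "OH-"          = c(H = 1, O = -2),
  "O2(aq)"       = c(O = 0),
  "H2(aq)"       = c(H = 0),
  "Fe+2"         = c(Fe = 2),
  "ferrihydrite" = c(Fe = 3, O = -2, H = 1),
  "goethite"     = c(Fe = 3, O = -2, H = 1),
  "lepidocrocite" = c(Fe = 3, O = -2, H = 1),
  "hematite"     = c(Fe = 3, O = -2),
  "magnetite"    = c(Fe = 8 / 3, O = -2),
  "pyrite"       = c(Fe = 2, S = -1),
  "siderite"     = c(Fe = 2, C = 4, O = -2),
  "HCO3-"        = c(H = 1, C = 4, O = -2),
  "CO3-2"        = c(C = 4, O = -2),
  "CO2(aq)"      = c(C = 4, O = -2),
  "CO(aq)"       = c(C = 2, O = -2),
  "CH4(aq)"      = c(C = -4, H = 1),
  "acetate"      = c(C = 0, H = 1, O = -2),
  "SO4-2"        = c(S = 6, O = -2),
  "HS-"          = c(S = -2, H = 1),
  "S0"           = c(S = 0),
  "Cl-"          = c(Cl = -1),
  "ClO4-"        = c(Cl = 7, O = -2),
  "NO3-"         = c(N = 5, O = -2),
  "NO2-"         = c(N = 3, O = -2),
  "NH4+"         = c(N = -3, H = 1),
  "Na+"          = c(Na = 1), "K+" = c(K = 1), "Ca+2" = c(Ca = 2)
)

.parse_side <- function(side, equation) {
  terms <- stringr::str_split(side, stringr::fixed(" + "))[[1]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) {
    abort(sprintf("empty reaction side in '%s'", equation),
          class = "ferroflux_parse_error")
  }
  m <- stringr::str_match(terms, "^([0-9]+(?:\\.[0-9]+)?)?\\s*(.+)$")
  bad <- which(is.na(m[, 3]))
  if (length(bad)) {
    abort(sprintf("malformed term '%s' (position %d) in '%s'",
                  terms[bad[1]], bad[1], equation),
          class = "ferroflux_parse_error")
  }
  nu <- ifelse(is.na(m[, 2]), 1, as.numeric(m[, 2]))
  species <- vapply(m[, 3], resolve_species, character(1), USE.NAMES = FALSE)
  agg <- tapply(nu, species, sum)[unique(species)]
  stats::setNames(as.vector(agg), names(agg))
}

#' Parse a reaction equation
#'
#' Terms are separated by `" + "`; sides by `"="` or a unicode double arrow.
#' Species names are resolved against the packaged thermodynamic table
#' (case-insensitive, aliases allowed; unqualified `FeOOH` resolves to
#' ferrihydrite, the kinetically expected fresh precipitate).
#'
#' @param equation Reaction string, e.g. `"4Fe+2 + O2 + 6H2O = 4FeOOH + 8H+"`.
#' @param reaction_id Optional identifier attached to the result.
#' @param iron_species,role Optional library annotations; when omitted the role
#'   is inferred from the iron-bearing reactant (Fe2+, pyrite and siderite act
#'   as electron donors; ferric (oxyhydr)oxides as acceptors).
#' @return An object of class `ferro_reaction`: named coefficient vectors
#'   `reactants` and `products` (all positive), plus identifiers.
#' @export
parse_reaction <- function(equation, reaction_id = NA_integer_,
                           iron_species = NULL, role = NULL) {
  eq <- stringr::str_replace_all(equation, "↔|⇌|<->|<=>", "=")
  sides <- stringr::str_split(eq, stringr::fixed("="))[[1]]
  if (length(sides) != 2) {
    abort(sprintf("expected exactly one '=' in '%s'", equation),
          class = "ferroflux_parse_error")
  }
  reactants <- .parse_side(sides[1], equation)
  products <- .parse_side(sides[2], equation)
  identity_rxn <- identical(reactants[sort(names(reactants))],
                            products[sort(names(products))])
  if (identity_rxn) {
    warn(sprintf("reaction '%s' has zero net stoichiometry", equation))
  }
  donors <- c("Fe+2", "pyrite", "siderite")
  acceptors <- c("ferrihydrite", "goethite", "lepidocrocite", "hematite",
                 "magnetite")
  fe_reactants <- intersect(names(reactants), c(donors, acceptors))
  if (is.null(iron_species)) {
    iron_species <- if (length(fe_reactants)) fe_reactants[1] else NA_character_
  } else {
    iron_species <- resolve_species(iron_species)
  }
  if (is.null(role)) {
    role <- if (length(fe_reactants) == 0) NA_character_
    else if (fe_reactants[1] %in% donors) "iron-as-donor" else "iron-as-acceptor"
  }
  lifestyle <- if (is.na(iron_species)) NA_character_
  else if (iron_species %in% c("Fe+2", "ferrihydrite")) "planktonic" else "biofilm"
  structure(
    list(reaction_id = reaction_id, equation = equation,
         reactants = reactants, products = products,
         iron_species = iron_species, role = role, lifestyle = lifestyle),
    class = "ferro_reaction"
  )
}

#' @export
print.ferro_reaction <- function(x, ...) {
  cat(sprintf("<reaction %s> %s\n", x$reaction_id, x$equation))
  invisible(x)
}

.expand_range <- function(id) {
  if (grepl("-", id, fixed = TRUE)) {
    parts <- as.integer(strsplit(id, "-", fixed = TRUE)[[1]])
    seq(parts[1], parts[2])
  } else {
    as.integer(id)
  }
}

#' Load and expand the packaged 48-reaction library
#'
#' Generic FeOOH electron-acceptor rows are instantiated three times, for
#' ferrihydrite, goethite and lepidocrocite (in that order, following the
#' library's id ranges); unqualified FeOOH produced by Fe2+-donor rows binds to
#' ferrihydrite. Reactions with aqueous Fe2+ or ferrihydrite are classed as
#' planktonic metabolisms, reactions with crystalline iron minerals as biofilm
#' metabolisms.
#'
#' @param variant `"rebalanced"` (default; rows 6/43/44/45 corrected to
#'   balance) or `"as-printed"` (verbatim table).
#' @param path Optional path to a library file in the packaged layout.
#' @return Tibble with one row per reaction: `reaction_id`, `equation`,
#'   `iron_species`, `role`, `lifestyle`, `n_e_printed` and a `reaction`
#'   list-column of parsed [parse_reaction()] objects.
#' @export
reaction_library <- function(variant = c("rebalanced", "as-printed"),
                             path = NULL) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    fname <- if (variant == "rebalanced") "reaction_library_rebalanced.tsv"
             else "reaction_library_printed.tsv"
    path <- system.file("extdata", fname, package = "ferroflux")
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(id = readr::col_character()))
  feooh <- c("FeOOH_fer", "FeOOH_goe", "FeOOH_lep")
  minerals <- c("ferrihydrite", "goethite", "lepidocrocite")
  rows <- purrr::pmap(raw, function(id, equation, iron_species, role,
                                    printed_n_e) {
    ids <- .expand_range(id)
    if (iron_species == "FeOOH") {
      stopifnot(length(ids) == 3)
      purrr::map2(ids, seq_along(ids), function(i, k) {
        eq <- stringr::str_replace_all(equation, "FeOOH\\b", feooh[k])
        tibble(reaction_id = i, equation = eq, iron_species = minerals[k],
               role = role, n_e_printed = printed_n_e)
      }) %>% bind_rows()
    } else {
      eq <- stringr::str_replace_all(equation, "FeOOH\\b", "FeOOH_fer")
      tibble(reaction_id = ids, equation = eq,
             iron_species = resolve_species(iron_species), role = role,
             n_e_printed = printed_n_e)
    }
  }) %>% bind_rows() %>% arrange(.data$reaction_id)
  rows %>%
    mutate(
      lifestyle = ifelse(.data$iron_species %in% c("Fe+2", "ferrihydrite"),
                         "planktonic", "biofilm"),
      reaction = purrr::pmap(
        list(.data$equation, .data$reaction_id, .data$iron_species, .data$role),
        function(eq, id, fe, ro) parse_reaction(eq, id, fe, ro)
      )
    ) %>%
    select("reaction_id", "equation", "iron_species", "role", "lifestyle",
           "n_e_printed", "reaction")
}

# accumulate named vectors: sum of sign * nu_i * per_species_value_i
.accumulate <- function(values) {
  all_names <- unique(unlist(lapply(values, names)))
  out <- stats::setNames(rep(0, length(all_names)), all_names)
  for (v in values) out[names(v)] <- out[names(v)] + v
  out
}

# signed stoichiometric totals per element (products minus reactants)
.element_totals <- function(reaction) {
  tab <- thermo_table()
  per_species <- function(species, nu, sign) {
    purrr::map2(species, nu, function(s, v) {
      sign * v * parse_formula(tab$formula[match(s, tab$name)])
    })
  }
  acc <- .accumulate(c(
    per_species(names(reaction$products), unname(reaction$products), 1),
    per_species(names(reaction$reactants), unname(reaction$reactants), -1)
  ))
  acc[abs(acc) < 1e-9] <- 0
  acc
}

#' Check mass and charge balance of a reaction
#'
#' Imbalances are products minus reactants; an all-zero report means the
#' equation is balanced.
#'
#' @param reaction A `ferro_reaction`.
#' @return List of class `ferro_balance`: `reaction_id`, `element_imbalance`
#'   (named vector), `charge_imbalance`, `balanced`.
#' @export
check_balance <- function(reaction) {
  tab <- thermo_table()
  el <- .element_totals(reaction)
  charge <- function(species, nu) sum(nu * tab$charge[match(species, tab$name)])
  dz <- charge(names(reaction$products), unname(reaction$products)) -
    charge(names(reaction$reactants), unname(reaction$reactants))
  structure(
    list(reaction_id = reaction$reaction_id, element_imbalance = el,
         charge_imbalance = dz,
         balanced = all(el == 0) && dz == 0),
    class = "ferro_balance"
  )
}

#' Balance report for a reaction library
#'
#' @param library A library tibble from [reaction_library()].
#' @return Tibble with per-reaction imbalance summaries (one column per element
#'   with any nonzero imbalance, plus `charge_imbalance` and `balanced`).
#' @export
balance_report <- function(library) {
  reports <- purrr::map(library$reaction, check_balance)
  els <- sort(unique(unlist(purrr::map(reports, ~ names(.x$element_imbalance)))))
  purrr::map2(reports, library$reaction_id, function(r, id) {
    v <- stats::setNames(rep(0, length(els)), els)
    v[names(r$element_imbalance)] <- r$element_imbalance
    tibble(reaction_id = id, !!!as.list(v),
           charge_imbalance = r$charge_imbalance, balanced = r$balanced)
  }) %>% bind_rows()
}

#' Count electrons transferred through the non-iron redox couple
#'
#' For each element other than iron, electrons gained are the drop in summed
#' oxidation state from reactants to products. When the iron species donates
#' electrons the couple is the oxidant (positive gains are summed); when an
#' iron mineral accepts electrons the couple is the donor (losses are summed).
#' This rule reproduces the printed per-reaction electron counts of the
#' packaged library, including rows whose printed stoichiometry is unbalanced,
#' because it never relies on overall balance.
#'
#' @param reaction A `ferro_reaction` with a `role`.
#' @return Integer electron count (0 with a warning if no redox change).
#' @export
count_electrons <- function(reaction) {
  tab <- thermo_table()
  ox_total <- function(species, nu) {
    .accumulate(purrr::map2(species, nu, function(s, v) {
      ox <- .ox_states[[s]]
      if (is.null(ox)) {
        abort(sprintf("no oxidation-state assignment for '%s'", s),
              class = "ferroflux_ox_state")
      }
      f <- parse_formula(tab$formula[match(s, tab$name)])
      v * f[names(ox)] * unlist(ox)
    }))
  }
  r <- ox_total(names(reaction$reactants), unname(reaction$reactants))
  p <- ox_total(names(reaction$products), unname(reaction$products))
  # an element is redox-active only if its per-atom oxidation state differs
  # between participating species; spectator elements (O at -2 throughout,
  # H at +1 throughout) are excluded so that mass-imbalanced printed rows
  # still yield the couple's electron count
  all_sp <- c(names(reaction$reactants), names(reaction$products))
  per_atom <- purrr::map(all_sp, ~ .ox_states[[.x]])
  active <- function(el) {
    states <- unlist(purrr::map(per_atom, ~ .x[el]))
    states <- states[!is.na(states)]
    length(unique(round(states, 9))) > 1
  }
  els <- setdiff(union(names(r), names(p)), "Fe")
  els <- els[vapply(els, active, logical(1))]
  get0n <- function(v, el) if (el %in% names(v)) v[[el]] else 0
  gained <- vapply(els, function(el) get0n(r, el) - get0n(p, el), numeric(1))
  role <- reaction$role
  n <- if (is.na(role %||% NA_character_)) {
    max(sum(pmax(gained, 0)), sum(pmax(-gained, 0)))
  } else if (role == "iron-as-donor") {
    sum(pmax(gained, 0))
  } else {
    sum(pmax(-gained, 0))
  }
  n <- round(n, 9)
  if (n == 0) {
    warn(sprintf("no redox couple found in '%s'; electron count 0",
                 reaction$equation))
  }
  n
}

#' Reaction quotient (log10 Q) under a site activity map
#'
#' Minerals and liquid water contribute nothing (unit activity). Species whose
#' activity was floored (true concentration zero or below detection) use the
#' floored activity, and the result is flagged approximate.
#'
#' @param reaction A `ferro_reaction`.
#' @param activities An activity map from [build_activity_map()].
#' @return log10 Q with attribute `approximate` (logical).
#' @export
reaction_quotient <- function(reaction, activities) {
  amap <- activities
  log_a <- function(species, nu) {
    tot <- 0
    approx <- FALSE
    tab <- thermo_table()
    for (i in seq_along(species)) {
      phase <- tab$phase[match(species[i], tab$name)]
      if (phase != "aqueous") next
      row <- match(species[i], amap$species)
      if (is.na(row)) {
        abort(sprintf("species '%s' missing from activity map", species[i]),
              class = "ferroflux_missing_activity")
      }
      a <- amap$activity_floored[row]
      if (!is.na(amap$flag[row]) && amap$flag[row] == "below_floor") approx <- TRUE
      tot <- tot + nu[i] * log10(a)
    }
    list(tot = tot, approx = approx)
  }
  p <- log_a(names(reaction$products), unname(reaction$products))
  r <- log_a(names(reaction$reactants), unname(reaction$reactants))
  structure(p$tot - r$tot, approximate = p$approx || r$approx)
}

#' In situ Gibbs energy of a reaction at one site
#'
#' \eqn{\Delta G_r = \ln(10) R T (\log Q - \log K)} at the site temperature,
#' in kJ per mole of reaction as written, plus the per-electron value using the
#' library's electron count.
#'
#' @param reaction A `ferro_reaction`.
#' @param site An activity map from [build_activity_map()].
#' @param n_e Electron count; defaults to [count_electrons()].
#' @return One-row tibble: `reaction_id`, `site_id`, `logK`, `logQ`,
#'   `delta_g_kj_mol`, `delta_g_kj_mol_e`, `flags`.
#' @export
delta_g <- function(reaction, site, n_e = NULL) {
  T_K <- attr(site, "T_K")
  lk <- log_k(reaction, T_K)
  lq <- reaction_quotient(reaction, site)
  dg <- log(10) * .R_GAS * T_K * (as.numeric(lq) - lk) / 1000
  if (is.null(n_e)) n_e <- suppressWarnings(count_electrons(reaction))
  tibble(
    reaction_id = reaction$reaction_id,
    site_id = attr(site, "site_id"),
    logK = lk, logQ = as.numeric(lq),
    delta_g_kj_mol = dg,
    delta_g_kj_mol_e = if (n_e > 0) dg / n_e else NA_real_,
    flags = if (isTRUE(attr(lq, "approximate"))) "approximate" else ""
  )
}
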