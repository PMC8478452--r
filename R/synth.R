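# Gene-family pools per annotation category (emulated vocabularies).
.family_pools <- list(
  "iron oxidation" = c("Cyc2_cluster1", "Cyc2_cluster2", "Cyc2_cluster3",
                       "MtoA", "FoxB"),
  "iron reduction" = c("OmcF", "OmcS", "OmcZ", "DFE_0448", "DFE_0449",
                       "MtrA", "other_porin_cytochrome"),
  "iron acquisition-siderophore transport" = c("TonB", "ExbB", "ExbD", "FepC"),
  "iron acquisition-iron transport" = c("FeoA", "FeoB", "FutA"),
  "iron acquisition-siderophore synthesis" = c("MbtI", "EntA"),
  "iron storage" = c("Bfr", "FtnA", "Dps"),
  "iron gene regulation" = c("Fur", "PchR", "RirA"),
  "Metal reduction" = c("MtrB", "MtrC"),
  "Oxidative phosphorylation" = c("CoxA", "CoxB"),
  "Oxygen Metabolism (Oxidative phosphorylation Complex IV)" = c("CcoN"),
  "Hydrogenases" = c("HyaB", "HybC", "HndD"),
  "Nitrate reduction" = c("NarG", "NapA"),
  "Carbon fixation" = c("RbcL", "AclB"),
  "Organic carbon oxidation" = c("AcsA", "Pta"),
  "Methane oxidation" = c("PmoA", "McrA"),
  "Ammonia oxidation" = c("AmoA")
)

.default_taxa <- c(
  "Gallionellaceae", "Rhodocyclaceae", "Thermodesulfovibrionia",
  "Desulfobulbaceae", "Ignavibacteriales", "Ca. Zixibacteria",
  "Gemmatimonadota", "Deferrisomatota", "Nitrospirota", "MBNT15"
)

# Per-metagenome expected category fractions (of total genes). The iron-rich
# profile puts energy iron genes near 4.5e-4 of the metagenome; the control
# profiles emulate a distinct service-water-like community and a surface
# community with no detectable iron-energy genes.
.category_fractions <- function(profile = c("iron_rich", "sulfidic",
                                            "sw_control", "wc_control")) {
  profile <- match.arg(profile)
  base <- c(
    "fegenie|iron oxidation" = 1.5e-4,
    "fegenie|iron reduction" = 2.5e-4,
    "fegenie|iron acquisition-siderophore transport" = 4e-4,
    "fegenie|iron acquisition-iron transport" = 3e-4,
    "fegenie|iron acquisition-siderophore synthesis" = 2e-5,
    "fegenie|iron storage" = 8e-5,
    "fegenie|iron gene regulation" = 2.5e-4,
    "metabolic|Metal reduction" = 1e-4,
    "metabolic|Oxidative phosphorylation" = 8e-4,
    "metabolic|Oxygen Metabolism (Oxidative phosphorylation Complex IV)" = 4e-4,
    "metabolic|Hydrogenases" = 6e-4,
    "metabolic|Nitrate reduction" = 5e-4,
    "metabolic|Carbon fixation" = 7e-4,
    "metabolic|Organic carbon oxidation" = 9e-4,
    "metabolic|Methane oxidation" = 1e-4
  )
  scale <- switch(profile,
    iron_rich = base,
    sulfidic = {
      b <- base
      b[grepl("iron oxidation|iron reduction|Metal reduction", names(b))] <-
        b[grepl("iron oxidation|iron reduction|Metal reduction", names(b))] / 5
      b
    },
    sw_control = {
      b <- base / 2
      b["fegenie|iron reduction"] <- 0
      b
    },
    wc_control = {
      b <- base
      b[grepl("fegenie", names(b))] <- 0
      b["metabolic|Metal reduction"] <- 1e-5
      b * 2
    }
  )
  scale
}

#' Specification for the synthetic-data generator
#'
#' Defaults emulate the shape of the study system: six subsurface sites along
#' an iron-rich to sulfidic gradient plus two control communities, a few
#' hundred thousand genes per metagenome, iron-gene relative abundances of
#' order 1e-4, a small dual-pipeline ambiguous fraction, and 515 genome bins
#' whose housekeeping-combination mix reproduces the reported 49.5 / 19.8 /
#' 15.7 percent split.
#'
#' @param seed Integer seed (mandatory; every generated byte is a function of
#'   the spec and this seed).
#' @param n_sites Number of geochemistry sites.
#' @param n_metagenomes Number of metagenomes (last two are the control-like
#'   profiles when >= 3).
#' @param total_genes Total gene count per metagenome (recycled).
#' @param ambiguous_fraction Fraction of annotated hits planted as
#'   dual-pipeline ambiguous features.
#' @param n_legit_dual Per metagenome, number of agreeing dual-pipeline ORFs
#'   (FeGenie iron reduction + METABOLIC Metal reduction) that must survive
#'   reconciliation.
#' @param n_mags Number of genome bins.
#' @param mag_combo_counts Named integer vector of planted housekeeping
#'   combinations (names as in [housekeeping_combos()] output).
#' @param taxa Taxon label pool.
#' @return List of class `ferro_synth_spec`.
#' @export
synth_spec <- function(seed,
                       n_sites = 6,
                       n_metagenomes = 8,
                       total_genes = 3e5,
                       ambiguous_fraction = 0.0013,
                       n_legit_dual = 5,
                       n_mags = 515,
                       mag_combo_counts = c(
                         "acquisition+storage+regulation" = 255,
                         "acquisition+regulation" = 102,
                         "regulation" = 81,
                         "acquisition" = 20,
                         "storage" = 10,
                         "acquisition+storage" = 15,
                         "storage+regulation" = 15,
                         "none" = 17
                       ),
                       taxa = .default_taxa) {
  if (missing(seed)) abort("seed is mandatory", class = "ferroflux_input_error")
  stopifnot(ambiguous_fraction >= 0, ambiguous_fraction <= 1,
            n_sites >= 1, n_metagenomes >= 1, all(total_genes > 0))
  if (n_mags > 0 && sum(mag_combo_counts) != n_mags) {
    abort("mag_combo_counts must sum to n_mags",
          class = "ferroflux_input_error")
  }
  structure(
    list(seed = as.integer(seed), n_sites = n_sites,
         n_metagenomes = n_metagenomes,
         total_genes = rep_len(total_genes, n_metagenomes),
         ambiguous_fraction = ambiguous_fraction,
         n_legit_dual = n_legit_dual, n_mags = n_mags,
         mag_combo_counts = mag_combo_counts, taxa = taxa),
    class = "ferro_synth_spec"
  )
}

# log-uniform analyte bounds (mg/liter) bracketing the packaged site table
.geochem_bounds <- tibble::tribble(
  ~analyte, ~lo,     ~hi,
  "DOC",    0.2,     0.5,
  "NO3-",   0.2,     1.2,
  "NH4+",   0.02,    1.5,
  "Fe2+",   0.3,     3.0,
  "Total_Fe", 0.3,   7.0,
  "S2-",    0.004,   0.6,
  "DO",     0.01,    0.06,
  "SO4-2",  80,      4200,
  "Cl-",    15,      220,
  "CH4",    5e-6,    5e-3,
  "H2",     1e-7,    3.1e-7,
  "CO2",    0.002,   0.1,
  "CO",     2.5e-6,  9e-6
)

#' Generate a synthetic site geochemistry table
#'
#' Analytes are drawn log-uniformly within bounds bracketing the packaged
#' site table; the last site is a sulfidic preset (no ferrous iron, high
#' sulfide) so downstream energy densities for Fe2+-donor reactions are
#' forced to zero there. Output is loadable by [load_site_table()] and
#' byte-identical across reruns at a fixed spec and seed.
#'
#' @param spec A [synth_spec()].
#' @param path Optional output path (tab-separated, site-table layout).
#' @return Site tibble (invisibly the path when written).
#' @export
gen_geochem <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "ferro_synth_spec"))
  b <- .geochem_bounds
  if (any(b$lo <= 0 | b$hi <= b$lo)) {
    abort("invalid analyte bounds", class = "ferroflux_input_error")
  }
  sites <- withr::with_seed(spec$seed, {
    n <- spec$n_sites
    draw <- function(lo, hi) 10^stats::runif(n, log10(lo), log10(hi))
    out <- tibble(
      site_id = sprintf("S%d", seq_len(n)),
      depth_m = round(stats::runif(n, 200, 1500)),
      temperature_C = round(stats::runif(n, 10, 32), 1),
      pH = round(stats::runif(n, 7.0, 8.7), 1),
      orp_mV = round(stats::runif(n, -200, -60))
    )
    for (i in seq_len(nrow(b))) {
      out[[b$analyte[i]]] <- signif(draw(b$lo[i], b$hi[i]), 3)
    }
    # sulfidic preset: iron-free, sulfide-rich end member
    out$`Fe2+`[n] <- 0
    out$Total_Fe[n] <- 0
    out$`S2-`[n] <- signif(max(out$`S2-`) * 2, 3)
    out
  })
  if (!is.null(path)) {
    hdr <- c("Parameter", sites$site_id)
    rows <- list(
      c("Depth_m", format(sites$depth_m)),
      c("Temp_C", format(sites$temperature_C)),
      c("pH", format(sites$pH)),
      c("ORP_mV", format(sites$orp_mV))
    )
    for (a in .geochem_bounds$analyte) {
      rows <- c(rows, list(c(a, sprintf("%.6g", sites[[a]]))))
    }
    lines <- vapply(c(list(hdr), rows),
                    function(r) paste(trimws(r), collapse = "\t"),
                    character(1))
    writeLines(c("# synthetic site geochemistry (ferroflux generator)",
                 sprintf("# seed=%d n_sites=%d", spec$seed, spec$n_sites),
                 lines), path)
  }
  sites
}

#' Generate synthetic annotation hit tables with planted structure
#'
#' Per-category hit counts are drawn multinomially from planted fractions of
#' the per-metagenome total gene count (so totals are exact and recovery is
#' testable with closed-form binomial intervals). A planted number of
#' dual-pipeline "ambiguous" ORFs (mismatched category pairs) is injected on
#' top, plus a planted number of agreeing dual-pipeline ORFs that must
#' survive reconciliation. A truth table records exact planted counts.
#'
#' @param spec A [synth_spec()].
#' @param dir Optional output directory; writes `hits.tsv`, `totals.tsv`,
#'   `truth_counts.tsv`, `truth_summary.tsv`.
#' @return List: `hits`, `totals`, `truth_counts` (kept hits per
#'   metagenome/tool/category), `truth_summary` (per metagenome: planted
#'   ambiguous features/hits).
#' @export
gen_annotations <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "ferro_synth_spec"))
  profiles <- c("iron_rich", "sulfidic", "sw_control", "wc_control")
  mg_profile <- function(i) {
    if (spec$n_metagenomes >= 3 && i == spec$n_metagenomes) "wc_control"
    else if (spec$n_metagenomes >= 3 && i == spec$n_metagenomes - 1) "sw_control"
    else if (i %% 3 == 0) "sulfidic" else "iron_rich"
  }
  res <- withr::with_seed(spec$seed + 1L, {
    all_hits <- list(); truth <- list(); summaries <- list()
    for (i in seq_len(spec$n_metagenomes)) {
      mg <- sprintf("MG%02d", i)
      tg <- spec$total_genes[i]
      frac <- .category_fractions(mg_profile(i))
      p <- c(frac, other = 1 - sum(frac))
      counts <- as.vector(stats::rmultinom(1, tg, p))
      names(counts) <- names(p)
      counts <- counts[names(frac)]
      hit_rows <- purrr::imap(counts, function(k, key) {
        if (k == 0) return(NULL)
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        fams <- .family_pools[[parts[2]]]
        tibble(metagenome_id = mg, tool = parts[1], category = parts[2],
               gene_family = sample(fams, k, replace = TRUE))
      }) %>% bind_rows()
      if (nrow(hit_rows)) {
        hit_rows <- hit_rows[sample.int(nrow(hit_rows)), ]
        hit_rows$orf_id <- sprintf("%s_c%05d_orf%03d", mg,
                                   seq_len(nrow(hit_rows)),
                                   sample.int(999, nrow(hit_rows),
                                              replace = TRUE))
        hit_rows$taxon <- sample(spec$taxa, nrow(hit_rows), replace = TRUE)
      } else {
        hit_rows <- tibble(metagenome_id = character(), tool = character(),
                           category = character(), gene_family = character(),
                           orf_id = character(), taxon = character())
      }
      # agreeing dual-pipeline ORFs: share orf ids between the two tools
      ir <- which(hit_rows$tool == "fegenie" &
                    hit_rows$category == "iron reduction")
      mr <- which(hit_rows$tool == "metabolic" &
                    hit_rows$category == "Metal reduction")
      n_dual <- min(spec$n_legit_dual, length(ir), length(mr))
      if (n_dual > 0) {
        hit_rows$orf_id[mr[seq_len(n_dual)]] <-
          hit_rows$orf_id[ir[seq_len(n_dual)]]
      }
      # ambiguous features: mismatched dual-pipeline category pairs
      n_amb <- round(spec$ambiguous_fraction * nrow(hit_rows))
      amb <- NULL
      if (n_amb > 0) {
        fe_cat <- sample(setdiff(.fegenie_categories, "iron reduction"),
                         n_amb, replace = TRUE)
        me_cat <- sample(.metabolic_categories, n_amb, replace = TRUE)
        amb_ids <- sprintf("%s_amb%04d_orf%03d", mg, seq_len(n_amb),
                           sample.int(999, n_amb, replace = TRUE))
        amb <- bind_rows(
          tibble(metagenome_id = mg, tool = "fegenie", category = fe_cat,
                 gene_family = purrr::map_chr(fe_cat,
                                              ~ sample(.family_pools[[.x]], 1)),
                 orf_id = amb_ids,
                 taxon = sample(spec$taxa, n_amb, replace = TRUE)),
          tibble(metagenome_id = mg, tool = "metabolic", category = me_cat,
                 gene_family = purrr::map_chr(me_cat,
                                              ~ sample(.family_pools[[.x]], 1)),
                 orf_id = amb_ids,
                 taxon = sample(spec$taxa, n_amb, replace = TRUE))
        )
      }
      all_hits[[i]] <- bind_rows(hit_rows, amb)
      truth[[i]] <- tibble(
        metagenome_id = mg,
        tool = sub("\\|.*", "", names(counts)),
        category = sub(".*\\|", "", names(counts)),
        planted_hits = unname(counts)
      )
      summaries[[i]] <- tibble(metagenome_id = mg, total_genes = tg,
                               n_ambiguous_features = n_amb,
                               n_ambiguous_hits = if (n_amb > 0) 2L * n_amb else 0L,
                               n_agreeing_dual = n_dual)
    }
    list(hits = bind_rows(all_hits), truth_counts = bind_rows(truth),
         truth_summary = bind_rows(summaries))
  })
  totals <- tibble(metagenome_id = sprintf("MG%02d", seq_len(spec$n_metagenomes)),
                   total_genes = spec$total_genes)
  out <- list(hits = res$hits %>%
                select("metagenome_id", "orf_id", "tool", "category",
                       "gene_family", "taxon"),
              totals = totals, truth_counts = res$truth_counts,
              truth_summary = res$truth_summary)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out$hits, file.path(dir, "hits.tsv"))
    readr::write_tsv(out$totals, file.path(dir, "totals.tsv"))
    readr::write_tsv(out$truth_counts, file.path(dir, "truth_counts.tsv"))
    readr::write_tsv(out$truth_summary, file.path(dir, "truth_summary.tsv"))
  }
  out
}

#' Generate a synthetic MAG table with planted housekeeping combinations
#'
#' Each genome bin receives housekeeping-category hits realizing exactly its
#' planted combination, so [housekeeping_combos()] recovers the planted
#' percentages exactly; a subset of bins additionally carries iron
#' oxidation/reduction genes for taxon-matrix summaries.
#'
#' @param spec A [synth_spec()].
#' @param energy_fraction Fraction of MAGs carrying at least one
#'   energy-category gene.
#' @param dir Optional output directory; writes `mags.tsv`, `mag_hits.tsv`,
#'   `truth_combos.tsv`.
#' @return List: `mags`, `hits` (per-ORF with `mag_id`), `truth_combos`.
#' @export
gen_mags <- function(spec, energy_fraction = 0.25, dir = NULL) {
  stopifnot(inherits(spec, "ferro_synth_spec"))
  if (spec$n_mags == 0) {
    empty_mags <- tibble(mag_id = character(), metagenome_id = character(),
                         taxon = character(), completeness = numeric())
    empty_hits <- tibble(metagenome_id = character(), orf_id = character(),
                         tool = character(), category = character(),
                         gene_family = character(), mag_id = character(),
                         taxon = character())
    return(list(mags = empty_mags, hits = empty_hits,
                truth_combos = tibble(combination = character(),
                                      n_mags = integer())))
  }
  group_cat <- c(acquisition = "iron acquisition-iron transport",
                 storage = "iron storage",
                 regulation = "iron gene regulation")
  res <- withr::with_seed(spec$seed + 2L, {
    combo_of <- rep(names(spec$mag_combo_counts), spec$mag_combo_counts)
    combo_of <- sample(combo_of)
    mags <- tibble(
      mag_id = sprintf("MAG%04d", seq_len(spec$n_mags)),
      metagenome_id = sprintf("MG%02d",
                              sample.int(max(1, spec$n_metagenomes),
                                         spec$n_mags, replace = TRUE)),
      taxon = sample(spec$taxa, spec$n_mags, replace = TRUE),
      completeness = round(stats::runif(spec$n_mags, 14, 100), 1),
      combination = combo_of
    )
    hk_hits <- purrr::pmap(mags, function(mag_id, metagenome_id, taxon,
                                          completeness, combination) {
      if (combination == "none") return(NULL)
      groups <- strsplit(combination, "+", fixed = TRUE)[[1]]
      purrr::map(groups, function(g) {
        cat <- group_cat[[g]]
        tibble(metagenome_id = metagenome_id,
               orf_id = sprintf("%s_hk_%s", mag_id, g),
               tool = "fegenie", category = cat,
               gene_family = sample(.family_pools[[cat]], 1),
               mag_id = mag_id, taxon = taxon)
      }) %>% bind_rows()
    }) %>% bind_rows()
    n_energy <- round(energy_fraction * spec$n_mags)
    energy_hits <- NULL
    if (n_energy > 0) {
      pick <- sample.int(spec$n_mags, n_energy)
      energy_hits <- purrr::map(pick, function(i) {
        cat <- sample(.energy_categories, 1)
        tibble(metagenome_id = mags$metagenome_id[i],
               orf_id = sprintf("%s_en", mags$mag_id[i]),
               tool = "fegenie", category = cat,
               gene_family = sample(.family_pools[[cat]], 1),
               mag_id = mags$mag_id[i], taxon = mags$taxon[i])
      }) %>% bind_rows()
    }
    list(mags = mags, hits = bind_rows(hk_hits, energy_hits))
  })
  truth <- res$mags %>% count(.data$combination, name = "n_mags") %>%
    rename(combination = "combination")
  mags_out <- res$mags %>% select(-"combination")
  out <- list(mags = mags_out, hits = res$hits, truth_combos = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(mags_out, file.path(dir, "mags.tsv"))
    readr::write_tsv(out$hits, file.path(dir, "mag_hits.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth_combos.tsv"))
  }
  out
}
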