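# serialize config -> md5 hash (stable across runs for identical settings)
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

.output_header <- function(config, seed = NA) {
  version <- as.character(utils::packageVersion("ferroflux"))
  sprintf("# ferroflux %s; config_hash=%s; seed=%s",
          version, .config_hash(config),
          ifelse(is.na(seed), "none", seed))
}

.write_table <- function(df, path, header) {
  body <- readr::format_tsv(df)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Run the full energetics pipeline and write its outputs
#'
#' Loads a site table, builds activity maps, evaluates the reaction library
#' and writes: the long-format energy table (`energy_table.tsv`), the balance
#' report (`balance_report.tsv`), one activity report per site
#' (`activity_<site>.tsv`) and the resolved configuration
#' (`run_config.yaml`). Outputs are deterministic: identical inputs and
#' configuration give byte-identical files.
#'
#' @param sites_path Site geochemistry table (tab-separated).
#' @param out_dir Output directory (created if needed).
#' @param library_variant `"rebalanced"` or `"as-printed"`.
#' @param config Settings from [geochem_config()].
#' @param units Energy-density units.
#' @return The `ferro_energy` matrix, invisibly.
#' @export
run_energetics <- function(sites_path, out_dir,
                           library_variant = c("rebalanced", "as-printed"),
                           config = geochem_config(),
                           units = "J_per_kg") {
  library_variant <- match.arg(library_variant)
  if (!file.exists(sites_path)) {
    abort(sprintf("site file not found: %s", sites_path),
          class = "ferroflux_input_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sites <- load_site_table(sites_path)
  lib <- reaction_library(library_variant)
  full_config <- c(config, list(library_variant = library_variant,
                                units = units))
  header <- .output_header(full_config)
  energy <- site_energy_matrix(lib, sites, config, units)
  fmt <- as_tibble(energy)
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], signif, digits = 10)
  .write_table(fmt, file.path(out_dir, "energy_table.tsv"), header)
  .write_table(balance_report(lib),
               file.path(out_dir, "balance_report.tsv"), header)
  for (i in seq_len(nrow(sites))) {
    am <- build_activity_map(sites[i, ], config)
    write_activity_map(am, file.path(out_dir,
                                     sprintf("activity_%s.tsv",
                                             sites$site_id[i])))
  }
  writeLines(c(header, yaml::as.yaml(full_config)),
             file.path(out_dir, "run_config.yaml"))
  invisible(energy)
}

#' Run the gene-profile pipeline and write its outputs
#'
#' Reads hit and totals tables, reconciles dual-pipeline ambiguous features,
#' normalizes to relative abundances, clusters metagenomes on
#' energy-metabolism iron genes (Bray-Curtis + UPGMA) and, when MAG inputs
#' are given, writes genome-bin summaries. Outputs: `profile.tsv`,
#' `bray_curtis.tsv`, `tree.nwk`, `recategorized.tsv`, optionally
#' `mag_presence.tsv`, `taxon_matrix.tsv`, `housekeeping_combos.tsv`, plus
#' `run_config.yaml`.
#'
#' @param hits_path,totals_path Tab-separated hit and totals tables.
#' @param out_dir Output directory.
#' @param mags_path Optional MAG table.
#' @param mag_hits_path Optional MAG-resolved hit table.
#' @param key Reconciliation key (`"orf"` or `"contig"`).
#' @param mapping Recategorization map.
#' @return List of result objects, invisibly.
#' @export
run_profiles <- function(hits_path, totals_path, out_dir,
                         mags_path = NULL, mag_hits_path = NULL,
                         key = "orf", mapping = default_recategorization()) {
  for (p in c(hits_path, totals_path)) {
    if (!file.exists(p)) {
      abort(sprintf("input file not found: %s", p),
            class = "ferroflux_input_error")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hits <- readr::read_tsv(hits_path, show_col_types = FALSE, progress = FALSE)
  .check_hits(hits)
  totals <- readr::read_tsv(totals_path, show_col_types = FALSE,
                            progress = FALSE)
  config <- list(key = key, mapping = as.list(mapping))
  header <- .output_header(config)

  rec <- reconcile_ambiguous(hits, key = key)
  prof <- relative_abundance(rec$kept, totals)
  merged <- recategorize(prof, mapping)
  fe_prof <- prof %>% filter(.data$tool == "fegenie")
  class(fe_prof) <- class(prof)
  attr(fe_prof, "total_genes") <- attr(prof, "total_genes")
  D <- bray_curtis(fe_prof)
  tree <- upgma(D)

  .write_table(as_tibble(prof), file.path(out_dir, "profile.tsv"), header)
  .write_table(as_tibble(merged), file.path(out_dir, "recategorized.tsv"),
               header)
  dmat <- as_tibble(as.data.frame(D), rownames = "metagenome_id")
  .write_table(dmat, file.path(out_dir, "bray_curtis.tsv"), header)
  write_newick(tree, file.path(out_dir, "tree.nwk"))

  out <- list(reconciliation = rec, profile = prof, recategorized = merged,
              dissimilarity = D, tree = tree)
  if (!is.null(mags_path) && !is.null(mag_hits_path)) {
    mags <- readr::read_tsv(mags_path, show_col_types = FALSE,
                            progress = FALSE)
    mag_hits <- readr::read_tsv(mag_hits_path, show_col_types = FALSE,
                                progress = FALSE)
    ms <- mag_summary(mag_hits, mags)
    combos <- housekeeping_combos(ms$presence, mags)
    .write_table(ms$presence, file.path(out_dir, "mag_presence.tsv"), header)
    .write_table(ms$taxon_matrix, file.path(out_dir, "taxon_matrix.tsv"),
                 header)
    .write_table(combos, file.path(out_dir, "housekeeping_combos.tsv"),
                 header)
    out$mag_summary <- ms
    out$housekeeping_combos <- combos
  }
  writeLines(c(header, yaml::as.yaml(config)),
             file.path(out_dir, "run_config.yaml"))
  invisible(out)
}

#' Heat-map of gene-profile relative abundances
#'
#' @param object A `ferro_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ferro_profile <- function(object, ...) {
  df <- as_tibble(object)
  feature <- if ("gene_family" %in% names(df)) {
    paste(df$category, df$gene_family, sep = "|")
  } else {
    df$category
  }
  df$feature <- feature
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$metagenome_id,
                                   fill = log10(.data$rel_abundance + 1e-8))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ abundance)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' @export
tidy.ferro_upgma <- function(x, ...) {
  tibble(step = seq_along(x$height),
         left = x$merge[, 1], right = x$merge[, 2],
         merge_dissimilarity = x$height,
         node_height = x$node_height)
}

#' @export
glance.ferro_upgma <- function(x, ...) {
  tibble(n_leaves = length(x$labels),
         root_height = max(x$node_height),
         ultrametric = TRUE)
}
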