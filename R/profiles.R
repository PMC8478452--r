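# Category vocabulary of the emulated annotation pipelines.
.fegenie_categories <- c(
  "iron oxidation", "iron reduction",
  "iron acquisition-siderophore transport",
  "iron acquisition-iron transport",
  "iron acquisition-siderophore synthesis",
  "iron storage", "iron gene regulation"
)
.metabolic_categories <- c(
  "Metal reduction", "Oxidative phosphorylation",
  "Oxygen Metabolism (Oxidative phosphorylation Complex IV)",
  "Hydrogenases", "Nitrate reduction", "Carbon fixation",
  "Organic carbon oxidation", "Methane oxidation", "Ammonia oxidation"
)

#' Category vocabulary for annotation hits
#' @return Named list with `fegenie` and `metabolic` character vectors.
#' @export
category_vocabulary <- function() {
  list(fegenie = .fegenie_categories, metabolic = .metabolic_categories)
}

.energy_categories <- c("iron oxidation", "iron reduction")
.housekeeping_groups <- c(acquisition = "iron acquisition",
                          storage = "iron storage",
                          regulation = "iron gene regulation")

.check_hits <- function(hits) {
  needed <- c("metagenome_id", "orf_id", "tool", "category", "gene_family")
  missing <- setdiff(needed, names(hits))
  if (length(missing)) {
    abort(sprintf("hit table is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "ferroflux_input_error")
  }
  invisible(hits)
}

#' Remove dual-pipeline ambiguous annotations
#'
#' A feature annotated by both pipelines is kept only when its category pair
#' is exactly FeGenie "iron reduction" with METABOLIC "Metal reduction" — the
#' one combination where the two vocabularies genuinely agree. Every other
#' dual-pipeline combination is reannotated ambiguous and removed before
#' normalization. Single-pipeline features are always kept.
#'
#' @param hits Hit tibble (columns `metagenome_id`, `orf_id`, `tool`,
#'   `category`, `gene_family`, optionally `contig_id`).
#' @param key `"orf"` (default) or `"contig"`: the identifier on which the
#'   dual-annotation test is made. Contig keying requires a `contig_id`
#'   column.
#' @return List: `kept` (hit tibble), `removed` (hit tibble),
#'   `removed_features` (count of ambiguous ORFs/contigs), `removed_hits`
#'   (count of removed rows).
#' @export
reconcile_ambiguous <- function(hits, key = c("orf", "contig")) {
  key <- match.arg(key)
  .check_hits(hits)
  keycol <- if (key == "orf") "orf_id" else "contig_id"
  if (!keycol %in% names(hits)) {
    abort(sprintf("key column '%s' not present", keycol),
          class = "ferroflux_input_error")
  }
  status <- hits %>%
    group_by(.data$metagenome_id, .data[[keycol]]) %>%
    summarise(
      both = dplyr::n_distinct(.data$tool) > 1,
      agreeing = all(
        (.data$tool == "fegenie" & .data$category == "iron reduction") |
          (.data$tool == "metabolic" & .data$category == "Metal reduction")
      ),
      .groups = "drop"
    ) %>%
    mutate(ambiguous = .data$both & !.data$agreeing)
  joined <- hits %>%
    left_join(status, by = c("metagenome_id", keycol))
  kept <- joined %>% filter(!.data$ambiguous) %>%
    select(-"both", -"agreeing", -"ambiguous")
  removed <- joined %>% filter(.data$ambiguous) %>%
    select(-"both", -"agreeing", -"ambiguous")
  list(kept = kept, removed = removed,
       removed_features = sum(status$ambiguous),
       removed_hits = nrow(removed))
}

#' Normalize hit counts to relative abundances
#'
#' Each (metagenome, category, gene family) hit count is divided by the
#' metagenome's total gene count, giving exact fractions. Metagenomes present
#' in `total_genes` but without hits are retained as all-zero rows, so a
#' community with no detected iron genes (a surface-control-like outgroup)
#' stays representable.
#'
#' @param hits Kept hit tibble (after [reconcile_ambiguous()]).
#' @param total_genes Named numeric vector or two-column tibble
#'   (`metagenome_id`, `total_genes`).
#' @return Tibble of class `ferro_profile`: `metagenome_id`, `tool`,
#'   `category`, `gene_family`, `hits`, `rel_abundance`; attribute
#'   `total_genes`.
#' @export
relative_abundance <- function(hits, total_genes) {
  .check_hits(hits)
  if (!is.data.frame(total_genes)) {
    total_genes <- tibble(metagenome_id = names(total_genes),
                          total_genes = as.numeric(total_genes))
  }
  stopifnot(all(total_genes$total_genes > 0))
  missing <- setdiff(unique(hits$metagenome_id), total_genes$metagenome_id)
  if (length(missing)) {
    abort(sprintf("no total-genes entry for: %s",
                  paste(missing, collapse = ", ")),
          class = "ferroflux_input_error")
  }
  counts <- hits %>%
    count(.data$metagenome_id, .data$tool, .data$category, .data$gene_family,
          name = "hits")
  combos <- counts %>% distinct(.data$tool, .data$category, .data$gene_family)
  if (nrow(combos) == 0) {
    combos <- tibble(tool = character(), category = character(),
                     gene_family = character())
  }
  grid <- tidyr::crossing(
    metagenome_id = total_genes$metagenome_id, combos
  )
  prof <- grid %>%
    left_join(counts,
              by = c("metagenome_id", "tool", "category", "gene_family")) %>%
    mutate(hits = tidyr::replace_na(.data$hits, 0)) %>%
    left_join(total_genes, by = "metagenome_id") %>%
    mutate(rel_abundance = .data$hits / .data$total_genes) %>%
    select(-"total_genes") %>%
    arrange(.data$metagenome_id, .data$tool, .data$category, .data$gene_family)
  structure(prof,
            total_genes = stats::setNames(total_genes$total_genes,
                                          total_genes$metagenome_id),
            class = c("ferro_profile", class(prof)))
}

#' Default pathway recategorization map
#'
#' Merge rules combining the two pipelines' vocabularies into pathway-level
#' categories: oxygen reduction absorbs the two oxidative-phosphorylation
#' categories, hydrogen oxidation absorbs "Hydrogenases", and iron reduction
#' combines the FeGenie and METABOLIC metal/iron-reduction calls.
#'
#' @return Named character vector: input category -> merged category.
#' @export
default_recategorization <- function() {
  c("Oxidative phosphorylation" = "Oxygen reduction",
    "Oxygen Metabolism (Oxidative phosphorylation Complex IV)" = "Oxygen reduction",
    "Hydrogenases" = "Hydrogen oxidation",
    "iron reduction" = "Iron reduction",
    "Metal reduction" = "Iron reduction",
    "iron oxidation" = "Iron oxidation")
}

#' Merge profile categories into broader pathways
#'
#' Abundances of categories mapping to the same target are summed (over both
#' pipelines). Categories absent from the map pass through unchanged when
#' `passthrough = TRUE` (the default) and are reported via the
#' `unmapped` attribute.
#'
#' @param profile A `ferro_profile`.
#' @param mapping Named character vector (input category -> merged category).
#'   A category may appear only once.
#' @param passthrough Keep unmapped categories under their own names?
#' @return Recategorized `ferro_profile` (summed over `tool` and
#'   `gene_family`, columns `metagenome_id`, `category`, `hits`,
#'   `rel_abundance`).
#' @export
recategorize <- function(profile, mapping = default_recategorization(),
                         passthrough = TRUE) {
  if (anyDuplicated(names(mapping))) {
    abort(sprintf("category mapped twice: %s",
                  paste(unique(names(mapping)[duplicated(names(mapping))]),
                        collapse = ", ")),
          class = "ferroflux_input_error")
  }
  unmapped <- setdiff(unique(profile$category), names(mapping))
  if (!passthrough && length(unmapped)) {
    abort(sprintf("unmapped categories: %s", paste(unmapped, collapse = ", ")),
          class = "ferroflux_input_error")
  }
  out <- as_tibble(profile) %>%
    mutate(category = dplyr::coalesce(mapping[.data$category], .data$category)) %>%
    group_by(.data$metagenome_id, .data$category) %>%
    summarise(hits = sum(.data$hits),
              rel_abundance = sum(.data$rel_abundance), .groups = "drop") %>%
    arrange(.data$metagenome_id, .data$category)
  structure(out, total_genes = attr(profile, "total_genes"),
            unmapped = unmapped,
            class = c("ferro_profile", class(out)))
}

#' Split categories into energy metabolism vs housekeeping
#'
#' Iron oxidation and reduction are energy metabolisms; iron acquisition,
#' storage and regulation are housekeeping functions.
#'
#' @param category Character vector of FeGenie-style categories.
#' @return Factor with levels `energy`, `housekeeping`, `other`.
#' @export
categorize_energy_housekeeping <- function(category) {
  hk <- stringr::str_detect(
    category,
    "iron acquisition|iron storage|iron gene regulation"
  )
  out <- ifelse(tolower(category) %in% .energy_categories, "energy",
                ifelse(hk, "housekeeping", "other"))
  factor(out, levels = c("energy", "housekeeping", "other"))
}

#' Bray-Curtis dissimilarity between metagenome gene profiles
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} over the profile
#' vectors. By default the comparison is restricted to energy-metabolism iron
#' genes (iron oxidation / iron reduction), the convention used for site
#' clustering. A pair of all-zero profiles is defined to have dissimilarity 0
#' (with a warning) so an outgroup without iron genes remains representable.
#'
#' @param profile A `ferro_profile` (family-level).
#' @param subset Categories to retain; `NULL` keeps all.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(profile, subset = .energy_categories) {
  df <- as_tibble(profile)
  if (!is.null(subset)) df <- df %>% filter(.data$category %in% subset)
  wide <- df %>%
    mutate(feature = paste(.data$category, .data$gene_family, sep = "|")) %>%
    select("metagenome_id", "feature", "rel_abundance") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "rel_abundance",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$metagenome_id
  if (ncol(m) == 0) m <- matrix(0, nrow(wide), 1,
                                dimnames = list(wide$metagenome_id, "none"))
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (anyNA(d)) {
    warn("all-zero profile pair(s); Bray-Curtis defined as 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' UPGMA (average-linkage) clustering of a dissimilarity matrix
#'
#' Deterministic unweighted pair-group average linkage: at each step the pair
#' at minimal dissimilarity merges, ties broken by the lexicographically
#' smallest pair of cluster indices; cluster-to-cluster distances update as
#' size-weighted averages. Merge node heights are half the merge
#' dissimilarity, so the tree is ultrametric with leaf-to-root path lengths
#' equal to half the cophenetic distance.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal (row names are
#'   used as leaf labels).
#' @return Object of class `ferro_upgma`: `merge` and `height` in
#'   [stats::hclust()] layout (heights are merge dissimilarities), `node_height`
#'   (= height/2), `labels`, and `phylo`, an [ape::phylo] ultrametric tree.
#' @export
upgma <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-12)) {
    abort("dissimilarity matrix must be symmetric",
          class = "ferroflux_input_error")
  }
  n <- nrow(D)
  labels <- rownames(D) %||% paste0("L", seq_len(n))
  stopifnot(n >= 2)
  # active clusters: id (negative = leaf, positive = internal node), size
  ids <- -seq_len(n)
  sizes <- rep(1, n)
  d <- D
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(ids)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (d[i, j] < best[1] - 1e-15) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best[1]
    newd <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  hc <- structure(
    list(merge = merge, height = height, order = .upgma_order(merge, n),
         labels = labels, method = "average",
         call = match.call(), dist.method = "bray"),
    class = "hclust"
  )
  phylo <- ape::as.phylo(hc)
  structure(list(merge = merge, height = height, node_height = height / 2,
                 labels = labels, hclust = hc, phylo = phylo),
            class = "ferro_upgma")
}

# leaf ordering compatible with the merge matrix (left-to-right traversal)
.upgma_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.ferro_upgma <- function(x, ...) {
  cat(sprintf("UPGMA tree over %d leaves; merge node heights: %s\n",
              length(x$labels),
              paste(signif(x$node_height, 4), collapse = ", ")))
  invisible(x)
}

#' Write a UPGMA tree to Newick
#'
#' Branch lengths follow the ultrametric node heights (half the merge
#' dissimilarity), so leaf-to-root depth equals the root node height.
#'
#' @param tree A `ferro_upgma` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Per-MAG gene presence and taxon-level summaries
#'
#' Gene annotations on metagenome-assembled genomes are presence-only data
#' (bin completeness varies), so summaries never claim absence of a gene from
#' an organism. Returns a MAG-by-gene-family presence table and a
#' taxon-by-gene matrix restricted to the energy categories (iron oxidation /
#' iron reduction); MAGs with no energy-category hit are excluded from the
#' taxon matrix. Hits whose `mag_id` is missing from the MAG table are kept
#' under `"unbinned"` with a warning.
#'
#' @param hits Hit tibble with `mag_id` and `taxon` columns populated where
#'   known.
#' @param mags MAG tibble (`mag_id`, `taxon`, optionally `metagenome_id`,
#'   `completeness`).
#' @return List: `presence` (tibble mag_id x category x gene_family, one row
#'   per present combination), `taxon_matrix` (tibble taxon x gene_family x
#'   n_mags for energy categories), `n_mags_with_energy_genes`.
#' @export
mag_summary <- function(hits, mags) {
  .check_hits(hits)
  if (!"mag_id" %in% names(hits)) {
    abort("hit table has no mag_id column", class = "ferroflux_input_error")
  }
  if (!"taxon" %in% names(hits)) hits$taxon <- NA_character_
  binned <- hits %>% filter(!is.na(.data$mag_id))
  orphan <- setdiff(unique(binned$mag_id), mags$mag_id)
  if (length(orphan)) {
    warn(sprintf("mag_id not in MAG table, kept as 'unbinned': %s",
                 paste(orphan, collapse = ", ")))
    binned <- binned %>%
      mutate(mag_id = ifelse(.data$mag_id %in% orphan, "unbinned",
                             .data$mag_id))
  }
  presence <- binned %>%
    distinct(.data$mag_id, .data$category, .data$gene_family) %>%
    mutate(present = TRUE) %>%
    arrange(.data$mag_id, .data$category, .data$gene_family)
  energy <- binned %>%
    filter(.data$category %in% .energy_categories) %>%
    left_join(mags %>% select("mag_id", "taxon"), by = "mag_id",
              suffix = c("", ".mag")) %>%
    mutate(taxon = dplyr::coalesce(.data$taxon.mag, .data$taxon)) %>%
    select(-"taxon.mag")
  taxon_matrix <- energy %>%
    distinct(.data$mag_id, .data$taxon, .data$category, .data$gene_family) %>%
    count(.data$taxon, .data$category, .data$gene_family, name = "n_mags") %>%
    arrange(.data$taxon, .data$category, .data$gene_family)
  list(presence = presence, taxon_matrix = taxon_matrix,
       n_mags_with_energy_genes = dplyr::n_distinct(energy$mag_id))
}

#' Housekeeping-category combinations across MAGs
#'
#' For the three housekeeping groups (iron acquisition, storage, regulation),
#' tabulates the fraction of MAGs possessing each of the eight
#' presence/absence combinations. Percentages sum to 100.
#'
#' @param presence MAG presence table (from [mag_summary()]) or any tibble
#'   with `mag_id` and `category`.
#' @param mags MAG tibble giving the full MAG universe (`mag_id`); MAGs with
#'   no housekeeping hits count toward the `"none"` combination.
#' @return Tibble: `combination`, `n_mags`, `percent`.
#' @export
housekeeping_combos <- function(presence, mags) {
  flags <- presence %>%
    mutate(group = dplyr::case_when(
      stringr::str_detect(.data$category, "iron acquisition") ~ "acquisition",
      stringr::str_detect(.data$category, "iron storage") ~ "storage",
      stringr::str_detect(.data$category, "iron gene regulation") ~ "regulation",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$group)) %>%
    distinct(.data$mag_id, .data$group)
  combos <- tibble(mag_id = mags$mag_id) %>%
    left_join(
      flags %>%
        group_by(.data$mag_id) %>%
        summarise(combination = paste(
          sort(factor(.data$group,
                      levels = c("acquisition", "storage", "regulation"))),
          collapse = "+"), .groups = "drop"),
      by = "mag_id"
    ) %>%
    mutate(combination = tidyr::replace_na(.data$combination, "none"))
  levels_all <- c("acquisition", "storage", "regulation",
                  "acquisition+storage", "acquisition+regulation",
                  "storage+regulation", "acquisition+storage+regulation",
                  "none")
  out <- combos %>%
    count(.data$combination, name = "n_mags") %>%
    mutate(percent = 100 * .data$n_mags / nrow(mags))
  tibble(combination = levels_all) %>%
    left_join(out, by = "combination") %>%
    mutate(n_mags = tidyr::replace_na(.data$n_mags, 0L),
           percent = tidyr::replace_na(.data$percent, 0))
}
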