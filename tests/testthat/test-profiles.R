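test_that("ambiguity rule keeps only the agreeing dual-pipeline pair", {
  hits <- dplyr::bind_rows(
    hit_row("M1", "orf1", "fegenie", "iron oxidation"),
    hit_row("M1", "orf1", "metabolic", "Metal reduction"),
    hit_row("M1", "orf2", "fegenie", "iron reduction"),
    hit_row("M1", "orf2", "metabolic", "Metal reduction"),
    hit_row("M1", "orf3", "fegenie", "iron storage"),
    hit_row("M1", "orf4", "fegenie", "iron reduction"),
    hit_row("M1", "orf4", "metabolic", "Hydrogenases")
  )
  rec <- reconcile_ambiguous(hits)
  expect_equal(rec$removed_features, 2) # orf1 and orf4
  expect_equal(rec$removed_hits, 4)
  expect_setequal(unique(rec$kept$orf_id), c("orf2", "orf3"))
  expect_equal(nrow(rec$kept), 3)
})

test_that("contig keying groups ORFs sharing a contig", {
  hits <- dplyr::bind_rows(
    hit_row("M1", "orfA", "fegenie", "iron oxidation"),
    hit_row("M1", "orfB", "metabolic", "Metal reduction")
  )
  hits$contig_id <- "c1"
  rec_orf <- reconcile_ambiguous(hits, key = "orf")
  expect_equal(rec_orf$removed_features, 0) # different ORFs, both single-tool
  rec_ctg <- reconcile_ambiguous(hits, key = "contig")
  expect_equal(rec_ctg$removed_features, 1) # same contig, mismatched pair
})

test_that("relative abundances are exact fractions with zero rows retained", {
  hits <- dplyr::bind_rows(
    purrr::map(1:5, ~ hit_row("M1", paste0("o", .x), "fegenie",
                              "iron oxidation", "Cyc2_cluster1"))
  )
  prof <- relative_abundance(hits, c(M1 = 1000, M_empty = 500))
  m1 <- prof[prof$metagenome_id == "M1", ]
  expect_equal(m1$rel_abundance, 0.005)
  # the empty community appears with an all-zero row
  m0 <- prof[prof$metagenome_id == "M_empty", ]
  expect_equal(nrow(m0), 1)
  expect_equal(m0$rel_abundance, 0)
  expect_error(relative_abundance(hits, c(Other = 10)),
               class = "ferroflux_input_error")

  # additivity: family entries sum to the category total
  hits2 <- dplyr::bind_rows(
    hit_row("M1", "a", "fegenie", "iron oxidation", "Cyc2_cluster1"),
    hit_row("M1", "b", "fegenie", "iron oxidation", "Cyc2_cluster3"),
    hit_row("M1", "c", "fegenie", "iron reduction", "OmcS")
  )
  prof2 <- relative_abundance(hits2, c(M1 = 100))
  cat_tot <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(prof2), category),
    ra = sum(rel_abundance)
  )
  expect_equal(cat_tot$ra[cat_tot$category == "iron oxidation"], 2 / 100)
})

test_that("recategorization merges pathway categories per the mapping rules", {
  hits <- dplyr::bind_rows(
    hit_row("M1", "a", "metabolic", "Oxidative phosphorylation"),
    hit_row("M1", "b", "metabolic",
            "Oxygen Metabolism (Oxidative phosphorylation Complex IV)"),
    hit_row("M1", "b2", "metabolic",
            "Oxygen Metabolism (Oxidative phosphorylation Complex IV)"),
    hit_row("M1", "c", "fegenie", "iron reduction"),
    hit_row("M1", "d", "metabolic", "Metal reduction"),
    hit_row("M1", "e", "fegenie", "iron storage")
  )
  prof <- relative_abundance(hits, c(M1 = 1000))
  merged <- recategorize(prof)
  ra <- function(cat) merged$rel_abundance[merged$category == cat]
  expect_equal(ra("Oxygen reduction"), 0.003)
  expect_equal(ra("Iron reduction"), 0.002)
  expect_equal(ra("iron storage"), 0.001) # passthrough
  expect_true("iron storage" %in% attr(merged, "unmapped"))

  # identity mapping leaves abundances unchanged
  ident <- recategorize(prof, mapping = character(0))
  expect_equal(sum(ident$rel_abundance), sum(prof$rel_abundance))

  dup <- c("iron storage" = "A", "iron storage" = "B")
  expect_error(recategorize(prof, dup), class = "ferroflux_input_error")
})

test_that("energy vs housekeeping categorization follows the convention", {
  got <- categorize_energy_housekeeping(c(
    "iron oxidation", "iron reduction",
    "iron acquisition-siderophore transport", "iron storage",
    "iron gene regulation", "Hydrogenases"
  ))
  expect_equal(as.character(got),
               c("energy", "energy", "housekeeping", "housekeeping",
                 "housekeeping", "other"))
})

test_that("Bray-Curtis: closed-form cases and brute-force agreement", {
  m <- rbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(1, 2, 3),
             D = c(0, 0, 4))
  colnames(m) <- paste0("f", 1:3)
  prof <- profile_from_matrix(m)
  D <- bray_curtis(prof, subset = NULL)
  expect_equal(D["A", "C"], 0)
  expect_equal(D["A", "B"], 4 / 12, tolerance = 1e-12)
  # disjoint supports -> 1
  m2 <- rbind(X = c(1, 1, 0, 0), Y = c(0, 0, 2, 3))
  colnames(m2) <- paste0("f", 1:4)
  D2 <- bray_curtis(profile_from_matrix(m2), subset = NULL)
  expect_equal(D2["X", "Y"], 1)

  # random matrices match the double-loop oracle to 1e-12
  set.seed(7)
  for (rep in 1:5) {
    r <- matrix(stats::runif(6 * 8), 6, 8,
                dimnames = list(paste0("S", 1:6), paste0("g", 1:8)))
    r[r < 0.25] <- 0
    Dr <- bray_curtis(profile_from_matrix(r), subset = NULL)
    expect_true(max(abs(Dr - bc_brute(r)[rownames(Dr), colnames(Dr)])) < 1e-12)
  }

  # all-zero pair defined as 0 with a warning
  m3 <- rbind(P = c(0, 0), Q = c(0, 0), R = c(1, 2))
  colnames(m3) <- paste0("f", 1:2)
  expect_warning(D3 <- bray_curtis(profile_from_matrix(m3), subset = NULL),
                 "all-zero")
  expect_equal(D3["P", "Q"], 0)
})

test_that("clustering subset restricts to iron energy categories", {
  hits <- dplyr::bind_rows(
    hit_row("M1", "a", "fegenie", "iron oxidation", "Cyc2_cluster1"),
    hit_row("M2", "b", "fegenie", "iron storage", "Bfr"),
    hit_row("M2", "c", "fegenie", "iron oxidation", "Cyc2_cluster1")
  )
  prof <- relative_abundance(hits, c(M1 = 100, M2 = 100))
  D <- bray_curtis(prof) # default: energy categories only
  expect_equal(D["M1", "M2"], 0) # identical once storage is excluded
})

test_that("UPGMA reproduces hand-computed merges and heights", {
  # d(A,B) = 2, d(A,C) = d(B,C) = 6: (A,B) joins at node height 1, C at 3
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  expect_equal(tr$node_height, c(1, 3))
  expect_equal(tr$merge[1, ], c(-2, -1))
  ph <- tr$phylo
  depths <- ape::node.depth.edgelength(ph)
  expect_equal(max(depths[1:3]), 3)

  # two leaves merge at half their dissimilarity
  D2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2,
               dimnames = list(c("X", "Y"), c("X", "Y")))
  tr2 <- upgma(D2)
  expect_equal(tr2$node_height, 0.4)

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "ferroflux_input_error")
})

test_that("UPGMA matches average-linkage hclust and stays ultrametric", {
  set.seed(11)
  for (n in c(4, 6, 9)) {
    x <- matrix(stats::rnorm(n * 3), n)
    rownames(x) <- paste0("L", seq_len(n))
    D <- as.matrix(stats::dist(x))
    tr <- upgma(D)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(tr$height, hc$height, tolerance = 1e-12)
    expect_true(ape::is.ultrametric(tr$phylo, tol = 1e-8))
    # cophenetic check: tree depths equal half the cophenetic distances
    coph <- as.matrix(stats::cophenetic(tr$hclust))
    expect_equal(coph[rownames(D), colnames(D)],
                 as.matrix(stats::cophenetic(hc))[rownames(D), colnames(D)],
                 tolerance = 1e-12)
  }
})

test_that("UPGMA topology is invariant to leaf permutation", {
  set.seed(23)
  x <- matrix(stats::rnorm(4 * 3), 4)
  rownames(x) <- c("A", "B", "C", "D")
  D <- as.matrix(stats::dist(x))
  tr <- upgma(D)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    Dp <- D[perm, perm]
    trp <- upgma(Dp)
    expect_equal(sort(trp$height), sort(tr$height), tolerance = 1e-12)
    expect_equal(ape::dist.topo(ape::unroot(tr$phylo),
                                ape::unroot(trp$phylo))[1], 0)
  }
})

test_that("Newick export preserves leaves and ultrametric heights", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, c("A", "B", "C"))
  expect_true(ape::is.ultrametric(ph, tol = 1e-8))
})

test_that("MAG summaries are presence-only with energy-category restriction", {
  mags <- tibble::tibble(mag_id = c("MAG1", "MAG2", "MAG3"),
                         taxon = c("T1", "T2", "T3"))
  hits <- dplyr::bind_rows(
    hit_row("M1", "o1", "fegenie", "iron reduction", "OmcS", "MAG1", "T1"),
    hit_row("M1", "o2", "fegenie", "iron storage", "Bfr", "MAG2", "T2"),
    hit_row("M1", "o3", "fegenie", "iron oxidation", "Cyc2_cluster1",
            "MAG9", "T9")
  )
  expect_warning(ms <- mag_summary(hits, mags), "unbinned")
  expect_true(any(ms$presence$mag_id == "MAG1" &
                    ms$presence$gene_family == "OmcS"))
  # MAG2 has no energy-category hit -> absent from the taxon matrix
  expect_false("T2" %in% ms$taxon_matrix$taxon)
  # orphan MAG kept under unbinned
  expect_true("unbinned" %in% ms$presence$mag_id)
  expect_equal(ms$n_mags_with_energy_genes, 2) # MAG1 + unbinned
})

test_that("housekeeping combinations partition MAGs and sum to 100%", {
  mags <- tibble::tibble(mag_id = paste0("G", 1:4))
  presence <- dplyr::bind_rows(
    tibble::tibble(mag_id = "G1",
                   category = c("iron acquisition-iron transport",
                                "iron storage", "iron gene regulation")),
    tibble::tibble(mag_id = "G2",
                   category = c("iron acquisition-siderophore transport",
                                "iron storage", "iron gene regulation")),
    tibble::tibble(mag_id = "G3", category = "iron gene regulation")
  )
  hc <- housekeeping_combos(presence, mags)
  expect_equal(sum(hc$percent), 100)
  all3 <- hc$percent[hc$combination == "acquisition+storage+regulation"]
  expect_equal(all3, 50)
  expect_equal(hc$percent[hc$combination == "regulation"], 25)
  expect_equal(hc$percent[hc$combination == "none"], 25)

  # all-empty universe: everything lands in none
  hc0 <- housekeeping_combos(presence[0, ], mags)
  expect_equal(hc0$percent[hc0$combination == "none"], 100)
})
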