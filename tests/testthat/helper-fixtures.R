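# shared helpers for building small in-code fixtures

hit_row <- function(mg, orf, tool, category, family = "fam1",
                    mag_id = NA_character_, taxon = NA_character_) {
  tibble::tibble(metagenome_id = mg, orf_id = orf, tool = tool,
                 category = category, gene_family = family,
                 mag_id = mag_id, taxon = taxon)
}

# brute-force Bray-Curtis oracle: double loop over a sample-by-feature matrix
bc_brute <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- sum(abs(m[i, ] - m[j, ]))
      den <- sum(m[i, ] + m[j, ])
      out[i, j] <- if (den == 0) 0 else num / den
    }
  }
  out
}

# profile tibble straight from a wide abundance matrix (rows = metagenomes)
profile_from_matrix <- function(m, category = "iron oxidation") {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "metagenome_id"),
    -"metagenome_id", names_to = "gene_family", values_to = "rel_abundance"
  )
  df$tool <- "fegenie"
  df$category <- category
  df$hits <- df$rel_abundance * 1000
  structure(df, class = c("ferro_profile", class(df)))
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(x), abs(y), 1e-300)))
}
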