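# Small fixtures shared across test files; everything is generated in code.

# write a minimal PGS-Catalog-style scoring file and return its path
write_fixture_scoring <- function(rows, score_id = "PGS_TEST",
                                  trait = "height",
                                  dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0(score_id, ".txt"))
  con <- file(path, "wt")
  writeLines(c(paste0("#pgs_id=", score_id),
               paste0("#trait_reported=", trait),
               paste(c("rsID", "chr_name", "chr_position", "effect_allele",
                       "other_allele", "effect_weight"), collapse = "\t")),
             con)
  if (nrow(rows) > 0)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)
  path
}

# a tiny fixed panel: chr 1, positions 1..n, alternating allele pairs
fixture_panel <- function(n = 5) {
  variant_panel(chr = "1", pos = seq_len(n),
                ref = rep(c("A", "C"), length.out = n),
                alt = rep(c("G", "T"), length.out = n))
}

# harmonized scoring built directly (bypassing file round trips)
make_harmonized <- function(panel, weights, score_id = "s1",
                            trait = "height") {
  idx <- seq_along(weights)
  structure(list(score_id = score_id, trait_label = trait,
                 records = data.frame(chr = panel$chr[idx],
                                      pos = panel$pos[idx],
                                      ref = panel$ref[idx],
                                      alt = panel$alt[idx],
                                      weight = weights,
                                      stringsAsFactors = FALSE),
                 n_flipped = 0L, n_dropped = 0L),
            class = "harmonized_scoring")
}

# genotypes + correlated component scores + outcome, for mixer tests
fixture_sim <- function(n = 600, m = 40, h2 = 0.5, seed = 1) {
  cfg <- sim_config(h2 = h2, m_causal = m, n_gwas = 100,
                    n_train_grid = 100, n_test = 50, n_replicates = 1,
                    seed = seed)
  g <- simulate_genotypes(n, m, seed = seed + 1)
  B <- simulate_effects(cfg, seed = seed + 2)
  ph <- simulate_phenotype(g, B, h2, seed = seed + 3)
  list(cfg = cfg, genotypes = g, effects = B, pheno = ph)
}
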