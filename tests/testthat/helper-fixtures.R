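# Small cohorts built in code for unit tests.

# Minimal cohort: 4 samples, the 8 cell subsets plus two genes.
tiny_cohort <- function() {
  cells <- immune_cell_subsets()
  mat <- rbind(
    A = c(5.3, 2, 0.6, 1.4, 0.1, 0.2, 5.9, 1.3, 3000, 100),
    B = c(rep(0, 8), 1500, 200),
    C = c(1, 1, 1, 1, 1, 1, 1, 1, 2000, 50),
    D = c(2, 2, 2, 2, 2, 2, 2, 2, 800, 400)
  )
  colnames(mat) <- c(cells, "GENE1", "GENE2")
  records <- data.frame(
    sample_id = rownames(mat),
    group = c("long", "short", "long", "short"),
    pfs_months = c(90, 4, 62, 7), pfs_censored = c(TRUE, FALSE, FALSE, FALSE),
    pfs_alt = c(NA, NA, 51, NA),
    os_months = c(90, 6, 77, 20), os_censored = c(TRUE, FALSE, TRUE, FALSE),
    os_alt = c(NA, NA, 66, 15),
    maint_bev = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  kinds <- stats::setNames(c(rep("cell_percent", 8), rep("gene_tpm", 2)),
                           colnames(mat))
  cohort(records, mat, kinds)
}

# Two-group cohort (n long / n short) with one informative gene among noise.
planted_cohort <- function(seed, effect = 2, n_long = 11, n_short = 8,
                           n_noise = 4) {
  specs <- c(
    list(analyte_spec("planted", "gene_tpm", log_mean = 3, log_sd = 1,
                      group_effect = c(long = effect / 2, short = -effect / 2))),
    lapply(seq_len(n_noise), function(i)
      analyte_spec(paste0("noise", i), "gene_tpm", log_mean = 3, log_sd = 1))
  )
  generate_cohort(synth_config(
    group_sizes = c(long = n_long, short = n_short, intermediate = 0),
    analytes = specs, seed = seed))
}
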