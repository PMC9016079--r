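# Shared generators for the test suite. Everything is built in code; no
# stored fixtures.

# A simulated exonic-mode data set under the standard study conditions.
sim_dataset <- function(n = 500, maf = 0.4, beta = 0, var_b = 1,
                        var_eps = 0.5, mu = log(1e-4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  des <- simulate_ase_design(n, maf, 1e6)
  simulate_counts(des, mu, beta, var_b, var_eps)
}

het_subset <- function(design) {
  design[design$pattern %in% c("A", "a"), , drop = FALSE]
}

# Collapse a heterozygous-only design into (y_A, n) pairs.
het_pairs <- function(design) {
  het <- het_subset(design)
  ids <- unique(het$subject_id)
  yA <- het$y[het$X == 1][match(ids, het$subject_id[het$X == 1])]
  ya <- het$y[het$X == 0][match(ids, het$subject_id[het$X == 0])]
  data.frame(subject_id = ids, yA = yA, ya = ya, n = yA + ya)
}

# Subject tables for build_design() with explicit genotypes.
subjects_table <- function(dosage, y_eff, y_oth, library_size = 1e6) {
  data.frame(subject_id = paste0("S", seq_along(dosage)), dosage = dosage,
             y_eff = y_eff, y_oth = y_oth, library_size = library_size)
}
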