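# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops, no data.table) so they cannot share a
# defect with the implementation they check.

# enumerate-and-rank rollup oracle: top peptides by cross-run summed
# intensity, top fragments within each, ties by lexicographic id
oracle_rollup <- function(frags, runs, top_pep = 10L, top_frag = 6L) {
  prot_ids <- sort(unique(frags$protein_id))
  run_ids <- runs$run_id
  out <- matrix(0, length(prot_ids), length(run_ids),
                dimnames = list(prot_ids, run_ids))
  for (p in prot_ids) {
    fp <- frags[frags$protein_id == p, ]
    pep_strength <- sapply(split(fp$intensity, fp$peptide_id), sum)
    ord <- order(-pep_strength, names(pep_strength))
    sel_peps <- names(pep_strength)[ord][seq_len(min(top_pep,
                                                     length(ord)))]
    for (pep in sel_peps) {
      fpp <- fp[fp$peptide_id == pep, ]
      fr_strength <- sapply(split(fpp$intensity, fpp$fragment_id), sum)
      ordf <- order(-fr_strength, names(fr_strength))
      sel_frags <- names(fr_strength)[ordf][seq_len(min(top_frag,
                                                        length(ordf)))]
      sel <- fpp[fpp$fragment_id %in% sel_frags, ]
      for (i in seq_len(nrow(sel)))
        out[p, sel$run_id[i]] <- out[p, sel$run_id[i]] + sel$intensity[i]
    }
  }
  out
}

# randomized long-format fragment table; a fraction of rows is dropped to
# exercise the missing-as-absent policy
random_fragment_table <- function(n_prot = 5L, n_pep = 15L, n_frag = 9L,
                                  n_runs = 4L, drop_frac = 0.1,
                                  seed = 42L) {
  set.seed(seed)
  runs <- data.frame(run_id = sprintf("R%d", seq_len(n_runs)),
                     sample_id = sprintf("S%d", seq_len(n_runs)),
                     replicate_index = 1L, stringsAsFactors = FALSE)
  g <- expand.grid(frag = seq_len(n_frag), pep = seq_len(n_pep),
                   prot = seq_len(n_prot), run = seq_len(n_runs))
  frags <- data.frame(
    protein_id = sprintf("P%02d", g$prot),
    peptide_id = sprintf("P%02d_pep%02d", g$prot, g$pep),
    fragment_id = sprintf("P%02d_pep%02d_f%02d", g$prot, g$pep, g$frag),
    run_id = sprintf("R%d", g$run),
    intensity = 10^runif(nrow(g), 2, 6), stringsAsFactors = FALSE)
  keep <- runif(nrow(frags)) >= drop_frac
  list(fragments = frags[keep, ], runs = runs)
}

# small synthetic cohort used across tests: paper-shaped design at reduced
# protein and feature counts
small_cohort <- function(seed = 1L, n_proteins = 150L, n_de = 30L,
                         effect = 0.4, noise_cv = 0.2,
                         n_subgroup = 9L, missing_rate = 0.05) {
  generate_cohort(cohort_config(
    n_proteins = n_proteins, n_de_proteins = n_de,
    n_subgroup_cases = n_subgroup,
    peptides_per_protein = list(mean = 3),
    fragments_per_peptide = list(mean = 4),
    effect_log10fc = effect, noise_cv = noise_cv,
    missing_rate = missing_rate, seed = seed))
}

quantify_quiet <- function(cohort, ...) {
  suppressWarnings(quantify_cohort(cohort$fragments, cohort$runs, ...))
}

pca_quiet <- function(...) suppressWarnings(sqrt_pareto_pca(...))

# averaged-stage matrix straight from a values matrix
averaged_matrix <- function(values) protein_matrix(values, "averaged")

# deterministic sample table for directly constructed matrices
make_samples <- function(n_case, n_control) {
  data.frame(
    sample_id = c(sprintf("P%d", seq_len(n_case)),
                  sprintf("C%d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE)
}

# null protein matrix (log-normal noise, no group signal) for classifier
# calibration tests, bypassing fragment-level generation for speed
null_matrix <- function(n_prot = 60L, n_case = 11L, n_control = 9L,
                        seed = 1L) {
  set.seed(seed)
  samples <- make_samples(n_case, n_control)
  values <- 10^matrix(rnorm(n_prot * (n_case + n_control), 5, 0.3),
                      n_prot,
                      dimnames = list(sprintf("PR%03d", seq_len(n_prot)),
                                      samples$sample_id))
  list(matrix = averaged_matrix(values), samples = samples)
}
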