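# Shared fixtures built in code.

# Hand-workable toy protein: M K T A Y I A K Q R Q I S F V K S H F S P E
toy_protein <- function() protein_record("toy1", "MKTAYIAKQRQISFVKSHFSPE")

toy_proteome <- function() {
  p <- toy_protein()
  setNames(list(p), p$id)
}

# Planted protease: strong preference for F/Y/L in P1', no preference
# elsewhere.
fyl_model <- function(propensity = 0.1) {
  set_subsite_preference(specificity_model(propensity = propensity),
                         "P1'", c(F = 0.40, Y = 0.30, L = 0.20))
}

# Run the full simulate -> parse -> classify -> reconstruct chain in one
# call, via on-disk PSM tables so the file dialect is exercised.
run_recovery <- function(n_proteins, seed, model = fyl_model(),
                         config = simulation_config(seed = seed),
                         design = experiment_design()) {
  proteome <- random_proteome(n_proteins, seed = seed)
  sim <- simulate_experiment(proteome, model, config)
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write_psm_table(sim$psm$control, file.path(d, "control.csv"))
  write_psm_table(sim$psm$treated, file.path(d, "treated.csv"))
  records <- rbind(parse_psm_table(file.path(d, "control.csv")),
                   parse_psm_table(file.path(d, "treated.csv")))
  index <- proteome_index(proteome)
  classified <- classify_peptides(records, design, index)
  recon <- reconstruct_sites(classified, index, design)
  list(proteome = proteome, sim = sim, recon = recon,
       background = background_frequencies(proteome), model = model)
}

# Minimal valid PSM table written to a temp file.
write_toy_psm <- function(rows, path) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  write_psm_table(df, path)
  path
}

psm_row <- function(peptide, proteins = "toy1",
                    modifications = "dimethyl-heavy@nterm(34.06)",
                    confidence = 1, sample = "treated") {
  list(peptide = peptide, proteins = proteins,
       modifications = modifications, confidence = confidence,
       sample = sample)
}

# Random cleavage-free windows drawn from proteome positions: the null for
# enrichment and significance checks.
sample_null_windows <- function(proteome, n) {
  k <- sample(length(proteome), n, replace = TRUE)
  vapply(k, function(i) {
    s <- proteome[[i]]$sequence
    p1 <- sample(6:(nchar(s) - 6), 1)
    substr(s, p1 - 5, p1 + 6)
  }, character(1))
}

# Strip class and bookkeeping attributes, keep dim/dimnames: for comparing
# matrices that travelled through JSON.
unname_attrs <- function(m) {
  out <- unclass(m)
  attributes(out) <- list(dim = dim(out), dimnames = dimnames(out))
  out
}
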