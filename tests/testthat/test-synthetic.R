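test_that("tryptic digestion of the toy protein matches rule-by-rule application", {
  d <- digest_protein(toy_protein(), trypsin(), max_missed = 0)
  expect_identical(d$peptide, c("MK", "TAYIAK", "QR", "QISFVK", "SHFSPE"))
  expect_identical(d$start, c(1L, 3L, 9L, 11L, 17L))
  expect_identical(d$end, c(2L, 8L, 10L, 16L, 22L))

  d6 <- digest_protein(toy_protein(), trypsin(), max_missed = 0,
                       min_length = 6)
  expect_identical(nrow(d6), 3L)

  single <- digest_protein(protein_record("p", "AAAA"), trypsin())
  expect_identical(single$peptide, "AAAA")
  expect_identical(single$start, 1L)
  expect_identical(single$end, 4L)
})

test_that("proline suppresses tryptic cleavage and missed cleavages enumerate", {
  p <- protein_record("p", "AAKPAAKAAA")
  d0 <- digest_protein(p, trypsin(), 0)
  expect_identical(d0$peptide, c("AAKPAAK", "AAA"))  # K|P not cut
  d1 <- digest_protein(p, trypsin(), 1)
  expect_true("AAKPAAKAAA" %in% d1$peptide)
  expect_identical(sum(d1$missed == 1), 1L)
})

test_that("digestion with no missed cleavages partitions the protein", {
  proteome <- random_proteome(200, min_length = 50, max_length = 150,
                              seed = 71)
  for (enzyme in list(trypsin(), gluc())) {
    for (p in proteome[seq(1, 200, by = 8)]) {
      d <- digest_protein(p, enzyme, 0)
      expect_identical(paste(d$peptide, collapse = ""), p$sequence)
      expect_identical(d$start[1], 1L)
      expect_identical(d$end[nrow(d)], nchar(p$sequence))
      expect_true(all(d$start[-1] == d$end[-nrow(d)] + 1L))
    }
  }
})

test_that("libraries carry the enzyme's composition constraint", {
  proteome <- random_proteome(20, seed = 13)
  for (spec in list(list(enz = trypsin(block_proline = FALSE),
                         internal = c("K", "R")),
                    list(enz = gluc(), internal = c("D", "E")))) {
    cfg <- simulation_config(library_enzyme = spec$enz, seed = 13)
    lib <- build_library(proteome, cfg)
    internal <- substr(lib$peptide, 1, nchar(lib$peptide) - 1L)
    hits <- vapply(strsplit(internal, ""), function(ch)
      any(ch %in% spec$internal), logical(1))
    expect_false(any(hits))
    # last residue is a P1 residue or a protein C-terminus
    last <- substr(lib$peptide, nchar(lib$peptide), nchar(lib$peptide))
    lens <- vapply(proteome[lib$protein], function(p) nchar(p$sequence),
                   integer(1))
    expect_true(all(last %in% spec$enz$p1_residues | lib$end == lens))
  }
  expect_error(build_library(list(), simulation_config()), "empty")
})

test_that("a P1'-phenylalanine protease cuts the toy peptide at the planted bond", {
  model <- set_subsite_preference(specificity_model(propensity = 1),
                                  "P1'", c(F = 1))
  sim <- simulate_experiment(toy_proteome(), model,
                             simulation_config(seed = 3))
  gt <- sim$ground_truth
  # QISFVK(11-16) is cut between S13 and F14; hand-sliced window
  row <- gt[gt$peptide_start == 11, ]
  expect_identical(row$p1, 13L)
  expect_identical(row$window, "KQRQISFVKSHF")
  expect_true("FVK" %in%
    sim$treated$peptide[sim$treated$origin == "prime_side_product"])
})

test_that("zero propensity means no cuts and a pass-through treated channel", {
  model <- specificity_model(propensity = 0)
  sim <- simulate_experiment(toy_proteome(), model,
                             simulation_config(seed = 3))
  expect_identical(nrow(sim$ground_truth), 0L)
  expect_identical(sort(sim$treated$peptide),
                   sort(sim$library$peptide))
  expect_true(all(sim$treated$origin == "library_peptide"))
})

test_that("every ground-truth window re-slices identically from its protein", {
  proteome <- random_proteome(20, seed = 29)
  sim <- simulate_experiment(proteome, fyl_model(),
                             simulation_config(seed = 29))
  gt <- sim$ground_truth
  expect_gt(nrow(gt), 0)
  for (i in seq_len(nrow(gt))) {
    pseq <- proteome[[gt$protein[i]]]$sequence
    resliced <- paste0(
      substr(pseq, gt$p1[i] - 5, gt$p1[i]),
      substr(pseq, gt$p1[i] + 1, gt$p1[i] + 6))
    # interior sites only; X-padded edges are covered by slice contract
    if (gt$p1[i] > 5 && gt$p1[i] + 6 <= nchar(pseq))
      expect_identical(gt$window[i], resliced)
    expect_identical(nchar(gt$window[i]), 12L)
  }
})

test_that("identical seeds give byte-identical emitted tables", {
  proteome <- random_proteome(10, seed = 17)
  cfg <- simulation_config(seed = 17, identification_rate = 0.8,
                           decoy_rate = 0.1)
  a <- simulate_experiment(proteome, fyl_model(), cfg)
  b <- simulate_experiment(proteome, fyl_model(), cfg)
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  write_psm_table(a$psm$treated, pa)
  write_psm_table(b$psm$treated, pb)
  expect_identical(readLines(pa), readLines(pb))
  expect_identical(a$psm$control, b$psm$control)
})

test_that("emitted row counts follow identification and decoy settings", {
  proteome <- random_proteome(10, seed = 19)
  cfg <- simulation_config(seed = 19)
  sim <- simulate_experiment(proteome, fyl_model(), cfg)
  in_bounds <- function(x) nchar(x) >= cfg$min_length &
    nchar(x) <= cfg$max_length
  expect_identical(nrow(sim$psm$control), sum(in_bounds(sim$library$peptide)))
  expect_identical(nrow(sim$psm$treated), sum(in_bounds(sim$treated$peptide)))

  none <- simulate_experiment(proteome, fyl_model(),
                              simulation_config(seed = 19,
                                                identification_rate = 0))
  expect_identical(nrow(none$psm$control), 0L)
  expect_identical(nrow(none$psm$treated), 0L)

  noisy_cfg <- simulation_config(seed = 19, decoy_rate = 0.1)
  noisy <- simulate_experiment(proteome, fyl_model(), noisy_cfg)
  again <- simulate_experiment(proteome, fyl_model(), noisy_cfg)
  expect_identical(nrow(noisy$psm$decoys$treated),
                   nrow(again$psm$decoys$treated))
  expect_gt(nrow(noisy$psm$decoys$treated) + nrow(noisy$psm$decoys$control), 0)
  # decoy rows are present in the emitted table and flagged in the registry
  expect_true(all(noisy$psm$decoys$treated$peptide %in%
                    noisy$psm$treated$peptide))
})

test_that("dimethyl labels mark channel on the N-terminus and lysines", {
  proteome <- toy_proteome()
  sim <- simulate_experiment(proteome, specificity_model(propensity = 0),
                             simulation_config(seed = 1))
  ctrl <- sim$psm$control
  expect_true(all(grepl("dimethyl-light@nterm\\(28.05\\)", ctrl$modifications)))
  trt <- sim$psm$treated
  expect_true(all(grepl("dimethyl-heavy@nterm\\(34.06\\)", trt$modifications)))
  # TAYIAK has its lysine at position 6
  tay <- ctrl[ctrl$peptide == "TAYIAK", ]
  expect_match(tay$modifications, "dimethyl-light@6\\(28.05\\)")
})

test_that("substrate digestion ground truth matches its products", {
  cfg <- simulation_config(seed = 101)
  sub <- random_proteome(1, min_length = 300, max_length = 300,
                         seed = 101, prefix = "SUB")[[1]]
  dig <- simulate_substrate_digest(sub, fyl_model(propensity = 0.05), cfg)
  gt <- dig$ground_truth
  expect_gt(nrow(gt), 0)
  # products concatenate to the full sequence before length filtering only;
  # every emitted product boundary is a ground-truth cut or a terminus
  bounds <- sort(unique(c(dig$products$start - 1L, dig$products$end)))
  bounds <- setdiff(bounds, c(0L, nchar(sub$sequence)))
  expect_true(all(bounds %in% gt$p1))
})

test_that("simulation configuration rejects undetectable settings", {
  expect_error(simulation_config(min_length = 3), "min_length")
  expect_error(simulation_config(identification_rate = 1.2),
               "identification_rate")
  expect_error(specificity_model(propensity = 2), "propensity")
  m <- matrix(1 / 20, 20, 12)
  m[1, 1] <- 0.5
  expect_error(specificity_model(m), "sum to 1")
})
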