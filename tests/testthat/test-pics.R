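test_that("PSM tables parse, threshold and validate their schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_psm(list(
    psm_row("FVK"),
    psm_row("QISFVK", modifications = "dimethyl-light@nterm(28.05);dimethyl-light@6(28.05)",
            sample = "control"),
    psm_row("TAYIAK", confidence = 0.5)), path)
  expect_message(recs <- parse_psm_table(path, 0.99), "excluded 1")
  expect_identical(nrow(recs), 2L)
  expect_identical(attr(recs, "n_excluded_confidence"), 1L)
  mods <- recs$mods[[2]]
  expect_identical(mods$position, c("nterm", "6"))
  expect_equal(mods$delta, c(28.05, 28.05))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("proteins,modifications,confidence,sample", "a,b,1,c"), bad)
  expect_error(parse_psm_table(bad), "peptide")
})

test_that("unparsable modification strings are row-level errors, not fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_psm(list(psm_row("FVK"),
                     psm_row("FSPE", modifications = "garbage!!")), path)
  recs <- parse_psm_table(path)
  expect_identical(nrow(recs), 1L)
  expect_length(attr(recs, "row_errors"), 1)
  expect_match(attr(recs, "row_errors"), "garbage")
})

test_that("peptides map to every exact proteome occurrence", {
  two <- list(toy1 = toy_protein(),
              dup = protein_record("dup", "AAAFVKAAA"))
  index <- proteome_index(two)
  hit <- map_peptide("FVK", proteome_index(toy_proteome()))
  expect_identical(hit$protein, "toy1")
  expect_identical(hit$start, 14L)
  expect_identical(hit$end, 16L)
  expect_identical(nrow(map_peptide("WWW", index)), 0L)
  expect_identical(nrow(map_peptide("FVK", index)), 2L)
  # I/L collapse is mapping-only and off by default
  il <- proteome_index(list(p = protein_record("p", "AAILAA")),
                       collapse_il = TRUE)
  expect_identical(nrow(map_peptide("AALL", il)), 1L)
  expect_identical(nrow(map_peptide("AALL", proteome_index(
    list(p = protein_record("p", "AAILAA"))))), 0L)
})

test_that("channel and origin classification follows the design rules", {
  index <- proteome_index(toy_proteome())
  design <- experiment_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_psm(list(
    psm_row("FVK"),                                        # heavy, S|FVK
    psm_row("QISFVK",
            modifications = "dimethyl-light@nterm(28.05);dimethyl-light@6(28.05)",
            sample = "control"),                           # light, R|QISFVK
    psm_row("SHFSPE", modifications = "acetyl@nterm(42.01)"),
    psm_row("WWWWW")), path)                               # unmappable
  cl <- classify_peptides(parse_psm_table(path), design, index)
  expect_identical(cl$channel, c("treated", "control", "unknown", "treated"))
  expect_identical(cl$origin,
                   c("prime_side_product", "library_peptide",
                     "ambiguous", "ambiguous"))
  expect_identical(cl$reason[3], "blocked_nterm")
  expect_identical(cl$reason[4], "unmappable")
})

test_that("prime products observed in the control channel are demoted", {
  index <- proteome_index(toy_proteome())
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_psm(list(
    psm_row("FVK"),
    psm_row("FVK", modifications = "dimethyl-light@nterm(28.05);dimethyl-light@3(28.05)",
            sample = "control")), path)
  strict <- classify_peptides(parse_psm_table(path), experiment_design(), index)
  expect_identical(strict$origin[1], "ambiguous")
  expect_identical(strict$reason[1], "observed_in_control")
  lax <- classify_peptides(parse_psm_table(path),
                           experiment_design(require_treated_only = FALSE),
                           index)
  expect_identical(lax$origin[1], "prime_side_product")
})

test_that("site reconstruction rebuilds the hand-worked toy window", {
  index <- proteome_index(toy_proteome())
  design <- experiment_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_psm(list(psm_row("FVK")), path)
  cl <- classify_peptides(parse_psm_table(path), design, index)
  recon <- reconstruct_sites(cl, index, design)
  expect_identical(nrow(recon$sites), 1L)
  expect_identical(recon$sites$window, "KQRQISFVKSHF")
  expect_identical(recon$sites$p1_position, 13L)
  expect_identical(recon$sites$attribution, "target_protease")
})

test_that("windows are X-padded near protein termini", {
  # prime peptide mapping at start = 4: P1 = 3, so subsites P6-P4 fall
  # before the protein start and are X-padded
  p <- protein_record("short", "QCADEFGHIW")
  index <- proteome_index(setNames(list(p), "short"))
  design <- experiment_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_psm(list(psm_row("DEFGHIW", proteins = "short")), path)
  cl <- classify_peptides(parse_psm_table(path), design, index)
  recon <- reconstruct_sites(cl, index, design)
  expect_identical(recon$sites$window, "XXXQCADEFGHI")
  expect_identical(nchar(recon$sites$window), 12L)
  expect_identical(substr(recon$sites$window, 6, 6), "A")   # P1
  expect_identical(substr(recon$sites$window, 7, 7), "D")   # P1'
})

test_that("identical windows deduplicate with a supporting-peptide count", {
  p <- protein_record("p", "GGGGGTSFVAAAWWGGGGGTSFVAAAWW")
  index <- proteome_index(setNames(list(p), "p"))
  design <- experiment_design()
  path <- withr::local_tempfile(fileext = ".csv")
  # two distinct prime peptides whose windows coincide
  write_toy_psm(list(psm_row("SFVAAAWWGGGGGTSFVAAAWW", proteins = "p"),
                     psm_row("SFVAAAWW", proteins = "p")), path)
  cl <- classify_peptides(parse_psm_table(path),
                          experiment_design(require_treated_only = FALSE),
                          index)
  recon <- reconstruct_sites(cl, index, design)
  expect_identical(nrow(recon$sites), 1L)
  expect_identical(recon$sites$n_supporting_peptides, 2L)
})

test_that("census counts are conserved and sites never vanish as rows accrue", {
  res <- run_recovery(10, seed = 37)
  cen <- res$recon$census
  expect_identical(cen$input_peptides,
                   cen$prime_side_products + cen$library_peptides +
                     cen$ambiguous)
  # monotonicity: reconstructing from a subset yields a subset of windows
  d <- withr::local_tempdir()
  sim <- res$sim
  half <- sim$psm$treated[seq(1, nrow(sim$psm$treated), by = 2), ]
  write_psm_table(half, file.path(d, "half.csv"))
  write_psm_table(sim$psm$treated, file.path(d, "full.csv"))
  index <- proteome_index(res$proteome)
  design <- experiment_design(require_treated_only = FALSE)
  rh <- reconstruct_sites(classify_peptides(parse_psm_table(file.path(d, "half.csv")),
                                            design, index), index, design)
  rf <- reconstruct_sites(classify_peptides(parse_psm_table(file.path(d, "full.csv")),
                                            design, index), index, design)
  expect_true(all(rh$sites$window %in% rf$sites$window))
})

test_that("sites after library-enzyme residues are excluded as library bias", {
  # prime peptide whose preceding residue is K: indistinguishable from a
  # ragged library terminus, so it must not enter the target profile
  index <- proteome_index(toy_proteome())
  design <- experiment_design(require_treated_only = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_psm(list(psm_row("SHFSPE")), path)  # context K16|SHFSPE
  cl <- classify_peptides(parse_psm_table(path), design, index)
  expect_identical(cl$origin[1], "library_peptide")
  recon <- reconstruct_sites(cl, index, design)
  expect_identical(nrow(recon$sites), 0L)
})

test_that("noiseless simulation is recovered exactly on a toy proteome", {
  res <- run_recovery(10, seed = 53)
  gtw <- sort(unique(res$sim$ground_truth$window[
    res$sim$ground_truth$recoverable]))
  expect_identical(sort(res$recon$sites$window), gtw)
})
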