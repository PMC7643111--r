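# picspec

Protease cleavage-site specificity profiling from proteome-derived peptide
libraries (PICS-style degradomics) and intact protein-substrate digests.

## The problem

Knowing *where* a protease cuts is the first step to knowing *what it is
for*. Degradomics experiments measure this in two complementary ways:

1. **Peptide-library profiling (PICS).** A proteome extract is digested
   with trypsin or GluC into a peptide library, the library is incubated
   with the protease of interest, and cleavage products are identified
   together with uncleaved library peptides by quantitative MS with stable
   isotope dimethyl labels (light = control, heavy = treated). The
   prime-side product of each cut carries the neo-N-terminus; the nonprime
   context is reconstructed bioinformatically from the source proteome.
2. **Protein-substrate digests.** A defined set of intact substrates is
   digested by the protease alone or followed by trypsin (sequential
   protocol) to make long products detectable; both peptide termini carry
   site evidence.

`picspec` implements the complete analysis: PSM-table parsing, dimethyl
channel classification, peptide-to-protein mapping, reconstruction of
unique P6–P6′ cleavage windows (Schechter–Berger subsites), sequence
coverage maps, unique-site set algebra across experiments, and the three
standard specificity statistics per subsite *s* and residue *a*:

* relative occurrence `p(a, s) = count(a, s) / N(s)`,
* fold enrichment over natural abundance `p(a, s) / p_bg(a)`,
* iceLogo-style percent difference `100 (p(a, s) − p_bg(a))` with a
  two-sided z-test against the background proportion.

A ground-truthed simulator (synthetic proteome, in-silico digestion,
position-weight-matrix protease, channel labeling, identification noise)
makes every stage verifiable by parameter recovery.

## Worked example

Simulate a protease that prefers F > Y > L in P1′ acting on a tryptic
library from a 50-protein synthetic proteome, then run the full profiling
pipeline on the emitted PSM tables:

```r
library(picspec)
proteome <- random_proteome(50, seed = 11)
model <- set_subsite_preference(specificity_model(propensity = 0.1),
                                "P1'", c(F = 0.40, Y = 0.30, L = 0.20))
sim <- run_simulate(proteome, model, simulation_config(seed = 11), "demo")
res <- run_pics_profile(
  c("demo/psm_control.csv", "demo/psm_treated.csv"),
  "demo/proteome.fasta", experiment_design(), "demo/out")
res$census[c("input_peptides", "prime_side_products", "library_peptides",
             "ambiguous", "unique_windows")]
#> $input_peptides
#> [1] 2314
#> $prime_side_products
#> [1] 538
#> $library_peptides
#> [1] 1744
#> $ambiguous
#> [1] 32
#> $unique_windows
#> [1] 532

prof <- specificity_profile(res$sites, background_frequencies(proteome))
round(sort(prof$enrichment[, "P1'"], decreasing = TRUE)[1:5], 2)
#>    F    Y    L    A    E
#> 8.45 6.05 3.96 0.20 0.19
```

Of 2,314 identified peptides, 538 are prime-side cleavage products that
collapse to 532 unique P6–P6′ windows. The planted P1′ preference is
recovered in the correct order — F, Y, L enriched 8.5-, 6.1- and 4.0-fold
over natural abundance — while unpreferred residues are depleted, and the
percent-difference profile flags all 20 P1′ cells as significant at
alpha = 0.05. The reconstructed window set equals the simulator's
recoverable ground-truth set exactly (this is asserted in the test suite).

The same statistics apply to substrate digests via
`infer_substrate_sites()`, `compute_coverage()` and `site_set_algebra()`;
`inst/cli/picspec.R` is a thin command-line wrapper over the `run_*`
pipeline functions.

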