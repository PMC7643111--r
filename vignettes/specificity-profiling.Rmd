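---
title: "Cleavage-site specificity profiling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-site specificity profiling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picspec)
```

## The measurement this package models

A protease's sequence specificity is described by which residues it prefers
around the scissile bond, indexed by the Schechter–Berger subsites P6..P1
(amino-terminal, "nonprime") and P1'..P6' (carboxy-terminal, "prime").
`picspec` reconstructs complete 12-residue P6–P6' cleavage windows from two
complementary experiment types and summarises them with three statistics.

**Peptide-library profiling (PICS).** A whole-proteome extract is digested
with a library enzyme (trypsin or GluC), the resulting peptide library is
incubated with the protease of interest, and control and protease-treated
aliquots are distinguished by stable-isotope dimethyl labels on peptide
amino termini and lysines (light, nominally +28.05 Da, for the control;
heavy, +34.06 Da, for the treated sample). A cleaved library peptide yields
a prime-side product whose amino terminus is the neo-amino-terminus created
by the protease. Because the library derives from a known proteome, the
nonprime side of the cut — which the product itself no longer carries — can
be read from the protein sequence once the product is mapped back. This is
the inference implemented in `classify_peptides()` and
`reconstruct_sites()`:

* channel from the amino-terminal label; blocked termini (acetyl,
  pyroglutamate) or missing labels make a peptide ambiguous;
* a treated-channel peptide whose preceding residue is *not* a
  library-enzyme P1 residue is a prime-side product; a peptide whose
  preceding residue matches the library enzyme (or a protein amino
  terminus) is an ordinary library peptide;
* each prime-side product places a site at P1 = start − 1; the window is
  sliced from the protein with `X` padding beyond the protein ends;
* sites whose P1 residue belongs to the library enzyme are excluded: they
  are indistinguishable from ragged library termini. This is the structural
  library bias — a tryptic library can never show cleavage after K/R — and
  is exactly why such experiments are run with two different library
  enzymes;
* peptides whose multiple proteome mappings disagree on the window are
  dropped rather than guessed; sites are deduplicated on the window string,
  so the headline count is *unique* P6–P6' sites.

**Protein-substrate profiling.** A defined set of intact substrates is
digested with the protease alone, or — because many products are too long
for mass spectrometry — followed by trypsin ("sequential" protocol). Here
both peptide termini carry evidence (`infer_substrate_sites()`): an
amino-terminal site at P1 = start − 1 and a carboxy-terminal site at
P1 = end, excluding substrate termini. In sequential mode every candidate
whose P1 residue is K or R is attributed to trypsin and removed; genuine
protease cleavage after K/R is knowingly sacrificed, since P1 identity is
the only available discriminator. Substrates enter as mature sequences
(signal peptides stripped with `mature_form()`), and all positions are
reported in mature coordinates.

## The three statistics

For a set of windows, `build_subsite_matrix()` counts residue occurrences
per subsite, skipping `X` cells and shrinking the per-subsite totals
accordingly. From the 20 × 12 count matrix:

* **relative occurrence** — column-stochastic frequencies per subsite;
* **fold enrichment** — occurrence divided by the background ("natural
  abundance") frequency of the residue in a reference proteome;
* **percent difference** — `100 (p_obs − p_bg)` percentage points per cell,
  the quantity drawn in iceLogo-style plots, with a two-sided one-sample
  z-test of the observed proportion against the background
  (`se = sqrt(p_bg (1 − p_bg) / N)`, `N` the subsite's countable total).

No multiple-testing correction is applied by default, matching the logo
tools this emulates; a Bonferroni option exists. Cells with expected count
`N · p_bg < 1` are flagged low-information. The background defaults to
frequencies computed from the same proteome FASTA used for reconstruction,
which keeps observed and reference composition comparable; a custom table
can be supplied. Unobserved residues yield fold enrichment 0 and are meant
to be marked, not smoothed: the pseudocount default is 0, and a symmetric
pseudocount (added to *all* counts before normalisation) is available for
small site sets.

## The simulator and what it does (and does not) emulate

Every stage is verifiable by parameter recovery because the synthetic-data
module generates inputs with known ground truth:

* `random_proteome()` draws protein sequences i.i.d. from a typical
  bacterial residue composition (lengths uniform in 200–400 by default);
* `build_library()` digests it in silico (trypsin: after K/R, not before P;
  GluC: after D/E; 0 missed cleavages by default — the missed-cleavage
  level is a config knob since real libraries vary);
* `simulate_protease_cleavage()` cuts each library peptide at most once
  (first accepted bond scanning N→C), with per-bond probability
  `propensity × prod_s(20 · w_s)` capped at 1, where `w_s` is the model
  weight of the residue in subsite `s`. The `20 ·` factor makes uniform
  weights exactly neutral: a fully uniform model cuts every bond with
  probability `propensity`, and `propensity = 0` disables cleavage. Window
  context is read from the parent protein, so nonprime context extends
  beyond the peptide start. X-padded context is neutral;
* `emit_psm_tables()` writes both channels with dimethyl modification
  strings, withholding coordinates (the pipeline must re-map), optionally
  subsampling by an identification rate and injecting shuffled-sequence
  decoys flagged only in the ground truth;
* `simulate_substrate_digest()` models the intact-substrate experiment:
  every bond cut independently, optional second-step trypsin digestion.

Peptides shorter than 4 residues are considered undetectable (a cleavage
one residue from a peptide end "would generate a tripeptide" invisible to
the instrument); the default detectable length window is 4–45 residues.
Ground truth records, per simulated site, whether it is *recoverable* from
the emitted tables: the prime fragment must be detectable, its sequence
must map to a unique window, it must not collide with a control-channel
library peptide, and its P1 residue must not belong to the library enzyme.
Recovery tests assert set *equality* between reconstructed windows and
recoverable ground-truth windows — sites failing those conditions are
information-theoretically absent from the input, not pipeline losses.

The simulator does **not** emulate spectra, intensities, retention times,
m/z, or FDR structure beyond a confidence column; sequences are i.i.d.
rather than homology-structured, so multi-mapping is far rarer than in a
real proteome with paralogues. Passing recovery tests therefore shows the
*inference logic* is correct, not that search-engine identification issues
are handled — those enter the pipeline only through the confidence
threshold (default 0.99, emulating a 1% FDR cut) and the ambiguity rules.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout; a cleavage site is
  identified by its P1 index (the bond is between P1 and P1 + 1).
* Non-standard residues (U/B/Z/J and friends) map to `X` on input and are
  excluded from every count, since the statistics are defined over the 20
  proteinogenic amino acids.
* I and L are distinct by default; an I=L collapse exists for mapping only.
* Site uniqueness is window-level, so identical windows from homologous
  proteins collapse; the census also reports protein+position-level counts.
* Whether doubly observed peptides should count: a prime-side product whose
  sequence also appears in the control channel is demoted to ambiguous by
  default (`require_treated_only`), trading sensitivity for specificity.
* Molecular masses use the standard monoisotopic residue table by default
  (average available); masses are a sanity-check utility, not part of site
  inference. Modification deltas are carried as nominal names (+28.05 /
  +34.06), not recomputed from atomic composition.
* The z-test (rather than a sampling-based significance estimate) is the
  documented choice for the percent-difference profile; at the subsite
  totals used here (hundreds of sites) the normal approximation is
  adequate, and the type-I rate is verified by simulation to stay near the
  nominal 5%.
* Ties in rank-recovery checks: with very large site sets, residues with
  tied true weights dilute a Spearman comparison through midranks, so
  recovery statistics are computed at the ~500-site scale with an
  expected-count filter (≥ 5 expected observations at the subsite), which
  keeps the residues about which the data are actually informative.

## Problem sizes used in the tests

The tests and the acceptance script run on: a 50-protein proteome
(~2,300 library peptides, ~500 unique reconstructed sites) for end-to-end
recovery and specificity statistics; 50 replicates of 400 null windows for
the type-I check; 1,000 random proteins for the digestion partition
property; six synthetic substrates for the substrate pipeline. These sizes
give stable Monte-Carlo behaviour while keeping a full run in well under a
minute on one CPU.

## Known limitations

* Target cleavage after a library-enzyme residue (K/R in tryptic
  libraries, D/E in GluC) is structurally invisible in PICS mode, and
  cleavage after K/R is removed in sequential substrate mode; profiles for
  those residues at P1 must come from the complementary experiment.
* Nonprime-side subsites of library-derived windows are depleted of the
  library enzyme's residues (library peptides carry none internally); this
  is a property of the experiment, visible as a mild negative percent
  difference for K/R (or D/E) at nonprime subsites.
* The per-cell z-test ignores the compositional dependence between
  residues within a subsite column and applies no multiplicity correction
  by default.
* Quantification, kinetics and preferential-degradation ranking of
  substrates are out of scope; the pipeline consumes identifications only.
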