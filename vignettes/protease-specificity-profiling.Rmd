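---
title: "Protease specificity profiling with protspec: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protease specificity profiling with protspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protspec)
```

## The problem

A protease incubated with a complex native proteome leaves a record of its
substrate specificity in the peptides it generates: every peptide terminus
that is not a protein terminus marks a scissile bond the enzyme cleaved.
`protspec` turns peptide identification tables from unspecific (no-enzyme)
database searches into quantitative specificity fingerprints — positional
enrichment matrices, cleavage entropies, condition differentials — and uses
those fingerprints to predict and design substrates.

Throughout the package, subsites follow the standard nomenclature: the
scissile bond lies between P1 and P1'; P8…P1 are the non-prime (N-terminal)
residues and P1'…P8' the prime residues. "Cleavage after residue *i*" means
P1 is protein residue *i* and P1' is residue *i + 1*. Coordinates are
1-based and inclusive.

## From peptides to cleavage windows

Records are quality-filtered before anything else. The default
`filter_policy()` retains peptides with posterior error probability
`pep <= 0.05` and search-engine `score > 40` (note the boundary semantics:
PEP is inclusive, score strictly greater), drops decoys and contaminants,
and restricts lengths to 5–40 residues, the usual cap of unspecific search
spaces. All thresholds are configurable.

Each located peptide then contributes up to two candidate cleavage sites,
`start − 1` and `end`. Sites 0 and L (protein termini) are discarded so the
fingerprint is not biased by native protein ends. Windows of 2×8 residues
are read off the parent protein and padded with `-` beyond its boundaries;
gap positions contribute neither to counts nor to column totals, so
boundary-adjacent sites do not inject fictitious residue mass. Within each
(sample, replicate) the same (protein, site) is counted once, so stacks of
overlapping peptides cannot overweight a single bond. The same site observed
in different replicates is kept once per replicate: replicate-level
variation is exactly what the downstream statistics consume.

Initiator-methionine excision is not modelled; only sites 0 and L are
treated as protein termini.

## Enrichment against a sampled null

The null model is deliberately simple: for each position independently,
counts are drawn from a multinomial over the database's global amino-acid
composition, with the same number of residues as the observed matrix. This
is a *sampled* null, not a closed-form one — the reference distribution the
whole field of positional-logo statistics uses.

For k observed replicates and k matched null members, each cell (residue,
position) gets

* `log2fc = log2((mean observed frequency + ε) / (mean null frequency + ε))`,
  with pseudo-frequency ε = 1e-4 guarding the logarithm. At realistic depths
  (thousands of windows) ε is far below any frequency of interest; it is
  recorded in every output.
* a two-sided paired t-test pairing replicate r with null member r,
  Benjamini–Hochberg adjusted across all 20 × W cells. Cells whose paired
  differences have zero variance (e.g. a self-comparison) are flagged
  degenerate with p = 1.

**Power is governed by the replicate count, not only the window count.**
With k = 3 the paired test has 2 degrees of freedom, so even a cell with an
enormous effect cannot reach a very small p-value when the sample standard
deviation happens to be inflated — `2 * pt(-t, df = 2)` decays only as
1/t². Detecting the *depleted* residues at a specific subsite (effect size
~0.05 in frequency units) against a BH threshold of ~6e-4 therefore needs
tens of thousands of windows per replicate, the scale real digests actually
produce. The simulation studies below are sized accordingly. Users with
k = 3 designs and shallow data should expect conservative significance
calls; adding a replicate helps far more than adding depth.

## Cleavage entropy

Positional entropy is the normalized Shannon entropy of each column,
`S_p = −Σ q log2 q / log2 20`, mapping to [0, 1]: 0 for a perfectly
specific subsite, 1 for a fully promiscuous one. The default is the raw
window distribution; a background-corrected mode (frequencies divided by
database composition and renormalized) is available because the two
conventions coexist in the literature; with a uniform background they
coincide exactly.

Block entropy generalizes this to k consecutive subsites: the plug-in joint
entropy of the observed k-mers. The gap `Σ marginal − joint` (the
multi-information, "cooperativity") is non-negative up to estimator noise
and measures how strongly subsites co-vary. The plug-in estimator is biased
upward by sparse sampling, so spans wider than 4 are refused by default and
any block with fewer than 20^k windows is flagged undersampled. No
bias-corrected (NSB-type) estimators are provided.

## Comparing proteases and conditions

* **Similarity**: Pearson correlation over flattened matrix cells;
  average-linkage clustering on 1 − r. Inputs are sorted by name first, so
  leaf order is reproducible and input order is irrelevant.
* **Matrix-level paired t-test** (`matrix_ttest`): cells of the two mean
  matrices paired across the grid. Note that two complete frequency
  matrices always have mean cell difference exactly zero, so this test is
  only informative for matrices that are *not* both column-normalized
  (e.g. after a targeted perturbation); identical inputs are reported as
  degenerate (NaN) rather than p = 1.
* **Differential specificity**: the difference of log2 fold changes,
  reported only where a cell is significant in at least one condition
  (configurable to "both"), with per-cell Welch t-tests on the replicate
  frequencies — unpaired, because conditions are separate digests.
* **Activity**: the number of unique peptides is the activity proxy;
  `log2(meanA/meanB)` with a delta-method standard error from the
  replicate variances.

## The motif score and the three-step substrate funnel

A candidate site's motif score is the sum over P4–P4' of the significant
log2 fold changes of its residues (non-significant cells contribute 0;
significant depletions subtract). Scanning a proteome emits one candidate
per internal site with a full window — `L − 7` per protein. The funnel
then narrows the candidate space in three steps:

1. **FPR threshold.** Against a user-supplied truth list (known cleavage
   sites, or bare 8-mers), a ROC is built and the score cut-off is the
   smallest score with empirical FPR at or below the target (default 1%;
   configurable). AUC uses the rank formula, so it is invariant under
   monotone transforms and handles ties.
2. **Accessibility.** A candidate survives only if all 8 window residues
   are exposed in the user-supplied mask. Residues missing from the mask
   are treated as exposed by default (configurable to buried/drop).
3. **Protein prioritization.** Surviving proteins are ranked (dense,
   descending, ties share a rank) on co-citation count, number of candidate
   sites, and blood concentration; the final score is the product of the
   three inverse ranks, in (0, 1]. Proteins with unreported concentration
   or zero co-citations are removed before ranking.

## Reporter-substrate design

`design_substrate` picks, per requested position, the residue with the
largest log2 fold change among significantly *enriched* cells (ties break
by smaller adjusted p, then alphabetically), with the two runners-up
reported as alternates. An alternative mode ranks by p instead. Designed
peptides are assumed NH2-…-COOH; `peptide_mz` uses the standard
monoisotopic residue masses with water 18.010565 Da and proton 1.007276 Da,
and `fragment_pair` checks the hydrolysis water balance
`M_prefix + M_suffix = M_parent + M_water` to 1e-4 Da.

## What the simulator emulates — and what it does not

`digest()` performs PWM-driven in-silico proteolysis: per replicate and
internal site, cleavage is an independent Bernoulli draw with probability
`plogis(steepness × PWMscore + qlogis(efficiency))`; peptides form between
consecutive cuts, are length-filtered (default 5–40), and can be dropped
with a detection-miss probability. The PWM stores per-position log2 boosts
over a background; each column's implied probabilities sum to 1.

The generator reproduces the features the statistics rely on — replicate
structure, PWM-shaped windows, nonspecific background cleavage, missed
cleavages — but not ionization physics, retention behaviour, spectral
interference, PTMs, or protein abundance structure. One *deliberate*
realism it does include: because short and over-long fragments escape
detection, cleavage sites adjacent to other cleavage-prone residues are
slightly under-detected, depleting the preferred residues at non-P1
positions by a fraction of a log2 unit. Real degradomics data carry the
same coupling. Passing parameter-recovery tests therefore shows the
pipeline recovers a known specificity *under realistic detection
coupling*; it does not certify performance on data with abundance bias or
modification-driven artefacts.

### Study conditions used by the tests and the acceptance script

These sizes were chosen once, from the power analysis sketched above, as
the package's own account of a realistic study, and are stated here rather
than hidden in test code:

* **Parameter recovery** (trypsin-like enzyme, R/K +6 log2 boosts at P1):
  4000-protein universe of 200–600-residue synthetic proteins, k = 3
  replicates, cleavage probability ≈ 0.4 after R/K (`efficiency = 0.027`,
  `steepness = 1`) and ≈ 0.2% elsewhere — a realistic missed-cleavage level
  that also keeps the detection-coupling bias below the BH threshold at
  the resulting ~6e4 windows per replicate. Reported: Pearson r between
  true log-odds and estimated log2FC, and sensitivity/FDR of the
  significant-cell set against the truth's non-zero cells.
* **Allosteric change**: +1.5 log2-odds boost of Leu at P2 versus the base
  enzyme, 2000 proteins, k = 4 replicates per condition. Four replicates
  (within the usual 3–4 range of such studies) give the per-condition
  significance gate of the differential matrix enough degrees of freedom.
  The planted cell should be the top |Δlog2FC| cell and P2 entropy should
  drop. The perturbed residue must be a common one: boosting a *rare*
  residue moves its frequency toward 1/e and thereby *raises* column
  entropy — an instructive property of −p·log p, not a bug.
* **Substrate scanning / ROC**: a thrombin-like enzyme (G at P4, I/V at
  P3, P at P2, R at P1, small residues prime-side) profiled at the same
  study scale, scanning a 200-protein synthetic secretome. A
  single-position enzyme is unusable here — nearly all candidate scores
  tie, and no FPR threshold exists — which is why multi-position
  specificity is the reference case for the funnel.

## Numerical and degenerate-input conventions

* Matrices are 20 × W with rows fixed in alphabetical residue order;
  exports reorder rows physicochemically only for the heat map.
* `0 · log 0 := 0` in all entropy computations.
* Empty window sets refuse to build a matrix; a single replicate refuses
  enrichment (no variance); B < 2 refuses a null ensemble (the paired test
  needs pairs).
* All sampling goes through derived seeds and restores the global RNG
  state; identical seeds give bit-identical outputs, including the written
  CSVs.
* Ties: design ties break by adjusted p then residue; ranking ties share a
  dense rank with accession-ordered output; clustering leaf order is fixed
  by name-sorting the inputs.

## Known limitations

* The paired t-test with few replicates is conservative (see above); a
  z-test against a large null ensemble would be more powerful for k = 2–3
  designs but is not currently exposed.
* The accessibility step consumes a precomputed mask; no structure
  prediction is run.
* Truth lists for ROC must overlap the candidate universe; there is no
  fuzzy site matching beyond exact (protein, site) or exact 8-mer.
* Multi-mapping peptides are expanded to all matching sites; a shared
  (protein, site) is still counted once per replicate, but a peptide
  mapping to several proteins contributes a window to each.
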