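---
title: "Mining and characterizing class I hydrophobins with hfbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and characterizing class I hydrophobins with hfbscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfbscan)
```

## The problem

Hydrophobins (HFBs) are small secreted fungal proteins whose eight conserved
cysteines form four disulfide loops; they self-assemble into amphipathic
films at interfaces, and class I members form SDS-resistant rodlets. Because
the family is defined less by overall sequence similarity than by the
*spacing* of those cysteines, a census of HFB genes in a newly sequenced
mushroom genome is naturally a rule-based screen: scan every predicted
protein for an 8-cysteine skeleton whose inter-cysteine gap lengths fall in
characteristic windows. `hfbscan` implements that screen and the standard
characterization steps that follow it — physicochemical descriptors,
a distance-based phylogeny, stage-wise expression quantification, and the
contact-angle arithmetic used to evaluate a purified hydrophobin's surface
activity — with a synthetic-data generator that makes the whole pipeline
testable end to end with known ground truth.

## Spacing grammars

A grammar (`cys_grammar()`) is an ordered set of residue-count constraints:
a leader range before the first cysteine, seven gap ranges between the eight
skeleton cysteines (adjacent "CC" pairs are the fixed range 0–0), and a tail
range. `hfb_grammars()` ships four:

* **typical** — `X2–38 C X5–9 CC X11–44 C X8–23 C X5–9 CC X6–18 C X2–14`.
  This broad pattern is the primary census filter.
* **class_I** — the narrower published class I consensus
  (`C X6–7 CC X33–41 C X19–25 C X5 CC X12–17 C`, leader and tail free).
* **class_II** — `C X9–10 CC X11 C X16 C X8–9 CC X10 C`.
* **gf_strain** (optional) — a strain-specific pattern with gap windows
  `7–8, 0, 13–32, 12–13, 5–6, 0, 11–12`. Its fourth window is printed
  ambiguously in its source ("C12/13"); we interpret it as `X12–13`, the
  only reading consistent with an 8-cysteine skeleton.

The typical pattern, not the class I consensus, drives candidacy because
the two are mutually inconsistent for real basidiomycete hydrophobins: the
class I consensus demands 33–41 residues between cysteines 3 and 4, while
observed family members can have as few as 13. Classification therefore
proceeds: length gate → class II (narrower, tested first) → typical
(reported as `typical_class_I` when class II fails) → atypical → rejected.

Two details matter for reproducibility:

* **Forbidden letters.** Gaps may not contain cysteine (an extra cysteine
  would belong to the skeleton). A stricter mode additionally bans
  tryptophan from gaps, a published convention whose biological rationale
  is unclear; it is configurable (`hfb_grammars(mode = "paper_strict")`)
  and off by default.
* **More than eight cysteines.** `match_grammar()` enumerates 8-subsets of
  the cysteine positions in lexicographic order (so the first hit minimizes
  the leader) up to a cap of 5,000 combinations, beyond which the sequence
  is flagged rather than silently truncated. With cysteine banned from
  gaps, only skeletons whose surplus cysteines sit in the leader or tail
  can match, so the cap is generous in practice.

**Length window.** Candidates must be 80–400 residues, inclusive at both
ends; a 79-residue protein with perfect spacing is rejected on length.

**Atypical calls.** Proteins inside the length window with 6, 7 or 9
cysteines and no satisfiable grammar are reported as `atypical` — these are
hydrophobin-like sequences the census counts as candidates but not as
typical class I members.

Signal-peptide and subcellular-location calls are *consumed* from an
optional annotation table produced by external predictors and reported as
`"unknown"` when absent; they are never computed here.

## Physicochemical descriptors

`physchem_profile()` reproduces the standard protein-parameter computations:

* **Molecular weight** — sum of average (not monoisotopic) residue masses
  plus one water (18.01524 Da), matching 2-decimal reference values.
* **GRAVY** — mean Kyte–Doolittle hydropathy over all residues; positive
  values mean a hydrophobic protein.
* **Theoretical pI** — the pH at which the Henderson–Hasselbalch net charge
  crosses zero, found by bisection on (0, 14) to |charge| < 1e-4. The pKa
  set is the Bjellqvist table used by the ProtParam service (C-terminus
  3.55; side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0;
  residue-specific N-terminal values with a 7.5 default), overridable via
  `bjellqvist_pka()`. The charge function is strictly decreasing in pH, so
  the bisection root is unique; tests cross-check it against a brute-force
  1e-4 pH grid scan.
* **Charged residues** — negatives D + E, positives K + R, histidine
  excluded by the usual convention.
* **Hydropathy profiles** — unweighted sliding means; the window defaults
  to 9 residues, a common choice for globular proteins (the method's
  originators suggested 7–11; results are insensitive within that range).

## Phylogeny

`nj_tree()` implements Saitou–Nei neighbor joining directly so that its
numerical behaviour is fully specified: Q-matrix ties are broken by the
lowest (row, column) index pair, negative branch-length estimates are
clamped to zero, and internal edges of exactly zero length are collapsed
(an all-zero matrix yields a star tree). For additive distances the tree
reproduces the input matrix exactly; tests verify topology recovery against
both an independent edge-enumeration oracle and `ape::nj()`. Distances are
p-distance by default — the common default for protein NJ in the widely
used desktop phylogenetics tools — with a Poisson correction available;
gaps are handled by pairwise deletion. `bootstrap_support()` resamples
columns with replacement, one `sample.int()` draw per replicate from a
single seeded generator, and scores each internal bipartition of the
original tree as a percentage; trees are emitted unrooted (no outgroup is
assumed) with supports as integer node labels in Newick.

Alignment construction is out of scope: the module consumes an existing
MSA (`read_msa()`).

## Expression

`fold_change_ddct()` is the pure 2^−ΔΔCt model with amplification
efficiency fixed at 2: per replicate, ΔCt = Ct(target) − Ct(reference) at
the same stage and replicate index; ΔΔCt subtracts the calibrator-stage
mean; the calibrator fold is exactly 1 by construction, and adding any
constant to all Ct values (a machine offset) cancels. Replicate spread is
reported on the fold scale by the delta method, `fold · ln 2 · sd(ΔCt)`
— the reporting scale of the SD had to be chosen, and the delta method
keeps error bars interpretable next to the fold values; the choice is
recorded in the output documentation. `one_way_anova()` is the classical
equal-variance F test (delegating to `stats::oneway.test`), with the
degenerate all-identical case defined as F = 0, p = 1.
`stage_transition_report()` compares each stage to its predecessor
(Myc → Pri → Yfb → Mfb) with an equal-variance two-sample t test on the
replicate ΔCt values, starring p < 0.05 and p < 0.01; transitions across a
missing stage are reported as gaps. No multiplicity correction is applied
anywhere — the number of tests run is attached to the report so users can
correct downstream if they wish.

## Surface assays

`wettability_alteration()` and `rinse_resilience()` encode the two
denominator conventions of contact-angle reporting: coating-induced change
is relative to the *blank* surface, post-SDS-rinse change is relative to
the *coated* (pre-rinse) surface. Both report magnitudes rounded half-up
to two decimals with the direction retained. `gf_wca_measurements()` ships
the published instrument means this arithmetic consumes;
`wca_report()` reproduces all eight published percentages, with golden
tests allowing ±0.02 percentage points to absorb the source's rounding
mode (one published value, 15.91%, recomputes exactly as 15.92%).

## The synthetic-data generator

`generate_proteome()` emulates the census conditions: 19 planted typical
class I proteins, 3 atypical variants (two with 7 cysteines, one with 6),
and 80 decoys, for 102 records under the default plan (seed 42). Design
choices:

* Planted sequences draw layout parameters uniformly from the typical
  grammar's windows, extend the leader (within its 2–38 window) when the
  draw falls under the 80-residue gate, and draw gap residues from a
  hydrophobic-biased alphabet without cysteine or tryptophan, then
  rejection-sample into the published physicochemical envelope
  (GRAVY 0.27–0.951, pI 3.57–8.50) and away from the class II grammar.
* Atypical variants are typical constructions with one or two singleton
  skeleton cysteines replaced by alanine, preserving the architecture
  while breaking the 8-cysteine skeleton.
* 20% of decoys are *near-misses*: a typical layout with exactly one gap
  pushed out of range by one residue — the sharpest possible negative for
  the classifier. The remainder are random sequences whose cysteine count
  is drawn from {0–5, 8, 10–12}: counts 6, 7 and 9 are excluded because
  such a sequence would *correctly* be an atypical candidate, which would
  change the planted census arithmetic rather than test the classifier.
  All decoys are rejection-sampled so no grammar matches.

All randomness flows through one seeded generator, so a fixed plan is
byte-identical across runs. `generate_ct_table()` plants per-gene,
per-stage log2 effects in a 4-stage × 3-replicate design with a constant-
expectation reference gene and Gaussian Ct noise (default 0.2 cycles, a
typical replicate spread for SYBR assays); noise-free tables invert
exactly. `generate_msa()` evolves sequences along a known tree under
symmetric Jukes–Cantor-style substitutions over the 20-letter alphabet.

What the generator does *not* emulate: real proteomes' homology structure
(decoys are i.i.d., not paralogs), realistic intron/codon structure, shared
evolutionary history between planted hydrophobins, non-Gaussian qPCR error,
or amplification-efficiency variation. Passing the census tests therefore
demonstrates that the classifier implements its rules exactly — not that
those rules have any particular sensitivity or specificity on real
proteomes, where borderline paralogs and fragmented gene models dominate
the error budget.

## Numerical choices and problem sizes

* pI bisection: tolerance 1e-4 on |charge|, with a 1e-10 interval-width
  backstop; reported to 2 decimals.
* Percent changes: rounded half away from zero to 2 decimals
  (`round_half_up()`), so printed values match hand arithmetic.
* NJ: Q compared with a 1e-12 slack so floating-point noise cannot
  reorder exact ties; the deterministic tie-break is the lowest index pair.
* Grammar enumeration cap: 5,000 8-subsets (≥ C(12,8) = 495 with a wide
  margin for ordinary proteins).
* Test problem sizes were chosen to exercise each property at desk scale:
  1,000 random sequences for the matcher/oracle equivalence, 100 random
  additive matrices of 4–12 taxa for NJ recovery, 10,000 Monte-Carlo
  replicates for the ANOVA null calibration, 200 simulated genes for ΔΔCt
  parameter recovery.

## Known limitations

* The census grammars are windows over gap lengths; they cannot express
  correlated constraints (e.g. "gap 3 long *only if* the leader is short").
* Distance-based NJ only; no likelihood or Bayesian trees, and no
  alignment construction.
* Intron counts are derived from exon features; annotations listing UTR
  introns are flagged as discrepant rather than reconciled.
* The pure 2^−ΔΔCt model assumes doubling per cycle; efficiency-corrected
  variants are out of scope.
* Published per-protein descriptor values for the original census cannot
  be checked directly because the underlying sequences are not deposited;
  they constrain the generator's target ranges instead.
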