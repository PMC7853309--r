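---
title: "Scoring RBCS helix hydrophobicity and counting pyrenoid losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring RBCS helix hydrophobicity and counting pyrenoid losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrescore)
```

## The model

The pyrenoid is a chloroplast microcompartment, built mainly of Rubisco,
that drives the CO2-concentrating mechanism of most eukaryotic algae.
Pyrenoid assembly depends on interactions made by two surface alpha-helices
of the Rubisco small subunit (RBCS) — helices A and B — with other Rubisco
holoenzymes and with the linker protein EPYC1. The working hypothesis this
package operationalizes is that the *surface hydrophobicity* of these two
helices modulates those interactions, and that a drop in hydrophobicity
accompanies (and may drive) evolutionary loss of the pyrenoid.

The statistic is deliberately simple. Helices A and B are defined on the
numbering of the *Chlamydomonas reinhardtii* RBCS1 precursor (transit
peptide included): positions 68–80 and 131–144, 27 residues in all. Six of
these positions (71, 75, 78, 134, 138, 141) face the protein core — their
side-chain exposure ratio falls below 15% — and are excluded. The score of
a homolog is

$$ H = \sum_{i \in \text{exposed helix positions}} \mathrm{KD}(a_i), $$

the sum of Kyte–Doolittle hydropathy over the 21 exposed positions
(Ala = 1.8, Pro = −1.6, range −4.5 to 4.5 per residue; so $H$ is bounded by
±94.5). A single Ala→Pro substitution at position 131 — the change that
separates a pyrenoid-containing species from its pyrenoid-lacking sister —
shifts $H$ by exactly −3.4.

Group comparison between pyrenoid-containing and pyrenoid-lacking species
uses the Brunner–Munzel rank test of stochastic superiority
$p = P(X < Y) + \tfrac12 P(X = Y)$, which tolerates unequal variances; the
two groups in the packaged data are in fact completely separated, which is
a degenerate case the implementation must (and does) handle explicitly.
Finally, the number of independent pyrenoid losses on the species tree is
counted by parsimony.

## Mapping queries onto the reference numbering

Homologs are mapped onto the reference coordinates by pairwise global
alignment (BLOSUM62, affine gaps with open 10 / extend 0.5, terminal gaps
free). RBCS homologs are far above the twilight zone (>60% identity), so
the helix mapping is insensitive to these constants; they are fixed so
results are deterministic. Free terminal gaps let mature-protein queries
(transit peptide absent) map onto the precursor numbering without penalty.
Because the field's alignment conventions here are not prescriptive, this
scheme is the package's own choice; on short, low-identity toys an
ends-free aligner may legitimately prefer shifting a terminal residue over
opening an internal gap, which is why the test fixtures use
realistic-length sequences.

A query deletion at a helix position yields `-` in the 27-symbol slice;
scoring then counts that position as 0 and flags the record
(`gap-in-window`), and `n_scored` reports how many of the 21 positions
actually contributed. We chose contribution 0 over imputation because no
deletion policy is prescribed by the underlying analysis; the flag plus
`n_scored` lets users exclude incomplete slices rather than silently
absorbing an imputation.

## The exposure mask

The packaged mask {71, 75, 78, 134, 138, 141} is authoritative: it is the
set of embedded positions used throughout, and the default pipeline never
needs a structure. For users who want to recompute a mask from a PDB file,
the package ships a Shrake–Rupley solvent-accessible surface area engine:

* heavy atoms only, van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å,
  probe 1.4 Å;
* a deterministic golden-spiral quadrature (default 960 points/atom).
  Isolated-sphere and two-sphere analytic oracles are matched within 1–2%;
  the total area of a small peptide changes by under 1% when the point
  count is quadrupled. Translations leave the result exactly unchanged
  (the point set moves rigidly with the atoms); rotations re-sample the
  fixed point set and perturb the total by up to ~0.4% at 960 points
  (~0.1% at 3840), which is the expected anisotropy of a fixed spherical
  quadrature, not an implementation artefact;
* the exposure ratio divides a residue's side-chain area by a random-coil
  reference. The classical reference is the average side-chain area of X
  in Gly-X-Gly over random conformations; that table is cited, not
  reprinted, in the literature this package follows, so
  `COIL_SIDE_CHAIN_REF` was computed once with this very engine on
  extended Gly-X-Gly models built from idealized residue geometries and is
  packaged as the default (overridable via `coil_refs`). This makes the
  ratio self-consistent: the `gly_ala_gly` toy fixture scores an Ala
  exposure ratio of ~1 by construction;
* a position is *embedded* when its ratio is strictly below the threshold
  (default 0.15; a ratio of exactly 0.15 is exposed).

Whether a recomputed mask should be derived from the RBCS monomer or the
assembled holoenzyme is genuinely open; exposure is therefore computed in
the context of all chains present in the input file, and the packaged mask
sidesteps the question for the default pipeline.

## Brunner–Munzel with a degenerate-separation fallback

With pooled-midrank mean $\bar R_y$, the estimator is
$\hat p = (\bar R_y - (n_y+1)/2)/n_x$; the studentized statistic uses
within-group variances of (pooled rank − within-group rank) and a
Satterthwaite-type degrees-of-freedom, referred to a t distribution. The
implementation's statistic is tested against an independent pair-counting
implementation, and its p-value against exact studentized permutation.

When the two samples are completely separated (or all-tied within groups),
both variance estimates are zero and the t statistic is undefined — and
this is exactly the situation of the packaged 20-vs-12 comparison. The test
then switches to a permutation reference for $|\hat p - 0.5|$:

* fully separated, no cross-group ties: the extreme value 0.5 is attained
  by exactly the two one-sided assignments, so the exact two-sided p is
  $2/\binom{n_x+n_y}{n_y}$ in closed form (for 20 vs 12, $8.9\times10^{-9}$);
* otherwise, full enumeration when $\binom{n}{n_y} \le 2\times10^6$;
* otherwise, seeded Monte Carlo with an add-one estimator (the only
  stochastic path; `seed` makes it reproducible).

Two numerical caveats are worth stating. First, permutation p-values are
discrete; identical-sample inputs short-circuit to p = 1. Second, at very
small samples (n ≤ 8 per group) the t approximation deviates from the exact
permutation p by a few percent (we measure 0.01–0.05); this is a known
limitation of the t reference in the regime where permutation is
recommended anyway, and the package's own permutation path is the exact
answer there.

Group summaries use linear-interpolation quartiles (R's default type 7);
only the extremes are compared against published values.

## Counting losses

`fitch_min_changes()` computes the parsimony minimum by unit-cost dynamic
programming over the two states, which reproduces Fitch counting on binary
trees and is exact on multifurcations. `count_losses()` enumerates *all*
minimum-change labelings whose root is fixed at the outgroup state
(present, since all outgroups bear pyrenoids) and reports the set of loss
counts across them.

The default transition model forbids regain (Dollo). This is a deliberate
deviation from plain unordered parsimony: on the packaged five-species
ladder, unordered Fitch admits an equally parsimonious labeling in which
the pyrenoid is lost once on an internal edge and *re-gained* on a tip
edge, making the loss count ambiguous ({1, 2}). Re-evolving a complex
organelle is not a biologically admissible event at this timescale, and
the no-regain assumption is what makes "how many times was it lost?"
well-posed; under it the packaged topology gives the unambiguous answer 2.
`model = "fitch"` exposes the unordered behaviour, and both models are
tested against brute-force enumeration over all internal labelings.

## Clone-consensus filtering

Sanger-sequenced clones of RT-PCR products carry sporadic errors; a
sequence is admitted only when the identical string (exact full-length
match after uppercasing) occurs in at least `min_support = 2` clones.
No error correction or sub-alignment is attempted: any mismatch makes a
distinct clone, and trimming differences are the caller's responsibility
(trim to a common window first). The filter is idempotent and monotone in
`min_support`, and the synthetic clone generator calibrates the workflow:
at a 0.3% per-base error over a 307-bp window a clone is error-free with
probability ≈0.40, so 8 clones recover the true sequence with ≥2 supporting
copies in ≈89% of loci — the regime in which the rule is useful without
being wasteful.

One bookkeeping subtlety: the clone-verification window spans CDS positions
156–465 (310 nt) minus one whole-codon deletion, i.e. 307 nt
(`cds_window_length(156, 465, deleted_codons = 1)`). Position 156 is not a
codon boundary and the verification frame is not prescribed, so
`translate_cds()` takes an explicit `frame` argument instead of guessing.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads.

* `gen_helix_slices(n, mean, sd)` emulates the score distributions of the
  published table: the study conditions are n = 20 present-group sequences
  around −24 and n = 12 absent-group sequences around −31 (the published
  spreads are roughly ±2.5 and ±1). Targets are drawn from N(mean, sd) and
  residues assigned greedily (jittered near-ties, alphabetical exact ties,
  final two positions by joint enumeration), guaranteeing the realized
  score is within 0.5 of its target. Masked positions are filled with
  random residues precisely so tests can prove scoring ignores them. The
  sequences are *not* evolutionarily realistic — composition is whatever
  meets the score target, there are no indels and no phylogenetic
  correlation — so passing tests demonstrate correctness of the scoring
  and testing machinery, not biological realism.
* `gen_clone_set()` applies i.i.d. per-base substitutions; real Sanger
  errors cluster at read ends, so the calibration above is conservative in
  structure but not a read-quality model.
* `gen_toy_structure()` produces the analytic-oracle fixtures
  (single atom, two spheres, buried shell) and the extended Gly-Ala-Gly
  tripeptide built from internal coordinates.
* `gen_trait_tree()` plants a known number of independent losses on a
  random topology and verifies, by construction, that the parsimony
  minimum equals the planted count.

All generators are deterministic given `seed`, to the byte, across runs.

## Problem sizes and runtimes

The test suite runs at desk scale by choice: permutation oracles enumerate
up to $\binom{16}{8}$ assignments, brute-force parsimony oracles cover all
internal labelings of trees with ≤8 tips, the SASA convergence checks use
960 vs 3840 points on a 14-atom peptide, and the power check runs 500
simulated 20-vs-12 studies (mean shift 7 scale units, sd 1), which detects
the group difference at p < 0.001 in ≥99% of replicates in well under two
minutes. The full suite completes in about a minute.

## Known limitations

* Per-accession scores for the published table require the deposited
  sequences; the package therefore ships the published values as data and
  recomputes the statistics, not the per-accession scores themselves.
* The packaged exposure mask is taken as ground truth; mask recomputation
  is best-effort and depends on which assembly (monomer vs holoenzyme) the
  user supplies.
* The Brunner–Munzel t approximation is unreliable below ~10 observations
  per group; the permutation path is authoritative there.
* The aligner is pairwise-global only; remote homologs or sequences with
  large rearrangements should be pre-aligned by other means and fed through
  `slice_from_alignment()`.
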