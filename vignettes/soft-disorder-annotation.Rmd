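---
title: "Soft-disorder annotation from crystallographic ensembles: methods and design"
author: "softdisorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-disorder annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softdisorder)
```

## The model

A protein residue can be ordered in one crystal form and invisible or
highly mobile in another. Soft disorder captures this ensemble-level
ambiguity. Given a *cluster* of chains whose sequences are nearly
identical (alternative crystal structures, point mutants, co-crystals),
each chain contributes three per-residue tracks:

* **missing** — the residue is in the construct (SEQRES) but absent from
  the model, i.e. listed under `REMARK 465`;
* **flexible** — the residue's normalized Cα B-factor exceeds a threshold:
  $b_i = (B_i - \bar B)/\sigma_B > 3$, with $\bar B$ and $\sigma_B$ the
  mean and *population* standard deviation of the Cα B-factors of the
  present residues of that chain;
* **interface** — the residue contacts another protein chain (Cα–Cα
  distance ≤ 5 Å) or loses accessible surface area when nucleic chains of
  the same entry are added.

Tracks are mapped through per-member alignments onto the cluster
representative — the chain from the structure with the best (lowest)
resolution, ties broken by R-value, then lexicographically — and counted
per site. With $n_\text{aligned}$ chains observing a site,
$n_\text{missing}$ of them missing it and $n_\text{soft}$ marking it
missing-or-flexible:

* **ID** (intrinsic disorder): $n_\text{missing} = n_\text{aligned} > 0$.
  The site never has coordinates, so its soft-disorder frequency is
  undefined and masked.
* **SD** (soft disorder): $n_\text{soft} \ge 1$ and not ID; frequency
  $f = n_\text{soft}/n_\text{aligned}$.
* **DtO** (disorder-to-order), a flag compatible with SD:
  $1 \le n_\text{missing} < n_\text{aligned}$.
* **none / unaligned** otherwise.

Binary dataset labels use the at-least-once rule ($f > 0 \Rightarrow 1$);
the frequency track is kept alongside for uncertainty-aware consumers.

### Assumptions and conventions

Several conventions are deliberate choices where common practice varies;
each is a parameter or documented behavior:

* **Population standard deviation** for $\sigma_B$: the chain is the whole
  population of its residues, not a sample from a larger one. With $n$
  present residues of which $k$ are candidates, the largest attainable
  $b_i$ is $\sqrt{(n-k)/k}$, so the $b_i > 3$ flag is only reachable when
  flexible residues are fewer than a tenth of the chain — a structural
  property of the statistic worth keeping in mind when interpreting flags
  on short chains.
* $\sigma_B = 0$ (constant B-factors) yields all $b_i = 0$: nothing is
  flagged, and no division by zero occurs.
* The flag inequality is **strict** ($b_i > 3$), and the contact cutoff is
  **inclusive** (≤ 5.0 Å); both are arguments (`threshold`, `cutoff`).
* Only the Cα B-factor is used. A present residue without a Cα keeps its
  presence flag but has no $b_i$ and is never flagged flexible.
* Among alternate locations the highest-occupancy one is kept; ties go to
  the first encountered. This makes parsing deterministic.
* Nonstandard residues map to `X`; selenomethionine (MSE) maps to `M` to
  preserve alignability of selenomethionine derivatives.
* Only X-ray entries enter by default (`xray_only = TRUE`); the flag
  exists because cryo-EM and NMR B-factor columns mean different things.

## Sequence clustering and leakage control

Pairwise global alignment (Needleman–Wunsch, BLOSUM62, gap open 11 /
extend 1, via Biostrings) underlies clustering, pruning and position
mapping. **Identity is the number of identical aligned pairs divided by
the shorter sequence length** — the CD-HIT convention. Construction-style
clustering (default 90% identity / 90% coverage) and train/test pruning
use the same convention so that a threshold means the same thing in both
places; tools mix denominators, and exact replication of any particular
external tool's cluster inventory is a non-goal.

Greedy clustering processes sequences by decreasing length (ties broken
by key), joining the first cluster whose representative matches at both
thresholds. The result is deterministic and order-independent. Clusters
are then re-anchored on the best-resolved member (`reanchor_cluster`),
which recomputes the member-to-representative maps.

`prune_against` removes queries reaching the identity threshold to any
reference; `prune_splits` applies it to validation/test records against
train. Datasets keep only sequences of 20–2048 residues (inclusive), and
splits follow 70/10/20 fractions with largest-remainder rounding, so
round totals split exactly.

## Interfaces

Protein–protein contacts use a cell-list grid with cells the size of the
cutoff; it is contractually identical to the all-pairs search (`method =
"brute"`), which the tests assert on random geometries.

ASA uses a Shrake–Rupley sampler with a deterministic golden-spiral point
set. Chain records keep one representative atom per residue, so the ASA
model is **one sphere per residue** (radius 1.9 Å, probe 1.4 Å); the
result object carries this approximation tag. The default of 7680 points
per sphere makes per-residue values stable to better than 0.5% under
point doubling on chain-like geometries; an isolated sphere reproduces
the analytic $4\pi(r+p)^2$ essentially exactly because no point is ever
occluded. A nucleic interface residue is one whose isolated-chain ASA
exceeds its in-complex ASA by more than `epsilon` (default 0.01 Å², just
above sampling noise; the quantization step at 7680 points is about
0.018 Å², so genuinely buried residues clear it by orders of magnitude).

## The fixture generator

`generate_cluster` emulates exactly the statistical structure the
pipeline consumes, not protein physics:

* chains are extended Cα traces at 3.8 Å spacing;
* cluster members share a base sequence with Binomial(L, 2%) point
  substitutions, truncated at 4% of the length so any two members stay
  ≥ 92% identical and a planted cluster can never split at the default
  90% clustering threshold — this truncation is part of the generator's
  contract that planted truth is exact;
* missing and flexible segment loci are chosen per cluster and carried by
  a controlled fraction of members, so expected per-site frequencies are
  known in closed form; flexible segments are escalated until their
  normalized B-factor exceeds 3 *after* rounding to the PDB's two
  decimals, while base B-factors are drawn from a bounded uniform whose
  maximal deviation is $\sqrt 3$ population SDs — no unplanted residue
  can ever be flagged;
* a protein partner chain sits 4.0 Å from the planted contact span:
  inside the 5 Å cutoff, while sequence neighbors at
  $\sqrt{3.8^2+4^2} = 5.52$ Å stay outside — the contact truth is exactly
  the span;
* an optional nucleic partner sits 6.0 Å away: inside the single-sphere
  occlusion reach $r_i + r_j + 2p = 6.6$ Å, with neighbors at 7.1 Å
  outside it — the burial truth is exactly the span;
* entry metadata (resolution 1.5 + 0.05·(member−1)) makes representative
  selection deterministic.

What the generator does **not** emulate: real backbone geometry, side
chains, crystal packing, correlated B-factor structure, alignment gaps
(members differ by substitutions only), heterogeneous chain lengths
within a cluster, or modified residues. Passing the recovery tests
therefore demonstrates the correctness of the counting, mapping,
threshold and I/O logic under controlled conditions — not robustness to
the full messiness of archive files (altloc and insertion-code handling
are exercised by dedicated parser fixtures instead).

`generate_predictions` draws positive scores from Beta($a$, 1) and
negative scores from Beta(1, 1); since $P(X > Y) = E[X] = a/(a+1)$ for
$X\sim\mathrm{Beta}(a,1)$ and uniform $Y$, setting $a = t/(1-t)$ gives an
analytic ROC AUC of exactly $t$. A target of 1 uses disjoint supports.

## Evaluation metrics

All metrics pool evaluable residues (unmasked label, non-missing score)
across profiles — per-protein averaging is available by calling the
metrics per profile. Conventions where the field is silent: a score
exactly at the decision threshold counts positive; MCC and F1 are 0 when
a denominator vanishes; ROC AUC uses midranks (Mann–Whitney), equal to
trapezoidal ROC area; PR AUC is the average-precision step sum with tied
scores as one threshold group (so uniform scores give AP = prevalence);
max-F1 scans 0.00–1.00 inclusive at step 0.01 and returns the smallest
maximizing threshold. `coverage_filter` drops profiles whose scored
fraction of labeled residues falls below a floor and reports the retained
share of the residue pool, which is how coverage-restricted comparisons
are made fair.

## Problem sizes and tolerances in the tests

The suite checks arithmetic oracles to 1e-12 on 1000 random chains,
grid-versus-brute contact agreement on 100 random two-chain geometries at
cutoffs 4/5/6 Å, exact planted-truth recovery on 50 generated clusters
(4–8 members, lengths 60–90, carrier fractions 0.25/0.5/1, with and
without nucleic partners), pruning against the exhaustive filter at
thresholds 0.9/0.7/0.5/0.3/0.25, split exactness on 1000 records, metric
oracles by enumeration on 12–15-residue instances, and prediction
calibration at AUC 0.8 with 10⁴ residues (tolerance ±0.02, the ~2-sigma
sampling band). These sizes keep the full suite under a minute while
every code path — including the file round trip — is exercised.

## Known limitations

* mmCIF input is not implemented; convert to PDB format first.
* ASA on real all-atom structures would need per-atom spheres and a vdW
  radii table; the single-sphere-per-residue model is calibrated for the
  package's Cα-level records and is not a substitute for an all-atom SASA
  when side-chain burial matters.
* Greedy clustering is quadratic in the number of cluster
  representatives; it is meant for desk-scale inputs (10³–10⁴ chains),
  not archive-scale sweeps.
* SEQRES-to-author-numbering reconciliation assumes the observed plus
  missing residues enumerate the construct; engineered numbering schemes
  that violate this fall back to observed records with a warning.
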