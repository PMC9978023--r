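---
title: "Models and methods behind the STEM-PCR simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the STEM-PCR simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stempcr)
```

STEM-PCR turns the *position of a molecular end* into an amplifiable
signal. This vignette documents the models the package uses to emulate
that mechanism, the defaults and why they were chosen, what the synthetic
data generator does and does not capture, and the numerical and design
choices a maintainer should know about.

## The reaction model

### Digestion

Methylation-dependent restriction enzymes are modeled as degenerate IUPAC
motifs with per-position 5-mC requirements on the recognized strand, plus
a cut rule: either a fixed spacer downstream of the motif (MspJI +9,
FspEI +12, LpnPI +10) or an intra-motif offset (GlaI). GlaI's offset is
not published alongside its motif; the default of 2 — a centered blunt
cut in R(5mC)GY — matches its known blunt-cutting behavior and is exposed
in the enzyme registry for users who need a different geometry.

Cuts are blunt double-strand breaks at the recognized strand's cut point.
Only the informative strand's 5' end drives the mechanism, so modeling
the second nick position would add bookkeeping without changing any
outcome the package reports.

Spacer-type enzymes additionally require a cut helper. Two modeling
choices matter here:

* *Coverage*: a helper gates a site when its target interval fully
  contains the recognition motif, the minimal reading of a helper that
  "encompasses" the site.
* *Strand*: the digestion protocol melts the template and lets the helper
  re-form a short duplex; everything else stays single-stranded, and these
  enzymes do not cut single-stranded DNA. A helper therefore activates
  only sites recognized on the strand it hybridizes to. This is load
  bearing: a fully methylated CCGG LpnPI site is recognized on both
  strands, and without strand-resolved gating the antisense-directed cut
  would land inside the very fragment the assay is trying to create.

Digestion efficiency defaults to 1.0 (complete digestion, deterministic
and idempotent); a lower value distributes molecules multinomially over
cut subsets, because incomplete digestion is a documented failure mode of
competing enzyme-based methods and worth simulating.

### Extension, folding, and yield

Per fragment, TFP extension is pure coordinate arithmetic: the capture
region (CR) anneals at its template window and extension proceeds to
`stop = max(fragment 5' end, proximal edge of a bound PNA)`. A PNA binds
only when its footprint lies fully inside the fragment and matches
perfectly — one mismatch (the wild-type base) unbinds it. Relative to the
designed FR boundary `c5`:

* `overhang3 = max(0, c5 - stop)` — extra 3' bases after folding;
* `fr_deleted = max(0, stop - c5)` — FR bases missing from FRa.

Self-priming requires a zero overhang and an FR deletion within a
configurable maximum (default 3). The yield table is a multiplicative
lookup taken directly from the truncation studies: any 3' overhang ≥ 1 nt
gives 0; FR deletions of 2–3 nt give 0.1; one missing CR base gives 0.2
and two or more give 0. The 1-nt FR deletion factor defaults to 1.0
because only the 2–3-nt deletions were quantified; it is a parameter of
`penalty_table()`.

### Quantification

Effective P3 copies are
`N0 = Σ copies × yield × digestion_eff × hybridization_eff`, and
`Ct = ln(Nq/N0) / ln(1+E)`, censored negative when `N0 = 0` or
`Ct > max_cycles` (default 50, matching the 10 + 40 two-stage protocol).
Defaults `E = 0.9` and `Nq = 1e10` are ordinary qPCR magnitudes; the
hybridization efficiency of 0.5 applies only to the PNA- and bridge-primer
(BP)-mediated linear steps, encoding the qualitative observation that
enzymatic digestion is more efficient than blocker/bridge hybridization.
Only the ratio `Nq/N0` is identified by Ct data; the absolute values are
conventions.

An optional exponential efficiency decay in P1 length
(`length_decay_rate`, per nt beyond 45) reproduces the trend of rising Ct
with inter-cut distance in co-methylation mode; it is off by default
because only the trend, not a rate, is established, and at 0.01/nt the
longest supported P1 (165 nt) remains comfortably detectable.

### Co-methylation fragment classes

After digestion, each fragment is classified against the two designed cut
coordinates: T1 no specific end, T2 specific 5' only, T3 specific 3'
only, T4 both. Only T4 amplifies. T3 is reported as starting linear
extension but yields 0 at the fold step (the long 3' overhang blocks
self-priming); whether real T3 molecules contribute trace background is
not quantified anywhere we know of, so 0 is the faithful choice.

## Thermodynamics

Duplexes use the unified nearest-neighbor parameters (SantaLucia 1998)
with initiation terms, shipped as `inst/extdata/nn_santalucia1998.csv`,
the entropy salt correction `ΔS' = ΔS + 0.368 (n−1) ln[Na+]`, and a
two-state bimolecular Tm at `CT/4` (equal, non-self-complementary
strands). The implementation is cross-checked in the test suite against
values frozen from an independent published NN calculator; agreement is
within 0.01 °C.

Hairpins treat the stem as stacked pairs and assign the tabulated
hairpin-loop ΔG37 (Jacobson–Stockmayer extrapolated beyond 30 nt)
entirely to the entropy, giving a loop-penalized unimolecular Tm. This
two-state model reproduces the observed ordering — stability rising
monotonically with stem length at fixed loop, falling with loop size —
which is all the package relies on; no partition function or suboptimal
folds are computed.

The fold-vs-AP competition is a coupled mass-action equilibrium: a
unimolecular fold (`K_f`) competing with a bimolecular AP duplex (`K_a`)
under conservation of both totals, solved in closed form (quadratic in
the bound-AP variable, with the numerically stable root). It reproduces
the stated behavior — more AP pulls material out of the folded and
unstructured states — and is exact to machine precision; free energies
beyond ±500 RT raise an error asking for rescaled inputs rather than
returning overflowed garbage.

PNA:DNA duplexes reuse the DNA table plus a uniform stabilization of
−0.35 kcal/mol per base pair (configurable). Only the sign of the PNA
effect is established; the default magnitude gives PNA oligos a realistic
5–10 °C Tm advantage at typical lengths.

### Cross-dimer screen

All unordered oligo pairs (self-pairs included) are scored by exhaustive
ungapped antiparallel alignment; the interaction free energy is the most
stable *single contiguous* complementary run (a duplex seed — summing
disjoint runs would pretend mismatch loops are free). A pair is flagged
below −12 kcal/mol, roughly an 8-bp GC-clamped seed that is still stable
at reaction temperatures; CpG-island-targeted designs are unavoidably
GC-rich, and a stricter cutoff rejects nearly every usable design for
interactions that melt far below annealing temperature. Separately, a
mutual 3'-terminal complement of ≥ 4 bp — the geometry a polymerase can
extend into a primer dimer — is always flagged.

Oligos are screened within their *reaction stage*: cut helpers act during
digestion and are heat-inactivated before amplification, and in the
co-methylation workflow the BP/TFP linear extension and the AP2s/AP3s
exponential phase are separate reactions. Only oligos that share a tube
are screened against each other; in particular AP2s is the exact
complement of the TFP's AP2a tail *by design*, and flagging that pair
would be a category error.

## The designer

FR selection enumerates lengths 15–20 nt, keeps those with 50–70% GC, and
picks the most stable hairpin stem (NN ΔG at the 40-nt reference loop),
ties to the shorter length. Cut helpers search 18–22-nt windows
(preferring 20) on the allowed strand(s) with the CpG inside the final
5 nt of the 3' end, accepting predicted Tm in 65–70 °C; when both strands
qualify, the one with fewer self-structure flags wins, ties to the sense
strand. The blocker is recorded as 6 nt-equivalent (PEG18). Capture
regions target 66 °C, TSP 65 °C and probes +8 °C over primers; these are
soft targets — the closest achievable window is taken — because the
template dictates what exists, while the FR, GC, helper-Tm and blocker
constraints above are hard and designs violating them are rejected.

Artificial primers come from a shipped library of ten 22-mers with
balanced GC, built once with the package's own self- and cross-dimer
screen; at design time a candidate is used only if it shares no 12-mer
(either orientation) with the template.

Oligo geometry along P1 (single-site mode): FR, a 2-nt gap, the probe,
a 2-nt gap, the TSP, a 5-nt gap, then the CR. The expected amplicon is
`|AP| + |FR| + (TSP 5' offset from the FR 3' boundary)`, verified in the
tests by independent recounts. In co-methylation mode the exact placement
of the AP2a tag relative to FRs is not recoverable from the available
descriptions; this package adopts TFP = AP2a–FRs–blocker–AP1a (the AP1a
3' end captures the bridge-extended product) as a documented convention.

## The synthetic-data generator

`synth_template()` draws i.i.d. bases at a target GC of 0.65 — the
composition of the CpG-island promoters these assays actually target —
and plants concrete motif instances with 5-mC marks on one or both
strands (the methyl-required cytosine is placed in CpG context whenever
the motif allows). `fragmentize()` emulates sonicated cfDNA: by default
`round(L/mean_len) − 1` breaks per copy placed uniformly without
replacement (a geometric per-position model is available), mean fragment
length 150 nt. `make_mixture()` builds methylated spike-ins over
unmethylated backgrounds. All generators are seed-deterministic.

What the generator does *not* emulate: real promoter sequence
(CpG clustering, repeats), biased cfDNA fragmentation around
nucleosomes, hemimethylation patterns, polymerase errors, or fluorescence
chemistry. Passing tests therefore demonstrate that the mechanism,
designer and thermodynamics behave correctly on sequences with the right
composition and marks — not that any particular clinical target is
designable.

Design batches (`design_batch()`) draw templates and *reject undesignable
ones*: the designer refuses sites where no oligo window can satisfy the
printed constraints, exactly as a practitioner discards such sites, and
the batch redraws under a deterministic seed sequence until it has `n`
designs. Typical acceptance is ~40–60% at these settings; the rejection
rule is part of the generator's definition, not a tuning knob.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; cut points are inter-base
  indices in `[0, L]`, which keeps every offset rule a plain addition.
* Fully methylated CpGs are two marks (top C, bottom C under the G);
  validation rejects marks on chemically impossible bases, naming the
  position.
* `competition_fractions` uses the conjugate quadratic root when the
  linear coefficient is positive, avoiding catastrophic cancellation for
  strong folds.
* Degenerate cases: zero-copy inputs and copies lost to Poisson sampling
  are censored rows, not errors; cut indices outside a fragment are
  skipped; an empty event list returns the pool unchanged; a 0-copy level
  in a dilution series is excluded from the regression.
* Reported problem sizes: the test suite and the acceptance script use
  50-design batches on 220-nt templates, 20-fixture truth tables per
  mode, 100-template digestion-oracle comparisons, 300–1000-copy
  fragmented pools, and 5 × 3 dilution series; these sizes make every
  property exact or tightly concentrated while keeping a full run in the
  low minutes on one core.

## Known limitations

* Two-state thermodynamics only: no partition function, no mismatch or
  dangling-end parameters, no divalent-cation correction (Tm values are
  monovalent-referenced; the 65–70 °C helper window is interpreted under
  the package's stated default conditions).
* Digestion is all-or-none per site with a single efficiency; no star
  activity, no off-target cutting.
* The stochastic mode Poisson-samples input copies only; per-cycle
  branching noise is not modeled, so replicate scatter at very low copy
  numbers is understated relative to a full branching process.
* The PNA model is binary (perfect match binds, any mismatch does not);
  real PNA discrimination is a free-energy difference.
* MSRE/isoschizomer workflows, bisulfite pipelines, digital-PCR
  partitioning and fluorescence curve shapes are out of scope.
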