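---
title: "Methods: codon optimization and expression diagnostics for CTG-clade yeasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon optimization and expression diagnostics for CTG-clade yeasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonopt)
```

## The problem

Expressing a foreign gene — a fluorescent protein, say — in *Candida
albicans* requires rewriting its coding sequence. Two organism-specific
facts drive this. First, *C. albicans* belongs to the CTG clade: the CUG
codon is decoded predominantly as serine (about 97 of 100 events), not
leucine, so any CTG in a heterologous gene is both a potential
missense position and an ambiguity to be avoided outright. Second, its
synonymous codon preferences differ from those of the yeasts and mammalian
systems most constructs were designed for, and those preferences correlate
with translational efficiency. `codonopt` implements the standard
in-silico toolbox around these facts: usage tables, optimization
strategies, sequence diagnostics, and the statistics used to relate codon
design to measured brightness.

## Codon usage tables and CAI

A usage table holds per-codon counts (from an entire genome, a gene set,
or a file). From the counts we derive, per codon:

* occurrences per 1000 codons (whole-table normalization, stops included);
* the **synonymous fraction** `f`, the codon's share within its synonymous
  family (stops excluded). A zero-count codon has `f = 0`; a family with
  no counts at all falls back to uniform;
* the **relative adaptiveness** `w = f' / max(f')` within the family,
  where `f'` is computed after replacing zero counts with a 0.5
  pseudo-count, the usual CAI convention, so every `w` is strictly
  positive and log-averages are defined.

The **codon adaptation index** of a coding sequence is the geometric mean
of `w` over its codons, excluding stop codons and the single-codon
families (ATG, TGG): their `w` is identically 1 and including them only
dilutes the index. CAI = 1 means every codon is its family's most
frequent.

Keeping `f` unsmoothed while smoothing only `w` is deliberate: sampling
strategies must never emit a codon the reference set does not use
(`f = 0`), while CAI must remain finite for sequences that contain such
codons.

A design choice that matters: **all rarity thresholds in this package
operate on the within-family synonymous fraction, not on per-1000 genome
frequency.** Genome-wide per-1000 values rarely reach 10–15%, so
thresholds in that range are only meaningful per family. The two
thresholds in play are the optimizer's elimination cutoff (default 0.10)
and the diagnostics' rare-codon cutoff (default 0.15).

## Optimization strategies

All strategies guarantee: the variant translates back to the input
protein; no forbidden codon appears; and with a fixed seed and
configuration the output is bit-reproducible. Under the table-12 code,
CTG is forbidden by default for every residue — even as a serine codon it
carries a few-percent leucine mistranslation risk, which is unacceptable
in a heterologous construct — and this can be switched off
(`forbidden_codons = character(0)`).

* **Threshold-random** (IDT-style): codons with `f` below the cutoff are
  eliminated, the surviving fractions renormalized, and one codon drawn
  per residue. A complexity-repair pass then resamples codons
  participating in homopolymers (> 8 nt), exact direct repeats (≥ 12 nt),
  or 50-nt windows with GC outside [0.30, 0.70]. The published tool names
  these behaviours but not its rules; the homopolymer/repeat/GC-window
  heuristics here are explicit stand-ins with the same intent, and every
  resampling is logged. The threshold is applied before repair; repair
  draws from the thresholded set unless that would leave no alternative.
* **Guided-random** (OPTIMIZER-style Monte Carlo): one codon per residue,
  probability proportional to `f`, no threshold. The "entire-genome" and
  "highly-expressed-gene" flavours differ only in the table supplied.
  Sampling is independent across positions — the simplest reading of
  guided random selection; no codon-pair or autocorrelation structure is
  modelled.
* **Bulk maximal-CAI** (ATGme-style): every residue gets its most
  frequent allowed codon; ties break alphabetically. This attains the
  maximum CAI achievable under the allowed-codon set (verified against
  exhaustive enumeration for short proteins in the tests). When no
  forbidden codon excludes a family maximum the result has CAI = 1
  exactly.
* **Scaffold transfer**: for a target protein closely related to a
  well-expressed scaffold (substitutions only, no indels), scaffold
  codons are copied verbatim at identical residues; substituted residues
  get the most frequent allowed codon, with ties broken by fewest
  nucleotide changes from the scaffold codon, then alphabetically.

## Rare-codon runs and folding

Rare-codon runs are maximal stretches of ≥ `min_run_length` consecutive
codons with `f` below the rarity cutoff — a proxy for ribosome slow-down
sites. A run counts once regardless of length and runs never overlap. The
default minimum run length is 2 consecutive codons; 3 is an equally
defensible convention for calling a "stretch", and both are reachable
through `diagnostics_config()` — the package does not resolve that
ambiguity, it exposes it.

The folding score is a **weighted base-pair-maximization dynamic program**
(Nussinov-style recursion, implemented in C++): over all pseudoknot-free
structures whose hairpin loops contain at least 3 unpaired nucleotides, it
maximizes the total pair score (GC = 3, AU = 2, GU = 1) and reports the
negated optimum, so more structure is more negative. Traceback ties are
resolved by pairing the leftmost position with its smallest admissible
partner, making the reported structure deterministic. Lonely pairs are
allowed; there are no dangles or coaxial terms. This is a pseudo-energy
for *ranking* variants by folding propensity — it is not a thermodynamic
ΔG and its values are not comparable to kcal/mol output of
nearest-neighbour models. The engine contract (nucleotide string in,
score + dot-bracket out) lets a thermodynamic engine be swapped in:
`fold_config(engine = "rnafold")` shells out to ViennaRNA's RNAfold when
the binary is available. The built-in engine is verified against an
independent exhaustive enumeration of all pair sets for sequences up to
14 nt. Diagnostics report the score for the full coding region and for
its first 250 nt, the region most implicated in translation-initiation
effects.

## Expression analysis

Replicate mean-fluorescence records are processed as a flow-cytometry
panel would be:

1. each replicate is corrected by subtracting the **mean** wild-type
   autofluorescence of its channel (replicates are not paired across
   strains, so per-replicate pairing would be arbitrary);
2. corrected replicates are averaged per variant, with SEM = sd/√n;
3. each variant is normalized to the brightest variant of its
   fluorescent-protein group (never across groups), so the best variant
   scores 1. Variants dimmer than the wild type keep their negative
   corrected means and are flagged rather than clipped.

Group comparisons use one-way ANOVA on replicate means (n = 3 per group)
followed by Tukey's HSD over all pairs, with the contrasts against the
brightest variant highlighted and starred (**** p < 0.0001, *** p < 0.001,
** p < 0.01, * p < 0.05). Head-to-head comparisons between two proteins
use a two-sided, equal-variance Student's t-test — the default meaning of
the named test.

Parameter–brightness association reports Pearson and Spearman
coefficients. With fewer than six variants per panel the output is marked
**descriptive-only and no p-values are emitted**: at n = 4–5 a correlation
test has essentially no power and reporting one would lend false
precision. Constant parameters are flagged and their coefficients omitted.

## The synthetic-data generator

The generator makes the whole pipeline testable without downloads. What it
emulates, and how:

* **Usage table**: per-family fractions drawn from a symmetric Dirichlet
  with concentration 0.5 — small enough that most families are visibly
  skewed, as real genomes are.
* **Gene set**: residues drawn uniformly; the codons realizing each
  family are allocated by largest-remainder proportional rounding and
  placed randomly among that family's positions. Tabulating the gene set
  therefore recovers the source fractions to within integer rounding
  (about 10⁻⁴ at the default 200 genes × 500 codons = 10⁵ codons) rather
  than multinomial noise, which at that size would be an order of
  magnitude larger. The gene set's *purpose* is recoverability; iid
  sampling would defeat it.
* **Proteins**: uniform random residues with an initial methionine;
  default 239 residues, the length of a GFP-family fluorescent protein.
* **Brightness**: `log10(B) = beta0 + beta1 · mfe_5prime + N(0, sigma)`
  per replicate, plus an additive autofluorescence draw (truncated
  normal) on the raw scale — additive so that the analysis stage's
  subtraction is the exact inverse and correction bias is testable. The
  defaults `beta1 = 0.05` per score unit and `sigma = 0.02` (log10)
  encode a clear but noisy positive dependence of expression on 5'-region
  folding score; `beta0 = 15` places a typical 250-nt-region score
  (about −220 under the default pair weights) near 10⁴ a.u., a realistic
  mean-fluorescence scale; autofluorescence is 100 ± 10 a.u.; three
  biological replicates per strain. The effect is placed on the 5'-region
  score, the region with the clearest mechanistic link to expression.

What the generator does **not** emulate: per-cell FACS event clouds,
optics, amino-acid composition bias, codon-pair effects, or any coupling
between CAI and folding beyond what optimization itself induces. Passing
tests on synthetic data therefore demonstrate the pipeline's internal
correctness and statistical behaviour, not biological validity of any
particular optimization strategy.

## Numerical and scale choices

* Sequences are DNA (T) internally; conversion to RNA (U) happens only at
  the folding boundary.
* A trailing stop codon on an input CDS is preserved verbatim, excluded
  from CAI, profiles and runs, and never resampled by repair.
* Repair runs at most 100 scan/resample iterations, then returns the best
  effort with unresolved violations listed; a forbidden codon whose
  family has no alternative raises an error immediately.
* The exhaustive folding oracle is capped at 14 nt (structure counts grow
  exponentially); DP-vs-oracle equivalence is checked on 200 seeded
  random sequences up to 12 nt.
* Test and example problem sizes (80–239-residue proteins, 10⁵-codon gene
  sets, 100 simulation replicates) were chosen so the full suite runs in
  about a minute on a laptop while keeping every statistical check at a
  scale where its expected behaviour is unambiguous.

## Known limitations

* The built-in folding engine ranks; it does not predict kcal/mol.
  Absolute MFE values from thermodynamic folders are reproducible only
  via the external engine.
* Scaffold transfer supports substitutions only; indels between scaffold
  and target are rejected.
* The repair heuristics treat violations independently; a sequence can
  exist whose constraints are jointly unsatisfiable by synonymous
  changes, in which case the unresolved list says so.
* Only genetic code tables 1 and 12 are built in.
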