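---
title: "Interpreting restriction-protection assays of cytosine-5 MTases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting restriction-protection assays of cytosine-5 MTases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdigest)
```

# The problem

A DNA (cytosine-5) methyltransferase (MTase) expressed in a cell methylates
its own expression plasmid. Because many restriction endonucleases are
blocked by 5-methylcytosine in specific sequence contexts, digesting the
purified plasmid with a panel of methylation-sensitive enzymes turns the
invisible methylation pattern into a visible band pattern: a site that
resists cleavage fuses its two neighbouring fragments into one larger,
diagnostic band. This package formalises that interpretive chain — from a
hypothesised MTase specificity, through per-site blocking decisions, to
predicted fragment sizes — and inverts it: given observed band sizes, which
specificities are consistent? It also covers the two companion computations
such a study needs: simulating an error-prone PCR library subjected to
restriction-based selection, and Michaelis–Menten analysis of methyl
transfer measured by incorporation of tritiated methyl groups.

# The model

## Substrates and coordinates

A `duplex_seq` stores the top strand of a double-stranded DNA molecule with
explicit topology. All coordinates are 1-based top-strand positions, and
bottom-strand features are reported in top-strand coordinates; for circular
molecules position arithmetic is modular. A self-complementary recognition
sequence is one locus with two strand-specific context annotations, because
the assay reasons about the two strands of one site (hemimethylation versus
full methylation).

## MTase specificity

An `mtase_specificity` is the hypothesis object: a set of core dinucleotides
drawn from CG/CA/CC/CT whose 5' cytosine is methylated, two multiplicative
flank-weight maps, and a per-strand efficiency. The 5' flank is the base
before the methylated C; the 3' flank is the base after the *dinucleotide*
(the `NNccNN` reading). This convention matters: it is what lets a CC-specific
enzyme distinguish a site whose CC is "followed by" A from one followed by
G even when both cytosines sit inside a recognition sequence.

The two strands of a site are methylated in independent events, so a
hemimethylated site never gains or loses eligibility on the other strand.
Deterministic mode marks every target whose weight
(`flank5_weight * flank3_weight`) reaches a threshold (default 0.5);
stochastic mode marks each target independently with probability
`efficiency * weight`. All-1 weights recover pure dinucleotide specificity.

The shipped `quadruple_mutant_cc_profile()` encodes the qualitative flank
preference of an evolved CC-specific enzyme — strong preference for A and C
after the CC (weights 1 and 0.6; G and T at 0.05), and a disfavoured A
before it (0.4 versus 1 for G/C/T). These numbers are a configurable
ordering, not measured constants: the underlying activity comparison is
graphical, so the profile is meant to separate "preferred" from "very poor"
substrates under the 0.5 threshold, nothing finer.

## Blocking rules

A `restriction_enzyme` carries a recognition motif, a top-strand cut offset,
and a list of sensitivity rules. Each rule watches named cytosine positions
of the motif and fires in one of two modes: `blocked_if_any_strand`
(hemimethylation suffices) or `blocked_if_both_strands` (both strands of the
palindromic pair must be marked). All nine shipped enzymes have
self-complementary motifs, so watched positions are expanded automatically
to both orientations of the duplex site. Only the documented cytosines are
watched — methylation elsewhere inside a site does not block — because that
is precisely the interpretive model applied to the gels; the table format
accepts additional rules if a user needs them.

Digestion is complete and deterministic: every unblocked site is cut, and
partial bands are modelled exclusively as molecule-to-molecule methylation
heterogeneity in `digest_population()`, never as stochastic enzyme failure.
Fragment lengths come from cut coordinates with circular wraparound, are
origin-independent, and are reported exactly; gel-reading uncertainty lives
in the comparison tolerance of `patterns_consistent()` (default 5% relative,
capped at 20%), not in the digest.

## Inference

`infer_specificities()` tests every candidate in the hypothesis space — the
15 non-empty subsets of {CG, CA, CC, CT} with flat flanks, plus an inactive
baseline — against every observation, and keeps the candidates consistent
with all of them. Band matching is bijective and greedy on size-sorted
lists; an observed "full-length linear" call matches any single-cut
prediction, "uncut" only a zero-cut one. Ranking is by core-set cardinality
then name, mirroring the parsimony argument used when a protected fragment
is compatible with more than one specificity. Flank-weighted profiles are
excluded from the default space to keep the search exact and small; they can
be appended explicitly.

# The synthetic substrates

No plasmid sequence is available for this system, so the generators build
substrates that reproduce the published digest arithmetic exactly.

`make_alw44i_fixture()` plants three GTGCAC sites on a random circular
6421 bp backbone so that complete digestion yields 1935, 3986 and 500 bp,
then scrubs the background of further GTGCAC, GTMKAC and GGWCC matches. The
per-site 3'-flank contexts are the unique solution of the published
protection statements: the site fusing 3986+500 (the 4486 bp band) is A/G
flanked, the 1935|3986 site is C/C, and the 500|1935 site is C/T. In
particular the second flank of the 1935|3986 site must be C: a G there would
let CG methylation protect two sites, an A would give CA methylation extra
fragments, and a T would let CT methylation produce a 5921 bp band — each
contradicting a stated observation. The plasmid's absolute origin is
arbitrary; fragment multisets are origin-independent, so no claim is made
about the original coordinates.

`make_selection_fixture()` builds the Eco47I selection substrate: three
GGWCC sites whose six terminal-cytosine contexts cover CA, CC and CT but
never CG (one site is T/A flanked), plus a single GTMKAC site flanked by A
on both strands. This is the design point of the selection: full Eco47I
digestion kills CG-specific clones and spares CH-specific ones, while the
XmiI site reports CA activity separately. The T/A-flanked site is protected
under CC specificity through the motif-internal CC (GGW**C**C), which
`selection_suitability()` reports as a secondary protection route.

The oligonucleotide panels are 23-mer linear duplexes with the variable
cassette centred on an A/T-only backbone, so the backbone contributes no
cytosine target on either strand. The hemimethylated CG control carries a
single bottom-strand 5mC, leaving the top-strand target C free. What the
generators do *not* emulate: real plasmid backbones (site counts of the
other enzymes on the true plasmids are not reproducible), gel mobility and
band intensity, and host (Dam/Dcm) methylation. Passing tests therefore
demonstrate the correctness of the interpretive logic on substrates with
the published site layout, not re-analysis of the original material.

# The evolution simulator

Error-prone PCR is modelled as a per-clone Poisson substitution count
(default mean 2.5 per gene) with a joint spectrum over the 12 substitution
types. The default spectrum puts 0.4 on A→G and 0.4 on its strand mirror
T→C — together the ~80% A:T→G:C transition bias reported for this kind of
mutagenesis — and 0.02 on each remaining type; the residual mass is a free
configuration choice since only the transition fraction is documented. The
spectrum is joint rather than conditional-per-base because a row-stochastic
(to|from) map with uniform placement cannot concentrate 80% of observed
substitutions on A→G on any base composition. Indels are excluded; codon
deletions are constructed explicitly with `make_deletion_variant()`.

Selection is binary uncut-survival: a clone survives iff the deterministic
self-methylation implied by its phenotype blocks every site of the selection
enzyme. Phenotype maps are user-supplied lookups — no sequence-to-function
prediction is attempted. Transformation efficiency, re-ligation and
multi-round kinetics are out of scope; rounds compose.

# Kinetics

Units are fixed: nM, min, µl, Bq, pmol. `mm_rate()` is the Michaelis–Menten
velocity `v = kcat·E·S/(KM+S)`; `simulate_timecourse()` integrates substrate
depletion through the closed-form implicit solution
`t = (P + KM·ln(S0/(S0−P)))/(kcat·E)` solved by `uniroot()` per time point
(tolerance `1e-12·S0`), with the product ceiling at `S0` because each duplex
substrate carries exactly one methylatable cytosine. Label accounting is
`Bq = pmol(product) × specific activity` with the default 130 Bq/pmol and
30 µl volume of the standard assay, and is exactly invertible. SAM is
assumed saturating and is not modelled.

`fit_mm()` is unweighted nonlinear least squares (Levenberg–Marquardt via
minpack.lm, which is robust on zero-residual noise-free data), initialised
from a double-reciprocal linear fit with a median-S fallback when the
linearisation is degenerate; non-convergence is an error, never silent.
Initial velocities default to the earliest positive time point of a time
course (`initial_rates()`), mirroring an early-aliquot design; no baseline
correction or weighting is applied because none is documented for the
original fits.

# Numerical and design choices

* Deterministic threshold 0.5: separates the preferred (≥0.6) from the very
  poor (≤0.05·1) contexts under the shipped profile with margin on both
  sides.
* Band tolerance default 0.05 (gel-reading accuracy); tests of the exact
  fixture arithmetic use tolerance 0.
* Greedy sorted bijective band matching, ties toward the larger predicted
  fragment, as in manual gel reading.
* Coincident cuts from overlapping sites count once; a single cut on a
  circle yields one full-length linear fragment.
* Watched motif positions that are degenerate (e.g. the M of GTMKAC) are
  evaluated against the concrete base at the site: a watched position that
  is not a C in this concretisation is simply absent from the rule.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so fixtures, libraries and population digests are byte-stable.
* Problem sizes in the test suite — plasmids up to ~6.4 kb, 1000-clone
  libraries, 4000-molecule population digests — were chosen as the smallest
  sizes at which the statistical checks (3 standard errors) are meaningful.

# Known limitations

* Real-enzyme sensitivities beyond the documented rules (e.g. effects of
  marks at unnamed cytosines) are not modelled; the enzyme-table format
  permits adding them.
* Host Dcm methylation (CCWGG) overlaps some sites in vivo but is off by
  default, as the assay interpretation never invokes it.
* The flank-weight profile is an ordering, not a calibration; quantitative
  band-intensity fitting and Bayesian posteriors over specificities are
  explicitly out of scope.
* The mutagenesis model is substitution-only and ignores PCR cycle
  structure and dITP chemistry.
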