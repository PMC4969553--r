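---
title: "Non-B DNA motif discovery and co-localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-B DNA motif discovery and co-localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonbscan)
```

# Scope and model

Repetitive DNA can leave the canonical right-handed B-form duplex. Two of the
best-characterized alternatives are targeted here:

* **H-DNA** (intramolecular triplex) forms at homopurine/homopyrimidine
  *mirror repeats*: half of the repeat dissociates and its purine-rich strand
  lies in the major groove of the remaining duplex, bound by Hoogsteen
  hydrogen bonds. The geometry requires the second arm to be the *reversal*
  of the first on the same strand — no complementation. This is the single
  most common implementation error in this area (reverse-complement logic
  finds inverted repeats, a different structure: cruciforms), so the package
  states it in code, documentation and tests.
* **Z-DNA**, the left-handed duplex, forms at alternating purine–pyrimidine
  tracts, most readily at GC repeats, more weakly at GT/CA repeats. Because
  the Z helix propagates in dinucleotide units (alternating syn/anti
  glycosidic angles), the natural scoring unit is the non-overlapping
  dinucleotide step.

Both searches are pure sequence analyses: no thermodynamics, supercoiling
or protein context is modeled (see *Limitations*).

# H-DNA search

## Rules

A hit consists of two arms of equal length `a` and a spacer of length `g`,
with:

* `a >= min_arm` (default 6 bp) and `min_spacer <= g <= max_spacer`
  (defaults 1 and 12 bp) — longer spacers destabilize the triplex;
* every arm base in one purity class (purine `{A,G}` or pyrimidine `{C,T}`;
  `N` is in neither class and breaks tracts), both arms in the same class;
* mirror symmetry: pairing position `i` of arm 1 with position `a - 1 - i`
  of arm 2, at most `max_mismatches` unequal pairs (default 1), tolerated
  only when the final arm length reaches `mismatch_arm_threshold` (default
  10 bp). A mismatched base must still satisfy the class purity — a
  pyrimidine inside a purine arm is a tract break, not a tolerable mismatch.

Spacer composition is unconstrained by default (`require_pure_spacer =
FALSE`): the third strand does not pair across the spacer, and this reading
also permits the common case of two pure arms separated by a single
opposite-class base. A flag restores the stricter interpretation in which
the whole motif lies in one homopurine/homopyrimidine tract.

## Maximality and suppression

Poly-purine runs are combinatorially full of mirror symmetries, so raw
enumeration is not useful output. Two rules make hits discrete:

1. For each spacer placement `(position, length)` the arms grow outward
   symmetrically and only the *longest admissible* arm is kept. Because the
   mismatch budget opens at the gate length, admissibility is not monotone
   in `a` (an arm of 9 carrying a mismatch is inadmissible while 10 is not);
   the maximum is taken over all admissible lengths.
2. A hit whose interval is wholly contained in another candidate's interval
   with an arm at least as long is suppressed. The rule is evaluated against
   the full candidate set, which makes it order-free and deterministic:
   intervals of equal extent always differ in arm length, so exactly one
   representative survives per covered locus.

Output ordering is (start ascending, arm length descending, spacer length
ascending).

## Implementation and oracle

The production scanner is a small C++ kernel (Rcpp): for each of the
`O(L * max_spacer)` spacer placements it grows the arm until purity or the
mismatch budget breaks, which is geometrically short on realistic sequence
(purity runs decay like 2^-k), giving near-linear behavior in practice and
about a second per megabase. `brute_force_mirror_repeats()` is an
independent R implementation that enumerates every (position, spacer, arm)
triple and evaluates each rule literally; the suite requires exact equality
of the two on hundreds of seeded random sequences. The test suite, not the
scanner, is where the oracle lives — it is quadratic and intended for
sequences of a few kilobases at most.

# Z-DNA search

Alternating tracts are maximal runs where the purine/pyrimidine class flips
at every step; `N` breaks runs. Within a tract, non-overlapping dinucleotide
steps are laid down starting at offset 0 or 1 (*frames*); a flanking
unpaired base contributes nothing. Step weights (defaults): GC/CG 25,
GT/TG/CA/AC 3, AT/TA 0. The complement/reversal identifications are forced
by strand symmetry — a GC step read on the other strand is still a GC step.
A tract is reported when its better frame totals at least `min_score`
(default 75), i.e. three GC steps or twenty-five CA steps; ties go to frame
0. Since all weights are non-negative, the maximal-scoring segment of a
tract in a frame is its whole step span, so the default output is one hit
per qualifying tract, and the hit interval covers exactly the scored steps.

Choices worth making explicit:

* **AT steps score 0.** Alternating A/T is formally purine–pyrimidine but
  is not credited by this weighting; the weight is exposed as a parameter
  because the in-field conventions differ. AT steps still count toward tract
  alternation, so they can bridge two GC runs into one tract.
* **Minimum tract length 6** — the shortest fragment that can reach the
  default threshold; configurable.
* **Frame ties** go to frame 0. One knock-on effect, documented in the
  tests: for an odd-length tract whose two frames tie, the reported step
  span on the reverse complement is the reflection of the *other* frame,
  shifting coordinates by one base. Scores and step counts are unaffected.

`brute_force_zdna()` re-derives tracts by literal pairwise checking and
scores every maximal even-length segment directly; equality with the
scanner is enforced on seeded random sequences.

# Breakpoint co-localization

Breakpoints are single-base events (wider BED records are reduced to their
midpoint with a warning). A breakpoint co-localizes with the motif set when
some motif interval overlaps the half-open window
`[pos - w, pos + w + 1)`; each breakpoint counts once. Distances are
measured to motif *edges*, matching the reading of "within ±N bp" as
proximity to the motif sequence, with distance 0 inside a motif.

The enrichment test repositions breakpoints, not motifs — motif positions
are fixed properties of the sequence, whereas the breakpoint catalog is the
sampled quantity. Under the null each breakpoint is placed uniformly within
its region, independently per permutation; regions default to whole
sequences and can be restricted (e.g. to a gene body) to condition the null.
The empirical p-value uses the add-one rule
`p = (1 + #{null >= observed}) / (1 + B)`, which is never exactly zero and
keeps the test valid at finite `B`. When several windows (e.g. 100 and
200 bp) are analyzed jointly, `enrichment_scan()` applies
Benjamini–Hochberg correction across windows; a single-window run is
reported uncorrected.

Because the statistic is a discrete count, the test is conservative in the
presence of ties; the acceptance suite checks that the realized type-I
error at α = 0.05 stays within [0.03, 0.07] over 500 null datasets (100
breakpoints over 100 kb landscapes carrying 20 planted motifs, 1000
permutations each — sizes chosen to keep the count statistic well spread
while the whole check runs in well under a minute).

# Fluctuation-assay statistics

The reporter design: a structure-forming insert (or B-form control) sits
between a *URA3* reporter and a telomere seed on a yeast artificial
chromosome; structure-induced double-strand breaks cause loss of *URA3*,
selected on 5-FOA. Mutation frequency is FOA-resistant colonies over total
colonies (optionally scaled by a dilution factor for differential plating),
and fold induction is the ratio of mean structure to mean control
frequencies. These are *frequencies*, not rates: no Luria–Delbrück
correction is applied, deliberately, since plated-culture frequencies are
what such screens tabulate. Replicate uncertainty: paired replicates give
the standard error of per-replicate ratios; unpaired groups use the delta
method, `Var(R) ≈ Var(m_s)/m_c² + m_s² Var(m_c)/m_c⁴`; single replicates
yield `NA`. A zero control mean yields an `NA` fold with a warning rather
than an infinite value.

# Synthetic data and what passing tests mean

The generator plants motifs in i.i.d. background at a requested GC content.
Guard-base construction is the load-bearing subtlety:

* mirror repeats are flanked by two opposite-class bases, so the arms
  cannot extend outward, and the first and last *spacer* bases are also
  opposite-class — otherwise a longer-arm/shorter-spacer reading of the
  same interval can be a chance mirror and would out-compete the planted
  geometry under the suppression rule;
* GC/CA repeats are flanked by same-class bases on each side, so the
  alternating tract terminates exactly at the repeat regardless of the
  background.

With these guards the planted geometry is provably maximal, and the suite
requires scanners to recover every plant at exact coordinates across
hundreds of datasets. Extra hits arising by chance in the background are
expected and permitted — only the planted truth is asserted.

The background is i.i.d. by design. Real promoter sequence is not: it has
dinucleotide correlation, CpG islands and repeat families, all of which
raise the background rate of motif hits. Passing calibration and recovery
tests therefore demonstrates correctness of the algorithms and the
statistical validity of the permutation test under the stated null — not
that any particular genomic hit is biologically active, and not that the
uniform null is the right null for a GC-skewed locus (a matched null is out
of scope).

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; conversions happen
  only at file boundaries (BED in, GFF3 out) and are tested as mutual
  inverses.
* Sequences shorter than `2 * min_arm + min_spacer` return empty hit tables
  without error; empty FASTA files give empty outputs and exit 0 in the
  CLI.
* IUPAC ambiguity codes are accepted on input and mapped to `N`; `N`
  matches nothing and terminates all tracts.
* Seeded functions (`generate_*`, `permutation_enrichment`) restore the
  caller's RNG state, so library calls do not perturb user scripts.
* Problem sizes in the test suite: oracle equivalence on 500 sequences of
  100–500 bp per scanner; planted recovery on 200 datasets of 1.5 kb;
  calibration on 500 null datasets at 1000 permutations; a 1 Mb scan is
  required to finish in under a minute. These sizes exercise every rule
  while keeping the default suite fast.

# Limitations

* No thermodynamic stability scoring (H-DNA pH/divalent-cation dependence,
  Z-propensity energy models) and no supercoiling-dependent transition
  prediction; the scanners classify sequence potential only.
* G-quadruplex and inverted-repeat (cruciform) searches are deliberately
  absent — mature external tools cover them.
* The permutation null is uniform-within-region; GC- or replication-timing-
  matched nulls are not provided.
* Assay statistics stop at frequencies and fold inductions; no mutation-rate
  estimation (MSS-MLE) and no inter-strain hypothesis tests, which would
  require raw per-culture counts.
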