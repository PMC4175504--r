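---
title: "Tracking length variation and membership across superfamily database updates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking length variation and membership across superfamily database updates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domdiff)
```

## The problem

Structure classification resources such as SCOP group protein domains into
superfamilies — sets of domains that share a fold despite low sequence
identity — and alignment databases built on top of them distribute one
structure-based multiple sequence alignment per superfamily. Every release of
the upstream classification reshuffles this world: new structures join
superfamilies, old entries are dropped or replaced by better-resolution
structures of the same protein, whole superfamilies split or merge, and the
*length* composition of a superfamily (how much its members' domain lengths
spread around the mean) can change qualitatively. `domdiff` implements that
bookkeeping as a reusable pipeline: length-variation statistics and
classification, version-to-version diffing with a staged rescue cascade for
members that go missing, alignment-quality scoring, and a synthetic-data
generator that produces version pairs with known ground truth so every step
can be validated end to end.

## The length-variation statistic

For a superfamily with member lengths $\ell_1, \dots, \ell_n$ and mean length
$\bar\ell$, each member's extent of length variation is the signed percentage

$$v_i = \frac{\ell_i - \bar\ell}{\bar\ell} \times 100 .$$

`superfamily_profile()` reports the $v_i$, their population standard
deviation (the superfamily is the complete population of its members, so no
sample correction is applied), and $\max_i |v_i|$. Two identities follow
directly from the definition and are enforced by tests: the signed $v_i$ sum
to zero, and rescaling all lengths by a common factor leaves every $v_i$
unchanged. Histograms (`bin_variations()`, `class_distribution()`) use
half-open 5-point bins $[0,5), [5,10), \dots$ with an open-ended terminal bin
$\ge 45\%$, so a value of exactly 5 lands in $[5,10)$; binning by superfamily
defaults to $\max_i |v_i|$ with the mean absolute variation and the SD
selectable, since the choice of per-superfamily summary is genuinely open.

## Two classification schemes

A member is *length-deviant* when $|v_i| > 30$ and *length-rigid* when
$|v_i| < 10$ (cutoffs configurable via `classification_config()`); the band
in between is *length-normal*. The **old scheme** (`classify_old()`) labels a
superfamily deviant (rigid) when at least 75% of members are deviant
(rigid), and normal otherwise.

The **improved scheme** (`classify_improved()`) treats sparsely populated
superfamilies separately, because a 75% majority is a very blunt instrument
for a 4-member superfamily:

* **Dense branch** ($n \ge 10$): the three-way majority rule above.
* **Sparse branch** ($n < 10$): two deviant members already make the
  superfamily deviant (the "more-than-one" rule; the single-member variant is
  reachable with `sparse_deviant_min = 1`); otherwise the deviant and rigid
  member counts are compared and the majority wins.

Three decisions here were genuinely open and are fixed as follows. First,
with "fewer than 10" and "more than 10" both defensible readings of the
sparse threshold, $n = 10$ is treated as dense. Second, the dense-branch
rigid rule mirrors the deviant rule at the same 75% majority; the symmetry is
assumed rather than stated by the scheme's description. Third, equal nonzero
deviant and rigid counts in the sparse branch are a genuine tie: the default
resolves ties to length-normal and sets `tie_broken = TRUE` (a `manual_map`
tie rule accepts an explicit code-to-label map, standing in for
case-by-case manual curation); when both counts are zero every member sits in
the middle band, which is plainly length-normal, so the flag stays unset.

## Diffing two database versions

`map_superfamilies()` partitions superfamily codes into common / absent /
new. `detect_splits_merges()` builds the bipartite member-overlap graph
between the versions (members identified by id) and reports an old
superfamily connected to $\ge 2$ new ones as a split, and the symmetric
pattern as a merge; one shared member suffices for an edge by default, since
no threshold is canonically right and the events are reported with their
shared-member counts for inspection.

Member-level bookkeeping (`assign_member_fates()`) gives every old-version
member the first fate that applies:

1. **retained** — same id present in the new version;
2. **superseded** — the new version of its superfamily holds the same
   protein under a different PDB code: equal length and 100% global sequence
   identity;
3. **outlier** — listed in the new version's outlier set (members that could
   not be structurally aligned with the rest of their superfamily);
4. **rescued_by_search** — best global identity against the new members of
   its superfamily $\ge 40\%$. This is a deterministic stand-in for sequence
   searches (BLAST/HMM-style) against the new release, with the threshold
   chosen to mirror the database's own 40% redundancy cutoff;
5. **rescued_by_identity** — best identity $> 30\%$, standing in for
   forced-alignment percent-identity placement;
6. **unaccounted** — nothing above applies (including a superfamily that
   vanished entirely).

`accounting_cascade()` aggregates the fates into the staged counts used to
audit an update: total, carried over, missing, outlier-filtered, query set,
search hits, still-missing, identity-rescued, unaccounted. The stages
telescope exactly (each stage count is the previous one minus the members the
stage explains). One bookkeeping decision was required: a superseded member
is not "carried over" by id, yet it would be found by any search at 100%
identity — it is therefore counted as a search-stage hit, which keeps the
telescoping identities exact for every input.

## The pairwise aligner and its identity convention

All identity computations use a Needleman–Wunsch global aligner written for
this package (C++ core) with match $+1$, mismatch $-1$, gap $-2$, and a fixed
traceback tie-break (prefer diagonal, then up, then left) so results are
deterministic. Percent identity is $100 \times$ matches / aligned residue
pairs, where only columns holding a residue in *both* sequences count toward
the denominator. The test suite pins the aligner to a brute-force oracle that
enumerates every global alignment for short sequences, including the
tie-break order.

This gap-excluded denominator has a consequence worth knowing: for two
*unrelated* random sequences of similar length it concentrates near 20–25%,
and when one sequence is much shorter than the other (length ratio
$\ge$ ~1.5) the short sequence simply aligns to its best-matching subset of
the long one and the measure saturates around 40–50% — for any sequence
content. Identity thresholds on this scale are therefore only meaningful
between comparably long sequences, which shapes the generator design below.

## Alignment quality

`initial_equivalences()` counts alignment columns with a residue in every
member — the package's operational definition of an equivalenced position
(the upstream alignment tools have their own internal definitions, which are
not reproduced here). `sst_equivalences()` counts the gapless columns whose
members all carry the same secondary-structure state over the coarse 3-state
alphabet {H, E, C}; it can never exceed the initial equivalences.

`kabsch_superpose()` is the standard SVD solution for least-squares rigid
superposition with the determinant correction that excludes reflections.
`consensus_superpose()` fits all members with coordinates to a common
framework: starting from the first member in lexicographic id order (for
determinism), each member is superposed onto the current mean coordinates at
the all-member-gapless columns, the mean is recomputed, and the loop repeats
until the mean moves by less than `tol` (default $10^{-6}$ Å, `max_iter` 50).
The summed squared deviation from the mean is non-increasing across
iterations, which the tests assert. `quality_report()` reports both RMSD
summaries — the mean of pairwise Kabsch RMSDs (each pair superposed on the
columns gapless across that pair) and the consensus RMSD — because which of
the two a given published RMSD corresponds to is often unknowable; having
both costs little.

## The synthetic generator: what it emulates, and what it does not

`generate_superfamily()` forces a classification label with margin: rigid
superfamilies get equal-length members ($v_i = 0$), deviant ones the required
number of members at $\pm 45\%$ (balanced so the signed deviations sum to
zero and the realised mean equals the target), normal ones members in the
$[12, 25]\%$ band in zero-sum layouts. The margins (at least 10 points from
every cutoff) make label recovery by `classify_improved()` exact rather than
probabilistic, which is what a deterministic validation suite needs.

`generate_version_pair()` realises a fate plan: retained members are copied,
superseded members re-emitted under new PDB codes with identical sequences,
outliers moved to the outlier list, search- and identity-rescuable members
replaced by substitution-mutated homologs whose *measured* identity to the
lost member is verified at generation time to fall in a safe band (45–95%
for search rescue, 31.5–38.5% for identity rescue), and unaccounted members
dropped. Splits and merges are realised by reassigning superfamily codes to
retained members.

Sequence content is where the generator deliberately departs from uniform
randomness. Because unrelated uniform 20-letter sequences already measure
~22% identity under the gap-excluded convention — with best-of-$k$ tails
crossing 40% — a planned-unaccounted member could not reliably stay below
the 30% placement cutoff against ten candidates. The generator therefore
draws ordinary members from a uniform 16-letter background and
planned-unaccounted members from the disjoint 4-letter remainder {H, M, W,
Y}: sharing no letters with any candidate pins their best identity at
exactly 0. At most one unaccounted member per superfamily is supported (two
would share the small alphabet and breach the redundancy rule between
themselves). Standalone `generate_superfamily()` keeps the full 20-letter
background. Relatedly, the <40% mutual-identity constraint between members
is enforced at draw time only for pairs of comparable length (ratio
$\le 1.5$); beyond that ratio the saturation described above makes the
constraint unattainable for any content, which also means exact fate-plan
recovery is guaranteed for rigid (equal-length) superfamily plans and fate
properties are tested on those.

`mutate_to_identity()` reaches a target identity by random substitutions with
an adaptive substitution count; for targets $\le 10$ the replacement alphabet
is restricted to the letters rarest in the input, since otherwise spurious
optimal-alignment matches floor the achievable identity near 20%.

Length changes are realised as terminal extensions in the alignment (a
common core padded with trailing gaps), the simplest indel model consistent
with a gapped alignment; coordinates are an idealised helix (rise 1.5 Å,
~100° per residue, radius 2.3 Å) plus isotropic Gaussian noise. None of this
emulates real evolutionary sequence divergence, real protein geometry, or
realistic gap structure — so a passing suite demonstrates that the
*bookkeeping and statistics* are correct, not that the pipeline's thresholds
are well-calibrated for any particular real database.

## Worked fixtures

`cascade_fixture()` builds a deterministic 64-superfamily pair realising a
documented update audit: 809 members of which 333 are carried over, 162
outlier-filtered, 201 recovered by search, 80 by identity placement, and 33
left unaccounted; `accounting_cascade()` recovers every stage count exactly,
and the seed only changes the sequences, never the composition.
`split_fixture()` provides minimal pairs for three documented events: a viral
coat/capsid superfamily (49611) splitting into four (88633, 88645, 88648,
88650), an ovomucoid/PC-1-like inhibitor superfamily (57467) splitting into
two (100895, 100897), and the ETFP adenine-nucleotide-binding superfamily
(52431) merging into the adenine nucleotide α-hydrolase-like superfamily
(52402).

```{r cascade}
fx <- cascade_fixture()
accounting_cascade(fx$v1, fx$v2)
```

Database-scale published outcomes (label counts like 67/416/152 over a full
release, or whole-database distribution shifts) depend on the original
release data, which is not available in machine-readable form; they are
documented context, not reproduction targets of this package.

## Statistics

`welch_t_test()` wraps the standard unequal-variance t-test (two-sided), the
appropriate default when comparing per-superfamily metrics between two
releases whose superfamily sets differ — the samples are unpaired and there
is no reason to assume equal variances. `compare_versions()` runs it on
per-superfamily member counts, mean lengths, and RMSDs where coordinates
exist, alongside membership histograms (bins of five members: 1–5, 6–10, …)
and variation/SD histograms. Tests that cannot run (no coordinates,
degenerate variance) are reported as omitted with the reason rather than
silently dropped. Raw p-values are reported without stars or multiple-testing
correction — with three planned comparisons there is little to correct, and
starring conventions are left to the reader.

## Numerical and degenerate-input choices

* Gap character is `'-'` only; `'.'` is a format error rather than a second
  dialect.
* Coordinates: PDB `ATOM` records keep CA atoms of the first model with
  blank or `'A'` altloc, in file order.
* `kabsch_superpose()` requires $\ge 3$ points; collinear input still returns
  the SVD solution (the rotation about the collinear axis is arbitrary but
  the RMSD is well-defined).
* JSON reports are written with sorted keys and refuse non-finite numbers,
  so outputs are byte-stable across runs and safely round-trip.
* All generator randomness flows from a single integer seed, and the
  caller's RNG state is saved and restored around every seeded operation.

## Problem sizes used in the validation suite

The test suite and the reproduction script regenerate everything from code:
the 809-member cascade fixture (seconds), 100-seed fate-partition and
label-recovery sweeps on small version pairs (a few superfamilies of 4–6
members each), exhaustive alignment-oracle sweeps over short strings, and
5-point superposition toys against a numeric rotation-search oracle. These
sizes were chosen so the whole suite documents the pipeline's properties in
well under ten minutes on a single CPU while still covering every rule
branch; none of the checked properties are size-dependent.

## Known limitations

* The search-rescue rule is an identity-threshold stand-in, not a real
  profile or heuristic search; members recoverable only through remote-
  homology statistics would stay unaccounted here.
* Percent identity is only meaningful between comparably long sequences
  under the gap-excluded convention (see above); callers comparing domains
  of very different lengths should interpret the value as a best-subset
  match fraction.
* Members are tracked across versions by id; a renamed chain is recoverable
  only through the supersession or rescue rules.
* The generator's alignments are terminal-padding constructions; internal
  indel placement, and hence any position-specific conclusions, are out of
  scope.
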