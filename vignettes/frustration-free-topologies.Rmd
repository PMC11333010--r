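---
title: "Frustration-free topologies and lattice designability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frustration-free topologies and lattice designability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frustfree)
```

## The problem

A small number of protein folds — the superfolds — recur across many
non-homologous families, while most folds are confined to a single family
and many theoretically possible folds are never observed at all.  For
alpha/beta proteins there is a second striking regularity: the C-terminal
beta-strand strongly prefers the edge of the beta-sheet while the
N-terminal strand sits in the middle.  `frustfree` implements a
physics-based account of both observations for pure parallel beta-sheet
topologies: folds that can simultaneously satisfy a small set of local
structural rules ("frustration-free" topologies) are exactly the folds that
can be highly designable, and the edge preference is a combinatorial
consequence of frustration-freeness.

The package has three layers: a combinatorial topology classifier, an
occurrence statistic (OFHT) over a hierarchical domain classification, and
an exhaustive two-dimensional lattice HP model with sequence-independent
penalty motifs.

## Topologies and their classification

A pure parallel sheet topology of $n$ strands is the left-to-right order of
the sequentially numbered strands: an occupant permutation, with the
position of strand $k$ written $p(k)$.  A topology and its left-right
mirror are the same fold, so there are $n!/2$ classes; the canonical
representative is the lexicographically smaller of the occupant vector and
its reversal.  For the study range $n = 3\dots6$ this gives
$3 + 12 + 60 + 360 = 435$ classes.

Every consecutive strand pair is joined by a crossover connection carrying
an alpha-helix.  Assuming the (near-universal) right-handedness of
crossover connections, the face of the sheet a connection passes over is
fixed by its crossing direction; the package assigns rightward connections
($p(k{+}1) > p(k)$) to the front face.  A global face flip changes nothing
downstream, so the convention is purely a naming choice.

**Clash rule.**  A connection runs from the top of strand $k$ down to the
bottom of strand $k{+}1$, so on its face it is a monotone curve from
$(p(k), \text{top})$ to $(p(k{+}1), \text{bottom})$.  Two connections on
the same face clash when those curves must cross, i.e. when their order
along the top edge differs from their order along the bottom edge.  Nested
connections and connections sharing a strand never clash.  This was a
genuinely open design point: an alternative reading — same-face position
*spans* that strictly interleave — is close but not equivalent.  We chose
the monotone-curve rule because it is the literal geometry of a crossover
connection and because it is the variant consistent with the full set of
published census counts (167 clash-free topologies out of 435, terminal
edge probabilities of 37.1%, and 23 reverse-asymmetric pairs; the
interleaving variant gives 162 and 26).  The test suite checks the rule
against an independent segment-intersection oracle.

**Frustration.**  Connection $k$ defines an alpha-beta unit (helix $k$,
strand $k{+}1$).  Two units whose strands occupy adjacent sheet positions
(a hydrogen-bonded parallel pair) while their helices sit on opposite faces
form a frustrated alpha-beta-unit pairing (FαβP): no arrangement of
register shifts and side-chain orientations can satisfy the
right-handedness rule, the alpha-beta orientation rule and the N-terminal
register-shift rule at once.  $N_{F\alpha\beta P}$ counts such unit pairs.
A jump is a sequence-adjacent strand pair that is not sheet-adjacent;
$N_j$ counts jumps.  A topology is *frustration-free* when
$N_{F\alpha\beta P} = 0$ and $N_j \le 1$.  Chain reversal relabels strand
$k$ as $n{+}1{-}k$; it preserves clash-freeness and $N_j$ but not
$N_{F\alpha\beta P}$ — that asymmetry is the heart of the analysis, since
it is the only classifier feature that can distinguish a fold from its
reverse.

Of the 167 clash-free topologies, 14 are frustration-free, and the six
superfolds of the domain-classification analysis are among them.  The
reverse-asymmetric pair count (pairs $\{T, \mathrm{rev}(T)\}$ with exactly
one frustration-free member) is 23 over the clash-free set; over all 435
permutations it would be 71, so the clash-free set is the universe in
which that census is meaningful — the package defaults to it and exposes
the other choice as an option.

## OFHT

The Occurrence Frequency of Homologous-group in a Topology aggregates a
hierarchical classification (homology groups $\supset$ family groups
$\supset$ domains):

$$\mathrm{OR}(T, i) = \frac{1}{N_{\mathrm{fam}}(i)}
  \sum_{j} \frac{N_{\mathrm{dom}}(T, i, j)}{N_{\mathrm{dom}}(i, j)},
\qquad
\mathrm{OFHT}(T) = \sum_i \mathrm{OR}(T, i).$$

Domains without a pure parallel sheet keep their place in the denominators
but contribute to no numerator, so $\sum_T \mathrm{OFHT}(T)$ equals the
number of homology groups exactly when every domain is labelled — a
property the tests assert on complete synthetic tables.  Topologies with
OFHT $\ge 3$ are superfolds (adopted by at least three independent
homology groups), those with $0 < \mathrm{OFHT} < 3$ normal folds, the
rest unobserved.

Real classification ingestion (ECOD, STRIDE, PISCES) is out of scope; the
package consumes a four-column TSV and derives topology labels from
abstract per-domain sheet records by the four extraction criteria
(all-parallel adjacent pairings, open sheet, single sheet, inter-strand
loops under 100 residues).  Criterion (iii) is read as "all of the
domain's strands belong to one sheet", which the record schema encodes
directly as `sheet_count == 1`; records for domains with several
qualifying sheets are expected to be split upstream, one record per sheet.

## The lattice model

Conformations are self-avoiding walks on the square lattice, counted up to
the 8 lattice symmetries (canonical form: first step $+x$, first turn
left), giving 802,075 conformations at the study length $L = 16$.  That
length is retained from the original model because a 4x4 compact walk
buries 4 of 16 residues — the surface-to-interior ratio of a small
globular protein.  Sequences use the H/P alphabet and the energy is

$$E(\Gamma) = -\epsilon_{HH}\, n_{HH}(\Gamma)
            + \epsilon_{\mathrm{penalty}}\, n_{\mathrm{penalty}}(\Gamma),$$

with defaults $\epsilon_{HH} = 1.0$, $\epsilon_{\mathrm{penalty}} = 2.0$
and a robustness sweep over $\{0.1, 0.5, 1.0, 3.0, 4.0\}$.

**Motif templates.**  The model's penalty motifs are defined pictorially in
the source material, so the package fixes them from their required
properties rather than from a drawing.  Working in turn-string notation
(S/L/R at each interior residue; matching a template means matching its
turn string up to a global L/R swap, which is exactly matching all 8
point-group images with the chain direction respected), the frustrated
local structure (FLS) is the 4-residue motif `SL` — a straight step
followed by a bend — and the three penalty motifs are its three
self-avoiding one-residue C-terminal extensions `SLS`, `SLL`, `SLR`.
`verify_fls_frustration()` checks the defining properties directly:

* every self-avoiding one-residue C-terminal extension of the FLS contains
  a penalty motif (the extensions *are* the penalty motifs);
* the FLS itself contains none, so an FLS flush with the C-terminal chain
  end costs nothing;
* the reverse FLS (`LS` read backwards) admits a penalty-free extension on
  both ends simultaneously.

This makes the FLS the lattice analogue of an FαβP: frustrated in the
forward chain direction, unfrustrated in reverse.  Because each
non-terminal FLS window extends to exactly one penalty window,
$N_\mathrm{FLS}$ (which, for the same reason, counts FLS occurrences *not*
flush with the C-terminal end) coincides with $n_{\mathrm{penalty}}$; this
identity is what makes the frustration bookkeeping of the model exact.
The choice is not merely the simplest set passing the verification: it is
the unique small template set that also reproduces every published count
of the exhaustive scan (below), which a transcription from the drawings
would have had to satisfy anyway.

**Designability scan.**  For each of the $2^{16}$ sequences the minimum of
$E$ over all 802,075 conformations is found and a sequence is
*protein-like* when exactly one conformation attains it; the designability
$N_s$ of a structure is the number of sequences for which it is that
unique ground state.  Conformations are grouped by contact set; within a
group only the smallest penalty count can minimise the energy (penalties
are sequence-independent), so each group carries its minimal-penalty
multiplicity and degenerate minima are detected exactly.  Energies are
compared in integer arithmetic (parameters scaled by 10 or 100), so ties
are exact, never floating-point accidents.  With
$\epsilon_{\mathrm{penalty}} = 0$ the grouping degenerates and the model
reduces to the original HP model, which the tests assert.  A dense
per-conformation scan written independently in R serves as the oracle at
$L = 10$ and smaller.

At the study scale the scan finds 10,139 protein-like sequences; the most
designable structure has $N_s = 1614$ while its chain reversal — same
contact count, but FLS-containing — has $N_s = 3$.  All 17 highly
designable structures ($N_s \ge 100$) lie in the region
$N_c \ge 7,\ N_{\mathrm{FLS}} = 0$, which holds only 48 of the 802,075
structures.  Overlapping motif occurrences each count toward
$n_{\mathrm{penalty}}$ (no exclusion rule is stated for the model, and the
templates overlap freely in compact walks).

In the penalty sweep, FLS-free members of reversal pairs never lose to
their frustrated counterparts at any swept $\epsilon_{\mathrm{penalty}}$
(26 strict wins, 0 losses at the default parameters); the vast majority of
the 2,029 asymmetric pairs tie at $N_s = 0$ because both members are
poorly designable, so the tested property is "at least as designable in a
strict majority of pairs, strictly more designable whenever the pair is
unequal".  At $\epsilon_{\mathrm{penalty}} = 4$ no structure with a
penalty is any sequence's unique ground state: overly strict rules
eliminate frustrated native states entirely.

## Synthetic data

The generators provide seeded inputs with the statistical shape the
analysis assumes, not imitations of real databases.
`generate_ecod_like_table()` builds an H-group/F-group/domain hierarchy in
which each homology group draws an ancestral topology from a heavy-tailed
stick-breaking distribution (break fraction `skew` over a shuffled
universe), families inherit it, and labelled domains repeat their family
topology with probability `within_f_coherence` — the within-family
correlation that common ancestry produces.  `frustration_bias`
down-weights frustrated topologies multiplicatively and
`unlabeled_fraction` removes labels, mimicking domains without a pure
parallel sheet.  Defaults (40 H-groups, up to 8 families of up to 25
domains, skew 0.5, 30% unlabeled, bias 0.15) produce tables with a
realistic top-heavy OFHT spectrum; the generator targets qualitative
shape, not a fit to any real histogram.  What passing tests on synthetic
tables show is that the OFHT algebra and the category bookkeeping are
correct — not that real ECOD statistics are reproduced, which is exactly
why all database-dependent percentages are out of scope.

Each generator runs on a private RNG stream restored on exit, so adding a
generator (or calling one) never perturbs other seeded results.

## Numerical choices and limitations

* All censuses and scans are exhaustive and exact; nothing is sampled, so
  determinism is structural rather than seeded (seeds matter only for the
  synthetic generators).
* Enumeration guards: topology enumeration refuses $n > 9$ and walk
  enumeration $L > 18$ by default (factorial and ~$2.64^L$ growth); the
  sequence scan requires $L \le 16$ ($2^L$ sequences).
* Test problem sizes: oracle comparisons run at $L = 7$–$10$ (dense scan,
  DFS enumeration) and $n \le 5$ (segment-geometry clash oracle); the full
  $L = 16$ scan and the five-point penalty sweep run in the acceptance
  tests, each scan taking a few seconds thanks to the bound-pruned grouped
  scan.
* Mixed and antiparallel sheets, barrels, multi-sheet topologies,
  handedness measured from 3D coordinates, and residue-level register
  shifts are out of scope; the classifier speaks only about pure parallel
  open sheets, and the lattice model only about 2D H/P chains.
* The model's grid cell $(N_{F\alpha\beta P}=1, N_j=1)$ holds 10
  clash-free topologies under this classifier; we note that one published
  fraction implies 16 there, which is inconsistent with the remaining
  published counts that this implementation reproduces exactly.
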