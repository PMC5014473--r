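---
title: "Detecting and characterising recombination with recscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising recombination with recscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recscan)
```

## The problem

Recombination between related viral (or bacterial) genomes produces mosaic
sequences whose different segments have different evolutionary histories.
Left unaccounted for, such mosaics distort phylogenies, molecular clocks and
selection analyses; studied in their own right, the positions and pairings of
recombination breakpoints reveal mechanistic and selective constraints on
sequence exchange. `recscan` detects individual recombination events in a
plain nucleotide alignment **without reference sequences**: every triplet of
sequences is tested under the hypothesis that one member is a recombinant and
the other two represent its parents.

## The triplet scan

For a triplet, the package strips every column gapped or ambiguous in any of
the three rows and classifies the rest. Two site sets matter:

* **variable sites** — columns with at least two distinct residues among the
  three rows;
* **informative sites** of a candidate recombinant — columns where the two
  putative parents differ and the candidate matches exactly one of them,
  recorded as a symbol `A` (matches the first parent) or `B` (the second).

Six signal statistics are implemented:

* **rdp** — sliding-window pairwise identities. A window is flagged when the
  locally most-similar pair differs from the overall most-similar pair; the
  maximal run of consistently flagged windows is the candidate region, and
  its p-value is the exact binomial tail of the winning pair's identity
  excess over its alignment-wide identity, Bonferroni-multiplied by the
  number of windows. We deliberately use a *top-rank inversion* flag: the
  pair not involving the recombinant is unchanged by an event, so a rule
  keyed to the overall most-distant pair cannot fire on a standard implant.
* **maxchi** — over the variable sites, a `2w`-site frame slides along one
  pair's match/mismatch vector; each frame position is scored by the 2x2
  chi-square of (match, mismatch) x (left half, right half), **without**
  continuity correction (the uncorrected statistic is what the exhaustive
  oracle reproduces; a worked example: twenty matches followed by twenty
  mismatches with `w = 20` gives chi-square 40 at the frame centre). The peak
  (leftmost on ties) is tested by permuting the site labels.
* **chimaera** — identical machinery applied to the A/B informative-site
  vector of a candidate recombinant.
* **threeseq-style walk** — the informative vector is read as a random walk
  (+1 at `A`, -1 at `B`); the statistic is the maximum descent, the interval
  achieving it is the region, and the null is a permutation of the vector.
  Because a descent is orientation-specific, the scan tries both parent
  orderings; the low-level `max_descent()` primitive is deliberately
  *not* symmetrized so that it matches the walk arithmetic exactly.
* **siscan-style z-scores** — per window, the three pairwise-match counts are
  compared with their distribution under independent within-column
  permutation of the three residues. A window's null depends only on its
  column-pattern composition (`xxx` columns always match in all pairs, `xxy`
  columns assign their single matching pair uniformly), which the
  implementation exploits by drawing multinomial counts rather than
  permuting characters.
* **bootscan** — per window, bootstrap replicates of the Jukes-Cantor
  distance matrix of the triplet plus an outgroup vote for the 4-taxon
  topology by the four-point condition; a parent-support switch flanked by
  confident windows on both sides is a signal, and the follow-up p-value is
  the binomial identity tail over the informative sites of the switch
  region (keeping all methods' p-values on a comparable footing).

### Selection and multiple testing

Within a triplet, maxchi/chimaera spend permutations only on the candidate
vector with the largest peak statistic and multiply the resulting p by the
number of vectors considered; the walk statistic is not comparable across
candidates (a near-constant vector has a huge mirrored descent), so each
candidate is permuted — cheaply, with sequential early stopping — and the
best p is Bonferroni-multiplied by the number tried. Permutation p-values
use the `(k+1)/(N+1)` estimator and a sequential sampler that stops once 12
exceedances have accumulated; p-values below any interesting threshold are
always computed from the full permutation budget. Across triplets the engine
multiplies each raw p by the number of triplets examined (Bonferroni);
window- and candidate-level corrections already live inside the methods, so
the two levels compose without double counting. On recombination-free
simulations every method's per-triplet raw p is super-uniform (empirical CDF
at 0.05 below 0.08 over 600 triplets — checked in the test suite).

### Recombinant identification

A triplet signal implicates an unordered (recombinant, donor) pair; which
member is the recombinant is decided by an affinity-flip score: for each
candidate, the signed parental affinity (+1 toward the first parent, -1
toward the second) is averaged over informative sites inside and outside the
region, and the candidate with the most negative product flips hardest and
is called recombinant. Near-ties (within 0.05) are labelled
"ambiguous - possible recombinant misidentification". A triplet whose third
member sits in the donor's clade genuinely cannot resolve the mirror
attribution; the consolidation layer resolves it by voting across triplets
(see below).

## Breakpoint placement

Breakpoints live at boundaries *between informative sites* — the data cannot
localize them more finely — and are reported at the midpoint (rounded down)
of the two flanking informative columns. Two devices are used:

* a **two-state HMM** over the informative vector (state = tracked parent,
  emission error = probability a site contradicts its state, switch
  probability per step), decoded by Viterbi. The emission error is fitted in
  two passes: Viterbi at 0.05, then the add-one estimate `(d+1)/(n+2)` from
  the segmentation, then one refit. Full EM gives no measurable improvement
  at these data sizes.
* a **single-switch posterior** for each breakpoint: every boundary `k` is
  scored by the product of emissions left (state A) and right (state B) of
  it, the better parent orientation is kept, and the normalized scores form
  a posterior under a uniform prior. The 95% HPD interval is the smallest
  contiguous boundary set containing the mode with at least 0.95 mass.
  An event's begin posterior is fitted on the left flank plus region, the
  end posterior on the region plus right flank; a region edge touching the
  view boundary pins that breakpoint with a degenerate interval.

Over 200 simulated single-junction triplets (1 kb, parents at JC ~0.2) the
95% HPD contains the boundary nearest the true junction in ~94% of
replicates (recomputed by `scripts/acceptance.R`).

## Event consolidation and iterative disassembly

Retained candidates are greedily clustered: a candidate joins an event when
its region overlaps the event's seed region by at least half **of the
smaller region** (robust to one method's inflated region estimate) and its
implicated pair or donor cluster is compatible (donor compatibility =
single-linkage JC clusters at 0.05). The event's recombinant set is chosen
by vote: sequences implicated by at least half as many candidates as the
top-voted one, excluding any sequence that an accepted recombinant's
candidates name as the donor (this resolves the mirror attribution). The
best surviving candidate supplies the triplet on which breakpoints and
parents are reported.

The engine then loops: scan, consolidate, accept the best event, split each
of its recombinant rows into a region-only row and a complement row (gaps
are placed, columns never deleted, so coordinates stay stable), and rescan;
it stops when a scan is empty or after `max_iterations` (default 100). Like
any greedy exploratory strategy of this kind, the loop can attribute signals
shared by several sequences to a single ancestral event and will under-count
in that situation; this bias is documented, not corrected.

## Pattern statistics

* `hotspot_test()` — sliding-window breakpoint counts against a null that
  re-places each breakpoint uniformly (or over a detectability mask when
  provided). Hot/cold calls use a *global* envelope (quantiles of the
  across-window maximum/minimum per permutation), so the family-wise false
  call rate under the null stays at or below the nominal 5%; per-window
  envelopes are reported for plotting.
* `breakpoint_pair_matrix()` — 2-D histogram of (begin, end) pairs; the null
  permutes begins and ends independently with `begin < end` enforced by
  rejection; cells above the cell-wise 97.5% permutation percentile are
  flagged as hotspot pairs.
* `region_count_matrix()` — for a coarse grid (default 100 points), counts
  per site pair the sequences in which both sites derive from the same
  parental fragment; the null re-places each event's ordered (begin, end)
  pair uniformly, and the lower triangle reports each pair's permutation CDF
  position. The uniform re-placement null is a stated, testable choice for
  what "random recombination" means in this display.
* `feature_association_test()` — mean distance from breakpoints to the
  nearest feature boundary, with association and avoidance tails reported
  separately.

The detectability-mask hook exists because breakpoints are only detectable
where parents differ; computing a full detectability correction from the
alignment is deferred and documented as a limitation.

## Phylogenetic compatibility

`compatibility_matrix()` builds an NJ tree (JC distances) per window and
reports Robinson-Foulds distances (lower triangle) against an SH-like
support (upper triangle): per-site JC log-likelihoods of both trees on a
window's data — fixed topologies, NJ branch lengths with one coarse global
rescaling pass — are RELL-resampled, and the support of tree `j` for window
`i` is the fraction of resamples in which the centered log-likelihood
difference does not fall below the observed one. This is deliberately
labelled *SH-like*: it is a RELL approximation on NJ topologies, not the
full test, and the multiscale-bootstrap "approximately unbiased" variant is
out of scope. Windows with fewer than four pairwise-distinct sequences yield
missing entries.

## The simulator and what passing tests mean

`simulate_tree_alignment()` evolves sites independently along a tree under
Jukes-Cantor (via `phangorn::simSeq`), and `implant_recombination()` copies
the donor's *current* row into the acceptor over a region, so nested events
are expressible and every event is truth-labelled. The standard study
conditions used throughout the tests and the acceptance script are:

* a triplet scenario `((R:0.02,P1:0.02):0.08,D:0.10)` — recombinant `R`, a
  close major-parent representative `P1`, donor `D` at JC ~0.2 from `P1` —
  with a 400 nt event in a 1 kb genome;
* a two-clade six-taxon tree (within-clade JC ~0.08, across ~0.2) with three
  disjoint 500 nt events donated across clades, for event counting;
* random nonclock 10-taxon trees rescaled to mean pairwise JC 0.2 for the
  2 kb recombination-free (type-I) runs.

These sizes keep the whole acceptance run in the tens of minutes on one
core. The simulator draws i.i.d. sites without rate variation, indels,
or substitution-model misspecification; real alignments add misalignment,
selection and rate heterogeneity, so passing these tests demonstrates
correctness of the machinery under its own model, not field accuracy.

## Defaults and numerical choices

| parameter | default | rationale |
|---|---|---|
| rdp window / step | 30 / 1 columns | resolves ~100 nt regions at viral divergences |
| maxchi / chimaera frame half-width | 35 variable sites | classic choice; stable chi-square counts |
| maxchi / chimaera permutations | 2000 | p floor 1/2001 deep enough for triplet-level Bonferroni at moderate n |
| walk permutations | 1000 | the statistic needs fewer to stabilize |
| siscan window / step / draws / z | 100 / 20 / 500 / 3 | match-count z-scores need ~100-column windows |
| bootscan window / step / replicates / support | 200 / 20 / 100 / 0.7 | 4-taxon trees need ~200 columns for stable votes |
| alpha | 0.05 | conventional |
| overlap fraction | 0.5 (of the smaller region) | merges one event's differing regional estimates |
| parent cluster threshold | JC 0.05 | within-lineage donors are interchangeable |
| tie margin (identification) | 0.05 | below it, mirror attributions are honest ties |
| max iterations | 100 | far beyond any realistic event count |

Ties in peak locations break leftmost everywhere (frames, descents, HPD
windows), which makes every scan reproducible bit-for-bit from the config
seed; all permutation machinery runs on R's RNG so `set.seed()` governs the
C++ loops too. `siscan` and `bootscan` are implemented, tested and
config-enabled but not in the default method set: on the simulated
conditions they add runtime without adding detections beyond the four
default methods, and bootscan additionally requires a fourth sequence.

## Known limitations

* Bonferroni across triplets is conservative when many triplets share
  sequences; power at large n leans on the rdp binomial statistic, whose
  p-values can be arbitrarily small, while permutation-based methods are
  floored at `(number of vectors)/(N+1)` times the triplet count.
* The greedy consolidation inherits the ancestral-event under-counting bias
  discussed above, and mirror attribution at exactly three sequences is
  fundamentally unresolvable; the per-event warnings flag these cases.
* Breakpoint posteriors condition on a single switch per flank and on the
  triplet's informative sites; model averaging over triplets is not
  attempted.
* Genomes are treated as linear; windows never wrap.
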