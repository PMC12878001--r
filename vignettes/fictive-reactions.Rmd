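---
title: "Template-based fictive reactions: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based fictive reactions: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnforge)
```

## The problem and the model

Public reaction corpora are template-imbalanced: sorted by the number of
example reactions per retrosynthesis template, they follow a steep
power-law-like curve. A retrosynthesis model trained on such data
performs well on the frequent transformations and poorly on the rest,
which is visible as a large gap between per-reaction round-trip accuracy
(RTA) and its unweighted per-template average (TA-RTA).

`rxnforge` flattens that distribution by *generating* reactions rather
than collecting them. The generative loop is:

* extract retro templates from the atom-mapped corpus (radius 0 and 1),
* apply each template to a pool of known molecules as products `P`,
  yielding candidate starting materials `SM`,
* predict reagents `R` for the `SM -> P` conversion,
* tag the atoms of `SM` whose environment the template changes with a
  `!` token (`SM*`),
* ask a forward model for `P` given `SM* + R`, and keep the candidate
  only if the predicted product matches and the model's confidence score
  exceeds the gate.

The accepted records are *fictive reactions*: plausible, never-observed
reactions that inherit their credibility from the forward model's
confidence, not from experimental provenance. Capping the number of
accepted reactions per template yields a template-equilibrated corpus.

### Changed-atom criterion

An atom is changed iff, comparing its reactant-side and product-side
occurrence by atom-map number, any of these differ: the multiset of
(neighbor map number, bond order) pairs, the formal charge, or the total
hydrogen count. Atoms present on only one side are changed on that side.
This rule is explicit and testable, and reproduces textbook reaction
centers (for an esterification, the carbonyl carbon, the leaving
hydroxyl and the alcohol oxygen). It requires the starting materials to
be fully atom-mapped; a species with unmapped atoms adjacent to a change
cannot be attributed and extraction refuses it rather than guessing.

### Template encoding

Radius-0 patterns constrain changed atoms by element, aromaticity,
formal charge and hydrogen count. Radius-1 patterns add the first-shell
neighbors, constrained by element, aromaticity, charge and *degree*
(heavy-atom neighbor count) but not hydrogen count. Hydrogen count on
the core pins down the transformation's bookkeeping (what leaves, what
bonds form); degree on the shell is the generality/exclusivity knob that
the hierarchical correction step exploits. Matching is induced subgraph
matching: pattern bonds must map to equal-order molecule bonds and
matched atoms must carry no extra mutual bonds, so a template never
rewrites bonds it does not describe.

Two structural rules in retro application are worth stating because they
define what counts as a candidate:

* one starting-material species per reactant pattern — an application
  whose edit fuses two reactant patterns into a single fragment is an
  intramolecular variant of a bimolecular template and is dropped;
* every outcome must pass a valence screen (element- and charge-aware
  allowed-valence table); unsanitizable outcomes are dropped and
  counted, not raised.

### Template correction

Templates are deduplicated by a canonical, renumbering-invariant hash of
their serialized pattern. The correction step then merges r1 templates
sharing a parent r0 hash iff they are *behaviorally* equivalent: each
one's retro application regenerates the recorded starting materials for
every example reaction of the other. The merged class is represented by
the member with the fewest specified atom properties (ties broken by the
lexicographically smallest pattern text). Behavioral equivalence was
chosen over pattern-graph isomorphism because it is the property the
pipeline actually relies on, and it is decidable with the machinery the
package already has. Only mutual equivalences merge; one-directional
subsumption (A covers B's examples but not vice versa) passes through
untouched.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cap_per_template` | 5000 | validated reactions collected per template before the loop stops |
| `confidence_threshold` | 0.95 | forward-validation gate; acceptance requires CS **strictly** greater |
| `n_pool_subsets` | 1000 | shards of the product pool, visited in seeded random order |
| `max_reagent_candidates` | 1 | top reagent predictions considered per SM-set |
| equilibration `cap` | 100 | per-template maximum in the training subset |
| split `ratios` | 80:10:10 | template-grouped train/validation/test fractions |

The strict `>` at the threshold makes the boundary case (CS exactly
0.95) a rejection; with a discrete oracle this is observable and tested.
The pool sharding exists for resumability and sampling order, not
parallelism: membership of each shard is a seeded random choice, while
each shard preserves pool order internally, so within-shard processing
is deterministic. Confidence for external sequence models is
`exp(sum(token log-probabilities))` — the product of top-beam token
probabilities — isolated behind one adapter function so a
length-normalized variant can be swapped in.

All randomness flows from one seed through named sub-streams (shard,
per-template subset order, equilibration, split, oracle noise), so any
stage can be re-run independently with identical results, and a
checkpointed campaign resumes to a byte-identical dataset. Checkpoint
granularity is one template, matching the outer loop.

## The toy world: what it emulates, what it does not

The fixture generator builds a closed chemistry from six hand-coded
template families — esterification, amide coupling, Williamson ether
synthesis, aryl–aryl coupling (2 product tags each), epoxide aminolysis
(3 tags) and alkene dihydroxylation (4 tags) — over a small substituent
library. The two extra families exist so tag-count stratification has
buckets at 2, 3 and 4 tags. Reagents are fixed per family (mirroring a
reagent predictor's tendency to return the most probable reagents).
Ground truth — template identity, changed-atom sets, the SM/R partition
— is recorded at construction because the product is built by forward
template application that preserves the atom maps.

The toy world reproduces the *mechanics* of the real setting: mapped
reactions, leaving groups, aromatic systems, multi-site products
(diesters give two disconnections), reagents that must be classed as R,
and r0 templates that overgeneralize (the ether template disconnects
esters into acid + alkyl bromide — a valid alkylation reading). It does
**not** model: stereochemistry, tautomerism, protecting-group logic,
mapping errors, or a forward model with chemical judgment — the oracle
validator applies the generating template, so its forward-consistency on
toy data is exactly 1 and acceptance collapses to the confidence gate.
Green tests therefore certify the pipeline's bookkeeping and gating
logic, not chemical accuracy of any trained model.

## Numerical and serialization choices

* **Canonicalization** is iterative neighborhood refinement over
  (element, aromaticity, charge, H count, isotope, stereo label), with
  remaining ties resolved by individualizing each member of the first
  tied cell and keeping the lexicographically smallest emission. The
  candidate search is capped at 2000 leaves; molecules of the sizes
  handled here resolve in a handful. Atom maps are excluded from the
  ranking invariants (so mapped and plain copies share a skeleton order)
  but included in emitted strings.
* **Stereochemistry**: atom stereocenter tags (`@`, `@@`) are carried
  through parsing, canonical invariants and output as opaque labels, so
  records differing only in stereo stay distinct (the conservative
  default; `stereo = FALSE` on the key functions collapses them). The
  package does not re-derive parity under renumbering, and double-bond
  geometry marks (`/`, `\`) are normalized away on input. The toy world
  is achiral, so every fixture path is exact.
* **Tagging order**: tags are placed in the canonical-order token
  stream, making tagged strings unique; a `!` goes immediately after its
  atom token, before ring-closure digits (flag-reversible).
* **Percentages** are rounded half-away-from-zero to one decimal, the
  convention that reproduces printed corpus statistics deterministically.
* **Ties in the equilibration and split samplers** are resolved by
  seeded uniform sampling (equilibration) and a seeded shuffle before
  the greedy descending-size split; the greedy rule assigns each
  template to the currently most-underfilled split, which bounds the
  realized-ratio deviation by the largest template's weight.
* **Degenerate inputs**: empty change sets are a no-reaction error at
  extraction; empty prediction lists are unsuccessful records (not
  errors); a single-template tag bucket reports a standard deviation of
  0; a zero denominator in percentage reporting is an error.
* **Overlap counting** uses distinct keys (not raw rows) so "shared" is
  well-defined under duplicates; a raw-row flag exists. "Shared under
  different conditions" is the SM→P-shared set minus the SM→P
  projections of the SM+R→P-shared set.
* **TA-RTA** is the unweighted mean of per-template RTAs — the only
  reading independent of the number of examples per template; duplicating
  a template's records changes RTA but not TA-RTA, and the test suite
  uses that as a discriminating property.

## Problem sizes

The test suite and the acceptance script run the toy world at sizes
chosen to exercise every code path while staying desk-sized: pools of
36–120 molecules, 12–34 mapped reactions per family (204 reactions for
the dual-radius round-trip check), campaigns of a few hundred
candidates, and metric suites over a few thousand randomized records.
Round-trip, gate, cap, overlap and tagging guarantees are exact at these
sizes; nothing about them is asymptotic.

## Known limitations

* Chemistry support covers the organic subset plus bracket atoms with
  charge, isotope and map fields; aromaticity is taken from the input
  (lowercase/aromatic bonds) rather than re-perceived, so Kekulé and
  aromatic writings of the same ring are distinct records.
* Species-level reactant patterns are assumed connected when read back
  from TSV (true for every template this package writes).
* The correction step's behavioral-equivalence check is quadratic in the
  size of a parent-r0 group; corpus-scale correction would want
  screening by pattern size first.
* The oracle validator is a test double. Scientific conclusions about a
  real corpus require an external forward model plugged in through the
  adapter protocol.
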