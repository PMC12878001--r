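# rxnforge

Reaction corpora used to train retrosynthesis models are heavily skewed: a
handful of transformations (ester hydrolyses, amide couplings, common
protections) dominate, while most reaction templates have only a few
examples. Models trained on such data look accurate *per reaction* while
failing on the long tail of transformations — the gap shows up as soon as
accuracy is averaged *per template*.

`rxnforge` implements a data-augmentation scheme that equilibrates a
reaction corpus with **fictive reactions**: reactions that were never
observed, but are generated by applying retrosynthesis templates to known
product molecules and accepted only when a forward prediction model
regenerates the product with high confidence. It is aimed at
cheminformaticians building or evaluating single-step retrosynthesis
models.

## The method

For an atom-mapped reaction corpus with species partitioned into starting
materials (SM), reagents (R) and a single product (P):

1. **Reaction centers.** An atom is *changed* iff its multiset of
   (neighbor map number, bond order) pairs, its formal charge or its total
   hydrogen count differs between the reactant and product side; atoms
   present on only one side are changed on that side.
2. **Templates.** A radius-0 (r0) retro template covers exactly the
   changed product atoms; a radius-1 (r1) template adds their first-shell
   neighbors. Templates are canonicalized (renumbering-invariant hashes)
   and hierarchically corrected: within a parent-r0 group, behaviorally
   equivalent r1 variants are merged into the most general pattern.
3. **Generation.** Each template's product pattern is searched against a
   molecule pool (split into subsets scanned in random order); retro
   application `P -> SM` proposes precursors, a reagent predictor (T2
   role) supplies R, and the changed atoms in SM are tagged with a `!`
   token to form SM*.
4. **Validation.** A forward predictor (T3* role) predicts P from
   SM* + R with a confidence score CS = exp(sum of token
   log-probabilities). The candidate is accepted iff the predicted product
   equals P *and* CS > 0.95 (strict). Up to 5000 validated reactions are
   collected per template; training subsets are further equilibrated to at
   most 100 reactions per template.
5. **Evaluation.** Round-trip accuracy (RTA) is the fraction of test
   products regenerated among the top-N predicted precursor sets; TA-RTA
   is the unweighted mean of per-template RTAs, the metric that exposes
   template imbalance. Both are also stratified by the number of tagged
   atoms.

The pluggable predictor contract ships with a deterministic
template-oracle (for testing and pipeline validation) and a line-protocol
adapter for external sequence models. A self-contained toy-chemistry
world (six template families, tag counts 2–4) makes every stage testable
without any external data.

## Worked example

```r
library(rxnforge)

rxn <- parse_reaction(
  "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>O=S(=O)(O)O>[CH3:1][C:2](=[O:3])[O:6][CH3:5]",
  source_id = "uspto-example")

detect_changed_atoms(rxn)
#> <changed_atoms> reactant side {2,4,6}, product side {2,6}

t1 <- extract_template(rxn, "r1")
t1
#> <retro_template r1_b34ba043a9> radius r1, 2 tags, 1 example(s)
#>   [C;+0;D1:1]-[C;+0;H0;!:2](=[O;+0;D1:3])-[O;+0;H0;!:4]-[C;+0;D1:5]>>
#>   [C;+0;D1:1]-[C;+0;H0;!:2](=[O;+0;D1:3])-[O;+0;H1;!:6].[C;+0;D1:5]-[O;+0;H1;!:4]

sets <- apply_retro(t1, "CC(=O)OC")
sets[[1]]$key
#> [1] "CC(=O)O.CO"

sapply(tag_changed_atoms(sets[[1]]), tagged_to_string)
#> [1] "CC!(=O)O!" "CO!"
```

Reading the output: the esterification's reaction center is the carbonyl
carbon (map 2), the acid hydroxyl that leaves (map 4) and the alcohol
oxygen (map 6); the extracted r1 template carries the two changed product
atoms (`!`) plus their first-shell neighbors (degree-constrained, `D`).
Applied in retro to methyl acetate it regenerates acetic acid and
methanol, whose changed atoms are then tagged to give the SM*
representation `CC!(=O)O!` + `CO!` that a forward validator consumes.

A full campaign over a molecule pool:

```r
w <- toy_world()
pool <- enumerate_pool(w, 120)
pred <- list(reagent = oracle_predictor(w$templates, w$reagent_table),
             forward = oracle_predictor(w$templates, base_confidence = 1.0))
cfg <- generation_config(cap_per_template = 100, n_pool_subsets = 8, seed = 1)
res <- run_campaign(w$templates, pool, pred, cfg)
fictive <- res$dataset[res$dataset$accepted, ]
eq <- equilibrate(fictive, cap = 100, seed = 1)
```

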