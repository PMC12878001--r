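# Shared fixtures: one toy world, a small mapped-reaction set with ground
# truth, and a small product pool, built once per test run.

toy <- toy_world(seed = 42L)

toy_gen <- generate_toy_reactions(toy, n_per_template = 4L)
toy_pool <- enumerate_pool(toy, 36L)

# a small fictive dataset via a zero-noise campaign (used by dataset tests)
toy_campaign <- run_campaign(
  toy$templates, toy_pool,
  predictors = list(
    reagent = oracle_predictor(toy$templates, toy$reagent_table),
    forward = oracle_predictor(toy$templates, base_confidence = 1.0)
  ),
  config = generation_config(cap_per_template = 50L, n_pool_subsets = 4L,
                             seed = 11L)
)
toy_fictive <- toy_campaign$dataset[toy_campaign$dataset$accepted, ,
                                    drop = FALSE]

# independent canonicalization oracle (RDKit via the system python)
rdkit_canon <- function(smiles) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for s in sys.argv[1:]:",
    "    print(Chem.CanonSmiles(s))",
    sep = "\n"
  )
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), vapply(smiles, shQuote,
                                                      character(1))),
            stdout = TRUE, stderr = FALSE)
  )
  if (!is.null(attr(out, "status"))) return(NULL)
  out
}

# graph-level molecule equality through the package's own canonical form
same_mol <- function(a, b) {
  identical(plain_smiles(a), plain_smiles(b))
}

expect_same_mol <- function(a, b) {
  expect_identical(plain_smiles(a), plain_smiles(b))
}
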