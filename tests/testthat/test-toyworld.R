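test_that("pool enumeration is deterministic, canonical and distinct", {
  p1 <- enumerate_pool(toy, 24)
  p2 <- enumerate_pool(toy, 24)
  expect_identical(p1, p2)
  expect_length(p1, 24L)
  expect_false(anyDuplicated(p1) > 0)
  expect_identical(p1, vapply(p1, plain_smiles, character(1),
                              USE.NAMES = FALSE))
  expect_length(enumerate_pool(toy, 1), 1L)
  # family-restricted enumeration: esters form acid x alcohol combinations
  est <- suppressWarnings(enumerate_pool(toy, 1000, families = "toy_ester"))
  expect_identical(length(est),
                   length(toy$substituents$acid) *
                     length(toy$substituents$alcohol))
})

test_that("generated reactions are fully mapped with reagents as R", {
  gen <- generate_toy_reactions(toy, 2)
  expect_length(gen$reactions, 12L)
  for (rxn in gen$reactions) {
    expect_true(all(vapply(rxn$sm, function(m) all(m$map > 0L), logical(1))))
    expect_true(all(rxn$product$map > 0L))
    r <- partition_roles(rxn)
    expect_length(r$reagents, 1L)
    expect_length(r$sm, 2L)
  }
  expect_length(generate_toy_reactions(toy, 0)$reactions, 0L)
  # same seed, same output
  g2 <- generate_toy_reactions(toy, 2)
  expect_identical(vapply(g2$reactions, reaction_smiles, character(1)),
                   vapply(gen$reactions, reaction_smiles, character(1)))
})

test_that("extraction on generated reactions is hash-stable per family", {
  gen <- toy_gen
  fams <- vapply(gen$truth, `[[`, character(1), "template_id")
  for (fam in unique(fams)) {
    idx <- which(fams == fam)[1:2]
    hashes <- vapply(idx, function(i) {
      extract_template(partition_roles(gen$reactions[[i]]), "r0",
                       check = FALSE)$hash
    }, character(1))
    expect_identical(hashes[1], hashes[2])
  }
})

test_that("perturbed dataset pairs realize the requested overlap", {
  ds <- toy_fictive[!duplicated(toy_fictive$smrp_key), ][1:10, ]
  pp <- perturb_dataset(ds, 0.5, seed = 2, n_diff_conditions = 2)
  ov <- overlap_analysis(pp$A, pp$B)
  expect_identical(ov$smrp_shared, 5L)
  expect_identical(ov$different_conditions, 2L)
  # full overlap: identical key sets
  full <- perturb_dataset(ds, 1, seed = 2)
  expect_setequal(full$B$smrp_key, ds$smrp_key)
  # zero overlap with no condition variants: disjoint in both views
  none <- perturb_dataset(ds, 0, seed = 2)
  ovn <- overlap_analysis(none$A, none$B)
  expect_identical(ovn$sm_p_shared, 0L)
  expect_identical(ovn$smrp_shared, 0L)
})

test_that("fixture files are written in plain-text formats", {
  d <- tempfile("fixtures")
  write_toy_fixtures(toy, d, n_pool = 12, n_per_template = 2)
  expect_true(file.exists(file.path(d, "pool.smi")))
  expect_length(readLines(file.path(d, "pool.smi")), 12L)
  rr <- read_reactions(file.path(d, "reactions.txt"))
  expect_length(rr$reactions, 12L)
  expect_identical(nrow(rr$rejected), 0L)
  tr <- readLines(file.path(d, "truth.jsonl"))
  expect_length(tr, 12L)
  expect_identical(jsonlite::fromJSON(tr[1])$template_id, "toy_ester")
})

test_that("the CLI pipeline runs end to end on fixtures", {
  d <- tempfile("cli")
  rxnforge_run("fixtures", list(out = d, n_pool = "12",
                                n_per_template = "2", seed = "5"))
  tsv <- file.path(d, "templates.tsv")
  rxnforge_run("extract", list(reactions = file.path(d, "reactions.txt"),
                               radius = "r0", out = tsv))
  tt <- read_template_tsv(tsv)
  expect_gte(length(tt), 5L)
  gdir <- file.path(d, "gen")
  rxnforge_run("generate", list(templates = tsv,
                                pool = file.path(d, "pool.smi"),
                                out = gdir, cap = "3", subsets = "2",
                                seed = "5"))
  ds <- read_fictive_jsonl(file.path(gdir, "fictive.jsonl"))
  expect_true(all(table(ds$template_id) <= 3))
  eq <- file.path(d, "eq.jsonl")
  rxnforge_run("equilibrate", list(`in` = file.path(gdir, "fictive.jsonl"),
                                   cap = "2", out = eq, seed = "5"))
  expect_true(all(table(read_fictive_jsonl(eq)$template_id) <= 2))
  # unknown option / missing input fails loudly
  expect_identical(run_cli(c("equilibrate", "--cap", "2")), 2L)
  expect_identical(run_cli(character(0)), 2L)
})
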