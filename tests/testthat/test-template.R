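ester_rxn <- function(maps = 1:6) {
  parse_reaction(sprintf(
    "[CH3:%d][C:%d](=[O:%d])[OH:%d].[CH3:%d][OH:%d]>>[CH3:%d][C:%d](=[O:%d])[O:%d][CH3:%d]",
    maps[1], maps[2], maps[3], maps[4], maps[5], maps[6],
    maps[1], maps[2], maps[3], maps[6], maps[5]))
}

test_that("radius-0 extraction covers exactly the changed atoms", {
  t0 <- extract_template(ester_rxn(), "r0")
  expect_identical(t0$n_tags, 2L)
  expect_length(t0$prod$elem, 2L)
  sets <- apply_retro(t0, "CC(=O)OC")
  expect_identical(vapply(sets, `[[`, character(1), "key"), "CC(=O)O.CO")
})

test_that("radius-1 extraction adds the first-shell neighbors", {
  t1 <- extract_template(ester_rxn(), "r1")
  expect_gt(length(t1$prod$elem), 2L)
  # shell covers the carbonyl oxygen and both alkyl carbons
  expect_setequal(t1$prod$elem, c("C", "O"))
  expect_identical(sum(t1$prod$changed), 2L)
  expect_identical(sum(!t1$prod$changed), 3L)
  # self-consistency on the source reaction
  sets <- apply_retro(t1, ester_rxn()$product)
  expect_true("CC(=O)O.CO" %in% vapply(sets, `[[`, character(1), "key"))
})

test_that("template hashes are invariant to atom renumbering", {
  t0a <- extract_template(ester_rxn(1:6), "r0")
  t0b <- extract_template(ester_rxn(c(11, 12, 13, 14, 15, 16)), "r0")
  t0c <- extract_template(ester_rxn(c(6, 5, 4, 3, 2, 1)), "r0")
  expect_identical(template_hash(t0a), template_hash(t0b))
  expect_identical(template_hash(t0a), template_hash(t0c))
  t1 <- extract_template(ester_rxn(), "r1")
  expect_false(template_hash(t1) == template_hash(t0a))
  amide <- parse_reaction(paste0(
    "[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][CH3:6]>>",
    "[CH3:1][C:2](=[O:3])[NH:5][CH3:6]"))
  expect_false(template_hash(extract_template(amide, "r0")) ==
                 template_hash(t0a))
})

test_that("every product matching an r1 template matches its r0 parent", {
  for (rxn in toy_gen$reactions[seq(1, 24, by = 3)]) {
    r <- partition_roles(rxn)
    t0 <- extract_template(r, "r0", check = FALSE)
    t1 <- extract_template(r, "r1", check = FALSE)
    for (m in toy_pool) {
      if (length(match_pattern(t1$prod, parse_smiles(m), max_matches = 1))) {
        expect_length(
          match_pattern(t0$prod, parse_smiles(m), max_matches = 1), 1L)
      }
    }
  }
})

test_that("corpus extraction groups renumbered duplicates under one hash", {
  rxns <- list(ester_rxn(1:6), ester_rxn(11:16), ester_rxn(c(3, 1, 6, 2, 5, 4)))
  for (i in seq_along(rxns)) rxns[[i]]$source_id <- paste0("e", i)
  ex <- extract_templates(rxns, "r0")
  expect_length(ex$templates, 1L)
  expect_identical(ex$templates[[1]]$n_examples, 3L)
  expect_setequal(ex$templates[[1]]$example_ids, c("e1", "e2", "e3"))
  # min_examples filter
  ex2 <- extract_templates(rxns, "r0", min_examples = 4L)
  expect_length(ex2$templates, 0L)
})

test_that("equivalent r1 variants merge; different r0 parents never compared", {
  # same transformation from two atom-renumbered reactions plus a different
  # alcohol: the methyl and ethyl r1 templates are NOT merged (different
  # shell degree environment would still match, so test behavioral rule)
  r_me1 <- ester_rxn(1:6)
  r_me2 <- ester_rxn(11:16)
  r_me1$source_id <- "m1"; r_me2$source_id <- "m2"
  amide <- parse_reaction(paste0(
    "[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][CH3:6]>>",
    "[CH3:1][C:2](=[O:3])[NH:5][CH3:6]"), "a1")
  ex <- extract_templates(list(r_me1, r_me2, amide), "r1")
  by_hash <- list()
  rxns <- list(m1 = r_me1, m2 = r_me2, a1 = amide)
  for (t in ex$templates) {
    by_hash[[t$hash]] <- unname(rxns[t$example_ids])
  }
  merged <- correct_templates(ex$templates, by_hash)
  # renumbered duplicates already share a hash; amide stays separate
  expect_length(merged, 2L)
  expect_setequal(vapply(merged, `[[`, integer(1), "n_examples"), c(2L, 1L))
  # a group of one passes through unchanged
  single <- correct_templates(ex$templates[2], by_hash)
  expect_identical(single[[1]]$hash, ex$templates[[2]]$hash)
})

test_that("templates differing only beyond the first shell share one hash", {
  # propanoyl vs butanoyl esterification: identical radius-1 environment
  r1a <- parse_reaction(paste0(
    "[CH3:7][CH2:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>>",
    "[CH3:7][CH2:1][C:2](=[O:3])[O:6][CH3:5]"), "v1")
  r1b <- parse_reaction(paste0(
    "[CH3:17][CH2:18][CH2:11][C:12](=[O:13])[OH:14].[CH3:15][OH:16]>>",
    "[CH3:17][CH2:18][CH2:11][C:12](=[O:13])[O:16][CH3:15]"), "v2")
  ta <- extract_template(r1a, "r1")
  tb <- extract_template(r1b, "r1")
  expect_identical(ta$parent_r0_hash, tb$parent_r0_hash)
  expect_identical(ta$hash, tb$hash)
})

test_that("behaviorally equivalent r1 variants merge to the general pattern", {
  # a strict template and a relaxed variant (one shell degree constraint
  # dropped): equal behavior on the pooled examples, so they merge, and the
  # representative is the pattern with fewer specified atom properties
  r1a <- parse_reaction(paste0(
    "[CH3:7][CH2:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6]>>",
    "[CH3:7][CH2:1][C:2](=[O:3])[O:6][CH3:5]"), "v1")
  strict <- extract_template(r1a, "r1")
  relaxed <- strict
  shell <- which(!relaxed$prod$changed)[1]
  relaxed$prod$deg[shell] <- NA_integer_
  mp <- relaxed$prod$map[shell]
  for (k in seq_along(relaxed$reactants)) {
    hit <- which(relaxed$reactants[[k]]$map == mp)
    if (length(hit)) relaxed$reactants[[k]]$deg[hit] <- NA_integer_
  }
  cano <- rxnforge:::.template_canonicalize2(relaxed$prod, relaxed$reactants)
  relaxed$pattern_text <- cano$full
  relaxed$hash <- rxnforge:::.md5_string(paste0("r1::", cano$full))
  relaxed$template_id <- "r1_relaxed"
  by_hash <- stats::setNames(list(list(r1a), list(r1a)),
                             c(strict$hash, relaxed$hash))
  merged <- correct_templates(list(strict, relaxed), by_hash)
  expect_length(merged, 1L)
  expect_identical(merged[[1]]$template_id, "r1_relaxed")
  expect_identical(merged[[1]]$n_examples, 2L)
})

test_that("template TSV round-trips and preserves behavior", {
  ts <- lapply(c("r0", "r1"), function(rad)
    extract_template(ester_rxn(), rad))
  f <- tempfile(fileext = ".tsv")
  write_template_tsv(ts, f)
  back <- read_template_tsv(f)
  expect_length(back, 2L)
  expect_identical(back[[1]]$hash, ts[[1]]$hash)
  expect_identical(back[[1]]$n_tags, ts[[1]]$n_tags)
  sets <- apply_retro(back[[1]], "CC(=O)OC")
  expect_identical(sets[[1]]$key, "CC(=O)O.CO")
})

test_that("match_products screens a pool in order", {
  t0 <- extract_template(ester_rxn(), "r0")
  pool <- c("CC(=O)OC", "c1ccccc1", "CC(OCC)=O", "CCO")
  hits <- match_products(t0, pool)
  expect_identical(hits, c("CC(=O)OC", "CC(OCC)=O"))
  expect_length(match_products(t0, character(0)), 0L)
  expect_length(match_products(t0, c("CCO", "c1ccccc1")), 0L)
})
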