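test_that("confidence is the exponential of summed log-probabilities", {
  expect_identical(confidence_from_token_logprobs(c(0, 0)), 1)
  expect_equal(confidence_from_token_logprobs(c(log(0.5), log(0.5))), 0.25)
  expect_identical(confidence_from_token_logprobs(-1e9), 0)
  expect_error(confidence_from_token_logprobs(numeric(0)),
               class = "contract_error")
  expect_error(confidence_from_token_logprobs(c(0, NaN)),
               class = "contract_error")
})

test_that("the reagent oracle is a ranked table lookup", {
  pred <- oracle_predictor(toy$templates, toy$reagent_table)
  s <- apply_retro(toy$templates$toy_ester, "CC(=O)OC")[[1]]
  out <- predict_reagents(pred, s, "CC(=O)OC", k = 1,
                          template_id = "toy_ester")
  expect_length(out, 1L)
  expect_identical(out[[1]]$reagents, "O=S(=O)(O)O")
  expect_identical(out[[1]]$score, 1)
  # absent template -> empty
  expect_length(predict_reagents(pred, s, "CC(=O)OC",
                                 template_id = "nope"), 0L)
  # two entries, k = 2, ranked
  pred2 <- oracle_predictor(toy$templates,
                            list(toy_ester = list("O", "OO")))
  out2 <- predict_reagents(pred2, s, "CC(=O)OC", k = 2,
                           template_id = "toy_ester")
  expect_length(out2, 2L)
  expect_true(out2[[1]]$score >= out2[[2]]$score)
})

test_that("the forward oracle validates through the generating template", {
  s <- apply_retro(toy$templates$toy_ester, "CC(=O)OC")[[1]]
  tg <- tag_changed_atoms(s)
  pred <- oracle_predictor(toy$templates, base_confidence = 1.0)
  out <- predict_product(pred, tg, template_id = "toy_ester")
  expect_same_mol(out$product, "CC(=O)OC")
  expect_identical(out$confidence, 1)
  # configured confidence is reported as-is
  pred5 <- oracle_predictor(toy$templates, base_confidence = 0.5)
  out5 <- predict_product(pred5, tg, template_id = "toy_ester")
  expect_same_mol(out5$product, "CC(=O)OC")
  expect_identical(out5$confidence, 0.5)
  # SM* not matching the template -> no product, zero confidence
  bad <- tag_changed_atoms(list(parse_smiles("c1ccccc1"),
                                parse_smiles("CO")), integer(0))
  outb <- predict_product(pred, bad, template_id = "toy_ester")
  expect_null(outb$product)
  expect_identical(outb$confidence, 0)
})

test_that("oracle outputs are deterministic for fixed input and seed", {
  s <- apply_retro(toy$templates$toy_ester, "CC(=O)OC")[[1]]
  tg <- tag_changed_atoms(s)
  p1 <- oracle_predictor(toy$templates, base_confidence = 0.9,
                         noise_sd = 0.05, seed = 7L)
  p2 <- oracle_predictor(toy$templates, base_confidence = 0.9,
                         noise_sd = 0.05, seed = 7L)
  a <- predict_product(p1, tg, template_id = "toy_ester")
  b <- predict_product(p2, tg, template_id = "toy_ester")
  expect_identical(a$confidence, b$confidence)
  # noise is actually applied and clipped into [0, 1]
  expect_true(a$confidence >= 0 && a$confidence <= 1)
  p3 <- oracle_predictor(toy$templates, base_confidence = 0.9,
                         noise_sd = 0.05, seed = 8L)
  c3 <- predict_product(p3, tg, template_id = "toy_ester")$confidence
  expect_false(identical(a$confidence, c3))
})

test_that("the external adapter speaks the line protocol", {
  # fake model: echoes a fixed product and confidence per input line
  sh <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "while read -r line; do printf 'CC(OC)=O\\t0.97\\n'; done < \"$1\""),
             sh)
  Sys.chmod(sh, "0755")
  pred <- external_predictor(sh)
  s <- apply_retro(toy$templates$toy_ester, "CC(=O)OC")[[1]]
  tg <- tag_changed_atoms(s)
  out <- predict_product(pred, tg, reagents = "O=S(=O)(O)O",
                         template_id = "toy_ester")
  expect_same_mol(out$product, "CC(=O)OC")
  expect_equal(out$confidence, 0.97)
  # batch writer emits tagged tokens and the [SEP] marker
  f <- tempfile()
  write_forward_batch(list(tg), list("O=S(=O)(O)O"), f)
  line <- readLines(f)
  expect_length(line, 1L)
  expect_match(line, "\\[SEP\\]")
  expect_match(line, "!")
})
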