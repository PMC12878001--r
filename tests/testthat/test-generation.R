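test_that("pool sharding is balanced, disjoint, complete, deterministic", {
  pool <- as.character(1:10)
  sh <- shard_pool(pool, 3, seed = 5)
  expect_identical(sort(lengths(sh), decreasing = TRUE), c(4L, 3L, 3L))
  expect_setequal(unlist(sh), pool)
  expect_identical(shard_pool(pool, 3, seed = 5), sh)
  expect_false(identical(shard_pool(pool, 3, seed = 6), sh))
  expect_identical(shard_pool(pool, 1, seed = 1)[[1]], pool)
  expect_warning(sh2 <- shard_pool(pool[1:2], 5, seed = 1), "shrinking")
  expect_length(sh2, 2L)
})

test_that("the confidence gate is strict at the threshold", {
  s <- apply_retro(toy$templates$toy_ester, "CC(=O)OC")[[1]]
  draft <- list(template_id = "toy_ester", n_tags = 2L, sm = s$mols,
                sm_star = tag_changed_atoms(s),
                reagents = character(0), product_plain = "CC(OC)=O",
                sm_p_key = paste0(s$key, ">>CC(OC)=O"),
                smrp_key = paste0(s$key, ">>", ">CC(OC)=O"))
  for (conf in c(0.97, 0.95, 0.99)) {
    v <- oracle_predictor(toy$templates, base_confidence = conf)
    fr <- validate_candidate(draft, v, threshold = 0.95)
    expect_identical(fr$accepted, conf > 0.95)
    expect_identical(fr$confidence, conf)
    expect_true(fr$forward_consistent)
  }
  # mismatching product: rejected at any confidence
  draft2 <- draft
  draft2$product_plain <- "CC(OCC)=O"
  v <- oracle_predictor(toy$templates, base_confidence = 0.99)
  fr2 <- validate_candidate(draft2, v, threshold = 0.95)
  expect_false(fr2$accepted)
  expect_false(fr2$forward_consistent)
  expect_identical(fr2$confidence, 0.99)
})

test_that("per-template generation stops early at the cap", {
  pool <- enumerate_pool(toy, 24, families = "toy_ester")
  subsets <- shard_pool(pool, 4, seed = 2)
  pred <- list(reagent = NULL,
               forward = oracle_predictor(toy$templates,
                                          base_confidence = 1.0))
  cfg <- generation_config(cap_per_template = 2L, n_pool_subsets = 4L,
                           seed = 2L)
  out <- generate_for_template(toy$templates$toy_ester, subsets, pred, cfg)
  expect_identical(out$stats$accepted, 2L)
  expect_identical(out$stats$candidates, 2L)   # early stop: no extra work
  # below-threshold oracle: all candidates consistent, none accepted
  pred5 <- list(reagent = NULL,
                forward = oracle_predictor(toy$templates,
                                           base_confidence = 0.5))
  out5 <- generate_for_template(toy$templates$toy_ester, subsets, pred5, cfg)
  expect_identical(out5$stats$accepted, 0L)
  expect_identical(out5$stats$forward_consistent, out5$stats$candidates)
  expect_identical(out5$stats$candidates, length(pool))  # pool exhausted
  # template matching nothing
  none <- generate_for_template(toy$templates$toy_amide, subsets, pred, cfg)
  expect_identical(none$stats$candidates, 0L)
  expect_identical(nrow(none$reactions), 0L)
})

test_that("campaign totals conserve per-template accepted counts", {
  stats <- toy_campaign$stats
  ds <- toy_campaign$dataset
  expect_identical(sum(ds$accepted), sum(stats$accepted))
  for (i in seq_len(nrow(stats))) {
    tid <- stats$template_id[i]
    expect_identical(sum(ds$accepted[ds$template_id == tid]),
                     stats$accepted[i])
    expect_true(stats$accepted[i] <= stats$forward_consistent[i])
    expect_true(stats$forward_consistent[i] <= stats$candidates[i])
  }
  # smrp keys unique within template (dedup before the cap)
  for (tid in unique(ds$template_id)) {
    expect_false(anyDuplicated(ds$smrp_key[ds$template_id == tid]) > 0)
  }
})

test_that("campaigns are deterministic and resumable", {
  pool <- toy_pool[1:18]
  cfg <- generation_config(cap_per_template = 5L, n_pool_subsets = 3L,
                           seed = 9L)
  pred <- list(reagent = oracle_predictor(toy$templates, toy$reagent_table),
               forward = oracle_predictor(toy$templates,
                                          base_confidence = 1.0))
  r1 <- run_campaign(toy$templates, pool, pred, cfg)
  r2 <- run_campaign(toy$templates, pool, pred, cfg)
  expect_identical(r1$dataset, r2$dataset)
  # resume: run the first 3 templates with a checkpoint, then all 6
  ck <- tempfile("ckpt")
  partial <- run_campaign(toy$templates[1:3], pool, pred, cfg,
                          checkpoint_dir = ck)
  full <- run_campaign(toy$templates, pool, pred, cfg,
                       checkpoint_dir = ck)
  expect_equal(full$dataset, r1$dataset)
  # mismatched configuration refuses to resume
  cfg2 <- generation_config(cap_per_template = 7L, n_pool_subsets = 3L,
                            seed = 9L)
  expect_error(run_campaign(toy$templates, pool, pred, cfg2,
                            checkpoint_dir = ck),
               class = "checkpoint_mismatch")
})

test_that("accepted membership is pool-shuffle independent when uncapped", {
  pool <- enumerate_pool(toy, 20, families = "toy_amide")
  pred <- list(reagent = NULL,
               forward = oracle_predictor(toy$templates,
                                          base_confidence = 1.0))
  keysets <- lapply(c(1L, 99L), function(sd) {
    cfg <- generation_config(cap_per_template = 5000L, n_pool_subsets = 5L,
                             seed = sd)
    out <- run_campaign(toy$templates["toy_amide"], pool, pred, cfg)
    sort(out$dataset$smrp_key[out$dataset$accepted])
  })
  expect_identical(keysets[[1]], keysets[[2]])
})

test_that("fictive datasets round-trip through JSONL", {
  ds <- toy_fictive[1:5, ]
  f <- tempfile(fileext = ".jsonl")
  write_fictive_jsonl(ds, f)
  back <- read_fictive_jsonl(f)
  rownames(ds) <- NULL
  expect_equal(back, ds)
})
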