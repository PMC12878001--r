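fake_dataset <- function(counts) {
  rows <- do.call(rbind, lapply(names(counts), function(tid) {
    n <- counts[[tid]]
    data.frame(template_id = tid,
               smrp_key = sprintf("%s_r%03d", tid, seq_len(n)),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

test_that("equilibration keeps min(count, cap) per template", {
  ds <- fake_dataset(c(A = 250, B = 40, C = 100))
  eq <- equilibrate(ds, cap = 100, seed = 3)
  expect_identical(as.integer(table(eq$template_id)[c("A", "B", "C")]),
                   c(100L, 40L, 100L))
  expect_identical(nrow(eq), 240L)
  # cap above the maximum leaves the dataset unchanged
  expect_identical(equilibrate(ds, cap = 300, seed = 3), ds)
  # deterministic given the seed
  expect_identical(equilibrate(ds, cap = 100, seed = 3), eq)
  expect_false(identical(equilibrate(ds, cap = 100, seed = 4), eq))
})

test_that("template-grouped splitting never straddles a template", {
  ds <- fake_dataset(c(T1 = 80, T2 = 10, T3 = 10))
  sp <- split_by_template(ds, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(unname(sp$counts), c(80L, 10L, 10L))
  expect_identical(unname(sp$realized), c(0.8, 0.1, 0.1))
  expect_false(anyDuplicated(sp$assignment$template_id) > 0)
  # 100 equal templates: realized ratios within one template's weight
  ds2 <- fake_dataset(stats::setNames(rep(5, 100), sprintf("q%03d", 1:100)))
  sp2 <- split_by_template(ds2, c(0.8, 0.1, 0.1), seed = 2)
  expect_true(all(abs(sp2$realized - c(0.8, 0.1, 0.1)) <= 5 / 500))
  expect_identical(sum(sp2$counts), 500L)
  expect_error(split_by_template(fake_dataset(c(A = 3)), c(0.5, 0.5)),
               class = "split_error")
})

test_that("overlap analysis separates exact and different-condition sharing", {
  A <- data.frame(
    sm_p_key = c("a.b>>c", "d>>e"),
    smrp_key = c("a.b>X>c", "d>Y>e"),
    stringsAsFactors = FALSE
  )
  B <- data.frame(
    sm_p_key = c("a.b>>c", "f>>g"),
    smrp_key = c("a.b>Z>c", "f>Y>g"),
    stringsAsFactors = FALSE
  )
  ov <- overlap_analysis(A, B)
  expect_identical(ov$sm_p_shared, 1L)
  expect_identical(ov$smrp_shared, 0L)
  expect_identical(ov$different_conditions, 1L)
  expect_identical(unname(ov$frac_of_A["sm_p"]), 0.5)
  # identity and disjoint cases
  self <- overlap_analysis(A, A)
  expect_identical(unname(self$frac_of_A), c(1, 1))
  expect_identical(self$different_conditions, 0L)
  disj <- overlap_analysis(A, data.frame(sm_p_key = "x>>y",
                                         smrp_key = "x>W>y"))
  expect_identical(disj$sm_p_shared + disj$smrp_shared, 0L)
  # invariants: smrp-shared never exceeds sm_p-shared; counts symmetric
  ov2 <- overlap_analysis(B, A)
  expect_identical(ov2$sm_p_shared, ov$sm_p_shared)
  expect_identical(ov2$smrp_shared, ov$smrp_shared)
  expect_true(ov$smrp_shared <= ov$sm_p_shared)
})

test_that("novelty analysis works on distinct species", {
  A <- data.frame(sm = c("x.y", "z"), reagents = c("r1", ""),
                  stringsAsFactors = FALSE)
  B <- data.frame(sm = "x", reagents = "r1.r2", stringsAsFactors = FALSE)
  nv <- novelty_analysis(A, B)
  expect_equal(nv$sm$novelty, 2 / 3)
  expect_equal(nv$sm$coverage_of_B, 1)
  expect_equal(nv$reagents$novelty, 0)
  expect_equal(nv$reagents$coverage_of_B, 1 / 2)
  # A subset of B -> novelty 0; disjoint -> novelty 1, coverage 0
  expect_equal(novelty_analysis(B, B)$sm$novelty, 0)
  nv2 <- novelty_analysis(A, data.frame(sm = "q", reagents = "q"))
  expect_equal(nv2$sm$novelty, 1)
  expect_equal(nv2$sm$coverage_of_B, 0)
})

test_that("tag-count histograms report percentages summing to 100", {
  h <- tag_count_distribution(data.frame(n_tags = c(2L, 2L, 3L)))
  expect_identical(h$count, c(2L, 1L))
  expect_equal(h$percent, c(200 / 3, 100 / 3))
  expect_equal(sum(h$percent), 100)
  h1 <- tag_count_distribution(list(toy$templates$toy_diol))
  expect_identical(h1$n_tags, 4L)
  expect_identical(h1$percent, 100)
  expect_identical(nrow(tag_count_distribution(data.frame(
    n_tags = integer(0)))), 0L)
  # toy template library spans tag counts 2 to 4
  ht <- tag_count_distribution(unname(toy$templates))
  expect_setequal(ht$n_tags, 2:4)
})

test_that("element frequencies match atoms, not substrings", {
  ds <- data.frame(
    reagents = c("O=C([O-])[O-].[Na+].[Na+]",   # sodium carbonate
                 "c1ccc(P(c2ccccc2)c3ccccc3)cc1",  # triphenylphosphine
                 "CN",                          # methylamine: N, not Na
                 "CCCC[Sn](CCCC)CCCC",          # tributyltin: Sn, not S/N
                 ""),                           # reagent-free
    stringsAsFactors = FALSE
  )
  f <- element_frequency(ds, c("Na", "P", "N", "Sn", "S", "Au"))
  expect_equal(unname(f["Na"]), 1 / 5)
  expect_equal(unname(f["P"]), 1 / 5)
  expect_equal(unname(f["N"]), 1 / 5)
  expect_equal(unname(f["Sn"]), 1 / 5)
  expect_equal(unname(f["S"]), 0)
  expect_equal(unname(f["Au"]), 0)
  expect_error(element_frequency(ds, "Xx"), class = "element_error")
})

test_that("percentages use half-away-from-zero rounding to one decimal", {
  expect_identical(as_percentage(1, 1), 100)
  expect_identical(as_percentage(1, 3), 33.3)
  expect_identical(as_percentage(2, 3), 66.7)
  expect_identical(as_percentage(1, 8), 12.5)
  expect_identical(as_percentage(15, 10000), 0.2)   # 0.15 rounds away
  expect_error(as_percentage(1, 0), class = "percentage_error")
})
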