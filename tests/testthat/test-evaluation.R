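mk <- function(id, sec, type, start, len) {
  adr_mention(id, sec, type, start, len, strrep("x", sum(len)))
}

test_that("score_mentions handles the documented cases", {
  g <- list(mk("G1", "S1", "AdverseReaction", 0L, 4L),
            mk("G2", "S1", "Severity", 10L, 4L))
  expect_equal(score_mentions(g, g), c(precision = 1, recall = 1, f1 = 1))

  ## 2 correct + 2 spurious: p = 0.5, r = 1, f1 = 2/3
  p <- c(g, list(mk("P3", "S1", "AdverseReaction", 20L, 3L),
                 mk("P4", "S2", "Factor", 0L, 2L)))
  expect_equal(score_mentions(g, p),
               c(precision = 0.5, recall = 1, f1 = 2 / 3))

  ## degenerate: no predictions
  expect_equal(score_mentions(g, list()), c(precision = 0, recall = 0, f1 = 0))
})

test_that("matching is exact on section, span set and type (one-to-one)", {
  g <- list(mk("G1", "S1", "AdverseReaction", 0L, 4L))
  ## wrong type
  expect_equal(score_mentions(g, list(mk("P1", "S1", "Severity", 0L, 4L)))[["f1"]], 0)
  ## wrong section
  expect_equal(score_mentions(g, list(mk("P1", "S2", "AdverseReaction", 0L, 4L)))[["f1"]], 0)
  ## partial overlap gets no credit
  expect_equal(score_mentions(g, list(mk("P1", "S1", "AdverseReaction", 0L, 3L)))[["f1"]], 0)
  ## multi-span sets must match exactly
  g2 <- list(mk("G2", "S1", "AdverseReaction", c(0L, 10L), c(4L, 3L)))
  expect_equal(score_mentions(g2, g2)[["f1"]], 1)
  expect_equal(score_mentions(g2, list(mk("P", "S1", "AdverseReaction", 0L, 4L)))[["f1"]], 0)
  ## one-to-one: a duplicate prediction is not two true positives
  dup <- list(mk("P1", "S1", "AdverseReaction", 0L, 4L),
              mk("P2", "S1", "AdverseReaction", 0L, 4L))
  s <- score_mentions(g, dup)
  expect_equal(s[["precision"]], 0.5)
  expect_equal(s[["recall"]], 1)
})

test_that("score_normalization reproduces the hand-computed example", {
  gold <- list(L1 = c("A", "B"), L2 = "C")
  pred <- list(L1 = "A", L2 = c("C", "D"))
  s <- score_normalization(gold, pred)
  expect_equal(unname(s$micro), c(2 / 3, 2 / 3, 2 / 3))
  expect_equal(s$macro[["f1"]], 2 / 3)

  same <- list(L1 = c("A", "B"), L2 = character(0))
  s2 <- score_normalization(same, same)
  expect_equal(unname(s2$micro), c(1, 1, 1))
  expect_equal(unname(s2$macro), c(1, 1, 1))

  ## empty gold & empty pred label scores (1,1,1) and leaves others alone
  gold3 <- list(L1 = "A", L2 = character(0))
  pred3 <- list(L1 = "A", L2 = character(0))
  s3 <- score_normalization(gold3, pred3)
  expect_equal(s3$per_label$f1, c(1, 1))

  expect_error(score_normalization(list(L1 = "A"), list(L2 = "A")), "keys")
})

test_that("micro is partition-invariant, macro is order-invariant", {
  set.seed(83)
  sets <- random_pt_sets(6L)
  s <- score_normalization(sets$gold, sets$pred)
  ## repartition: merge all labels into one (micro must not change)
  tag_pairs <- function(sets) list(ALL = unlist(lapply(names(sets), function(k)
    if (length(sets[[k]])) paste(k, sets[[k]], sep = "/") else character(0))))
  merged_g <- tag_pairs(sets$gold)
  merged_p <- tag_pairs(sets$pred)
  s_m <- score_normalization(merged_g, merged_p)
  expect_equal(s$micro, s_m$micro)
  ## reorder labels (macro must not change)
  ord <- rev(names(sets$gold))
  s_r <- score_normalization(sets$gold[ord], sets$pred[ord])
  expect_equal(s$macro, s_r$macro)
})

test_that("adding a correct prediction never lowers scores; an incorrect one never raises recall", {
  set.seed(89)
  for (r in 1:20) {
    sets <- random_pt_sets(4L)
    s0 <- score_normalization(sets$gold, sets$pred)
    k <- sample(names(sets$gold), 1L)
    missing_correct <- setdiff(sets$gold[[k]], sets$pred[[k]])
    if (length(missing_correct)) {
      pred2 <- sets$pred
      pred2[[k]] <- c(pred2[[k]], missing_correct[1L])
      s1 <- score_normalization(sets$gold, pred2)
      expect_gte(s1$micro[["precision"]] + 1e-12, s0$micro[["precision"]])
      expect_gte(s1$micro[["recall"]] + 1e-12, s0$micro[["recall"]])
      expect_gte(s1$micro[["f1"]] + 1e-12, s0$micro[["f1"]])
    }
    pred3 <- sets$pred
    pred3[[k]] <- c(pred3[[k]], "WRONG_PT")
    s2 <- score_normalization(sets$gold, pred3)
    expect_lte(s2$micro[["recall"]], s0$micro[["recall"]] + 1e-12)
  }
})

test_that("metric oracle: module scores match the brute-force counters", {
  set.seed(97)
  types <- c("AdverseReaction", "Severity", "Factor")
  for (r in 1:40) {
    g <- list(); p <- list()
    for (i in seq_len(sample(0:6, 1L)))
      g[[length(g) + 1L]] <- mk(paste0("G", i), sample(c("S1", "S2"), 1L),
                                sample(types, 1L), sample(0:20, 1L) * 10L,
                                sample(2:6, 1L))
    for (i in seq_len(sample(0:6, 1L)))
      p[[length(p) + 1L]] <- mk(paste0("P", i), sample(c("S1", "S2"), 1L),
                                sample(types, 1L), sample(0:20, 1L) * 10L,
                                sample(2:6, 1L))
    expect_equal(score_mentions(g, p), score_mentions_brute(g, p))

    sets <- random_pt_sets(sample(2:5, 1L))
    s <- score_normalization(sets$gold, sets$pred)
    b <- score_normalization_brute(sets$gold, sets$pred)
    expect_equal(s$micro, b$micro)
    expect_equal(s$macro, b$macro)
  }
})

test_that("eval_report assembles and prints the table layout", {
  g <- list(mk("G1", "S1", "AdverseReaction", 0L, 4L))
  rep <- eval_report(g, g, list(L1 = "A"), list(L1 = "A"))
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$mention_f1, 1)
  expect_equal(rep$norm_micro_f1, 1)
  expect_output(print(rep), "Identification")
})
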