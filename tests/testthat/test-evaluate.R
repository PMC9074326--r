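test_that("confusion metrics reproduce benchmark worked examples", {
  # synthetic scale-10 row: counts forced by the printed FPR/TPR/ACC
  m <- confusion_metrics(tp = 8, fp = 0, fn = 1, tn = 41)
  expect_equal(round(m$mcc, 4), 0.9315)
  expect_equal(round(m$ppv, 4), 1.0000)
  expect_equal(round(m$acc, 4), 0.9800)
  expect_equal(round(m$tpr, 4), 0.8889)
  expect_equal(round(m$fpr, 4), 0.0000)

  m2 <- confusion_metrics(tp = 7, fp = 3, fn = 3, tn = 77)
  expect_equal(round(m2$mcc, 4), 0.6625)
  expect_equal(round(m2$acc, 4), 0.9333)

  m3 <- confusion_metrics(tp = 9, fp = 1, fn = 0, tn = 40)
  expect_equal(round(m3$mcc, 4), 0.9370)

  m4 <- confusion_metrics(tp = 9, fp = 9, fn = 1, tn = 71)
  expect_equal(round(m4$mcc, 4), 0.6187)

  m5 <- confusion_metrics(tp = 6, fp = 67, fn = 4, tn = 13)
  expect_equal(round(m5$mcc, 4), -0.1907)
})

test_that("degenerate confusion cases follow the stated conventions", {
  expect_message(m <- confusion_metrics(tp = 0, fp = 0, fn = 5, tn = 45))
  expect_identical(m$tpr, 0)
  expect_identical(m$ppv, 0)
  expect_identical(m$mcc, 0)
  expect_error(confusion_metrics(tp = 0, fp = 1, fn = 0, tn = 9), "no positive")
  expect_error(confusion_metrics(tp = 1, fp = 0, fn = 9, tn = 0), "no negative")
})

test_that("MCC is symmetric under class swap", {
  set.seed(13)
  for (i in 1:20) {
    cts <- sample(0:30, 4, replace = TRUE)
    cts[1] <- cts[1] + 1; cts[4] <- cts[4] + 1   # keep both classes present
    m <- suppressMessages(confusion_metrics(cts[1], cts[2], cts[3], cts[4]))
    msw <- suppressMessages(confusion_metrics(cts[4], cts[3], cts[2], cts[1]))
    expect_equal(abs(m$mcc), abs(msw$mcc), tolerance = 1e-12)
  }
})

toy_gold <- function() {
  data.frame(regulator = c("A", "B"), target = c("B", "C"),
             stringsAsFactors = FALSE)
}

toy_scores <- function(s) {
  u <- make_universe(c("A", "B", "C"))
  u$score <- s
  u
}

test_that("roc_auc covers the trivial ranking conventions", {
  gold <- toy_gold()
  u <- make_universe(c("A", "B", "C"))
  lab <- paste(u$regulator, u$target) %in% c("A B", "B C")
  perfect <- toy_scores(ifelse(lab, 1, 0))
  expect_equal(roc_auc(perfect, gold, u), 1)
  flat <- toy_scores(rep(0.4, 6))
  expect_equal(roc_auc(flat, gold, u), 0.5)
  inverted <- toy_scores(ifelse(lab, 0, 1))
  expect_equal(roc_auc(inverted, gold, u), 0)
})

test_that("roc_auc equals the concordant-pair fraction and ignores monotone transforms", {
  set.seed(14)
  for (i in 1:30) {
    n_genes <- sample(3:5, 1)
    genes <- paste0("g", seq_len(n_genes))
    u <- make_universe(genes)
    npos <- sample(seq_len(nrow(u) - 1), 1)
    pos_idx <- sample(nrow(u), npos)
    gold <- u[pos_idx, c("regulator", "target")]
    sc <- u
    sc$score <- sample(c(0, 0.2, 0.5, 0.9), nrow(u), replace = TRUE)
    lab <- seq_len(nrow(u)) %in% pos_idx
    expect_equal(roc_auc(sc, gold, u), brute_force_auc(sc$score, lab),
                 tolerance = 1e-12)
    sc2 <- sc
    sc2$score <- exp(3 * sc$score)       # strictly monotone transform
    expect_equal(roc_auc(sc2, gold, u), roc_auc(sc, gold, u), tolerance = 1e-12)
  }
})

test_that("roc_auc scores the documented 4-pair example at 0.75", {
  u <- data.frame(regulator = c("r1", "r2", "r3", "r4"),
                  target = rep("t", 4))
  gold <- u[c(1, 3), ]
  sc <- u; sc$score <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(roc_auc(sc, gold, u), 0.75)
})

test_that("roc_auc treats unscored universe pairs as zero and validates inputs", {
  gold <- toy_gold()
  u <- make_universe(c("A", "B", "C"))
  partial <- data.frame(regulator = "A", target = "B", score = 1)
  auc <- roc_auc(partial, gold, u)
  # one positive at 1 beats all 4 negatives; the other ties 4 zeros
  expect_equal(auc, (4 + 0.5 * 4) / 8)
  expect_error(roc_auc(partial, data.frame(regulator = character(0),
                                           target = character(0)), u),
               "degenerate")
})

test_that("per-gene AUC matches hand enumeration on a small toy", {
  genes <- c("A", "B", "C")
  u <- make_universe(genes)
  gold <- data.frame(regulator = c("A", "A"), target = c("B", "C"))
  sc <- u
  sc$score <- c(0.9, 0.4, 0.2, 0.1, 0.8, 0.3)[match(
    paste(u$regulator, u$target),
    c("A B", "A C", "B A", "B C", "C A", "C B"))]
  res <- per_gene_auc(sc, gold, u, axis = "by_target", cutoff = 0.8)
  # target B: pos A->B (0.9) vs neg C->B (0.3) -> 1; target C: pos A->C (0.4)
  # vs neg B->C (0.1) -> 1; target A: no positives -> excluded
  expect_equal(unname(res$per_gene[c("B", "C")]), c(1, 1))
  expect_identical(res$n_excluded, 1L)
  expect_equal(res$mean, 1)
  expect_identical(res$count_above, 2L)
  expect_equal(res$fraction_above, 100)

  gold_one <- data.frame(regulator = "A", target = "B")
  byreg <- per_gene_auc(sc, gold_one, u, axis = "by_regulator")
  # regulator A: pos A->B (0.9) vs neg A->C (0.4) -> 1; B and C have no
  # positives -> excluded
  expect_equal(unname(byreg$per_gene["A"]), 1)
  expect_identical(byreg$n_excluded, 2L)
  # no eligible gene at all is an explicit failure
  expect_error(per_gene_auc(sc, gold_one, u[u$regulator == "B", , drop = FALSE],
                            axis = "by_regulator"),
               "no gene")
})

test_that("evaluate_prediction scores the oracle prediction perfectly", {
  cfg <- sim_config(8, n_samples = 10, seed = 19)
  g <- generate_network(cfg)
  u <- make_universe(g$genes)
  oracle <- g$edges[, c("regulator", "target")]
  oracle$strength <- 1
  m <- evaluate_prediction(oracle, g, u, threshold = 0.5)
  expect_equal(m$tpr, 1); expect_equal(m$fpr, 0)
  expect_equal(m$acc, 1); expect_equal(m$ppv, 1)
  expect_equal(m$mcc, 1); expect_equal(m$auc, 1)

  empty <- data.frame(regulator = character(0), target = character(0),
                      strength = numeric(0))
  m0 <- suppressMessages(evaluate_prediction(empty, g, u, threshold = 0.5))
  expect_equal(m0$tpr, 0); expect_equal(m0$fpr, 0)

  bad <- data.frame(regulator = "NOT_A_GENE", target = "G1", strength = 1)
  expect_error(evaluate_prediction(bad, g, u), "NOT_A_GENE")
})
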