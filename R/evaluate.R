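#' Confusion-matrix metric battery
#'
#' Computes the standard confusion-derived scores used to benchmark
#' network predictions: true positive rate (TPR, sensitivity), false
#' positive rate (FPR), accuracy (ACC), positive predictive value (PPV,
#' precision) and the Matthews correlation coefficient (MCC).
#' Conventions for degenerate cases: PPV is 0 when nothing is predicted
#' positive, and MCC is 0 when any factor of its denominator is 0; both
#' are reported with a message rather than an error so batch evaluation
#' never aborts.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.  The gold standard must
#'   contain at least one positive (`tp + fn > 0`) and one negative
#'   (`fp + tn > 0`).
#' @return A one-row data frame with columns `tpr`, `fpr`, `acc`, `ppv`,
#'   `mcc`.
#' @examples
#' confusion_metrics(tp = 8, fp = 0, fn = 1, tn = 41)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (tp + fn == 0) stop("gold standard has no positive pairs")
  if (fp + tn == 0) stop("gold standard has no negative pairs")
  total <- tp + fp + fn + tn
  ppv <- if (tp + fp == 0) {
    message("no positive predictions: PPV reported as 0")
    0
  } else tp / (tp + fp)
  denom_sq <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom_sq == 0) {
    message("degenerate confusion matrix: MCC reported as 0")
    0
  } else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom_sq)
  data.frame(tpr = tp / (tp + fn), fpr = fp / (fp + tn),
             acc = (tp + tn) / total, ppv = ppv, mcc = mcc)
}

#' Candidate-pair universe for evaluation
#'
#' The set of ordered (regulator, target) pairs over which predictions
#' are scored.  No benchmark defines this implicitly here: it is always
#' an explicit argument to the evaluation functions.  Self-pairs are
#' excluded; sources may be restricted to a regulator set.
#'
#' @param genes Character vector of gene identifiers.
#' @param regulators Optional character vector restricting pair sources.
#' @return Data frame with columns `regulator`, `target`.
#' @export
make_universe <- function(genes, regulators = NULL) {
  stopifnot(!anyDuplicated(genes))
  if (is.null(regulators)) regulators <- genes
  stopifnot(all(regulators %in% genes))
  u <- expand.grid(target = genes, regulator = regulators,
                   stringsAsFactors = FALSE)[, c("regulator", "target")]
  u <- u[u$regulator != u$target, , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Area under the ROC curve over a pair universe
#'
#' Rank (Mann-Whitney) formulation with ties counted one half, equivalent
#' to the trapezoidal area under the ROC curve over all thresholds: the
#' probability that a uniformly random true edge outranks a uniformly
#' random non-edge.  Pairs in the universe without a score are treated as
#' scored 0.
#'
#' @param scores Data frame with columns `regulator`, `target` and a
#'   numeric score column (`strength`, `score` or `value`).
#' @param gold Gold standard: a `gold_network` or a data frame of true
#'   edges (`regulator`, `target`; an optional `value` column keeps rows
#'   with value > 0).
#' @param universe Pair universe from [make_universe()]; must contain at
#'   least one positive and one negative pair.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, gold, universe) {
  lab <- universe_labels(gold, universe)
  s <- universe_scores(scores, universe)
  npos <- sum(lab)
  nneg <- sum(!lab)
  if (npos == 0L || nneg == 0L) {
    stop("degenerate universe: ", npos, " positive and ", nneg,
         " negative pairs")
  }
  r <- rank(s, ties.method = "average")
  (sum(r[lab]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Per-gene AUC summary
#'
#' AUC computed separately for each gene along one axis: `by_target`
#' scores the candidate regulators of each target gene, `by_regulator`
#' scores the putative targets of each regulator — the per-TG / per-TF
#' decomposition used when a network is too large for a single global
#' ROC.  Genes whose per-gene universe lacks a positive or a negative
#' pair are excluded and counted in `n_excluded`.
#'
#' @param scores,gold,universe As in [roc_auc()].
#' @param axis `"by_target"` or `"by_regulator"`.
#' @param cutoff AUC cutoff for the count/fraction summary (default 0.8).
#' @return A list: `per_gene` (named AUC vector), `min`, `max`, `median`,
#'   `mean`, `count_above`, `fraction_above` (percentage), `n_excluded`.
#' @export
per_gene_auc <- function(scores, gold, universe,
                         axis = c("by_target", "by_regulator"),
                         cutoff = 0.8) {
  axis <- match.arg(axis)
  col <- if (axis == "by_target") "target" else "regulator"
  groups <- split(seq_len(nrow(universe)), universe[[col]])
  aucs <- numeric(0)
  n_excluded <- 0L
  for (g in names(groups)) {
    u <- universe[groups[[g]], , drop = FALSE]
    lab <- universe_labels(gold, u)
    if (sum(lab) == 0L || sum(!lab) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    aucs[g] <- roc_auc(scores, gold, u)
  }
  if (length(aucs) == 0L) {
    stop("no gene has both a positive and a negative pair along axis ", axis)
  }
  list(per_gene = aucs,
       min = min(aucs), max = max(aucs),
       median = stats::median(aucs), mean = mean(aucs),
       count_above = sum(aucs > cutoff),
       fraction_above = 100 * mean(aucs > cutoff),
       n_excluded = n_excluded)
}

#' Score a predicted network against a gold standard
#'
#' Produces the full benchmark row: predictions are binarized at
#' `threshold` (strength >= threshold predicts an edge) for the confusion
#' battery of [confusion_metrics()], while the continuous strengths feed
#' [roc_auc()].
#'
#' @param pred Predicted network: data frame with `regulator`, `target`
#'   and a score column.
#' @param gold Gold standard (see [roc_auc()]).
#' @param universe Pair universe from [make_universe()].
#' @param threshold Binarization threshold for the confusion counts.
#' @return One-row data frame: `tpr`, `fpr`, `acc`, `ppv`, `mcc`, `auc`.
#' @export
evaluate_prediction <- function(pred, gold, universe, threshold = 0.5) {
  ug <- unique(c(universe$regulator, universe$target))
  pg <- unique(c(pred$regulator, pred$target))
  unknown <- setdiff(pg, ug)
  if (length(unknown) > 0L) {
    stop("predicted gene(s) absent from the evaluation universe: ",
         paste(unknown, collapse = ", "))
  }
  gold_edges <- as_gold_edges(gold)
  gg <- unique(c(gold_edges$regulator, gold_edges$target))
  unknown_g <- setdiff(gg, ug)
  if (length(unknown_g) > 0L) {
    stop("gold-standard gene(s) absent from the evaluation universe: ",
         paste(unknown_g, collapse = ", "))
  }
  lab <- universe_labels(gold, universe)
  s <- universe_scores(pred, universe)
  predicted <- s >= threshold
  m <- confusion_metrics(tp = sum(predicted & lab), fp = sum(predicted & !lab),
                         fn = sum(!predicted & lab), tn = sum(!predicted & !lab))
  m$auc <- roc_auc(pred, gold, universe)
  m
}

#' Write a metric report as TSV
#'
#' @param report One-row data frame from [evaluate_prediction()] (or any
#'   data frame of metrics).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(report), collapse = "\t"), con)
  for (i in seq_len(nrow(report))) {
    writeLines(paste(vapply(report[i, ], function(x)
      if (is.numeric(x)) num_fmt(x) else as.character(x), character(1L)),
      collapse = "\t"), con)
  }
  invisible(path)
}

pair_key <- function(reg, tgt) paste(reg, tgt, sep = "\r")

as_gold_edges <- function(gold) {
  if (inherits(gold, "gold_network")) return(gold$edges[, c("regulator", "target")])
  stopifnot(is.data.frame(gold), all(c("regulator", "target") %in% names(gold)))
  if ("value" %in% names(gold)) gold <- gold[gold$value > 0, , drop = FALSE]
  gold[, c("regulator", "target")]
}

universe_labels <- function(gold, universe) {
  e <- as_gold_edges(gold)
  pair_key(universe$regulator, universe$target) %in% pair_key(e$regulator, e$target)
}

universe_scores <- function(scores, universe) {
  stopifnot(is.data.frame(scores), all(c("regulator", "target") %in% names(scores)))
  score_col <- intersect(c("strength", "score", "value"), names(scores))[1L]
  if (is.na(score_col)) stop("scores need a 'strength', 'score' or 'value' column")
  idx <- match(pair_key(universe$regulator, universe$target),
               pair_key(scores$regulator, scores$target))
  s <- scores[[score_col]][idx]
  s[is.na(s)] <- 0
  s
}
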