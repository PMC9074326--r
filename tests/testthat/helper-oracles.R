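# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check.

# Exact minimizer of  mean(|y - X b|) + sum(penalty_j |b_j|)  for tiny k, n
# by vertex enumeration of the hyperplane arrangement
# {x_i' b = y_i} U {b_j = 0}: the objective is piecewise linear and
# coercive (penalty > 0), so a minimum is attained at a vertex, i.e. at the
# intersection of k of the n+k hyperplanes.
oracle_l1_objective <- function(y, X, penalty) {
  n <- length(y)
  k <- ncol(X)
  obj <- function(b) mean(abs(y - X %*% b)) + sum(penalty * abs(b))
  # hyperplanes as rows of A b = c
  A <- rbind(X, diag(k))
  cc <- c(y, rep(0, k))
  best <- obj(rep(0, k))
  for (idx in utils::combn(n + k, k, simplify = FALSE)) {
    Ak <- A[idx, , drop = FALSE]
    b <- tryCatch(solve(Ak, cc[idx]), error = function(e) NULL)
    if (is.null(b) || !all(is.finite(b))) next
    best <- min(best, obj(b))
  }
  best
}

# Concordant-pair fraction AUC with ties counted one half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Three-gene chain A -> B -> C used by several silencing tests.
chain_network <- function(w_ab = 0.8, w_bc = 0.7) {
  genes <- c("A", "B", "C")
  structure(list(
    genes = genes, regulators = genes,
    edges = data.frame(regulator = c("A", "B"), target = c("B", "C"),
                       weight = c(w_ab, w_bc), stringsAsFactors = FALSE),
    rank = stats::setNames(1:3, genes)),
    class = "gold_network")
}

random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0("G", seq_len(n_genes)),
                         paste0("S", seq_len(n_samples))))
}
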