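#' Solver parameters for the constrained L1 regression
#'
#' Parameters of the per-target optimization
#' \deqn{\tilde\beta = \arg\min_\beta \|y - X\beta\|_1 + \lambda\|\beta\|_1
#'   + \gamma \|\hat\beta \otimes \beta\|_1,}
#' where \eqn{\hat\beta \in \{0,1\}^k} marks the candidates that pay the
#' extra redundancy-silencing penalty.  High-dependence (enhancement)
#' candidates have \eqn{\hat\beta_j = 0} and so pay only \eqn{\lambda};
#' mid-dependence candidates pay \eqn{\lambda + \gamma}.  This differential
#' penalty is what gives enhancement candidates priority to be kept.
#'
#' @param lam Sparsity weight \eqn{\lambda \ge 0} applied to every
#'   coefficient.  Default 0.1.
#' @param gamma Extra redundancy-silencing weight \eqn{\gamma \ge 0}
#'   applied to non-enhancement coefficients.  Default 0.1.
#' @param alpha Balance parameter in `[0, 1]` mixing normalized regression
#'   strength (`alpha`) with normalized MI (`1 - alpha`) in the final edge
#'   score.  Default 0.5.
#' @param silence_threshold Coefficients with `|beta|` at or below this
#'   value are silenced (dropped) between recursion steps.  Default `1e-6`,
#'   i.e. numerical-zero support detection.
#' @param protect_fraction Enhancement protection is kept across recursion
#'   steps only by candidates whose `|beta|` stays at or above this
#'   fraction of the largest `|beta|` in the current fit; weaker
#'   high-dependence candidates lose protection and pay the full
#'   `lam + gamma` penalty in the next refit.  This is what resolves
#'   near-collinear candidate pairs (e.g. a regulator and its own
#'   upstream neighbour) toward the stronger member.  Default 0.5.
#' @param max_iterations Cap on silencing iterations.  Default 100.
#' @export
solver_params <- function(lam = 0.1, gamma = 0.1, alpha = 0.5,
                          silence_threshold = 1e-6, protect_fraction = 0.5,
                          max_iterations = 100L) {
  stopifnot(lam >= 0, gamma >= 0, alpha >= 0, alpha <= 1,
            silence_threshold >= 0,
            protect_fraction >= 0, protect_fraction <= 1,
            max_iterations >= 1)
  structure(list(lam = lam, gamma = gamma, alpha = alpha,
                 silence_threshold = silence_threshold,
                 protect_fraction = protect_fraction,
                 max_iterations = as.integer(max_iterations)),
            class = "solver_params")
}

#' Solve the constrained L1 regression exactly by linear programming
#'
#' Minimizes `mean(|y - X b|) + lam * sum(|b|) + gamma * sum(mask * |b|)`
#' over `b` through the standard exact LP reformulation: `b = b+ - b-`,
#' residuals split into `e+ - e-`, all auxiliaries nonnegative, objective
#' `mean(e+ + e-) + sum((lam + gamma * mask) * (b+ + b-))` subject to
#' `X (b+ - b-) + e+ - e- = y`.  Solved with the simplex method
#' ([boot::simplex()]), so the returned coefficients are a global
#' minimizer and exact zeros are produced at the vertex solution.
#'
#' The residual term is averaged over samples (as in penalized-regression
#' packages such as glmnet) so that `lam` and `gamma` keep the same
#' meaning at every sample size.
#'
#' @param y Numeric target vector (length `n >= 2`).
#' @param X Numeric `n x k` matrix of candidate regulator profiles.
#' @param enhancement_mask 0/1 vector of length `k`; 1 marks candidates
#'   paying the extra `gamma` penalty, 0 marks protected (enhancement)
#'   candidates.  Default: all 1 (no protected candidates).
#' @param params A [solver_params()] object.
#' @return A `strength_vector` list: `beta` (named if `X` has column
#'   names), `objective` (optimal value), and `support` (indices with
#'   `|beta|` above the silence threshold).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("R", 1:4)))
#' y <- X %*% c(1, -0.8, 0, 0) + rnorm(10, sd = 0.1)
#' solve_constrained_l1(y, X, params = solver_params(lam = 0.2, gamma = 0.2))
#' @export
solve_constrained_l1 <- function(y, X, enhancement_mask = NULL,
                                 params = solver_params()) {
  stopifnot(inherits(params, "solver_params"))
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  n <- length(y)
  k <- ncol(X)
  if (k == 0L) {
    return(structure(list(beta = numeric(0), objective = mean(abs(y)),
                          support = integer(0)),
                     class = "strength_vector"))
  }
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (n < 2L) stop("need at least 2 samples")
  if (is.null(enhancement_mask)) enhancement_mask <- rep(1, k)
  if (length(enhancement_mask) != k || !all(enhancement_mask %in% c(0, 1))) {
    stop("enhancement_mask must be a 0/1 vector of length ncol(X)")
  }
  penalty <- params$lam + params$gamma * enhancement_mask

  # variables: b+ (k), b- (k), e+ (n), e- (n), all >= 0
  a <- c(penalty, penalty, rep(1 / n, n), rep(1 / n, n))
  A3 <- cbind(X, -X, diag(n), -diag(n))
  b3 <- y
  neg <- b3 < 0            # boot::simplex needs nonnegative constants
  if (any(neg)) {
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
  }
  sol <- boot::simplex(a = a, A3 = A3, b3 = b3, maxi = FALSE,
                       n.iter = 100L * (n + 2L * (n + k)))
  if (sol$solved != 1L) {
    stop("internal error: LP solver did not converge (status ", sol$solved, ")")
  }
  beta <- as.numeric(sol$soln[seq_len(k)] - sol$soln[k + seq_len(k)])
  names(beta) <- colnames(X)
  structure(list(beta = beta,
                 objective = as.numeric(sol$value),
                 support = which(abs(beta) > params$silence_threshold)),
            class = "strength_vector")
}

# objective of the constrained L1 problem at a given beta
l1_objective <- function(y, X, beta, enhancement_mask, params) {
  penalty <- params$lam + params$gamma * enhancement_mask
  mean(abs(y - X %*% beta)) + sum(penalty * abs(beta))
}
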