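#' Recursive redundancy silencing for one target gene
#'
#' Starting from the screened candidate set (`mid` plus `high` of the
#' partition), repeatedly (1) fit the constrained L1 regression of the
#' target on the current candidates, (2) silence candidates whose
#' `|beta|` falls at or below `params$silence_threshold`, (3) update the
#' enhancement mask: protection is kept only by high-dependence
#' candidates whose `|beta|` stays at or above
#' `params$protect_fraction` of the strongest coefficient, and (4) refit
#' on the survivors, until neither the surviving set nor the protected
#' set changes, or `params$max_iterations` is reached.  Both sets only
#' ever shrink, so the loop always terminates.
#'
#' The mask update is what removes indirect regulators that are nearly
#' collinear with a direct one (a regulator's own upstream neighbour):
#' with equal penalties the L1 fit splits their shared signal
#' arbitrarily, but once the weaker member loses protection it pays
#' `lam + gamma` while the stronger pays `lam`, and the refit moves the
#' entire shared weight onto the protected member, zeroing the indirect
#' candidate exactly.
#'
#' @param expr Expression matrix (genes x samples); rows are z-scored
#'   internally unless `standardize = FALSE`.
#' @param target Target gene identifier.
#' @param partition A `candidate_partition` from [classify_candidates()].
#' @param params A [solver_params()] object.
#' @param standardize Z-score each gene before fitting (default `TRUE`).
#' @return A list: `beta` (named coefficients of the survivors),
#'   `support` (surviving gene identifiers), `iterations` (number of LP
#'   fits), `converged` (`TRUE` if a fixed point was reached), and
#'   `support_sizes` (candidate-set size at each iteration).
#' @export
recursive_silencing <- function(expr, target, partition,
                                params = solver_params(),
                                standardize = TRUE) {
  stopifnot(inherits(partition, "candidate_partition"),
            identical(partition$target, target))
  expr <- as_expression(expr)
  if (standardize) expr <- zscore_rows(expr)
  y <- expr[target, ]
  current <- c(partition$high, partition$mid)
  protected <- partition$high
  iterations <- 0L
  converged <- FALSE
  support_sizes <- integer(0)
  beta <- stats::setNames(numeric(0), character(0))
  while (iterations < params$max_iterations) {
    support_sizes <- c(support_sizes, length(current))
    if (length(current) == 0L) {
      iterations <- iterations + 1L
      converged <- TRUE
      break
    }
    X <- t(expr[current, , drop = FALSE])
    mask <- as.numeric(!(current %in% protected))
    fit <- solve_constrained_l1(y, X, enhancement_mask = mask, params = params)
    iterations <- iterations + 1L
    ab <- abs(fit$beta)
    keep <- ab > params$silence_threshold
    survivors <- current[keep]
    beta <- fit$beta[keep]
    if (length(survivors) == 0L) {
      current <- survivors
      converged <- TRUE
      break
    }
    strong <- current[ab >= params$protect_fraction * max(ab)]
    new_protected <- intersect(protected, intersect(survivors, strong))
    if (length(survivors) == length(current) &&
        length(new_protected) == length(protected)) {
      converged <- TRUE
      current <- survivors
      break
    }
    current <- survivors
    protected <- new_protected
  }
  if (!converged) {
    warning("target '", target, "': silencing did not converge within ",
            params$max_iterations, " iterations; returning last iterate")
  }
  list(beta = beta, support = current, iterations = iterations,
       converged = converged, support_sizes = support_sizes)
}

#' Combine regression strengths with MI into final edge scores
#'
#' For the surviving regulators of one target, the combined strength is
#' `alpha * norm(|beta|) + (1 - alpha) * norm(MI)`, where `norm()` is
#' max-normalization within the target's survivor set (a vector whose
#' maximum is 0 maps to all 1, so an all-equal vector always maps to 1).
#' Combining a linear (regression) and a nonlinear (MI) strength is what
#' lets the final score rank both kinds of dependence.
#'
#' @param beta Named coefficient vector over the surviving regulators.
#' @param mi MI matrix from [mi_matrix()] (or a named MI vector for the
#'   target).
#' @param target Target gene identifier.
#' @param params A [solver_params()] object (uses `alpha`).
#' @return Named nonnegative vector of combined strengths in `[0, 1]`.
#' @export
combine_strengths <- function(beta, mi, target, params = solver_params()) {
  regs <- names(beta)
  if (length(regs) == 0L) return(stats::setNames(numeric(0), character(0)))
  mi_v <- if (is.matrix(mi)) mi[regs, target] else mi[regs]
  mi_v[is.na(mi_v)] <- 0
  maxnorm <- function(v) {
    m <- max(v)
    if (m <= 0) rep(1, length(v)) else v / m
  }
  s <- params$alpha * maxnorm(abs(beta)) + (1 - params$alpha) * maxnorm(mi_v)
  stats::setNames(as.numeric(s), regs)
}

#' Infer a directed gene regulatory network
#'
#' Full pipeline: for every gene taken as target, screen the candidate
#' regulators by Gaussian MI into low/mid/high dependence classes
#' ([classify_candidates()]), run the recursive silencing regression on
#' the mid+high candidates ([recursive_silencing()]), and score the
#' surviving regulators by mixing normalized `|beta|` with normalized MI
#' ([combine_strengths()]).  Deterministic for fixed inputs.
#'
#' @param expr Expression matrix, genes x samples (>= 2 genes, >= 3
#'   samples), gene identifiers as row names.
#' @param regulators Optional character vector restricting edge sources
#'   (e.g. a transcription-factor list).  Default: every gene may
#'   regulate every other gene.
#' @param thresholds A [screen_thresholds()] object.
#' @param params A [solver_params()] object.
#' @param standardize Z-score each gene before MI-independent regression
#'   (default `TRUE`; MI is scale-invariant either way).
#' @return A `weighted_network` data frame with columns `regulator`,
#'   `target`, `strength`, `beta`, `mi`, sorted by strength descending
#'   then lexicographically.  Targets whose per-target fit fails are
#'   skipped with a warning; the call fails only if every target fails.
#' @examples
#' sim <- sim_config(n_genes = 10, n_samples = 20, seed = 1)
#' net <- generate_network(sim)
#' expr <- simulate_expression(net, sim)
#' infer_network(expr)
#' @export
infer_network <- function(expr, regulators = NULL,
                          thresholds = screen_thresholds(),
                          params = solver_params(),
                          standardize = TRUE) {
  expr <- as_expression(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  genes <- rownames(expr)
  if (!is.null(regulators)) {
    missing <- setdiff(regulators, genes)
    if (length(missing) > 0L) {
      stop("regulator(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  mi <- mi_matrix(expr)
  zex <- if (standardize) zscore_rows(expr) else expr
  rows <- vector("list", length(genes))
  failures <- character(0)
  for (g in genes) {
    res <- tryCatch({
      part <- classify_candidates(mi, g, thresholds, candidates = regulators)
      fit <- recursive_silencing(zex, g, part, params, standardize = FALSE)
      strengths <- combine_strengths(fit$beta, mi, g, params)
      if (length(strengths) == 0L) NULL else
        data.frame(regulator = names(strengths), target = g,
                   strength = as.numeric(strengths),
                   beta = as.numeric(fit$beta[names(strengths)]),
                   mi = as.numeric(mi[names(strengths), g]),
                   stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("target '", g, "' skipped: ", conditionMessage(e))
      failures <<- c(failures, g)
      NULL
    })
    rows[[match(g, genes)]] <- res
  }
  if (length(failures) == length(genes)) {
    stop("network inference failed for every target")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(regulator = character(0), target = character(0),
                      strength = numeric(0), beta = numeric(0),
                      mi = numeric(0), stringsAsFactors = FALSE)
  }
  out <- sort_edges(out)
  class(out) <- c("weighted_network", "data.frame")
  out
}

zscore_rows <- function(expr) {
  m <- rowMeans(expr)
  s <- apply(expr, 1L, stats::sd)
  s[s == 0] <- 1   # constant gene stays constant (all zeros after centering)
  (expr - m) / s
}
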