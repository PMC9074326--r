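#' Gaussian mutual information between two expression profiles
#'
#' Under a bivariate Gaussian model the mutual information between two
#' profiles is
#' \deqn{MI(A,B) = \tfrac12 \log\frac{|M(A)|\,|M(B)|}{|M(A,B)|}
#'              = -\tfrac12 \log(1 - r^2),}
#' where \eqn{M(\cdot)} are (co)variance matrices and \eqn{r} is the sample
#' correlation.  The value is in nats (natural log), nonnegative, and 0 iff
#' the profiles are uncorrelated.
#'
#' The covariance determinant is clamped below at `1e-300` and the result
#' capped at `cap` nats so that collinear profiles (\eqn{|r| \to 1}) give a
#' large finite value instead of `Inf`.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @param cap Ceiling, in nats, for near-collinear pairs.
#' @return Nonnegative scalar, the mutual information in nats.
#' @examples
#' set.seed(1)
#' a <- rnorm(100); b <- 0.8 * a + rnorm(100, sd = 0.6)
#' gaussian_mi(a, b)
#' @export
gaussian_mi <- function(x, y, cap = 50) {
  if (length(x) != length(y)) {
    stop("profiles have different lengths (", length(x), " vs ", length(y), ")")
  }
  if (length(x) < 3L) stop("need at least 3 samples to estimate MI")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 || vy == 0) {
    stop("mutual information undefined for a zero-variance profile")
  }
  det2 <- det(stats::cov(cbind(x, y)))
  det2 <- max(det2, 1e-300)
  mi <- 0.5 * log(vx * vy / det2)
  min(max(mi, 0), cap)
}

#' Pairwise Gaussian mutual information matrix
#'
#' Computes [gaussian_mi()] for every gene pair of an expression matrix
#' (or, when `regulators` is given, for every regulator-gene pair; other
#' entries are `NA`).  Constant genes cannot carry information: their rows
#' and columns are set to 0 with a warning rather than aborting the run.
#' The diagonal is `NA` (self-information is not meaningful here).
#'
#' @param expr Numeric matrix, genes in rows, samples in columns (at least
#'   3 samples), with gene identifiers as row names.
#' @param regulators Optional character vector restricting one side of each
#'   pair to a regulator set.
#' @param cap Passed to [gaussian_mi()].
#' @return Symmetric numeric matrix of MI values, gene x gene.
#' @export
mi_matrix <- function(expr, regulators = NULL, cap = 50) {
  expr <- as_expression(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples to estimate MI")
  genes <- rownames(expr)
  if (!is.null(regulators)) {
    missing <- setdiff(regulators, genes)
    if (length(missing) > 0L) {
      stop("regulator(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  sds <- apply(expr, 1L, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("constant gene(s) treated as MI 0: ",
            paste(genes[constant], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(t(expr)))
  r[constant, ] <- 0
  r[, constant] <- 0
  r2 <- pmin(r^2, 1 - 1e-300)
  mi <- -0.5 * log1p(-r2)
  mi <- pmin(pmax(mi, 0), cap)
  diag(mi) <- NA_real_
  if (!is.null(regulators)) {
    other <- setdiff(genes, regulators)
    mi[other, other] <- NA_real_
  }
  dimnames(mi) <- list(genes, genes)
  mi
}

#' Screening thresholds for the dependence classes
#'
#' The MI screen splits the candidate regulators of each target into
#' low-dependence (`MI < theta_low`, discarded), mid-dependence
#' (`theta_low <= MI < theta_high`, enter the regression) and
#' high-dependence (`MI >= theta_high`, enter the regression as protected
#' enhancement candidates).  The defaults 0.05 / 0.2 nats are the settings
#' used for small benchmark networks.
#'
#' @param theta_low Lower threshold (nats), nonnegative.
#' @param theta_high Upper threshold (nats), `>= theta_low`.
#' @export
screen_thresholds <- function(theta_low = 0.05, theta_high = 0.2) {
  stopifnot(is.numeric(theta_low), is.numeric(theta_high),
            length(theta_low) == 1L, length(theta_high) == 1L,
            theta_low >= 0, theta_high >= 0)
  if (theta_low > theta_high) {
    stop("theta_low (", theta_low, ") must not exceed theta_high (", theta_high, ")")
  }
  structure(list(theta_low = theta_low, theta_high = theta_high),
            class = "screen_thresholds")
}

#' Partition a target's candidate regulators by MI dependence
#'
#' Three-way split of the candidates of `target` using half-open intervals
#' `[0, theta_low)` (low), `[theta_low, theta_high)` (mid) and
#' `[theta_high, Inf)` (high).  `mid` and `high` together form the
#' regression candidate set; `high` alone forms the enhancement set.
#'
#' @param mi MI matrix from [mi_matrix()].
#' @param target Gene identifier present in `mi`.
#' @param thresholds A [screen_thresholds()] object.
#' @param candidates Optional character vector of allowed regulators
#'   (defaults to every other gene with a finite MI against `target`).
#' @return A `candidate_partition` list with elements `target`, `low`,
#'   `mid`, `high`.
#' @export
classify_candidates <- function(mi, target, thresholds = screen_thresholds(),
                                candidates = NULL) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  if (!target %in% rownames(mi)) stop("target '", target, "' not in MI matrix")
  if (is.null(candidates)) {
    candidates <- setdiff(rownames(mi), target)
  } else {
    candidates <- setdiff(candidates, target)
    missing <- setdiff(candidates, rownames(mi))
    if (length(missing) > 0L) {
      stop("candidate(s) not in MI matrix: ", paste(missing, collapse = ", "))
    }
  }
  v <- mi[candidates, target]
  v[is.na(v)] <- 0
  part <- list(
    target = target,
    low  = candidates[v < thresholds$theta_low],
    mid  = candidates[v >= thresholds$theta_low & v < thresholds$theta_high],
    high = candidates[v >= thresholds$theta_high]
  )
  structure(part, class = "candidate_partition")
}

#' Dump an MI matrix to TSV for inspection
#'
#' @param mi MI matrix from [mi_matrix()].
#' @param path Output path.
#' @export
write_mi_matrix <- function(mi, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(mi)), collapse = "\t"), con)
  for (i in seq_len(nrow(mi))) {
    writeLines(paste(c(rownames(mi)[i], num_fmt(mi[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}
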