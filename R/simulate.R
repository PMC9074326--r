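#' Configuration for the synthetic network/expression simulator
#'
#' Defaults mirror small-benchmark conditions: sparse directed networks
#' with average degree about 2 and additive expression noise with a
#' standard deviation equal to 10% of the signal standard deviation.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_regulators Number of genes allowed as edge sources (the first
#'   `n_regulators` gene identifiers).  Default: all genes.
#' @param avg_degree Target average out-degree; the expected edge count is
#'   `avg_degree * n_genes`.  Default 2.
#' @param n_samples Number of expression samples.  Default 20.
#' @param noise_fraction Additive noise level as a fraction of the
#'   noiseless signal standard deviation, per gene.  Default 0.10.
#' @param seed Integer seed; fixed seed gives bit-identical networks and
#'   expression.
#' @param universe Candidate-pair universe used downstream in evaluation:
#'   `"all_pairs"` (every ordered non-self pair) or
#'   `"regulator_restricted"` (sources limited to the regulator set).
#' @export
sim_config <- function(n_genes, n_regulators = n_genes, avg_degree = 2,
                       n_samples = 20L, noise_fraction = 0.10, seed = NULL,
                       universe = c("all_pairs", "regulator_restricted")) {
  stopifnot(n_genes >= 2, n_regulators >= 1, n_regulators <= n_genes,
            avg_degree >= 0, n_samples >= 1,
            noise_fraction >= 0, noise_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_regulators = as.integer(n_regulators),
                 avg_degree = avg_degree,
                 n_samples = as.integer(n_samples),
                 noise_fraction = noise_fraction,
                 seed = seed,
                 universe = match.arg(universe)),
            class = "sim_config")
}

#' Generate a sparse acyclic gold-standard network
#'
#' Genes are given a random topological rank; every ordered pair whose
#' source is a regulator and precedes its target in that rank is a
#' candidate edge, and candidates are sampled independently with a
#' probability chosen so the expected edge count is
#' `avg_degree * n_genes` (binomial edge count).  Edge weights are drawn
#' uniformly from `[-1, -0.3] U [0.3, 1]`: the magnitude floor keeps every
#' planted edge recoverable at small sample sizes, and acyclicity makes
#' feed-forward expression simulation well-defined.
#'
#' @param config A [sim_config()] object.
#' @return A `gold_network` list: `genes`, `regulators`, `edges` (data
#'   frame `regulator`, `target`, `weight`), and the topological `rank`
#'   used.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_genes
  genes <- paste0("G", seq_len(n))
  regulators <- genes[seq_len(config$n_regulators)]
  rank <- sample.int(n)          # position in topological order
  names(rank) <- genes
  # candidate pairs: regulator precedes target in topological rank
  reg_idx <- seq_len(config$n_regulators)
  src <- rep(reg_idx, each = n)
  tgt <- rep(seq_len(n), times = config$n_regulators)
  ok <- rank[src] < rank[tgt]
  src <- src[ok]; tgt <- tgt[ok]
  n_cand <- length(src)
  target_edges <- config$avg_degree * n
  if (target_edges == 0 || n_cand == 0L) {
    edges <- data.frame(regulator = character(0), target = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(genes = genes, regulators = regulators,
                          edges = edges, rank = rank),
                     class = "gold_network"))
  }
  p <- target_edges / n_cand
  if (p > 1) {
    stop("avg_degree ", config$avg_degree, " is too large: only ", n_cand,
         " candidate pairs are compatible with acyclicity")
  }
  keep <- stats::runif(n_cand) < p
  src <- src[keep]; tgt <- tgt[keep]
  w <- stats::runif(length(src), 0.3, 1) * sample(c(-1, 1), length(src),
                                                 replace = TRUE)
  edges <- data.frame(regulator = genes[src], target = genes[tgt],
                      weight = w, stringsAsFactors = FALSE)
  structure(list(genes = genes, regulators = regulators, edges = edges,
                 rank = rank),
            class = "gold_network")
}

#' Simulate expression data from a gold-standard network
#'
#' Linear Gaussian feed-forward model: genes without parents are drawn
#' i.i.d. standard normal per sample; each other gene, visited in
#' topological order, is the weighted sum of its parents plus additive
#' Gaussian noise whose standard deviation is
#' `noise_fraction * sd(noiseless signal)` for that gene.  Fails with a
#' named cycle if the network is not acyclic.
#'
#' @param net A `gold_network` (or any list with `genes` and an `edges`
#'   data frame with `regulator`, `target`, `weight`).
#' @param config A [sim_config()] object (uses `n_samples`,
#'   `noise_fraction`, `seed`).
#' @return Numeric matrix, genes x samples, gene identifiers as row names.
#' @export
simulate_expression <- function(net, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- net$genes
  edges <- net$edges
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target")], directed = TRUE,
    vertices = data.frame(name = genes))
  if (!igraph::is_dag(g)) {
    cyc <- igraph::girth(g)$circle
    stop("network contains a cycle: ",
         paste(names(cyc), collapse = " -> "))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  ord <- names(igraph::topo_sort(g, mode = "out"))
  n_s <- config$n_samples
  expr <- matrix(0, nrow = length(genes), ncol = n_s,
                 dimnames = list(genes, paste0("S", seq_len(n_s))))
  parents <- split(seq_len(nrow(edges)), edges$target)
  for (gname in ord) {
    pe <- parents[[gname]]
    if (is.null(pe)) {
      expr[gname, ] <- stats::rnorm(n_s)
    } else {
      signal <- drop(edges$weight[pe] %*% expr[edges$regulator[pe], , drop = FALSE])
      noise_sd <- config$noise_fraction * stats::sd(signal)
      if (!is.finite(noise_sd)) noise_sd <- 0
      expr[gname, ] <- signal + stats::rnorm(n_s, sd = noise_sd)
    }
  }
  expr
}

#' Canonical planted-regulator test case
#'
#' Builds the canonical one-target fixture used throughout testing: a
#' target gene `G` with three direct regulators (`R1`-`R3`, true parents),
#' three indirect regulators (`R4`-`R6`, each acting on the target only
#' through one direct regulator), and four noise regulators (`R7`-`R10`,
#' independent of everything).  A correct inference keeps exactly the
#' three direct edges into the target and filters out the indirect and
#' noise regulators.
#'
#' @param n_samples Number of simulated samples.  Default 50.
#' @param noise_fraction Additive noise level.  Default 0.10.
#' @param seed Integer seed.  Default 1.
#' @return A list with `network` (`gold_network`) and `expr` (expression
#'   matrix).
#' @export
planted_regulator_case <- function(n_samples = 50L, noise_fraction = 0.10,
                                   seed = 1L) {
  genes <- c("G", paste0("R", 1:10))
  direct <- paste0("R", 1:3)
  indirect <- paste0("R", 4:6)
  edges <- rbind(
    data.frame(regulator = direct, target = "G",
               weight = c(0.8, -0.7, 0.6), stringsAsFactors = FALSE),
    data.frame(regulator = indirect, target = direct,
               weight = c(0.9, 0.8, -0.85), stringsAsFactors = FALSE)
  )
  rank <- stats::setNames(c(11L, 4:6, 1:3, 7:10), genes)
  net <- structure(list(genes = genes, regulators = paste0("R", 1:10),
                        edges = edges, rank = rank),
                   class = "gold_network")
  cfg <- sim_config(n_genes = length(genes), n_samples = n_samples,
                    noise_fraction = noise_fraction, seed = seed)
  list(network = net, expr = simulate_expression(net, cfg))
}
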