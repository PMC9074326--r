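#' Read a gene expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample identifiers and
#' a first column of gene identifiers (genes in rows, samples in columns).
#' Lines starting with `#` are ignored.  Parsing is strict: duplicate gene
#' identifiers, ragged rows and non-numeric cells are rejected with the
#' offending location rather than coerced.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines$fields) < 2L) {
    stop("expression file '", path, "' needs a header line and at least one gene row")
  }
  header <- lines$fields[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) {
    stop("expression file '", path, "' header has no sample columns (line ",
         lines$lineno[1L], ")")
  }
  n_col <- length(header)
  body <- lines$fields[-1L]
  body_lineno <- lines$lineno[-1L]
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != n_col) {
      stop("expression file '", path, "' line ", body_lineno[i], ": expected ",
           n_col, " fields, found ", length(f))
    }
    gene_ids[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("expression file '", path, "' line ", body_lineno[i], ", column ",
           bad + 1L, ": non-numeric value '", f[bad + 1L], "'")
    }
    values[i, ] <- v
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop("expression file '", path, "' has duplicate gene identifier(s): ",
         paste(unique(dup), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop("expression file '", path, "' contains non-finite values")
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  values
}

#' Write a gene expression matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene`, then one column per
#' sample.  Values are written with full precision so a read/write round
#' trip is lossless.
#'
#' @param expr Numeric matrix, genes in rows (row names required).
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  expr <- as_expression(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  for (i in seq_len(nrow(expr))) {
    writeLines(paste(c(rownames(expr)[i], num_fmt(expr[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a 3-column edge list
#'
#' Parses DREAM-style edge lists: `regulator TAB target TAB value`, where
#' value is 0/1 for gold standards or a real score for predictions.
#' Duplicate ordered pairs are an error; self-edges are dropped with a
#' warning.  Comment lines (`#`) are ignored.
#'
#' @param path Path to a TSV edge list.
#' @return A data frame with columns `regulator`, `target`, `value`.
#' @export
read_edge_list <- function(path) {
  lines <- read_tsv_lines(path)
  n <- length(lines$fields)
  reg <- character(n); tgt <- character(n); val <- numeric(n)
  for (i in seq_len(n)) {
    f <- lines$fields[[i]]
    if (length(f) != 3L) {
      stop("edge list '", path, "' line ", lines$lineno[i], ": expected 3 ",
           "tab-separated columns, found ", length(f))
    }
    v <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(v)) {
      stop("edge list '", path, "' line ", lines$lineno[i],
           ": non-numeric value '", f[3L], "'")
    }
    reg[i] <- f[1L]; tgt[i] <- f[2L]; val[i] <- v
  }
  edges <- data.frame(regulator = reg, target = tgt, value = val,
                      stringsAsFactors = FALSE)
  self <- edges$regulator == edges$target
  if (any(self)) {
    warning("edge list '", path, "': dropped ", sum(self), " self-edge(s)")
    edges <- edges[!self, , drop = FALSE]
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1L, ]
    stop("edge list '", path, "' has duplicate pair ", d$regulator, " -> ", d$target)
  }
  rownames(edges) <- NULL
  edges
}

#' Write a weighted network as a ranked edge list
#'
#' Writes `regulator TAB target TAB strength` (or the extended 5-column
#' form adding `beta` and `mi`), sorted by strength descending with
#' lexicographic `(regulator, target)` tie-breaking so output is
#' bit-reproducible.  The column header is written as a `#` comment line,
#' keeping the file readable by DREAM-style edge-list parsers.
#'
#' @param net A `weighted_network` data frame as returned by
#'   [infer_network()], or any data frame with `regulator`, `target`,
#'   `strength` columns.
#' @param path Output path.
#' @param extended Write the 5-column form with `beta` and `mi`.
#' @param min_strength Optional filter: drop edges with strength strictly
#'   below this value before writing.
#' @export
write_network <- function(net, path, extended = FALSE, min_strength = NULL) {
  stopifnot(is.data.frame(net),
            all(c("regulator", "target", "strength") %in% names(net)))
  if (!is.null(min_strength)) {
    net <- net[net$strength >= min_strength, , drop = FALSE]
  }
  net <- sort_edges(net)
  cols <- c("regulator", "target", "strength")
  if (extended) cols <- c(cols, intersect(c("beta", "mi"), names(net)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(net) > 0L) {
    rows <- vapply(seq_len(nrow(net)), function(i) {
      vals <- vapply(cols, function(cn) {
        x <- net[[cn]][i]
        if (is.numeric(x)) num_fmt(x) else as.character(x)
      }, character(1L))
      paste(vals, collapse = "\t")
    }, character(1L))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write a gold-standard network as a DREAM-style edge list
#'
#' One line per true edge: `regulator TAB target TAB 1`.
#'
#' @param net A `gold_network` (see [generate_network()]).
#' @param path Output path.
#' @export
write_gold <- function(net, path) {
  stopifnot(inherits(net, "gold_network"))
  e <- net$edges
  ord <- order(e$regulator, e$target)
  e <- e[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(e) > 0L) {
    writeLines(paste(e$regulator, e$target, "1", sep = "\t"), con)
  }
  invisible(path)
}

# strength desc, then regulator, then target (C collation for stability)
sort_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  ord <- order(-edges$strength, edges$regulator, edges$target)
  out <- edges[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  raw <- readLines(path)
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(fields = strsplit(raw[keep], "\t", fixed = TRUE), lineno = lineno[keep])
}

num_fmt <- function(x) formatC(x, format = "g", digits = 17)

as_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr))) {
    stop("expression matrix must have gene identifiers as row names")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  }
  expr
}
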