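#' Rank genes by expression variance
#'
#' Computes the per-gene variance across samples and orders genes by
#' decreasing variance. Ties are broken by lexicographic gene identifier so
#' the ranking is deterministic. Genes with zero variance are placed last and
#' flagged; their log-variance is undefined (NA).
#'
#' @param layer An `expression_layer`.
#' @return A `variance_curve`: data.frame with columns `gene`, `variance`,
#'   `log_variance` (log10), `zero_variance`, ordered by rank.
#' @export
rank_variances <- function(layer) {
  stopifnot(inherits(layer, "expression_layer"))
  if (length(layer$samples) < 2) stop("variance needs at least 2 samples")
  v <- apply(layer$values, 1, stats::var)
  if (all(v == 0)) stop("all genes are constant; nothing to rank")
  ord <- order(-v, layer$genes)
  curve <- data.frame(gene = layer$genes[ord], variance = v[ord],
                      log_variance = ifelse(v[ord] > 0, log10(v[ord]), NA_real_),
                      zero_variance = v[ord] == 0,
                      stringsAsFactors = FALSE, row.names = NULL)
  class(curve) <- c("variance_curve", "data.frame")
  curve
}

#' Suggest a top-variant gene count from the ranked log-variance curve
#'
#' Data-driven guide for the variance filter: the ranked log10-variance curve
#' is smoothed with a centered moving average (window
#' `max(5, 1%% of genes)`, forced odd) and the rank maximizing the magnitude
#' of the discrete second difference of the smoothed curve — the sharpest
#' bend, i.e. the dominant inflection — is suggested as the number of genes
#' to keep. All local inflections (local maxima of the second-difference
#' magnitude) are reported so the user can pick a different elbow.
#'
#' The suggestion is scale-equivariant: rescaling all variances by a positive
#' constant shifts the log curve without moving its inflections.
#'
#' @param curve A `variance_curve` from [rank_variances()].
#' @param window Smoothing window; `NULL` uses the default above.
#' @return List with `suggestion` (integer rank), `inflections` (integer
#'   vector of local-inflection ranks, ascending) and `window`.
#' @export
suggest_topvar <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "variance_curve"))
  y <- curve$log_variance[!curve$zero_variance]
  n <- length(y)
  if (is.null(window)) window <- max(5L, ceiling(0.01 * n))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < window + 2L) {
    warning("curve shorter than smoother window; falling back to full length")
    return(list(suggestion = nrow(curve), inflections = integer(0), window = window))
  }
  sm <- stats::filter(y, rep(1 / window, window), sides = 2)
  valid <- which(!is.na(sm))
  s <- as.numeric(sm[valid])
  d2 <- diff(s, differences = 2)           # d2[i] belongs to rank valid[i + 1]
  mag <- abs(d2)
  tol <- 1e-10 * max(1, max(abs(s)))
  if (max(mag) <= tol) {
    warning("no inflection detected (curve is linear); falling back to full length")
    return(list(suggestion = nrow(curve), inflections = integer(0), window = window))
  }
  is_peak <- vapply(seq_along(mag), function(i) {
    left <- if (i > 1) mag[i - 1] else -Inf
    right <- if (i < length(mag)) mag[i + 1] else -Inf
    mag[i] > tol && mag[i] >= left && mag[i] >= right
  }, logical(1))
  inflections <- valid[which(is_peak) + 1L]
  suggestion <- valid[which.max(mag) + 1L]
  list(suggestion = as.integer(suggestion),
       inflections = as.integer(sort(inflections)),
       window = window)
}

#' Keep the n most variant genes of a layer
#'
#' The variance filter of the pre-integration phase; the count can be set
#' per layer independently, or the step skipped by passing the full gene
#' count. Ties at the boundary rank are resolved by lexicographic gene
#' identifier (the ordering of [rank_variances()]).
#'
#' @param layer An `expression_layer`.
#' @param n Number of genes to keep, `1 <= n <=` gene count.
#' @return A new `expression_layer` restricted to the selected genes, samples
#'   unchanged.
#' @export
filter_top_variant <- function(layer, n) {
  stopifnot(inherits(layer, "expression_layer"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > length(layer$genes))
    stop("n must be in [1, ", length(layer$genes), "], got ", n)
  keep <- rank_variances(layer)$gene[seq_len(n)]
  if (n == 1L) {
    # single-gene result cannot satisfy the layer constructor; return the
    # gene directly as a 1-row matrix wrapper
    vals <- layer$values[keep, , drop = FALSE]
    return(structure(list(name = layer$name, genes = keep,
                          samples = layer$samples, values = vals),
                     class = "expression_layer"))
  }
  expression_layer(layer$values[keep, , drop = FALSE], name = layer$name)
}

#' Pairwise gene-gene correlations of a layer
#'
#' Computes the full symmetric matrix of pairwise Pearson or Spearman
#' correlation coefficients across samples. Spearman uses average ranks for
#' ties. Constant genes have undefined correlations and carry the NA marker;
#' they never enter a network.
#'
#' @param layer An `expression_layer`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_result`: list with `genes`, `method` and the
#'   symmetric `matrix` (diagonal NA: self-pairs are excluded).
#' @export
compute_correlations <- function(layer, method = c("pearson", "spearman")) {
  stopifnot(inherits(layer, "expression_layer"))
  method <- match.arg(method)
  if (length(layer$samples) < 2) stop("correlation needs at least 2 samples")
  m <- suppressWarnings(stats::cor(t(layer$values), method = method))
  diag(m) <- NA_real_
  correlation_result(m, method = method, genes = layer$genes)
}

#' Wrap a precomputed correlation matrix
#'
#' Accepts correlation values computed elsewhere (e.g. by another tool) for
#' use in cutoff statistics and network construction.
#'
#' @param matrix Symmetric numeric matrix with gene identifiers as dimnames;
#'   values in `[-1, 1]` or NA.
#' @param method Label recorded as the method (default `"precomputed"`).
#' @param genes Optional gene vector; defaults to the matrix rownames.
#' @return A `correlation_result`.
#' @export
correlation_result <- function(matrix, method = "precomputed", genes = NULL) {
  if (is.null(genes)) genes <- rownames(matrix)
  if (is.null(genes)) stop("correlation matrix needs gene dimnames")
  if (nrow(matrix) != ncol(matrix)) stop("correlation matrix must be square")
  offdiag <- matrix[upper.tri(matrix)]
  if (any(abs(offdiag) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation values outside [-1, 1]")
  if (!isTRUE(all.equal(matrix[upper.tri(matrix)], t(matrix)[upper.tri(matrix)],
                        tolerance = 1e-12, check.attributes = FALSE)))
    stop("correlation matrix is not symmetric")
  diag(matrix) <- NA_real_
  dimnames(matrix) <- list(genes, genes)
  structure(list(genes = genes, method = method, matrix = matrix),
            class = "correlation_result")
}

#' Default correlation-cutoff grid
#'
#' 50 evenly spaced candidate cutoffs spanning 0.9 to 1.0, the working range
#' for thresholding strong positive co-expression.
#'
#' @return Ascending numeric vector of length 50.
#' @export
default_cutoff_grid <- function() seq(0.9, 1.0, length.out = 50)

#' Cutoff-selection guide statistics
#'
#' For each candidate cutoff, forms the graph whose edges are gene pairs with
#' correlation coefficient `>=` cutoff (the threshold is inclusive and is
#' applied to the signed coefficient: only positive co-expression forms
#' edges) and records four criteria: the scale-free-topology fit R-squared of
#' the logged node-degree distribution, the number of edges, the number of
#' non-isolated nodes, and the number of connected components. Edge and node
#' counts are monotone non-increasing along the ascending grid because the
#' thresholded edge sets are nested.
#'
#' @param corr A `correlation_result`.
#' @param cutoffs Ascending candidate thresholds in `(0, 1]`; default
#'   [default_cutoff_grid()].
#' @return A `cutoff_statistics` data.frame with columns `cutoff`,
#'   `r_squared`, `n_edges`, `n_nodes`, `n_components`.
#' @export
cutoff_statistics <- function(corr, cutoffs = default_cutoff_grid()) {
  stopifnot(inherits(corr, "correlation_result"))
  if (length(cutoffs) == 0) stop("cutoff list is empty")
  if (any(cutoffs <= 0 | cutoffs > 1)) stop("cutoffs must lie in (0, 1]")
  if (is.unsorted(cutoffs, strictly = FALSE)) cutoffs <- sort(cutoffs)
  ut <- which(upper.tri(corr$matrix), arr.ind = TRUE)
  w <- corr$matrix[ut]
  keep <- !is.na(w) & w >= min(cutoffs)
  ut <- ut[keep, , drop = FALSE]
  w <- w[keep]
  rows <- lapply(cutoffs, function(ct) {
    sel <- w >= ct
    i <- ut[sel, 1]; j <- ut[sel, 2]
    n_edges <- sum(sel)
    if (n_edges == 0) {
      return(data.frame(cutoff = ct, r_squared = NA_real_, n_edges = 0L,
                        n_nodes = 0L, n_components = 0L))
    }
    ids <- c(i, j)
    deg <- table(ids)
    g <- igraph::graph_from_edgelist(cbind(as.character(i), as.character(j)),
                                     directed = FALSE)
    data.frame(cutoff = ct,
               r_squared = degree_distribution_r2(as.integer(deg)),
               n_edges = as.integer(n_edges),
               n_nodes = length(deg),
               n_components = igraph::components(g)$no)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_statistics", "data.frame")
  out
}

#' Scale-free-topology fit of a degree distribution
#'
#' Least-squares fit of `log10(frequency)` on `log10(degree)` over the
#' distinct positive degrees (raw frequencies per distinct degree, not binned;
#' isolated nodes excluded). Returns the coefficient of determination of that
#' fit — near 1 indicates a power-law-like, scale-free degree distribution.
#' With fewer than 2 distinct positive degrees the fit is undefined and NA is
#' returned.
#'
#' @param degrees Integer vector of node degrees (a multiset).
#' @return R-squared in `[0, 1]`, or NA when undefined.
#' @export
degree_distribution_r2 <- function(degrees) {
  if (length(degrees) == 0) stop("empty degree list")
  degrees <- degrees[degrees > 0]
  if (length(degrees) == 0) stop("no node with degree >= 1")
  tab <- table(degrees)
  if (length(tab) < 2) return(NA_real_)
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  if (stats::var(y) == 0) return(1)  # flat log-frequency: horizontal line fits exactly
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Heuristic cutoff choice from guide statistics
#'
#' Convenience default only — the guide table is the primary product and the
#' cutoff is normally chosen by the user. Among cutoffs retaining at least
#' `min_nodes` non-isolated genes, picks the one maximizing the
#' scale-free-topology R-squared (ties: the larger cutoff, i.e. the sparser
#' network). If no cutoff in that range has a defined R-squared, the largest
#' qualifying cutoff is returned.
#'
#' @param stats A `cutoff_statistics` table.
#' @param min_nodes Minimum acceptable node count; default one third of the
#'   largest node count seen on the grid.
#' @return A single cutoff value.
#' @export
select_cutoff <- function(stats, min_nodes = NULL) {
  stopifnot(inherits(stats, "cutoff_statistics"))
  if (is.null(min_nodes)) min_nodes <- max(stats$n_nodes) / 3
  cand <- stats[stats$n_nodes >= min_nodes & stats$n_edges > 0, , drop = FALSE]
  if (nrow(cand) == 0) stop("no cutoff retains min_nodes = ", min_nodes, " genes")
  defined <- cand[!is.na(cand$r_squared), , drop = FALSE]
  if (nrow(defined) == 0) return(max(cand$cutoff))
  best <- defined[defined$r_squared == max(defined$r_squared), , drop = FALSE]
  max(best$cutoff)
}

#' Write the cutoff guide table as TSV
#'
#' @param stats A `cutoff_statistics` table.
#' @param path Output path.
#' @export
write_cutoff_statistics <- function(stats, path) {
  stopifnot(inherits(stats, "cutoff_statistics"))
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
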