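# Fixed label palette: standard colour names assigned to modules by
# descending size, for human-readable module identities across runs.
module_color_names <- c(
  "lightblue", "gold", "wheat", "orchid", "plum", "lightgreen", "turquoise",
  "darkorange", "steelblue", "maroon", "darkgreen", "indianred", "khaki",
  "salmon", "seagreen", "sienna", "slateblue", "tan", "tomato", "violet",
  "yellowgreen", "aquamarine", "coral", "cornflowerblue", "darkgoldenrod",
  "darkkhaki", "darkmagenta", "darkolivegreen", "darksalmon", "darkseagreen",
  "darkslateblue", "darkturquoise", "deeppink", "deepskyblue", "firebrick",
  "forestgreen", "hotpink", "lightcoral", "lightpink", "lightsalmon",
  "lightseagreen", "lightskyblue", "mediumorchid", "mediumpurple",
  "mediumseagreen", "olivedrab", "palegreen", "peru", "rosybrown",
  "royalblue", "saddlebrown", "sandybrown", "skyblue", "springgreen",
  "thistle", "navy", "chocolate", "crimson", "dodgerblue", "goldenrod"
)

supported_algorithms <- c("leiden", "louvain", "fast_greedy",
                          "edge_betweenness", "walktrap", "infomap")

#' Detect co-expression modules by community detection
#'
#' Partitions the network's genes into modules (communities of genes with
#' similar expression patterns) by maximizing weighted modularity. The
#' default algorithm is Leiden at resolution 1.0; Louvain, fast-greedy,
#' edge-betweenness, walktrap and infomap are available alternatives. All
#' stochastic algorithms are run under the given seed and the seed is
#' recorded in the partition, so the same input and seed always reproduce
#' the same assignment.
#'
#' Module labels are colour names drawn from a fixed list, assigned by
#' descending module size (ties broken by the lexicographically smallest
#' member gene); modules beyond the list get `module_<k>` labels.
#'
#' @param network A non-empty `coexpression_network`.
#' @param algorithm One of `"leiden"`, `"louvain"`, `"fast_greedy"`,
#'   `"edge_betweenness"`, `"walktrap"`, `"infomap"`.
#' @param resolution Resolution parameter (Leiden/Louvain only), default 1.0.
#' @param seed Integer RNG seed, default 1.
#' @return A `module_partition`: list with `assignment` (named character
#'   vector gene -> label), `unassigned` (character vector), `sizes` (named
#'   integer vector, descending), and provenance (`algorithm`, `resolution`,
#'   `seed`, `min_size`).
#' @export
detect_modules <- function(network, algorithm = "leiden", resolution = 1.0,
                           seed = 1L) {
  stopifnot(inherits(network, "coexpression_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("cannot cluster an empty network")
  if (!algorithm %in% supported_algorithms)
    stop("unknown algorithm '", algorithm, "'; options: ",
         paste(supported_algorithms, collapse = ", "))
  w <- igraph::E(g)$weight
  comm <- with_seed(seed, switch(
    algorithm,
    leiden = igraph::cluster_leiden(g, objective_function = "modularity",
                                    weights = w, resolution = resolution,
                                    n_iterations = 10),
    louvain = igraph::cluster_louvain(g, weights = w, resolution = resolution),
    fast_greedy = igraph::cluster_fast_greedy(g, weights = w),
    edge_betweenness = igraph::cluster_edge_betweenness(g, weights = w),
    walktrap = igraph::cluster_walktrap(g, weights = w),
    infomap = igraph::cluster_infomap(g, e.weights = w)
  ))
  membership <- igraph::membership(comm)
  label_partition(split(igraph::V(g)$name, membership),
                  algorithm = algorithm, resolution = resolution, seed = seed)
}

# Assign deterministic colour-name labels to a list of gene groups, ordered
# by descending size then by smallest member gene.
label_partition <- function(groups, algorithm, resolution, seed,
                            unassigned = character(0), min_size = 1L) {
  groups <- lapply(groups, sort)
  if (length(groups) > 0) {
    first_gene <- vapply(groups, `[`, character(1), 1)
    ord <- order(-vapply(groups, length, integer(1)), first_gene)
    groups <- groups[ord]
    labels <- if (length(groups) <= length(module_color_names))
      module_color_names[seq_along(groups)]
    else c(module_color_names,
           paste0("module_", seq(length(module_color_names) + 1, length(groups))))[seq_along(groups)]
    names(groups) <- labels
  }
  assignment <- stats::setNames(rep(names(groups), lengths(groups)),
                                unlist(groups, use.names = FALSE))
  sizes <- stats::setNames(lengths(groups), names(groups))
  structure(list(assignment = assignment, unassigned = sort(unassigned),
                 sizes = sizes, algorithm = algorithm,
                 resolution = resolution, seed = seed, min_size = min_size),
            class = "module_partition")
}

#' Dissolve modules below a minimum size
#'
#' Modules smaller than `min_size` (default 25 genes) are dissolved and their
#' genes moved to the unassigned pool; surviving modules are relabelled by
#' descending size so labels always reflect the final size order.
#'
#' @param partition A `module_partition`.
#' @param min_size Minimum retained module size, default 25.
#' @return A filtered `module_partition`.
#' @export
filter_min_size <- function(partition, min_size = 25L) {
  stopifnot(inherits(partition, "module_partition"))
  min_size <- as.integer(min_size)
  if (min_size < 1L) stop("min_size must be >= 1")
  groups <- split(names(partition$assignment), partition$assignment)
  keep <- vapply(groups, length, integer(1)) >= min_size
  dropped <- unlist(groups[!keep], use.names = FALSE)
  label_partition(groups[keep], algorithm = partition$algorithm,
                  resolution = partition$resolution, seed = partition$seed,
                  unassigned = c(partition$unassigned, dropped),
                  min_size = min_size)
}

#' Genes of one module
#'
#' @param partition A `module_partition`.
#' @param module Module label.
#' @return Character vector of gene identifiers.
#' @export
module_genes <- function(partition, module) {
  stopifnot(inherits(partition, "module_partition"))
  if (!module %in% names(partition$sizes))
    stop("no module '", module, "'; available: ",
         paste(names(partition$sizes), collapse = ", "))
  sort(names(partition$assignment)[partition$assignment == module])
}

#' Summarize modules by mean GFC per layer and condition
#'
#' Builds the module x (layer, group) matrix behind the module heatmap: each
#' cell is the arithmetic mean of the defined GFC values of the module's
#' genes for that layer and group. Genes absent from a layer's GFC table, or
#' with an undefined (NA) GFC, contribute nothing to that layer's cells —
#' absence of measurement is not treated as absence of change. A cell with
#' no defined GFC at all carries the NA marker.
#'
#' @param partition A `module_partition`.
#' @param gfcs A single `gfc_table` or a list of them (one per layer).
#' @return A `module_summary`: list with `matrix` (modules x conditions,
#'   rows in size order, columns `<layer>.<group>`), `sizes`, and `columns`
#'   (data.frame mapping column -> layer, group).
#' @export
module_summary <- function(partition, gfcs) {
  stopifnot(inherits(partition, "module_partition"))
  if (inherits(gfcs, "gfc_table")) gfcs <- list(gfcs)
  lapply(gfcs, function(g) stopifnot(inherits(g, "gfc_table")))
  modules <- names(partition$sizes)
  if (length(modules) == 0) stop("partition has no modules to summarize")
  cols <- do.call(rbind, lapply(gfcs, function(g) {
    data.frame(layer = g$layer, group = colnames(g$values),
               stringsAsFactors = FALSE)
  }))
  cols$column <- paste(cols$layer, cols$group, sep = ".")
  mat <- matrix(NA_real_, nrow = length(modules), ncol = nrow(cols),
                dimnames = list(modules, cols$column))
  for (g in gfcs) {
    for (grp in colnames(g$values)) {
      cn <- paste(g$layer, grp, sep = ".")
      for (m in modules) {
        vals <- g$values[intersect(module_genes(partition, m),
                                   rownames(g$values)), grp]
        vals <- vals[!is.na(vals)]
        if (length(vals) > 0) mat[m, cn] <- mean(vals)
      }
    }
  }
  structure(list(matrix = mat, sizes = partition$sizes, columns = cols),
            class = "module_summary")
}

#' Order conditions by hierarchical clustering of mean-GFC profiles
#'
#' Agglomerative hierarchical clustering of the summary's condition columns
#' on the Euclidean distance between their module-mean-GFC profiles
#' (complete linkage by default). Undefined cells trigger pairwise-complete
#' distances with a warning. The leaf order is deterministic for a given
#' matrix.
#'
#' @param summary A `module_summary` with at least 2 columns.
#' @param linkage `stats::hclust` method, default `"complete"`.
#' @return List with `order` (column names, leaf order), `hclust` (the tree)
#'   and `linkage`.
#' @export
order_conditions <- function(summary, linkage = "complete") {
  stopifnot(inherits(summary, "module_summary"))
  mat <- summary$matrix
  if (ncol(mat) < 2) stop("need at least 2 condition columns to order")
  if (anyNA(mat))
    warning("undefined summary cells; using pairwise-complete distances")
  d <- stats::dist(t(mat))  # dist() rescales over pairwise-complete entries
  if (anyNA(d)) stop("condition pair with no common defined module; cannot order")
  hc <- stats::hclust(d, method = linkage)
  list(order = colnames(mat)[hc$order], hclust = hc, linkage = linkage)
}

#' Hub genes of a module
#'
#' Ranks the module's genes by a hub score computed on the module-induced
#' subgraph of the network. The default score is the weighted degree (sum of
#' incident edge weights within the module) — the simplest defensible notion
#' of a hub; unweighted degree and betweenness are exposed as alternatives.
#' Ties are broken by lexicographic gene identifier, so rankings are stable
#' across reruns.
#'
#' @param network A `coexpression_network`.
#' @param partition A `module_partition` over its genes.
#' @param module Module label.
#' @param k Number of top genes to return (`k >=` module size returns the
#'   whole module, ranked).
#' @param score `"weighted_degree"` (default), `"degree"` or `"betweenness"`.
#' @return data.frame with columns `gene`, `score`, `rank`.
#' @export
hub_genes <- function(network, partition, module, k = 10L,
                      score = c("weighted_degree", "degree", "betweenness")) {
  stopifnot(inherits(network, "coexpression_network"))
  score <- match.arg(score)
  if (k < 1) stop("k must be >= 1")
  genes <- module_genes(partition, module)
  sub <- igraph::induced_subgraph(network$graph,
                                  intersect(genes, network_nodes(network)))
  s <- switch(score,
              weighted_degree = igraph::strength(sub, weights = igraph::E(sub)$weight),
              degree = igraph::degree(sub),
              betweenness = igraph::betweenness(sub, weights = 1 / igraph::E(sub)$weight))
  nm <- igraph::V(sub)$name
  ord <- order(-s, nm)
  k <- min(as.integer(k), length(nm))
  data.frame(gene = nm[ord][seq_len(k)], score = unname(s[ord])[seq_len(k)],
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Write a module partition as TSV
#'
#' One row per gene: `gene`, `module` (label or `"unassigned"`). Rows are
#' sorted by module label then gene for byte-stable output.
#'
#' @param partition A `module_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  df <- data.frame(gene = c(names(partition$assignment), partition$unassigned),
                   module = c(unname(partition$assignment),
                              rep("unassigned", length(partition$unassigned))),
                   stringsAsFactors = FALSE)
  df <- df[order(df$module, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a module summary as long-format TSV
#'
#' Columns: `module`, `layer`, `group`, `mean_gfc`, `size`.
#'
#' @param summary A `module_summary`.
#' @param path Output path.
#' @export
write_module_summary <- function(summary, path) {
  stopifnot(inherits(summary, "module_summary"))
  cols <- summary$columns
  df <- do.call(rbind, lapply(rownames(summary$matrix), function(m) {
    data.frame(module = m, layer = cols$layer, group = cols$group,
               mean_gfc = summary$matrix[m, cols$column],
               size = unname(summary$sizes[m]), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", length(x$sizes), " module(s), ",
      length(x$assignment), " assigned / ", length(x$unassigned),
      " unassigned genes (", x$algorithm, ", resolution=", x$resolution,
      ", seed=", x$seed, ")\n", sep = "")
  invisible(x)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
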