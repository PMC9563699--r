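#' Build a co-expression network by thresholding correlations
#'
#' Edges are gene pairs whose signed correlation coefficient is greater than
#' or equal to the cutoff (inclusive: a pair exactly at the cutoff keeps its
#' edge; negative co-expression never forms an edge). Genes left without any
#' edge are dropped from the node set. Edge weights are the correlation
#' coefficients; per-layer provenance is stored on every edge so that
#' integrated networks remain queryable layer by layer.
#'
#' @param corr A `correlation_result`.
#' @param cutoff Minimum correlation in `(0, 1]` for a pair to form an edge.
#' @param name Layer name recorded in the provenance; defaults to the
#'   correlation's gene source if unnamed, `"layer"`.
#' @return A `coexpression_network`: list with the igraph `graph`, `origin`
#'   (`"single_layer"`), `layers` (names), and `policy` (NA pre-integration).
#' @export
build_network <- function(corr, cutoff, name = "layer") {
  stopifnot(inherits(corr, "correlation_result"))
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must be a single value in (0, 1]")
  ut <- which(upper.tri(corr$matrix), arr.ind = TRUE)
  w <- corr$matrix[ut]
  sel <- !is.na(w) & w >= cutoff
  edges <- data.frame(from = corr$genes[ut[sel, 1]],
                      to = corr$genes[ut[sel, 2]],
                      weight = w[sel], stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    warning("no gene pair reaches cutoff ", cutoff, "; network is empty")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges[[paste0("w_", name)]] <- edges$weight
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  structure(list(graph = g, origin = "single_layer", layers = name,
                 policy = NA_character_, reference = NULL),
            class = "coexpression_network")
}

#' Edge table of a co-expression network
#'
#' @param network A `coexpression_network`.
#' @return data.frame with `from`, `to`, resolved `weight` and one `w_<layer>`
#'   column per layer (NA where the edge is absent from that layer).
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  g <- network$graph
  if (igraph::ecount(g) == 0) {
    cols <- c("from", "to", "weight", paste0("w_", network$layers))
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  el <- igraph::as_edgelist(g)
  out <- data.frame(from = el[, 1], to = el[, 2],
                    weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  for (ly in network$layers) {
    at <- paste0("w_", ly)
    out[[at]] <- if (at %in% igraph::edge_attr_names(g))
      igraph::edge_attr(g, at) else NA_real_
  }
  out
}

#' Node (gene) set of a co-expression network
#'
#' @param network A `coexpression_network`.
#' @return Character vector of gene identifiers.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  igraph::V(network$graph)$name %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a multi-edge weight across layers
#'
#' An edge present in several layer networks carries one weight per layer;
#' the integrated edge gets the minimum, mean or maximum of those. The
#' default policy is minimum: it approximates the true co-expression by its
#' lower bound and thins the integrated network, which helps the subsequent
#' community detection. The mean is taken over the layers that contain the
#' edge only — absence from a layer is structural, never counted as weight 0.
#'
#' @param weights Named numeric vector, layer name -> weight; NAs (absent
#'   layers) are dropped.
#' @param policy `"min"`, `"mean"` or `"max"`.
#' @return The resolved weight.
#' @export
resolve_multiedge <- function(weights, policy = c("min", "mean", "max")) {
  policy <- match.arg(policy)
  weights <- weights[!is.na(weights)]
  if (length(weights) == 0) stop("no weights to resolve")
  switch(policy, min = min(weights), mean = mean(weights), max = max(weights))
}

# Collect the canonical (sorted-pair) edge tables of several networks into one
# wide table with a w_<layer> column per layer.
collect_layer_edges <- function(networks) {
  layer_names <- vapply(networks, function(n) n$layers[1], character(1))
  dup <- unique(layer_names[duplicated(layer_names)])
  if (length(dup) > 0) stop("duplicate layer name(s): ", paste(dup, collapse = ", "))
  tabs <- lapply(seq_along(networks), function(i) {
    e <- network_edges(networks[[i]])
    if (nrow(e) == 0)
      return(data.frame(a = character(0), b = character(0), w = numeric(0)))
    data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to), w = e$weight,
               stringsAsFactors = FALSE)
  })
  keys <- unique(unlist(lapply(tabs, function(t) paste(t$a, t$b, sep = "\r"))))
  wide <- matrix(NA_real_, nrow = length(keys), ncol = length(networks),
                 dimnames = list(keys, layer_names))
  for (i in seq_along(tabs)) {
    t <- tabs[[i]]
    if (nrow(t) > 0) wide[paste(t$a, t$b, sep = "\r"), i] <- t$w
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  list(a = vapply(parts, `[`, character(1), 1),
       b = vapply(parts, `[`, character(1), 2),
       weights = wide, layers = layer_names)
}

make_integrated <- function(a, b, weights, layers, policy, origin, reference = NULL) {
  resolved <- if (length(a) == 0) numeric(0)
              else apply(weights, 1, resolve_multiedge, policy = policy)
  edges <- data.frame(from = a, to = b, weight = resolved,
                      stringsAsFactors = FALSE)
  for (ly in layers) edges[[paste0("w_", ly)]] <- weights[, ly]
  g <- if (nrow(edges) == 0) igraph::make_empty_graph(0, directed = FALSE)
       else igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g, origin = origin, layers = layers,
                 policy = policy, reference = reference),
            class = "coexpression_network")
}

#' Integrate layer networks by union
#'
#' The integrated node set is the union of the layer node sets and the edge
#' set the union of the layer edge sets, so co-expression unique to a single
#' layer is retained alongside shared co-expression. Edges present in
#' several layers keep their full per-layer provenance and get a single
#' resolved weight via [resolve_multiedge()]. The union is commutative and
#' associative at the edge-set level, and the mean policy is computed over
#' all layers at once, so the result does not depend on layer order.
#'
#' @param networks List of two or more single-layer `coexpression_network`s
#'   over the same gene namespace (exact identifier matching).
#' @param policy Multi-edge weight policy, default `"min"`.
#' @return An integrated `coexpression_network` with `origin = "union"`.
#' @export
integrate_union <- function(networks, policy = c("min", "mean", "max")) {
  policy <- match.arg(policy)
  if (length(networks) < 2) stop("union integration needs at least 2 networks")
  lapply(networks, function(n) stopifnot(inherits(n, "coexpression_network")))
  ce <- collect_layer_edges(networks)
  make_integrated(ce$a, ce$b, ce$weights, ce$layers, policy, "union")
}

#' Integrate layer networks against a reference
#'
#' One layer's network serves as the reference: the integrated node and edge
#' sets are exactly the reference's, and every reference edge is annotated
#' with its presence and weight in each other layer, so the analysis can ask
#' how the reference co-expression changes elsewhere. Resolved weights are
#' recomputed by policy over the layers that contain the edge (the per-layer
#' provenance keeps the reference's own weight available).
#'
#' @param networks List of single-layer `coexpression_network`s.
#' @param reference Layer name of the reference network.
#' @param policy Multi-edge weight policy, default `"min"`.
#' @return An integrated `coexpression_network` with `origin = "intersection"`.
#' @export
integrate_intersection <- function(networks, reference,
                                   policy = c("min", "mean", "max")) {
  policy <- match.arg(policy)
  if (length(networks) < 2) stop("intersection integration needs at least 2 networks")
  lapply(networks, function(n) stopifnot(inherits(n, "coexpression_network")))
  ce <- collect_layer_edges(networks)
  if (!reference %in% ce$layers)
    stop("reference '", reference, "' is not among the layers: ",
         paste(ce$layers, collapse = ", "))
  keep <- !is.na(ce$weights[, reference])
  make_integrated(ce$a[keep], ce$b[keep],
                  ce$weights[keep, , drop = FALSE], ce$layers, policy,
                  "intersection", reference = reference)
}

#' Export a network as a Cytoscape-ready edge-list TSV
#'
#' Columns: `gene1`, `gene2`, resolved `weight`, then one column per layer
#' with that layer's original weight (empty where absent).
#'
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  e <- network_edges(network)
  names(e)[1:2] <- c("gene1", "gene2")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry the gene identifier (and, if a partition has been attached via
#' `module` vertex attribute, the module label); edges carry the resolved
#' weight plus one attribute per layer weight. The file imports directly into
#' Cytoscape.
#'
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @param partition Optional `module_partition`; when given, each node gets a
#'   `module` attribute (label or `"unassigned"`).
#' @export
write_graphml <- function(network, path, partition = NULL) {
  stopifnot(inherits(network, "coexpression_network"))
  g <- network$graph
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "module_partition"))
    lab <- partition$assignment[igraph::V(g)$name]
    lab[is.na(lab)] <- "unassigned"
    g <- igraph::set_vertex_attr(g, "module", value = unname(lab))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back
#'
#' Round-trip companion to [write_graphml()] for re-importing exported
#' networks (origin and policy metadata are not stored in GraphML and are
#' recorded as `"imported"`).
#'
#' @param path GraphML file path.
#' @return A `coexpression_network`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # strip the id attribute graphml import adds
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  layers <- sub("^w_", "", grep("^w_", igraph::edge_attr_names(g), value = TRUE))
  structure(list(graph = g, origin = "imported",
                 layers = if (length(layers)) layers else "imported",
                 policy = NA_character_, reference = NULL),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("<coexpression_network> origin=", x$origin,
      " layers=[", paste(x$layers, collapse = ", "), "] ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  invisible(x)
}
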