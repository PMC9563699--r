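#' Over-representation of gene sets in one module
#'
#' One-sided hypergeometric upper-tail test per gene set: with a universe of
#' N genes of which K belong to the set and a module of n universe genes
#' showing an overlap of k with the set, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Both the module and every
#' set are intersected with the universe before testing, so genes outside
#' the universe can neither help nor hurt a term. An overlap of 0 gives
#' p = 1 exactly. Only over-representation is tested (no depletion).
#'
#' Benjamini-Hochberg adjustment is applied across all sets of the
#' collection for this one module (see [enrich_modules()] for the per-module
#' scope across a partition).
#'
#' @param genes Character vector: the module's genes.
#' @param collection A `gene_set_collection`.
#' @param universe Character vector of background genes (non-empty). The
#'   recommended default in this workflow is the node set of the integrated
#'   network — the object being interpreted.
#' @param module Label recorded in the `module` column.
#' @return An `enrichment_result` data.frame with columns `module`, `set`,
#'   `overlap`, `module_size`, `set_size`, `universe_size`, `p_value`,
#'   `p_adjusted` (plus attribute `source`, the collection provenance).
#' @export
over_representation <- function(genes, collection, universe,
                                module = "module") {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe is empty")
  m <- intersect(unique(genes), universe)
  if (length(m) == 0)
    warning("module '", module, "' shares no genes with the universe; all p = 1")
  N <- length(universe)
  n <- length(m)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(m, s))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(module = module, set = nm, overlap = k, module_size = n,
               set_size = K, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_bh(out$p_value)
  attr(out, "source") <- collection$source
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate control for a vector of p-values; adjusted values
#' are capped at 1 and monotone in the p-value ranks.
#'
#' @param p_values Numeric vector with values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Enrich every module of a partition against a collection
#'
#' Runs [over_representation()] per module; the BH adjustment scope is all
#' sets of the collection within each module, matching the per-module
#' top-term filtering applied downstream.
#'
#' @param partition A `module_partition`.
#' @param collection A `gene_set_collection`.
#' @param universe Background gene vector.
#' @return A combined `enrichment_result`.
#' @export
enrich_modules <- function(partition, collection, universe) {
  stopifnot(inherits(partition, "module_partition"))
  out <- do.call(rbind, lapply(names(partition$sizes), function(m) {
    over_representation(module_genes(partition, m), collection, universe,
                        module = m)
  }))
  attr(out, "source") <- collection$source
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Top significant terms per module
#'
#' Per module, keeps the terms with adjusted p-value at most `alpha`
#' (default 0.1), then the `n` (default 5) smallest adjusted p-values. Ties
#' at the boundary are broken by the smaller raw p-value, then by
#' lexicographic set name. A module with no term passing the threshold is
#' absent from the output — no significantly enriched terms were found for
#' it.
#'
#' @param result An `enrichment_result`.
#' @param n Number of terms kept per module, default 5.
#' @param alpha Adjusted-p threshold, default 0.1.
#' @return A filtered `enrichment_result`.
#' @export
top_terms <- function(result, n = 5L, alpha = 0.1) {
  stopifnot(inherits(result, "enrichment_result"))
  if (n < 1) stop("n must be >= 1")
  keep <- result[result$p_adjusted <= alpha, , drop = FALSE]
  out <- do.call(rbind, lapply(split(keep, keep$module), function(df) {
    df <- df[order(df$p_adjusted, df$p_value, df$set), , drop = FALSE]
    utils::head(df, n)
  }))
  if (is.null(out))
    out <- result[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- attr(result, "source")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Transcription-factor target enrichment of modules
#'
#' Over-representation of TF-target gene sets (GMT collections keyed by TF
#' name) in each module, using exactly the machinery of
#' [over_representation()] — an offline test on user-supplied target
#' libraries; no web service is queried. TFs with no target in the universe
#' are dropped with a warning before testing. When the integrated network is
#' supplied, the result additionally reports, per (module, TF), which pairs
#' of that TF's targets are connected by an edge of the network (attribute
#' `target_edges`), supporting target-wiring displays.
#'
#' @param partition A `module_partition`.
#' @param tf_targets A `gene_set_collection` keyed by TF name.
#' @param universe Background gene vector.
#' @param network Optional integrated `coexpression_network`.
#' @return An `enrichment_result`; with `network`, attribute `target_edges`
#'   is a data.frame (`module`, `tf`, `gene1`, `gene2`, `weight`).
#' @export
tf_enrichment <- function(partition, tf_targets, universe, network = NULL) {
  stopifnot(inherits(tf_targets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  in_universe <- vapply(tf_targets$sets,
                        function(s) length(intersect(s, universe)) > 0,
                        logical(1))
  if (any(!in_universe)) {
    warning("dropping ", sum(!in_universe),
            " TF(s) with no target in the universe: ",
            paste(names(tf_targets$sets)[!in_universe], collapse = ", "))
    if (!any(in_universe)) stop("no TF has targets in the universe")
    tf_targets <- gene_set_collection(tf_targets$sets[in_universe],
                                      source = tf_targets$source)
  }
  out <- enrich_modules(partition, tf_targets, universe)
  if (!is.null(network)) {
    stopifnot(inherits(network, "coexpression_network"))
    edges <- network_edges(network)
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    te <- do.call(rbind, lapply(names(partition$sizes), function(m) {
      mg <- module_genes(partition, m)
      do.call(rbind, lapply(names(tf_targets$sets), function(tf) {
        tg <- intersect(tf_targets$sets[[tf]], mg)
        if (length(tg) < 2) return(NULL)
        pairs <- utils::combn(sort(tg), 2)
        pk <- paste(pairs[1, ], pairs[2, ])
        hit <- match(pk, key)
        found <- !is.na(hit)
        if (!any(found)) return(NULL)
        data.frame(module = m, tf = tf, gene1 = pairs[1, found],
                   gene2 = pairs[2, found], weight = edges$weight[hit[found]],
                   stringsAsFactors = FALSE)
      }))
    }))
    attr(out, "target_edges") <- te
  }
  out
}

#' Write an enrichment result as TSV
#'
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
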