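#' Per-group mean expression of every gene
#'
#' The condition groups are the distinct labels of the annotation's grouping
#' column; they partition the layer's samples into disjoint subsets. Group
#' means are plain arithmetic means of the expression values as given (the
#' package takes no position on linear vs log scale; means are computed on
#' the input scale and this is documented behaviour).
#'
#' @param layer An `expression_layer`.
#' @param annotation The layer's `annotation_table`.
#' @return A `group_means_table`: list with `layer`, `groups`, `control`
#'   (label or NULL) and `means` (gene x group matrix).
#' @export
group_means <- function(layer, annotation) {
  stopifnot(inherits(layer, "expression_layer"),
            inherits(annotation, "annotation_table"))
  if (!setequal(layer$samples, annotation$samples))
    stop("annotation samples do not match layer '", layer$name, "'")
  labels <- as.character(annotation$data[[annotation$grouping_column]])
  names(labels) <- annotation$samples
  labels <- labels[layer$samples]
  groups <- unique(labels)
  empty <- groups[!groups %in% labels]
  if (length(empty) > 0) stop("empty group(s): ", paste(empty, collapse = ", "))
  means <- vapply(groups, function(g) {
    rowMeans(layer$values[, labels == g, drop = FALSE])
  }, numeric(length(layer$genes)))
  means <- matrix(means, nrow = length(layer$genes),
                  dimnames = list(layer$genes, groups))
  structure(list(layer = layer$name, groups = groups,
                 control = annotation$control_label, means = means),
            class = "group_means_table")
}

#' Group Fold-Changes without control samples
#'
#' For a gene g with group means `m_g(x_1), ..., m_g(x_k)` over the label set
#' X, the GFC for condition `x_i` is the ratio of that group's mean to the
#' unweighted average of all group means:
#' `GFC(g, x_i) = m_g(x_i) / ((1/|X|) * sum_j m_g(x_j))`.
#' By construction the GFCs of each gene average exactly 1 across groups.
#' GFCs are raw ratios, not log fold-changes; set `log2 = TRUE` for an
#' optional log2 transform of the ratios.
#'
#' Genes whose group means average to zero have undefined GFCs and carry the
#' NA marker (with a warning); nothing is clamped or imputed.
#'
#' @param means A `group_means_table` with no control label set.
#' @param log2 Apply log2 to the ratios (default FALSE).
#' @return A `gfc_table`: list with `layer`, `mode = "no_control"`, `control`
#'   and `values` (gene x group matrix).
#' @export
gfc_no_control <- function(means, log2 = FALSE) {
  stopifnot(inherits(means, "group_means_table"))
  if (!is.null(means$control))
    stop("control label is set for layer '", means$layer,
         "'; use gfc_with_control()")
  grand <- rowMeans(means$means)
  values <- means$means / grand
  bad <- grand == 0
  if (any(bad)) {
    values[bad, ] <- NA_real_
    warning(sum(bad), " gene(s) with zero grand mean; GFCs undefined (NA)")
  }
  if (log2) values <- log2(values)
  structure(list(layer = means$layer, mode = "no_control", control = NULL,
                 values = values),
            class = "gfc_table")
}

#' Group Fold-Changes relative to a control group
#'
#' With control samples present, the GFC of gene g for group `x_i` in a layer
#' n is the ratio of the group mean to the control-group mean of the same
#' layer: `GFC(g, x_i, n) = m_g(x_i, n) / m_g(x_c, n)`. The computation is
#' layer-local, which is what lets a control-anchored analysis absorb
#' differences in sample sizes and condition spaces between layers. The
#' control column is identically 1 for every defined gene.
#'
#' Genes with control mean zero have undefined GFCs (NA marker + warning) and
#' are excluded from downstream module-mean summaries.
#'
#' @param means A `group_means_table` whose annotation declared a control
#'   label.
#' @param log2 Apply log2 to the ratios (default FALSE).
#' @return A `gfc_table` with `mode = "with_control"`.
#' @export
gfc_with_control <- function(means, log2 = FALSE) {
  stopifnot(inherits(means, "group_means_table"))
  if (is.null(means$control))
    stop("no control label set for layer '", means$layer,
         "'; use gfc_no_control()")
  if (!means$control %in% means$groups)
    stop("control group '", means$control, "' has no samples in layer '",
         means$layer, "'")
  ctrl <- means$means[, means$control]
  values <- means$means / ctrl
  bad <- ctrl == 0
  if (any(bad)) {
    values[bad, ] <- NA_real_
    warning(sum(bad), " gene(s) with zero control mean; GFCs undefined (NA)")
  }
  if (log2) values <- log2(values)
  structure(list(layer = means$layer, mode = "with_control",
                 control = means$control, values = values),
            class = "gfc_table")
}

#' Compute the GFC table for one layer
#'
#' Dispatches to the with-control or no-control formula according to whether
#' the annotation declares a control label.
#'
#' @param layer An `expression_layer`.
#' @param annotation Its `annotation_table`.
#' @param log2 Apply log2 to the ratios (default FALSE).
#' @return A `gfc_table`.
#' @export
compute_gfc <- function(layer, annotation, log2 = FALSE) {
  gm <- group_means(layer, annotation)
  if (is.null(gm$control)) gfc_no_control(gm, log2 = log2)
  else gfc_with_control(gm, log2 = log2)
}

#' Long-format view of a GFC table
#'
#' @param x A `gfc_table`.
#' @param ... Unused.
#' @return data.frame with columns `gene`, `layer`, `group`, `gfc`.
#' @export
as.data.frame.gfc_table <- function(x, ...) {
  data.frame(gene = rep(rownames(x$values), times = ncol(x$values)),
             layer = x$layer,
             group = rep(colnames(x$values), each = nrow(x$values)),
             gfc = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' Write a GFC table as long-format TSV
#'
#' @param gfc A `gfc_table`.
#' @param path Output path.
#' @export
write_gfc <- function(gfc, path) {
  stopifnot(inherits(gfc, "gfc_table"))
  utils::write.table(as.data.frame(gfc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
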