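#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file with gene identifiers in the first column and
#' one column per sample (header row carries sample identifiers). Values must
#' be numeric, finite and complete: this package operates downstream of
#' normalization (and, where needed, batch correction), so missing cells are
#' treated as an input error, never imputed.
#'
#' @param path Path to a TSV or CSV file.
#' @param delimiter Field delimiter. `NULL` (default) auto-detects tab vs
#'   comma from the header line; only `"\t"` and `","` are accepted.
#' @param name Layer name; defaults to the file name without extension.
#' @return An `expression_layer`: list with `name`, `genes`, `samples` and the
#'   numeric `values` matrix (genes x samples).
#' @export
read_expression <- function(path, delimiter = NULL, name = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, quote = "\"", comment.char = "")
  if (ncol(df) < 3) stop("expression file needs a gene-ID column and >= 2 sample columns: ", path)
  genes <- trimws(as.character(df[[1]]))
  values <- df[, -1, drop = FALSE]
  bad <- !vapply(values, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(values)[bad], collapse = ", "))
  }
  values <- as.matrix(values)
  rownames(values) <- genes
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  expression_layer(values, name = name)
}

#' Construct an expression layer from a matrix
#'
#' @param values Numeric matrix, genes as rows (rownames), samples as columns
#'   (colnames). All values must be finite.
#' @param name Layer name.
#' @return An `expression_layer` object.
#' @export
expression_layer <- function(values, name = "layer") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  genes <- trimws(rownames(values))
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("expression matrix needs gene rownames and sample colnames")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("an expression layer needs at least 2 genes and 2 samples")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0)
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0)
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("missing or non-finite expression value at gene '", genes[idx[1]],
         "', sample '", samples[idx[2]], "'")
  }
  rownames(values) <- genes
  structure(list(name = name, genes = genes, samples = samples, values = values),
            class = "expression_layer")
}

#' Write an expression layer to delimited text
#'
#' Inverse of [read_expression()]: the written file read back reproduces the
#' matrix at full precision.
#'
#' @param layer An `expression_layer`.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @export
write_expression <- function(layer, path, delimiter = "\t") {
  stopifnot(inherits(layer, "expression_layer"))
  df <- data.frame(gene = layer$genes, layer$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' First column holds sample identifiers; remaining columns are categorical
#' metadata. One column is designated as the grouping column whose labels
#' define the condition groups; optionally one of those labels marks control
#' samples.
#'
#' @param path Path to a TSV or CSV file.
#' @param grouping_column Name of the metadata column defining groups.
#' @param control_label Optional label within the grouping column marking
#'   control samples.
#' @param delimiter `NULL` auto-detects tab vs comma.
#' @return An `annotation_table`: list with `samples`, `data` (data.frame of
#'   metadata), `grouping_column`, `control_label`.
#' @export
read_annotation <- function(path, grouping_column, control_label = NULL,
                            delimiter = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  samples <- trimws(as.character(df[[1]]))
  data <- df[, -1, drop = FALSE]
  rownames(data) <- samples
  annotation_table(data, grouping_column, control_label)
}

#' Construct an annotation table from a data frame
#'
#' @param data Data frame of metadata, sample identifiers as rownames.
#' @param grouping_column Name of the column defining condition groups.
#' @param control_label Optional control label occurring in that column.
#' @return An `annotation_table` object.
#' @export
annotation_table <- function(data, grouping_column, control_label = NULL) {
  samples <- rownames(data)
  if (is.null(samples)) stop("annotation data needs sample rownames")
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0)
    stop("duplicate sample identifier(s) in annotation: ", paste(dup, collapse = ", "))
  if (!grouping_column %in% colnames(data))
    stop("grouping column '", grouping_column, "' not found; available: ",
         paste(colnames(data), collapse = ", "))
  labels <- as.character(data[[grouping_column]])
  if (anyNA(labels) || any(labels == ""))
    stop("grouping column '", grouping_column, "' contains empty labels")
  if (!is.null(control_label) && !control_label %in% labels)
    stop("control label '", control_label, "' does not occur in grouping column '",
         grouping_column, "'")
  structure(list(samples = samples, data = data,
                 grouping_column = grouping_column,
                 control_label = control_label),
            class = "annotation_table")
}

#' Write an annotation table to delimited text
#'
#' @param annotation An `annotation_table`.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @export
write_annotation <- function(annotation, path, delimiter = "\t") {
  stopifnot(inherits(annotation, "annotation_table"))
  df <- data.frame(sample = annotation$samples, annotation$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated; field 1 is the set
#' name, field 2 a description (ignored), fields 3+ the member genes.
#' Duplicate genes within a set are collapsed.
#'
#' @param path Path to a `.gmt` file.
#' @param source Provenance string stored with the collection; defaults to the
#'   file name.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, genes...)")
    nm <- trimws(fields[1])
    if (nm %in% names(sets))
      stop("duplicate gene-set name in GMT: '", nm, "' (line ", i, ")")
    genes <- unique(trimws(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop("GMT line ", i, " (set '", nm, "') has no genes")
    sets[[nm]] <- genes
  }
  gene_set_collection(sets, source = source)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member genes).
#' @param source Provenance string.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (length(sets) == 0) stop("gene-set collection is empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup) > 0)
    stop("duplicate gene-set name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("gene-set collection contains an empty set")
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$source, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pair expression layers with annotations into an analysis state
#'
#' Layers and annotations are paired positionally (first layer with first
#' annotation, and so on); each annotation's sample set must exactly match its
#' layer's. The returned state carries a `parameters` slot, recorded before
#' the stage that consumes each parameter, and named `results` slots filled
#' stage by stage (`variance`, `correlations`, `cutoff_stats`, `cutoffs`,
#' `gfc`, `networks`, `integrated`, `partition`, `summary`, `enrichment`).
#'
#' @param layers List of `expression_layer` objects.
#' @param annotations List of `annotation_table` objects, same length.
#' @return An `analysis_state` object.
#' @export
validate_state <- function(layers, annotations) {
  if (length(layers) == 0) stop("at least one layer is required")
  if (length(layers) != length(annotations))
    stop("got ", length(layers), " layers but ", length(annotations), " annotations")
  nms <- vapply(layers, function(l) l$name, character(1))
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0) stop("duplicate layer name(s): ", paste(dup, collapse = ", "))
  for (i in seq_along(layers)) {
    stopifnot(inherits(layers[[i]], "expression_layer"),
              inherits(annotations[[i]], "annotation_table"))
    ls <- layers[[i]]$samples
    as_ <- annotations[[i]]$samples
    if (!setequal(ls, as_)) {
      off <- c(setdiff(ls, as_), setdiff(as_, ls))
      stop("layer '", layers[[i]]$name, "': annotation samples do not match ",
           "expression samples; offending: ", paste(off, collapse = ", "))
    }
  }
  pairs <- lapply(seq_along(layers), function(i) {
    ann <- annotations[[i]]
    # align annotation rows to the expression column order
    ann$data <- ann$data[match(layers[[i]]$samples, ann$samples), , drop = FALSE]
    ann$samples <- layers[[i]]$samples
    list(expression = layers[[i]], annotation = ann)
  })
  names(pairs) <- nms
  structure(list(layers = pairs, parameters = list(),
                 results = list(variance = NULL, correlations = NULL,
                                cutoff_stats = NULL, cutoffs = NULL,
                                gfc = NULL, networks = NULL, integrated = NULL,
                                partition = NULL, summary = NULL,
                                enrichment = NULL)),
            class = "analysis_state")
}

#' Condition groups of an annotation table
#'
#' @param annotation An `annotation_table`.
#' @return Character vector of distinct grouping labels, in order of first
#'   appearance.
#' @export
group_labels <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_table"))
  unique(as.character(annotation$data[[annotation$grouping_column]]))
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) return("\t")
  if (grepl(",", header, fixed = TRUE)) return(",")
  stop("cannot auto-detect delimiter (neither tab nor comma in header) for: ", path)
}

#' @export
print.expression_layer <- function(x, ...) {
  cat("<expression_layer> '", x$name, "': ", length(x$genes), " genes x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, length, integer(1))
  cat("<gene_set_collection> '", x$source, "': ", length(x$sets),
      " sets (sizes ", min(sizes), "-", max(sizes), ")\n", sep = "")
  invisible(x)
}

#' @export
print.analysis_state <- function(x, ...) {
  cat("<analysis_state> with", length(x$layers), "layer(s):",
      paste(names(x$layers), collapse = ", "), "\n")
  done <- names(x$results)[!vapply(x$results, is.null, logical(1))]
  cat("  completed stages:", if (length(done)) paste(done, collapse = ", ") else "none", "\n")
  invisible(x)
}
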