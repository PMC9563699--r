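#' Read and validate a pipeline run configuration
#'
#' The configuration is a single declarative YAML file. Top-level keys:
#'
#' * `layers`: list of per-layer blocks with `expression` (path),
#'   `annotation` (path), `grouping_column`, optional `control_label`,
#'   optional `name`, `top_variant` (integer, `"suggest"` or `"all"`;
#'   default `"all"`) and `cutoff` (number or `"auto"`). Layers are paired
#'   with annotations positionally by these blocks, never by filename.
#' * `correlation`: `method` (`"pearson"` or `"spearman"`, default
#'   `"spearman"`).
#' * `cutoff_grid`: optional `from`, `to`, `n` (default 0.9, 1.0, 50).
#' * `integration`: `mode` (`"union"` or `"intersection"`), `policy`
#'   (`"min"`/`"mean"`/`"max"`, default `"min"`), `reference` (layer name,
#'   intersection only).
#' * `clustering`: `algorithm` (default `"leiden"`), `resolution` (default
#'   1.0), `seed` (default 1).
#' * `min_module_size`: default 25.
#' * `enrichment`: optional; `collections` (list of `name` + `gmt` path),
#'   `n_top` (default 5), `alpha` (default 0.1).
#' * `output_dir`: where artifacts are written.
#'
#' Validation is performed before any computation: referenced files must
#' exist and enumerated options must be recognized.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  if (is.null(cfg$layers) || length(cfg$layers) == 0)
    stop("config: at least one layer is required")
  for (i in seq_along(cfg$layers)) {
    ly <- cfg$layers[[i]]
    for (key in c("expression", "annotation", "grouping_column")) {
      if (is.null(ly[[key]])) stop("config: layer ", i, " is missing '", key, "'")
    }
    for (key in c("expression", "annotation")) {
      if (!file.exists(ly[[key]]))
        stop("config: layer ", i, " ", key, " file not found: ", ly[[key]])
    }
    tv <- ly$top_variant %||% "all"
    if (!(identical(tv, "all") || identical(tv, "suggest") ||
          (is.numeric(tv) && tv >= 1)))
      stop("config: layer ", i, " top_variant must be a count, 'suggest' or 'all'")
    cfg$layers[[i]]$top_variant <- tv
    ct <- ly$cutoff %||% "auto"
    if (!(identical(ct, "auto") || (is.numeric(ct) && ct > 0 && ct <= 1)))
      stop("config: layer ", i, " cutoff must be in (0,1] or 'auto'")
    cfg$layers[[i]]$cutoff <- ct
  }
  cfg$correlation$method <- match.arg(cfg$correlation$method %||% "spearman",
                                      c("spearman", "pearson"))
  grid <- cfg$cutoff_grid
  cfg$cutoff_grid <- seq(grid$from %||% 0.9, grid$to %||% 1.0,
                         length.out = grid$n %||% 50)
  mode <- cfg$integration$mode %||% "union"
  if (!mode %in% c("union", "intersection"))
    stop("config: unknown integration mode '", mode, "'")
  cfg$integration$mode <- mode
  cfg$integration$policy <- match.arg(cfg$integration$policy %||% "min",
                                      c("min", "mean", "max"))
  if (mode == "intersection" && is.null(cfg$integration$reference))
    stop("config: intersection integration needs a 'reference' layer name")
  alg <- cfg$clustering$algorithm %||% "leiden"
  if (!alg %in% supported_algorithms)
    stop("config: unknown clustering algorithm '", alg, "'; options: ",
         paste(supported_algorithms, collapse = ", "))
  cfg$clustering$algorithm <- alg
  cfg$clustering$resolution <- cfg$clustering$resolution %||% 1.0
  cfg$clustering$seed <- as.integer(cfg$clustering$seed %||% 1L)
  cfg$min_module_size <- as.integer(cfg$min_module_size %||% 25L)
  if (!is.null(cfg$enrichment)) {
    cfg$enrichment$n_top <- as.integer(cfg$enrichment$n_top %||% 5L)
    cfg$enrichment$alpha <- cfg$enrichment$alpha %||% 0.1
    for (cl in cfg$enrichment$collections) {
      if (is.null(cl$name) || is.null(cl$gmt))
        stop("config: each enrichment collection needs 'name' and 'gmt'")
      if (!file.exists(cl$gmt)) stop("config: GMT not found: ", cl$gmt)
    }
  }
  if (is.null(cfg$output_dir)) stop("config: 'output_dir' is required")
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the three phases end to end: per-layer preprocessing (variance
#' filter, correlations, cutoff guide, GFC, network construction), network
#' integration, and post-integration analysis (community detection, size
#' filter, module GFC summary, optional enrichment). Every artifact is
#' written to the configured output directory:
#'
#' * `cutoff_stats_<layer>.tsv` — the four-criteria cutoff guide per layer
#' * `gfc_<layer>.tsv` — long-format GFC tables
#' * `network_<layer>.graphml` / `.tsv` — per-layer networks
#' * `network_integrated.graphml` / `.tsv` — the integrated network
#' * `partition.tsv`, `module_summary.tsv`, `condition_order.txt`
#' * `enrichment_<collection>.tsv`, `enrichment_<collection>_top.tsv`
#' * `run_record.json` — every parameter, seed, package/R version and input
#'   content digest, sufficient (with the input files) to reproduce every
#'   output exactly.
#'
#' Any stage error aborts the run with the stage name and cause. Per-stage
#' timings are logged to stderr.
#'
#' @param config A `run_config`, or a path to a YAML config.
#' @return Invisibly, the completed `analysis_state` (results slots filled;
#'   the output directory is recorded in `state$parameters$output_dir`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  state <- stage("load", {
    layers <- list(); annotations <- list()
    for (i in seq_along(config$layers)) {
      ly <- config$layers[[i]]
      layers[[i]] <- read_expression(ly$expression, delimiter = ly$delimiter,
                                     name = ly$name %||% paste0("layer", i))
      annotations[[i]] <- read_annotation(ly$annotation, ly$grouping_column,
                                          ly$control_label,
                                          delimiter = ly$delimiter)
    }
    validate_state(layers, annotations)
  })
  state$parameters <- config[setdiff(names(config), "layers")]
  state$parameters$layers <- config$layers
  state$parameters$output_dir <- out

  vres <- stage("variance_filter", {
    res <- lapply(seq_along(state$layers), function(i) {
      tv <- config$layers[[i]]$top_variant
      layer <- state$layers[[i]]$expression
      curve <- rank_variances(layer)
      n <- if (identical(tv, "all")) length(layer$genes)
           else if (identical(tv, "suggest")) suggest_topvar(curve)$suggestion
           else as.integer(tv)
      list(curve = curve, n_kept = n,
           filtered = filter_top_variant(layer, n))
    })
    names(res) <- names(state$layers)
    res
  })
  for (nm in names(vres))
    state$layers[[nm]]$expression <- vres[[nm]]$filtered
  state$results$variance <- lapply(vres, function(v) v[c("curve", "n_kept")])

  state$results$correlations <- stage("correlations", {
    res <- lapply(state$layers, function(p)
      compute_correlations(p$expression, config$correlation$method))
    names(res) <- names(state$layers)
    res
  })

  state$results$cutoff_stats <- stage("cutoff_statistics", {
    res <- lapply(names(state$layers), function(nm) {
      cs <- cutoff_statistics(state$results$correlations[[nm]],
                              config$cutoff_grid)
      write_cutoff_statistics(cs, file.path(out, paste0("cutoff_stats_", nm, ".tsv")))
      cs
    })
    names(res) <- names(state$layers)
    res
  })

  state$results$cutoffs <- stage("cutoff_choice", {
    res <- lapply(seq_along(state$layers), function(i) {
      ct <- config$layers[[i]]$cutoff
      if (identical(ct, "auto"))
        select_cutoff(state$results$cutoff_stats[[i]])
      else ct
    })
    names(res) <- names(state$layers)
    res
  })

  state$results$gfc <- stage("gfc", {
    res <- lapply(state$layers, function(p) {
      g <- compute_gfc(p$expression, p$annotation)
      g
    })
    names(res) <- names(state$layers)
    for (nm in names(res))
      write_gfc(res[[nm]], file.path(out, paste0("gfc_", nm, ".tsv")))
    res
  })

  state$results$networks <- stage("layer_networks", {
    res <- lapply(names(state$layers), function(nm) {
      net <- build_network(state$results$correlations[[nm]],
                           state$results$cutoffs[[nm]], name = nm)
      write_graphml(net, file.path(out, paste0("network_", nm, ".graphml")))
      write_edge_list(net, file.path(out, paste0("network_", nm, ".tsv")))
      net
    })
    names(res) <- names(state$layers)
    res
  })

  state$results$integrated <- stage("integration", {
    nets <- state$results$networks
    net <- if (length(nets) == 1) nets[[1]]
    else if (config$integration$mode == "union")
      integrate_union(nets, config$integration$policy)
    else integrate_intersection(nets, config$integration$reference,
                                config$integration$policy)
    write_edge_list(net, file.path(out, "network_integrated.tsv"))
    net
  })

  state$results$partition <- stage("community_detection", {
    part <- detect_modules(state$results$integrated,
                           algorithm = config$clustering$algorithm,
                           resolution = config$clustering$resolution,
                           seed = config$clustering$seed)
    part <- filter_min_size(part, config$min_module_size)
    write_partition(part, file.path(out, "partition.tsv"))
    write_graphml(state$results$integrated,
                  file.path(out, "network_integrated.graphml"),
                  partition = part)
    part
  })

  state$results$summary <- stage("module_summary", {
    summ <- module_summary(state$results$partition,
                           unname(state$results$gfc))
    write_module_summary(summ, file.path(out, "module_summary.tsv"))
    if (ncol(summ$matrix) >= 2) {
      ord <- order_conditions(summ)
      writeLines(ord$order, file.path(out, "condition_order.txt"))
    }
    summ
  })

  if (!is.null(config$enrichment)) {
    state$results$enrichment <- stage("enrichment", {
      universe <- network_nodes(state$results$integrated)
      res <- lapply(config$enrichment$collections, function(cl) {
        coll <- read_gmt(cl$gmt, source = cl$name)
        enr <- enrich_modules(state$results$partition, coll, universe)
        write_enrichment(enr, file.path(out, paste0("enrichment_", cl$name, ".tsv")))
        top <- top_terms(enr, config$enrichment$n_top, config$enrichment$alpha)
        write_enrichment(top, file.path(out, paste0("enrichment_", cl$name, "_top.tsv")))
        enr
      })
      names(res) <- vapply(config$enrichment$collections, `[[`, character(1), "name")
      res
    })
  }

  stage("run_record", {
    inputs <- unlist(lapply(config$layers, function(ly)
      c(ly$expression, ly$annotation)))
    record <- list(
      parameters = unclass(config),
      selected_cutoffs = state$results$cutoffs,
      top_variant_kept = lapply(state$results$variance, `[[`, "n_kept"),
      versions = list(package = as.character(utils::packageVersion("coexweave")),
                      r = R.version.string,
                      igraph = as.character(utils::packageVersion("igraph"))),
      input_digests = as.list(tools::md5sum(inputs))
    )
    jsonlite::write_json(record, file.path(out, "run_record.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(state)
}

satellite_names <- c("suggest_topvar", "hub_genes", "pca_table",
                     "expression_distributions")

#' Run an optional satellite analysis
#'
#' Satellites run independently and in no particular order, subject only to
#' their declared stage dependencies: `suggest_topvar`, `pca_table` and
#' `expression_distributions` need only loaded layers, while `hub_genes`
#' needs the integrated network and the module partition. An unmet
#' dependency raises an error naming the missing stage. The analysis state
#' is never modified.
#'
#' Satellite parameters (`params`):
#' * `suggest_topvar`: `layer` (name, default first).
#' * `hub_genes`: `module` (required), `k` (default 10), `score`.
#' * `pca_table`: `layer`; returns one row per sample with >= 2 principal
#'   component scores (presentation-agnostic replacement for a PCA plot).
#' * `expression_distributions`: per-sample quantile summary of each layer
#'   (replacement for per-sample count-distribution plots).
#'
#' @param name Satellite name.
#' @param state An `analysis_state` (as returned by [run_pipeline()]).
#' @param params Named list of satellite parameters.
#' @return The satellite's artifact (a data.frame or list).
#' @export
run_satellite <- function(name, state, params = list()) {
  stopifnot(inherits(state, "analysis_state"))
  if (!name %in% satellite_names)
    stop("unknown satellite '", name, "'; options: ",
         paste(satellite_names, collapse = ", "))
  get_layer <- function() {
    nm <- params$layer %||% names(state$layers)[1]
    if (!nm %in% names(state$layers)) stop("no layer '", nm, "'")
    state$layers[[nm]]$expression
  }
  switch(name,
    suggest_topvar = suggest_topvar(rank_variances(get_layer())),
    hub_genes = {
      if (is.null(state$results$partition))
        stop("satellite 'hub_genes' requires the community_detection stage")
      if (is.null(state$results$integrated))
        stop("satellite 'hub_genes' requires the integration stage")
      if (is.null(params$module)) stop("hub_genes needs params$module")
      hub_genes(state$results$integrated, state$results$partition,
                params$module, k = params$k %||% 10L,
                score = params$score %||% "weighted_degree")
    },
    pca_table = {
      layer <- get_layer()
      pc <- stats::prcomp(t(layer$values), center = TRUE, scale. = FALSE)
      k <- max(2L, min(ncol(pc$x), params$n_components %||% 5L))
      data.frame(sample = layer$samples, pc$x[, seq_len(k), drop = FALSE],
                 row.names = NULL, check.names = FALSE)
    },
    expression_distributions = {
      do.call(rbind, lapply(state$layers, function(p) {
        q <- t(apply(p$expression$values, 2, stats::quantile,
                     probs = c(0, 0.25, 0.5, 0.75, 1)))
        data.frame(layer = p$expression$name, sample = p$expression$samples,
                   min = q[, 1], q25 = q[, 2], median = q[, 3], q75 = q[, 4],
                   max = q[, 5], mean = colMeans(p$expression$values),
                   row.names = NULL, stringsAsFactors = FALSE)
      }))
    })
}
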