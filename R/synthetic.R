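#' Generate multi-layer expression data with planted co-expression modules
#'
#' Produces normalized-scale expression layers in which blocks of genes
#' share a latent factor (giving a known within-module correlation) and each
#' module carries condition-group effect multipliers, so every stage of the
#' workflow — variance filtering, correlation, thresholding, integration,
#' community detection and GFC summarization — can be tested against known
#' ground truth.
#'
#' Each module gene in sample s is
#' `effect(module, group(s)) * (baseline + sqrt(rho) * z + sqrt(1-rho) * e)`
#' with a per-module, per-sample latent factor `z ~ N(0, noise_sd^2)` and
#' independent gene noise `e ~ N(0, noise_sd^2)`, giving pairwise
#' within-module, within-group correlation of approximately `rho =
#' within_module_corr`. Background genes are independent
#' `baseline + N(0, noise_sd^2)` noise. The baseline offset keeps all values
#' positive (a final deterministic shift is applied in the rare case any
#' value is non-positive) so GFC denominators are well behaved. Latent
#' factors are drawn independently per layer: layers agree on which genes
#' are co-expressed, not on sample-level values, mirroring independent
#' studies of the same biology.
#'
#' The default effect map assigns each module a distinct condition pattern
#' by cycling multipliers 2.0, 0.5, 1.5 over the non-control groups (module
#' 1: 2.0 in the first non-control group; module 2: 2.0 in the second; module
#' 3: 0.5 in the first; ...). Controls always have multiplier 1.
#'
#' All randomness flows from the single `seed`; regenerating with the same
#' arguments reproduces identical matrices, and the seed is recorded in the
#' returned truth object.
#'
#' @param n_layers Number of layers (datasets), default 2.
#' @param n_modules Number of planted modules, default 5.
#' @param genes_per_module Genes per module, default 40.
#' @param n_background Independent background genes, default 200.
#' @param groups Condition labels, default `c("ctrl", "A", "B")`.
#' @param samples_per_group Samples per group per layer, default 10.
#' @param within_module_corr Target within-module correlation in (0, 1),
#'   default 0.95.
#' @param effect_map Optional `n_modules x length(groups)` matrix of
#'   multipliers (colnames = groups); `NULL` uses the default pattern above.
#' @param noise_sd Noise standard deviation, default 1.
#' @param control_label Label in `groups` marking controls (`NULL` for a
#'   no-control design), default `"ctrl"`.
#' @param baseline Positive offset added before scaling, default 10.
#' @param seed Integer seed, default 1.
#' @return List with `layers` (list of `expression_layer`), `annotations`
#'   (list of `annotation_table`) and `truth` (a `synthetic_truth`: planted
#'   `modules` membership, `effect_map`, `within_module_corr`, `noise_sd`,
#'   `seed`).
#' @export
generate_layers <- function(n_layers = 2L, n_modules = 5L,
                            genes_per_module = 40L, n_background = 200L,
                            groups = c("ctrl", "A", "B"),
                            samples_per_group = 10L,
                            within_module_corr = 0.95, effect_map = NULL,
                            noise_sd = 1, control_label = "ctrl",
                            baseline = 10, seed = 1L) {
  if (within_module_corr <= 0 || within_module_corr >= 1)
    stop("within_module_corr must lie in (0, 1)")
  if (any(c(n_layers, n_modules, genes_per_module, samples_per_group) < 1))
    stop("all counts must be >= 1")
  if (length(groups) == 0) stop("at least one group label is required")
  if (!is.null(control_label) && !control_label %in% groups)
    stop("control label '", control_label, "' is not among the groups")
  if (is.null(effect_map))
    effect_map <- default_effect_map(n_modules, groups, control_label)
  if (nrow(effect_map) != n_modules || ncol(effect_map) != length(groups))
    stop("effect_map must be n_modules x length(groups)")
  colnames(effect_map) <- groups
  rownames(effect_map) <- paste0("M", seq_len(n_modules))

  module_of <- rep(rownames(effect_map), each = genes_per_module)
  gene_ids <- c(sprintf("M%d_G%03d", rep(seq_len(n_modules), each = genes_per_module),
                        rep(seq_len(genes_per_module), n_modules)),
                if (n_background > 0) sprintf("BG_G%03d", seq_len(n_background)))
  modules <- stats::setNames(c(module_of, rep("background", n_background)),
                             gene_ids)
  sample_groups <- rep(groups, each = samples_per_group)
  n_samples <- length(sample_groups)
  n_genes <- length(gene_ids)
  rho <- within_module_corr

  out <- with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      vals <- matrix(NA_real_, n_genes, n_samples)
      # latent factor per module per sample
      z <- matrix(stats::rnorm(n_modules * n_samples, sd = noise_sd),
                  n_modules, n_samples)
      for (m in seq_len(n_modules)) {
        idx <- which(module_of == rownames(effect_map)[m])
        e <- matrix(stats::rnorm(length(idx) * n_samples, sd = noise_sd),
                    length(idx), n_samples)
        signal <- baseline + sqrt(rho) * matrix(z[m, ], length(idx), n_samples,
                                                byrow = TRUE) +
          sqrt(1 - rho) * e
        vals[idx, ] <- signal * matrix(effect_map[m, sample_groups],
                                       length(idx), n_samples, byrow = TRUE)
      }
      if (n_background > 0) {
        idx <- which(modules == "background")
        vals[idx, ] <- baseline +
          matrix(stats::rnorm(n_background * n_samples, sd = noise_sd),
                 n_background, n_samples)
      }
      if (min(vals) <= 0) vals <- vals - min(vals) + 0.1
      rownames(vals) <- gene_ids
      colnames(vals) <- sprintf("L%d_S%02d", l, seq_len(n_samples))
      layer <- expression_layer(vals, name = paste0("layer", l))
      ann <- data.frame(group = sample_groups, row.names = colnames(vals),
                        stringsAsFactors = FALSE)
      list(layer = layer,
           annotation = annotation_table(ann, "group", control_label))
    })
  })
  truth <- structure(list(modules = modules, effect_map = effect_map,
                          within_module_corr = within_module_corr,
                          noise_sd = noise_sd, seed = seed),
                     class = "synthetic_truth")
  list(layers = lapply(out, `[[`, "layer"),
       annotations = lapply(out, `[[`, "annotation"),
       truth = truth)
}

# Cycle effect multipliers 2.0, 0.5, 1.5 over the non-control groups so each
# module gets a distinct, recoverable condition pattern.
default_effect_map <- function(n_modules, groups, control_label) {
  em <- matrix(1, n_modules, length(groups), dimnames = list(NULL, groups))
  noncontrol <- setdiff(groups, control_label)
  if (length(noncontrol) == 0) return(em)
  mults <- c(2.0, 0.5, 1.5)
  for (j in seq_len(n_modules)) {
    g <- noncontrol[(j - 1) %% length(noncontrol) + 1]
    em[j, g] <- mults[((j - 1) %/% length(noncontrol)) %% length(mults) + 1]
  }
  em
}

#' Write a synthetic dataset as pipeline-ready fixture files
#'
#' Writes each layer's expression matrix and annotation table in exactly the
#' TSV formats [read_expression()] and [read_annotation()] consume, plus a
#' `truth.tsv` with the planted module membership.
#'
#' @param data Result of [generate_layers()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named list of written paths.
#' @export
write_fixture <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (i in seq_along(data$layers)) {
    nm <- data$layers[[i]]$name
    pe <- file.path(dir, paste0(nm, "_expression.tsv"))
    pa <- file.path(dir, paste0(nm, "_annotation.tsv"))
    write_expression(data$layers[[i]], pe)
    write_annotation(data$annotations[[i]], pa)
    paths[[paste0(nm, "_expression")]] <- pe
    paths[[paste0(nm, "_annotation")]] <- pa
  }
  pt <- file.path(dir, "truth.tsv")
  utils::write.table(data.frame(gene = names(data$truth$modules),
                                module = unname(data$truth$modules)),
                     pt, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- pt
  invisible(paths)
}
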