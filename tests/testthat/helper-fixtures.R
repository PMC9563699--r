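# Small in-code fixtures shared across test files.

make_layer <- function(values, genes = NULL, samples = NULL, name = "test") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  rownames(values) <- genes
  colnames(values) <- samples
  expression_layer(values, name = name)
}

make_annotation <- function(samples, groups, control = NULL) {
  annotation_table(data.frame(group = groups, row.names = samples,
                              stringsAsFactors = FALSE),
                   "group", control)
}

# A correlation_result with prescribed off-diagonal values.
make_corr <- function(genes, pairs) {
  m <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- as.numeric(p[[3]])
    m[p[[2]], p[[1]]] <- as.numeric(p[[3]])
  }
  correlation_result(m, method = "precomputed")
}

# A single-layer coexpression_network straight from an edge table.
make_network <- function(edges, name = "layer") {
  genes <- unique(c(edges$from, edges$to))
  pairs <- lapply(seq_len(nrow(edges)),
                  function(i) list(edges$from[i], edges$to[i], edges$weight[i]))
  build_network(make_corr(genes, pairs), cutoff = min(edges$weight), name = name)
}

# Independent least-squares oracle for the degree-distribution fit.
r2_oracle <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 2) return(NA_real_)
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  yhat <- yb + slope * (x - xb)
  sst <- sum((y - yb)^2)
  if (sst == 0) return(1)
  1 - sum((y - yhat)^2) / sst
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# probability that a random draw of n from N (K marked) overlaps >= k.
hyper_oracle <- function(k, K, N, n) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(i) choose(K, i) * choose(N - K, n - i),
             numeric(1))) / total
}

# Direct step-up definition of Benjamini-Hochberg.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
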