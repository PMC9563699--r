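test_that("variance ranking orders genes, breaks ties by ID, flags constants", {
  vals <- rbind(c(0, 2, 4),    # var 4
                c(1, 1, 3),    # var ~1.33
                c(0, 3, 6),    # var 9
                c(5, 5, 5))    # constant
  layer <- make_layer(vals, genes = c("gb", "gc", "ga", "gz"))
  curve <- rank_variances(layer)
  expect_equal(curve$gene, c("ga", "gb", "gc", "gz"))
  expect_true(curve$zero_variance[4])
  expect_true(is.na(curve$log_variance[4]))
  expect_true(all(diff(curve$variance) <= 0))

  # duplicated profiles tie; lexicographic gene ID decides
  vals2 <- rbind(c(1, 2, 9), c(1, 2, 9), c(0, 0, 1))
  curve2 <- rank_variances(make_layer(vals2, genes = c("gm", "ga", "gz")))
  expect_equal(curve2$gene[1:2], c("ga", "gm"))

  expect_error(rank_variances(make_layer(matrix(1, 3, 3))), "constant")
})

test_that("top-variant filter keeps the n most variant genes", {
  vals <- rbind(c(0, 10), c(0, 1), c(0, 5), c(0, 7))
  layer <- make_layer(vals, genes = c("g1", "g2", "g3", "g4"))
  expect_equal(filter_top_variant(layer, 4)$genes, rank_variances(layer)$gene)
  expect_equal(filter_top_variant(layer, 2)$genes, c("g1", "g4"))
  one <- filter_top_variant(layer, 1)
  expect_equal(one$genes, "g1")
  expect_equal(one$samples, layer$samples)
  expect_error(filter_top_variant(layer, 0))
  expect_error(filter_top_variant(layer, 5))
})

test_that("elbow suggestion finds a planted inflection and is scale-equivariant", {
  set.seed(42)
  vars <- c(10 * exp(rnorm(100, sd = 0.05)), 0.1 * exp(rnorm(900, sd = 0.05)))
  vals <- t(vapply(vars, function(v) rnorm(10, sd = sqrt(v)), numeric(10)))
  # rank_variances re-estimates variances; plant the curve directly instead
  curve <- data.frame(gene = sprintf("g%04d", seq_along(vars)),
                      variance = sort(vars, decreasing = TRUE),
                      log_variance = log10(sort(vars, decreasing = TRUE)),
                      zero_variance = FALSE)
  class(curve) <- c("variance_curve", "data.frame")
  sug <- suggest_topvar(curve)
  expect_gte(sug$suggestion, 90)
  expect_lte(sug$suggestion, 110)

  # independent check: rolling-mean smoother + max second difference
  skip_if_not_installed("zoo")
  w <- sug$window
  sm <- zoo::rollmean(curve$log_variance, w, fill = NA, align = "center")
  valid <- which(!is.na(sm))
  d2 <- diff(sm[valid], differences = 2)
  oracle <- valid[which.max(abs(d2)) + 1L]
  expect_equal(sug$suggestion, oracle)

  # scale equivariance: rescaling variances moves nothing
  curve2 <- curve
  curve2$variance <- curve$variance * 37.5
  curve2$log_variance <- log10(curve2$variance)
  expect_equal(suggest_topvar(curve2)$suggestion, sug$suggestion)
})

test_that("degenerate curves fall back with a warning and stay in range", {
  lin <- data.frame(gene = sprintf("g%03d", 1:200),
                    variance = 10^seq(2, -2, length.out = 200),
                    log_variance = seq(2, -2, length.out = 200),
                    zero_variance = FALSE)
  class(lin) <- c("variance_curve", "data.frame")
  expect_warning(res <- suggest_topvar(lin), "no inflection")
  expect_equal(res$suggestion, 200)

  short <- lin[1:4, ]
  class(short) <- c("variance_curve", "data.frame")
  expect_warning(res2 <- suggest_topvar(short), "shorter")
  expect_equal(res2$suggestion, 4)

  set.seed(7)
  for (i in 1:5) {
    v <- sort(exp(rnorm(150)), decreasing = TRUE)
    rc <- data.frame(gene = sprintf("g%03d", 1:150), variance = v,
                     log_variance = log10(v), zero_variance = FALSE)
    class(rc) <- c("variance_curve", "data.frame")
    s <- suppressWarnings(suggest_topvar(rc)$suggestion)
    expect_gte(s, 1)
    expect_lte(s, 150)
  }
})

test_that("correlations match reference routine and flag constant genes", {
  # identical profiles correlate perfectly under both methods
  vals <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 1, 3, 2))
  layer <- make_layer(vals)
  for (m in c("pearson", "spearman")) {
    cr <- compute_correlations(layer, m)
    expect_equal(cr$matrix["g01", "g02"], 1)
    expect_true(is.na(cr$matrix["g01", "g01"]))
  }

  # monotone but non-linear: Spearman 1, Pearson < 1; Pearson checked
  # against the closed-form sum formula
  vals2 <- rbind(c(1, 2, 3), c(1, 4, 9), c(3, 1, 2))
  cr_s <- compute_correlations(make_layer(vals2), "spearman")
  cr_p <- compute_correlations(make_layer(vals2), "pearson")
  expect_equal(cr_s$matrix["g01", "g02"], 1)
  x <- c(1, 2, 3); y <- c(1, 4, 9)
  pearson_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(cr_p$matrix["g01", "g02"], 1)
  expect_equal(cr_p$matrix["g01", "g02"], pearson_manual, tolerance = 1e-12)

  # constant gene: undefined marker, not +-1
  vals3 <- rbind(c(1, 1, 1), c(1, 2, 3), c(5, 1, 2))
  cr3 <- compute_correlations(make_layer(vals3), "pearson")
  expect_true(is.na(cr3$matrix["g01", "g02"]))

  # agreement with stats::cor on random matrices, both methods
  set.seed(11)
  rand <- matrix(rnorm(500), 50, 10,
                 dimnames = list(sprintf("r%02d", 1:50), sprintf("c%02d", 1:10)))
  for (m in c("pearson", "spearman")) {
    got <- compute_correlations(expression_layer(rand), m)$matrix
    ref <- stats::cor(t(rand), method = m)
    diag(ref) <- NA
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("cutoff statistics count edges, nodes and components correctly", {
  corr <- make_corr(c("A", "B", "C", "D"),
                    list(list("A", "B", 0.99), list("A", "C", 0.95),
                         list("B", "C", 0.50), list("C", "D", 0.92)))
  cs <- cutoff_statistics(corr, c(0.9, 0.94, 0.96, 0.995))
  expect_equal(cs$n_edges, c(3L, 2L, 1L, 0L))
  expect_equal(cs$n_nodes, c(4L, 3L, 2L, 0L))
  expect_equal(cs$n_components, c(1L, 1L, 1L, 0L))
  expect_true(is.na(cs$r_squared[4]))

  # complete graph at a low cutoff: G(G-1)/2 edges, one component
  genes <- sprintf("g%d", 1:6)
  pairs <- utils::combn(genes, 2, simplify = FALSE)
  corr2 <- make_corr(genes, lapply(pairs, function(p) list(p[1], p[2], 0.95)))
  cs2 <- cutoff_statistics(corr2, c(0.9, 0.95))
  expect_equal(cs2$n_edges, c(15L, 15L))
  expect_equal(cs2$n_components, c(1L, 1L))

  expect_error(cutoff_statistics(corr, numeric(0)), "empty")
  expect_error(cutoff_statistics(corr, c(0, 0.5)), "\\(0, 1\\]")
})

test_that("thresholded edge sets are nested along the grid", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 25
    vals <- matrix(rnorm(n * 8), n, 8,
                   dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:8)))
    cs <- cutoff_statistics(compute_correlations(expression_layer(vals), "pearson"),
                            seq(0.05, 0.95, by = 0.1))
    expect_true(all(diff(cs$n_edges) <= 0))
    expect_true(all(diff(cs$n_nodes) <= 0))
  }
})

test_that("degree-distribution R2 matches the least-squares oracle", {
  # star K(1,5): two distinct degrees, two points determine a line
  expect_equal(degree_distribution_r2(c(5, 1, 1, 1, 1, 1)), 1)
  # cycle: one distinct degree, undefined
  expect_true(is.na(degree_distribution_r2(rep(2, 6))))
  expect_error(degree_distribution_r2(integer(0)), "empty")
  expect_error(degree_distribution_r2(c(0, 0)), "degree >= 1")

  set.seed(5)
  for (i in 1:100) {
    g <- igraph::sample_gnp(30, runif(1, 0.05, 0.4))
    deg <- igraph::degree(g)
    if (all(deg == 0)) next
    expect_lt(abs(degree_distribution_r2(deg) - r2_oracle(deg)), 1e-12)
  }
})

test_that("heuristic cutoff choice respects the node floor", {
  corr <- make_corr(c("A", "B", "C", "D"),
                    list(list("A", "B", 0.99), list("A", "C", 0.95),
                         list("C", "D", 0.92)))
  cs <- cutoff_statistics(corr, c(0.9, 0.93, 0.96))
  pick <- select_cutoff(cs, min_nodes = 2)
  expect_true(pick %in% cs$cutoff)
  expect_gte(cs$n_nodes[cs$cutoff == pick], 2)
})
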