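toy_grn <- function(edges_df, tfs = unique(edges_df$tf)) {
  edges_df$score <- rep(1, nrow(edges_df))
  edges_df$distance <- rep(0, nrow(edges_df))
  build_grn(edges_df, tfs)
}

test_that("the propagation operator is column-normalized", {
  g1 <- toy_grn(data.frame(tf = "T", target = "G"))
  W <- normalize_adjacency(g1)
  expect_equal(W["G", "T"], 1)
  g4 <- toy_grn(data.frame(tf = "T", target = c("a", "b", "c", "d")))
  W4 <- normalize_adjacency(g4)
  expect_equal(unname(Matrix::colSums(W4)["T"]), 1)
  expect_true(all(W4[c("a", "b", "c", "d"), "T"] == 0.25))
  expect_error(normalize_adjacency(toy_grn(
    data.frame(tf = character(), target = character()), tfs = "T")),
    "no edges")
})

test_that("propagation returns the seed at restart 1 and the linear-solve fixed point otherwise", {
  g <- toy_grn(data.frame(tf = "T", target = "G"))
  W <- normalize_adjacency(g)
  p <- propagate(c(T = 1), W, propagation_config(restart = 1))
  expect_equal(unname(p[c("G", "T")]), c(0, 1))
  cfg <- propagation_config(restart = 0.5, tol = 1e-10)
  p <- propagate(c(T = 1), W, cfg)
  direct <- solve(diag(2) - (1 - 0.5) * as.matrix(W),
                  0.5 * c(G = 0, T = 1))
  expect_equal(unname(p), unname(direct[names(p)]), tolerance = 1e-8)
  # fixed-point residual
  r <- 0.5
  p0 <- c(G = 0, T = 1)
  resid <- sum(abs((1 - r) * as.numeric(W %*% p) + r * p0 - p))
  expect_lt(resid, 1e-8)
  expect_error(propagate(c(T = 0, G = 0), W), "all-zero seed")
})

test_that("influence scoring handles degenerate cases as zero", {
  g <- toy_grn(data.frame(tf = c("T1", "T1", "T2"),
                          target = c("a", "b", "c")))
  W <- normalize_adjacency(g)
  # uniform |log2fc| over T1's exact targets: constant vector rule
  expect_equal(score_tf_influence("T1", g, c(a = 2, b = 2), W), 0)
  # TF with no path to any DEG
  expect_equal(score_tf_influence("T2", g, c(a = 2, b = 1.4), W), 0)
})

test_that("greedy selection covers with one sufficient TF and flags uncovered DEGs", {
  g <- toy_grn(data.frame(tf = "T", target = c("a", "b")))
  degs <- data.frame(gene = c("a", "b", "z"), timepoint = "5min",
                     log2fc = c(2, 1.5, 1.2), direction = "up")
  mod <- select_major_tfs(g, degs, "5min")
  expect_equal(mod$major_tfs$tf, "T")
  expect_setequal(mod$targets, c("a", "b"))
  expect_equal(mod$uncovered, "z")
  expect_lte(nrow(mod$major_tfs), 3)  # never more TFs than DEGs
  empty <- select_major_tfs(g, degs, "12h")
  expect_true(empty$empty)
  expect_equal(nrow(empty$major_tfs), 0L)
})

test_that("greedy coverage is sound and equals the exhaustive optimum on random instances", {
  set.seed(31)
  eq <- 0
  n_inst <- 10
  for (i in seq_len(n_inst)) {
    n_tf <- sample(3:6, 1)
    n_g <- sample(5:12, 1)
    tfs <- sprintf("T%d", seq_len(n_tf))
    genes <- sprintf("g%02d", seq_len(n_g))
    edges <- unique(data.frame(
      tf = sample(tfs, 3 * n_tf, replace = TRUE),
      target = sample(genes, 3 * n_tf, replace = TRUE)))
    g <- toy_grn(edges, tfs)
    deg_genes <- sample(genes, max(2, n_g %/% 2))
    degs <- data.frame(gene = deg_genes, timepoint = "t",
                       log2fc = runif(length(deg_genes), 1, 3),
                       direction = "up")
    mod <- select_major_tfs(g, degs, "t")
    targets_of <- split(g$edges$target, g$edges$tf)
    best <- brute_max_coverage(targets_of, deg_genes)
    expect_lte(length(mod$targets), best)
    if (length(mod$targets) == best) eq <- eq + 1
    expect_lte(nrow(mod$major_tfs), nrow(degs))
  }
  expect_gte(eq / n_inst, 0.9)
})

test_that("the master regulator has top influence at the earliest timepoint", {
  sim <- default_sim()
  g <- default_grn()$grn
  degs <- call_degs_all(expression_matrix(sim$counts))
  mod <- select_major_tfs(g, degs, "5min")
  expect_equal(mod$major_tfs$tf[1], sim$truth$master_tf)
  expect_equal(unname(which.max(mod$scores)),
               match(sim$truth$master_tf, names(mod$scores)))
  # intermediate TF is needed to cover the attenuated indirect regulon
  expect_true(sim$truth$intermediate_tf %in% mod$major_tfs$tf)
})

test_that("module target sets shrink as the planted response decays", {
  sim <- default_sim()
  g <- default_grn()$grn
  degs <- call_degs_all(expression_matrix(sim$counts))
  mods <- extract_modules(g, degs, c("5min", "1h", "3h", "12h"))
  sizes <- vapply(mods, function(m) length(m$targets), numeric(1))
  expect_gt(sizes[["5min"]], sizes[["3h"]])
  expect_gte(sizes[["5min"]], sizes[["1h"]])
})
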