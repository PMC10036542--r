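make_mat <- function(counts) {
  expression_matrix(counts)
}

toy_counts <- function(control, treated, tps = c("5min", "1h", "3h", "12h")) {
  # one replicate per timepoint, same treated means at each timepoint
  m <- cbind(control_1 = control,
             sapply(tps, function(tp) treated))
  colnames(m) <- c("control_1", paste0(tps, "_1"))
  rownames(m) <- sprintf("g%02d", seq_along(control))
  m
}

test_that("log2 fold change follows its closed form", {
  m <- toy_counts(c(100, 100, 0), c(100, 200, 0))
  mat <- make_mat(m)
  lfc <- compute_log2fc(mat, "5min")
  expect_equal(unname(lfc["g01"]), 0)
  expect_equal(unname(lfc["g02"]), log2(201 / 101))
  expect_equal(unname(lfc["g03"]), 0)  # pseudocount keeps 0/0 at 0
  expect_error(compute_log2fc(mat, "99h"), "unknown timepoint")
  expect_error(compute_log2fc(mat, "control"), "differ from control")
})

test_that("DEG calling is boundary-inclusive and sign-correct", {
  v <- c(a = 1.0, b = 0.99, c = -1.0, d = 2.0, e = -1.5, f = 0.2)
  degs <- call_degs(v, "5min")
  expect_setequal(degs$gene, c("a", "c", "d", "e"))
  expect_equal(degs$direction[degs$gene == "a"], "up")
  expect_equal(degs$direction[degs$gene == "c"], "down")
  expect_equal(sum(degs$direction == "up"), 2L)
  expect_equal(sum(degs$direction == "down"), 2L)
})

test_that("DEG calls obey sign symmetry, order invariance and threshold monotonicity", {
  set.seed(21)
  for (i in 1:10) {
    v <- stats::setNames(rnorm(30, sd = 1.2), sprintf("g%02d", 1:30))
    d <- call_degs(v, "t")
    flipped <- call_degs(-v, "t")
    expect_setequal(d$gene[d$direction == "up"],
                    flipped$gene[flipped$direction == "down"])
    expect_setequal(d$gene[d$direction == "down"],
                    flipped$gene[flipped$direction == "up"])
    shuffled <- call_degs(v[sample(names(v))], "t")
    expect_setequal(d$gene, shuffled$gene)
    stricter <- call_degs(v, "t", threshold = 1.5)
    expect_true(all(stricter$gene %in% d$gene))
  }
})

test_that("DEG set is invariant to replicate ordering", {
  set.seed(22)
  counts <- matrix(rpois(40 * 15, 200), 40, 15,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   paste0(rep(c("control", "5min", "1h",
                                                "3h", "12h"), each = 3),
                                          "_", 1:3)))
  d1 <- call_degs_all(expression_matrix(counts))
  d2 <- call_degs_all(expression_matrix(counts[, sample(ncol(counts))]))
  expect_setequal(paste(d1$gene, d1$timepoint),
                  paste(d2$gene, d2$timepoint))
})

test_that("z-score rows are standardized, zero-variance rows are zero", {
  set.seed(23)
  counts <- matrix(rpois(10 * 15, 300), 10, 15,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   paste0(rep(c("control", "5min", "1h",
                                                "3h", "12h"), each = 3),
                                          "_", 1:3)))
  counts["g01", ] <- 7  # constant gene
  z <- expression_zscores(expression_matrix(counts))
  expect_equal(unname(z["g01", ]), rep(0, 5))
  nz <- z[rowSums(abs(z)) > 0, ]
  expect_true(all(abs(rowMeans(nz)) < 1e-9))
  expect_true(all(abs(apply(nz, 1, sd) - 1) < 1e-9))
})

test_that("expression clustering separates planted patterns at the cut", {
  expect_equal(unname(cluster_expression(
    matrix(c(1, 2, 3, 1, 2, 3), 2, byrow = TRUE,
           dimnames = list(c("a", "b"), NULL)))),
    c(1L, 1L))
  set.seed(24)
  up <- matrix(rep(c(0, 2, 1, 0.5, 0.2), each = 10), 10,
               dimnames = list(sprintf("u%02d", 1:10), NULL))
  dn <- -up
  rownames(dn) <- sprintf("d%02d", 1:10)
  prof <- rbind(up, dn) + matrix(rnorm(100, sd = 0.05), 20, 5)
  cl <- cluster_expression(prof, linkage_cut = 3)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  single <- cluster_expression(prof[1, , drop = FALSE])
  expect_equal(unname(single), 1L)
})
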