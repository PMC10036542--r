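# Hand-built two-gene coverage scenarios: a contig with gene1 [0,100),
# gap, gene2, and a small expression matrix driving detector 4.
toy_pair_data <- function(gap_len, g1_cov, gap_cov, g2_cov,
                          strand = c("+", "+"),
                          e1 = c(10, 30, 20, 10, 5),
                          e2 = c(10, 30, 20, 10, 5)) {
  ann <- data.frame(gene = c("g1", "g2"), contig = "c1",
                    start = c(0L, 100L + gap_len),
                    end = c(100L, 200L + gap_len),
                    strand = strand, stringsAsFactors = FALSE)
  depth <- matrix(c(rep(g1_cov, 100), rep(gap_cov, gap_len),
                    rep(g2_cov, 100)), ncol = 1,
                  dimnames = list(NULL, "control_1"))
  coverage <- list(contig = "c1", samples = "control_1", depth = depth)
  tps <- c("control", "5min", "1h", "3h", "12h")
  counts <- rbind(g1 = round(e1 * 10), g2 = round(e2 * 10))
  colnames(counts) <- paste0(tps, "_1")
  mat <- expression_matrix(counts)
  list(coverage = coverage, annotation = ann, mat = mat)
}

test_that("flat identical coverage earns all six votes", {
  d <- toy_pair_data(gap_len = 50, g1_cov = 20, gap_cov = 20,
                     g2_cov = 20)
  pairs <- detect_operon_pairs(d$coverage, d$annotation, d$mat)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$votes, 6L)
  expect_true(pairs$call)
})

test_that("opposite-strand neighbours are not candidates", {
  d <- toy_pair_data(gap_len = 50, g1_cov = 20, gap_cov = 20,
                     g2_cov = 20, strand = c("+", "-"))
  pairs <- detect_operon_pairs(d$coverage, d$annotation, d$mat)
  expect_equal(nrow(pairs), 0L)
})

test_that("an empty long gap with uncorrelated expression fails the vote", {
  d <- toy_pair_data(gap_len = 200, g1_cov = 20, gap_cov = 0,
                     g2_cov = 22,
                     e1 = c(10, 30, 20, 10, 5),
                     e2 = c(20, 5, 18, 30, 9))
  pairs <- detect_operon_pairs(d$coverage, d$annotation, d$mat)
  # gap too long (d1), coverage heterogeneous (d2), empty gap (d3, d5),
  # uncorrelated profiles (d4): only d6 can vote yes
  expect_lte(pairs$votes, 2L)
  expect_false(pairs$call)
})

test_that("a zero-length gap votes from the boundary bases", {
  d <- toy_pair_data(gap_len = 0, g1_cov = 20, gap_cov = numeric(0),
                     g2_cov = 20)
  pairs <- detect_operon_pairs(d$coverage, d$annotation, d$mat)
  expect_equal(pairs$gap, 0L)
  expect_equal(pairs$votes, 6L)
})

test_that("votes are invariant to coverage sample ordering", {
  set.seed(41)
  sim <- default_sim()
  cov <- sim$coverage
  perm <- sample(ncol(cov$depth))
  cov2 <- list(contig = cov$contig, samples = cov$samples[perm],
               depth = cov$depth[, perm])
  mat <- expression_matrix(sim$counts)
  a <- detect_operon_pairs(cov, sim$annotation, mat)
  b <- detect_operon_pairs(cov2, sim$annotation, mat)
  expect_equal(a$votes, b$votes)
})

test_that("positive pairs chain transitively and break at negatives", {
  ann <- data.frame(gene = c("a", "b", "c", "d"), contig = "c1",
                    start = c(0L, 200L, 400L, 600L),
                    end = c(100L, 300L, 500L, 700L), strand = "+",
                    stringsAsFactors = FALSE)
  calls <- data.frame(gene1 = c("a", "b", "c"), gene2 = c("b", "c", "d"),
                      strand = "+", gap = 100L, votes = c(5L, 4L, 6L),
                      call = c(TRUE, TRUE, TRUE))
  ops <- chain_operons(calls, ann)
  expect_equal(length(ops), 1L)
  expect_equal(ops[[1]]$members, c("a", "b", "c", "d"))
  calls$call <- c(TRUE, FALSE, TRUE)
  ops <- chain_operons(calls, ann)
  expect_equal(lapply(unname(ops), `[[`, "members"),
               list(c("a", "b"), c("c", "d")))
  # minus-strand operons list members in transcription order
  calls$strand <- "-"
  calls$call <- c(TRUE, TRUE, TRUE)
  ann$strand <- "-"
  ops <- chain_operons(calls, ann)
  expect_equal(ops[[1]]$members, c("d", "c", "b", "a"))
})

test_that("operon values are the exact mean of member z-scores", {
  z <- rbind(a = c(1, 2, 0, -1, -2), b = c(3, 0, 0, 1, 1),
             c = c(0, 0, 0, 0, 0))
  colnames(z) <- c("control", "5min", "1h", "3h", "12h")
  prof <- operon_values(list(list(members = c("a", "b"))), z)
  expect_equal(unname(prof[1, ]), c(2, 1, 0, 0, -0.5))
  # identical member profiles reproduce the profile
  prof <- operon_values(list(list(members = c("a", "a"))), z)
  expect_equal(unname(prof[1, ]), unname(z["a", ]))
  # linearity in the member z-scores
  p1 <- operon_values(list(list(members = c("a", "b", "c"))), z)
  p3 <- operon_values(list(list(members = c("a", "b", "c"))), 3 * z)
  expect_equal(3 * p1, p3)
  expect_error(operon_values(list(list(members = c("a", "zz"))), z),
               "missing from the expression")
})

test_that("operon values match an independent tabular recomputation", {
  set.seed(42)
  sim <- default_sim()
  z <- expression_zscores(expression_matrix(sim$counts))
  ops <- lapply(1:5, function(i) {
    list(members = sample(rownames(z), 4))
  })
  prof <- operon_values(ops, z)
  for (i in 1:5) {
    manual <- colSums(z[ops[[i]]$members, ]) / 4
    expect_equal(unname(prof[i, ]), unname(manual))
  }
})

test_that("k-means recovers planted archetypes and is deterministic", {
  set.seed(43)
  arch <- archetype_profiles()
  cl <- cluster_operons(arch$profiles, k = 6, seed = 7)
  expect_gte(adjusted_rand(cl$cluster, arch$labels), 0.9)
  cl2 <- cluster_operons(arch$profiles, k = 6, seed = 7)
  expect_identical(cl$cluster, cl2$cluster)
  # k equal to the number of profiles puts each in its own cluster
  few <- arch$profiles[1:5, ]
  own <- cluster_operons(few, k = 5, seed = 1)
  expect_equal(length(unique(own$cluster)), 5L)
  expect_error(cluster_operons(few, k = 10, seed = 1), "sizing error")
})

test_that("genes belong to at most one operon and the in-operon fraction tracks the planting", {
  sim <- default_sim()
  mat <- expression_matrix(sim$counts)
  pairs <- detect_operon_pairs(sim$coverage, sim$annotation, mat)
  ops <- chain_operons(pairs, sim$annotation)
  members <- unlist(lapply(ops, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  frac_called <- length(members) / nrow(sim$annotation)
  frac_planted <- length(unlist(sim$truth$true_operons)) /
    nrow(sim$annotation)
  expect_lt(abs(frac_called - frac_planted), 0.10)
})
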