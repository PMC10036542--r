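# A reduced configuration keeps generator unit tests fast; the default
# configuration is exercised through the shared fixture and the
# planted-truth recovery tests.
small_config <- function(seed = 0, ...) {
  generator_config(n_genes = 60, n_ref_tfs = 8, n_strain_tfs = 4,
                   n_operons = 6, regulon_direct = 5,
                   regulon_indirect = 5, other_regulon_size = 3,
                   seed = seed, ...)
}

test_that("generation is bit-identical under a fixed seed", {
  a <- simulate_experiment(small_config(seed = 9))
  b <- simulate_experiment(small_config(seed = 9))
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$counts, b$counts)
  expect_identical(a$coverage$depth, b$coverage$depth)
  expect_identical(a$truth, b$truth)
  # and the serialized artifacts too
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_fasta(a$genome, file.path(d1, "g.fasta"))
  write_fasta(b$genome, file.path(d2, "g.fasta"))
  write_gff3(a$annotation, file.path(d1, "g.gff3"))
  write_gff3(b$annotation, file.path(d2, "g.gff3"))
  expect_identical(readLines(file.path(d1, "g.fasta")),
                   readLines(file.path(d2, "g.fasta")))
  expect_identical(readLines(file.path(d1, "g.gff3")),
                   readLines(file.path(d2, "g.gff3")))
  c_ <- simulate_experiment(small_config(seed = 10))
  expect_false(identical(a$genome, c_$genome))
})

test_that("infeasible configurations raise sizing errors", {
  expect_error(generator_config(n_genes = 50, n_operons = 40,
                                operon_size_range = c(2, 5)),
               "sizing error")
  expect_error(generator_config(n_strain_tfs = -1))
  expect_error(generator_config(effect_decay = c(1, 0.5)),
               "effect_decay")
  cfg <- small_config()
  cfg$n_strain_tfs <- 10L  # more strain TFs than references
  g <- generate_genome(cfg)
  tfdb <- generate_tf_database(cfg)
  expect_error(generate_strain_proteome(cfg, g, tfdb), "config error")
})

test_that("planted operons are same-strand adjacent blocks with bounded gaps", {
  sim <- default_sim()
  ann <- sim$annotation[order(sim$annotation$start), ]
  for (op in sim$truth$true_operons) {
    idx <- sort(match(op, ann$gene))
    expect_equal(idx, seq(idx[1], idx[1] + length(op) - 1L))
    expect_equal(length(unique(ann$strand[idx])), 1L)
    gaps <- ann$start[idx[-1]] - ann$end[idx[-length(idx)]]
    expect_true(all(gaps <= 50))
    expect_true(all(gaps >= 0))
  }
  lens <- ann$end - ann$start
  expect_true(all(lens >= 300 & lens <= 1500))
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))  # no overlap
})

test_that("the TF database is well-formed and seed-sensitive", {
  cfg <- generator_config(seed = 1)
  db <- generate_tf_database(cfg)
  expect_length(db$proteins, 20L)
  plens <- nchar(db$proteins)
  expect_true(all(plens >= 100 & plens <= 300))
  for (pwm in db$pwms) {
    expect_true(all(abs(colSums(pwm) - 1) < 1e-9))
    expect_true(ncol(pwm) >= 8 && ncol(pwm) <= 14)
  }
  db2 <- generate_tf_database(generator_config(seed = 2))
  cons <- function(db) vapply(db$pwms, bacgrn:::consensus_seq,
                              character(1))
  expect_false(identical(unname(cons(db)), unname(cons(db2))))
})

test_that("strain TFs are faithful mutated copies of distinct donors", {
  cfg <- small_config(seed = 4, tf_mutation_rate = 0)
  g <- generate_genome(cfg)
  tfdb <- generate_tf_database(cfg)
  p <- generate_strain_proteome(cfg, g, tfdb)
  for (tf in p$truth$true_tfs) {
    expect_identical(p$proteome[[tf]],
                     unname(tfdb$proteins[[p$truth$tf_donor[[tf]]]]))
  }
  expect_equal(anyDuplicated(p$truth$tf_donor), 0L)
  # no planted TFs at all
  cfg0 <- small_config(seed = 4)
  cfg0$n_strain_tfs <- 0L
  p0 <- generate_strain_proteome(cfg0, g, tfdb)
  expect_length(p0$truth$true_tfs, 0L)
  expect_length(p0$proteome, cfg0$n_genes)
})

test_that("planted sites sit in the promoter window and score at the PWM maximum", {
  sim <- default_sim()
  ann <- sim$annotation
  for (i in seq_len(nrow(sim$truth$planted_sites))) {
    s <- sim$truth$planted_sites[i, ]
    g <- ann[ann$gene == s$target, ]
    if (g$strand == "+") {
      expect_lte(s$end, g$start)
      expect_gte(s$start, g$start - 300)
    } else {
      expect_gte(s$start, g$end)
      expect_lte(s$end, g$end + 300)
    }
    # rescan the planted coordinates: consensus planting reaches the
    # maximal attainable log-odds score
    donor <- sim$truth$tf_donor[[s$tf]]
    lom <- pwm_log_odds(sim$tfdb$pwms[[donor]])
    L <- ncol(lom)
    window <- substr(sim$genome[[1]], s$start + 1, s$end)
    if (s$strand == "-") {
      window <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(window)))
    }
    v <- strsplit(window, "")[[1]]
    sc <- sum(vapply(seq_len(L), function(j) lom[v[j], j], numeric(1)))
    expect_equal(sc, attr(lom, "max_score"), tolerance = 1e-9)
  }
})

test_that("every true edge has exactly one planted site", {
  sim <- default_sim()
  key_e <- paste(sim$truth$true_edges$tf, sim$truth$true_edges$target)
  key_s <- paste(sim$truth$planted_sites$tf,
                 sim$truth$planted_sites$target)
  expect_equal(sort(key_e), sort(key_s))
  expect_equal(anyDuplicated(key_s), 0L)
})

test_that("true DEG sets decay monotonically and vanish without an effect", {
  sim <- default_sim()
  sizes <- vapply(sim$truth$true_degs, function(d) {
    length(d$up) + length(d$down)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  cfg <- small_config(seed = 6, effect_decay = c(0, 0, 0, 0))
  sim0 <- simulate_experiment(cfg)
  expect_true(all(vapply(sim0$truth$true_degs, function(d) {
    length(d$up) + length(d$down) == 0
  }, logical(1))))
})

test_that("replicate counts approach configured means as dispersion vanishes", {
  cfg <- small_config(seed = 8, nb_dispersion = 1e-4)
  sim <- simulate_experiment(cfg)
  mat <- expression_matrix(sim$counts)
  tm <- timepoint_means(mat)
  base <- tm[, "control"]
  # unperturbed genes: every timepoint mean within a few percent of control
  quiet <- setdiff(rownames(tm),
                   unique(sim$truth$true_edges$target))
  rel <- abs(tm[quiet, -1] - base[quiet]) / base[quiet]
  expect_lt(stats::median(rel), 0.05)
  # regulon genes shift by the planted effect at the first timepoint
  # (direct targets by 2.0, indirect by 2.0 * 0.7 = 1.4 log2 units)
  up5 <- sim$truth$true_degs[["5min"]]$up
  expect_true(all(log2(tm[up5, "5min"] / base[up5]) > 1.3))
})
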