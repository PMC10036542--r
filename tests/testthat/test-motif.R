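test_that("PWM transfer copies the donor matrix under the strain TF id", {
  cfg <- generator_config(seed = 2)
  tfdb <- generate_tf_database(cfg)
  screen <- data.frame(tf = c("gA", "gB"),
                       donor = c("refTF003", "refTF003"))
  pw <- transfer_pwm(screen, tfdb)
  expect_named(pw, c("gA", "gB"))
  expect_equal(unname(pw$gA), unname(tfdb$pwms$refTF003))
  expect_identical(pw$gA, pw$gB)
  expect_equal(length(transfer_pwm(screen[0, ], tfdb)), 0L)
  expect_error(transfer_pwm(data.frame(tf = "g", donor = "nope"), tfdb),
               "without a PWM")
})

test_that("log-odds scoring matches its closed form", {
  uni <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_true(all(abs(pwm_log_odds(uni)) < 1e-12))
  hard <- matrix(c(1, 0, 0, 0), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  lo <- pwm_log_odds(hard)
  expect_equal(unname(lo["A", 1]),
               log2((1 + 0.01 * 0.25) / (1.01 * 0.25)),
               tolerance = 1e-12)
  set.seed(1)
  m <- random_pwm(6)
  lo <- pwm_log_odds(m)
  expect_equal(attr(lo, "max_score"), sum(apply(lo, 2, max)))
  expect_error(pwm_log_odds(m, background = c(0.5, 0.5, 0, 0)),
               "strictly positive")
  bad <- m; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(pwm_log_odds(bad), "sum to 1")
})

test_that("an embedded consensus is the unique hit at threshold 1", {
  set.seed(4)
  pwm <- random_pwm(10)
  cons <- paste(c("A", "C", "G", "T")[apply(pwm, 2, which.max)],
                collapse = "")
  genome <- paste0(random_dna_seq(500), cons, random_dna_seq(500))
  # make sure the random flanks do not contain the consensus by chance
  hits <- scan_genome(pwm_log_odds(pwm), genome, threshold_frac = 1,
                      tf = "t")
  fw <- hits[hits$strand == "+", ]
  expect_true(any(fw$start == 500))
  expect_equal(nrow(fw[fw$start == 500, ]), 1L)
})

test_that("the scanner equals per-window brute-force rescoring", {
  set.seed(12)
  for (i in 1:3) {
    pwm <- random_pwm(sample(6:10, 1), min_dom = 0.5, max_dom = 0.9)
    lom <- pwm_log_odds(pwm)
    seq <- random_dna_seq(2000)
    got <- scan_genome(lom, seq, threshold_frac = 0.7, tf = "t")
    want <- brute_scan(lom, seq, 0.7)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("scanning is strand-symmetric and monotone in the threshold", {
  set.seed(13)
  pwm <- random_pwm(8, min_dom = 0.6, max_dom = 0.9)
  lom <- pwm_log_odds(pwm)
  seq <- random_dna_seq(3000)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  a <- scan_genome(lom, seq, threshold_frac = 0.7, tf = "t")
  b <- scan_genome(lom, rc, threshold_frac = 0.7, tf = "t")
  # a site at + coordinates [s, e) on seq appears on the reverse
  # complement at [G - e, G - s) with flipped strand
  G <- nchar(seq)
  expect_setequal(paste(a$start, a$strand),
                  paste(G - b$end, ifelse(b$strand == "+", "-", "+")))
  lo_thr <- scan_genome(lom, seq, threshold_frac = 0.5, tf = "t")
  expect_true(all(paste(a$start, a$strand) %in%
                    paste(lo_thr$start, lo_thr$strand)))
  expect_false(is.unsorted(a$start))
})

test_that("ambiguous bases score zero per position", {
  pwm <- matrix(c(0.97, 0.01, 0.01, 0.01), 4, 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  lom <- pwm_log_odds(pwm)
  hits <- scan_genome(lom, "AANA", threshold_frac = 0, tf = "t")
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$score, 3 * unname(lom["A", 1]) + 0)
})

test_that("every planted site is recovered at the default threshold", {
  sim <- default_sim()
  sites <- default_grn()$sites
  planted <- sim$truth$planted_sites
  key <- paste(sites$tf, sites$start, sites$end)
  expect_true(all(paste(planted$tf, planted$start, planted$end) %in% key))
})
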