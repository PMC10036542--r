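# Independent oracles and shared fixtures. The oracles deliberately use
# naive algorithms (cubic DP, per-window rescoring, combinatorial sums) so
# they share no code path with the implementation they check.

# Naive cubic-time affine-gap local alignment: explicit maximisation over
# all gap lengths at every cell. A gap of length k costs open + k * ext.
naive_sw <- function(query, subject, open = 11, ext = 1) {
  sub <- bacgrn:::blosum62_matrix()
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(q); n <- length(s)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cand <- c(0, H[i, j] + sub[q[i], s[j]])
      for (k in seq_len(i)) cand <- c(cand, H[i - k + 1, j + 1] - open - k * ext)
      for (k in seq_len(j)) cand <- c(cand, H[i + 1, j - k + 1] - open - k * ext)
      H[i + 1, j + 1] <- max(cand)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

random_peptide <- function(len) {
  paste(sample(bacgrn:::AA20, len, replace = TRUE,
               prob = bacgrn:::AA_FREQ), collapse = "")
}

random_pwm <- function(L, min_dom = 0.85, max_dom = 0.97) {
  m <- sapply(seq_len(L), function(j) {
    dom <- sample(4, 1)
    p <- runif(1, min_dom, max_dom)
    rest <- runif(3); rest <- rest / sum(rest) * (1 - p)
    col <- numeric(4); col[dom] <- p; col[-dom] <- rest
    col
  })
  rownames(m) <- c("A", "C", "G", "T")
  m
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Sliding-window rescoring oracle for the genome scanner: scores every
# window on both strands one at a time.
brute_scan <- function(lom, seq, threshold_frac) {
  L <- ncol(lom)
  maxs <- sum(apply(lom, 2, max))
  thr <- threshold_frac * maxs - 1e-9  # same float guard as the scanner
  score_one <- function(w) {
    v <- strsplit(w, "")[[1]]
    sum(vapply(seq_len(L), function(j) {
      if (v[j] %in% rownames(lom)) lom[v[j], j] else 0
    }, numeric(1)))
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  G <- nchar(seq)
  out <- list()
  for (k in seq_len(G - L + 1)) {
    sc <- score_one(substr(seq, k, k + L - 1))
    if (sc >= thr) {
      out[[length(out) + 1]] <- data.frame(start = k - 1, strand = "+",
                                           score = sc)
    }
    sc <- score_one(substr(rc, k, k + L - 1))
    if (sc >= thr) {
      out[[length(out) + 1]] <- data.frame(start = G - k + 1 - L,
                                           strand = "-", score = sc)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# Exhaustive hypergeometric upper tail from binomial coefficients.
brute_hyper <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exhaustive max-coverage over all TF subsets (feasible for <= 10 TFs).
brute_max_coverage <- function(targets_of, deg_set) {
  tfs <- names(targets_of)
  best <- 0
  for (mask in 0:(2^length(tfs) - 1)) {
    sel <- tfs[bitwAnd(mask, 2^(seq_along(tfs) - 1)) > 0]
    cov <- length(intersect(unique(unlist(targets_of[sel])), deg_set))
    best <- max(best, cov)
  }
  best
}

true_operon_pairs <- function(sim) {
  unlist(lapply(sim$truth$true_operons, function(op) {
    idx <- match(op, sim$annotation$gene)
    idx <- idx[order(sim$annotation$start[idx])]
    g <- sim$annotation$gene[idx]
    paste(g[-length(g)], g[-1])
  }))
}

# The default synthetic dataset is expensive; build it once per test run.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(generator_config())
    cache
  }
})

# GRN inferred from the default dataset with the generator's TF-candidate
# list (the TF-prediction stand-in), as the default pipeline runs it.
default_grn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- default_sim()
      screen <- screen_tfs(sim$proteome, sim$tfdb,
                           candidates = sim$truth$true_tfs)
      loms <- lapply(transfer_pwm(screen, sim$tfdb), pwm_log_odds)
      sites <- scan_genome(loms, sim$genome)
      raw <- assign_targets(sites, sim$annotation)
      cache <<- list(screen = screen, sites = sites, raw = raw,
                     grn = build_grn(raw, screen$tf))
    }
    cache
  }
})

# Six well-separated archetype time profiles for planted-partition
# clustering checks: early up/down (decaying), late up/down, transient
# mid-course up/down.
archetype_profiles <- function(copies = 10, noise_sd = 0.1) {
  arch <- rbind(
    c(0, 2.0, 1.0, 0.4, 0.1),
    c(0, -2.0, -1.0, -0.4, -0.1),
    c(0, 0.1, 0.4, 1.2, 2.0),
    c(0, -0.1, -0.4, -1.2, -2.0),
    c(0, 0.3, 2.0, 0.3, 0),
    c(0, -0.3, -2.0, -0.3, 0))
  prof <- arch[rep(seq_len(6), each = copies), ] +
    matrix(rnorm(6 * copies * 5, sd = noise_sd), 6 * copies, 5)
  rownames(prof) <- sprintf("op%03d", seq_len(nrow(prof)))
  colnames(prof) <- c("control", "5min", "1h", "3h", "12h")
  list(profiles = prof, labels = rep(seq_len(6), each = copies))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
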