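# shared small fixtures, built once per test run

tiny_cfg <- function(...) {
  args <- modifyList(
    list(n_loci = 60, n_subjects_conv = 6, n_controls = 8,
         de_fraction = 0.1, dispersion = 0.1, n_tissues = 2,
         lib_size_range = c(2e5, 4e5), seed = 101L),
    list(...))
  do.call(simulation_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_dataset <- function() {
  fixture("tiny_dataset", function() simulate_dataset(tiny_cfg()))
}

# a well-powered medium dataset reused by DE-oriented tests
de_dataset <- function() {
  fixture("de_dataset", function() {
    cfg <- simulation_config(n_loci = 250, n_subjects_conv = 12,
                             n_controls = 12, de_fraction = 0.08,
                             dispersion = 0.1, planted_lfc = 2, seed = 202L)
    ref <- simulate_te_reference(cfg)
    ex <- simulate_counts(ref$loci, cfg)
    list(cfg = cfg, loci = ref$loci, counts = ex$counts,
         metadata = ex$metadata, truth = ex$truth)
  })
}

# planted-feature construction shared by the Boruta checks: 5 informative
# features shifted 3 SD by class plus 50 pure-noise features, n = 60
boruta_fixture <- function() {
  fixture("boruta_fixture", function() {
    set.seed(100)
    n <- 60
    y <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * 55), n, 55,
                dimnames = list(NULL, sprintf("f%02d", 1:55)))
    X[y == "B", 1:5] <- X[y == "B", 1:5] + 3
    list(X = X, y = y)
  })
}

# independent brute-force histogram entropy (bits)
oracle_entropy <- function(values, n_bins = 10) {
  x <- log2(values + 1)
  if (max(x) == min(x)) return(0)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- vapply(seq_len(n_bins), function(i) {
    if (i == 1) sum(x >= edges[1] & x <= edges[2])
    else sum(x > edges[i] & x <= edges[i + 1])
  }, numeric(1))
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# exhaustive fixed-margin enumeration oracle for the two-sided Fisher p
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b
  if (m == 0 || n2 == 0 || k == 0 || k == a + b + c + d) return(1)
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  pr <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k))
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# brute-force semi-global DP (linear gaps, free end-gaps on target): score
# oracle for the aligner
oracle_semiglobal_score <- function(query, target, match = 2, mismatch = -1,
                                    gap = -2) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  D <- matrix(-Inf, n + 1, m + 1)
  D[1, ] <- 0                      # free leading gaps on target
  D[, 1] <- gap * (0:n)            # query must be fully aligned
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (q[i] == t[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap, D[i + 1, j] + gap)
    }
  }
  max(D[n + 1, ])                  # free trailing gaps on target
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
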