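test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_loci = 0), "positive")
  expect_error(simulation_config(class_mix = c(LINE = 0.5, SINE = 0.4)), "sum to 1")
  expect_error(simulation_config(frac_multimap = 0.7, frac_lowid = 0.5),
               "must not exceed 1")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(state_probs = c(bogus_state = 1)), "Unknown")
})

test_that("reference generation is deterministic and honours the class mix", {
  cfg <- tiny_cfg(n_loci = 100,
                  class_mix = c(LINE = .2, SINE = .2, LTR = .2, SVA = .2, DNA = .2),
                  seed = 7)
  r1 <- simulate_te_reference(cfg)
  r2 <- simulate_te_reference(cfg)
  expect_identical(r1$loci, r2$loci)
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))
  expect_equal(nrow(r1$loci), 100)
  # uniform mix: every class drawn, roughly balanced
  tab <- table(r1$loci$te_class)
  expect_setequal(names(tab), c("LINE", "SINE", "LTR", "SVA", "DNA"))
  expect_true(all(tab >= 8) && all(tab <= 35))

  one <- simulate_te_reference(tiny_cfg(n_loci = 1, class_mix = c(LINE = 1)))
  expect_equal(one$loci$te_class, "LINE")
})

test_that("loci are non-overlapping half-open intervals with in-range lengths", {
  loci <- tiny_dataset()$reference$loci
  expect_true(all(loci$start < loci$end))
  lens <- loci$end - loci$start
  expect_true(all(lens >= 300 & lens <= 7000))
  by_chrom <- split(loci, loci$chrom)
  for (lc in by_chrom) {
    lc <- lc[order(lc$start), ]
    expect_true(all(lc$start[-1] >= lc$end[-nrow(lc)]))
  }
  # sequence length matches the interval
  seqs <- tiny_dataset()$reference$sequences
  expect_equal(unname(Biostrings::width(seqs[loci$locus_id])), unname(lens))
})

test_that("transcript truth table matches the planted fractions exactly", {
  d <- tiny_dataset()
  cfg <- d$config
  truth <- d$transcripts$truth
  expect_equal(sum(truth$status == "low_identity"),
               round(cfg$frac_lowid * cfg$n_loci))
  expect_equal(sum(truth$status == "multimap"),
               round(cfg$frac_multimap * cfg$n_loci))
  # low-identity transcripts sit strictly below 95, others at/above
  expect_true(all(truth$pident[truth$status == "low_identity"] < 95))
  expect_true(all(truth$pident[truth$status != "low_identity"] >= 95))
  # multimappers have exactly two records, others one
  n_rec <- table(d$transcripts$alignments$transcript_id)
  mm <- truth$transcript_id[truth$status == "multimap"]
  expect_true(all(n_rec[mm] == 2))
  expect_true(all(n_rec[setdiff(truth$transcript_id, mm)] == 1))
})

test_that("recorded identity equals the value recomputed from the edit trace", {
  d <- tiny_dataset()
  truth <- d$transcripts$truth
  aln <- d$transcripts$alignments
  ref_seq <- as.character(d$reference$sequences)
  tx_seq <- as.character(d$transcripts$transcripts)
  primary <- truth |>
    dplyr::select("transcript_id", "locus_id") |>
    dplyr::inner_join(aln, by = c("transcript_id", "locus_id"))
  for (i in seq_len(nrow(primary))) {
    r <- strsplit(ref_seq[[primary$locus_id[i]]], "")[[1]]
    q <- strsplit(tx_seq[[primary$transcript_id[i]]], "")[[1]]
    expect_equal(length(q), primary$qlen[i])
    n_sub <- sum(r != q)
    expect_equal(primary$pident[i], (length(q) - n_sub) / length(q) * 100)
    expect_equal(primary$mismatch[i], n_sub)
  }
})

test_that("no multimap config yields single records everywhere", {
  cfg <- tiny_cfg(frac_multimap = 0, frac_lowid = 0)
  d <- simulate_transcripts(simulate_te_reference(cfg), cfg)
  expect_true(all(table(d$alignments$transcript_id) == 1))
  expect_true(all(d$alignments$pident >= 95))
})

test_that("null counts centre pre/post log-ratios at zero", {
  cfg <- tiny_cfg(n_loci = 200, de_fraction = 0, n_subjects_conv = 10,
                  seed = 33)
  ref <- simulate_te_reference(cfg)
  ex <- simulate_counts(ref$loci, cfg)
  expect_equal(nrow(ex$truth$de), 0)
  # depth-normalize before comparing group means
  m <- telex:::counts_matrix(calc_tpm(ex$counts))
  md <- ex$metadata
  pre <- rowMeans(m[, md$sample_id[md$group == "Converter_pre"]])
  post <- rowMeans(m[, md$sample_id[md$group == "Converter_post"]])
  lr <- log2((post + 0.5) / (pre + 0.5))
  expect_lt(abs(mean(lr)), 0.1)
})

test_that("planted fold-changes are recovered empirically", {
  cfg <- simulation_config(n_loci = 400, n_subjects_conv = 20, n_controls = 10,
                           de_fraction = 0.1, planted_lfc = 2, dispersion = 0.1,
                           frac_pre_signature = 0, seed = 55)
  ref <- simulate_te_reference(cfg)
  ex <- simulate_counts(ref$loci, cfg)
  m <- telex:::counts_matrix(calc_tpm(ex$counts))
  md <- ex$metadata
  tr <- ex$truth$de[ex$truth$de$contrast == "pre_vs_post", ]
  pre <- rowMeans(log2(m[tr$locus_id, md$sample_id[md$group == "Converter_pre"]] + 1))
  post <- rowMeans(log2(m[tr$locus_id, md$sample_id[md$group == "Converter_post"]] + 1))
  observed <- (post - pre) * tr$sign
  # mean planted effect within 3 SE of the nominal magnitude
  se <- sd(observed) / sqrt(length(observed))
  expect_lt(abs(mean(observed) - cfg$planted_lfc), 3 * se + 0.25)
})

test_that("fixed library size concentrates column totals", {
  # near-Poisson dispersion: the multinomial-style concentration bound
  # applies (overdispersion inflates column-sum variance otherwise)
  cfg <- tiny_cfg(lib_size_range = c(1e6, 1e6), n_loci = 100, seed = 77,
                  dispersion = 1e-3)
  ref <- simulate_te_reference(cfg)
  ex <- simulate_counts(ref$loci, cfg)
  cs <- colSums(telex:::counts_matrix(ex$counts))
  expect_true(all(abs(cs - 1e6) / 1e6 < 0.05))
})

test_that("age is independent of planted expression structure", {
  ex <- tiny_dataset()$expression
  md <- ex$metadata
  expect_true(all(md$age > 60 & md$age < 105))
  # paired samples share subject-level covariates
  pairs <- split(md, md$pair_id)
  for (p in pairs) {
    if (nrow(p) == 2) {
      expect_equal(p$age[1], p$age[2])
      expect_equal(p$sex[1], p$sex[2])
    }
  }
})

test_that("chromatin tracks tile chromosomes exactly, straddle loci get two states", {
  cfg <- tiny_cfg(n_tissues = 3)
  ref <- simulate_te_reference(cfg)
  straddle <- ref$loci$locus_id[c(1, 5)]
  ch <- simulate_chromatin_tracks(ref$loci, cfg, straddle = straddle,
                                  chrom_sizes = ref$chrom_sizes)
  seg <- ch$segments
  for (tis in unique(seg$tissue)) {
    for (chr in unique(seg$chrom)) {
      s <- seg[seg$tissue == tis & seg$chrom == chr, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 0)
      expect_equal(s$end[nrow(s)],
                   ref$chrom_sizes$size[ref$chrom_sizes$chrom == chr])
      expect_true(all(s$start[-1] == s$end[-nrow(s)])) # no gaps, no overlaps
    }
  }
  expect_true(all(ch$truth$state[ch$truth$locus_id %in% straddle] == "Mx"))
  # degenerate composition: a single state everywhere
  cfg_q <- tiny_cfg(state_probs = c("15_Quies" = 1), n_tissues = 1)
  ch_q <- simulate_chromatin_tracks(ref$loci, cfg_q,
                                    chrom_sizes = ref$chrom_sizes)
  expect_true(all(ch_q$segments$state == "15_Quies"))
})

test_that("generators are seed-stable across repeated full-dataset builds", {
  d1 <- simulate_dataset(tiny_cfg(seed = 9))
  d2 <- simulate_dataset(tiny_cfg(seed = 9))
  expect_identical(d1$expression$counts, d2$expression$counts)
  expect_identical(d1$chromatin$segments, d2$chromatin$segments)
  expect_identical(d1$transcript_counts, d2$transcript_counts)
  d3 <- simulate_dataset(tiny_cfg(seed = 10))
  expect_false(identical(d1$expression$counts, d3$expression$counts))
})
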