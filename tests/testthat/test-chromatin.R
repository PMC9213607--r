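seg_row <- function(tissue, chrom, start, end, state) {
  tibble::tibble(tissue = tissue, chrom = chrom, start = start, end = end,
                 state = state)
}

test_that("single-state coverage and boundary straddling label as specified", {
  loci <- tibble::tibble(locus_id = c("L1", "L2", "L3"), chrom = "chr1",
                         start = c(100, 500, 900), end = c(200, 700, 1000))
  segs <- dplyr::bind_rows(
    seg_row("blood", "chr1", 0, 600, "15_Quies"),
    seg_row("blood", "chr1", 600, 950, "7_Enh"),
    seg_row("blood", "chr1", 950, 2000, "5_TxWk"))
  st <- overlap_states(loci, segs)
  asg <- st$assignment
  expect_equal(asg$state[asg$locus_id == "L1"], "15_Quies")
  expect_equal(asg$state[asg$locus_id == "L2"], "Mx")   # straddles 600
  expect_equal(asg$state[asg$locus_id == "L3"], "Mx")   # straddles 950
  # overlap bp arithmetic
  brk <- st$breakdown
  expect_equal(brk$bp[brk$locus_id == "L2" & brk$state == "15_Quies"], 100L)
  expect_equal(brk$bp[brk$locus_id == "L2" & brk$state == "7_Enh"], 100L)
  # uncovered locus is NA
  st2 <- overlap_states(tibble::tibble(locus_id = "far", chrom = "chr9",
                                       start = 0, end = 10), segs)
  expect_true(is.na(st2$assignment$state))
  # overlapping segmentation triggers an error naming the tissue
  bad <- dplyr::bind_rows(seg_row("bad_tis", "chr1", 0, 500, "4_Tx"),
                          seg_row("bad_tis", "chr1", 400, 900, "9_Het"))
  expect_error(overlap_states(loci, bad), "bad_tis")
  expect_error(overlap_states(loci, seg_row("t", "chr1", 0, 10, "99_Nope")),
               "Unknown")
})

test_that("state labels are accepted with or without numeric prefixes", {
  loci <- tibble::tibble(locus_id = "L1", chrom = "c", start = 10, end = 20)
  st <- overlap_states(loci, seg_row("t", "c", 0, 100, "TxWk"))
  expect_equal(st$assignment$state, "5_TxWk")
})

test_that("per-state bp matches a base-resolution brute-force scan", {
  d <- tiny_dataset()
  loci <- d$reference$loci
  segs <- d$chromatin$segments
  st <- overlap_states(loci, segs)
  # brute force at single-base resolution on a subset
  set.seed(4)
  for (i in sample(nrow(loci), 10)) {
    for (tis in unique(segs$tissue)) {
      seg <- segs[segs$tissue == tis & segs$chrom == loci$chrom[i], ]
      bases <- seq(loci$start[i], loci$end[i] - 1)
      base_state <- vapply(bases, function(b) {
        seg$state[seg$start <= b & b < seg$end][1]
      }, character(1))
      expected <- table(base_state)
      got <- st$breakdown[st$breakdown$locus_id == loci$locus_id[i] &
                            st$breakdown$tissue == tis, ]
      expect_setequal(got$state, names(expected))
      expect_equal(got$bp[match(names(expected), got$state)],
                   unname(as.integer(expected)))
    }
  }
  # tiling: per-locus bp totals equal locus length
  totals <- dplyr::count(st$breakdown, locus_id, tissue, wt = bp)
  lens <- setNames(loci$end - loci$start, loci$locus_id)
  expect_true(all(totals$n == lens[totals$locus_id]))
})

test_that("assignments survive same-state splits and coordinate shifts", {
  loci <- tibble::tibble(locus_id = c("L1", "L2"), chrom = "c",
                         start = c(100, 400), end = c(300, 600))
  segs <- dplyr::bind_rows(seg_row("t", "c", 0, 350, "4_Tx"),
                           seg_row("t", "c", 350, 1000, "9_Het"))
  base <- overlap_states(loci, segs)
  # split an interval into adjacent same-state pieces
  split_segs <- dplyr::bind_rows(
    seg_row("t", "c", 0, 150, "4_Tx"), seg_row("t", "c", 150, 350, "4_Tx"),
    seg_row("t", "c", 350, 1000, "9_Het"))
  expect_equal(overlap_states(loci, split_segs)$assignment, base$assignment)
  # constant shift of all coordinates
  shift <- 10000
  shifted <- overlap_states(
    dplyr::mutate(loci, start = start + shift, end = end + shift),
    dplyr::mutate(segs, start = start + shift, end = end + shift))
  expect_equal(shifted$assignment$state, base$assignment$state)
})

test_that("active fractions report 0, 1 and planted compositions", {
  loci <- tibble::tibble(locus_id = paste0("L", 1:4), chrom = "c",
                         start = c(0, 100, 200, 300) + 10,
                         end = c(0, 100, 200, 300) + 90)
  quies <- seg_row("t", "c", 0, 1000, "15_Quies")
  st0 <- overlap_states(loci, quies)
  f0 <- active_fraction(st0, loci$locus_id, "t")
  expect_equal(f0$label_based, 0)
  expect_equal(f0$any_overlap, 0)
  enh <- seg_row("t", "c", 0, 1000, "7_Enh")
  f1 <- active_fraction(overlap_states(loci, enh), loci$locus_id, "t")
  expect_equal(f1$label_based, 1)
  expect_equal(f1$any_overlap, 1)
  expect_error(active_fraction(st0, loci$locus_id, "nope"), "Unknown tissue")

  # planted 70% active composition is recovered within a binomial CI
  cfg <- tiny_cfg(n_loci = 200, n_tissues = 1, seed = 71,
                  state_probs = c("7_Enh" = 0.4, "4_Tx" = 0.3,
                                  "15_Quies" = 0.2, "9_Het" = 0.1))
  ref <- simulate_te_reference(cfg)
  ch <- simulate_chromatin_tracks(ref$loci, cfg, chrom_sizes = ref$chrom_sizes)
  st <- overlap_states(ref$loci, ch$segments)
  fr <- active_fraction(st, ref$loci$locus_id, "tissue_01")
  ci_half <- 3 * sqrt(0.7 * 0.3 / 200)
  expect_lt(abs(fr$label_based - 0.7), ci_half)
})

test_that("state enrichment flags a planted enhancer excess and no self-flags", {
  loci <- tibble::tibble(locus_id = paste0("L", sprintf("%03d", 1:100)),
                         chrom = "c",
                         start = seq(0, by = 1000, length.out = 100) + 10,
                         end = seq(0, by = 1000, length.out = 100) + 500)
  # first 30 loci inside Enh, remainder Quies
  segs <- dplyr::bind_rows(
    seg_row("t", "c", 0, 30 * 1000 - 100, "7_Enh"),
    seg_row("t", "c", 30 * 1000 - 100, 2e5, "15_Quies"))
  st <- overlap_states(loci, segs)
  de <- loci$locus_id[1:25]            # 24/25 in Enh vs 30/100 overall
  res <- state_enrichment(st, de, loci$locus_id, "t")
  enh <- res[res$label == "7_Enh", ]
  expect_true(enh$significant)
  expect_equal(enh$direction, "enriched")
  null <- state_enrichment(st, loci$locus_id, loci$locus_id, "t")
  expect_true(all(!null$significant))
})

test_that("cross-tissue consistency: identical tracks agree, independent match expectation", {
  cfg <- tiny_cfg(n_loci = 150, n_tissues = 3, seed = 81)
  ref <- simulate_te_reference(cfg)
  ch <- simulate_chromatin_tracks(ref$loci, cfg, chrom_sizes = ref$chrom_sizes)
  # identical tracks: duplicate one tissue
  one <- ch$segments[ch$segments$tissue == "tissue_01", ]
  dup <- dplyr::bind_rows(one, dplyr::mutate(one, tissue = "tissue_01b"),
                          dplyr::mutate(one, tissue = "tissue_01c"))
  cc_same <- cross_tissue_consistency(overlap_states(ref$loci, dup))
  expect_equal(mean(cc_same$locus_agreement$agreement), 1)
  expect_true(all(cc_same$dendrogram$height < 1e-12))
  # independent tracks: agreement approximates sum of squared state freqs
  cc_ind <- cross_tissue_consistency(overlap_states(ref$loci, ch$segments))
  p_state <- cfg$state_probs
  expected <- sum(p_state^2)
  expect_lt(abs(mean(cc_ind$locus_agreement$agreement) - expected), 0.08)
  # two planted blocks split first in the dendrogram
  blocks <- dplyr::bind_rows(
    one, dplyr::mutate(one, tissue = "a2"),
    dplyr::mutate(ch$segments[ch$segments$tissue == "tissue_02", ],
                  tissue = "b1"),
    dplyr::mutate(ch$segments[ch$segments$tissue == "tissue_02", ],
                  tissue = "b2"))
  cc_b <- cross_tissue_consistency(overlap_states(ref$loci, blocks))
  merged_first <- stats::cutree(cc_b$dendrogram, k = 2)
  expect_equal(unname(merged_first[c("tissue_01", "a2")]),
               rep(merged_first[["tissue_01"]], 2))
  expect_equal(unname(merged_first[c("b1", "b2")]),
               rep(merged_first[["b1"]], 2))
  expect_false(merged_first[["tissue_01"]] == merged_first[["b1"]])
})
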