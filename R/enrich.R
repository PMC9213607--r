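#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test conditioning on both margins. The two-sided
#' p-value uses the point-probability ordering rule: the sum of the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table. Degenerate
#' margins give p = 1. The odds ratio is the sample `ad/bc` with the usual
#' 0/Inf conventions.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as
#'   `a` = in-set & in-class, `b` = in-set & not, `c` = out-of-set &
#'   in-class, `d` = out-of-set & not.
#' @return A list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Cell counts must be non-negative integers.")
  }
  if (sum(cells) == 0) abort("Table total must be positive.")
  m <- a + c          # class size
  n2 <- b + d         # out-of-class size
  k <- a + b          # set size
  odds_ratio <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else a * d / (b * c)
  if (m == 0 || n2 == 0 || k == 0 || k == sum(cells)) {
    return(list(odds_ratio = odds_ratio, p = 1))
  }
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = odds_ratio, p = min(1, p))
}

# upper-tail hypergeometric: P(overlap >= k) for |set1|=m, |set2|=n drawn
# from a universe of size N
.hyper_upper <- function(k, m, n, N) {
  if (k <= 0) return(1)
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' TE class/family enrichment of a DE set
#'
#' One Fisher 2x2 test per class (or family) label, comparing the label's
#' share of the DE set against its share of the rest of the expressed
#' background. Both enrichment and depletion are reported; labels with
#' p <= `alpha` are flagged (raw p, no multiple-testing correction, but BH
#' values are written alongside).
#'
#' @param de_set Character vector of DE locus ids (subset of
#'   `background`).
#' @param background Tibble of expressed loci with `locus_id` and the
#'   grouping column.
#' @param by Grouping column: `"te_class"` (default) or `"family"`.
#' @param alpha Flagging threshold on raw p. Default 0.01.
#' @return A tibble (label, a, b, c, d, odds_ratio, p, fdr, direction,
#'   significant).
#' @export
class_enrichment <- function(de_set, background, by = "te_class",
                             alpha = 0.01) {
  stopifnot(is.data.frame(background), by %in% names(background))
  if (!all(de_set %in% background$locus_id)) {
    abort("`de_set` must be a subset of the background locus ids.")
  }
  if (length(de_set) == 0) {
    return(tibble(label = character(), a = integer(), b = integer(),
                  c = integer(), d = integer(), odds_ratio = numeric(),
                  p = numeric(), fdr = numeric(), direction = character(),
                  significant = logical()))
  }
  labels <- background[[by]][match(background$locus_id, background$locus_id)]
  in_set <- background$locus_id %in% de_set
  out <- purrr::map_dfr(sort(unique(background[[by]])), function(lab) {
    in_class <- background[[by]] == lab
    a <- sum(in_set & in_class)
    b <- sum(in_set & !in_class)
    cc <- sum(!in_set & in_class)
    dd <- sum(!in_set & !in_class)
    ft <- fisher_exact_2x2(a, b, cc, dd)
    tibble(label = lab, a = a, b = b, c = cc, d = dd,
           odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out |>
    mutate(
      fdr = p.adjust(.data$p, method = "BH"),
      direction = ifelse(is.na(.data$odds_ratio) | .data$odds_ratio >= 1,
                         "enriched", "depleted"),
      significant = .data$p <= alpha
    )
}

#' Intersection test between two DE sets
#'
#' Hypergeometric upper-tail p for the observed overlap of two locus sets
#' drawn from a shared universe, plus a cross-tabulation of up/down
#' directions in the shared loci when classified results are supplied.
#'
#' @param set1,set2 Character vectors of locus ids (subsets of
#'   `universe`).
#' @param universe Character vector: all loci tested in both contrasts.
#' @param results1,results2 Optional classified `telex_de` tibbles used to
#'   tabulate shared-direction concordance.
#' @return A list with `overlap`, `overlap_size`, `p`, `expected` and (when
#'   results are given) `direction_table` and `concordant_fraction`.
#' @export
intersection_test <- function(set1, set2, universe,
                              results1 = NULL, results2 = NULL) {
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (!all(set1 %in% universe) || !all(set2 %in% universe)) {
    abort("Both sets must be subsets of the universe.")
  }
  ov <- intersect(set1, set2)
  N <- length(unique(universe))
  out <- list(
    overlap = ov,
    overlap_size = length(ov),
    expected = length(set1) * length(set2) / N,
    p = .hyper_upper(length(ov), length(set1), length(set2), N)
  )
  if (!is.null(results1) && !is.null(results2) && length(ov)) {
    d1 <- setNames(results1$direction, results1$locus_id)[ov]
    d2 <- setNames(results2$direction, results2$locus_id)[ov]
    out$direction_table <- table(first = d1, second = d2)
    out$concordant_fraction <- mean(d1 == d2)
  }
  out
}

#' Map TE loci to cis genes within a window
#'
#' A gene is assigned to a locus when the gene interval intersects the
#' locus interval expanded by `window` bp on both sides (half-open
#' intersection, gene-body rule).
#'
#' @param loci Tibble with `locus_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param window Expansion in bp on each side. Default 5000.
#' @return A tibble (locus_id, gene_id, distance, relation) where distance
#'   is 0 for direct overlap and the gap in bp otherwise; relation is one
#'   of overlap/upstream/downstream (gene left/right of the locus in
#'   genomic coordinates).
#' @export
cis_genes <- function(loci, genes, window = 5000) {
  stopifnot(is.data.frame(loci), is.data.frame(genes))
  shared <- intersect(unique(loci$chrom), unique(genes$chrom))
  orphan <- setdiff(unique(loci$chrom), unique(genes$chrom))
  if (length(orphan) && length(shared) == 0) {
    warn(sprintf("No gene annotation on %d locus chromosome(s).", length(orphan)))
  }
  out <- purrr::map_dfr(shared, function(ch) {
    lc <- loci[loci$chrom == ch, ]
    gn <- genes[genes$chrom == ch, ]
    lr <- IRanges::IRanges(start = lc$start - window + 1L, end = lc$end + window)
    gr <- IRanges::IRanges(start = gn$start + 1L, end = gn$end)
    hits <- IRanges::findOverlaps(lr, gr)
    if (length(hits) == 0) return(tibble())
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    tibble(
      locus_id = lc$locus_id[qi], gene_id = gn$gene_id[si],
      distance = pmax(0L, pmax(lc$start[qi] - gn$end[si],
                               gn$start[si] - lc$end[qi])),
      relation = dplyr::case_when(
        gn$end[si] > lc$start[qi] & gn$start[si] < lc$end[qi] ~ "overlap",
        gn$end[si] <= lc$start[qi] ~ "upstream",
        TRUE ~ "downstream"
      )
    )
  })
  arrange(out, .data$locus_id, .data$gene_id)
}

#' Correlation of log2 fold-changes between two DE analyses
#'
#' Pearson (and Spearman) correlation of per-locus logFC over the loci
#' present in both result tables.
#'
#' @param results1,results2 `telex_de` tibbles.
#' @return A list with `n`, `pearson`, `pearson_p`, `spearman`; `NA` with a
#'   warning when fewer than 3 loci are shared.
#' @export
fold_change_correlation <- function(results1, results2) {
  shared <- intersect(results1$locus_id, results2$locus_id)
  if (length(shared) < 3) {
    warn("Fewer than 3 shared loci; correlation undefined.")
    return(list(n = length(shared), pearson = NA_real_,
                pearson_p = NA_real_, spearman = NA_real_))
  }
  x <- setNames(results1$logFC, results1$locus_id)[shared]
  y <- setNames(results2$logFC, results2$locus_id)[shared]
  ok <- complete.cases(x, y)
  ct <- cor.test(x[ok], y[ok])
  list(n = sum(ok), pearson = unname(ct$estimate), pearson_p = ct$p.value,
       spearman = cor(x[ok], y[ok], method = "spearman"))
}
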