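test_that("dispersion estimation recovers Poisson and NB truth", {
  set.seed(8)
  md <- tibble::tibble(
    sample_id = paste0("s", 1:12), subject_id = paste0("u", 1:12),
    group = rep(c("Converter_pre", "NC"), each = 6),
    pair_id = NA_character_)
  mu <- exp(rnorm(300, 5, 1))
  pois <- sapply(1:12, function(k) rpois(300, mu))
  rownames(pois) <- paste0("g", 1:300); colnames(pois) <- md$sample_id
  disp_p <- estimate_dispersion(telex:::matrix_to_counts(pois), md, "pre_vs_nc")
  expect_lte(disp_p$common, 0.01)

  nb <- sapply(1:12, function(k) rnbinom(300, mu = mu, size = 1 / 0.2))
  rownames(nb) <- paste0("g", 1:300); colnames(nb) <- md$sample_id
  disp_nb <- estimate_dispersion(telex:::matrix_to_counts(nb), md, "pre_vs_nc")
  expect_gt(disp_nb$common, 0.13)
  expect_lt(disp_nb$common, 0.27)

  # infinite prior degrees of freedom collapse tagwise onto common
  disp_inf <- estimate_dispersion(telex:::matrix_to_counts(nb[1:50, ]), md,
                                  "pre_vs_nc", prior_df = 1e9)
  expect_equal(unname(disp_inf$tagwise), rep(disp_inf$common, 50),
               tolerance = 0.02)
})

test_that("two-group NB fit matches the closed-form group means", {
  set.seed(9)
  md <- tibble::tibble(
    sample_id = paste0("s", 1:10), subject_id = paste0("u", 1:10),
    group = rep(c("Converter_pre", "NC"), each = 5), pair_id = NA_character_)
  m <- rbind(g1 = c(rpois(5, 50), rpois(5, 200)),
             g2 = c(rpois(5, 100), rpois(5, 100)))
  colnames(m) <- md$sample_id
  unit <- structure(tibble::tibble(sample_id = md$sample_id, factor = 1),
                    class = c("telex_norm", class(tibble::tibble())))
  mean_ratio <- function(y) log2(mean(y[6:10]) / mean(y[1:5]))
  # with equal offsets the condition coefficient is exactly
  # log2(mean2/mean1); a filler locus equalizes the library sizes
  depth <- colSums(m)
  eq <- rbind(m, filler = max(depth) - depth + 10)
  disp <- structure(list(common = 0.05,
                         tagwise = c(g1 = 0.05, g2 = 0.05, filler = 0.05),
                         prior_df = 10), class = "telex_dispersion")
  res <- de_test(telex:::matrix_to_counts(eq), md, "pre_vs_nc",
                 factors = unit, dispersion = disp)
  for (g in c("g1", "g2")) {
    expect_equal(res$logFC[res$locus_id == g], mean_ratio(eq[g, ]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate loci are flagged, identical means give LR near 0", {
  md <- tibble::tibble(
    sample_id = paste0("s", 1:8), subject_id = paste0("u", 1:8),
    group = rep(c("Converter_pre", "NC"), each = 4), pair_id = NA_character_)
  m <- rbind(zero = rep(0, 8), flat = rep(c(40, 40), 4))
  colnames(m) <- md$sample_id
  disp <- structure(list(common = 0.1, tagwise = c(zero = 0.1, flat = 0.1),
                         prior_df = 10), class = "telex_dispersion")
  unit <- tibble::tibble(sample_id = md$sample_id, factor = 1)
  res <- de_test(telex:::matrix_to_counts(m), md, "pre_vs_nc",
                 factors = unit, dispersion = disp)
  expect_true(res$degenerate[res$locus_id == "zero"])
  expect_lt(res$LR[res$locus_id == "flat"], 1e-6)
  expect_gt(res$p[res$locus_id == "flat"], 0.99)
})

test_that("swapping condition labels negates logFC and preserves p", {
  d <- de_dataset()
  sub <- d$counts[1:80, ]
  r1 <- de_test(sub, d$metadata, "pre_vs_nc")
  r2 <- de_test(sub, d$metadata, "nc_vs_pre")
  expect_equal(r1$logFC, -r2$logFC, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("planted DE is recovered with correct signs; paired beats unpaired", {
  d <- de_dataset()
  res <- de_test(d$counts, d$metadata, "pre_vs_post", paired = TRUE)
  tr <- d$truth$de[d$truth$de$contrast == "pre_vs_post", ]
  s <- de_sets(res)
  calls <- c(s$up, s$down)
  recovered <- intersect(calls, tr$locus_id)
  expect_gte(length(recovered) / nrow(tr), 0.7)
  merged <- dplyr::inner_join(tr, res, by = "locus_id")
  strong <- merged[merged$p < 0.01, ]
  expect_true(all(sign(strong$logFC) == strong$sign))
  # paired advantage under strong subject effects
  unpaired <- de_test(d$counts, d$metadata, "pre_vs_post", paired = FALSE)
  p_paired <- res$p[match(tr$locus_id, res$locus_id)]
  p_unpaired <- unpaired$p[match(tr$locus_id, unpaired$locus_id)]
  expect_lt(median(p_paired, na.rm = TRUE), median(p_unpaired, na.rm = TRUE))
})

test_that("classification thresholds follow the nominal-p two-sided rule", {
  res <- tibble::tibble(
    locus_id = c("a", "b", "c", "d", "e"),
    logFC = c(2, 1.0, -2, 1.6, 1.6),
    p = c(0.005, 0.005, 0.005, 0.02, NA))
  out <- classify_de(res)
  expect_equal(out$direction, c("up", "ns", "down", "ns", "ns"))
  one <- classify_de(res, one_sided = TRUE)
  expect_equal(one$direction[3], "ns")
  expect_equal(attr(out, "n_de"), c(up = 1L, down = 1L))
})

test_that("BH adjustment is rank-monotone and bounded below by p", {
  d <- de_dataset()
  res <- de_test(d$counts[1:100, ], d$metadata, "pre_vs_nc")
  ok <- !is.na(res$p)
  o <- order(res$p[ok])
  expect_true(all(diff(res$fdr[ok][o]) >= -1e-12))
  expect_true(all(res$fdr[ok] >= res$p[ok] - 1e-12))
  expect_equal(res$fdr[ok], p.adjust(res$p[ok], "BH"))
})

test_that("PCA separates constructed clusters but not permuted labels", {
  set.seed(12)
  n <- 20
  md <- tibble::tibble(sample_id = paste0("s", 1:n),
                       group = rep(c("A", "B"), each = n / 2))
  m <- matrix(rnorm(50 * n), 50, n, dimnames = list(paste0("g", 1:50), md$sample_id))
  m[, md$group == "B"] <- m[, md$group == "B"] + 6
  pc <- pca_qc(telex:::matrix_to_counts(m), md)
  expect_gt(attr(pc, "separation"), 0.5)
  md_perm <- dplyr::mutate(md, group = sample(group))
  pc_perm <- pca_qc(telex:::matrix_to_counts(m), md_perm)
  expect_lt(abs(attr(pc_perm, "separation")), 0.25)
  # duplicated sample -> identical scores
  m2 <- cbind(m, s_dup = m[, 1])
  md2 <- dplyr::bind_rows(md, tibble::tibble(sample_id = "s_dup", group = "A"))
  pc2 <- pca_qc(telex:::matrix_to_counts(m2), md2)
  expect_equal(unlist(pc2[pc2$sample_id == "s_dup", -(1:2)]),
               unlist(pc2[pc2$sample_id == "s1", -(1:2)]))
  # constant matrix -> zero scores with warning
  expect_warning(pc0 <- pca_qc(telex:::matrix_to_counts(
    matrix(5, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))),
    tibble::tibble(sample_id = paste0("s", 1:4), group = rep("A", 4))),
    "Constant")
  expect_true(all(unlist(pc0[, -(1:2)]) == 0))
})

test_that("expression of DE loci shows no age association in controls", {
  d <- de_dataset()
  res <- de_test(d$counts, d$metadata, "pre_vs_post", paired = TRUE)
  de_ids <- unlist(de_sets(res))
  nc <- d$metadata[d$metadata$group == "NC", ]
  logcpm <- calc_logcpm(d$counts[d$counts$locus_id %in% de_ids,
                                 c("locus_id", nc$sample_id)])
  pc <- pca_qc(logcpm, nc)
  for (comp in c("PC1", "PC2")) {
    fit <- summary(lm(pc[[comp]] ~ nc$age))
    expect_gt(fit$coefficients[2, 4], 0.05)
  }
})
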