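.contrast_groups <- c(pre = "Converter_pre", post = "Converter_post", nc = "NC")

# Parse "a_vs_b" into the two group labels; logFC is b over a (second
# condition over first).
parse_contrast <- function(contrast) {
  parts <- strsplit(contrast, "_vs_")[[1]]
  if (length(parts) != 2 || !all(parts %in% names(.contrast_groups))) {
    abort(sprintf("Unknown contrast '%s'; use e.g. pre_vs_post, pre_vs_nc, nc_vs_post.",
                  contrast))
  }
  unname(.contrast_groups[parts])
}

# Subset metadata to the contrast's groups; for a paired design keep only
# subjects contributing exactly one sample per condition.
build_design <- function(metadata, contrast, paired = FALSE) {
  groups <- parse_contrast(contrast)
  md <- metadata |>
    filter(.data$group %in% groups) |>
    mutate(condition = factor(.data$group, levels = groups))
  if (paired) {
    complete <- md |>
      count(.data$subject_id, .data$condition) |>
      tidyr::pivot_wider(names_from = "condition", values_from = "n",
                         values_fill = 0) |>
      filter(dplyr::if_all(-"subject_id", ~ .x == 1))
    dropped <- setdiff(unique(md$subject_id), complete$subject_id)
    if (length(dropped)) {
      warn(sprintf("Dropping %d subject(s) without one sample per condition: %s",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
      md <- filter(md, .data$subject_id %in% complete$subject_id)
    }
    md <- mutate(md, subject = factor(.data$subject_id))
    design <- stats::model.matrix(~ subject + condition, data = md)
    reduced <- stats::model.matrix(~ subject, data = md)
  } else {
    design <- stats::model.matrix(~ condition, data = md)
    reduced <- stats::model.matrix(~ 1, data = md)
  }
  if (qr(design)$rank < ncol(design)) abort("Design matrix is not full rank.")
  list(metadata = md, design = design, reduced = reduced,
       coef = paste0("condition", groups[2]), groups = groups)
}

# Per-locus fitted means under a log-linear model with offsets, using a
# Poisson working fit (mean structure only; used to profile the dispersion).
.fitted_means <- function(m, design, offset) {
  t(vapply(seq_len(nrow(m)), function(g) {
    y <- m[g, ]
    if (all(y == 0)) return(rep(1e-8, ncol(m)))
    fit <- suppressWarnings(
      glm.fit(design, y, family = stats::poisson(), offset = offset)
    )
    pmax(fit$fitted.values, 1e-8)
  }, numeric(ncol(m))))
}

# Cox-Reid adjusted NB log-likelihood for one locus at dispersion phi,
# given plug-in fitted means.
.apl <- function(y, mu, phi, design) {
  ll <- sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(design * sqrt(w))
  ll - 0.5 * determinant(xtwx, logarithm = TRUE)$modulus[1]
}

#' Estimate negative-binomial dispersion
#'
#' Common dispersion maximizes the Cox-Reid adjusted profile likelihood,
#' summed over loci, over a log grid on \[1e-4, 4\] (refined by golden-section
#' search); tagwise dispersions maximize the per-locus adjusted likelihood
#' penalized toward the common value with weight `prior_df` (shared
#' likelihood weighting, so tagwise values collapse onto the common value
#' as `prior_df` grows).
#'
#' @param counts Counts tibble (expression-filtered).
#' @param metadata Sample metadata tibble.
#' @param contrast Contrast string, e.g. `"pre_vs_post"`.
#' @param paired Use the subject-blocked paired design?
#' @param factors Optional `telex_norm` factors; computed when `NULL`.
#' @param prior_df Shrinkage weight toward the common dispersion. Default 10.
#' @param grid_length Number of grid points. Default 19.
#' @return A list of class `telex_dispersion` with `common`, `tagwise`
#'   (named per locus) and `prior_df`.
#' @export
estimate_dispersion <- function(counts, metadata, contrast, paired = FALSE,
                                factors = NULL, prior_df = 10,
                                grid_length = 19) {
  ds <- build_design(metadata, contrast, paired = paired)
  m <- counts_matrix(counts)[, ds$metadata$sample_id, drop = FALSE]
  if (nrow(ds$design) - ncol(ds$design) < 2) {
    abort("Fewer than 2 residual degrees of freedom; add samples before estimating dispersion.")
  }
  if (is.null(factors)) factors <- calc_tmm_factors(matrix_to_counts(m))
  f <- setNames(factors$factor, factors$sample_id)[colnames(m)]
  offset <- log(colSums(m) * f)

  mu <- .fitted_means(m, ds$design, offset)
  grid <- exp(seq(log(1e-4), log(4), length.out = grid_length))
  ll <- vapply(grid, function(phi) {
    vapply(seq_len(nrow(m)), function(g) .apl(m[g, ], mu[g, ], phi, ds$design),
           numeric(1))
  }, numeric(nrow(m)))
  if (nrow(m) == 1) ll <- matrix(ll, nrow = 1)

  tot <- colSums(ll)
  i <- which.max(tot)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  common <- optimize(function(phi) {
    sum(vapply(seq_len(nrow(m)), function(g) .apl(m[g, ], mu[g, ], phi, ds$design),
               numeric(1)))
  }, lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)$maximum

  llbar <- colMeans(ll)
  # smooth interpolant of the shared likelihood keeps the tagwise
  # optimization O(loci) instead of O(loci^2)
  llbar_fun <- stats::splinefun(log(grid), llbar, method = "natural")
  tagwise <- vapply(seq_len(nrow(m)), function(g) {
    obj <- ll[g, ] + prior_df * llbar
    j <- which.max(obj)
    optimize(function(phi) {
      .apl(m[g, ], mu[g, ], phi, ds$design) + prior_df * llbar_fun(log(phi))
    }, lower = grid[max(1, j - 1)], upper = grid[min(length(grid), j + 1)],
    maximum = TRUE, tol = 1e-4)$maximum
  }, numeric(1))

  structure(list(common = common,
                 tagwise = setNames(tagwise, rownames(m)),
                 prior_df = prior_df),
            class = "telex_dispersion")
}

# One NB GLM fit with fixed dispersion; returns log-likelihood and
# coefficients, flagging non-convergence.
.nb_fit <- function(y, design, offset, phi) {
  if (all(y == 0)) {
    return(list(ll = 0, coef = setNames(rep(0, ncol(design)), colnames(design)),
                converged = TRUE, degenerate = TRUE))
  }
  fit <- tryCatch(
    suppressWarnings(glm.fit(
      design, y, family = MASS::negative.binomial(theta = 1 / phi),
      offset = offset, control = stats::glm.control(epsilon = 1e-10, maxit = 100)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(ll = NA_real_, coef = setNames(rep(NA_real_, ncol(design)),
                                               colnames(design)),
                converged = FALSE, degenerate = FALSE))
  }
  list(ll = sum(dnbinom(y, size = 1 / phi, mu = fit$fitted.values, log = TRUE)),
       coef = stats::coef(fit), converged = fit$converged, degenerate = FALSE)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Fits per-locus NB log-linear models with offsets `log(library size x TMM
#' factor)` - a subject-blocked design plus condition term for paired
#' contrasts (no interaction), condition only for unpaired - and tests the
#' condition term by likelihood ratio against the nested reduced model
#' (chi-squared, 1 df). log2 fold-changes are the second condition of the
#' contrast name over the first. BH-adjusted FDR is always computed;
#' direction labels use the nominal-p selection rule of [classify_de()].
#'
#' @inheritParams estimate_dispersion
#' @param dispersion Optional `telex_dispersion`; estimated when `NULL`.
#' @param dispersion_type `"tagwise"` (default) or `"common"`.
#' @param p_max,lfc_min Selection thresholds passed to [classify_de()].
#' @return A tibble of class `telex_de` (locus_id, logFC, logCPM, LR, p,
#'   fdr, direction) with the contrast, design and dispersion attached as
#'   attributes.
#' @export
de_test <- function(counts, metadata, contrast, paired = FALSE,
                    factors = NULL, dispersion = NULL, prior_df = 10,
                    dispersion_type = c("tagwise", "common"),
                    p_max = 0.01, lfc_min = 1.5) {
  dispersion_type <- match.arg(dispersion_type)
  ds <- build_design(metadata, contrast, paired = paired)
  m <- counts_matrix(counts)[, ds$metadata$sample_id, drop = FALSE]
  if (is.null(factors)) factors <- calc_tmm_factors(matrix_to_counts(m))
  f <- setNames(factors$factor, factors$sample_id)[colnames(m)]
  offset <- log(colSums(m) * f)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts = matrix_to_counts(m),
                                      metadata = ds$metadata,
                                      contrast = contrast, paired = paired,
                                      factors = factors, prior_df = prior_df)
  }
  phi <- if (dispersion_type == "common") {
    rep(dispersion$common, nrow(m))
  } else {
    dispersion$tagwise[rownames(m)]
  }

  logcpm <- rowMeans(counts_matrix(calc_logcpm(matrix_to_counts(m), factors)))
  res <- purrr::map_dfr(seq_len(nrow(m)), function(g) {
    full <- .nb_fit(m[g, ], ds$design, offset, phi[g])
    red <- .nb_fit(m[g, ], ds$reduced, offset, phi[g])
    lr <- 2 * (full$ll - red$ll)
    if (!is.na(lr) && lr < -1e-6) {
      abort(sprintf("Negative likelihood ratio (%.3g) at locus %s.",
                    lr, rownames(m)[g]))
    }
    lr <- if (is.na(lr)) NA_real_ else max(lr, 0)
    tibble(
      locus_id = rownames(m)[g],
      logFC = unname(full$coef[ds$coef]) / log(2),
      LR = lr,
      p = if (is.na(lr)) NA_real_ else pchisq(lr, df = 1, lower.tail = FALSE),
      converged = full$converged && red$converged,
      degenerate = full$degenerate
    )
  })
  res <- res |>
    mutate(logCPM = unname(logcpm[.data$locus_id]), .after = "logFC") |>
    mutate(fdr = p.adjust(.data$p, method = "BH"))
  res <- classify_de(res, p_max = p_max, lfc_min = lfc_min)
  attr(res, "contrast") <- contrast
  attr(res, "paired") <- paired
  attr(res, "dispersion") <- dispersion
  attr(res, "groups") <- ds$groups
  class(res) <- c("telex_de", class(tibble()))
  res
}

#' Classify DE results into up/down/ns
#'
#' A locus is `up` when `p < p_max` and `logFC >= lfc_min`, `down` when
#' `p < p_max` and `logFC <= -lfc_min` (set `one_sided = TRUE` to call only
#' the positive side), else `ns`. Selection uses nominal p-values; FDR is
#' reported alongside.
#'
#' @param results A `telex_de` tibble (or any tibble with `p` and `logFC`).
#' @param p_max Nominal p-value threshold. Default 0.01.
#' @param lfc_min Absolute log2 fold-change threshold. Default 1.5.
#' @param one_sided Call only up-regulation? Default FALSE.
#' @return The input with a refreshed `direction` column; the up/down
#'   counts are attached as attribute `"n_de"`.
#' @export
classify_de <- function(results, p_max = 0.01, lfc_min = 1.5,
                        one_sided = FALSE) {
  out <- results |>
    mutate(direction = dplyr::case_when(
      !is.na(.data$p) & .data$p < p_max & .data$logFC >= lfc_min ~ "up",
      !one_sided & !is.na(.data$p) & .data$p < p_max &
        .data$logFC <= -lfc_min ~ "down",
      TRUE ~ "ns"
    ))
  attr(out, "n_de") <- c(up = sum(out$direction == "up"),
                         down = sum(out$direction == "down"))
  out
}

#' Up/down locus-id sets from classified DE results
#'
#' @param results A classified `telex_de` tibble.
#' @return A list with `up` and `down` character vectors.
#' @export
de_sets <- function(results) {
  list(up = results$locus_id[results$direction == "up"],
       down = results$locus_id[results$direction == "down"])
}

#' PCA quality control of an expression matrix
#'
#' Centered (optionally scaled) principal components of the samples, with a
#' silhouette-style group-separation score (mean silhouette width over the
#' first `n_components` scores). The score is reported, not thresholded: it
#' is a QC readout of whether groups visibly separate.
#'
#' @param logcpm A logCPM tibble (`locus_id` + sample columns).
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param n_components Number of components to return. Default 2.
#' @param scale Scale loci to unit variance? Default FALSE.
#' @return A tibble of class `telex_pca` (sample_id, group, PC1, ...);
#'   attributes `separation` (mean silhouette width, 0 when < 2 groups) and
#'   `variance_explained`.
#' @export
pca_qc <- function(logcpm, metadata, n_components = 2, scale = FALSE) {
  m <- counts_matrix(logcpm)
  if (ncol(m) < 3) abort("PCA QC needs at least 3 samples.")
  X <- t(m)
  keep <- apply(X, 2, sd) > 0
  if (!any(keep)) {
    warn("Constant expression matrix; returning all-zero scores.")
    scores <- matrix(0, nrow(X), n_components)
    ve <- rep(0, n_components)
  } else {
    pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = scale)
    d <- min(n_components, ncol(pc$x))
    scores <- pc$x[, seq_len(d), drop = FALSE]
    ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(d)]
  }
  md <- metadata[match(rownames(X), metadata$sample_id), ]
  out <- bind_cols(
    tibble(sample_id = rownames(X), group = md$group),
    as_tibble(scores, .name_repair = ~ paste0("PC", seq_along(.x)))
  )
  sep <- 0
  if (length(unique(out$group)) >= 2 && any(apply(scores, 2, sd) > 0)) {
    sil <- cluster::silhouette(as.integer(factor(out$group)), dist(scores))
    sep <- mean(sil[, "sil_width"])
  }
  attr(out, "separation") <- sep
  attr(out, "variance_explained") <- ve
  class(out) <- c("telex_pca", class(tibble()))
  out
}
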