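#' Shannon entropy of one locus's expression profile
#'
#' Values are transformed to `log2(x + 1)` and binned into `n_bins`
#' equal-width bins over the observed range; the entropy is
#' `-sum p_i log2 p_i` over non-empty bins, in bits. A constant profile
#' occupies a single bin and has entropy 0; the maximum is
#' `log2(n_bins)`.
#'
#' @param values Numeric vector of per-sample expression for one locus
#'   (length >= 2).
#' @param n_bins Number of histogram bins. Default 10.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(values, n_bins = 10) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  if (length(values) < 2) abort("Need at least 2 samples.")
  x <- log2(values + 1)
  r <- range(x)
  if (diff(r) == 0) return(0)
  bins <- cut(x, breaks = seq(r[1], r[2], length.out = n_bins + 1),
              include.lowest = TRUE)
  p <- tabulate(bins, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-based feature prefilter
#'
#' Ranks loci by the Shannon entropy of their expression profile
#' (descending, ties broken by locus id) and retains the top `top_k`.
#'
#' @param expr Expression tibble (`locus_id` + one numeric column per
#'   sample); any monotone abundance scale works.
#' @param top_k Number of loci to retain. Default 10000.
#' @param n_bins Bins passed to [shannon_entropy()]. Default 10.
#' @return A tibble (locus_id, H, rank) of the retained loci, ordered by
#'   rank.
#' @export
entropy_prefilter <- function(expr, top_k = 10000, n_bins = 10) {
  if (top_k < 1) abort("`top_k` must be >= 1.")
  m <- counts_matrix(expr)
  H <- apply(m, 1, shannon_entropy, n_bins = n_bins)
  out <- tibble(locus_id = rownames(m), H = H) |>
    arrange(desc(.data$H), .data$locus_id) |>
    mutate(rank = dplyr::row_number())
  head(out, min(top_k, nrow(out)))
}

#' Boruta all-relevant feature selection
#'
#' Shadow-feature wrapper around random forests: each iteration appends a
#' column-permuted copy of every feature, fits a forest, and scores a
#' "hit" for each real feature whose importance exceeds the maximum shadow
#' importance. After each iteration, binomial tests on the hit count
#' (success probability 0.5, both tails, Bonferroni-corrected over all
#' features) confirm (upper tail) or reject (lower tail) features; the
#' loop stops at `max_runs` iterations or when nothing is undecided, and
#' anything left is tentative.
#'
#' @param X Numeric matrix or tibble, samples x features.
#' @param y Class labels (2+ classes, each with >= 2 samples).
#' @param p_value Decision threshold. Default 0.05.
#' @param n_tree Trees per forest. Default 10000 (use fewer for quick
#'   runs).
#' @param max_runs Maximum iterations. Default 100.
#' @param seed RNG seed for the permutations and forests.
#' @param importance ranger importance mode: `"permutation"` (out-of-bag
#'   permutation importance, default) or `"impurity"`.
#' @return A tibble of class `telex_boruta` (feature, status in
#'   confirmed/rejected/tentative, hit_count, n_iterations, decided_at).
#' @export
boruta_select <- function(X, y, p_value = 0.05, n_tree = 10000,
                          max_runs = 100, seed = 1,
                          importance = c("permutation", "impurity")) {
  importance <- match.arg(importance)
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) abort("`y` must contain at least 2 classes.")
  if (any(table(y) < 2)) abort("Each class needs at least 2 samples.")
  p <- ncol(X)
  feats <- colnames(X) %||% paste0("f", seq_len(p))
  colnames(X) <- feats

  status <- setNames(rep("tentative", p), feats)
  hits <- setNames(rep(0L, p), feats)
  decided_at <- setNames(rep(NA_integer_, p), feats)

  with_stream(seed, "boruta", {
    for (it in seq_len(max_runs)) {
      undecided <- names(status)[status == "tentative"]
      if (length(undecided) == 0) break
      shadow <- apply(X, 2, sample)
      colnames(shadow) <- paste0(".shadow_", feats)
      dat <- data.frame(cbind(X, shadow), check.names = FALSE)
      dat$.y <- y
      rf <- ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = n_tree, importance = importance,
        seed = stream_seed(seed, "forest") + it,
        num.threads = 1
      )
      imp <- rf$variable.importance
      shadow_max <- max(imp[startsWith(names(imp), ".shadow_")])
      hit <- imp[feats] > shadow_max
      hits[undecided] <- hits[undecided] + as.integer(hit[undecided])

      alpha <- p_value / p  # Bonferroni over all features
      up <- pbinom(hits[undecided] - 1L, it, 0.5, lower.tail = FALSE)
      lo <- pbinom(hits[undecided], it, 0.5)
      newly_conf <- undecided[up < alpha]
      newly_rej <- undecided[lo < alpha]
      status[newly_conf] <- "confirmed"
      status[newly_rej] <- "rejected"
      decided_at[c(newly_conf, newly_rej)] <- it
      n_it <- it
    }
    structure(
      tibble(feature = feats, status = unname(status[feats]),
             hit_count = unname(hits[feats]), n_iterations = n_it,
             decided_at = unname(decided_at[feats])),
      class = c("telex_boruta", class(tibble())))
  })
}

#' Subject-aware train/test split
#'
#' Splits at subject level whenever paired samples are present, so both
#' samples of a subject land on the same side and no subject leaks across
#' the split; with no pairing it reduces to a stratified sample-level
#' split.
#'
#' @param metadata Sample metadata (`sample_id`, `subject_id`, `group`,
#'   `pair_id`).
#' @param train_frac Fraction of subjects (or samples) for training.
#'   Default 0.70.
#' @param seed RNG seed.
#' @return A list with `train` and `test` sample-id vectors.
#' @export
paired_split <- function(metadata, train_frac = 0.70, seed = 1) {
  check_prob(train_frac, "train_frac")
  with_stream(seed, "split", {
    paired <- !is.na(metadata$pair_id)
    if (any(paired)) {
      subj <- unique(metadata$subject_id)
      n_train <- round(train_frac * length(subj))
      train_subj <- sample(subj, n_train)
      train <- metadata$sample_id[metadata$subject_id %in% train_subj]
    } else {
      train <- unlist(lapply(split(metadata$sample_id, metadata$group),
                             function(ids) {
                               sample(ids, round(train_frac * length(ids)))
                             }), use.names = FALSE)
    }
    list(train = train, test = setdiff(metadata$sample_id, train))
  })
}

# midrank AUC: P(score of a positive > score of a negative), ties at 1/2 -
# the Mann-Whitney statistic scaled by n1*n0
.auc_midrank <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Train and evaluate a random-forest classifier
#'
#' Trains a probability forest on a (optionally down-sampled) training
#' split selected by [paired_split()], sanity-checks it with stratified
#' k-fold cross-validation inside the training set, and reports ROC/AUC on
#' the held-out test samples. AUC is the midrank Mann-Whitney statistic
#' over predicted class probabilities.
#'
#' @param X Numeric matrix or tibble (samples x features) with rownames /
#'   a `sample_id` column matching the metadata.
#' @param metadata Sample metadata (`sample_id`, `subject_id`, `group`,
#'   `pair_id`) restricted to the two classes being discriminated.
#' @param features Feature names to use (e.g. Boruta-confirmed).
#' @param train_frac Training fraction. Default 0.70.
#' @param cv_folds Cross-validation folds. Default 5.
#' @param downsample Down-sample training classes to the minority size?
#'   Default TRUE.
#' @param n_tree Trees. Default 500.
#' @param seed RNG seed.
#' @return A list of class `telex_model`: `auc`, `accuracy`, `cv_accuracy`,
#'   `confusion`, `roc` (tibble threshold/tpr/fpr), `split`, `positive`
#'   class, `scores` (test-set probabilities), and the fitted forest.
#' @export
train_evaluate <- function(X, metadata, features, train_frac = 0.70,
                           cv_folds = 5, downsample = TRUE, n_tree = 500,
                           seed = 1) {
  if (length(features) == 0) abort("`features` must be non-empty.")
  if (is.data.frame(X) && "sample_id" %in% names(X)) {
    X <- as.data.frame(X)
    rownames(X) <- X$sample_id
    X$sample_id <- NULL
  }
  X <- as.matrix(X)[metadata$sample_id, features, drop = FALSE]
  y <- factor(metadata$group)
  if (nlevels(y) != 2) abort("Exactly 2 classes are required.")
  positive <- levels(y)[2]

  split <- paired_split(metadata, train_frac = train_frac, seed = seed)
  itr <- metadata$sample_id %in% split$train
  if (length(unique(y[itr])) < 2 || length(unique(y[!itr])) < 2) {
    abort("Both classes must be present in train and test after the split.")
  }

  with_stream(seed, "forest", {
    Xtr <- X[itr, , drop = FALSE]
    ytr <- y[itr]
    if (downsample) {
      n_min <- min(table(ytr))
      keep <- unlist(lapply(levels(ytr), function(cl) {
        sample(which(ytr == cl), n_min)
      }))
      Xtr <- Xtr[keep, , drop = FALSE]
      ytr <- ytr[keep]
    }
    fit_rf <- function(Xa, ya, sd_off = 0) {
      dat <- data.frame(Xa, check.names = FALSE)
      dat$.y <- ya
      ranger::ranger(dependent.variable.name = ".y", data = dat,
                     num.trees = n_tree, probability = TRUE,
                     seed = stream_seed(seed, "forest") + sd_off,
                     num.threads = 1)
    }
    # stratified k-fold CV inside the training set
    folds <- unsplit(lapply(split(seq_along(ytr), ytr), function(idx) {
      sample(rep_len(seq_len(cv_folds), length(idx)))
    }), ytr)
    cv_acc <- vapply(seq_len(cv_folds), function(k) {
      if (length(unique(ytr[folds != k])) < 2) return(NA_real_)
      rf_k <- fit_rf(Xtr[folds != k, , drop = FALSE], ytr[folds != k], sd_off = k)
      pr <- predict(rf_k, data.frame(Xtr[folds == k, , drop = FALSE],
                                     check.names = FALSE))$predictions
      mean((pr[, positive] > 0.5) == (ytr[folds == k] == positive))
    }, numeric(1))

    rf <- fit_rf(Xtr, ytr)
    pr <- predict(rf, data.frame(X[!itr, , drop = FALSE],
                                 check.names = FALSE))$predictions
    scores <- pr[, positive]
    yte <- y[!itr]
    auc <- .auc_midrank(scores, yte == positive)
    pred <- factor(ifelse(scores > 0.5, positive, levels(y)[1]),
                   levels = levels(y))
    thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
    roc <- tibble(
      threshold = thr,
      tpr = vapply(thr, function(t) mean(scores[yte == positive] >= t), 0),
      fpr = vapply(thr, function(t) mean(scores[yte != positive] >= t), 0)
    )
    structure(list(
      auc = auc, accuracy = mean(pred == yte),
      cv_accuracy = mean(cv_acc, na.rm = TRUE),
      confusion = table(predicted = pred, observed = yte),
      roc = roc, split = split, positive = positive,
      scores = tibble(sample_id = metadata$sample_id[!itr],
                      score = unname(scores), observed = as.character(yte)),
      features = features, forest = rf
    ), class = "telex_model")
  })
}

#' @export
print.telex_model <- function(x, ...) {
  cat("<telex random-forest model>\n")
  cat(sprintf("  features: %d   positive class: %s\n",
              length(x$features), x$positive))
  cat(sprintf("  test AUC: %.3f   test accuracy: %.3f   CV accuracy: %.3f\n",
              x$auc, x$accuracy, x$cv_accuracy))
  invisible(x)
}
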