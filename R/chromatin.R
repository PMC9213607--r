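cli_states <- function() chromatin_state_alphabet()$state

# Accept mnemonics with or without their numeric prefix ("5_TxWk" or
# "TxWk"); anything else is an input error.
normalize_state_labels <- function(x) {
  states <- cli_states()
  suffix <- sub("^[0-9]+_", "", states)
  out <- ifelse(x %in% states, x, states[match(x, suffix)])
  if (anyNA(out)) {
    abort(sprintf("Unknown chromatin state label(s): %s",
                  paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Overlap TE loci with per-tissue chromatin-state segmentations
#'
#' Computes, per locus and tissue, the bp of overlap with each chromatin
#' state (half-open interval intersection; adjacent same-state segments
#' are merged first), then assigns a single label: the state when exactly
#' one state overlaps, `"Mx"` (mixed) when two or more states overlap, and
#' `NA` when no segmentation covers the locus. States contributing less
#' than `min_minor_fraction` of a locus's covered bp can be ignored for
#' labeling.
#'
#' @param loci Tibble with `locus_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param segments Segmentation tibble (`tissue`, `chrom`, `start`, `end`,
#'   `state`); intervals within a tissue must not overlap.
#' @param min_minor_fraction Minimum fraction of a locus's covered bp for a
#'   state to count toward the mixed-state rule. Default 0.
#' @return A list of class `telex_states` with `assignment` (locus_id,
#'   tissue, state) and `breakdown` (locus_id, tissue, state, bp).
#' @export
overlap_states <- function(loci, segments, min_minor_fraction = 0) {
  stopifnot(is.data.frame(loci), is.data.frame(segments))
  segments <- mutate(segments, state = normalize_state_labels(.data$state))
  out_break <- list()
  for (tis in unique(segments$tissue)) {
    seg_t <- segments[segments$tissue == tis, ]
    for (ch in unique(seg_t$chrom)) {
      seg <- seg_t[seg_t$chrom == ch, ] |> arrange(.data$start)
      if (any(seg$start[-1] < seg$end[-nrow(seg)])) {
        abort(sprintf("Overlapping segmentation intervals in tissue '%s' (%s).",
                      tis, ch))
      }
      # merge adjacent same-state runs
      run <- cumsum(c(TRUE, seg$state[-1] != seg$state[-nrow(seg)] |
                        seg$start[-1] != seg$end[-nrow(seg)]))
      seg <- seg |>
        group_by(run = run) |>
        summarise(state = .data$state[1], start = min(.data$start),
                  end = max(.data$end), .groups = "drop")
      lc <- loci[loci$chrom == ch, ]
      if (nrow(lc) == 0) next
      lr <- IRanges::IRanges(start = lc$start + 1L, end = lc$end)
      sr <- IRanges::IRanges(start = seg$start + 1L, end = seg$end)
      hits <- IRanges::findOverlaps(lr, sr)
      if (length(hits) == 0) next
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      bp <- pmin(lc$end[qi], seg$end[si]) - pmax(lc$start[qi], seg$start[si])
      out_break[[length(out_break) + 1]] <- tibble(
        locus_id = lc$locus_id[qi], tissue = tis,
        state = seg$state[si], bp = as.integer(bp)
      )
    }
  }
  breakdown <- if (length(out_break)) {
    bind_rows(out_break) |>
      group_by(.data$locus_id, .data$tissue, .data$state) |>
      summarise(bp = sum(.data$bp), .groups = "drop")
  } else {
    tibble(locus_id = character(), tissue = character(),
           state = character(), bp = integer())
  }
  grid <- tidyr::expand_grid(locus_id = loci$locus_id,
                             tissue = unique(segments$tissue))
  assignment <- breakdown |>
    group_by(.data$locus_id, .data$tissue) |>
    summarise(state = {
      frac <- .data$bp / sum(.data$bp)
      st <- .data$state[frac >= min_minor_fraction & .data$bp > 0]
      if (length(st) == 0) NA_character_
      else if (length(st) == 1) st
      else "Mx"
    }, .groups = "drop") |>
    right_join(grid, by = c("locus_id", "tissue")) |>
    arrange(.data$locus_id, .data$tissue)
  structure(list(assignment = assignment, breakdown = breakdown),
            class = "telex_states")
}

#' Fraction of loci in functionally active chromatin states
#'
#' Reports two readings for a locus set in one tissue: `label_based`, the
#' fraction whose single-state label is in `active_set` (mixed-state loci
#' count as inactive), and `any_overlap`, the fraction overlapping at
#' least one active state by >= 1 bp (mixed-state loci count when any of
#' their states is active).
#'
#' @param states A `telex_states` object from [overlap_states()].
#' @param loci_set Character vector of locus ids (must be assigned in the
#'   tissue).
#' @param tissue Tissue id present in the assignment.
#' @param active_set Character vector of active state labels; defaults to
#'   the promoter/transcription/enhancer block (states 1-8).
#' @return A list with `label_based`, `any_overlap` and `n`.
#' @export
active_fraction <- function(states, loci_set, tissue,
                            active_set = default_active_states()) {
  asg <- states$assignment
  if (!tissue %in% asg$tissue) abort(sprintf("Unknown tissue '%s'.", tissue))
  active_set <- normalize_state_labels(active_set)
  asg <- asg[asg$tissue == tissue & asg$locus_id %in% loci_set, ]
  if (!all(loci_set %in% asg$locus_id)) {
    abort("All loci in the set must be assigned in the chosen tissue.")
  }
  brk <- states$breakdown
  brk <- brk[brk$tissue == tissue & brk$locus_id %in% loci_set & brk$bp > 0, ]
  any_active <- brk |>
    group_by(.data$locus_id) |>
    summarise(active = any(.data$state %in% active_set), .groups = "drop")
  list(
    label_based = mean(asg$state %in% active_set),
    any_overlap = mean(setNames(any_active$active, any_active$locus_id)[loci_set] %in% TRUE),
    n = length(loci_set)
  )
}

#' Chromatin-state enrichment of a DE set
#'
#' One Fisher 2x2 test per state label (mixed-state `"Mx"` is its own
#' category) comparing the DE set's state composition against the
#' background's, within one tissue. States absent from both sets are
#' skipped.
#'
#' @inheritParams active_fraction
#' @param de_set,background Character vectors of locus ids assigned in the
#'   tissue; `de_set` must be a subset of `background`.
#' @param alpha Flagging threshold on raw p. Default 0.01.
#' @return An enrichment tibble as in [class_enrichment()].
#' @export
state_enrichment <- function(states, de_set, background, tissue,
                             alpha = 0.01) {
  asg <- states$assignment
  asg <- asg[asg$tissue == tissue & !is.na(asg$state), ]
  bg <- asg[asg$locus_id %in% background, c("locus_id", "state")]
  class_enrichment(intersect(de_set, bg$locus_id), bg, by = "state",
                   alpha = alpha)
}

#' Cross-tissue consistency of chromatin-state assignments
#'
#' Per-locus label agreement across tissues (fraction of tissue pairs with
#' identical labels), a tissue-by-tissue disagreement distance matrix
#' (1 - fraction of loci with matching labels), and an average-linkage
#' dendrogram of tissues.
#'
#' @param states A `telex_states` object.
#' @return A list with `locus_agreement` (tibble locus_id, agreement),
#'   `distance` (matrix), and `dendrogram` (an `hclust`, or `NULL` with a
#'   single tissue).
#' @export
cross_tissue_consistency <- function(states) {
  wide <- states$assignment |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "state")
  tissues <- setdiff(names(wide), "locus_id")
  if (length(tissues) < 1) abort("No tissues in the assignment.")
  lab <- as.matrix(wide[tissues])
  agree_locus <- apply(lab, 1, function(v) {
    if (length(v) < 2) return(1)
    pairs <- utils::combn(length(v), 2)
    mean(v[pairs[1, ]] == v[pairs[2, ]], na.rm = TRUE)
  })
  out <- list(locus_agreement = tibble(locus_id = wide$locus_id,
                                       agreement = agree_locus))
  if (length(tissues) >= 2) {
    D <- matrix(0, length(tissues), length(tissues),
                dimnames = list(tissues, tissues))
    for (i in seq_along(tissues)) {
      for (j in seq_along(tissues)) {
        D[i, j] <- 1 - mean(lab[, i] == lab[, j], na.rm = TRUE)
      }
    }
    out$distance <- D
    out$dendrogram <- stats::hclust(stats::as.dist(D), method = "average")
  } else {
    out$distance <- NULL
    out$dendrogram <- NULL
  }
  out
}
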