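#' Simulation configuration
#'
#' Builds and validates the configuration driving every synthetic-data
#' generator. Defaults emulate the study design the pipeline targets: a
#' paired cohort of phenoconverters sampled before ("pre") and after
#' ("post") conversion plus an independent group of never-converting
#' controls ("NC"), with negative-binomial counts, a per-subject random
#' intercept shared by a subject's two samples, and differential expression
#' planted on a known set of loci.
#'
#' @param n_loci Number of TE loci in the synthetic reference.
#' @param class_mix Named numeric vector of proportions over
#'   `c("LINE","SINE","LTR","SVA","DNA")`; must sum to 1.
#' @param n_subjects_conv Number of paired converter subjects (each
#'   contributes one pre and one post sample).
#' @param n_controls Number of independent NC subjects.
#' @param de_fraction Fraction of loci planted as differentially expressed
#'   per contrast.
#' @param planted_lfc Magnitude of the planted log2 fold-change.
#' @param dispersion Negative-binomial dispersion phi (var = mu + phi mu^2).
#' @param lib_size_range Length-2 numeric, bounds of the per-sample library
#'   size (total assigned transcript counts).
#' @param n_tissues Number of synthetic chromatin segmentation tracks.
#' @param frac_multimap Fraction of transcripts given a second passing
#'   alignment to a different locus.
#' @param frac_lowid Fraction of transcripts generated below the identity
#'   threshold.
#' @param subject_sd SD (log2 scale) of the per-locus subject random
#'   intercept shared between a converter's pre and post samples.
#' @param frac_pre_signature Fraction of planted DE loci forming a
#'   pre-specific signature: expression shifted in the pre samples only, so
#'   the same loci are DE, with concordant direction, in both the
#'   pre-vs-post and pre-vs-NC contrasts.
#' @param state_probs Named numeric vector of proportions over the 15
#'   chromatin states used when drawing each locus's state.
#' @param seed Master RNG seed; every generator derives its own fixed
#'   stream from it.
#'
#' @return A validated list of class `telex_config`.
#' @export
simulation_config <- function(n_loci = 300,
                              class_mix = c(LINE = 0.35, SINE = 0.30, LTR = 0.20,
                                            SVA = 0.05, DNA = 0.10),
                              n_subjects_conv = 25,
                              n_controls = 64,
                              de_fraction = 0.05,
                              planted_lfc = 2,
                              dispersion = 0.1,
                              lib_size_range = c(5e5, 1.5e6),
                              n_tissues = 3,
                              frac_multimap = 0.10,
                              frac_lowid = 0.10,
                              subject_sd = 1,
                              frac_pre_signature = 0.25,
                              state_probs = NULL,
                              seed = 1L) {
  if (!is.numeric(n_loci) || n_loci <= 0) {
    abort("`n_loci` must be a positive count.")
  }
  cls <- te_classes()
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% cls)) {
    abort("`class_mix` must be named with TE classes (LINE, SINE, LTR, SVA, DNA).")
  }
  mix <- setNames(numeric(length(cls)), cls)
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    abort("`class_mix` proportions must be non-negative and sum to 1.")
  }
  for (nm in c("de_fraction", "frac_multimap", "frac_lowid", "frac_pre_signature")) {
    check_prob(get(nm), nm)
  }
  if (frac_multimap + frac_lowid > 1) {
    abort("`frac_multimap` + `frac_lowid` must not exceed 1.")
  }
  if (planted_lfc < 0) abort("`planted_lfc` must be >= 0.")
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2]) {
    abort("`lib_size_range` must be increasing positive bounds.")
  }
  if (n_tissues < 1) abort("`n_tissues` must be >= 1.")
  states <- chromatin_state_alphabet()$state
  if (is.null(state_probs)) {
    # genome-like composition: mostly quiescent/heterochromatic, modest
    # active block
    state_probs <- setNames(
      c(0.02, 0.02, 0.02, 0.05, 0.08, 0.03, 0.05, 0.03,
        0.08, 0.02, 0.02, 0.03, 0.05, 0.10, 0.40),
      states
    )
  }
  if (is.null(names(state_probs)) || !all(names(state_probs) %in% states)) {
    bad <- setdiff(names(state_probs), states)
    abort(sprintf("Unknown chromatin state label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  sp <- setNames(numeric(length(states)), states)
  sp[names(state_probs)] <- state_probs
  if (any(sp < 0) || sum(sp) <= 0) abort("`state_probs` must be non-negative.")
  sp <- sp / sum(sp)

  structure(
    list(
      n_loci = as.integer(n_loci), class_mix = mix,
      n_subjects_conv = as.integer(n_subjects_conv),
      n_controls = as.integer(n_controls),
      de_fraction = de_fraction, planted_lfc = planted_lfc,
      dispersion = dispersion, lib_size_range = lib_size_range,
      n_tissues = as.integer(n_tissues),
      frac_multimap = frac_multimap, frac_lowid = frac_lowid,
      subject_sd = subject_sd, frac_pre_signature = frac_pre_signature,
      state_probs = sp, seed = as.integer(seed)
    ),
    class = "telex_config"
  )
}

#' @export
print.telex_config <- function(x, ...) {
  cat("<telex simulation config>\n")
  cat(sprintf("  loci: %d   converters: %d (paired)   controls: %d\n",
              x$n_loci, x$n_subjects_conv, x$n_controls))
  cat(sprintf("  DE fraction: %.3g  planted |log2FC|: %.3g  dispersion: %.3g\n",
              x$de_fraction, x$planted_lfc, x$dispersion))
  cat(sprintf("  library sizes: [%.3g, %.3g]   tissues: %d   seed: %d\n",
              x$lib_size_range[1], x$lib_size_range[2], x$n_tissues, x$seed))
  invisible(x)
}
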