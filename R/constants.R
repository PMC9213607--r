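#' TE family/class lookup table
#'
#' Fixed mapping between RepeatMasker-style family names and the five TE
#' classes used throughout the package, with an evolutionary-age flag for
#' the families that are recent in the human lineage (human-specific or
#' hominid-restricted subfamilies such as L1HS, AluY, LTR5_Hs/HERVK, SVA_E/F).
#'
#' @return A tibble with columns `family`, `te_class` and `recent`.
#' @export
te_family_table <- function() {
  tribble(
    ~family,      ~te_class, ~recent,
    "L1HS",       "LINE",    TRUE,
    "L1PA2",      "LINE",    TRUE,
    "L1PA4",      "LINE",    TRUE,
    "L1M5",       "LINE",    FALSE,
    "L1ME3",      "LINE",    FALSE,
    "L2a",        "LINE",    FALSE,
    "AluY",       "SINE",    TRUE,
    "AluSx",      "SINE",    FALSE,
    "AluJb",      "SINE",    FALSE,
    "MIRb",       "SINE",    FALSE,
    "LTR5_Hs",    "LTR",     TRUE,
    "HERVK-int",  "LTR",     TRUE,
    "LTR7",       "LTR",     FALSE,
    "MER21A",     "LTR",     FALSE,
    "SVA_E",      "SVA",     TRUE,
    "SVA_F",      "SVA",     TRUE,
    "SVA_B",      "SVA",     FALSE,
    "HSMAR1",     "DNA",     FALSE,
    "MER1A",      "DNA",     FALSE,
    "Charlie1",   "DNA",     FALSE
  )
}

#' The Core 15-state chromatin alphabet
#'
#' Roadmap Epigenomics 15-state mnemonics learned from five histone marks
#' (H3K4me3, H3K4me1, H3K36me3, H3K27me3, H3K9me3). `active` marks the
#' promoter/transcription/enhancer block used as the default definition of
#' "functionally active" chromatin; the sentinel label `"Mx"` (mixed states,
#' assigned when a locus overlaps two or more states in a tissue) is not part
#' of the alphabet and never appears in segmentation input.
#'
#' @return A tibble with columns `state` and `active`.
#' @export
chromatin_state_alphabet <- function() {
  tibble(
    state = c(
      "1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG",
      "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv", "11_BivFlnk",
      "12_EnhBiv", "13_ReprPC", "14_ReprPCWk", "15_Quies"
    ),
    active = c(rep(TRUE, 8), rep(FALSE, 7))
  )
}

default_active_states <- function() {
  alpha <- chromatin_state_alphabet()
  alpha$state[alpha$active]
}

te_classes <- function() c("LINE", "SINE", "LTR", "SVA", "DNA")
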