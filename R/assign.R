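blast6_cols <- c("transcript_id", "locus_id", "pident", "aln_len", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore", "qlen")

#' Read tabular alignments (BLAST outfmt-6 dialect plus qlen)
#'
#' Twelve standard columns (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore) plus a 13th `qlen` column with
#' the full transcript length. Lines starting with `#` are skipped.
#'
#' @param path Path to a tab-separated alignment file.
#' @return A tibble of alignment records.
#' @export
read_blast_tab <- function(path) {
  readr::read_tsv(path, col_names = blast6_cols, comment = "#",
                  show_col_types = FALSE)
}

#' Filter transcript-to-TE alignments on identity and coverage
#'
#' Keeps records with at least `min_identity` percent identical matches that
#' align for at least `min_coverage` of the transcript's length (coverage =
#' `aln_len / qlen`, the denominator being the full transcript). Both
#' thresholds are inclusive. Input order is preserved.
#'
#' @param records Tibble of alignment records (see [read_blast_tab()] for
#'   the required columns).
#' @param min_identity Minimum percent identity, in (0, 100]. Default 95.
#' @param min_coverage Minimum transcript-length fraction aligned, in
#'   (0, 1]. Default 0.90.
#' @return The retained records.
#' @export
filter_alignments <- function(records, min_identity = 95, min_coverage = 0.90) {
  stopifnot(is.data.frame(records))
  if (min_identity <= 0 || min_identity > 100) abort("`min_identity` must be in (0, 100].")
  if (min_coverage <= 0 || min_coverage > 1) abort("`min_coverage` must be in (0, 1].")
  if (nrow(records) == 0) return(as_tibble(records))
  bad <- records$qlen <= 0 | is.na(records$qlen)
  if (any(bad)) {
    abort(sprintf("Malformed record(s) with qlen <= 0 for transcript(s): %s",
                  paste(unique(records$transcript_id[bad]), collapse = ", ")))
  }
  keep <- records$pident >= min_identity &
    records$aln_len / records$qlen >= min_coverage
  as_tibble(records[keep, , drop = FALSE])
}

#' Resolve filtered alignments to unique transcript-locus assignments
#'
#' Transcripts whose passing hits all point at one locus are assigned to
#' it; transcripts with passing hits to two or more distinct loci are
#' discarded as multi-mappers (several hits to the same locus, e.g. split
#' alignments, count as one). Optionally, a best-hit rescue assigns a
#' multi-mapper to its top locus when the top bitscore exceeds the runner-up
#' locus's best bitscore by at least `best_hit_margin`.
#'
#' @param records Alignment records that already passed
#'   [filter_alignments()].
#' @param best_hit_margin Bitscore margin for multi-map rescue; `NULL`
#'   (default) means strict discard.
#' @return A tibble (transcript_id, locus_id, status, reason) with status
#'   `assigned` or `discarded`; multi-mapped transcripts carry reason
#'   `"multimap"` and `NA` locus.
#' @export
resolve_unique <- function(records, best_hit_margin = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(tibble(transcript_id = character(), locus_id = character(),
                  status = character(), reason = character()))
  }
  per_tx <- records |>
    group_by(.data$transcript_id, .data$locus_id) |>
    summarise(bitscore = max(.data$bitscore), .groups = "drop_last") |>
    arrange(desc(.data$bitscore), .data$locus_id, .by_group = TRUE) |>
    summarise(
      n_loci = n(),
      top_locus = .data$locus_id[1],
      margin = if (n() > 1) .data$bitscore[1] - .data$bitscore[2] else Inf,
      .groups = "drop"
    )
  rescued <- if (is.null(best_hit_margin)) rep(FALSE, nrow(per_tx)) else {
    per_tx$margin >= best_hit_margin
  }
  per_tx |>
    mutate(
      assigned = .data$n_loci == 1 | rescued,
      locus_id = ifelse(.data$assigned, .data$top_locus, NA_character_),
      status = ifelse(.data$assigned, "assigned", "discarded"),
      reason = ifelse(.data$assigned, NA_character_, "multimap")
    ) |>
    select("transcript_id", "locus_id", "status", "reason") |>
    arrange(.data$transcript_id)
}

#' Assign transcripts to unique TE loci
#'
#' Runs the identity/coverage filter and multi-map resolution in one step
#' and returns the complete assignment table, including discarded
#' transcripts with their reasons. A transcript with no passing record is
#' discarded with the failure reason of its highest-bitscore record
#' (identity checked before coverage).
#'
#' @inheritParams filter_alignments
#' @inheritParams resolve_unique
#' @return A tibble (transcript_id, locus_id, status, reason); assigned and
#'   discarded transcript sets are disjoint and together equal the input
#'   transcript set.
#' @export
assign_transcripts <- function(records, min_identity = 95, min_coverage = 0.90,
                               best_hit_margin = NULL) {
  passing <- filter_alignments(records, min_identity, min_coverage)
  table <- resolve_unique(passing, best_hit_margin = best_hit_margin)
  failed_tx <- setdiff(unique(records$transcript_id), table$transcript_id)
  if (length(failed_tx)) {
    fail <- records |>
      filter(.data$transcript_id %in% failed_tx) |>
      group_by(.data$transcript_id) |>
      arrange(desc(.data$bitscore), .by_group = TRUE) |>
      summarise(
        reason = if (.data$pident[1] < min_identity) "low_identity" else "low_coverage",
        .groups = "drop"
      ) |>
      mutate(locus_id = NA_character_, status = "discarded") |>
      select("transcript_id", "locus_id", "status", "reason")
    table <- bind_rows(table, fail)
  }
  arrange(table, .data$transcript_id)
}

#' Semi-global alignment of a transcript against a reference TE
#'
#' Optimal semi-global alignment (query global, free end-gaps on the
#' target) by dynamic programming, used as a test-scale stand-in for a
#' seeded local aligner so fixtures can be recomputed from FASTA alone.
#' Percent identity is matches over aligned columns; `aln_len` is the
#' aligned query span.
#'
#' @param query,target DNA sequences (single strings over A/C/G/T/N).
#' @param match,mismatch,gap Alignment scores (gap is the per-base linear
#'   penalty, given as a negative number).
#' @param query_id,target_id Identifiers copied into the returned record.
#' @return A one-row alignment-record tibble.
#' @export
align_semiglobal <- function(query, target, match = 2, mismatch = -1, gap = -2,
                             query_id = "query", target_id = "target") {
  for (s in c(query, target)) {
    if (!nzchar(s) || grepl("[^ACGTN]", s)) {
      abort("Sequences must be non-empty strings over A, C, G, T, N.")
    }
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = target, type = "global-local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap
  )
  p <- as.character(Biostrings::pattern(aln))
  n_cols <- nchar(p)
  n_match <- Biostrings::nmatch(aln)
  qlen <- nchar(query)
  tibble(
    transcript_id = query_id, locus_id = target_id,
    pident = n_match / n_cols * 100,
    aln_len = qlen,
    mismatch = Biostrings::nmismatch(aln), gapopen = 0L,
    qstart = 1L, qend = qlen,
    sstart = Biostrings::start(Biostrings::subject(aln)),
    send = Biostrings::end(Biostrings::subject(aln)),
    evalue = NA_real_, bitscore = Biostrings::score(aln), qlen = qlen
  )
}

#' Collapse assigned transcript counts to locus-level counts
#'
#' Each locus's count is the sum of the counts of the transcripts assigned
#' to it; discarded transcripts contribute nothing.
#'
#' @param table Assignment table from [assign_transcripts()] (or
#'   [resolve_unique()]).
#' @param transcript_counts Tibble with a `transcript_id` column and one
#'   numeric column per sample.
#' @return A locus-level counts tibble (`locus_id` + sample columns); zero
#'   rows when every transcript was discarded.
#' @export
collapse_to_loci <- function(table, transcript_counts) {
  stopifnot(is.data.frame(table), is.data.frame(transcript_counts))
  missing_tx <- setdiff(transcript_counts$transcript_id, table$transcript_id)
  if (length(missing_tx)) {
    abort(sprintf("Transcript(s) in counts but absent from the assignment table: %s",
                  paste(head(missing_tx, 5), collapse = ", ")))
  }
  assigned <- table |> filter(.data$status == "assigned")
  transcript_counts |>
    inner_join(select(assigned, "transcript_id", "locus_id"),
               by = "transcript_id") |>
    select(-"transcript_id") |>
    group_by(.data$locus_id) |>
    summarise(across(dplyr::where(is.numeric), sum), .groups = "drop") |>
    arrange(.data$locus_id)
}
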