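#' Write sequences to FASTA
#' @param seqs A named [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path Input path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write TE loci as BED6
#'
#' Coordinates are emitted 0-based half-open, name = locus id, score =
#' consensus length, as BED convention requires.
#'
#' @param loci Locus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(loci, path) {
  readr::write_tsv(
    tibble(chrom = loci$chrom, start = loci$start, end = loci$end,
           name = loci$locus_id,
           score = loci$consensus_len %||% 0L, strand = loci$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Write TE loci as a RepeatMasker-style table
#'
#' 1-based inclusive coordinates, matching the RepeatMasker .out
#' convention.
#'
#' @inheritParams write_te_bed
#' @export
write_te_rmsk <- function(loci, path) {
  readr::write_tsv(
    tibble(chrom = loci$chrom, begin = loci$start + 1L, end = loci$end,
           strand = loci$strand, family = loci$family,
           te_class = loci$te_class, locus_id = loci$locus_id),
    path)
  invisible(path)
}

#' Read a TE BED6 annotation
#' @param path Input path.
#' @return A loci tibble (locus_id, chrom, start, end, strand).
#' @export
read_te_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                  show_col_types = FALSE) |>
    transmute(locus_id = .data$name, chrom = .data$chrom,
              start = .data$start, end = .data$end, strand = .data$strand)
}

#' Write chromatin segmentations as per-tissue BED4 files
#'
#' One `<tissue>.bed` per tissue with the state mnemonic in column 4.
#'
#' @param segments Segmentation tibble (tissue, chrom, start, end, state).
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_state_beds <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(segments$tissue), function(tis) {
    p <- file.path(dir, paste0(tis, ".bed"))
    readr::write_tsv(
      segments |> filter(.data$tissue == tis) |>
        select("chrom", "start", "end", "state") |>
        arrange(.data$chrom, .data$start),
      p, col_names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read per-tissue chromatin segmentation BED4 files
#'
#' @param paths Named character vector of BED paths; names are tissue ids
#'   (file basenames used when unnamed).
#' @return A segmentation tibble (tissue, chrom, start, end, state).
#' @export
read_state_beds <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.bed$", "", basename(paths))
  }
  purrr::imap_dfr(paths, function(p, tis) {
    readr::read_tsv(p, col_names = c("chrom", "start", "end", "state"),
                    show_col_types = FALSE) |>
      mutate(tissue = tis, .before = 1)
  })
}

#' Write/read a counts table as TSV
#'
#' @param counts Counts tibble (`locus_id` or `transcript_id` first
#'   column).
#' @param path File path.
#' @return `path` / a tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a gene annotation as BED6
#' @param genes Gene tibble (gene_id, chrom, start, end, strand).
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  readr::write_tsv(
    tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
           name = genes$gene_id, score = 0L,
           strand = genes$strand %||% "+"),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                  show_col_types = FALSE) |>
    transmute(gene_id = .data$name, chrom = .data$chrom,
              start = .data$start, end = .data$end, strand = .data$strand)
}
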