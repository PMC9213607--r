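#' Generate a synthetic TE reference
#'
#' Draws `n_loci` non-overlapping TE insertions on toy chromosomes, each
#' with a RepeatMasker-style family, class, strand and a random sequence of
#' 300-7000 nt. Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `loci` (tibble: locus_id, chrom, start, end, strand,
#'   family, te_class, consensus_len, recent; 0-based half-open
#'   coordinates), `sequences` (a [Biostrings::DNAStringSet] named by
#'   locus id) and `chrom_sizes` (tibble: chrom, size).
#' @export
simulate_te_reference <- function(cfg) {
  stopifnot(inherits(cfg, "telex_config"))
  with_stream(cfg$seed, "reference", {
    n <- cfg$n_loci
    fam_tbl <- te_family_table()
    classes <- sample(names(cfg$class_mix), n, replace = TRUE, prob = cfg$class_mix)
    family <- vapply(classes, function(cl) {
      sample(fam_tbl$family[fam_tbl$te_class == cl], 1)
    }, character(1))
    len <- sample(300:7000, n, replace = TRUE)

    n_chrom <- max(1L, min(3L, ceiling(n / 100)))
    chrom <- paste0("chrT", sort(rep_len(seq_len(n_chrom), n)))
    start <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      gaps <- sample(500:5000, length(idx), replace = TRUE)
      start[idx] <- cumsum(gaps) + cumsum(c(0L, len[idx][-length(idx)]))
    }
    loci <- tibble(
      locus_id = sprintf("te_%04d", seq_len(n)),
      chrom = chrom,
      start = start,
      end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      family = unname(family),
      te_class = classes
    ) |>
      left_join(fam_tbl, by = c("family", "te_class")) |>
      mutate(consensus_len = len, .before = "recent")

    seqs <- Biostrings::DNAStringSet(vapply(len, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1)))
    names(seqs) <- loci$locus_id

    chrom_sizes <- loci |>
      group_by(.data$chrom) |>
      summarise(size = max(.data$end) + 1000L, .groups = "drop")

    list(loci = loci, sequences = seqs, chrom_sizes = chrom_sizes)
  })
}

#' Generate synthetic TE transcripts and alignment records
#'
#' Derives one transcript per locus by substitution edits, so that each
#' alignment record's identity and coverage are exact functions of the edit
#' trace. A configured fraction of transcripts is generated below the 95%
#' identity threshold and a disjoint fraction receives a second passing hit
#' to a different locus (multi-mappers).
#'
#' @param reference Output of [simulate_te_reference()].
#' @param cfg A [simulation_config()].
#' @return A list with `transcripts` (DNAStringSet), `alignments` (tibble in
#'   BLAST outfmt-6 column order plus `qlen`) and `truth` (tibble:
#'   transcript_id, locus_id, status in ok/low_identity/multimap, pident,
#'   coverage).
#' @export
simulate_transcripts <- function(reference, cfg) {
  loci <- reference$loci
  if (nrow(loci) == 0) abort("`reference` contains no loci.")
  with_stream(cfg$seed, "transcripts", {
    n <- nrow(loci)
    n_low <- round(cfg$frac_lowid * n)
    n_multi <- round(cfg$frac_multimap * n)
    status <- rep("ok", n)
    pick <- sample.int(n, n_low + n_multi)
    status[pick[seq_len(n_low)]] <- "low_identity"
    if (n_multi > 0) status[pick[n_low + seq_len(n_multi)]] <- "multimap"

    tx_id <- sprintf("tx_%04d", seq_len(n))
    seqs <- as.character(reference$sequences[loci$locus_id])
    records <- vector("list", n)
    out_seq <- character(n)
    truth_pident <- numeric(n)

    for (i in seq_len(n)) {
      s <- strsplit(seqs[i], "")[[1]]
      len <- length(s)
      target_id <- if (status[i] == "low_identity") runif(1, 90, 94.9) else runif(1, 97, 100)
      n_sub <- round((1 - target_id / 100) * len)
      # force the planted status at the 95% boundary after rounding
      if (status[i] == "low_identity") {
        while ((len - n_sub) / len * 100 >= 95) n_sub <- n_sub + 1L
      } else {
        while (n_sub > 0 && (len - n_sub) / len * 100 < 95) n_sub <- n_sub - 1L
      }
      if (n_sub > 0) {
        pos <- sample.int(len, n_sub)
        s[pos] <- vapply(s[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      out_seq[i] <- paste(s, collapse = "")
      pident <- (len - n_sub) / len * 100
      truth_pident[i] <- pident
      rec <- tibble(
        transcript_id = tx_id[i], locus_id = loci$locus_id[i],
        pident = pident, aln_len = len, mismatch = n_sub, gapopen = 0L,
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = 0, bitscore = 2 * (len - n_sub), qlen = len
      )
      if (status[i] == "multimap") {
        other <- sample(setdiff(seq_len(n), i), 1)
        rec2 <- rec
        rec2$locus_id <- loci$locus_id[other]
        rec2$pident <- round(runif(1, 96, 99), 1)
        rec2$mismatch <- round((1 - rec2$pident / 100) * len)
        rec2$bitscore <- rec$bitscore - sample(5:50, 1)
        rec <- bind_rows(rec, rec2)
      }
      records[[i]] <- rec
    }

    transcripts <- Biostrings::DNAStringSet(out_seq)
    names(transcripts) <- tx_id
    list(
      transcripts = transcripts,
      alignments = bind_rows(records),
      truth = tibble(
        transcript_id = tx_id, locus_id = loci$locus_id, status = status,
        pident = truth_pident, coverage = 1
      )
    )
  })
}

#' Generate a synthetic locus x sample count matrix with planted DE
#'
#' Counts are negative-binomial around `library size x relative abundance x
#' planted fold-change`, with a per-locus, per-subject log-normal random
#' intercept shared by a converter's pre and post samples (this is what
#' makes the paired design strictly more powerful than an unpaired one).
#' Age is drawn independently of expression, providing a null covariate.
#'
#' Planted DE loci split into a pre-specific shared signature (expression
#' shifted in the pre samples only, so the loci are differential with
#' concordant direction against both the post and the NC groups) and
#' contrast-specific remainders. DE loci are sampled with extra weight on
#' LINE and LTR loci so class enrichment has signal to find.
#'
#' @param loci Locus tibble from [simulate_te_reference()].
#' @param cfg A [simulation_config()].
#' @return A list with `counts` (tibble, `locus_id` + one column per
#'   sample), `metadata` (tibble: sample_id, subject_id, group, sex, age,
#'   pair_id) and `truth` (list with `de` tibble of contrast/locus_id/
#'   sign/lfc and `informative_features` per contrast).
#' @export
simulate_counts <- function(loci, cfg) {
  stopifnot(is.data.frame(loci), nrow(loci) > 0)
  with_stream(cfg$seed, "counts", {
    n <- nrow(loci)
    n_conv <- cfg$n_subjects_conv
    n_nc <- cfg$n_controls

    conv_subj <- sprintf("subj_%03d", seq_len(n_conv))
    nc_subj <- sprintf("ncsubj_%03d", seq_len(n_nc))
    metadata <- bind_rows(
      tibble(
        sample_id = c(paste0("pre_", conv_subj), paste0("post_", conv_subj)),
        subject_id = rep(conv_subj, 2),
        group = rep(c("Converter_pre", "Converter_post"), each = n_conv),
        pair_id = rep(conv_subj, 2)
      ),
      tibble(
        sample_id = paste0("nc_", nc_subj), subject_id = nc_subj,
        group = "NC", pair_id = NA_character_
      )
    )
    subj_sex <- setNames(
      c(sample(c("F", "M"), n_conv, replace = TRUE, prob = c(14, 11) / 25),
        sample(c("F", "M"), n_nc, replace = TRUE, prob = c(43, 21) / 64)),
      c(conv_subj, nc_subj)
    )
    subj_age <- setNames(
      c(rnorm(n_conv, 81.2, 4.1), rnorm(n_nc, 81.6, 3.9)),
      c(conv_subj, nc_subj)
    )
    metadata$sex <- unname(subj_sex[metadata$subject_id])
    metadata$age <- round(unname(subj_age[metadata$subject_id]), 1)

    # planted DE sets
    n_de <- round(cfg$de_fraction * n)
    n_shared <- round(cfg$frac_pre_signature * n_de)
    w <- ifelse(loci$te_class %in% c("LINE", "LTR"), 2, 1)
    de_pool <- sample.int(n, size = min(n, 2 * n_de), prob = w)
    shared <- de_pool[seq_len(n_shared)]
    post_only <- de_pool[n_shared + seq_len(n_de - n_shared)]
    nc_only <- de_pool[(n_de) + seq_len(n_de - n_shared)]

    sgn <- function(k) sample(c(1, -1), k, replace = TRUE)
    s_shared <- sgn(length(shared))
    s_post <- sgn(length(post_only))
    s_nc <- sgn(length(nc_only))

    # per-group log2 multipliers; logFC convention is second condition of
    # the contrast name over the first (pre_vs_post -> log2 post/pre)
    mult_pre <- mult_post <- mult_nc <- rep(0, n)
    mult_pre[shared] <- s_shared * cfg$planted_lfc
    mult_post[post_only] <- s_post * cfg$planted_lfc
    mult_nc[nc_only] <- s_nc * cfg$planted_lfc

    de_truth <- bind_rows(
      tibble(contrast = "pre_vs_post", locus_id = loci$locus_id[shared],
             sign = -s_shared),
      tibble(contrast = "pre_vs_post", locus_id = loci$locus_id[post_only],
             sign = s_post),
      tibble(contrast = "pre_vs_nc", locus_id = loci$locus_id[shared],
             sign = -s_shared),
      tibble(contrast = "pre_vs_nc", locus_id = loci$locus_id[nc_only],
             sign = s_nc)
    )
    if (nrow(de_truth)) de_truth$lfc <- cfg$planted_lfc

    base <- exp(rnorm(n, 0, 1.25))
    lib <- runif(nrow(metadata), cfg$lib_size_range[1], cfg$lib_size_range[2])

    subj_all <- unique(metadata$subject_id)
    u <- matrix(rnorm(n * length(subj_all), 0, cfg$subject_sd),
                nrow = n, dimnames = list(loci$locus_id, subj_all))

    counts <- matrix(0, nrow = n, ncol = nrow(metadata),
                     dimnames = list(loci$locus_id, metadata$sample_id))
    group_mult <- list(Converter_pre = mult_pre, Converter_post = mult_post,
                       NC = mult_nc)
    for (k in seq_len(nrow(metadata))) {
      g <- metadata$group[k]
      lw <- base * 2^(u[, metadata$subject_id[k]] + group_mult[[g]])
      mu <- lib[k] * lw / sum(lw)
      counts[, k] <- rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    }

    list(
      counts = matrix_to_counts(counts),
      metadata = metadata,
      truth = list(
        de = de_truth,
        informative_features = list(
          pre_vs_post = loci$locus_id[c(shared, post_only)],
          pre_vs_nc = loci$locus_id[c(shared, nc_only)]
        ),
        pre_signature = loci$locus_id[shared]
      )
    )
  })
}

#' Generate synthetic per-tissue chromatin segmentations
#'
#' For each tissue, each chromosome is tiled without gaps or overlaps by
#' blocks whose boundaries fall at midpoints between consecutive loci, so
#' every locus lies inside a single state segment - except loci named in
#' `straddle`, whose block is split mid-locus into two distinct states to
#' exercise the mixed-state ("Mx") label.
#'
#' @param loci Locus tibble from [simulate_te_reference()].
#' @param cfg A [simulation_config()]; `cfg$state_probs` sets the state
#'   composition.
#' @param straddle Character vector of locus ids forced to overlap a state
#'   boundary in every tissue.
#' @param chrom_sizes Optional tibble (chrom, size); derived from loci when
#'   missing.
#' @return A list with `segments` (tibble: tissue, chrom, start, end,
#'   state) and `truth` (tibble: tissue, locus_id, state, where straddling
#'   loci are recorded as "Mx").
#' @export
simulate_chromatin_tracks <- function(loci, cfg, straddle = character(),
                                      chrom_sizes = NULL) {
  if (cfg$n_tissues < 1) abort("`n_tissues` must be >= 1.")
  bad <- setdiff(straddle, loci$locus_id)
  if (length(bad)) abort(sprintf("Unknown straddle locus id(s): %s",
                                 paste(bad, collapse = ", ")))
  if (is.null(chrom_sizes)) {
    chrom_sizes <- loci |>
      group_by(.data$chrom) |>
      summarise(size = max(.data$end) + 1000L, .groups = "drop")
  }
  states <- names(cfg$state_probs)
  with_stream(cfg$seed, "chromatin", {
    tissues <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
    seg_out <- list()
    truth_out <- list()
    for (tis in tissues) {
      for (ch in chrom_sizes$chrom) {
        lc <- loci[loci$chrom == ch, ] |> arrange(.data$start)
        size <- chrom_sizes$size[chrom_sizes$chrom == ch]
        if (nrow(lc) == 0) {
          seg_out[[length(seg_out) + 1]] <- tibble(
            tissue = tis, chrom = ch, start = 0L, end = size,
            state = sample(states, 1, prob = cfg$state_probs)
          )
          next
        }
        # block boundaries at midpoints of inter-locus gaps
        mids <- floor((lc$end[-nrow(lc)] + lc$start[-1]) / 2)
        lo <- c(0L, mids)
        hi <- c(mids, size)
        st <- sample(states, nrow(lc), replace = TRUE, prob = cfg$state_probs)
        is_straddle <- lc$locus_id %in% straddle
        segs <- vector("list", nrow(lc))
        for (i in seq_len(nrow(lc))) {
          if (is_straddle[i]) {
            second <- sample(setdiff(states, st[i]), 1)
            cut <- floor((lc$start[i] + lc$end[i]) / 2)
            segs[[i]] <- tibble(
              tissue = tis, chrom = ch, start = c(lo[i], cut),
              end = c(cut, hi[i]), state = c(st[i], second)
            )
          } else {
            segs[[i]] <- tibble(tissue = tis, chrom = ch, start = lo[i],
                                end = hi[i], state = st[i])
          }
        }
        seg_out[[length(seg_out) + 1]] <- bind_rows(segs)
        truth_out[[length(truth_out) + 1]] <- tibble(
          tissue = tis, locus_id = lc$locus_id,
          state = ifelse(is_straddle, "Mx", st)
        )
      }
    }
    list(segments = bind_rows(seg_out), truth = bind_rows(truth_out))
  })
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper running all four generators from one config.
#'
#' @param cfg A [simulation_config()].
#' @param straddle Locus ids forced to straddle a chromatin-state boundary.
#' @return A list with `reference`, `transcripts`, `expression`,
#'   `chromatin` and `genes` (a toy gene annotation placed near a subset of
#'   loci for cis-gene mapping).
#' @export
simulate_dataset <- function(cfg = simulation_config(), straddle = character()) {
  reference <- simulate_te_reference(cfg)
  transcripts <- simulate_transcripts(reference, cfg)
  expression <- simulate_counts(reference$loci, cfg)
  chromatin <- simulate_chromatin_tracks(reference$loci, cfg, straddle = straddle,
                                         chrom_sizes = reference$chrom_sizes)
  genes <- with_stream(cfg$seed, "pipeline", {
    loci <- reference$loci
    keep <- sample.int(nrow(loci), max(1, floor(nrow(loci) / 3)))
    offs <- sample(c(-8000:-200, 200:8000), length(keep), replace = TRUE)
    tibble(
      chrom = loci$chrom[keep],
      start = pmax(0L, loci$end[keep] + as.integer(offs)),
      gene_id = sprintf("gene_%04d", seq_along(keep)),
      strand = sample(c("+", "-"), length(keep), replace = TRUE)
    ) |>
      mutate(end = .data$start + sample(500:3000, length(keep), replace = TRUE),
             .after = "start") |>
      arrange(.data$chrom, .data$start)
  })
  # transcript-level counts: each transcript carries its source locus's
  # counts, so collapsing assigned transcripts recovers the locus matrix
  transcript_counts <- expression$counts |>
    inner_join(select(transcripts$truth, "transcript_id", "locus_id"),
               by = "locus_id") |>
    select("transcript_id", dplyr::everything(), -"locus_id")
  list(reference = reference, transcripts = transcripts,
       expression = expression, transcript_counts = transcript_counts,
       chromatin = chromatin, genes = genes, config = cfg)
}
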