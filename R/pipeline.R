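#' Pipeline configuration
#'
#' Schema-validated parameter set for [run_pipeline()]. Unknown keys are
#' rejected. Every stage parameter has a documented default matching the
#' analysis the pipeline implements.
#'
#' @param min_identity,min_coverage Assignment filter thresholds.
#' @param min_cpm,min_samples Expression filter.
#' @param trim_m,trim_a TMM trim fractions.
#' @param contrasts Contrasts to test; paired design is used automatically
#'   for `pre_vs_post`.
#' @param p_max,lfc_min DE selection thresholds.
#' @param prior_df Dispersion shrinkage weight.
#' @param window Cis-gene window in bp.
#' @param active_set Active chromatin states (defaults to states 1-8).
#' @param top_k Entropy prefilter size.
#' @param boruta_p,boruta_ntree,boruta_max_runs Boruta parameters.
#' @param train_frac,cv_folds,rf_ntree,downsample Classifier evaluation
#'   parameters.
#' @param ml_contrast Contrast used for the classifier stage.
#' @param stages Named logical toggles: enrichment, chromatin, ml.
#' @param seed Master seed for the stochastic stages.
#' @return A list of class `telex_pipeline_config`.
#' @export
pipeline_config <- function(min_identity = 95, min_coverage = 0.90,
                            min_cpm = 1, min_samples = 2,
                            trim_m = 0.30, trim_a = 0.05,
                            contrasts = c("pre_vs_post", "pre_vs_nc"),
                            p_max = 0.01, lfc_min = 1.5, prior_df = 10,
                            window = 5000,
                            active_set = default_active_states(),
                            top_k = 10000, boruta_p = 0.05,
                            boruta_ntree = 500, boruta_max_runs = 50,
                            train_frac = 0.70, cv_folds = 5,
                            rf_ntree = 500, downsample = TRUE,
                            ml_contrast = "pre_vs_post",
                            stages = list(enrichment = TRUE,
                                          chromatin = TRUE, ml = TRUE),
                            seed = 1L) {
  cfg <- mget(setdiff(names(formals()), "stages"))
  unknown <- setdiff(names(stages), c("enrichment", "chromatin", "ml"))
  if (length(unknown)) abort(sprintf("Unknown stage toggle(s): %s",
                                     paste(unknown, collapse = ", ")))
  cfg$stages <- modifyList(list(enrichment = TRUE, chromatin = TRUE, ml = TRUE),
                           as.list(stages))
  lapply(cfg$contrasts, parse_contrast)
  structure(cfg, class = "telex_pipeline_config")
}

# Load a demo directory written by make_demo() back into the in-memory
# dataset layout.
read_demo_dir <- function(dir) {
  list(
    reference = list(
      loci = readr::read_tsv(file.path(dir, "te_annotation.tsv"),
                             show_col_types = FALSE),
      sequences = read_fasta(file.path(dir, "te_reference.fasta"))
    ),
    transcripts = list(
      transcripts = read_fasta(file.path(dir, "transcripts.fasta")),
      alignments = read_blast_tab(file.path(dir, "alignments.tsv"))
    ),
    transcript_counts = read_counts_tsv(file.path(dir, "transcript_counts.tsv")),
    expression = list(
      counts = read_counts_tsv(file.path(dir, "locus_counts.tsv")),
      metadata = readr::read_tsv(file.path(dir, "metadata.tsv"),
                                 show_col_types = FALSE)
    ),
    chromatin = list(
      segments = read_state_beds(list.files(file.path(dir, "chromatin"),
                                            full.names = TRUE))
    ),
    genes = read_gene_bed(file.path(dir, "genes.bed"))
  )
}

#' Run the full TE expression pipeline
#'
#' Stages run in dependency order: transcript assignment, collapse to
#' locus counts, expression filter + TMM normalization, paired/unpaired NB
#' likelihood-ratio DE per contrast, class enrichment + DE-set
#' intersection + cis-gene mapping, chromatin-state annotation, and the
#' entropy/Boruta/random-forest classifier. Any stage failure stops the
#' run with the stage named.
#'
#' @param data A dataset list as produced by [simulate_dataset()], or a
#'   path to a directory written by [make_demo()].
#' @param config A [pipeline_config()].
#' @param outdir Optional directory for stage artifacts (TSV tables and
#'   the JSON report).
#' @return A list of class `telex_report` with one entry per stage that
#'   ran, each recording inputs, parameters and counts.
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "telex_pipeline_config"))
  if (is.character(data)) data <- read_demo_dir(data)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 version = as.character(utils::packageVersion("telex")))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # --- assignment -----------------------------------------------------
  assignment <- stage("assign", {
    assign_transcripts(data$transcripts$alignments,
                       min_identity = config$min_identity,
                       min_coverage = config$min_coverage)
  })
  locus_counts <- stage("collapse", {
    collapse_to_loci(assignment, data$transcript_counts)
  })
  report$assign <- list(
    transcripts_in = length(unique(data$transcripts$alignments$transcript_id)),
    assigned = sum(assignment$status == "assigned"),
    discarded = table(assignment$reason[assignment$status == "discarded"]),
    loci_with_counts = nrow(locus_counts),
    min_identity = config$min_identity, min_coverage = config$min_coverage
  )

  # --- normalization --------------------------------------------------
  norm <- stage("normalize", {
    keep <- filter_expressed(locus_counts, min_cpm = config$min_cpm,
                             min_samples = config$min_samples)
    counts <- locus_counts[locus_counts$locus_id %in% keep, ]
    factors <- calc_tmm_factors(counts, trim_m = config$trim_m,
                                trim_a = config$trim_a)
    list(counts = counts, factors = factors,
         logcpm = calc_logcpm(counts, factors))
  })
  report$normalize <- list(
    loci_in = nrow(locus_counts), loci_retained = nrow(norm$counts),
    reference_sample = attr(norm$factors, "reference_sample"),
    factor_range = range(norm$factors$factor)
  )

  metadata <- data$expression$metadata
  loci <- data$reference$loci

  # --- differential expression ---------------------------------------
  de <- stage("de", {
    setNames(lapply(config$contrasts, function(ctr) {
      de_test(norm$counts, metadata, ctr,
              paired = identical(ctr, "pre_vs_post"),
              prior_df = config$prior_df,
              p_max = config$p_max, lfc_min = config$lfc_min)
    }), config$contrasts)
  })
  report$de <- lapply(de, function(res) {
    s <- de_sets(res)
    list(tested = nrow(res), up = length(s$up), down = length(s$down),
         p_max = config$p_max, lfc_min = config$lfc_min)
  })

  # --- enrichment / intersection / cis genes --------------------------
  if (isTRUE(config$stages$enrichment)) {
    report$enrichment <- stage("enrichment", {
      out <- lapply(names(de), function(ctr) {
        res <- de[[ctr]]
        bg <- loci[loci$locus_id %in% res$locus_id, c("locus_id", "te_class", "family")]
        s <- de_sets(res)
        list(up = class_enrichment(s$up, bg),
             down = class_enrichment(s$down, bg))
      })
      names(out) <- names(de)
      if (length(de) >= 2) {
        r1 <- de[[1]]; r2 <- de[[2]]
        s1 <- de_sets(r1); s2 <- de_sets(r2)
        universe <- intersect(r1$locus_id, r2$locus_id)
        out$intersection <- intersection_test(
          c(s1$up, s1$down), c(s2$up, s2$down), universe, r1, r2)
        out$fc_correlation <- fold_change_correlation(r1, r2)
      }
      de_all <- unique(unlist(lapply(de, function(r) unlist(de_sets(r)))))
      out$cis <- cis_genes(loci[loci$locus_id %in% de_all, ], data$genes,
                           window = config$window)
      out
    })
  }

  # --- chromatin states ----------------------------------------------
  if (isTRUE(config$stages$chromatin)) {
    report$chromatin <- stage("chromatin", {
      tested <- de[[1]]$locus_id
      st <- overlap_states(loci[loci$locus_id %in% tested, ],
                           data$chromatin$segments)
      tissue1 <- st$assignment$tissue[1]
      s <- de_sets(de[[1]])
      fr <- lapply(s[lengths(s) > 0], active_fraction, states = st,
                   tissue = tissue1, active_set = config$active_set)
      enr <- if (length(s$up)) {
        state_enrichment(st, s$up, tested, tissue1)
      }
      consistency <- cross_tissue_consistency(st)
      list(states = st, tissue = tissue1, active_fractions = fr,
           state_enrichment = enr,
           mean_cross_tissue_agreement = mean(consistency$locus_agreement$agreement),
           active_set = config$active_set)
    })
  }

  # --- classifier ------------------------------------------------------
  if (isTRUE(config$stages$ml)) {
    report$ml <- stage("ml", {
      ctr <- config$ml_contrast
      groups <- parse_contrast(ctr)
      md <- metadata[metadata$group %in% groups, ]
      expr <- norm$logcpm[, c("locus_id", md$sample_id)]
      kept <- entropy_prefilter(expr, top_k = config$top_k)
      X <- t(counts_matrix(expr[expr$locus_id %in% kept$locus_id, ]))
      boruta <- boruta_select(X, md$group[match(rownames(X), md$sample_id)],
                              p_value = config$boruta_p,
                              n_tree = config$boruta_ntree,
                              max_runs = config$boruta_max_runs,
                              seed = config$seed)
      confirmed <- boruta$feature[boruta$status == "confirmed"]
      features <- if (length(confirmed)) confirmed else {
        head(boruta$feature[order(-boruta$hit_count)], 10)
      }
      model <- train_evaluate(X, md, features,
                              train_frac = config$train_frac,
                              cv_folds = config$cv_folds,
                              downsample = config$downsample,
                              n_tree = config$rf_ntree, seed = config$seed)
      list(contrast = ctr, prefiltered = nrow(kept),
           confirmed = confirmed, n_features = length(features),
           auc = model$auc, accuracy = model$accuracy,
           cv_accuracy = model$cv_accuracy, model = model,
           boruta = boruta)
    })
  }

  if (!is.null(outdir)) {
    readr::write_tsv(assignment, file.path(outdir, "assignment.tsv"))
    readr::write_tsv(norm$counts, file.path(outdir, "locus_counts_filtered.tsv"))
    readr::write_tsv(norm$factors, file.path(outdir, "tmm_factors.tsv"))
    for (ctr in names(de)) {
      readr::write_tsv(de[[ctr]], file.path(outdir, paste0("de_", ctr, ".tsv")))
    }
    jsonlite::write_json(report_summary(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report$results <- list(de = de, norm = norm, assignment = assignment)
  class(report) <- "telex_report"
  report
}

# numbers-only view of the report, suitable for JSON
report_summary <- function(report) {
  keep <- report[setdiff(names(report), "results")]
  strip <- function(x) {
    if (inherits(x, "telex_states") || inherits(x, "telex_model") ||
        inherits(x, "telex_boruta") || is.data.frame(x)) {
      return(NULL)
    }
    if (is.table(x)) return(as.list(x))
    if (is.list(x)) {
      x <- lapply(x, strip)
      return(x[!vapply(x, is.null, logical(1))])
    }
    x
  }
  strip(keep)
}

#' @export
print.telex_report <- function(x, ...) {
  cat("<telex pipeline report>\n")
  cat(sprintf("  transcripts: %d in, %d assigned\n",
              x$assign$transcripts_in, x$assign$assigned))
  cat(sprintf("  loci tested: %d\n", x$normalize$loci_retained))
  for (ctr in names(x$de)) {
    cat(sprintf("  %s: %d up, %d down\n", ctr, x$de[[ctr]]$up,
                x$de[[ctr]]$down))
  }
  if (!is.null(x$ml)) {
    cat(sprintf("  classifier (%s): AUC %.3f with %d features\n",
                x$ml$contrast, x$ml$auc, x$ml$n_features))
  }
  invisible(x)
}

#' Write a complete demo dataset to disk
#'
#' One command producing every input the pipeline consumes - reference
#' FASTA and annotation, transcript FASTA and alignments, transcript and
#' locus count tables, sample metadata, per-tissue chromatin BEDs, a gene
#' BED - together with the planted ground truth as JSON. The demo uses a
#' compact design (300 loci, 12 paired converters, 20 controls) so the
#' full pipeline runs in minutes while still recovering the planted
#' pre-specific signature.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed.
#' @param cfg Optional [simulation_config()] overriding the demo design.
#' @return The dataset list, invisibly.
#' @export
make_demo <- function(outdir, seed = 1L, cfg = NULL) {
  if (is.null(cfg)) {
    # the planted pre-specific signature is sized so it survives the ~20%
    # transcript-level attrition (low-identity + multi-map filtering) and
    # the moderate power of the unpaired pre-vs-NC contrast at this scale
    cfg <- simulation_config(n_loci = 300, n_subjects_conv = 12,
                             n_controls = 20, de_fraction = 0.1,
                             frac_pre_signature = 0.5, planted_lfc = 2.5,
                             seed = seed)
  }
  data <- simulate_dataset(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(data$reference$loci, file.path(outdir, "te_annotation.tsv"))
  write_te_bed(data$reference$loci, file.path(outdir, "te_annotation.bed"))
  write_fasta(data$reference$sequences, file.path(outdir, "te_reference.fasta"))
  write_fasta(data$transcripts$transcripts, file.path(outdir, "transcripts.fasta"))
  readr::write_tsv(data$transcripts$alignments, file.path(outdir, "alignments.tsv"),
                   col_names = FALSE)
  write_counts_tsv(data$transcript_counts, file.path(outdir, "transcript_counts.tsv"))
  write_counts_tsv(data$expression$counts, file.path(outdir, "locus_counts.tsv"))
  readr::write_tsv(data$expression$metadata, file.path(outdir, "metadata.tsv"))
  write_state_beds(data$chromatin$segments, file.path(outdir, "chromatin"))
  write_gene_bed(data$genes, file.path(outdir, "genes.bed"))
  jsonlite::write_json(
    list(
      de = data$expression$truth$de,
      pre_signature = data$expression$truth$pre_signature,
      informative_features = data$expression$truth$informative_features,
      transcript_truth = data$transcripts$truth,
      chromatin_truth = data$chromatin$truth
    ),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(data)
}
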