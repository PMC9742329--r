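#' Assemble a reproducible pipeline configuration
#'
#' Gathers every knob of the end-to-end extraction into one validated list
#' that serializes losslessly to JSON; [run_pipeline()] writes the resolved
#' configuration beside its outputs so any run can be replayed.
#'
#' @param quant_table Path to the quantification table (intensity mode) or
#'   ratio table (ratio mode).
#' @param output_dir Directory for all outputs (created if needed).
#' @param annotation_table Path to the localization annotation TSV; may be
#'   `NULL` when `thresholds` are injected.
#' @param design_file Path to a study-design JSON, or `NULL` for the
#'   packaged default.
#' @param mode `"intensities"` (raw reporter intensities; full pipeline) or
#'   `"ratios"` (pre-computed pair ratios; extraction and comparison only).
#' @param min_peptides,min_ratio_counts Evidence-filter thresholds
#'   (intensity mode).
#' @param strict_cutoff Use strict (`>`) instead of inclusive (`>=`)
#'   retention at the per-replicate cutoff.
#' @param stringent Also compute the stringent all-four-ratios proteomes.
#' @param alternative_pairing Use the alternative replicate pairing regime.
#' @param thresholds Optional named numeric vector (replicate label ->
#'   fixed cutoff ratio) replayed instead of ROC-derived cutoffs.
#' @param fit_differential Fit the moderated interaction model (intensity
#'   mode only).
#' @param top_n Top-N size for the proteome overlap report.
#' @param seed Integer seed recorded in the configuration (the pipeline
#'   itself is deterministic; the seed matters when the inputs are
#'   simulated).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(quant_table, output_dir,
                            annotation_table = NULL, design_file = NULL,
                            mode = c("intensities", "ratios"),
                            min_peptides = 2, min_ratio_counts = 2,
                            strict_cutoff = FALSE, stringent = FALSE,
                            alternative_pairing = FALSE, thresholds = NULL,
                            fit_differential = TRUE, top_n = 100,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (!is.null(thresholds)) {
    stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  }
  if (is.null(annotation_table) && is.null(thresholds)) {
    stop("need `annotation_table` (to compute cutoffs) or `thresholds`",
         call. = FALSE)
  }
  structure(
    list(quant_table = quant_table, output_dir = output_dir,
         annotation_table = annotation_table, design_file = design_file,
         mode = mode, min_peptides = min_peptides,
         min_ratio_counts = min_ratio_counts,
         strict_cutoff = strict_cutoff, stringent = stringent,
         alternative_pairing = alternative_pairing,
         thresholds = thresholds, fit_differential = fit_differential,
         top_n = top_n, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read or write a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  # keep replicate names through a length-1 unboxed vector
  if (!is.null(x$thresholds)) x$thresholds <- as.list(x$thresholds)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- if (!is.null(x$thresholds)) unlist(x$thresholds)
  pipeline_config(
    quant_table = x$quant_table, output_dir = x$output_dir,
    annotation_table = x$annotation_table, design_file = x$design_file,
    mode = x$mode, min_peptides = x$min_peptides,
    min_ratio_counts = x$min_ratio_counts,
    strict_cutoff = x$strict_cutoff, stringent = x$stringent,
    alternative_pairing = x$alternative_pairing, thresholds = thr,
    fit_differential = x$fit_differential, top_n = x$top_n, seed = x$seed
  )
}

safe_label <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Run the full extraction and comparison pipeline
#'
#' Composes the stages end to end — ingest, evidence filter, median
#' normalization, pair ratios, TP/FP classification, per-replicate ROC and
#' cutoff (or injected thresholds), replicate intersection, stage-proteome
#' comparison, and the moderated interaction model — writing every
#' intermediate artifact plus a manifest with stage-wise counts to
#' `config$output_dir`. Identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `pipeline_result` with elements
#'   `counts` (stage-wise record counts), `paths` (named vector of written
#'   files), `extraction`, `comparison`, and `fit` (NULL when not fitted).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  paths <- c(config = out("config.json"))
  write_pipeline_config(config, paths[["config"]])

  design <- if (!is.null(config$design_file)) {
    read_study_design(config$design_file)
  } else {
    default_study_design(
      pairing = if (config$alternative_pairing) "alternative" else "primary"
    )
  }
  counts <- list()

  if (config$mode == "intensities") {
    quant <- read_quant_table(config$quant_table, design)
    counts$detected <- nrow(quant)
    quant <- filter_evidence(quant, config$min_peptides,
                             config$min_ratio_counts)
    counts$post_evidence_filter <- nrow(quant)
    normalized <- normalize_to_protein_median(quant, design)
    ratios <- compute_pair_ratios(normalized, design)
  } else {
    ratios <- read_ratio_table(config$quant_table, design)
    normalized <- NULL
    counts$detected <- length(unique(ratios$accession))
    counts$post_evidence_filter <- counts$detected
  }

  labels <- NULL
  if (!is.null(config$annotation_table)) {
    ann <- read_annotation_table(config$annotation_table)
    labels <- classify_localization(ann, unique(ratios$accession))
    cc <- class_counts(labels)
    counts$n_tp <- cc$n_tp
    counts$n_fp <- cc$n_fp
    counts$n_unclassified <- cc$n_unclassified
  }

  thresholds <- if (!is.null(config$thresholds)) {
    tibble::tibble(replicate = names(config$thresholds),
                   threshold = unname(config$thresholds))
  }
  # drop proteins with undefined ratios before ranking; record how many
  defined <- !is.na(ratios$ratio) & is.finite(ratios$ratio)
  undefined_acc <- unique(ratios$accession[!defined])
  counts$n_undefined_ratio <- length(undefined_acc)
  ratios_ok <- dplyr::filter(ratios,
                             !.data$accession %in% undefined_acc)

  extraction <- extract_surfaceome(ratios_ok, labels, design,
                                   thresholds = thresholds,
                                   strict = config$strict_cutoff)
  if (!is.null(extraction$curves)) {
    for (r in names(extraction$curves)) {
      p <- out(paste0("roc_", safe_label(r), ".tsv"))
      readr::write_tsv(tibble::as_tibble(extraction$curves[[r]]), p)
      paths[[paste0("roc_", safe_label(r))]] <- p
    }
  }
  paths[["cutoffs"]] <- out("cutoffs.tsv")
  readr::write_tsv(extraction$cutoffs, paths[["cutoffs"]])
  for (r in names(extraction$replicate_lists)) {
    p <- out(paste0("postcutoff_", safe_label(r), ".tsv"))
    readr::write_tsv(extraction$replicate_lists[[r]], p)
    paths[[paste0("postcutoff_", safe_label(r))]] <- p
  }
  counts$post_cutoff <- as.list(stats::setNames(
    extraction$cutoffs$n_retained, extraction$cutoffs$replicate
  ))
  for (st in names(extraction$proteomes)) {
    p <- out(paste0("proteome_", safe_label(st), ".tsv"))
    readr::write_tsv(extraction$proteomes[[st]], p)
    paths[[paste0("proteome_", safe_label(st))]] <- p
  }
  counts$stage_proteomes <- lapply(extraction$proteomes, nrow)

  if (config$stringent) {
    stringent <- stringent_proteomes(ratios_ok, extraction$cutoffs, design)
    paths[["stringent"]] <- out("proteome_stringent.tsv")
    readr::write_tsv(stringent, paths[["stringent"]])
    counts$stringent_proteomes <- as.list(table(stringent$stage))
  }

  comparison <- NULL
  if (length(extraction$proteomes) == 2) {
    comparison <- compare_proteomes(extraction$proteomes[[1]],
                                    extraction$proteomes[[2]])
    overlap <- top_n_overlap(extraction$proteomes[[1]],
                             extraction$proteomes[[2]], config$top_n)
    report <- c(as.list(comparison$summary),
                list(top_n = config$top_n, top_n_overlap = overlap))
    paths[["comparison"]] <- out("comparison.json")
    jsonlite::write_json(report, paths[["comparison"]],
                         auto_unbox = TRUE, digits = NA)
    paths[["membership"]] <- out("membership.tsv")
    readr::write_tsv(tidy(comparison), paths[["membership"]])
  }

  fit <- NULL
  if (config$fit_differential && config$mode == "intensities") {
    fit <- fit_interaction_model(normalized, design)
    paths[["differential"]] <- out("differential.tsv")
    write_differential_table(fit, paths[["differential"]])
    counts$modeled_proteins <- nrow(fit$results)
  }

  manifest <- list(
    conventions = list(
      retention = if (config$strict_cutoff) "strict (>)" else
        "inclusive (>=)",
      cutoff_tie_rule = "largest threshold at tied maximal TPR-FPR",
      pairing = if (config$alternative_pairing) "alternative" else "primary"
    ),
    counts = counts,
    files = as.list(stats::setNames(basename(unlist(paths)), names(paths)))
  )
  paths[["manifest"]] <- out("manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(structure(
    list(counts = counts, paths = paths, extraction = extraction,
         comparison = comparison, fit = fit),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  utils::str(x$counts, give.attr = FALSE)
  invisible(x)
}
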