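required_meta_cols <- c("accession", "gene", "peptides", "ratio_counts")

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         tsv = "tsv", txt = "tsv", csv = "csv",
         xlsx = "xlsx", xls = "xlsx",
         stop("cannot guess format from extension of ", path, call. = FALSE))
}

read_table_any <- function(path, format, sheet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    tsv = readr::read_tsv(path, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal"),
    csv = readr::read_csv(path, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal"),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the readxl package", call. = FALSE)
      }
      tibble::as_tibble(readxl::read_excel(path, sheet = sheet),
                        .name_repair = "minimal")
    },
    stop("unknown format: ", format, call. = FALSE)
  )
}

check_unique_accessions <- function(x) {
  dup <- unique(x$accession[duplicated(x$accession)])
  if (length(dup) > 0) {
    stop("duplicate accession(s): ",
         paste(utils::head(dup, 10), collapse = ", "),
         if (length(dup) > 10) " ...", call. = FALSE)
  }
  invisible(x)
}

#' Read a protein-level quantification table
#'
#' Reads a TSV/CSV (or one sheet of an xlsx workbook) holding per-protein
#' reporter-ion intensities and evidence counts, and validates it against a
#' study design: the columns `accession`, `gene`, `peptides`,
#' `ratio_counts` and one intensity column per design channel must be
#' present, and accessions must be unique.
#'
#' @param path File path.
#' @param design A [study_design()] naming the expected channel columns.
#' @param format `"auto"` (from the extension), `"tsv"`, `"csv"` or
#'   `"xlsx"`.
#' @param sheet Sheet name or index, for xlsx input.
#' @return A tibble with the metadata columns followed by one numeric column
#'   per channel.
#' @seealso [read_ratio_table()] for input that already carries
#'   experimental:control ratios.
#' @export
read_quant_table <- function(path, design = default_study_design(),
                             format = c("auto", "tsv", "csv", "xlsx"),
                             sheet = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  x <- read_table_any(path, format, sheet)
  missing_cols <- setdiff(c(required_meta_cols, design$channels), names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[c(required_meta_cols, design$channels)]
  check_unique_accessions(x)
  for (ch in design$channels) x[[ch]] <- as.numeric(x[[ch]])
  tibble::as_tibble(x)
}

#' Write a quantification table as TSV
#'
#' @param quant A quantification tibble as returned by [read_quant_table()]
#'   or [simulate_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  readr::write_tsv(quant, path)
  invisible(path)
}

#' Read a table of pre-computed experimental:control ratios
#'
#' Some deposited datasets carry replicate-level TMT ratios rather than raw
#' channel intensities (median normalization and the pair quotient already
#' applied upstream). This reads such a table straight into the long ratio
#' format used by the cutoff stage, bypassing [normalize_to_protein_median()]
#' and [compute_pair_ratios()].
#'
#' @param path File path.
#' @param design A [study_design()]; its replicate labels name the expected
#'   ratio columns unless remapped via `ratio_columns`.
#' @param ratio_columns Optional named character vector mapping replicate
#'   label -> column name in the file, for files with non-default headers.
#' @param accession_column Name of the accession column (default
#'   `"accession"`).
#' @inheritParams read_quant_table
#' @return A long tibble with columns `accession`, `replicate`, `stage`,
#'   `ratio`.
#' @export
read_ratio_table <- function(path, design = default_study_design(),
                             format = c("auto", "tsv", "csv", "xlsx"),
                             sheet = NULL, ratio_columns = NULL,
                             accession_column = "accession") {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  x <- read_table_any(path, format, sheet)
  if (is.null(ratio_columns)) {
    ratio_columns <- stats::setNames(design$pairs$replicate,
                                     design$pairs$replicate)
  }
  missing_cols <- setdiff(c(accession_column, unname(ratio_columns)),
                          names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(accession = as.character(x[[accession_column]]))
  check_unique_accessions(out)
  for (rep_label in names(ratio_columns)) {
    out[[rep_label]] <- as.numeric(x[[ratio_columns[[rep_label]]]])
  }
  out <- tidyr::pivot_longer(out, -"accession",
                             names_to = "replicate", values_to = "ratio")
  out$stage <- design$pairs$stage[match(out$replicate,
                                        design$pairs$replicate)]
  out[c("accession", "replicate", "stage", "ratio")]
}

#' Filter proteins on identification evidence
#'
#' Retains proteins identified by at least `min_peptides` distinct peptides
#' and at least `min_ratio_counts` ratio counts (both default to 2). Row
#' order is preserved; the filter only removes rows and is idempotent.
#'
#' @param quant A quantification tibble with `peptides` and `ratio_counts`
#'   columns.
#' @param min_peptides,min_ratio_counts Inclusive lower bounds (>= 0).
#' @return The filtered tibble.
#' @export
filter_evidence <- function(quant, min_peptides = 2, min_ratio_counts = 2) {
  stopifnot(min_peptides >= 0, min_ratio_counts >= 0,
            all(c("peptides", "ratio_counts") %in% names(quant)))
  dplyr::filter(quant, .data$peptides >= min_peptides,
                .data$ratio_counts >= min_ratio_counts)
}

#' Normalize each protein's channels to their median
#'
#' Divides every reporter intensity by the median across that protein's
#' channels (even channel count: mean of the two central values), so all
#' channels of a protein share the same denominator and channel quotients
#' are unchanged. Proteins with any non-positive intensity are flagged
#' (`flagged = TRUE`) and should be excluded from model fitting; a protein
#' whose channels are all zero has no usable signal and raises an error.
#'
#' @param quant A quantification tibble with one column per design channel.
#' @param design A [study_design()].
#' @return The tibble with channel columns replaced by normalized values and
#'   a logical `flagged` column appended.
#' @export
normalize_to_protein_median <- function(quant,
                                        design = default_study_design()) {
  stopifnot(all(design$channels %in% names(quant)))
  m <- as.matrix(quant[design$channels])
  all_zero <- rowSums(m != 0, na.rm = TRUE) == 0
  if (any(all_zero)) {
    stop("all channel intensities are zero for: ",
         paste(utils::head(quant$accession[all_zero], 10), collapse = ", "),
         call. = FALSE)
  }
  med <- apply(m, 1, stats::median)
  out <- quant
  out[design$channels] <- tibble::as_tibble(m / med)
  out$flagged <- apply(m, 1, function(v) any(!is.finite(v) | v <= 0))
  out
}

#' Compute experimental:control ratios for every replicate pair
#'
#' For each replicate pair of the design, divides the experimental channel
#' value by the control channel value, protein by protein. Because every
#' channel of a protein shares the median denominator, the result is
#' identical whether computed on raw or median-normalized intensities.
#' A non-positive or missing control value makes the ratio undefined: the
#' protein/pair is kept with `ratio = NA` rather than silently dropped.
#'
#' @param quant A quantification tibble (raw or normalized) with one column
#'   per design channel.
#' @param design A [study_design()].
#' @return A long tibble with columns `accession`, `replicate`, `stage`,
#'   `ratio` (NA where undefined).
#' @export
compute_pair_ratios <- function(quant, design = default_study_design()) {
  stopifnot(all(design$channels %in% names(quant)))
  pairs <- design$pairs
  purrr::pmap_dfr(
    pairs[c("replicate", "experimental", "control", "stage")],
    function(replicate, experimental, control, stage) {
      num <- quant[[experimental]]
      den <- quant[[control]]
      ratio <- ifelse(is.finite(den) & den > 0 & is.finite(num),
                      num / den, NA_real_)
      tibble::tibble(accession = quant$accession, replicate = replicate,
                     stage = stage, ratio = ratio)
    }
  )
}
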