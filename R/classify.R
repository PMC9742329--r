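pm_term <- "plasma membrane"
fp_terms <- c("nucleus", "mitochondri", "cytoplasm")

#' Classify proteins as TP / FP / unclassified from localization terms
#'
#' Implements the annotation-anchored proxy truth of ratiometric surfaceome
#' analysis: a protein annotated to the plasma membrane is a true positive
#' (TP) regardless of other terms; a protein with nuclear, mitochondrial or
#' cytoplasmic annotation but no plasma-membrane annotation is a false
#' positive (FP); everything else — including proteins absent from the
#' annotation table — is unclassified. Matching is case-insensitive
#' substring matching on the canonical phrases ("plasma membrane",
#' "nucleus", "mitochondri...", "cytoplasm"), which tolerates the free-text
#' variation of subcellular-location annotation lines; unknown terms are
#' carried but ignored.
#'
#' @param annotations A data frame with columns `accession` and `terms`
#'   (semicolon-delimited compartment terms; may be empty).
#' @param accessions Character vector of accessions to classify. Defaults to
#'   every accession in `annotations`.
#' @return A tibble with columns `accession` and `class`
#'   (`"TP"`, `"FP"` or `"unclassified"`), one row per requested accession.
#' @examples
#' ann <- tibble::tibble(
#'   accession = c("P1", "P2", "P3"),
#'   terms = c("Plasma membrane; Cytoplasm", "Nucleus", "Secreted")
#' )
#' classify_localization(ann)
#' @export
classify_localization <- function(annotations,
                                  accessions = annotations$accession) {
  stopifnot(is.data.frame(annotations),
            all(c("accession", "terms") %in% names(annotations)))
  terms <- tolower(as.character(
    annotations$terms[match(accessions, annotations$accession)]
  ))
  terms[is.na(terms)] <- ""
  is_tp <- grepl(pm_term, terms, fixed = TRUE)
  is_fp <- !is_tp & Reduce(`|`, lapply(fp_terms, grepl, x = terms,
                                       fixed = TRUE))
  tibble::tibble(
    accession = accessions,
    class = dplyr::case_when(is_tp ~ "TP", is_fp ~ "FP",
                             TRUE ~ "unclassified")
  )
}

#' Tally TP / FP / unclassified labels
#'
#' @param labels A tibble from [classify_localization()], or a character
#'   vector of class labels.
#' @return A one-row tibble with columns `n_tp`, `n_fp`, `n_unclassified`.
#' @export
class_counts <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$class
  tibble::tibble(
    n_tp = sum(labels == "TP"),
    n_fp = sum(labels == "FP"),
    n_unclassified = sum(labels == "unclassified")
  )
}

#' Read a localization annotation table
#'
#' Expects a TSV with an accession column and a semicolon-delimited terms
#' column. `read_uniprot_annotations()` is a convenience for tab-separated
#' UniProt exports: it takes the `Entry` column as the accession and the
#' `Subcellular location [CC]` column (or the first column whose name
#' contains "subcellular") as the terms string, which the substring matcher
#' of [classify_localization()] can consume as-is.
#'
#' @param path File path.
#' @return A tibble with columns `accession` and `terms`.
#' @export
read_annotation_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("accession", "terms") %in% names(x))) {
    stop("annotation table needs columns `accession` and `terms`",
         call. = FALSE)
  }
  x$terms[is.na(x$terms)] <- ""
  check_unique_accessions(x)
  tibble::as_tibble(x[c("accession", "terms")])
}

#' @rdname read_annotation_table
#' @export
read_uniprot_annotations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  acc_col <- if ("Entry" %in% names(x)) "Entry" else names(x)[1]
  loc_col <- grep("subcellular", names(x), ignore.case = TRUE, value = TRUE)
  if (length(loc_col) == 0) {
    stop("no subcellular-location column found in ", path, call. = FALSE)
  }
  terms <- as.character(x[[loc_col[1]]])
  terms[is.na(terms)] <- ""
  terms <- sub("^SUBCELLULAR LOCATION:\\s*", "", terms)
  out <- tibble::tibble(accession = as.character(x[[acc_col]]),
                        terms = terms)
  check_unique_accessions(out)
  out
}
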