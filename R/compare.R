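proteome_accessions <- function(x) {
  if (is.data.frame(x)) x$accession else as.character(x)
}

#' Compare two stage proteomes at the set level
#'
#' Exact set arithmetic on accessions: the shared set, each stage's
#' exclusive set, the union, and the stage-specific count (union minus
#' shared).
#'
#' @param dev,mature Stage proteome tibbles (with an `accession` column) or
#'   plain accession vectors.
#' @return An object of class `proteome_comparison`: a list with `shared`,
#'   `exclusive_dev`, `exclusive_mature` (character vectors) and a `summary`
#'   one-row tibble (`n_dev`, `n_mature`, `n_shared`, `n_stage_specific`,
#'   `n_union`).
#' @examples
#' compare_proteomes(c("A", "B", "C"), c("B", "C", "D"))$summary
#' @export
compare_proteomes <- function(dev, mature) {
  dev <- unique(proteome_accessions(dev))
  mature <- unique(proteome_accessions(mature))
  shared <- intersect(dev, mature)
  excl_dev <- setdiff(dev, mature)
  excl_mat <- setdiff(mature, dev)
  summary <- tibble::tibble(
    n_dev = length(dev), n_mature = length(mature),
    n_shared = length(shared),
    n_stage_specific = length(excl_dev) + length(excl_mat),
    n_union = length(union(dev, mature))
  )
  structure(
    list(shared = shared, exclusive_dev = excl_dev,
         exclusive_mature = excl_mat, summary = summary),
    class = "proteome_comparison"
  )
}

#' @export
print.proteome_comparison <- function(x, ...) {
  cat("<proteome_comparison>\n")
  print(x$summary, ...)
  invisible(x)
}

#' Overlap of the top-N most enriched proteins of two proteomes
#'
#' Takes the first `n` accessions of each proteome — each must already be
#' ordered by its defining enrichment ratio, descending, as
#' [intersect_replicates()] and [extract_surfaceome()] produce — and counts
#' the accessions common to both. If `n` exceeds a proteome's size the full
#' list is used, with a warning.
#'
#' @inheritParams compare_proteomes
#' @param n Number of top proteins to compare (default 100).
#' @return Integer overlap count.
#' @export
top_n_overlap <- function(dev, mature, n = 100) {
  dev <- proteome_accessions(dev)
  mature <- proteome_accessions(mature)
  if (n > length(dev) || n > length(mature)) {
    warning("n = ", n, " exceeds a proteome size (",
            length(dev), ", ", length(mature), "); using full list(s)")
  }
  length(intersect(utils::head(dev, n), utils::head(mature, n)))
}

#' Correlation between two replicates' enrichment ratios
#'
#' Pearson correlation of per-protein ratios for two replicate pairs, over
#' all proteins with both ratios defined. By default the correlation is
#' computed on log2 ratios, which treats k-fold enrichment and depletion
#' symmetrically; `log2 = FALSE` uses raw ratios.
#'
#' @param ratios Long ratio tibble.
#' @param pair_a,pair_b Replicate labels.
#' @param log2 Correlate log2 ratios (default) or raw ratios.
#' @return The correlation coefficient (length-1 numeric).
#' @export
replicate_correlation <- function(ratios, pair_a, pair_b, log2 = TRUE) {
  a <- dplyr::filter(ratios, .data$replicate == pair_a)
  b <- dplyr::filter(ratios, .data$replicate == pair_b)
  merged <- dplyr::inner_join(a[c("accession", "ratio")],
                              b[c("accession", "ratio")],
                              by = "accession", suffix = c("_a", "_b"))
  merged <- merged[is.finite(merged$ratio_a) & merged$ratio_a > 0 &
                     is.finite(merged$ratio_b) & merged$ratio_b > 0, ]
  if (nrow(merged) < 3) {
    stop("fewer than 3 proteins with both ratios defined", call. = FALSE)
  }
  if (log2) {
    stats::cor(base::log2(merged$ratio_a), base::log2(merged$ratio_b))
  } else {
    stats::cor(merged$ratio_a, merged$ratio_b)
  }
}

#' Tally proteins per user-supplied functional category
#'
#' Functional categories (synaptic transmission, axon guidance,
#' extracellular matrix, ...) are curated knowledge; this only joins a
#' user-supplied accession-to-category table onto a proteome and counts.
#' Proteins absent from the table are tallied as `"uncategorized"`.
#'
#' @inheritParams compare_proteomes
#' @param proteome A stage proteome tibble or accession vector.
#' @param categories Data frame with columns `accession` and `category`.
#' @return A tibble (`category`, `n`), descending by `n`.
#' @export
category_counts <- function(proteome, categories) {
  stopifnot(all(c("accession", "category") %in% names(categories)))
  acc <- proteome_accessions(proteome)
  cat_of <- categories$category[match(acc, categories$accession)]
  cat_of[is.na(cat_of)] <- "uncategorized"
  dplyr::arrange(dplyr::count(tibble::tibble(category = cat_of),
                              .data$category, name = "n"),
                 dplyr::desc(.data$n))
}
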