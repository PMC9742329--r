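# Small in-code fixtures shared across test files.

toy_design <- function() default_study_design()

# A hand-sized quantification table over the default 8-plex.
toy_quant <- function() {
  d <- toy_design()
  q <- tibble::tibble(
    accession = c("P1", "P2", "P3"),
    gene = c("GnA", "GnB", "GnC"),
    peptides = c(5L, 2L, 9L),
    ratio_counts = c(6L, 2L, 9L)
  )
  set.seed(42)
  for (ch in d$channels) q[[ch]] <- stats::runif(3, 10, 100)
  q
}

# Long ratio tibble from named per-replicate ratio vectors.
ratios_from_named <- function(..., stage = NA_character_) {
  vals <- list(...)
  purrr::imap_dfr(vals, function(v, rep_label) {
    tibble::tibble(accession = names(v), replicate = rep_label,
                   stage = stage, ratio = unname(v))
  })
}

labels_tbl <- function(accessions, classes) {
  tibble::tibble(accession = accessions, class = classes)
}

# Independent brute-force cutoff oracle: scans every candidate threshold
# and recomputes TPR - FPR by direct counting, without any cumulative-sum
# machinery. Ties at the maximum resolve toward the largest threshold.
brute_force_cutoff <- function(ratio, class) {
  n_tp <- sum(class == "TP")
  n_fp <- sum(class == "FP")
  thresholds <- sort(unique(ratio), decreasing = TRUE)
  j <- vapply(thresholds, function(t) {
    sum(ratio >= t & class == "TP") / n_tp -
      sum(ratio >= t & class == "FP") / n_fp
  }, numeric(1))
  best <- max(j)
  list(threshold = max(thresholds[j == best]), j = best)
}
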