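#' Rank proteins by a replicate's experimental:control ratio
#'
#' Orders proteins by descending TMT ratio for one replicate pair. Ties are
#' broken by ascending accession so the ordering is deterministic, but tied
#' ratios are treated as a single threshold block by [compute_roc()], so ROC
#' results never depend on tie order.
#'
#' @param ratios Long ratio tibble (`accession`, `replicate`, `stage`,
#'   `ratio`) from [compute_pair_ratios()] or [read_ratio_table()].
#' @param replicate Replicate label to rank.
#' @return A tibble (`accession`, `ratio`) in descending ratio order.
#' @export
rank_by_ratio <- function(ratios, replicate) {
  x <- dplyr::filter(ratios, .data$replicate == !!replicate)
  if (nrow(x) == 0) {
    stop("no ratios found for replicate ", replicate, call. = FALSE)
  }
  bad <- x$accession[!is.finite(x$ratio)]
  if (length(bad) > 0) {
    stop("undefined ratio for replicate ", replicate, ": ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  dplyr::arrange(x[c("accession", "ratio")],
                 dplyr::desc(.data$ratio), .data$accession)
}

#' Build the ROC curve over TP/FP labels along a ratio ranking
#'
#' Walks the ranked list from the highest ratio down, accumulating
#' true-positive and false-positive counts among annotation-labeled proteins
#' only; unclassified proteins occupy rank positions but contribute to
#' neither count, so inserting or removing them leaves every (TPR, FPR)
#' point unchanged. One curve point is emitted per distinct ratio value
#' (candidate threshold), carrying the counts accumulated at and above it.
#'
#' @param ranked Output of [rank_by_ratio()].
#' @param labels Classification tibble from [classify_localization()]
#'   (`accession`, `class`). Accessions missing from `labels` count as
#'   unclassified.
#' @return A tibble of class `roc_curve` with columns `threshold` (distinct
#'   ratios, descending), `cum_tp`, `cum_fp`, `tpr`, `fpr` and `j`
#'   (= TPR - FPR), plus attributes `n_tp` and `n_fp`.
#' @export
compute_roc <- function(ranked, labels) {
  cls <- labels$class[match(ranked$accession, labels$accession)]
  cls[is.na(cls)] <- "unclassified"
  n_tp <- sum(cls == "TP")
  n_fp <- sum(cls == "FP")
  if (n_tp < 1 || n_fp < 1) {
    stop("ROC undefined: need at least one TP and one FP among ranked ",
         "proteins (have ", n_tp, " TP, ", n_fp, " FP)", call. = FALSE)
  }
  cum_tp <- cumsum(cls == "TP")
  cum_fp <- cumsum(cls == "FP")
  # last index of each block of tied ratios = counts at-or-above that ratio
  block_end <- which(ranked$ratio != dplyr::lead(ranked$ratio,
                                                 default = -Inf))
  block_tp <- cum_tp[block_end]
  block_fp <- cum_fp[block_end]
  curve <- tibble::tibble(
    threshold = ranked$ratio[block_end],
    cum_tp = block_tp,
    cum_fp = block_fp,
    tpr = block_tp / n_tp,
    fpr = block_fp / n_fp
  )
  curve$j <- curve$tpr - curve$fpr
  attr(curve, "n_tp") <- n_tp
  attr(curve, "n_fp") <- n_fp
  class(curve) <- c("roc_curve", class(curve))
  curve
}

#' Select the ratio cutoff maximizing TPR - FPR
#'
#' Picks the threshold at the maximum of J = TPR - FPR along the ROC curve
#' (the Youden-style operating point). When several thresholds tie at the
#' maximum, the largest (most stringent) threshold is chosen. The retention
#' rule associated with the cutoff is `ratio >= threshold` by default; see
#' [apply_cutoff()].
#'
#' @param curve A `roc_curve` from [compute_roc()].
#' @return A one-row tibble: `threshold`, `tpr`, `fpr`, `j`.
#' @export
select_cutoff <- function(curve) {
  stopifnot(nrow(curve) > 0)
  best <- which.max(curve$j)  # thresholds descend, so first max = largest
  tibble::as_tibble(curve[best, c("threshold", "tpr", "fpr", "j")])
}

#' Apply a ratio cutoff to one replicate
#'
#' Retains every protein — TP, FP and unclassified alike — whose ratio
#' passes the threshold, in descending ratio order. The final proteomes must
#' keep unclassified proteins: most surface proteins of interest are outside
#' the TP/FP decision vocabulary.
#'
#' @param ratios Long ratio tibble.
#' @param replicate Replicate label.
#' @param threshold Numeric threshold, or a one-row tibble with a
#'   `threshold` column (as returned by [select_cutoff()]).
#' @param strict If `FALSE` (default) retention is inclusive
#'   (`ratio >= threshold`); if `TRUE`, strict (`ratio > threshold`).
#' @return A tibble (`accession`, `ratio`), descending.
#' @export
apply_cutoff <- function(ratios, replicate, threshold, strict = FALSE) {
  if (is.data.frame(threshold)) threshold <- threshold$threshold[1]
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  ranked <- rank_by_ratio(ratios, replicate)
  keep <- if (strict) ranked$ratio > threshold else ranked$ratio >= threshold
  ranked[keep, ]
}

#' Intersect the post-cutoff lists of two biological replicates
#'
#' The stage proteome is the set of proteins surviving the cutoff in both
#' biological replicates, ordered by the mean of the two replicate ratios
#' (descending).
#'
#' @param list_a,list_b Post-cutoff tibbles (`accession`, `ratio`) from
#'   [apply_cutoff()].
#' @param stage Stage label attached to the result.
#' @return A tibble (`stage`, `accession`, `ratio_a`, `ratio_b`,
#'   `mean_ratio`), descending by `mean_ratio`.
#' @export
intersect_replicates <- function(list_a, list_b, stage = NA_character_) {
  merged <- dplyr::inner_join(
    dplyr::rename(list_a, ratio_a = "ratio"),
    dplyr::rename(list_b, ratio_b = "ratio"),
    by = "accession"
  )
  merged$mean_ratio <- (merged$ratio_a + merged$ratio_b) / 2
  merged$stage <- stage
  dplyr::arrange(
    merged[c("stage", "accession", "ratio_a", "ratio_b", "mean_ratio")],
    dplyr::desc(.data$mean_ratio), .data$accession
  )
}

#' Stringent extraction: pass the cutoff in all four replicate ratios
#'
#' The stringent variant retains a protein only if its ratio is strictly
#' greater than the replicate's threshold in every one of the four
#' replicate pairings. Proteins lacking a defined ratio for any pair are
#' excluded (and reported via a message). The result is always a subset of
#' each per-replicate default proteome.
#'
#' @param ratios Long ratio tibble covering all four replicates.
#' @param thresholds Tibble with columns `replicate` and `threshold`, one
#'   row per replicate pair (e.g. the bound rows of [select_cutoff()]
#'   results).
#' @param design A [study_design()] giving each replicate's stage.
#' @return A tibble (`stage`, `accession`, `mean_ratio`) of per-stage
#'   stringent proteomes, `mean_ratio` being the mean over that stage's two
#'   replicate ratios, descending within stage.
#' @export
stringent_proteomes <- function(ratios, thresholds,
                                design = default_study_design()) {
  stopifnot(all(c("replicate", "threshold") %in% names(thresholds)))
  reps <- design$pairs$replicate
  if (!setequal(thresholds$replicate, reps)) {
    stop("`thresholds` must cover exactly the design's replicates",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(ratios, .data$replicate %in% reps)[
      c("accession", "replicate", "ratio")],
    names_from = "replicate", values_from = "ratio"
  )
  complete <- stats::complete.cases(wide[reps]) &
    apply(is.finite(as.matrix(wide[reps])), 1, all)
  if (any(!complete)) {
    message(sum(!complete), " protein(s) excluded from stringent cutoff: ",
            "missing ratio in at least one pairing")
    wide <- wide[complete, ]
  }
  thr <- thresholds$threshold[match(reps, thresholds$replicate)]
  pass <- rep(TRUE, nrow(wide))
  for (i in seq_along(reps)) pass <- pass & wide[[reps[i]]] > thr[i]
  kept <- wide[pass, ]
  purrr::map_dfr(unique(design$pairs$stage), function(st) {
    st_reps <- design$pairs$replicate[design$pairs$stage == st]
    tibble::tibble(
      stage = st,
      accession = kept$accession,
      mean_ratio = rowMeans(as.matrix(kept[st_reps]))
    ) |>
      dplyr::arrange(dplyr::desc(.data$mean_ratio), .data$accession)
  })
}

#' Run the full ratiometric extraction across all replicates
#'
#' For every replicate pair of the design: rank proteins by ratio, build the
#' ROC over TP/FP labels, select the cutoff at the maximum of TPR - FPR
#' (or use an injected fixed threshold) and apply it; then intersect the two
#' replicates of each stage into the stage proteome. Fixed thresholds exist
#' so that published cutoff values can be replayed on a deposited ratio
#' table without reconstructing the annotation snapshot that produced them.
#'
#' @param ratios Long ratio tibble.
#' @param labels Classification tibble from [classify_localization()];
#'   may be `NULL` when `thresholds` are injected.
#' @param design A [study_design()].
#' @param thresholds Optional tibble (`replicate`, `threshold`) of fixed
#'   cutoffs; when supplied, no ROC is computed.
#' @param strict Retention rule passed to [apply_cutoff()].
#' @return An object of class `surfaceome_extraction`: a list with
#'   `curves` (named list of `roc_curve`s, or `NULL`), `cutoffs` (tibble:
#'   replicate, stage, threshold, tpr, fpr, j, n_retained), `replicate_lists`
#'   (named list of post-cutoff tibbles) and `proteomes` (named list of
#'   per-stage [intersect_replicates()] tibbles).
#' @export
extract_surfaceome <- function(ratios, labels = NULL,
                               design = default_study_design(),
                               thresholds = NULL, strict = FALSE) {
  reps <- design$pairs$replicate
  curves <- NULL
  if (is.null(thresholds)) {
    if (is.null(labels)) {
      stop("supply `labels` to compute cutoffs, or inject `thresholds`",
           call. = FALSE)
    }
    curves <- lapply(stats::setNames(reps, reps), function(r) {
      compute_roc(rank_by_ratio(ratios, r), labels)
    })
    cutoffs <- purrr::map_dfr(reps, function(r) {
      dplyr::mutate(select_cutoff(curves[[r]]), replicate = r,
                    .before = 1)
    })
  } else {
    stopifnot(all(c("replicate", "threshold") %in% names(thresholds)))
    missing_reps <- setdiff(reps, thresholds$replicate)
    if (length(missing_reps) > 0) {
      stop("no threshold for replicate(s): ",
           paste(missing_reps, collapse = ", "), call. = FALSE)
    }
    cutoffs <- tibble::tibble(
      replicate = reps,
      threshold = thresholds$threshold[match(reps, thresholds$replicate)],
      tpr = NA_real_, fpr = NA_real_, j = NA_real_
    )
  }
  cutoffs$stage <- design$pairs$stage[match(cutoffs$replicate, reps)]
  replicate_lists <- lapply(stats::setNames(reps, reps), function(r) {
    apply_cutoff(ratios, r, cutoffs$threshold[cutoffs$replicate == r],
                 strict = strict)
  })
  cutoffs$n_retained <- vapply(replicate_lists[cutoffs$replicate],
                               nrow, integer(1))
  stages <- unique(design$pairs$stage)
  proteomes <- lapply(stats::setNames(stages, stages), function(st) {
    st_reps <- design$pairs$replicate[design$pairs$stage == st]
    if (length(st_reps) != 2) {
      stop("stage ", st, " must have exactly two replicate pairs",
           call. = FALSE)
    }
    intersect_replicates(replicate_lists[[st_reps[1]]],
                         replicate_lists[[st_reps[2]]], stage = st)
  })
  structure(
    list(curves = curves, cutoffs = cutoffs,
         replicate_lists = replicate_lists, proteomes = proteomes,
         strict = strict, design = design),
    class = "surfaceome_extraction"
  )
}

#' @export
print.surfaceome_extraction <- function(x, ...) {
  cat("<surfaceome_extraction>\n")
  print(x$cutoffs, ...)
  sizes <- vapply(x$proteomes, nrow, integer(1))
  cat("stage proteomes:",
      paste(names(sizes), sizes, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
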