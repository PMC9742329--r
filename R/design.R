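#' Construct a TMT study design
#'
#' A study design maps reporter-ion channels to experimental roles and lists
#' the replicate pairings used for ratiometric analysis. Each replicate pairs
#' one labeled (experimental) channel with one negative-control channel from
#' the same developmental stage, so the experimental:control ratio isolates
#' proximity-labeling signal from background binding.
#'
#' @param channels Character vector of channel labels, in plex order.
#' @param channel_meta A data frame with columns `channel`, `stage` and
#'   `condition` (`"labeled"` or `"control"`), one row per channel.
#' @param pairs A data frame with columns `replicate`, `experimental` and
#'   `control`, one row per replicate pairing. The stage of each pair is
#'   derived from `channel_meta` and both channels must share it.
#'
#' @return An object of class `study_design`: a list with elements
#'   `channels`, `channel_meta` (tibble) and `pairs` (tibble with a derived
#'   `stage` column).
#' @seealso [default_study_design()] for the packaged 8-plex design.
#' @export
study_design <- function(channels, channel_meta, pairs) {
  channel_meta <- tibble::as_tibble(channel_meta)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(
    all(c("channel", "stage", "condition") %in% names(channel_meta)),
    all(c("replicate", "experimental", "control") %in% names(pairs))
  )
  if (anyDuplicated(channels)) {
    stop("duplicated channel labels in `channels`", call. = FALSE)
  }
  if (!setequal(channel_meta$channel, channels)) {
    stop("`channel_meta` must describe exactly the channels in `channels`",
         call. = FALSE)
  }
  if (!all(channel_meta$condition %in% c("labeled", "control"))) {
    stop("`condition` must be 'labeled' or 'control'", call. = FALSE)
  }
  meta_of <- function(ch, what) {
    channel_meta[[what]][match(ch, channel_meta$channel)]
  }
  missing_ch <- setdiff(c(pairs$experimental, pairs$control), channels)
  if (length(missing_ch) > 0) {
    stop("pair channels not in design: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  if (!all(meta_of(pairs$experimental, "condition") == "labeled")) {
    stop("every pair's experimental channel must have condition 'labeled'",
         call. = FALSE)
  }
  if (!all(meta_of(pairs$control, "condition") == "control")) {
    stop("every pair's control channel must have condition 'control'",
         call. = FALSE)
  }
  stage_exp <- meta_of(pairs$experimental, "stage")
  stage_ctl <- meta_of(pairs$control, "stage")
  if (!all(stage_exp == stage_ctl)) {
    bad <- pairs$replicate[stage_exp != stage_ctl]
    stop("pair(s) mix stages: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pairs$stage <- stage_exp
  structure(
    list(channels = channels, channel_meta = channel_meta, pairs = pairs),
    class = "study_design"
  )
}

#' The packaged 8-plex two-stage study design
#'
#' Eight TMT channels cover two developmental stages (developing, mature),
#' each with two labeled biological replicates and two negative controls.
#' The primary pairing is 129C/127C and 128C/127N (developing), 130N/128N and
#' 129N/126 (mature); the alternative pairing swaps control assignments
#' within each stage (129C/127N, 128C/127C, 130N/126, 129N/128N), which is
#' useful as a robustness check on the extraction.
#'
#' @param pairing `"primary"` or `"alternative"` replicate pairing regime.
#' @return A [study_design()] object.
#' @examples
#' default_study_design()$pairs
#' @export
default_study_design <- function(pairing = c("primary", "alternative")) {
  pairing <- match.arg(pairing)
  channels <- c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N")
  channel_meta <- tibble::tibble(
    channel   = channels,
    stage     = c("mature", "developing", "developing", "mature",
                  "developing", "mature", "developing", "mature"),
    condition = c("control", "control", "control", "control",
                  "labeled", "labeled", "labeled", "labeled")
  )
  pairs <- if (pairing == "primary") {
    tibble::tibble(
      replicate    = c("129C/127C", "128C/127N", "130N/128N", "129N/126"),
      experimental = c("129C", "128C", "130N", "129N"),
      control      = c("127C", "127N", "128N", "126")
    )
  } else {
    tibble::tibble(
      replicate    = c("129C/127N", "128C/127C", "130N/126", "129N/128N"),
      experimental = c("129C", "128C", "130N", "129N"),
      control      = c("127N", "127C", "126", "128N")
    )
  }
  study_design(channels, channel_meta, pairs)
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", length(x$channels), " channels, ",
      nrow(x$pairs), " replicate pairs\n", sep = "")
  print(x$pairs, ...)
  invisible(x)
}

#' Read or write a study design as JSON
#'
#' @param path File path.
#' @param design A [study_design()] object.
#' @return `read_study_design()` returns a `study_design`;
#'   `write_study_design()` returns `path` invisibly.
#' @export
read_study_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_design(x$channels, x$channel_meta, x$pairs)
}

#' @rdname read_study_design
#' @export
write_study_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  jsonlite::write_json(
    list(
      channels = design$channels,
      channel_meta = design$channel_meta,
      pairs = design$pairs[c("replicate", "experimental", "control")]
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
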