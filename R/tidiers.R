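#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a surfaceome extraction into one proteome tibble
#'
#' @param x A `surfaceome_extraction` from [extract_surfaceome()].
#' @param ... Unused.
#' @return All stage proteomes stacked into one tibble.
#' @method tidy surfaceome_extraction
#' @export
tidy.surfaceome_extraction <- function(x, ...) {
  dplyr::bind_rows(x$proteomes)
}

#' One-row summary of a surfaceome extraction
#'
#' @inheritParams tidy.surfaceome_extraction
#' @return A one-row tibble: one `n_<stage>` column per stage proteome,
#'   `n_union`, `n_shared` (when exactly two stages), and `strict`.
#' @method glance surfaceome_extraction
#' @export
glance.surfaceome_extraction <- function(x, ...) {
  sizes <- vapply(x$proteomes, nrow, integer(1))
  out <- tibble::as_tibble(as.list(stats::setNames(
    sizes, paste0("n_", names(sizes))
  )))
  if (length(x$proteomes) == 2) {
    cmp <- compare_proteomes(x$proteomes[[1]], x$proteomes[[2]])
    out$n_shared <- cmp$summary$n_shared
    out$n_union <- cmp$summary$n_union
  }
  out$strict <- x$strict
  out
}

#' Per-protein results of a moderated interaction fit
#'
#' @param x A `moderated_fit` from [fit_interaction_model()].
#' @param ... Unused.
#' @return The per-protein results tibble (coefficients, variances,
#'   ordinary and moderated t, p, q).
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) {
  x$results
}

#' One-row summary of a moderated interaction fit
#'
#' @inheritParams tidy.moderated_fit
#' @param fdr Significance threshold on `q` for the discovery count.
#' @return A one-row tibble: prior `d0` and `s0_2`, protein counts, and the
#'   number of q-significant interaction effects.
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, fdr = 0.05, ...) {
  tibble::tibble(
    d0 = x$prior$d0,
    s0_2 = x$prior$s0_2,
    n_proteins = nrow(x$results),
    n_excluded = nrow(x$excluded),
    n_significant = sum(x$results$q < fdr, na.rm = TRUE)
  )
}

#' Long membership table of a proteome comparison
#'
#' @param x A `proteome_comparison` from [compare_proteomes()].
#' @param ... Unused.
#' @return A tibble (`accession`, `set`) with `set` one of `"shared"`,
#'   `"developing_only"`, `"mature_only"`.
#' @method tidy proteome_comparison
#' @export
tidy.proteome_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(accession = x$shared, set = "shared"),
    tibble::tibble(accession = x$exclusive_dev, set = "developing_only"),
    tibble::tibble(accession = x$exclusive_mature, set = "mature_only")
  )
}

#' @rdname tidy.proteome_comparison
#' @method glance proteome_comparison
#' @export
glance.proteome_comparison <- function(x, ...) {
  x$summary
}
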