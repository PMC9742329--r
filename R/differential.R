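#' Build the stage-by-treatment interaction design matrix
#'
#' One observation row per channel, in design channel order, with columns
#' intercept, `MATURE` (1 for mature-stage channels), `TRT` (1 for labeled
#' channels) and their product. Under the default 8-plex there are two
#' channels per (stage, condition) cell and the residual degrees of freedom
#' per protein are 4. The interaction coefficient `b3` is the log2 mature
#' labeled:control enrichment minus the log2 developing labeled:control
#' enrichment — the developing-versus-mature contrast normalized by the
#' in-plex negative controls.
#'
#' @param design A [study_design()] with two stages and two conditions.
#' @return A numeric matrix with `length(design$channels)` rows and columns
#'   `(Intercept)`, `MATURE`, `TRT`, `MATURE:TRT`; channel labels as
#'   rownames.
#' @export
build_design_matrix <- function(design = default_study_design()) {
  meta <- design$channel_meta[match(design$channels,
                                    design$channel_meta$channel), ]
  stages <- unique(meta$stage)
  if (length(stages) != 2) {
    stop("design must have exactly two stages, got: ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  # "mature" is the reference-coded 1 level when present; otherwise the
  # second stage in channel order.
  mature_level <- if ("mature" %in% stages) "mature" else stages[2]
  mat <- as.numeric(meta$stage == mature_level)
  trt <- as.numeric(meta$condition == "labeled")
  cells <- table(mat, trt)
  if (length(cells) != 4 || any(cells == 0)) {
    stop("every (stage, condition) cell needs at least one channel",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, MATURE = mat, TRT = trt,
             `MATURE:TRT` = mat * trt)
  rownames(X) <- meta$channel
  X
}

#' Ordinary least-squares fit for a single protein
#'
#' Fits the interaction model to one protein's log2 responses by solving the
#' normal equations. Mostly useful for inspection; [fit_interaction_model()]
#' fits all proteins at once with the same algebra.
#'
#' @param y Numeric response vector (log2 median-normalized channel values),
#'   one element per design-matrix row.
#' @param X Design matrix from [build_design_matrix()].
#' @return A list with `coefficients` (named), `s2` (residual variance),
#'   `df` (residual degrees of freedom) and `cov_unscaled` (the unscaled
#'   coefficient covariance \eqn{(X'X)^{-1}}).
#' @export
fit_protein_ols <- function(y, X) {
  stopifnot(length(y) == nrow(X), all(is.finite(y)))
  xtx_inv <- solve(crossprod(X))
  coef <- drop(xtx_inv %*% crossprod(X, y))
  names(coef) <- colnames(X)
  resid <- y - drop(X %*% coef)
  df <- nrow(X) - ncol(X)
  list(coefficients = coef, s2 = sum(resid^2) / df, df = df,
       cov_unscaled = xtx_inv)
}

trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior across proteins
#'
#' Models per-protein residual variances as draws from a scaled inverse
#' chi-square (equivalently scaled-F) prior with `d0` degrees of freedom and
#' location `s0_2`, and estimates both hyperparameters by moment-matching
#' the log variances: with `z = log(s2)`, `E[z] = log(s0_2) +
#' digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)` and `Var[z] =
#' trigamma(df/2) + trigamma(d0/2)`. If the observed spread of `z` does not
#' exceed what the residual degrees of freedom alone imply, the prior is
#' taken as infinitely informative (`d0 = Inf`) with `s0_2` at the central
#' value. Zero variances (perfect fits) carry no information about the
#' spread and are excluded from the matching.
#'
#' @param s2 Numeric vector of residual variances.
#' @param df Residual degrees of freedom (scalar, or vector of a single
#'   unique value).
#' @return A list of class `variance_prior`: `d0`, `s0_2`, `n_used`.
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- unique(df)
  stopifnot(length(df) == 1, df > 0)
  use <- is.finite(s2) & s2 > 0
  if (sum(use) < 2) {
    stop("degenerate prior: need at least two positive residual variances",
         call. = FALSE)
  }
  z <- log(s2[use])
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e) - trigamma(df / 2)
  if (is.finite(e_var) && e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_2 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond chi-square sampling noise: the variances
    # are consistent with a single common value
    d0 <- Inf
    s0_2 <- mean(s2[use])
  }
  structure(list(d0 = d0, s0_2 = s0_2, n_used = sum(use)),
            class = "variance_prior")
}

#' Moderated t-statistics for the interaction coefficient
#'
#' Shrinks each protein's residual variance toward the prior,
#' `s2_post = (d0 * s0_2 + df * s2) / (d0 + df)`, and tests `b3 = 0` with
#' `t = b3 / sqrt(s2_post * v3)` on `d0 + df` degrees of freedom (`v3` is
#' the design-based unscaled variance factor of `b3`). With `d0 = Inf` every
#' protein uses `s0_2` and the reference distribution is standard normal;
#' with `d0 = 0` the ordinary t is recovered. The moderated t stays finite
#' for proteins whose residual variance happens to be exactly zero.
#'
#' @param b3 Interaction coefficient estimates.
#' @param s2 Residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @param v3 Unscaled variance factor of `b3` (diagonal element of
#'   \eqn{(X'X)^{-1}}).
#' @param prior A [estimate_variance_prior()] result (or list with `d0`,
#'   `s0_2`).
#' @return A tibble: `s2_post`, `t_moderated`, `df_total`, `p`.
#' @export
moderate_statistics <- function(b3, s2, df, v3, prior) {
  d0 <- prior$d0
  s0_2 <- prior$s0_2
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- rep(d0 + df, length(s2))
  }
  t_mod <- b3 / sqrt(s2_post * v3)
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t_mod)),
              2 * stats::pt(-abs(t_mod), df_total))
  tibble::tibble(s2_post = s2_post, t_moderated = t_mod,
                 df_total = df_total, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1
#' and mapped back to input order.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) {
    stop("p-values outside [0, 1] at position(s): ",
         paste(utils::head(which(!ok), 10), collapse = ", "), call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Fit the per-protein interaction model with moderated inference
#'
#' The full differential-enrichment stage: takes median-normalized channel
#' values, fits `log2(value) ~ MATURE * TRT` to every protein by ordinary
#' least squares, shrinks residual variances with the empirical-Bayes prior
#' estimated across proteins, computes moderated t-statistics for the
#' interaction coefficient `b3` (mature-versus-developing enrichment change,
#' control-normalized), and adjusts p-values with Benjamini-Hochberg FDR.
#' Proteins flagged for non-positive intensities are excluded from fitting
#' and reported in the result.
#'
#' @param normalized A normalized quantification tibble from
#'   [normalize_to_protein_median()] (channel columns + optional `flagged`).
#' @param design A [study_design()].
#' @return An object of class `moderated_fit`: a list with `results`
#'   (tibble: accession, gene if present, b0..b3, s2, df, t_ordinary,
#'   t_moderated, df_total, p, q), `prior` (the [estimate_variance_prior()]
#'   result), `design_matrix`, and `excluded` (accessions skipped, with
#'   reason).
#' @examples
#' sim <- simulate_study(simulation_config(n_proteins = 200, seed = 3))
#' fit <- sim$quant |>
#'   normalize_to_protein_median(sim$design) |>
#'   fit_interaction_model(sim$design)
#' generics::tidy(fit)
#' @export
fit_interaction_model <- function(normalized,
                                  design = default_study_design()) {
  X <- build_design_matrix(design)
  chans <- rownames(X)
  stopifnot(all(chans %in% names(normalized)))
  m <- as.matrix(normalized[chans])
  usable <- apply(is.finite(m) & m > 0, 1, all)
  if ("flagged" %in% names(normalized)) {
    usable <- usable & !normalized$flagged
  }
  excluded <- tibble::tibble(
    accession = normalized$accession[!usable],
    reason = "non-positive or missing channel value"
  )
  if (sum(usable) < 2) {
    stop("fewer than two fittable proteins", call. = FALSE)
  }
  y <- log2(m[usable, , drop = FALSE])
  xtx_inv <- solve(crossprod(X))
  hat <- xtx_inv %*% t(X)            # p x n_obs
  coef <- y %*% t(hat)               # proteins x p
  colnames(coef) <- colnames(X)
  resid <- y - coef %*% t(X)
  df <- nrow(X) - ncol(X)
  s2 <- rowSums(resid^2) / df
  v3 <- xtx_inv["MATURE:TRT", "MATURE:TRT"]
  b3 <- coef[, "MATURE:TRT"]
  prior <- estimate_variance_prior(s2, df)
  mod <- moderate_statistics(b3, s2, df, v3, prior)
  results <- tibble::tibble(
    accession = normalized$accession[usable],
    b0 = coef[, "(Intercept)"], b1 = coef[, "MATURE"],
    b2 = coef[, "TRT"], b3 = b3,
    s2 = s2, df = df,
    t_ordinary = b3 / sqrt(s2 * v3),
    t_moderated = mod$t_moderated,
    df_total = mod$df_total,
    p = mod$p,
    q = bh_fdr(mod$p)
  )
  if ("gene" %in% names(normalized)) {
    results <- dplyr::mutate(results,
                             gene = normalized$gene[usable],
                             .after = "accession")
  }
  structure(
    list(results = results, prior = prior, design_matrix = X,
         v3 = v3, excluded = excluded),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("<moderated_fit> ", nrow(x$results), " proteins (",
      nrow(x$excluded), " excluded); prior d0 = ",
      format(x$prior$d0, digits = 4), ", s0^2 = ",
      format(x$prior$s0_2, digits = 4), "\n", sep = "")
  print(x$results, ...)
  invisible(x)
}

#' Write a differential-enrichment table as TSV
#'
#' @param fit A `moderated_fit`.
#' @param path Output TSV path. The prior is written beside it as
#'   `<path>.prior.json`.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(fit, path) {
  stopifnot(inherits(fit, "moderated_fit"))
  readr::write_tsv(fit$results, path)
  jsonlite::write_json(
    list(d0 = fit$prior$d0, s0_2 = fit$prior$s0_2,
         n_used = fit$prior$n_used),
    paste0(path, ".prior.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
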