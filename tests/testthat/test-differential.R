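# Independent OLS oracle: pseudoinverse via SVD, no shared code with
# fit_protein_ols / fit_interaction_model.
pinv_fit <- function(y, X) {
  s <- svd(X)
  coef <- s$v %*% ((t(s$u) %*% y) / s$d)
  resid <- y - X %*% coef
  list(coef = drop(coef), s2 = sum(resid^2) / (nrow(X) - ncol(X)))
}

test_that("the interaction design matrix encodes stage and treatment", {
  X <- build_design_matrix(default_study_design())
  expect_equal(colSums(X), c(`(Intercept)` = 8, MATURE = 4, TRT = 4,
                             `MATURE:TRT` = 2))
  expect_equal(qr(X)$rank, 4)
  # two observations per (MATURE, TRT) cell -> residual df 4 per protein
  expect_equal(nrow(X) - ncol(X), 4)

  # single-stage design is rank-deficient for the interaction
  d <- default_study_design()
  meta <- d$channel_meta
  meta$stage <- "developing"
  pairs <- d$pairs[d$pairs$stage == "developing", ]
  single <- study_design(d$channels, meta, pairs)
  expect_error(build_design_matrix(single), "two stages")
})

test_that("per-protein OLS matches the saturated-mean solution and the
          pseudoinverse oracle", {
  X <- build_design_matrix(default_study_design())
  # channels ordered 126..130N; assign responses by role
  meta <- default_study_design()$channel_meta
  y <- numeric(8)
  y[meta$stage == "developing" & meta$condition == "control"] <- 0
  y[meta$stage == "developing" & meta$condition == "labeled"] <- 1
  y[meta$stage == "mature" & meta$condition == "control"] <- 0
  y[meta$stage == "mature" & meta$condition == "labeled"] <- 3
  fit <- fit_protein_ols(y, X)
  expect_equal(unname(fit$coefficients), c(0, 0, 1, 2))
  expect_equal(fit$s2, 0)
  expect_equal(fit$df, 4)

  # constant response: no stage, treatment or interaction effect
  fit_const <- fit_protein_ols(rep(2.5, 8), X)
  expect_equal(unname(fit_const$coefficients), c(2.5, 0, 0, 0))

  # random responses match the independent pseudoinverse solve
  set.seed(11)
  for (i in 1:20) {
    y <- rnorm(8)
    a <- fit_protein_ols(y, X)
    b <- pinv_fit(y, X)
    expect_equal(unname(a$coefficients), b$coef, tolerance = 1e-10)
    expect_equal(a$s2, b$s2, tolerance = 1e-10)
  }

  # permuting channel order leaves coefficients unchanged
  set.seed(12)
  y <- rnorm(8)
  perm <- sample(8)
  expect_equal(fit_protein_ols(y[perm], X[perm, ])$coefficients,
               fit_protein_ols(y, X)$coefficients, tolerance = 1e-12)
})

test_that("b3 equals the difference of stage-wise labeled-control
          contrasts under the balanced design", {
  sim <- simulate_study(simulation_config(n_proteins = 50, seed = 141))
  norm <- normalize_to_protein_median(sim$quant, sim$design)
  fit <- fit_interaction_model(norm, sim$design)
  meta <- sim$design$channel_meta
  chan <- function(st, cond) meta$channel[meta$stage == st &
                                            meta$condition == cond]
  y <- log2(as.matrix(norm[meta$channel]))
  colnames(y) <- meta$channel
  b3_direct <-
    (rowMeans(y[, chan("mature", "labeled")]) -
       rowMeans(y[, chan("mature", "control")])) -
    (rowMeans(y[, chan("developing", "labeled")]) -
       rowMeans(y[, chan("developing", "control")]))
  expect_equal(fit$results$b3, unname(b3_direct), tolerance = 1e-10)
})

test_that("variance-prior estimation matches its generative model", {
  # all variances identical: zero excess dispersion -> infinite d0
  prior <- estimate_variance_prior(rep(0.37, 50), 4)
  expect_true(is.infinite(prior$d0))
  expect_equal(prior$s0_2, 0.37, tolerance = 1e-9)

  # recovery of known hyperparameters from scaled inverse-chi-square draws
  set.seed(21)
  d0 <- 4; s0_2 <- 1; df <- 4; n <- 5000
  s2 <- s0_2 * d0 / rchisq(n, d0) * rchisq(n, df) / df
  est <- estimate_variance_prior(s2, df)
  expect_lt(abs(est$d0 - d0) / d0, 0.25)
  expect_lt(abs(est$s0_2 - s0_2) / s0_2, 0.10)

  # grid-search marginal check: the moment-matched (d0, s0_2) is close to
  # the profile maximizer of the log-likelihood of log(s2)
  loglik <- function(d0g) {
    # s2 / s0_2 ~ F(df, d0); profile s0_2 out via the log-moment equation
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    s0g <- exp(mean(e) + digamma(d0g / 2) - log(d0g / 2))
    sum(stats::df(s2 / s0g, df, d0g, log = TRUE)) - n * log(s0g)
  }
  grid <- seq(2, 8, by = 0.25)
  best_grid <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  expect_lt(abs(est$d0 - best_grid), 1.5)

  # two wildly different variances give a small finite d0
  est2 <- estimate_variance_prior(c(1e-4, 1e4), 4)
  expect_true(is.finite(est2$d0))
  expect_lt(est2$d0, 2)

  expect_error(estimate_variance_prior(c(0, 0), 4), "degenerate")
})

test_that("moderated t interpolates between ordinary t and the prior", {
  b3 <- c(1, -0.5, 2)
  s2 <- c(0.5, 0.1, 0)
  v3 <- 0.5
  df <- 4
  # d0 = 0: ordinary t recovered (protein with s2 = 0 diverges)
  m0 <- moderate_statistics(b3, s2, df, v3, list(d0 = 0, s0_2 = 1))
  expect_equal(m0$t_moderated[1:2], b3[1:2] / sqrt(s2[1:2] * v3))
  # d0 = Inf: every denominator uses s0_2, normal reference
  mi <- moderate_statistics(b3, s2, df, v3, list(d0 = Inf, s0_2 = 0.25))
  expect_equal(mi$t_moderated, b3 / sqrt(0.25 * v3))
  expect_equal(mi$p, 2 * pnorm(-abs(mi$t_moderated)))
  # finite d0 keeps a zero-variance protein finite, with the posterior
  # variance formula
  d0 <- 3; s0_2 <- 0.2
  mf <- moderate_statistics(b3, s2, df, v3, list(d0 = d0, s0_2 = s0_2))
  expect_true(all(is.finite(mf$t_moderated)))
  expect_equal(mf$t_moderated[3],
               b3[3] / (sqrt(d0 * s0_2 / (d0 + df)) * sqrt(v3)))
  expect_equal(mf$df_total, rep(d0 + df, 3))
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_fdr(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  # brute force over all j >= i, on shuffled input order
  set.seed(31)
  p <- runif(50)^2
  q <- bh_fdr(p)
  o <- order(p)
  m <- length(p)
  q_brute <- numeric(m)
  for (i in seq_len(m)) {
    q_brute[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  expect_equal(q, q_brute, tolerance = 1e-12)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  # monotone non-decreasing in p
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("equal residual variances give identical moderated and ordinary
          rankings", {
  set.seed(41)
  b3 <- rnorm(100)
  s2 <- rep(0.3, 100)
  prior <- estimate_variance_prior(s2, 4)
  m <- moderate_statistics(b3, s2, 4, 0.5, prior)
  t_ord <- b3 / sqrt(s2 * 0.5)
  expect_equal(order(abs(m$t_moderated)), order(abs(t_ord)))
})

test_that("the full fit agrees with an independent moderated-t
          implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_study(simulation_config(n_proteins = 400, seed = 151))
  norm <- normalize_to_protein_median(sim$quant, sim$design)
  fit <- fit_interaction_model(norm, sim$design)
  X <- build_design_matrix(sim$design)
  m <- log2(as.matrix(norm[rownames(X)]))
  lf <- limma::lmFit(m, design = X)
  eb <- limma::eBayes(lf)
  expect_equal(fit$results$b3, unname(lf$coefficients[, "MATURE:TRT"]),
               tolerance = 1e-10)
  expect_equal(fit$prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s0_2, eb$s2.prior, tolerance = 1e-6)
  expect_equal(fit$results$t_moderated, unname(eb$t[, "MATURE:TRT"]),
               tolerance = 1e-8)
  expect_equal(fit$results$p, unname(eb$p.value[, "MATURE:TRT"]),
               tolerance = 1e-8)
})

test_that("flagged proteins are excluded from fitting and reported", {
  sim <- simulate_study(simulation_config(n_proteins = 30, seed = 161))
  q <- sim$quant
  q[["127C"]][3] <- 0
  norm <- normalize_to_protein_median(q, sim$design)
  fit <- fit_interaction_model(norm, sim$design)
  expect_equal(fit$excluded$accession, q$accession[3])
  expect_equal(nrow(fit$results), 29)
})
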