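#' Configuration for the synthetic TMT study generator
#'
#' Collects and validates the generative parameters of [simulate_study()].
#' Defaults reproduce the composition of the motivating study design: 4752
#' detected proteins of which 819 carry a plasma-membrane annotation
#' (surface), 2228 carry only intracellular annotations, and the remainder
#' are unannotated.
#'
#' @param n_proteins Number of simulated proteins (positive integer).
#' @param class_proportions Length-3 numeric, fractions of
#'   (surface, intracellular, unannotated) proteins; must sum to 1.
#' @param base_abundance_log_mean,base_abundance_log_sd Mean and sd of the
#'   per-protein baseline reporter intensity on the log2 scale.
#' @param surface_enrichment_log2 Mean true log2 labeled:control effect for
#'   surface proteins; intracellular and unannotated proteins have zero mean
#'   effect.
#' @param stage_effect_log2_sd Sd of the per-protein, per-stage modulation of
#'   the labeling effect (surface proteins only); the mature-minus-developing
#'   difference of these modulations is the true interaction effect.
#' @param noise_log2_sd Sd of independent per-channel measurement noise on
#'   the log2 scale.
#' @param compression_gamma Ratio-compression factor in (0, 1]: the observed
#'   log2 ratio is `compression_gamma` times the true one, emulating the
#'   shrinkage toward 1 caused by co-isolation interference in isobaric
#'   quantification. 1 means no compression.
#' @param peptide_count_mean Mean of the shifted-Poisson
#'   (`1 + Poisson(mean - 1)`) distribution of distinct-peptide and
#'   ratio-count evidence.
#' @param seed Integer random seed; identical seeds give identical studies.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 4752,
                              class_proportions = c(819, 2228, 1705) / 4752,
                              base_abundance_log_mean = 20,
                              base_abundance_log_sd = 2,
                              surface_enrichment_log2 = 2,
                              stage_effect_log2_sd = 0.5,
                              noise_log2_sd = 0.3,
                              compression_gamma = 0.6,
                              peptide_count_mean = 6,
                              seed = 1L) {
  if (length(n_proteins) != 1 || !is.finite(n_proteins) || n_proteins < 1 ||
      n_proteins != round(n_proteins)) {
    stop("`n_proteins` must be a positive integer", call. = FALSE)
  }
  if (length(class_proportions) != 3 ||
      any(class_proportions < 0) || any(class_proportions > 1) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop("`class_proportions` must be 3 fractions in [0,1] summing to 1",
         call. = FALSE)
  }
  if (compression_gamma <= 0 || compression_gamma > 1) {
    stop("`compression_gamma` must be in (0, 1]", call. = FALSE)
  }
  sds <- c(base_abundance_log_sd, stage_effect_log2_sd, noise_log2_sd)
  if (any(sds < 0)) stop("sd parameters must be >= 0", call. = FALSE)
  if (peptide_count_mean < 1) {
    stop("`peptide_count_mean` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      class_proportions = as.numeric(class_proportions),
      base_abundance_log_mean = base_abundance_log_mean,
      base_abundance_log_sd = base_abundance_log_sd,
      surface_enrichment_log2 = surface_enrichment_log2,
      stage_effect_log2_sd = stage_effect_log2_sd,
      noise_log2_sd = noise_log2_sd,
      compression_gamma = compression_gamma,
      peptide_count_mean = peptide_count_mean,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate an 8-plex paired proximity-labeling study
#'
#' Generates a protein-level quantification table with known ground truth,
#' emulating a two-stage design with two labeled replicates and two negative
#' controls per stage. For protein *i* with true log2 labeling effect
#' `eff[i, stage]`, a labeled channel of that stage measures
#' `2^(base + gamma * eff + noise)` and a control channel `2^(base + noise)`,
#' with independent Gaussian log2 noise per channel and `gamma` the ratio
#' compression factor. Surface proteins have mean effect
#' `surface_enrichment_log2`; other classes have zero mean effect.
#'
#' @param config A [simulation_config()].
#' @param design A [study_design()]; defaults to [default_study_design()].
#'
#' @return A list of class `simulated_study` with elements
#'   \describe{
#'     \item{quant}{tibble: `accession`, `gene`, `peptides`, `ratio_counts`,
#'       then one reporter-intensity column per channel label.}
#'     \item{truth}{tibble: `accession`, `class`, true per-stage log2 effects
#'       `effect_developing` / `effect_mature`, and `interaction_effect`
#'       (mature minus developing).}
#'     \item{config, design}{the inputs, echoed.}
#'   }
#' @examples
#' sim <- simulate_study(simulation_config(n_proteins = 50, seed = 7))
#' sim$quant
#' @export
simulate_study <- function(config = simulation_config(),
                           design = default_study_design()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(design, "study_design"))
  n <- config$n_proteins
  meta <- design$channel_meta
  with_sim_seed(config$seed, {
    cls <- sample(c("surface", "intracellular", "unannotated"), n,
                  replace = TRUE, prob = config$class_proportions)
    base_log2 <- stats::rnorm(n, config$base_abundance_log_mean,
                              config$base_abundance_log_sd)
    mod_dev <- stats::rnorm(n, 0, config$stage_effect_log2_sd)
    mod_mat <- stats::rnorm(n, 0, config$stage_effect_log2_sd)
    is_surface <- cls == "surface"
    eff_dev <- ifelse(is_surface, config$surface_enrichment_log2 + mod_dev, 0)
    eff_mat <- ifelse(is_surface, config$surface_enrichment_log2 + mod_mat, 0)
    noise <- matrix(stats::rnorm(n * nrow(meta), 0, config$noise_log2_sd),
                    nrow = n)
    peptides <- 1L + stats::rpois(n, config$peptide_count_mean - 1)
    ratio_counts <- 1L + stats::rpois(n, config$peptide_count_mean - 1)

    eff_by_stage <- cbind(developing = eff_dev, mature = eff_mat)
    intensities <- vapply(seq_len(nrow(meta)), function(j) {
      eff_j <- if (meta$condition[j] == "labeled") {
        eff_by_stage[, meta$stage[j]]
      } else {
        0
      }
      2^(base_log2 + config$compression_gamma * eff_j + noise[, j])
    }, numeric(n))
    colnames(intensities) <- meta$channel

    acc <- sprintf("SIM%05d", seq_len(n))
    quant <- tibble::tibble(
      accession = acc,
      gene = sprintf("Gene%d", seq_len(n)),
      peptides = peptides,
      ratio_counts = ratio_counts
    )
    quant <- dplyr::bind_cols(
      quant, tibble::as_tibble(intensities[, design$channels, drop = FALSE])
    )
    truth <- tibble::tibble(
      accession = acc,
      class = cls,
      effect_developing = eff_dev,
      effect_mature = eff_mat,
      interaction_effect = eff_mat - eff_dev
    )
    structure(
      list(quant = quant, truth = truth, config = config, design = design),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> ", nrow(x$quant), " proteins x ",
      length(x$design$channels), " channels (seed ", x$config$seed, ")\n",
      sep = "")
  print(dplyr::count(x$truth, .data$class), ...)
  invisible(x)
}

#' Convert simulation ground truth into a localization annotation table
#'
#' Bridges the generator's class labels to the annotation vocabulary used by
#' [classify_localization()]: surface proteins receive the plasma-membrane
#' term, intracellular proteins one of the nucleus / mitochondrion /
#' cytoplasm terms (assigned round-robin, deterministically), and unannotated
#' proteins an empty term set.
#'
#' @param truth The `truth` tibble of a [simulate_study()] result (or the
#'   `simulated_study` itself).
#' @return A tibble with columns `accession` and `terms`
#'   (semicolon-delimited).
#' @export
truth_to_annotation <- function(truth) {
  if (inherits(truth, "simulated_study")) truth <- truth$truth
  stopifnot(is.data.frame(truth), nrow(truth) > 0,
            all(c("accession", "class") %in% names(truth)))
  intracellular_terms <- c("nucleus", "mitochondrion", "cytoplasm")
  idx <- cumsum(truth$class == "intracellular")
  tibble::tibble(
    accession = truth$accession,
    terms = dplyr::case_when(
      truth$class == "surface" ~ "plasma membrane",
      truth$class == "intracellular" ~
        intracellular_terms[(idx - 1L) %% 3L + 1L],
      TRUE ~ ""
    )
  )
}

#' Write a simulated study to disk
#'
#' Writes the quantification table and the ground truth as TSV and the
#' configuration as JSON, alongside each other.
#'
#' @param sim A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulated_study <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    quant = file.path(dir, "quant.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  readr::write_tsv(sim$quant, paths[["quant"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  jsonlite::write_json(unclass(sim$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
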