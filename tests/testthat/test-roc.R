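five_protein_fixture <- function() {
  list(
    ratios = ratios_from_named(
      `129C/127C` = c(A = 5, B = 4, C = 3, D = 2, E = 1)
    ),
    labels = labels_tbl(c("A", "B", "C", "D", "E"),
                        c("TP", "TP", "FP", "TP", "FP"))
  )
}

test_that("ranking is descending with deterministic tie-break", {
  r <- ratios_from_named(`129C/127C` = c(A = 5, C = 3, B = 4))
  expect_equal(rank_by_ratio(r, "129C/127C")$accession, c("A", "B", "C"))
  r2 <- ratios_from_named(`129C/127C` = c(B = 2, A = 2))
  expect_equal(rank_by_ratio(r2, "129C/127C")$accession, c("A", "B"))
  # a tied block is one ROC threshold
  curve <- compute_roc(rank_by_ratio(r2, "129C/127C"),
                       labels_tbl(c("A", "B"), c("TP", "FP")))
  expect_equal(nrow(curve), 1)
  # undefined ratios are an error naming the protein
  r3 <- ratios_from_named(`129C/127C` = c(A = 1, B = NA))
  expect_error(rank_by_ratio(r3, "129C/127C"), "B")
  # large ranking equals an independent sort oracle
  set.seed(7)
  big <- tibble::tibble(accession = sprintf("P%04d", 1:1000),
                        replicate = "x", stage = NA,
                        ratio = sample(round(rlnorm(1000), 2)))
  ranked <- rank_by_ratio(big, "x")
  oracle <- big[order(-big$ratio, big$accession), ]
  expect_equal(ranked$accession, oracle$accession)
})

test_that("ROC accumulates labeled proteins only, per ratio block", {
  fx <- five_protein_fixture()
  curve <- compute_roc(rank_by_ratio(fx$ratios, "129C/127C"), fx$labels)
  expect_equal(curve$threshold, c(5, 4, 3, 2, 1))
  expect_equal(curve$cum_tp, c(1, 2, 2, 3, 3))
  expect_equal(curve$cum_fp, c(0, 0, 1, 1, 2))
  expect_equal(curve$j, c(1/3, 2/3, 2/3 - 1/2, 1 - 1/2, 0),
               tolerance = 1e-12)
  # terminal point is (1, 1) with J = 0
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$j[nrow(curve)], 0)

  # one FP at the bottom: J = TPR until the final threshold
  lab2 <- labels_tbl(c("A", "B", "C", "D", "E"),
                     c("TP", "TP", "TP", "TP", "FP"))
  c2 <- compute_roc(rank_by_ratio(fx$ratios, "129C/127C"), lab2)
  expect_equal(c2$j[-nrow(c2)], c2$tpr[-nrow(c2)])

  # degenerate class composition is an error
  expect_error(
    compute_roc(rank_by_ratio(fx$ratios, "129C/127C"),
                labels_tbl(c("A", "B"), c("TP", "TP"))),
    "ROC undefined"
  )
})

test_that("unclassified proteins never move the curve", {
  fx <- five_protein_fixture()
  base_curve <- compute_roc(rank_by_ratio(fx$ratios, "129C/127C"),
                            fx$labels)
  # insert unclassified proteins at the top, middle and bottom
  with_u <- ratios_from_named(
    `129C/127C` = c(A = 5, U1 = 4.6, B = 4, C = 3, U2 = 2.5, D = 2,
                    E = 1, U3 = 0.5)
  )
  curve_u <- compute_roc(rank_by_ratio(with_u, "129C/127C"), fx$labels)
  expect_setequal(
    paste(base_curve$tpr, base_curve$fpr),
    unique(paste(curve_u$tpr, curve_u$fpr))
  )
  # and the selected cutoff retains the same labeled set
  expect_equal(select_cutoff(curve_u)$j, select_cutoff(base_curve)$j)
})

test_that("cutoff selection maximizes TPR - FPR, ties toward stringency", {
  fx <- five_protein_fixture()
  curve <- compute_roc(rank_by_ratio(fx$ratios, "129C/127C"), fx$labels)
  cut <- select_cutoff(curve)
  expect_equal(cut$threshold, 4)
  expect_equal(apply_cutoff(fx$ratios, "129C/127C", cut)$accession,
               c("A", "B"))
  # all-TP labels: maximum J = 1 reached at the minimum ratio
  all_tp <- labels_tbl(c("A", "B", "C", "D", "E"),
                       c("TP", "TP", "TP", "TP", "FP"))
  # (keep one FP for a defined ROC; J maxes where all TPs are in)
  c2 <- compute_roc(rank_by_ratio(fx$ratios, "129C/127C"), all_tp)
  expect_equal(select_cutoff(c2)$threshold, 2)
  # explicit tie at the maximum resolves to the larger threshold
  tie <- ratios_from_named(`x` = c(A = 3, B = 2, C = 1))
  tie_lab <- labels_tbl(c("A", "B", "C"), c("TP", "unclassified", "FP"))
  ct <- compute_roc(rank_by_ratio(tie, "x"), tie_lab)
  expect_equal(max(ct$j), 1)
  expect_equal(select_cutoff(ct)$threshold, 3)
})

test_that("cutoff selection agrees with the brute-force threshold scan", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(c(20, 100, 500, 2000), 1)
    ratio <- round(rlnorm(n, 0, 1), 2)
    class <- sample(c("TP", "FP", "unclassified"), n, replace = TRUE,
                    prob = c(0.2, 0.45, 0.35))
    if (sum(class == "TP") == 0) class[1] <- "TP"
    if (sum(class == "FP") == 0) class[2] <- "FP"
    acc <- sprintf("P%05d", seq_len(n))
    tbl <- tibble::tibble(accession = acc, replicate = "r", stage = NA,
                          ratio = ratio)
    cut <- select_cutoff(compute_roc(rank_by_ratio(tbl, "r"),
                                     labels_tbl(acc, class)))
    oracle <- brute_force_cutoff(ratio, class)
    expect_equal(cut$threshold, oracle$threshold)
    expect_equal(cut$j, oracle$j, tolerance = 1e-12)
  }
})

test_that("applying a cutoff retains unclassified proteins and respects
          the inclusive/strict convention", {
  r <- ratios_from_named(`x` = c(A = 5, F = 4.5, B = 4, C = 3))
  expect_equal(apply_cutoff(r, "x", 4)$accession, c("A", "F", "B"))
  expect_equal(apply_cutoff(r, "x", 4, strict = TRUE)$accession,
               c("A", "F"))
  expect_equal(nrow(apply_cutoff(r, "x", 99)), 0)
  expect_equal(nrow(apply_cutoff(r, "x", 3)), 4)
})

test_that("replicate intersection orders by mean ratio", {
  a <- tibble::tibble(accession = c("A", "B", "C"), ratio = c(5, 4, 3))
  b <- tibble::tibble(accession = c("B", "C", "D"), ratio = c(1, 9, 2))
  p <- intersect_replicates(a, b, "developing")
  expect_setequal(p$accession, c("B", "C"))
  expect_equal(p$accession, c("C", "B"))  # means 6 vs 2.5
  expect_equal(p$mean_ratio, c(6, 2.5))
  expect_equal(nrow(intersect_replicates(a, a[0, ], "s")), 0)
})

test_that("a J-maximizing cutoff enriches the retained TP fraction", {
  sim <- simulate_study(simulation_config(n_proteins = 800, seed = 111))
  labels <- classify_localization(truth_to_annotation(sim))
  ratios <- compute_pair_ratios(sim$quant, sim$design)
  for (rep_label in sim$design$pairs$replicate) {
    ranked <- rank_by_ratio(ratios, rep_label)
    curve <- compute_roc(ranked, labels)
    cut <- select_cutoff(curve)
    expect_gt(cut$j, 0)
    kept <- apply_cutoff(ratios, rep_label, cut)
    cls_all <- labels$class[match(ranked$accession, labels$accession)]
    cls_kept <- labels$class[match(kept$accession, labels$accession)]
    frac <- function(cls) sum(cls == "TP") / sum(cls %in% c("TP", "FP"))
    expect_gt(frac(cls_kept), frac(cls_all))
  }
})

test_that("stringent all-four-ratio proteomes are subsets of the default", {
  sim <- simulate_study(simulation_config(n_proteins = 600, seed = 121))
  labels <- classify_localization(truth_to_annotation(sim))
  ratios <- compute_pair_ratios(sim$quant, sim$design)
  ext <- extract_surfaceome(ratios, labels, sim$design)
  stringent <- stringent_proteomes(ratios, ext$cutoffs, sim$design)
  for (st in names(ext$proteomes)) {
    str_acc <- stringent$accession[stringent$stage == st]
    expect_true(all(str_acc %in% ext$proteomes[[st]]$accession))
    # and a subset of every per-replicate default list
    for (r in sim$design$pairs$replicate) {
      expect_true(all(str_acc %in% ext$replicate_lists[[r]]$accession))
    }
  }
  # protein above three of four thresholds is excluded
  thr <- tibble::tibble(replicate = sim$design$pairs$replicate,
                        threshold = 1)
  four <- ratios_from_named(
    `129C/127C` = c(P = 2), `128C/127N` = c(P = 2),
    `130N/128N` = c(P = 2), `129N/126` = c(P = 0.5)
  )
  expect_equal(nrow(stringent_proteomes(four, thr, sim$design)), 0)
  four$ratio[four$replicate == "129N/126"] <- 2
  expect_equal(nrow(stringent_proteomes(four, thr, sim$design)), 2)
})

test_that("extraction with injected thresholds replays fixed cutoffs", {
  sim <- simulate_study(simulation_config(n_proteins = 300, seed = 131))
  ratios <- compute_pair_ratios(sim$quant, sim$design)
  thr <- tibble::tibble(replicate = sim$design$pairs$replicate,
                        threshold = c(1.5, 1.4, 1.6, 1.3))
  ext <- extract_surfaceome(ratios, design = sim$design, thresholds = thr)
  expect_null(ext$curves)
  for (i in seq_len(4)) {
    r <- thr$replicate[i]
    expect_true(all(ext$replicate_lists[[r]]$ratio >= thr$threshold[i]))
  }
  expect_error(extract_surfaceome(ratios, design = sim$design),
               "labels")
})
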