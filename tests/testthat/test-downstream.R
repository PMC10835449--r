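test_that("per-amino-acid optimality contrast excludes neutral and 1-codon aas", {
  ds <- shared_dataset()
  oc <- optimality_contrast_by_aa(ds$annotated, ds$model)
  expect_false(any(oc$aa %in% c("M", "W")))
  expect_equal(oc$diff, oc$score_reducing - oc$score_increasing)
  expect_true(all(oc$ci_low <= oc$diff & oc$diff <= oc$ci_high))
  expect_true(all(oc$n_reducing > 0 & oc$n_increasing > 0))
})

test_that("GERP contrast is one-sided with Bonferroni adjustment", {
  ds <- shared_dataset()
  g <- gerp_contrast(ds$annotated)
  # two-codon filter keeps only degeneracy-2 amino acids
  deg <- codon_table()$degeneracy
  expect_true(all(deg[g$aa] == 2))
  expect_equal(g$p_adj, pmin(1, g$p * nrow(g)))
  # the generator shifts reducing-variant GERP up by 1
  expect_true(all(g$median_reducing > g$median_increasing))

  # identical distributions give p >= 0.5 under the one-sided alternative
  v <- ds$annotated[ds$annotated$aa == "H", ][1:200, ]
  v$gerp <- rep(rnorm(100), 2)
  v$optimality <- rep(c("reducing", "increasing"), each = 100)
  g0 <- gerp_contrast(v)
  expect_gte(g0$p, 0.5)
  v$gerp <- NA_real_
  expect_error(gerp_contrast(v), "GERP")
})

test_that("saturation fractions use Wilson intervals and opportunity baselines", {
  # toy: 30 reducing of 100 observed; universe with symmetric mutability
  v <- data.frame(aa = "H", degeneracy = 2,
                  optimality = rep(c("reducing", "increasing"), c(30, 70)))
  u <- data.frame(aa = "H", degeneracy = 2,
                  optimality = c("reducing", "increasing"), mu = c(0.2, 0.2))
  s <- saturation_by_aa(v, u)
  expect_equal(s$observed_fraction, 0.30)
  expect_equal(s$expected_fraction, 0.5)
  expect_equal(unname(unlist(s[, c("ci_low", "ci_high")])),
               unname(unlist(wilson_ci(30, 100))))

  # Wilson lower bound at 0 successes is 0
  expect_equal(wilson_ci(0, 10)$low, 0, tolerance = 1e-12)

  # asymmetric mutability tilts the expected baseline
  u2 <- data.frame(aa = "H", degeneracy = 2,
                   optimality = c("reducing", "increasing"), mu = c(0.3, 0.1))
  expect_equal(saturation_by_aa(v, u2)$expected_fraction, 0.75)
})

test_that("saturation on simulated data stays within [0, 1] with baselines", {
  ds <- shared_dataset()
  u <- possible_changes(ds$reference, ds$metrics$mutability, ds$metrics$csc)
  s <- saturation_by_aa(ds$annotated, u)
  expect_true(all(s$observed_fraction >= 0 & s$observed_fraction <= 1))
  expect_true(all(s$expected_fraction > 0 & s$expected_fraction < 1))
  expect_true(all(codon_table()$degeneracy[s$aa] == 2))
})

test_that("constrained-gene scoring takes the lowest-LOEUF 30% of genes", {
  ds <- shared_dataset()
  cg <- constrained_gene_scores(ds$annotated, ds$model)
  G <- length(unique(ds$annotated$gene_id))
  expect_equal(unique(cg$n_genes[cg$set == "constrained"]), ceiling(0.3 * G))
  # generator plants extra selection in constrained genes
  for (opt in c("reducing", "increasing")) {
    expect_gt(cg$score[cg$set == "constrained" & cg$optimality == opt],
              cg$score[cg$set == "all" & cg$optimality == opt])
  }
  v <- ds$annotated
  v$loeuf <- NA_real_
  expect_error(constrained_gene_scores(v, ds$model), "LOEUF")
})

test_that("splice classes split at the threshold and report Welch contrasts", {
  ds <- shared_dataset()
  sp <- splice_class_scores(ds$annotated, ds$model)
  expect_equal(nrow(sp), 8)
  expect_setequal(unique(sp$class),
                  c("donor_loss", "donor_gain", "acceptor_loss",
                    "acceptor_gain"))
  # thresholding: a single variant with donor_loss 0.6 and 0.1 elsewhere is
  # high only in donor loss
  n_ann <- sum(stats::complete.cases(
    ds$annotated[, c("spliceai_donor_loss", "spliceai_donor_gain",
                     "spliceai_acceptor_loss", "spliceai_acceptor_gain")]))
  counts <- tapply(sp$n_variants, sp$class, sum)
  expect_true(all(counts == n_ann))
  v <- ds$annotated
  v[, c("spliceai_donor_loss", "spliceai_donor_gain",
        "spliceai_acceptor_loss", "spliceai_acceptor_gain")] <- NA_real_
  expect_error(splice_class_scores(v, ds$model), "annotated")
})

test_that("predictor quartiles hold equal counts with stable tie-breaking", {
  ds <- shared_dataset()
  v <- ds$annotated[1:100, ]
  v$cadd <- 1:100
  pq <- predictor_quartile_scores(v, "cadd", ds$model)
  expect_equal(pq$scores$n_variants, rep(25L, 4))
  expect_equal(pq$scores$score_min, c(1, 26, 51, 76))
  expect_equal(nrow(pq$contrasts), 3)
  v$cadd <- NA_real_
  expect_error(predictor_quartile_scores(v, "cadd", ds$model), "missing")
  v$cadd <- rep(c(1, 2), 50)
  expect_error(predictor_quartile_scores(v, "cadd", ds$model), "distinct")
})

test_that("quartile selection scores track a planted monotone signal", {
  ds <- shared_dataset()
  pq <- predictor_quartile_scores(ds$annotated, "cadd", ds$model)
  # generator makes CADD increase with the planted selection offset
  expect_true(all(diff(pq$scores$score) > 0) ||
                pq$scores$score[4] > pq$scores$score[1])
  expect_gt(pq$scores$score[4], pq$scores$score[1])
})

test_that("ClinVar groups merge likely labels and reference benign", {
  ds <- shared_dataset()
  cv <- clinvar_group_scores(ds$annotated, ds$model)
  expect_setequal(cv$clinvar_class, c("benign_like", "VUS", "pathogenic_like"))
  expect_equal(cv$diff_vs_benign[cv$clinvar_class == "benign_like"], 0)
  n_merged <- cv$n_variants[cv$clinvar_class == "pathogenic_like"]
  n_raw <- sum(ds$annotated$clinvar_label %in%
                 c("pathogenic", "likely_pathogenic"))
  expect_equal(n_merged, n_raw)
  # planted ordering: pathogenic-like > VUS > benign-like, on the
  # label-enriched dataset where the class counts give adequate power
  dcv <- clinvar_dataset()
  cv2 <- clinvar_group_scores(dcv$annotated, dcv$model)
  sc <- stats::setNames(cv2$score, cv2$clinvar_class)
  expect_gt(sc[["pathogenic_like"]], sc[["VUS"]])
  expect_gt(sc[["VUS"]], sc[["benign_like"]])
  v <- ds$annotated
  v$clinvar_label <- "none"
  expect_error(clinvar_group_scores(v, ds$model), "benign")
})

test_that("analysis reports write as TSV with optional JSON", {
  ds <- shared_dataset()
  cv <- clinvar_group_scores(ds$annotated, ds$model)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(cv, path, json = TRUE)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(cv))
  expect_true(file.exists(paste0(path, ".json")))
})
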