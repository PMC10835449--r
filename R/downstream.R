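#' Optimality contrast per amino acid
#'
#' For each amino acid with synonymous variants on both sides, computes the
#' difference between the selection scores of optimality-reducing (dCSC < 0)
#' and optimality-increasing (dCSC > 0) variants, with a confidence interval
#' combining the two Wilson half-widths in quadrature, and a Welch contrast.
#' Neutral-labeled variants are excluded; amino acids with an empty side are
#' skipped with a message.
#'
#' @param variants annotated variant data.frame (see
#'   [attach_codon_annotations()] and [assign_context()]).
#' @param model a `calibration_model`.
#' @param min_n minimum per-context size for the Welch test.
#' @return data.frame per amino acid: `aa`, `n_reducing`, `n_increasing`,
#'   `score_reducing`, `score_increasing`, `diff`, `ci_low`, `ci_high`,
#'   `p`, `p_adj`.
#' @export
optimality_contrast_by_aa <- function(variants, model, min_n = 20) {
  variants <- variants[variants$optimality %in% c("reducing", "increasing"), ,
                       drop = FALSE]
  aas <- sort(unique(variants$aa))
  rows <- list()
  for (aa in aas) {
    red <- variants[variants$aa == aa & variants$optimality == "reducing", ,
                    drop = FALSE]
    inc <- variants[variants$aa == aa & variants$optimality == "increasing", ,
                    drop = FALSE]
    if (nrow(red) == 0 || nrow(inc) == 0) {
      message("skipping amino acid ", aa, ": one side has no variants")
      next
    }
    s_red <- score_subset(red, model)
    s_inc <- score_subset(inc, model)
    hw <- sqrt(((s_red$ci_high - s_red$ci_low) / 2)^2 +
                 ((s_inc$ci_high - s_inc$ci_low) / 2)^2)
    p <- tryCatch(score_contrast(red, inc, model, min_n = min_n)$p,
                  error = function(e) NA_real_)
    rows[[aa]] <- data.frame(
      aa = aa, n_reducing = nrow(red), n_increasing = nrow(inc),
      score_reducing = s_red$score, score_increasing = s_inc$score,
      diff = s_red$score - s_inc$score,
      ci_low = s_red$score - s_inc$score - hw,
      ci_high = s_red$score - s_inc$score + hw,
      p = p, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * sum(!is.na(out$p)))
  rownames(out) <- NULL
  out
}

#' GERP conservation contrast per amino acid
#'
#' Compares the GERP score distributions of optimality-reducing and
#' optimality-increasing synonymous variants with a one-sided
#' Mann-Whitney-Wilcoxon test (alternative: reducing > increasing),
#' Bonferroni-adjusted across the amino acids tested. Higher GERP marks more
#' conserved positions, so a significant shift indicates that
#' optimality-reducing changes fall at constrained loci.
#'
#' @param variants annotated variant data.frame with a `gerp` column.
#' @param two_codon_only restrict to amino acids with exactly two codons
#'   (default), where the reducing/increasing dichotomy is sharpest.
#' @return data.frame per amino acid: `aa`, `n_reducing`, `n_increasing`,
#'   `median_reducing`, `median_increasing`, `statistic`, `p`, `p_adj`.
#' @export
gerp_contrast <- function(variants, two_codon_only = TRUE) {
  if (!("gerp" %in% names(variants)) || all(is.na(variants$gerp)))
    stop("no GERP scores available")
  variants <- variants[!is.na(variants$gerp) &
                         variants$optimality %in% c("reducing", "increasing"), ,
                       drop = FALSE]
  if (two_codon_only)
    variants <- variants[variants$degeneracy == 2, , drop = FALSE]
  aas <- sort(unique(variants$aa))
  rows <- list()
  for (aa in aas) {
    g_red <- variants$gerp[variants$aa == aa & variants$optimality == "reducing"]
    g_inc <- variants$gerp[variants$aa == aa &
                             variants$optimality == "increasing"]
    if (length(g_red) == 0 || length(g_inc) == 0) next
    wt <- stats::wilcox.test(g_red, g_inc, alternative = "greater",
                             exact = FALSE)
    rows[[aa]] <- data.frame(
      aa = aa, n_reducing = length(g_red), n_increasing = length(g_inc),
      median_reducing = stats::median(g_red),
      median_increasing = stats::median(g_inc),
      statistic = unname(wt$statistic), p = wt$p.value,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Enumerate possible synonymous changes in a reference with mutability
#'
#' Expands every codon occurrence in the reference sequences into its possible
#' synonymous single-base changes, attaching the coding-strand context, the
#' optimality label and the context mutability (averaged over methylation
#' bins where several exist). This is the opportunity universe used for
#' saturation baselines.
#'
#' @param reference from [simulate_reference()] (or any list with a `genes`
#'   data.frame of equal-length `seq` strings).
#' @param mut_table mutability table.
#' @param csc named per-codon CSC vector.
#' @param table a [codon_table()].
#' @return data.frame with one row per possible change: `gene_id`, `aa`,
#'   `degeneracy`, `ref_codon`, `alt_codon`, `optimality`, `mu`.
#' @export
possible_changes <- function(reference, mut_table, csc,
                             table = codon_table()) {
  genes <- reference$genes
  ex <- expand_reference_changes(genes, table)
  key_no_meth <- paste0(
    normalize_context(ex$context3, ex$alt_base)$context3, ">",
    normalize_context(ex$context3, ex$alt_base)$alt)
  mt_key <- paste0(
    normalize_context(mut_table$context3, mut_table$alt)$context3, ">",
    normalize_context(mut_table$context3, mut_table$alt)$alt)
  mu_by_key <- tapply(mut_table$mu, mt_key, mean)
  mu <- as.numeric(mu_by_key[key_no_meth])
  if (anyNA(mu)) stop("context key(s) absent from mutability table")
  d_csc <- unname(csc[ex$alt_codon] - csc[ex$ref_codon])
  data.frame(
    gene_id = genes$gene_id[ex$gene_i],
    aa = ex$aa, degeneracy = ex$degeneracy,
    ref_codon = ex$ref_codon, alt_codon = ex$alt_codon,
    optimality = classify_optimality(d_csc),
    mu = mu, stringsAsFactors = FALSE
  )
}

#' Saturation of optimality-reducing variants per two-codon amino acid
#'
#' For each two-codon amino acid, the observed fraction of
#' optimality-reducing variants among classified variants, with a Wilson
#' interval, against the expected baseline: the mutability-weighted share of
#' optimality-reducing opportunities among all possible synonymous changes
#' for that amino acid in the sequence universe. An observed fraction below
#' the baseline means the optimality-reducing side is depleted (its pool of
#' optimal codons is exhausted more slowly); above means oversaturation of
#' the reducing side.
#'
#' @param variants annotated variant data.frame.
#' @param universe opportunity universe from [possible_changes()].
#' @param conf confidence level.
#' @return data.frame per amino acid: `aa`, `n_reducing`, `n_total`,
#'   `observed_fraction`, `ci_low`, `ci_high`, `expected_fraction`.
#' @export
saturation_by_aa <- function(variants, universe, conf = 0.95) {
  variants <- variants[variants$degeneracy == 2 &
                         variants$optimality %in% c("reducing", "increasing"), ,
                       drop = FALSE]
  universe <- universe[universe$degeneracy == 2 &
                         universe$optimality %in% c("reducing", "increasing"), ,
                       drop = FALSE]
  rows <- list()
  for (aa in sort(unique(variants$aa))) {
    v <- variants[variants$aa == aa, , drop = FALSE]
    u <- universe[universe$aa == aa, , drop = FALSE]
    if (nrow(v) == 0) next
    n_red <- sum(v$optimality == "reducing")
    ci <- wilson_ci(n_red, nrow(v), conf)
    expected <- if (nrow(u) > 0)
      sum(u$mu[u$optimality == "reducing"]) / sum(u$mu) else NA_real_
    rows[[aa]] <- data.frame(
      aa = aa, n_reducing = n_red, n_total = nrow(v),
      observed_fraction = n_red / nrow(v),
      ci_low = ci$low, ci_high = ci$high,
      expected_fraction = expected, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Selection scores in constrained genes versus all genes
#'
#' Defines the constrained set as the `ceiling(0.3 * G)` genes with the
#' lowest LOEUF (the 30% most loss-of-function-intolerant genes) and scores
#' the constrained and full variant sets for each optimality label.
#'
#' @param variants annotated variant data.frame with a `loeuf` column.
#' @param model a `calibration_model`.
#' @param quantile_cut fraction of genes considered constrained.
#' @return data.frame with columns `set` (`constrained`/`all`), `optimality`,
#'   `n_genes`, and the [score_subset()] columns.
#' @export
constrained_gene_scores <- function(variants, model, quantile_cut = 0.3) {
  if (!("loeuf" %in% names(variants)) || all(is.na(variants$loeuf)))
    stop("no LOEUF values available")
  gene_loeuf <- tapply(variants$loeuf, variants$gene_id,
                       function(x) x[1])
  gene_loeuf <- gene_loeuf[!is.na(gene_loeuf)]
  n_take <- ceiling(quantile_cut * length(gene_loeuf))
  constrained_genes <- names(sort(gene_loeuf))[seq_len(n_take)]
  sets <- list(
    constrained = variants[variants$gene_id %in% constrained_genes, ,
                           drop = FALSE],
    all = variants
  )
  rows <- list()
  for (set_name in names(sets)) {
    for (opt in c("reducing", "increasing")) {
      sub <- sets[[set_name]]
      sub <- sub[sub$optimality == opt, , drop = FALSE]
      if (nrow(sub) == 0) next
      rows[[paste(set_name, opt)]] <- cbind(
        data.frame(set = set_name, optimality = opt,
                   n_genes = if (set_name == "constrained") n_take
                             else length(gene_loeuf),
                   stringsAsFactors = FALSE),
        score_subset(sub, model))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Selection scores by predicted splice-disruption class
#'
#' For each SpliceAI prediction class (donor loss, donor gain, acceptor loss,
#' acceptor gain) independently, splits annotated variants at the delta-score
#' threshold (high: score at or above the threshold) and scores both sides,
#' with a Welch contrast per class Bonferroni-adjusted over the four classes.
#' Variants without SpliceAI annotation are excluded.
#'
#' @param variants annotated variant data.frame with the four
#'   `spliceai_*` columns.
#' @param model a `calibration_model`.
#' @param threshold delta-score threshold for high splice-disruption
#'   potential (default 0.5).
#' @param min_n minimum per-context size for the Welch test.
#' @return data.frame with one row per class x side: `class`, `side`
#'   (`high`/`low`), the [score_subset()] columns, and `p`, `p_adj` of the
#'   class's high-vs-low Welch contrast.
#' @export
splice_class_scores <- function(variants, model, threshold = 0.5,
                                min_n = 20) {
  cols <- c(donor_loss = "spliceai_donor_loss",
            donor_gain = "spliceai_donor_gain",
            acceptor_loss = "spliceai_acceptor_loss",
            acceptor_gain = "spliceai_acceptor_gain")
  if (!all(cols %in% names(variants)))
    stop("missing SpliceAI delta-score column(s)")
  annotated <- stats::complete.cases(variants[, cols])
  if (!any(annotated)) stop("no SpliceAI-annotated variants")
  variants <- variants[annotated, , drop = FALSE]
  rows <- list()
  for (k in names(cols)) {
    hi <- variants[variants[[cols[[k]]]] >= threshold, , drop = FALSE]
    lo <- variants[variants[[cols[[k]]]] < threshold, , drop = FALSE]
    if (nrow(hi) == 0 || nrow(lo) == 0)
      stop("class ", k, " has an empty side at threshold ", threshold)
    ct <- tryCatch(
      score_contrast(hi, lo, model, family_size = length(cols),
                     min_n = min_n),
      error = function(e) data.frame(p = NA_real_, p_adj = NA_real_))
    for (side in c("high", "low")) {
      sub <- if (side == "high") hi else lo
      rows[[paste(k, side)]] <- cbind(
        data.frame(class = k, side = side, stringsAsFactors = FALSE),
        score_subset(sub, model),
        data.frame(p = ct$p, p_adj = ct$p_adj))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Selection scores by quartile of an external predictor
#'
#' Splits variants carrying the given score column into four equal-size
#' quartiles (ties broken by stable rank order, boundaries inclusive on the
#' left), scores each quartile, and reports adjacent-quartile Welch
#' contrasts Bonferroni-adjusted over the three comparisons. Rows missing the
#' score are excluded.
#'
#' @param variants annotated variant data.frame.
#' @param score_column `"cadd"` or `"synvep"` (any numeric column works).
#' @param model a `calibration_model`.
#' @param min_n minimum per-context size for the Welch tests.
#' @return list with `scores` (data.frame per quartile: `quartile`,
#'   score-range columns and the [score_subset()] columns) and `contrasts`
#'   (data.frame of adjacent-quartile Welch tests).
#' @export
predictor_quartile_scores <- function(variants, score_column, model,
                                      min_n = 20) {
  if (!(score_column %in% names(variants)))
    stop("missing score column: ", score_column)
  x <- variants[[score_column]]
  variants <- variants[!is.na(x), , drop = FALSE]
  x <- x[!is.na(x)]
  if (nrow(variants) == 0) stop("all rows missing ", score_column)
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct values of ", score_column)
  ord <- order(x)  # stable: ties keep input order
  q <- integer(length(x))
  q[ord] <- ceiling(4 * seq_along(x) / length(x))
  variants$.quartile <- q
  parts <- split(variants, variants$.quartile)
  scores <- do.call(rbind, lapply(names(parts), function(k) {
    sub <- parts[[k]]
    cbind(data.frame(quartile = paste0("Q", k),
                     score_min = min(sub[[score_column]]),
                     score_max = max(sub[[score_column]]),
                     stringsAsFactors = FALSE),
          score_subset(sub, model))
  }))
  contrasts <- do.call(rbind, lapply(1:3, function(i) {
    ct <- tryCatch(
      score_contrast(parts[[i + 1]], parts[[i]], model,
                     family_size = 3, min_n = min_n),
      error = function(e) data.frame(diff = NA_real_, statistic = NA_real_,
                                     df = NA_real_, p = NA_real_,
                                     p_adj = NA_real_, method = NA_character_))
    cbind(data.frame(comparison = paste0("Q", i + 1, " vs Q", i),
                     stringsAsFactors = FALSE), ct)
  }))
  rownames(scores) <- rownames(contrasts) <- NULL
  list(scores = scores, contrasts = contrasts)
}

#' Selection-score differences between ClinVar classes
#'
#' Merges "likely pathogenic" with "pathogenic" and "likely benign" with
#' "benign", scores each merged class, and reports each class's score
#' difference relative to the benign-like reference (difference CI combines
#' the two Wilson half-widths in quadrature).
#'
#' @param variants annotated variant data.frame with a `clinvar_label` column
#'   (labels among benign/likely_benign/VUS/likely_pathogenic/pathogenic;
#'   anything else, `"none"` or `NA` is treated as unlabeled and excluded).
#' @param model a `calibration_model`.
#' @return data.frame per merged class: `clinvar_class`, the [score_subset()]
#'   columns, `diff_vs_benign`, `diff_ci_low`, `diff_ci_high`.
#' @export
clinvar_group_scores <- function(variants, model) {
  lab <- variants$clinvar_label
  merged <- rep(NA_character_, length(lab))
  merged[lab %in% c("benign", "likely_benign")] <- "benign_like"
  merged[lab %in% c("VUS", "uncertain_significance")] <- "VUS"
  merged[lab %in% c("pathogenic", "likely_pathogenic")] <- "pathogenic_like"
  variants$clinvar_class <- merged
  variants <- variants[!is.na(merged), , drop = FALSE]
  if (!any(variants$clinvar_class == "benign_like"))
    stop("benign-like reference group is empty")
  parts <- split(variants, variants$clinvar_class)
  scored <- lapply(parts, score_subset, model = model)
  ref <- scored[["benign_like"]]
  ref_hw <- (ref$ci_high - ref$ci_low) / 2
  out <- do.call(rbind, lapply(names(scored), function(k) {
    s <- scored[[k]]
    hw <- sqrt(((s$ci_high - s$ci_low) / 2)^2 + ref_hw^2)
    d <- s$score - ref$score
    cbind(data.frame(clinvar_class = k, stringsAsFactors = FALSE), s,
          data.frame(diff_vs_benign = d,
                     diff_ci_low = if (k == "benign_like") 0 else d - hw,
                     diff_ci_high = if (k == "benign_like") 0 else d + hw))
  }))
  rownames(out) <- NULL
  out
}

#' Write an analysis report as TSV (and optionally JSON)
#'
#' @param report a data.frame produced by one of the analysis functions.
#' @param path output TSV path.
#' @param json also write `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, json = FALSE) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (json)
    jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
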