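#' Configuration for the synthetic gnomAD-like data generator
#'
#' Defines the generative conditions for all simulations: a coding-sequence
#' universe, per-codon optimality metrics, a mutational-context mutability
#' law, a neutral singleton-probability curve that is affine in the square
#' root of mutability (emulating saturation and mutational recurrence in
#' large cohorts), and planted class-specific selection offsets.
#'
#' The singleton probability of a variant is
#' `clamp(a0 + a1 * sqrt(mu) + delta)`, where `delta` collects the planted
#' selection: `w_tai * (-dTAI) + w_csc * (-dCSC) + w_gc * (-dGC)` plus
#' splice-class, ClinVar-class, constrained-gene and tagged-class offsets.
#' Because the neutral curve is affine in `sqrt(mu)`, the sqrt-transform
#' (TRAPS) calibration is correctly specified while the identity-transform
#' (MAPS) calibration is misspecified, reproducing the known
#' low-mutability bias of the latter.
#'
#' @param seed integer seed; fully determines every generated object.
#' @param n_genes,codons_per_gene size of the coding universe.
#' @param usage_conc Dirichlet-like concentration for codon usage weights;
#'   smaller values give stronger codon usage bias.
#' @param mu_ranges log-uniform mutability ranges per mutational class
#'   (relative rates); the CpG-transition class sits roughly 100-fold above
#'   the non-CpG-transition center.
#' @param meth_mult mutability multipliers for CpG methylation bins 0-2.
#' @param meth_probs sampling probabilities of methylation bins at CpG sites.
#' @param a0,a1 neutral singleton-probability curve coefficients (on the
#'   `sqrt(mu)` scale; `a1 < 0`: more mutable contexts have fewer singletons).
#' @param w_tai,w_csc,w_gc selection weights on the (negated) per-substitution
#'   deltas.
#' @param splice_loss_offset,splice_gain_offset extra singleton-probability
#'   offsets for variants with a high (>= 0.5) SpliceAI delta score of the
#'   loss resp. gain type.
#' @param splice_high_frac fraction of variants assigned a high score in each
#'   of the four SpliceAI classes.
#' @param spliceai_frac,cadd_frac,synvep_frac,gerp_frac fractions of variants
#'   carrying each optional score annotation (others are `NA`).
#' @param clinvar_probs probabilities of ClinVar labels
#'   (none/benign/likely_benign/VUS/likely_pathogenic/pathogenic).
#' @param clinvar_offsets singleton-probability offsets for benign-like, VUS
#'   and pathogenic-like ClinVar classes.
#' @param loeuf_boost extra offset for variants in the 30% most constrained
#'   (lowest-LOEUF) genes.
#' @param tag_fraction,tag_offset a randomly tagged variant class receiving a
#'   known offset `tag_offset`; used for offset-recovery experiments (tagged
#'   rows are flagged in the ground truth and excluded from neutral
#'   calibration there).
#' @param gerp_shift_reducing additive GERP shift for optimality-reducing
#'   variants (GERP is otherwise standard normal).
#' @param sampling_rate probability that a possible synonymous change is
#'   observed in the cohort.
#' @param decoy_frac fraction of additional non-synonymous decoy records
#'   (missense/pLoF consequences) included to exercise filtering.
#' @param n_transcripts transcripts in the synthetic half-life experiment.
#' @param eps clamping bound for probabilities.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 200,
                       codons_per_gene = 300,
                       usage_conc = 5,
                       mu_ranges = list(
                         "transversion" = c(0.004, 0.012),
                         "non-CpG transition" = c(0.015, 0.06),
                         "CpG transition" = c(1.0, 3.0)
                       ),
                       meth_mult = c(0.5, 1, 1.5),
                       meth_probs = c(0.25, 0.35, 0.4),
                       a0 = 0.60, a1 = -0.22,
                       w_tai = 0.05, w_csc = 0.08, w_gc = 0.03,
                       splice_loss_offset = 0.10,
                       splice_gain_offset = 0.05,
                       splice_high_frac = 0.02,
                       spliceai_frac = 0.8,
                       cadd_frac = 0.9, synvep_frac = 0.9, gerp_frac = 1,
                       clinvar_probs = c(none = 0.94, benign = 0.015,
                                         likely_benign = 0.015, VUS = 0.02,
                                         likely_pathogenic = 0.005,
                                         pathogenic = 0.005),
                       clinvar_offsets = c(benign_like = 0, VUS = 0.02,
                                           pathogenic_like = 0.06),
                       loeuf_boost = 0.03,
                       tag_fraction = 0, tag_offset = 0,
                       gerp_shift_reducing = 1,
                       sampling_rate = 0.4,
                       decoy_frac = 0.05,
                       n_transcripts = 500,
                       eps = 0.01) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1 || cfg$codons_per_gene < 1)
    stop("genes must have positive length")
  stopifnot(a1 < 0, eps > 0, eps < 0.5)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a coding-sequence reference
#'
#' Draws `n_genes` coding sequences of sense codons from the configured codon
#' usage weights, along with per-gene LOEUF values and the genome-wide codon
#' usage counts of the simulated universe. Deterministic under the config
#' seed.
#'
#' @param config a [sim_config()].
#' @param table a [codon_table()].
#' @return list with `genes` (data.frame `gene_id`, `seq`, `loeuf`),
#'   `usage` (named codon counts) and `usage_weights` (the generating
#'   weights).
#' @export
simulate_reference <- function(config, table = codon_table()) {
  set.seed(config$seed + 101L)
  sense <- table$sense_codons
  # Gamma draws normalized within each amino acid give Dirichlet-like codon
  # usage bias; smaller usage_conc -> stronger bias.
  w <- stats::rgamma(length(sense), shape = config$usage_conc, rate = 1)
  names(w) <- sense
  total <- config$n_genes * config$codons_per_gene
  codons <- sample(sense, total, replace = TRUE, prob = w)
  mat <- matrix(codons, nrow = config$n_genes, byrow = TRUE)
  seqs <- apply(mat, 1, paste, collapse = "")
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(config$n_genes)),
    seq = seqs,
    loeuf = stats::runif(config$n_genes, 0.05, 2),
    stringsAsFactors = FALSE
  )
  usage <- table(factor(codons, levels = sense))
  list(genes = genes,
       usage = stats::setNames(as.numeric(usage), names(usage)),
       usage_weights = w / sum(w))
}

#' Simulate codon optimality metrics with known ground truth
#'
#' Produces (i) planted per-codon CSC values together with a transcript codon
#' frequency matrix and half-life vector constructed so that [compute_csc()]
#' recovers the planted values closely; (ii) tRNA gene copy numbers with the
#' resulting tAI; and (iii) the mutability table implied by the config's
#' mutability law. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param table a [codon_table()].
#' @return list with `csc` (planted per-codon CSC), `freq_matrix`,
#'   `half_lives`, `trna_copies`, `tai`, `mutability`.
#' @export
simulate_metrics <- function(config, table = codon_table()) {
  set.seed(config$seed + 202L)
  sense <- table$sense_codons
  n_codon <- length(sense)
  base <- stats::rgamma(n_codon, shape = 8, rate = 1)
  base <- base / sum(base) * 1000

  # Planted CSC: within each amino acid, codons get evenly spaced values
  # around a random amino-acid-level center (plus jitter), so synonymous
  # codons are meaningfully separated, as empirical CSC tables are.
  csc <- stats::setNames(numeric(n_codon), sense)
  for (aa in names(table$aa_to_codons)) {
    codons <- table$aa_to_codons[[aa]]
    k <- length(codons)
    center <- stats::runif(1, -0.25, 0.25)
    vals <- center + 0.15 * (sample(k) - (k + 1) / 2) +
      stats::runif(k, -0.02, 0.02)
    csc[codons] <- vals
  }
  # Center by codon weight so per-thousand normalization leaves the
  # transcript-level correlations essentially untouched.
  csc <- csc - sum(base * csc) / sum(base)
  if (any(abs(csc) >= 1)) stop("planted CSC out of (-1, 1)")

  nt <- config$n_transcripts
  z <- as.numeric(scale(stats::rnorm(nt)))
  # Per-codon frequency perturbations with the planted sample correlation to
  # z: residualize the noise against z so the correlation is exact before
  # per-thousand normalization.
  freq <- matrix(0, nt, n_codon, dimnames = list(NULL, sense))
  for (j in seq_len(n_codon)) {
    e <- stats::rnorm(nt)
    e_perp <- as.numeric(scale(stats::residuals(stats::lm(e ~ z))))
    g <- csc[j] * z + sqrt(1 - csc[j]^2) * e_perp
    freq[, j] <- pmax(base[j] * (1 + 0.25 * g), 0.01)
  }
  half_lives <- 5 + 2 * z

  wc_anticodons <- revcomp(sense)
  copies <- stats::rpois(n_codon, lambda = 5)
  copies[stats::runif(n_codon) < 0.15] <- 0
  if (all(copies == 0)) copies[1] <- 1
  trna_copies <- tapply(copies, wc_anticodons, sum)
  trna_copies <- stats::setNames(as.numeric(trna_copies), names(trna_copies))
  tai <- compute_tai(trna_copies, table = table)

  list(csc = csc, freq_matrix = freq, half_lives = half_lives,
       trna_copies = trna_copies, tai = tai,
       mutability = simulate_mutability(config))
}

# Expand every codon occurrence in a set of equal-length coding sequences
# into its possible synonymous single-base changes, with the coding-strand
# trinucleotide context. Changes at the first and last base of a gene have no
# full context and are dropped.
expand_reference_changes <- function(genes, table = codon_table()) {
  changes <- enumerate_synonymous_changes(table)
  L <- nchar(genes$seq[1])
  if (any(nchar(genes$seq) != L)) stop("genes must have equal length")
  n_codons <- L %/% 3

  occ_gene <- rep(seq_len(nrow(genes)), each = n_codons)
  occ_idx <- rep(seq_len(n_codons), times = nrow(genes))
  starts <- (occ_idx - 1L) * 3L + 1L
  occ_codon <- substring(genes$seq[occ_gene], starts, starts + 2L)

  ch_by_codon <- split(seq_len(nrow(changes)), changes$ref_codon)
  n_ch <- vapply(ch_by_codon, length, integer(1))[occ_codon]
  n_ch[is.na(n_ch)] <- 0L
  keep <- n_ch > 0L
  rep_idx <- rep(which(keep), n_ch[keep])
  ch_idx <- unlist(ch_by_codon[occ_codon[keep]], use.names = FALSE)

  gene_i <- occ_gene[rep_idx]
  codon_i <- occ_idx[rep_idx]
  ch <- changes[ch_idx, , drop = FALSE]
  pos_in_gene <- (codon_i - 1L) * 3L + ch$pos + 1L

  in_range <- pos_in_gene > 1L & pos_in_gene < L
  out <- ch[in_range, , drop = FALSE]
  out$gene_i <- gene_i[in_range]
  out$codon_i <- codon_i[in_range]
  out$pos_in_gene <- pos_in_gene[in_range]
  out$context3 <- substring(genes$seq[out$gene_i],
                            out$pos_in_gene - 1L, out$pos_in_gene + 1L)
  rownames(out) <- NULL
  out
}

# Mutability table over all strand-normalized (context, alt, methylation bin)
# keys, drawn log-uniformly within the class ranges; CpG-transition keys get
# one row per methylation bin with the configured multipliers.
simulate_mutability <- function(config) {
  set.seed(config$seed + 303L)
  ctx <- as.vector(outer(
    as.vector(outer(DNA_BASES, c("C", "T"), function(a, b) paste0(a, b))),
    DNA_BASES, paste0))
  grid <- expand.grid(context3 = ctx, alt = DNA_BASES,
                      stringsAsFactors = FALSE)
  grid <- grid[substr(grid$context3, 2, 2) != grid$alt, , drop = FALSE]
  grid$class <- context_class(grid$context3, grid$alt)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cls <- grid$class[i]
    rng <- config$mu_ranges[[cls]]
    base_mu <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
    if (cls == "CpG transition") {
      data.frame(context3 = grid$context3[i], alt = grid$alt[i],
                 methylation_bin = 0:2, mu = base_mu * config$meth_mult,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(context3 = grid$context3[i], alt = grid$alt[i],
                 methylation_bin = 0L, mu = base_mu,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a gnomAD-like annotated variant table with ground truth
#'
#' Enumerates every possible synonymous single-base change in the reference,
#' samples which are observed, assigns allele counts with a
#' mutability-dependent singleton probability plus the configured planted
#' selection offsets, and attaches external score columns (GERP, SpliceAI,
#' CADD, synVep, LOEUF, ClinVar) with the configured dependence on the
#' planted selection. A fraction of non-synonymous decoy records is appended
#' to exercise consequence filtering. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param reference from [simulate_reference()].
#' @param metrics from [simulate_metrics()].
#' @param table a [codon_table()].
#' @return list with `variants` (canonical variant data.frame including
#'   decoys) and `truth` (data.frame aligned to the synonymous rows:
#'   `delta_true`, `tagged`, `splice_class`, `constrained`, plus the config).
#' @export
simulate_variant_table <- function(config, reference, metrics,
                                   table = codon_table()) {
  set.seed(config$seed + 404L)
  genes <- reference$genes
  L <- nchar(genes$seq[1])
  ex <- expand_reference_changes(genes, table)
  gene_i <- ex$gene_i
  codon_i <- ex$codon_i
  pos_in_gene <- ex$pos_in_gene
  ctx <- ex$context3
  ch <- ex

  cls <- context_class(ctx, ch$alt_base)
  meth <- integer(length(cls))
  is_cpg <- cls == "CpG transition"
  meth[is_cpg] <- sample(0:2, sum(is_cpg), replace = TRUE,
                         prob = config$meth_probs)

  mut <- metrics$mutability
  mu <- mut$mu[match(context_key(ctx, ch$alt_base, meth),
                     context_key(mut$context3, mut$alt,
                                 mut$methylation_bin))]
  if (anyNA(mu)) stop("internal: context key missing from mutability table")

  d_csc <- unname(metrics$csc[ch$alt_codon] - metrics$csc[ch$ref_codon])
  d_tai <- unname(metrics$tai[ch$alt_codon] - metrics$tai[ch$ref_codon])
  d_gc <- gc_count(ch$alt_codon) - gc_count(ch$ref_codon)

  n_all <- length(mu)
  delta <- config$w_tai * (-d_tai) + config$w_csc * (-d_csc) +
    config$w_gc * (-d_gc)

  # SpliceAI: four delta-score columns; a small fraction of variants gets a
  # high (>= 0.5) score in one class and the corresponding planted offset.
  splice_class <- rep("none", n_all)
  classes <- c("donor_loss", "donor_gain", "acceptor_loss", "acceptor_gain")
  u <- stats::runif(n_all)
  hi <- u < 4 * config$splice_high_frac
  splice_class[hi] <- sample(classes, sum(hi), replace = TRUE)
  sai <- matrix(stats::runif(n_all * 4, 0, 0.2), n_all, 4,
                dimnames = list(NULL, classes))
  for (k in classes) {
    pick <- splice_class == k
    sai[pick, k] <- stats::runif(sum(pick), 0.5, 1)
  }
  delta <- delta +
    ifelse(splice_class %in% c("donor_loss", "acceptor_loss"),
           config$splice_loss_offset, 0) +
    ifelse(splice_class %in% c("donor_gain", "acceptor_gain"),
           config$splice_gain_offset, 0)

  clinvar <- sample(names(config$clinvar_probs), n_all, replace = TRUE,
                    prob = config$clinvar_probs)
  cv_off <- config$clinvar_offsets
  delta <- delta +
    ifelse(clinvar %in% c("benign", "likely_benign"), cv_off[["benign_like"]],
    ifelse(clinvar == "VUS", cv_off[["VUS"]],
    ifelse(clinvar %in% c("pathogenic", "likely_pathogenic"),
           cv_off[["pathogenic_like"]], 0)))

  loeuf <- genes$loeuf[gene_i]
  constrained <- loeuf <= stats::quantile(genes$loeuf, 0.3)
  delta <- delta + ifelse(constrained, config$loeuf_boost, 0)

  tagged <- stats::runif(n_all) < config$tag_fraction
  delta <- delta + ifelse(tagged, config$tag_offset, 0)

  p_raw <- config$a0 + config$a1 * sqrt(mu) + delta
  n_out <- sum(p_raw < 0 | p_raw > 1)
  if (n_out > 0)
    warning(n_out, " singleton probabilities clamped to [",
            config$eps, ", ", 1 - config$eps, "]")
  p <- pmin(pmax(p_raw, config$eps), 1 - config$eps)

  observed <- stats::runif(n_all) < config$sampling_rate
  idx <- which(observed)
  n_obs <- length(idx)
  if (n_obs == 0) stop("no variants observed; increase sampling_rate")

  singleton <- stats::rbinom(n_obs, 1, p[idx]) == 1
  ac <- ifelse(singleton, 1L,
               2L + stats::rgeom(n_obs, prob = 0.3))
  an <- 251496L

  gerp <- stats::rnorm(n_obs) +
    config$gerp_shift_reducing * as.numeric(d_csc[idx] < 0)
  gerp[stats::runif(n_obs) >= config$gerp_frac] <- NA_real_
  cadd <- 12 + 120 * delta[idx] + stats::rnorm(n_obs, sd = 2)
  cadd[stats::runif(n_obs) >= config$cadd_frac] <- NA_real_
  synvep <- pmin(pmax(0.5 + 8 * delta[idx] + stats::rnorm(n_obs, sd = 0.08),
                      0), 1)
  synvep[stats::runif(n_obs) >= config$synvep_frac] <- NA_real_
  sai_obs <- sai[idx, , drop = FALSE]
  sai_na <- stats::runif(n_obs) >= config$spliceai_frac
  sai_obs[sai_na, ] <- NA_real_

  variants <- data.frame(
    chrom = "1",
    pos = (gene_i[idx] - 1L) * (L + 1000L) + pos_in_gene[idx],
    ref = substr(ch$ref_codon[idx], ch$pos[idx] + 1L, ch$pos[idx] + 1L),
    alt = ch$alt_base[idx],
    ac = ac, an = an,
    gene_id = genes$gene_id[gene_i[idx]],
    transcript_id = paste0(genes$gene_id[gene_i[idx]], ".t1"),
    most_severe_consequence = "synonymous_variant",
    strand = "+",
    context3 = ctx[idx],
    methylation_bin = meth[idx],
    ref_codon = ch$ref_codon[idx],
    alt_codon = ch$alt_codon[idx],
    codon_index = codon_i[idx],
    gerp = gerp,
    spliceai_donor_loss = sai_obs[, "donor_loss"],
    spliceai_donor_gain = sai_obs[, "donor_gain"],
    spliceai_acceptor_loss = sai_obs[, "acceptor_loss"],
    spliceai_acceptor_gain = sai_obs[, "acceptor_gain"],
    cadd = cadd, synvep = synvep,
    loeuf = loeuf[idx],
    clinvar_label = clinvar[idx],
    stringsAsFactors = FALSE
  )
  variants$is_singleton <- variants$ac == 1L

  truth <- data.frame(
    delta_true = delta[idx],
    p_singleton = p[idx],
    tagged = tagged[idx],
    splice_class = splice_class[idx],
    constrained = constrained[idx],
    stringsAsFactors = FALSE
  )

  if (config$decoy_frac > 0) {
    n_decoy <- round(n_obs * config$decoy_frac)
    if (n_decoy > 0) {
      pick <- sample(n_obs, n_decoy, replace = TRUE)
      decoys <- variants[pick, , drop = FALSE]
      decoys$most_severe_consequence <- sample(
        c("missense_variant", "stop_gained", "splice_donor_variant",
          "splice_region_variant"),
        n_decoy, replace = TRUE)
      decoys$pos <- decoys$pos + 1L  # distinct sites
      variants <- rbind(variants, decoys)
      rownames(variants) <- NULL
    }
  }

  list(variants = variants, truth = truth, config = config)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_reference()], [simulate_metrics()]
#' and [simulate_variant_table()] in sequence.
#'
#' @param config a [sim_config()].
#' @return list with `reference`, `metrics`, `variants`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  reference <- simulate_reference(config)
  metrics <- simulate_metrics(config)
  sim <- simulate_variant_table(config, reference, metrics)
  list(reference = reference, metrics = metrics,
       variants = sim$variants, truth = sim$truth, config = config)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the TSV and VCF variant-table dialects read by
#' [read_variant_table()], the mutability/CSC/tRNA/usage tables, a ground
#' truth JSON and a manifest listing every file with its row count.
#'
#' @param dataset from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    variants_tsv = file.path(dir, "variants.tsv"),
    variants_vcf = file.path(dir, "variants.vcf"),
    mutability = file.path(dir, "mutability.tsv"),
    csc = file.path(dir, "csc.tsv"),
    trna = file.path(dir, "trna_copies.tsv"),
    usage = file.path(dir, "codon_usage.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_variant_table(dataset$variants, paths[["variants_tsv"]], "tsv")
  write_variant_table(dataset$variants, paths[["variants_vcf"]], "vcf")
  write_mutability_table(dataset$metrics$mutability, paths[["mutability"]])
  write_metric_table(dataset$metrics$csc, paths[["csc"]],
                     names_to = "codon", values_to = "csc")
  write_metric_table(dataset$metrics$trna_copies, paths[["trna"]],
                     names_to = "anticodon", values_to = "copies")
  write_metric_table(dataset$reference$usage, paths[["usage"]],
                     names_to = "codon", values_to = "count")
  cfg <- dataset$config
  jsonlite::write_json(
    list(config = unclass(cfg), truth = dataset$truth),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  rows <- c(nrow(dataset$variants), nrow(dataset$variants),
            nrow(dataset$metrics$mutability), length(dataset$metrics$csc),
            length(dataset$metrics$trna_copies),
            length(dataset$reference$usage), nrow(dataset$truth), NA)
  utils::write.table(
    data.frame(file = basename(paths), rows = rows),
    paths[["manifest"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
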