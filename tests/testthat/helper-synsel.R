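# Shared helpers: pipeline shorthand and memoized datasets so the suite
# generates each fixture once.

.helper_cache <- new.env(parent = emptyenv())

# Config with all planted selection switched off (neutral null); individual
# switches can be turned back on through ...
neutral_config <- function(seed, ...) {
  args <- list(seed = seed,
               w_tai = 0, w_csc = 0, w_gc = 0,
               splice_loss_offset = 0, splice_gain_offset = 0,
               clinvar_offsets = c(benign_like = 0, VUS = 0,
                                   pathogenic_like = 0),
               loeuf_boost = 0, decoy_frac = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Filter + context + codon annotation in one step.
annotate_variants <- function(variants, metrics) {
  v <- suppressMessages(filter_synonymous(variants))
  v <- assign_context(v, metrics$mutability)
  suppressMessages(
    attach_codon_annotations(v, metrics$csc, metrics$tai))
}

# Default-scale dataset with planted selection, annotated and calibrated.
shared_dataset <- function() {
  if (is.null(.helper_cache$ds)) {
    ds <- suppressWarnings(simulate_dataset(sim_config(seed = 42)))
    ds$annotated <- annotate_variants(ds$variants, ds$metrics)
    ds$model <- fit_calibration(aggregate_contexts(ds$annotated), "sqrt")
    .helper_cache$ds <- ds
  }
  .helper_cache$ds
}

# Larger neutral dataset (GERP shift still on by default) for the
# conservation-contrast experiment, where 500 variants per side per
# two-codon amino acid are subsampled.
gerp_dataset <- function() {
  if (is.null(.helper_cache$gerp)) {
    ds <- simulate_dataset(neutral_config(23, n_genes = 1000))
    ds$annotated <- annotate_variants(ds$variants, ds$metrics)
    .helper_cache$gerp <- ds
  }
  .helper_cache$gerp
}

# Dataset with ClinVar-label fractions enriched enough to power the
# planted-ordering check (real ClinVar-labelled synonymous variants are
# rarer; offsets are the generator defaults).
clinvar_dataset <- function() {
  if (is.null(.helper_cache$clinvar)) {
    ds <- suppressWarnings(simulate_dataset(sim_config(
      seed = 19, n_genes = 400,
      clinvar_probs = c(none = 0.70, benign = 0.10, likely_benign = 0.05,
                        VUS = 0.10, likely_pathogenic = 0.02,
                        pathogenic = 0.03))))
    ds$annotated <- annotate_variants(ds$variants, ds$metrics)
    ds$model <- fit_calibration(aggregate_contexts(ds$annotated), "sqrt")
    .helper_cache$clinvar <- ds
  }
  .helper_cache$clinvar
}

# Small neutral dataset for cheap structural tests.
small_dataset <- function() {
  if (is.null(.helper_cache$small)) {
    ds <- simulate_dataset(neutral_config(7, n_genes = 40))
    ds$annotated <- annotate_variants(ds$variants, ds$metrics)
    ds$model <- fit_calibration(aggregate_contexts(ds$annotated), "sqrt")
    .helper_cache$small <- ds
  }
  .helper_cache$small
}

# Hand-built scorable variant table: n variants per context with the given
# mutabilities and singleton counts.
toy_variants <- function(mu, n, s) {
  stopifnot(length(mu) == length(n), length(n) == length(s))
  rows <- lapply(seq_along(mu), function(i) {
    data.frame(context_key = paste0("ctx", i),
               context_class = "transversion",
               mu = mu[i],
               is_singleton = rep(c(TRUE, FALSE), c(s[i], n[i] - s[i])))
  })
  do.call(rbind, rows)
}

# Calibration model with exact intercept/slope, built from a two-context
# exact fit (two points determine the line).
toy_model <- function(alpha, beta, transform = "identity") {
  t1 <- 0.1; t2 <- 0.2
  mu <- if (transform == "sqrt") c(t1, t2)^2 else c(t1, t2)
  agg <- data.frame(
    context_key = c("a", "b"), mu = mu, context_class = "transversion",
    n = c(10L, 10L),
    s = c(round(10 * (alpha + beta * t1)), round(10 * (alpha + beta * t2))),
    ps = c(alpha + beta * t1, alpha + beta * t2))
  fit_calibration(agg, transform)
}
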