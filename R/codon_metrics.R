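#' Codon stability coefficients from codon frequencies and half-lives
#'
#' The codon stability coefficient (CSC) of a codon is the Pearson correlation,
#' across transcripts, between the codon's frequency in a transcript and the
#' transcript's experimentally measured half-life. Positive CSC marks codons
#' whose usage associates with more stable transcripts (optimal codons).
#'
#' Frequencies are taken per-thousand codons within each transcript before
#' correlating; half-lives are used untransformed.
#'
#' @param freq_matrix numeric matrix, transcripts x codons (column names are
#'   codons). Entries may be raw codon counts or pre-normalized frequencies.
#' @param half_lives numeric vector of per-transcript half-lives (hours),
#'   length `nrow(freq_matrix)`.
#' @param normalize logical; if `TRUE` (default) rows are rescaled to
#'   per-thousand frequencies.
#' @return named numeric vector of CSC values per codon; `NA` where the codon's
#'   frequency has zero variance (e.g. absent from every transcript).
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(5 * 3, 20), 5, 3, dimnames = list(NULL, c("AAA", "GAA", "CAT")))
#' compute_csc(m, half_lives = c(1, 2, 3, 4, 5))
#' @export
compute_csc <- function(freq_matrix, half_lives, normalize = TRUE) {
  if (!is.matrix(freq_matrix)) freq_matrix <- as.matrix(freq_matrix)
  if (nrow(freq_matrix) < 3)
    stop("compute_csc() needs at least 3 transcripts")
  if (length(half_lives) != nrow(freq_matrix))
    stop("half_lives must have one value per transcript")
  if (anyNA(half_lives) || stats::sd(half_lives) == 0)
    stop("half_lives must be non-missing and non-constant")
  if (normalize) {
    totals <- rowSums(freq_matrix)
    if (any(totals <= 0)) stop("every transcript needs a positive codon total")
    freq_matrix <- freq_matrix / totals * 1000
  }
  csc <- suppressWarnings(
    as.vector(stats::cor(freq_matrix, half_lives, method = "pearson"))
  )
  names(csc) <- colnames(freq_matrix)
  csc[apply(freq_matrix, 2, stats::sd) == 0] <- NA_real_
  csc
}

#' Default wobble-pairing penalties for the tRNA adaptation index
#'
#' Selective constraints `s` for each codon-anticodon pairing geometry at the
#' wobble position, following the constrained-optimization values of the
#' canonical tAI formulation for eukaryotes. Watson-Crick pairs carry no
#' penalty; inosine and U/G wobble pairs are down-weighted.
#'
#' @return named numeric vector with elements `WC` (Watson-Crick), `GU`
#'   (anticodon G reading codon-ending U), `IC` (inosine reading C), `IA`
#'   (inosine reading A), `UG` (anticodon U reading codon-ending G).
#' @export
tai_default_s <- function() {
  c(WC = 0, GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68)
}

# Anticodons able to decode a codon, with the pairing geometry at the wobble
# position. The anticodon is written 5'->3' in DNA letters, so its first base
# pairs the codon's third base. Inosine arises from A at the wobble position.
decoding_anticodons <- function(codon) {
  wc <- revcomp(codon)
  third <- substr(codon, 3, 3)
  rest <- substr(wc, 2, 3)
  out <- data.frame(anticodon = wc, pairing = "WC", stringsAsFactors = FALSE)
  extra <- switch(third,
    "T" = c("G", "GU"),
    "C" = c("A", "IC"),
    "A" = c("A", "IA"),
    "G" = c("T", "UG")
  )
  # Met ATG is decoded only by its Watson-Crick anticodon CAT: U:G wobble from
  # the isoleucine TAT anticodon is disallowed in the standard tAI formulation.
  if (!is.null(extra) && codon != "ATG") {
    out <- rbind(out, data.frame(anticodon = paste0(extra[1], rest),
                                 pairing = extra[2], stringsAsFactors = FALSE))
  }
  out
}

#' tRNA adaptation index from tRNA gene copy numbers
#'
#' For each sense codon, availability is the penalty-weighted sum of gene copy
#' numbers over the anticodons able to decode it, `W = sum (1 - s) * copies`;
#' the tAI is `W / max(W)`. Codons with zero direct availability receive the
#' geometric mean of the nonzero tAI values (flagged via the
#' `"substituted"` attribute), the standard convention for missing anticodons.
#'
#' @param trna_copies named numeric vector of tRNA gene copy numbers keyed by
#'   anticodon (DNA letters, 5'->3'). Anticodons absent from the vector count
#'   as zero copies.
#' @param s wobble penalties, see [tai_default_s()].
#' @param table a [codon_table()].
#' @return named numeric vector of tAI over the 61 sense codons, max exactly 1,
#'   with attribute `substituted` naming codons that received the
#'   geometric-mean fill-in.
#' @export
compute_tai <- function(trna_copies, s = tai_default_s(),
                        table = codon_table()) {
  if (any(trna_copies < 0)) stop("copy numbers must be non-negative")
  if (all(trna_copies == 0)) stop("all tRNA copy numbers are zero")
  if (any(s < 0 | s > 1)) stop("pairing penalties must lie in [0, 1]")
  W <- vapply(table$sense_codons, function(codon) {
    dec <- decoding_anticodons(codon)
    copies <- trna_copies[dec$anticodon]
    copies[is.na(copies)] <- 0
    sum((1 - s[dec$pairing]) * copies)
  }, numeric(1))
  if (max(W) == 0) stop("no codon has positive availability")
  w <- W / max(W)
  zero <- names(w)[w == 0]
  if (length(zero)) w[zero] <- exp(mean(log(w[w > 0])))
  attr(w, "substituted") <- zero
  w
}

#' Per-substitution optimality deltas
#'
#' Given a synonymous single-base codon change, computes the change in codon
#' stability coefficient, tRNA adaptation index and GC content (alt minus ref),
#' the degeneracy of the amino acid, and the optimality label.
#'
#' @param ref_codon,alt_codon single codons differing at exactly one position
#'   and encoding the same amino acid.
#' @param csc named numeric vector of per-codon CSC values (may contain `NA`).
#' @param tai named numeric vector of per-codon tAI values.
#' @param table a [codon_table()].
#' @return A one-row data.frame (`delta_record`) with columns `ref_codon`,
#'   `alt_codon`, `aa`, `degeneracy`, `delta_csc`, `delta_tai`, `delta_gc`,
#'   `optimality`.
#' @export
delta_metrics <- function(ref_codon, alt_codon, csc, tai,
                          table = codon_table()) {
  if (nchar(ref_codon) != 3 || nchar(alt_codon) != 3)
    stop("codons must be length-3 strings")
  ndiff <- sum(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
  if (ndiff != 1)
    stop("ref and alt codons must differ at exactly one position")
  aa_ref <- table$codon_to_aa[[ref_codon]]
  aa_alt <- table$codon_to_aa[[alt_codon]]
  if (!identical(aa_ref, aa_alt) || aa_ref == "*")
    stop("codon pair is not a sense-codon synonymous change")
  d_csc <- unname(csc[alt_codon] - csc[ref_codon])
  d_tai <- unname(tai[alt_codon] - tai[ref_codon])
  rec <- data.frame(
    ref_codon = ref_codon, alt_codon = alt_codon, aa = aa_ref,
    degeneracy = unname(table$degeneracy[[aa_ref]]),
    delta_csc = if (length(d_csc)) d_csc else NA_real_,
    delta_tai = if (length(d_tai)) d_tai else NA_real_,
    delta_gc = gc_count(alt_codon) - gc_count(ref_codon),
    stringsAsFactors = FALSE
  )
  rec$optimality <- classify_optimality(rec$delta_csc)
  rec
}

#' Classify a synonymous change by its effect on codon optimality
#'
#' A change to a codon with lower CSC is optimality-reducing, to a higher CSC
#' optimality-increasing; a zero delta is neutral and is excluded from
#' optimality contrasts. Signs are used rather than an optimal/nonoptimal
#' dichotomy so that amino acids whose codons all have negative CSC (e.g.
#' histidine) remain classifiable.
#'
#' @param delta_csc numeric vector of CSC deltas (alt minus ref).
#' @return character vector with levels `"reducing"`, `"increasing"`,
#'   `"neutral"`, or `"unclassified"` where the delta is missing.
#' @export
classify_optimality <- function(delta_csc) {
  out <- rep("unclassified", length(delta_csc))
  out[!is.na(delta_csc) & delta_csc < 0] <- "reducing"
  out[!is.na(delta_csc) & delta_csc > 0] <- "increasing"
  out[!is.na(delta_csc) & delta_csc == 0] <- "neutral"
  out
}

#' Average codon usage bias per amino acid
#'
#' For each amino acid with degeneracy k > 1, bias is the excess of the most
#' used codon's within-amino-acid fraction over the uniform expectation 1/k,
#' rescaled to \[0, 1\] by dividing by (1 - 1/k). A 50/50 two-codon amino acid
#' scores 0; complete skew scores 1.
#'
#' @param usage named numeric vector of genome-wide codon usage counts or
#'   frequencies over the sense codons.
#' @param table a [codon_table()].
#' @return data.frame with columns `aa`, `degeneracy`, `max_fraction`, `bias`.
#'   Single-codon amino acids (Met, Trp) are skipped.
#' @export
usage_bias <- function(usage, table = codon_table()) {
  if (any(usage < 0)) stop("usage values must be non-negative")
  rows <- lapply(names(table$aa_to_codons), function(aa) {
    codons <- table$aa_to_codons[[aa]]
    k <- length(codons)
    if (k < 2) return(NULL)
    u <- usage[codons]
    u[is.na(u)] <- 0
    if (sum(u) == 0) return(NULL)
    frac <- u / sum(u)
    data.frame(aa = aa, degeneracy = k, max_fraction = max(frac),
               bias = (max(frac) - 1 / k) / (1 - 1 / k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write two-column codon metric tables
#'
#' Tab-separated tables with a header: CSC tables are `(codon, csc)`, tRNA
#' tables `(anticodon, copies)`, usage tables `(codon, count)`.
#'
#' @param path file path.
#' @return a named numeric vector keyed by the first column.
#' @export
read_metric_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("metric table needs two columns")
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' @rdname read_metric_table
#' @param x named numeric vector to write.
#' @param names_to,values_to header names for the two columns.
#' @export
write_metric_table <- function(x, path, names_to = "codon",
                               values_to = "value") {
  df <- data.frame(a = names(x), b = unname(x))
  names(df) <- c(names_to, values_to)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
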