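#' Canonical variant-table columns
#'
#' Variant tables are plain data.frames with one row per variant-transcript
#' record. Mandatory columns: `chrom`, `pos`, `ref`, `alt`, `ac`
#' (allele count), `an` (allele number), `gene_id`, `transcript_id`,
#' `most_severe_consequence`, `strand`, `context3` (coding-strand
#' trinucleotide centered on the site), `methylation_bin` (0-2),
#' `ref_codon`, `alt_codon`, `codon_index`. Optional score columns:
#' `gerp`, `spliceai_donor_loss`, `spliceai_donor_gain`,
#' `spliceai_acceptor_loss`, `spliceai_acceptor_gain`, `cadd`, `synvep`,
#' `loeuf`, `clinvar_label`. `is_singleton` is derived as `ac == 1`.
#'
#' @return character vector of mandatory column names.
#' @export
variant_columns <- function() {
  c("chrom", "pos", "ref", "alt", "ac", "an", "gene_id", "transcript_id",
    "most_severe_consequence", "strand", "context3", "methylation_bin",
    "ref_codon", "alt_codon", "codon_index")
}

variant_score_columns <- function() {
  c("gerp", "spliceai_donor_loss", "spliceai_donor_gain",
    "spliceai_acceptor_loss", "spliceai_acceptor_gain",
    "cadd", "synvep", "loeuf", "clinvar_label")
}

#' Default consequence severity ordering
#'
#' A VEP-style ordering from most to least severe, used to interpret
#' `most_severe_consequence` strings. Filtering on "synonymous_variant as the
#' most severe consequence" under this ordering excludes missense, pLoF and
#' canonical-splice-disrupting records, and also splice-region-annotated rows;
#' supplying a custom ordering relaxes that.
#'
#' @return character vector of consequence terms, most severe first.
#' @export
vep_severity_order <- function() {
  c("transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
    "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
    "transcript_amplification", "inframe_insertion", "inframe_deletion",
    "missense_variant", "protein_altering_variant",
    "splice_donor_5th_base_variant", "splice_region_variant",
    "splice_donor_region_variant", "splice_polypyrimidine_tract_variant",
    "incomplete_terminal_codon_variant", "start_retained_variant",
    "stop_retained_variant", "synonymous_variant",
    "coding_sequence_variant", "mature_miRNA_variant",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "non_coding_transcript_exon_variant", "intron_variant",
    "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant")
}

# INFO key <-> column mapping for the package's VCF dialect.
vcf_info_map <- function() {
  c(AC = "ac", AN = "an", GENE = "gene_id", TX = "transcript_id",
    CSQ = "most_severe_consequence", STRAND = "strand", CTX = "context3",
    METH = "methylation_bin", RCODON = "ref_codon", ACODON = "alt_codon",
    CIDX = "codon_index", GERP = "gerp", SAI_DL = "spliceai_donor_loss",
    SAI_DG = "spliceai_donor_gain", SAI_AL = "spliceai_acceptor_loss",
    SAI_AG = "spliceai_acceptor_gain", CADD = "cadd", SYNVEP = "synvep",
    LOEUF = "loeuf", CLNSIG = "clinvar_label")
}

#' Read an annotated variant table
#'
#' Reads a flat tab-separated table (one named column per variant field) or a
#' VCF whose INFO field carries the annotations, into the canonical variant
#' data.frame. Rows violating basic invariants (`ac < 1`, `ac > an`,
#' non-single-base ref/alt) are rejected; counts of rejected rows are reported
#' via a message and the `"rejected"` attribute.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return variant data.frame with a derived `is_singleton` column.
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- switch(format, tsv = read_variant_tsv(path), vcf = read_variant_vcf(path))
  missing_cols <- setdiff(variant_columns(), names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  numeric_cols <- intersect(
    c("pos", "ac", "an", "methylation_bin", "codon_index",
      setdiff(variant_score_columns(), "clinvar_label")),
    names(df)
  )
  for (cc in numeric_cols) df[[cc]] <- as.numeric(df[[cc]])
  ok <- !is.na(df$ac) & !is.na(df$an) & df$ac >= 1 & df$ac <= df$an &
    nchar(df$ref) == 1 & nchar(df$alt) == 1 & df$ref != df$alt &
    nchar(df$context3) == 3 &
    substr(df$context3, 2, 2) == df$ref
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(n_bad, " malformed row(s) rejected while reading ", basename(path))
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  df$is_singleton <- df$ac == 1
  attr(df, "rejected") <- n_bad
  df
}

read_variant_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  df <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                   ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  map <- vcf_info_map()
  for (key in names(map)) {
    vals <- vcfR::extract.info(v, element = key)
    if (!all(is.na(vals))) df[[map[[key]]]] <- vals
  }
  df
}

#' Write a variant table
#'
#' Writes the canonical variant data.frame as TSV, or as a VCF v4.2 whose INFO
#' field carries all annotation columns (the dialect [read_variant_table()]
#' reads back).
#'
#' @param variants variant data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  df <- variants[setdiff(names(variants), "is_singleton")]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  map <- vcf_info_map()
  present <- map[map %in% names(df)]
  info <- vapply(seq_len(nrow(df)), function(i) {
    vals <- vapply(unname(present), function(cc) as.character(df[[cc]][i]),
                   character(1))
    keep <- !is.na(vals) & vals != "NA"
    paste(paste0(names(present)[keep], "=", vals[keep]), collapse = ";")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=synsel",
    vapply(names(present), function(key) {
      type <- if (present[[key]] %in% c("ac", "an", "methylation_bin",
                                        "codon_index")) "Integer"
              else if (present[[key]] %in% setdiff(variant_score_columns(),
                                                   "clinvar_label")) "Float"
              else "String"
      sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
              key, type, present[[key]])
    }, character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", info,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter to variants whose most severe consequence is synonymous
#'
#' Keeps records whose `most_severe_consequence` is exactly
#' `"synonymous_variant"`, removing missense, pLoF and
#' splice-site-disrupting SNVs. The filter is idempotent and
#' order-independent.
#'
#' @param variants variant data.frame.
#' @param severity consequence ordering used to validate strings, see
#'   [vep_severity_order()].
#' @param strict if `TRUE` (default) an unknown consequence string is an
#'   error; otherwise unknown rows are dropped with a warning.
#' @return the synonymous subset.
#' @export
filter_synonymous <- function(variants, severity = vep_severity_order(),
                              strict = TRUE) {
  if (nrow(variants) == 0) return(variants)
  known <- variants$most_severe_consequence %in% severity
  if (any(!known)) {
    bad <- unique(variants$most_severe_consequence[!known])
    if (strict)
      stop("unknown consequence string(s): ", paste(bad, collapse = ", "))
    warning("dropping ", sum(!known), " row(s) with unknown consequence: ",
            paste(bad, collapse = ", "))
    variants <- variants[known, , drop = FALSE]
  }
  out <- variants[variants$most_severe_consequence == "synonymous_variant", ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-normalize a trinucleotide context
#'
#' Mutability tables are symmetric under reverse complement, so context keys
#' are stored with a pyrimidine (C/T) middle base: purine-middle contexts are
#' reverse-complemented and the alternate allele complemented accordingly.
#' Codon fields are unaffected (they stay on the coding strand).
#'
#' @param context3 character vector of trinucleotides whose middle base is the
#'   reference allele.
#' @param alt character vector of alternate alleles.
#' @return data.frame with normalized `context3` and `alt`.
#' @export
normalize_context <- function(context3, alt) {
  flip <- substr(context3, 2, 2) %in% c("A", "G")
  context3[flip] <- revcomp(context3[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  data.frame(context3 = context3, alt = alt, stringsAsFactors = FALSE)
}

#' Mutational class of a context/alternate pair
#'
#' Every possible (trinucleotide, alternate allele) pair falls in exactly one
#' of three classes: CpG transition (C>T with a 3' G), non-CpG transition, or
#' transversion.
#'
#' @param context3,alt vectors as in [normalize_context()] (normalized
#'   internally).
#' @return character vector of class labels.
#' @export
context_class <- function(context3, alt) {
  norm <- normalize_context(context3, alt)
  ref <- substr(norm$context3, 2, 2)
  third <- substr(norm$context3, 3, 3)
  transition <- (ref == "C" & norm$alt == "T") | (ref == "T" & norm$alt == "C")
  cpg <- ref == "C" & norm$alt == "T" & third == "G"
  out <- rep("transversion", length(ref))
  out[transition] <- "non-CpG transition"
  out[cpg] <- "CpG transition"
  out
}

context_key <- function(context3, alt, methylation_bin) {
  norm <- normalize_context(context3, alt)
  paste0(norm$context3, ">", norm$alt, "|", methylation_bin)
}

#' Attach mutational context class and mutability to variants
#'
#' Looks up each variant's strand-normalized (context, alt, methylation bin)
#' key in the mutability table and attaches the key, class label and relative
#' mutation rate `mu`.
#'
#' @param variants variant data.frame.
#' @param mut_table mutability table: data.frame with columns `context3`,
#'   `alt`, `methylation_bin`, `mu` (all `mu > 0`), keys unique and
#'   pyrimidine-middle.
#' @return `variants` with `context_key`, `context_class` and `mu` columns.
#' @export
assign_context <- function(variants, mut_table) {
  stopifnot(all(c("context3", "alt", "methylation_bin", "mu") %in%
                  names(mut_table)))
  if (any(mut_table$mu <= 0)) stop("mutability values must be positive")
  keys <- context_key(mut_table$context3, mut_table$alt,
                      mut_table$methylation_bin)
  if (anyDuplicated(keys)) stop("duplicate keys in mutability table")
  vk <- context_key(variants$context3, variants$alt, variants$methylation_bin)
  idx <- match(vk, keys)
  if (anyNA(idx)) {
    missing_keys <- unique(vk[is.na(idx)])
    stop("context key(s) absent from mutability table: ",
         paste(utils::head(missing_keys, 5), collapse = ", "))
  }
  variants$context_key <- vk
  variants$context_class <- context_class(variants$context3, variants$alt)
  variants$mu <- mut_table$mu[idx]
  variants
}

#' Attach codon-level optimality annotations to variants
#'
#' Joins the per-substitution deltas (CSC, tAI, GC, degeneracy, optimality
#' label) onto each variant by its (ref codon, alt codon) pair. Rows whose
#' codon pair is not a single-base synonymous change are rejected with a
#' message. The operation is idempotent.
#'
#' @param variants variant data.frame.
#' @param csc,tai named per-codon metric vectors.
#' @param table a [codon_table()].
#' @return annotated variants with columns `aa`, `degeneracy`, `delta_csc`,
#'   `delta_tai`, `delta_gc`, `optimality`.
#' @export
attach_codon_annotations <- function(variants, csc, tai,
                                     table = codon_table()) {
  universe <- enumerate_synonymous_changes(table)
  universe$delta_csc <- unname(csc[universe$alt_codon] -
                                 csc[universe$ref_codon])
  universe$delta_tai <- unname(tai[universe$alt_codon] -
                                 tai[universe$ref_codon])
  universe$delta_gc <- gc_count(universe$alt_codon) -
    gc_count(universe$ref_codon)
  universe$optimality <- classify_optimality(universe$delta_csc)
  pair <- paste(variants$ref_codon, variants$alt_codon)
  idx <- match(pair, paste(universe$ref_codon, universe$alt_codon))
  if (anyNA(idx))
    message(sum(is.na(idx)),
            " row(s) with non-synonymous codon pairs rejected")
  variants <- variants[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  for (cc in c("aa", "degeneracy", "delta_csc", "delta_tai", "delta_gc",
               "optimality"))
    variants[[cc]] <- universe[[cc]][idx]
  rownames(variants) <- NULL
  variants
}

#' Read or write a mutability table
#'
#' Tab-separated with header columns `context3`, `alt`, `methylation_bin`,
#' `mu`; keys are strand-normalized (pyrimidine middle base).
#'
#' @param path file path.
#' @return the mutability data.frame.
#' @export
read_mutability_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("context3", "alt", "methylation_bin", "mu")
  if (!all(need %in% names(df)))
    stop("mutability table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_mutability_table
#' @param mut_table mutability data.frame to write.
#' @export
write_mutability_table <- function(mut_table, path) {
  utils::write.table(mut_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
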