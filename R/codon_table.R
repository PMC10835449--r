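.synsel_cache <- new.env(parent = emptyenv())

#' The standard genetic code as a codon table
#'
#' Builds the codon table used throughout the package: the 61 sense codons and
#' 3 stop codons of the standard nuclear code, the codon-to-amino-acid map, and
#' the per-amino-acid codon sets from which degeneracy is derived.
#'
#' @return An object of class `codon_table`: a list with
#'   \item{codon_to_aa}{named character vector over all 64 codons; stops are `"*"`.}
#'   \item{aa_to_codons}{named list mapping each amino acid (one-letter code) to
#'     its codon set.}
#'   \item{sense_codons}{character vector of the 61 sense codons.}
#'   \item{degeneracy}{named integer vector: number of codons per amino acid.}
#' @examples
#' ct <- codon_table()
#' ct$degeneracy[["H"]]  # histidine: CAT, CAC
#' @export
codon_table <- function() {
  if (!is.null(.synsel_cache$table)) return(.synsel_cache$table)
  code <- Biostrings::GENETIC_CODE
  codon_to_aa <- as.character(code)
  names(codon_to_aa) <- names(code)
  sense <- names(codon_to_aa)[codon_to_aa != "*"]
  aa_to_codons <- split(names(codon_to_aa), codon_to_aa)
  aa_to_codons <- aa_to_codons[names(aa_to_codons) != "*"]
  out <- structure(
    list(
      codon_to_aa = codon_to_aa,
      aa_to_codons = aa_to_codons,
      sense_codons = sense,
      degeneracy = vapply(aa_to_codons, length, integer(1))
    ),
    class = "codon_table"
  )
  .synsel_cache$table <- out
  out
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  n <- nchar(comp)
  if (all(n == 3))  # fast path for codons/trinucleotide contexts
    return(paste0(substr(comp, 3, 3), substr(comp, 2, 2),
                  substr(comp, 1, 1)))
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""),
         character(1))
}

#' Enumerate all single-base synonymous codon changes
#'
#' Lists every (ref codon, position, alternate base) combination that swaps a
#' sense codon for a different codon encoding the same amino acid. Stop-to-stop
#' changes are excluded. This set is the universe of possible synonymous SNVs
#' at the codon level.
#'
#' @param table a [codon_table()].
#' @return A data.frame with columns `ref_codon`, `pos` (0-based position in
#'   the codon), `alt_base`, `alt_codon`, `aa`, `degeneracy`. Exhaustive and
#'   duplicate-free.
#' @examples
#' ch <- enumerate_synonymous_changes(codon_table())
#' subset(ch, ref_codon == "CAT")  # histidine CAT -> CAC only
#' @export
enumerate_synonymous_changes <- function(table = codon_table()) {
  default <- identical(table, codon_table())
  if (default && !is.null(.synsel_cache$changes)) return(.synsel_cache$changes)
  out <- list()
  for (codon in table$sense_codons) {
    aa <- table$codon_to_aa[[codon]]
    bases <- strsplit(codon, "")[[1]]
    for (pos in 0:2) {
      for (alt in setdiff(DNA_BASES, bases[pos + 1])) {
        alt_bases <- bases
        alt_bases[pos + 1] <- alt
        alt_codon <- paste(alt_bases, collapse = "")
        if (identical(table$codon_to_aa[[alt_codon]], aa)) {
          out[[length(out) + 1]] <- data.frame(
            ref_codon = codon, pos = pos, alt_base = alt,
            alt_codon = alt_codon, aa = aa,
            degeneracy = unname(table$degeneracy[[aa]]),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (default) .synsel_cache$changes <- res
  res
}

#' Count G/C bases of codons
#'
#' @param codon character vector of codons.
#' @return integer vector of G+C counts (0-3).
#' @export
gc_count <- function(codon) {
  nchar(codon) - nchar(gsub("[GC]", "", codon))
}
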