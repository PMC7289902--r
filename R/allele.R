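# Deterministic sequence arithmetic for a CRISPR dropout allele: genotyping
# amplicon sizes, frameshift translation to the premature stop, and the
# predicted mass of the truncated product.

# Average (not monoisotopic) residue masses in Da, i.e. amino acid masses
# less one water, as used by common protein MW calculators. Source:
# standard IUPAC average atomic weights.
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.0153

#' Genotyping amplicon length of a deletion allele
#'
#' The mutant PCR product of a clean dropout allele is the wild-type
#' amplicon shortened by the deletion; e.g. a 176 bp deletion turns a 624 bp
#' wild-type product into a 448 bp mutant amplicon. The deletion must lie
#' strictly inside the amplified span, otherwise a primer site is lost and
#' no product of predictable size exists.
#'
#' @param wt_amplicon Wild-type product length in bp (positive integer).
#' @param deletion Deleted span in bp (`0 <= deletion < wt_amplicon`).
#' @return Mutant amplicon length in bp.
#' @examples
#' amplicon_length(624, 176)  # 448
#' @export
amplicon_length <- function(wt_amplicon, deletion) {
  if (!is_count(wt_amplicon) || wt_amplicon <= 0) {
    stopf("`wt_amplicon` must be a positive integer length in bp")
  }
  if (!is_count(deletion)) {
    stopf("`deletion` must be a non-negative integer length in bp")
  }
  if (deletion >= wt_amplicon) {
    stopf("deletion (%d bp) spans the whole %d bp amplicon: primer site lost",
          deletion, wt_amplicon)
  }
  wt_amplicon - deletion
}

#' Predict the truncated product of a coding-sequence deletion
#'
#' Applies a clean dropout deletion to a reference CDS and translates from
#' the original ATG to the first in-frame stop codon (standard genetic
#' code). A deletion whose length is not a multiple of 3 shifts the reading
#' frame, typically creating a premature stop; the count of residues
#' translated before that stop and the average mass of the predicted
#' product are returned.
#'
#' @param cds Reference coding sequence: a character string (or
#'   [Biostrings::DNAString]) of A/C/G/T, length divisible by 3, starting
#'   with ATG and ending with a stop codon.
#' @param del_start,del_end Deletion interval within the CDS, 0-based
#'   half-open.
#' @return A list of class `truncation_prediction`: `residues` (count before
#'   the first stop, excluding it), `peptide`, `mass_da`, `frameshift`
#'   (deletion length not a multiple of 3), `runs_through` (no stop reached
#'   before the sequence ends), `start_lost` (deletion removed part of the
#'   start codon; all other fields `NA`).
#' @examples
#' # deleting codon 2 of ATG-AAA-TAA leaves ATG-TAA: one residue (Met)
#' predict_truncation("ATGAAATAA", 3, 6)
#' @export
predict_truncation <- function(cds, del_start, del_end) {
  cds <- toupper(as.character(cds))
  if (length(cds) != 1 || !grepl("^[ACGT]+$", cds)) {
    stopf("`cds` must be a single A/C/G/T nucleotide string")
  }
  n <- nchar(cds)
  if (n %% 3 != 0) stopf("`cds` length (%d) is not a multiple of 3", n)
  if (substr(cds, 1, 3) != "ATG") stopf("`cds` must start with ATG")
  code <- Biostrings::GENETIC_CODE
  last <- substr(cds, n - 2, n)
  if (code[[last]] != "*") stopf("`cds` must end with a stop codon")
  if (!is_count(del_start) || !is_count(del_end) ||
      del_start >= del_end || del_end > n) {
    stopf("deletion must satisfy 0 <= start < end <= CDS length")
  }
  del_len <- del_end - del_start
  if (del_start < 3) {
    return(structure(
      list(residues = NA_integer_, peptide = NA_character_,
           mass_da = NA_real_, frameshift = del_len %% 3 != 0,
           runs_through = FALSE, start_lost = TRUE),
      class = "truncation_prediction"
    ))
  }
  mutant <- paste0(substr(cds, 1, del_start),
                   substr(cds, del_end + 1, n))
  n_codon <- nchar(mutant) %/% 3  # trailing partial codon never translates
  codons <- substring(mutant, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aas <- unname(code[codons])
  stop_at <- which(aas == "*")
  runs_through <- length(stop_at) == 0
  peptide <- if (runs_through) paste(aas, collapse = "") else
    paste(aas[seq_len(stop_at[1] - 1)], collapse = "")
  structure(
    list(residues = nchar(peptide), peptide = peptide,
         mass_da = protein_mass(peptide),
         frameshift = del_len %% 3 != 0,
         runs_through = runs_through, start_lost = FALSE),
    class = "truncation_prediction"
  )
}

#' @export
print.truncation_prediction <- function(x, ...) {
  if (isTRUE(x$start_lost)) {
    cat("truncation prediction: start codon lost; no product predicted\n")
    return(invisible(x))
  }
  cat(sprintf(
    "truncation prediction: %d residue(s), %.1f Da (%.1f kDa)%s%s\n",
    x$residues, x$mass_da, x$mass_da / 1000,
    if (x$frameshift) ", frameshifted" else ", in frame",
    if (x$runs_through) ", no stop reached (runs through)" else ""
  ))
  invisible(x)
}

#' Average molecular mass of a peptide
#'
#' Sum of standard average residue masses plus one water (18.02 Da); the
#' empty chain therefore weighs one water. Matches the convention of common
#' protein MW calculators (average, not monoisotopic, masses).
#'
#' @param residues One-letter amino acid string drawn from the 20 standard
#'   residues (case-insensitive). May be empty.
#' @return Mass in Da.
#' @examples
#' protein_mass("G")  # 75.07 (glycine)
#' @export
protein_mass <- function(residues) {
  if (length(residues) != 1 || !is.character(residues) || is.na(residues)) {
    stopf("`residues` must be a single character string")
  }
  if (nchar(residues) == 0) return(WATER_MASS)
  aa <- strsplit(toupper(residues), "")[[1]]
  m <- AA_RESIDUE_MASS[aa]
  if (anyNA(m)) {
    stopf("unknown residue '%s' at position %d",
          aa[which(is.na(m))[1]], which(is.na(m))[1])
  }
  sum(m) + WATER_MASS
}
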