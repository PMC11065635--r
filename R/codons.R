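# Codon-level vocabulary: the 61 sense codons, the stop codons, amino-acid
# assignments, and the Watson-Crick anticodon -> cognate codon map.

#' The 61 sense codons
#'
#' Codons of the standard genetic code excluding the three stop codons
#' (TAA, TAG, TGA), in alphabetical order. This fixed ordering is used for
#' every codon-usage vector in the package.
#'
#' @return character vector of 61 codons.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' The three stop codons
#' @return character vector \code{c("TAA", "TAG", "TGA")}.
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

#' Codon table with amino-acid assignments
#'
#' @return data.frame with columns \code{codon}, \code{amino_acid} (one-letter)
#'   and \code{amino_acid3} (three-letter) over the 61 sense codons.
#' @export
codon_table <- function() {
  codons <- sense_codons()
  aa1 <- unname(Biostrings::GENETIC_CODE[codons])
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
             E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
             M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
             Y = "Tyr", V = "Val")
  data.frame(codon = codons, amino_acid = aa1,
             amino_acid3 = unname(three[aa1]),
             stringsAsFactors = FALSE)
}

#' Cognate codon of an anticodon
#'
#' Maps a tRNA anticodon to the codon it decodes by exact Watson-Crick
#' pairing: the reverse complement. This is the only notion of "cognate" the
#' package uses; wobble decoding is never inferred.
#'
#' @param anticodon character vector of 3-mers over \{A, C, G, T\}.
#' @return character vector of cognate codons.
#' @export
#' @examples
#' anticodon_to_codon("TAT")  # "ATA", decoded by Ile-TAT tRNAs
#' anticodon_to_codon("TCT")  # "AGA", decoded by Arg-TCT tRNAs
anticodon_to_codon <- function(anticodon) {
  anticodon <- toupper(anticodon)
  bad <- !grepl("^[ACGT]{3}$", anticodon)
  fail_if(any(bad), "invalid anticodon(s): %s",
          paste(anticodon[bad], collapse = ", "))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(anticodon)))
}
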