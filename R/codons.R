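#' Degenerate codons
#'
#' A degenerate codon is a three-letter IUPAC DNA string (e.g. `"NNK"`)
#' standing for the set of concrete codons obtained by expanding each
#' position, every allowed base being equiprobable. `NNK` (N = A/C/G/T,
#' K = G/T) expands to 32 codons covering all 20 amino acids with a single
#' stop (amber, TAG); it is the workhorse scheme for monobody loop
#' diversification.
#'
#' @slot iupac three-letter IUPAC DNA string.
#' @name DegenerateCodon-class
#' @aliases DegenerateCodon
#' @exportClass DegenerateCodon
setClass("DegenerateCodon", representation(iupac = "character"))

.IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

setValidity("DegenerateCodon", function(object) {
  s <- object@iupac
  if (length(s) != 1L || is.na(s)) return("'iupac' must be a single string")
  if (nchar(s) != 3L) return("a codon has exactly three letters")
  letters3 <- strsplit(toupper(s), "")[[1]]
  if (!all(letters3 %in% names(.IUPAC_DNA)))
    return(sprintf("non-IUPAC character in codon '%s'", s))
  TRUE
})

#' Construct a degenerate codon
#'
#' @param iupac three-letter IUPAC DNA string, e.g. `"NNK"`.
#' @return A [DegenerateCodon-class] object.
#' @examples
#' degenerateCodon("NNK")
#' @export
degenerateCodon <- function(iupac) {
  new("DegenerateCodon", iupac = toupper(as.character(iupac)))
}

setMethod("show", "DegenerateCodon", function(object) {
  exp <- expandDegenerateCodon(object)
  cat(sprintf("DegenerateCodon %s (%d concrete codons)\n",
              object@iupac, nrow(exp)))
})

#' Expand a degenerate codon into concrete codons
#'
#' Enumerates every concrete codon compatible with the IUPAC pattern. Each
#' position contributes its allowed bases with equal probability, so each
#' concrete codon has probability `1 / (product of per-position degeneracies)`.
#'
#' @param codon a [DegenerateCodon-class] or a three-letter IUPAC string.
#' @return A data.frame with columns `codon` and `probability`
#'   (probabilities sum to 1).
#' @examples
#' nrow(expandDegenerateCodon("NNK"))  # 32
#' @export
expandDegenerateCodon <- function(codon) {
  if (!is(codon, "DegenerateCodon")) codon <- degenerateCodon(codon)
  validObject(codon)
  pos <- lapply(strsplit(codon@iupac, "")[[1]], function(ch) .IUPAC_DNA[[ch]])
  grid <- expand.grid(pos[[3]], pos[[2]], pos[[1]],
                      stringsAsFactors = FALSE)
  codons <- paste0(grid[[3]], grid[[2]], grid[[1]])
  codons <- sort(codons)
  data.frame(codon = codons,
             probability = rep(1 / length(codons), length(codons)),
             stringsAsFactors = FALSE)
}

#' Amino-acid distribution of a degenerate codon
#'
#' Translates every concrete codon in the expansion with the standard genetic
#' code (NCBI table 1) and accumulates probabilities per amino acid. The stop
#' is reported under `"*"`; for `NNK` only the amber codon TAG contributes,
#' giving a stop probability of 1/32. Amber suppression can be assumed with
#' `suppressAmber = TRUE`, which reassigns TAG to glutamine (supE-style
#' suppressor hosts); design math keeps it off because in-loop stops are
#' treated as invalid downstream.
#'
#' @inheritParams expandDegenerateCodon
#' @param suppressAmber logical; count amber TAG as Gln instead of stop.
#' @return Named numeric vector of probabilities over amino acids (and `"*"`),
#'   summing to 1.
#' @examples
#' aaDistribution("NNK")["*"]  # 1/32
#' @export
aaDistribution <- function(codon, suppressAmber = FALSE) {
  exp <- expandDegenerateCodon(codon)
  aa <- vapply(exp$codon, function(cd) {
    if (suppressAmber && cd == "TAG") return("Q")
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, character(1))
  out <- tapply(exp$probability, aa, sum)
  out <- setNames(as.numeric(out), names(out))
  out[order(names(out))]
}
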