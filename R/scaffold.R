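#' Scaffold template for a displayed cassette
#'
#' Reference definition of the phagemid display cassette: the cassette DNA,
#' its translation, the reading-frame offset, per-loop fixed flanking anchors
#' (with the wild-type coordinates of the variable stretch they bracket), and
#' the restriction sites a functional clone must carry.
#'
#' @slot name scaffold name.
#' @slot dna reference cassette DNA (character, A/C/G/T).
#' @slot protein reference translation of the coding region.
#' @slot frameOffset 0-based nucleotide offset of codon 1 within `dna`.
#' @slot loops named list; per loop a list with `anchor5`, `anchor3`
#'   (fixed flank subsequences, each occurring exactly once in `dna`),
#'   `wtStartCodon` (1-based codon index, wild-type numbering, of the first
#'   variable codon) and `wtLength` (codon count of the wild-type stretch).
#' @slot requiredSites named character vector of restriction-site recognition
#'   sequences (e.g. HindIII, BamHI, NotI, KpnI).
#' @name ScaffoldTemplate-class
#' @aliases ScaffoldTemplate
#' @exportClass ScaffoldTemplate
setClass("ScaffoldTemplate", representation(
  name = "character", dna = "character", protein = "character",
  frameOffset = "integer", loops = "list", requiredSites = "character"))

setValidity("ScaffoldTemplate", function(object) {
  msg <- character(0)
  dna <- object@dna
  if (grepl("[^ACGT]", dna)) msg <- c(msg, "scaffold dna must be A/C/G/T only")
  for (id in names(object@loops)) {
    lp <- object@loops[[id]]
    for (a in c("anchor5", "anchor3")) {
      n <- length(gregexpr(lp[[a]], dna, fixed = TRUE)[[1]])
      if (n != 1L || regexpr(lp[[a]], dna, fixed = TRUE) < 0)
        msg <- c(msg, sprintf("loop %s %s must occur exactly once", id, a))
    }
  }
  ncod <- (nchar(dna) - object@frameOffset) %/% 3
  cds <- substr(dna, object@frameOffset + 1L, object@frameOffset + 3L * ncod)
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  if (substr(tr, 1, nchar(object@protein)) != object@protein)
    msg <- c(msg, "translation of dna does not match 'protein'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScaffoldTemplate", function(object) {
  cat(sprintf("ScaffoldTemplate '%s': %d nt, %d aa, %d loop(s) [%s], %d sites\n",
              object@name, nchar(object@dna), nchar(object@protein),
              length(object@loops), paste(names(object@loops), collapse = ", "),
              length(object@requiredSites)))
})

#' @describeIn ScaffoldTemplate-class loop definitions.
#' @param x a `ScaffoldTemplate`.
#' @export
scaffoldLoops <- function(x) x@loops

#' @describeIn ScaffoldTemplate-class required restriction sites.
#' @export
requiredSites <- function(x) x@requiredSites

# preferred E. coli codon per amino acid, used to reverse-translate the
# reference protein into a concrete cassette
.CODON_PREF <- c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                 M = "ATG", N = "AAT", P = "CCG", Q = "CAG", R = "CGT",
                 S = "AGC", T = "ACC", V = "GTT", W = "TGG", Y = "TAT")

# wild-type tenth FN3 domain protein (1FNA numbering, 94 residues)
.FN3_WT <- paste0(
  "VSDVPRDLEVVAATPTSLLISWDAPAVTVRYYRITYGETGGNSPVQEFTVPGSKSTATISGLKPGVDYTI",
  "TVYAVTGRGDSPASSKPISINYRT")

#' Synthetic tenth-FN3 display cassette
#'
#' Builds the default scaffold template used throughout the package: the
#' wild-type tenth fibronectin type III domain (1FNA numbering, 94 residues)
#' reverse-translated with common E. coli codons and flanked by
#' HindIII/BamHI (5') and NotI/KpnI (3') restriction sites, mirroring the
#' layout of a monobody phagemid cassette. The BC loop variable stretch
#' occupies wild-type codons 25-29 and the FG stretch codons 75-81; the fixed
#' 18-nt flanks on either side serve as orientation/frame anchors.
#'
#' This cassette is a synthetic stand-in constructed in code (no deposited
#' cassette sequence is available); clones generated by
#' [genLibraryReads()] and validated by [validateClone()] both use it.
#'
#' @return A [ScaffoldTemplate-class].
#' @examples
#' fn3Scaffold()
#' @export
fn3Scaffold <- function() {
  aa <- strsplit(.FN3_WT, "")[[1]]
  cds <- paste(.CODON_PREF[aa], collapse = "")
  lead <- "AAGCTTGGATCCACC"                      # HindIII + BamHI + spacer
  trail <- "GCGGCCGCTGGTACCAA"                   # NotI + spacer + KpnI
  dna <- paste0(lead, cds, trail)
  frameOffset <- nchar(lead)
  codon_nt <- function(i) substr(dna, frameOffset + 3L * (i - 1L) + 1L,
                                 frameOffset + 3L * i)
  span_nt <- function(from, to) paste(vapply(from:to, codon_nt, character(1)),
                                      collapse = "")
  loops <- list(
    BC = list(anchor5 = span_nt(19, 24), anchor3 = span_nt(30, 35),
              wtStartCodon = 25L, wtLength = 5L),
    FG = list(anchor5 = span_nt(69, 74), anchor3 = span_nt(82, 87),
              wtStartCodon = 75L, wtLength = 7L))
  sites <- c(HindIII = "AAGCTT", BamHI = "GGATCC",
             NotI = "GCGGCCGC", KpnI = "GGTACC")
  obj <- new("ScaffoldTemplate", name = "fn3-synthetic", dna = dna,
             protein = .FN3_WT, frameOffset = as.integer(frameOffset),
             loops = loops, requiredSites = sites)
  validObject(obj)
  obj
}

#' Read/write a scaffold template as JSON
#'
#' @param x a [ScaffoldTemplate-class].
#' @param path file path.
#' @return `readScaffoldTemplate` returns a `ScaffoldTemplate`;
#'   `writeScaffoldTemplate` returns `path` invisibly.
#' @export
writeScaffoldTemplate <- function(x, path) {
  stopifnot(is(x, "ScaffoldTemplate"))
  obj <- list(name = x@name, dna = x@dna, protein = x@protein,
              frame_offset = x@frameOffset, loops = x@loops,
              required_sites = as.list(x@requiredSites))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeScaffoldTemplate
#' @export
readScaffoldTemplate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loops <- lapply(obj$loops, function(lp)
    list(anchor5 = lp$anchor5, anchor3 = lp$anchor3,
         wtStartCodon = as.integer(lp$wtStartCodon),
         wtLength = as.integer(lp$wtLength)))
  out <- new("ScaffoldTemplate", name = obj$name, dna = obj$dna,
             protein = obj$protein, frameOffset = as.integer(obj$frame_offset),
             loops = loops, requiredSites = unlist(obj$required_sites))
  validObject(out)
  out
}
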