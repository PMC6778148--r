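#' @include codons.R scaffold.R
NULL

#' Loop diversification design
#'
#' One diversified loop: where it sits on the scaffold (1-based codon index,
#' wild-type numbering, of the first variable codon), the inclusive range of
#' loop lengths to build, and the degenerate codon scheme used at every
#' variable position.
#'
#' @slot loopId loop name, e.g. `"BC"` or `"FG"`.
#' @slot anchorCodon 1-based codon index of the first variable codon.
#' @slot lengthRange inclusive `c(min, max)` codon counts.
#' @slot codonScheme a [DegenerateCodon-class].
#' @name LoopDesign-class
#' @aliases LoopDesign
#' @exportClass LoopDesign
setClass("LoopDesign", representation(
  loopId = "character", anchorCodon = "integer", lengthRange = "integer",
  codonScheme = "DegenerateCodon"))

setValidity("LoopDesign", function(object) {
  r <- object@lengthRange
  if (length(r) != 2L || r[1] < 1L || r[1] > r[2])
    return("lengthRange must be c(min, max) with 1 <= min <= max")
  TRUE
})

#' @param loopId,anchorCodon,lengthRange,codonScheme see slots.
#' @rdname LoopDesign-class
#' @export
loopDesign <- function(loopId, anchorCodon, lengthRange, codonScheme = "NNK") {
  if (!is(codonScheme, "DegenerateCodon"))
    codonScheme <- degenerateCodon(codonScheme)
  obj <- new("LoopDesign", loopId = loopId,
             anchorCodon = as.integer(anchorCodon),
             lengthRange = as.integer(lengthRange), codonScheme = codonScheme)
  validObject(obj)
  obj
}

#' Library design
#'
#' A full combinatorial library design: a scaffold plus one or more
#' non-overlapping loop designs. The default [fn3LibraryDesign()] reproduces
#' the published scheme: 5-9 NNK codons at position 25 (BC loop) and 7-13 NNK
#' codons at position 75 (FG loop) of the wild-type tenth-FN3 numbering.
#'
#' @slot scaffold a [ScaffoldTemplate-class].
#' @slot loops list of [LoopDesign-class].
#' @slot translationTableId NCBI translation table (only 1 supported).
#' @name LibraryDesign-class
#' @aliases LibraryDesign
#' @exportClass LibraryDesign
setClass("LibraryDesign", representation(
  scaffold = "ScaffoldTemplate", loops = "list",
  translationTableId = "integer"))

setValidity("LibraryDesign", function(object) {
  if (length(object@loops) < 1L) return("at least one loop required")
  if (!all(vapply(object@loops, is, logical(1), "LoopDesign")))
    return("loops must all be LoopDesign objects")
  anchors <- vapply(object@loops, function(l) l@anchorCodon, integer(1))
  if (anyDuplicated(anchors)) return("loop anchors must differ")
  TRUE
})

#' @param scaffold,loops,translationTableId see slots.
#' @rdname LibraryDesign-class
#' @export
libraryDesign <- function(scaffold, loops, translationTableId = 1L) {
  obj <- new("LibraryDesign", scaffold = scaffold, loops = loops,
             translationTableId = as.integer(translationTableId))
  validObject(obj)
  obj
}

#' @rdname LibraryDesign-class
#' @export
fn3LibraryDesign <- function(scaffold = fn3Scaffold()) {
  libraryDesign(scaffold, list(
    loopDesign("BC", 25L, c(5L, 9L), "NNK"),
    loopDesign("FG", 75L, c(7L, 13L), "NNK")))
}

setMethod("show", "LibraryDesign", function(object) {
  cat(sprintf("LibraryDesign on '%s' with %d loop(s):\n",
              object@scaffold@name, length(object@loops)))
  for (lp in object@loops)
    cat(sprintf("  %s: %d-%d x %s at codon %d\n", lp@loopId,
                lp@lengthRange[1], lp@lengthRange[2],
                lp@codonScheme@iupac, lp@anchorCodon))
})

#' Mutagenic oligonucleotides for one loop design
#'
#' Produces one oligo specification per loop length: a 5' fixed flank of
#' `flankLen` scaffold codons, `L` copies of the degenerate codon (IUPAC
#' letters preserved), and a 3' fixed flank of `flankLen` codons, all in the
#' scaffold reading frame. A 5-9 codon range yields five oligos; 7-13 yields
#' seven, matching the published oligo sets.
#'
#' @param design a [LoopDesign-class].
#' @param scaffold a [ScaffoldTemplate-class].
#' @param flankLen fixed-flank length in codons (default 6).
#' @return data.frame with columns `name`, `loop_id`, `n_random_codons`,
#'   `oligo` (IUPAC DNA string).
#' @examples
#' nrow(designLoopOligos(loopDesign("BC", 25, c(5, 9)), fn3Scaffold()))  # 5
#' @export
designLoopOligos <- function(design, scaffold, flankLen = 6L) {
  stopifnot(is(design, "LoopDesign"), is(scaffold, "ScaffoldTemplate"))
  flankLen <- as.integer(flankLen)
  lp <- scaffold@loops[[design@loopId]]
  if (is.null(lp))
    stop(sprintf("scaffold has no loop '%s'", design@loopId), call. = FALSE)
  if (lp$wtStartCodon != design@anchorCodon)
    stop("design anchor codon does not match scaffold loop position",
         call. = FALSE)
  ncodons <- (nchar(scaffold@dna) - scaffold@frameOffset) %/% 3L
  first5 <- design@anchorCodon - flankLen
  last3 <- design@anchorCodon + lp$wtLength - 1L + flankLen
  if (first5 < 1L || last3 > ncodons)
    stop("anchor/flank outside scaffold", call. = FALSE)
  codon_nt <- function(i) substr(scaffold@dna,
                                 scaffold@frameOffset + 3L * (i - 1L) + 1L,
                                 scaffold@frameOffset + 3L * i)
  flank5 <- paste(vapply(first5:(design@anchorCodon - 1L), codon_nt,
                         character(1)), collapse = "")
  flank3 <- paste(vapply((design@anchorCodon + lp$wtLength):last3, codon_nt,
                         character(1)), collapse = "")
  lens <- design@lengthRange[1]:design@lengthRange[2]
  data.frame(
    name = sprintf("%s_%02dx%s", design@loopId, lens,
                   design@codonScheme@iupac),
    loop_id = design@loopId,
    n_random_codons = lens,
    oligo = vapply(lens, function(L) paste0(
      flank5, strrep(design@codonScheme@iupac, L), flank3), character(1)),
    stringsAsFactors = FALSE)
}

#' Write oligo specifications as FASTA
#'
#' @param oligos data.frame from [designLoopOligos()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeOligoFasta <- function(oligos, path) {
  set <- Biostrings::DNAStringSet(oligos$oligo)
  names(set) <- oligos$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Exact theoretical diversity of a library design
#'
#' Counts the variants a design encodes: within each loop, the sum over its
#' length range of per-length variant counts; across loops, the product. At
#' the DNA level each degenerate codon contributes its expansion size (32 for
#' NNK); at the protein level it contributes the number of distinct encoded
#' residues (20 for NNK when `stopFree`, since only amber TAG is lost).
#' Counts are computed in exact integer arithmetic (they exceed 2^53 for the
#' full design) and returned as a decimal string with log10 alongside.
#'
#' @param design a [LibraryDesign-class].
#' @param level `"dna"` or `"protein"`.
#' @param stopFree exclude stop-containing variants (protein level).
#' @return list with `count` (decimal string) and `log10` (numeric).
#' @examples
#' theoreticalDiversity(fn3LibraryDesign())$log10  # ~ 33.1
#' @export
theoreticalDiversity <- function(design, level = c("dna", "protein"),
                                 stopFree = FALSE) {
  stopifnot(is(design, "LibraryDesign"))
  level <- match.arg(level)
  per_loop <- lapply(design@loops, function(lp) {
    if (level == "dna") {
      k <- nrow(expandDegenerateCodon(lp@codonScheme))
    } else {
      dist <- aaDistribution(lp@codonScheme)
      sym <- names(dist)[dist > 0]
      if (stopFree) sym <- setdiff(sym, "*")
      k <- length(sym)
    }
    tot <- big_from_int(0)
    for (L in lp@lengthRange[1]:lp@lengthRange[2])
      tot <- big_add(tot, big_pow(k, L))
    tot
  })
  out <- Reduce(big_mul, per_loop)
  list(count = big_to_string(out), log10 = big_log10(out))
}

#' Fraction of library variants free of stop codons
#'
#' Product over all diversified codons of (1 - per-codon stop probability),
#' averaged over loop-length combinations with equal weights (the mutagenic
#' oligos are mixed equimolar). For NNK the per-codon stop probability is
#' 1/32 (amber TAG).
#'
#' @param design a [LibraryDesign-class].
#' @return probability in (0, 1].
#' @examples
#' stopFreeFraction(fn3LibraryDesign())
#' @export
stopFreeFraction <- function(design) {
  stopifnot(is(design, "LibraryDesign"))
  # equal length weights + independent loops: the combination average
  # factorizes into per-loop means
  means <- vapply(design@loops, function(lp) {
    dist <- aaDistribution(lp@codonScheme)
    p_stop <- if ("*" %in% names(dist)) unname(dist["*"]) else 0
    lens <- lp@lengthRange[1]:lp@lengthRange[2]
    mean((1 - p_stop)^lens)
  }, numeric(1))
  prod(means)
}

#' Collision-based lower bound on library diversity
#'
#' Birthday-problem lower confidence bound on the number of distinct clones
#' in a library, from the number of pairwise sequence collisions observed
#' among `nSampled` randomly picked colonies under uniform sampling: the
#' smallest diversity `D` at which observing `nCollisions` or fewer colliding
#' pairs has probability at least `1 - confidence`. With zero collisions the
#' exact product formula `P = prod_{i=0}^{n-1}(1 - i/D)` is solved for `D`;
#' with collisions a Poisson model on the `choose(n, 2)` pairs is used.
#'
#' @param nSampled number of sequenced colonies.
#' @param nCollisions number of colliding (identical-sequence) pairs.
#' @param confidence confidence level in (0, 1).
#' @return integer-valued lower bound on the distinct-clone count.
#' @examples
#' collisionDiversityBound(96, 0, 0.95)
#' @export
collisionDiversityBound <- function(nSampled, nCollisions, confidence = 0.95) {
  assert_scalar_number(nSampled, "nSampled", lower = 1)
  assert_scalar_number(nCollisions, "nCollisions", lower = 0)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1)
    stop("'confidence' must be in (0, 1)", call. = FALSE)
  n <- as.numeric(nSampled)
  npairs <- n * (n - 1) / 2
  if (nCollisions >= npairs) return(1)
  alpha <- 1 - confidence
  if (nCollisions == 0) {
    logp <- function(D) sum(log1p(-(0:(n - 1)) / D))  # exact product
    lo <- n   # zero collisions among n draws implies at least n clones
  } else {
    logp <- function(D) ppois(nCollisions, npairs / D, log.p = TRUE)
    lo <- 1
  }
  if (logp(lo) >= log(alpha)) return(lo)
  hi <- 2 * lo
  while (logp(hi) < log(alpha)) hi <- hi * 2
  root <- uniroot(function(D) logp(D) - log(alpha), c(lo, hi), tol = 1e-9)$root
  D <- ceiling(root)
  while (D > lo && logp(D - 1) >= log(alpha)) D <- D - 1
  D
}

#' Serialize a library design as JSON
#'
#' @param design a [LibraryDesign-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeLibraryDesign <- function(design, path) {
  stopifnot(is(design, "LibraryDesign"))
  obj <- list(
    scaffold = design@scaffold@name,
    translation_table = design@translationTableId,
    loops = lapply(design@loops, function(lp) list(
      loop_id = lp@loopId, anchor_codon = lp@anchorCodon,
      length_range = lp@lengthRange, codon = lp@codonScheme@iupac)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
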