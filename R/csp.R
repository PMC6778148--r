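#' Combined amide chemical shift perturbation
#'
#' Weighted combination of the backbone amide 15N and 1HN chemical shift
#' changes between the free and bound forms:
#' `ddNH = sqrt(0.14 (dd15N)^2 + (dd1HN)^2)` (the 0.14 weight sits outside
#' the square, scaling the nitrogen term for its wider ppm range). The
#' common alternative convention `(0.14 dd15N)^2` is available behind
#' `weightInsideSquare`; the default matches the formula as usually printed.
#'
#' @param d15N 15N shift change (ppm); vectorized.
#' @param d1HN 1HN shift change (ppm); vectorized.
#' @param weightInsideSquare square the weighted nitrogen term instead of
#'   weighting the squared term.
#' @return combined perturbation (ppm), symmetric in the sign of both
#'   inputs.
#' @examples
#' combinedCsp(1, 0)  # sqrt(0.14) ~ 0.374
#' @export
combinedCsp <- function(d15N, d1HN, weightInsideSquare = FALSE) {
  if (any(!is.finite(d15N)) || any(!is.finite(d1HN)))
    stop("shift changes must be finite", call. = FALSE)
  if (weightInsideSquare) sqrt((0.14 * d15N)^2 + d1HN^2)
  else sqrt(0.14 * d15N^2 + d1HN^2)
}

#' Per-residue epitope map
#'
#' @slot map data.frame with columns `residue`, `csp` (ppm), `class`
#'   (`strong`/`moderate`/`background`/`broadened`/`no-data`).
#' @slot thresholds `c(strong, moderate)` ppm cut-offs.
#' @name EpitopeMap-class
#' @aliases EpitopeMap
#' @exportClass EpitopeMap
setClass("EpitopeMap", representation(map = "data.frame",
                                      thresholds = "numeric"))

setValidity("EpitopeMap", function(object) {
  cls <- c("strong", "moderate", "background", "broadened", "no-data")
  if (!all(object@map$class %in% cls))
    return("classes must be strong/moderate/background/broadened/no-data")
  if (anyDuplicated(object@map$residue)) return("one row per residue")
  TRUE
})

setMethod("show", "EpitopeMap", function(object) {
  tab <- table(factor(object@map$class,
                      c("strong", "moderate", "background", "broadened",
                        "no-data")))
  cat(sprintf(
    "EpitopeMap: %d residues (>%g ppm: %d strong; >%g ppm: %d moderate; %d broadened; %d no-data)\n",
    nrow(object@map), object@thresholds[1], tab[["strong"]],
    object@thresholds[2], tab[["moderate"]], tab[["broadened"]],
    tab[["no-data"]]))
})

#' @describeIn EpitopeMap-class residues in the perturbed classes.
#' @param x an `EpitopeMap`.
#' @param classes classes counted as perturbed.
#' @export
epitopeResidues <- function(x, classes = c("strong", "moderate")) {
  x@map$residue[x@map$class %in% classes]
}

#' Read a chemical-shift table CSV
#'
#' Columns: `residue` (number), `resname`, `d1HN` (ppm), `d15N` (ppm), and
#' optional logical flags `broadened`, `missing`, `ambiguous`.
#'
#' @param path CSV path.
#' @return data.frame with normalized columns.
#' @export
readShiftTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  for (fl in c("broadened", "missing", "ambiguous"))
    if (is.null(d[[fl]])) d[[fl]] <- FALSE else d[[fl]] <- as.logical(d[[fl]])
  d
}

#' Map a binding epitope from free/bound shift tables
#'
#' Computes the combined perturbation per residue present in both states
#' and classifies: `strong` above the first threshold (default 0.3 ppm),
#' `moderate` above the second (default 0.15 ppm), else `background`.
#' Residues broadened beyond detection in the bound state are classed
#' `broadened` regardless of any measurable shift (exchange broadening is
#' itself evidence of contact); residues missing or ambiguous in either
#' state are `no-data`.
#'
#' @param free,bound shift tables (see [readShiftTable()]) sharing residue
#'   numbering.
#' @param thresholds `c(strong, moderate)` in ppm.
#' @param weightInsideSquare passed to [combinedCsp()].
#' @return An [EpitopeMap-class].
#' @export
epitopeMap <- function(free, bound, thresholds = c(0.3, 0.15),
                       weightInsideSquare = FALSE) {
  stopifnot(length(thresholds) == 2, thresholds[1] >= thresholds[2])
  if (length(intersect(free$residue, bound$residue)) == 0)
    stop(sprintf(
      "residue numbering mismatch between states; free-only: %s / bound-only: %s",
      paste(head(setdiff(free$residue, bound$residue), 10), collapse = ","),
      paste(head(setdiff(bound$residue, free$residue), 10), collapse = ",")),
      call. = FALSE)
  residues <- sort(unique(c(free$residue, bound$residue)))
  fr <- free[match(residues, free$residue), ]
  bo <- bound[match(residues, bound$residue), ]
  csp <- combinedCsp(
    ifelse(is.finite(bo$d15N - fr$d15N), bo$d15N - fr$d15N, 0),
    ifelse(is.finite(bo$d1HN - fr$d1HN), bo$d1HN - fr$d1HN, 0),
    weightInsideSquare)
  nodata <- is.na(match(residues, free$residue)) |
    is.na(match(residues, bound$residue)) |
    (fr$missing %in% TRUE) | (bo$missing %in% TRUE) |
    (fr$ambiguous %in% TRUE) | (bo$ambiguous %in% TRUE)
  broad <- (bo$broadened %in% TRUE) & !nodata
  cls <- ifelse(nodata, "no-data",
         ifelse(broad, "broadened",
         ifelse(csp > thresholds[1], "strong",
         ifelse(csp > thresholds[2], "moderate", "background"))))
  csp[nodata] <- NA_real_
  out <- new("EpitopeMap",
             map = data.frame(residue = residues, csp = csp, class = cls,
                              stringsAsFactors = FALSE),
             thresholds = thresholds)
  validObject(out)
  out
}

#' Compare two epitope maps
#'
#' Set comparison of the perturbed residues (strong + moderate by default)
#' of two maps over the same residue universe: shared and unique residues
#' and the Jaccard index.
#'
#' @param mapA,mapB [EpitopeMap-class] objects over the same residues.
#' @param classes classes counted as perturbed.
#' @return list with `shared`, `uniqueA`, `uniqueB`, `jaccard`,
#'   `sharedStrong`.
#' @export
compareEpitopes <- function(mapA, mapB,
                            classes = c("strong", "moderate")) {
  stopifnot(is(mapA, "EpitopeMap"), is(mapB, "EpitopeMap"))
  if (length(intersect(mapA@map$residue, mapB@map$residue)) == 0)
    stop("maps share no residues", call. = FALSE)
  ea <- epitopeResidues(mapA, classes)
  eb <- epitopeResidues(mapB, classes)
  inter <- intersect(ea, eb)
  uni <- union(ea, eb)
  list(shared = inter, uniqueA = setdiff(ea, eb), uniqueB = setdiff(eb, ea),
       jaccard = if (length(uni) == 0) 1 else length(inter) / length(uni),
       sharedStrong = intersect(epitopeResidues(mapA, "strong"),
                                epitopeResidues(mapB, "strong")))
}

#' Export an epitope map
#'
#' Writes the per-residue table as CSV and, optionally, a plain-text
#' residue-list fragment (comma-separated residue numbers per class) usable
#' for colouring residues in a structure viewer.
#'
#' @param map an [EpitopeMap-class].
#' @param csv CSV output path (or `NULL`).
#' @param residueList plain-text output path (or `NULL`).
#' @return invisible list of written paths.
#' @export
writeEpitopeMap <- function(map, csv = NULL, residueList = NULL) {
  if (!is.null(csv)) write.csv(map@map, csv, row.names = FALSE)
  if (!is.null(residueList)) {
    lines <- vapply(c("strong", "moderate", "broadened"), function(cl)
      sprintf("%s: %s", cl,
              paste(map@map$residue[map@map$class == cl], collapse = ",")),
      character(1))
    writeLines(lines, residueList)
  }
  invisible(list(csv = csv, residueList = residueList))
}
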