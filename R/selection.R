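#' Phage titer from absorbance at 268 nm
#'
#' Converts the A268 of a phage preparation to particles per mL using the
#' standard spectrophotometric constant: an OD268 of 1.0 corresponds to
#' 5e12 phage per mL. The dilution factor of the measured aliquot multiplies
#' the result.
#'
#' @param od absorbance at 268 nm (>= 0).
#' @param dilution dilution factor (>= 1).
#' @return phage per mL.
#' @examples
#' titerFromOd268(1.0)      # 5e12
#' titerFromOd268(0.5, 10)  # 2.5e13
#' @export
titerFromOd268 <- function(od, dilution = 1) {
  assert_scalar_number(od, "od", lower = 0)
  assert_scalar_number(dilution, "dilution", lower = 1)
  od * 5e12 * dilution
}

#' Phage/cfu titer from colony counts
#'
#' @param colonies colony count on the plate.
#' @param dilution dilution factor of the plated aliquot.
#' @param platedVolume plated volume in mL (> 0).
#' @return colony-forming units per mL.
#' @examples
#' titerFromColonies(50, 1e6, 0.01)  # 5e9
#' @export
titerFromColonies <- function(colonies, dilution, platedVolume) {
  assert_scalar_number(colonies, "colonies", lower = 0)
  assert_scalar_number(dilution, "dilution", lower = 0, strict_lower = TRUE)
  assert_scalar_number(platedVolume, "platedVolume", lower = 0,
                       strict_lower = TRUE)
  colonies * dilution / platedVolume
}

#' Combine a serial-dilution series into one titer estimate
#'
#' Per-plate titers (colonies x dilution / volume) are averaged weighted by
#' colony count, i.e. total colonies divided by total effective volume -- the
#' maximum-likelihood estimate under Poisson plating noise.
#'
#' @param colonies colony counts per plate.
#' @param dilutions dilution factor per plate.
#' @param platedVolume plated volume (mL), recycled.
#' @return cfu per mL.
#' @export
titerFromSeries <- function(colonies, dilutions, platedVolume) {
  stopifnot(length(colonies) == length(dilutions))
  eff <- platedVolume / dilutions  # effective undiluted volume per plate
  sum(colonies) / sum(eff)
}

#' One round of biopanning
#'
#' @slot roundIndex round number (>= 1).
#' @slot targetConcentration target concentration in nM.
#' @slot elutedTargetTiter phage/mL eluted from the target sort.
#' @slot elutedControlTiter phage/mL eluted from the negative control.
#' @name PanningRound-class
#' @aliases PanningRound
#' @exportClass PanningRound
setClass("PanningRound", representation(
  roundIndex = "integer", targetConcentration = "numeric",
  elutedTargetTiter = "numeric", elutedControlTiter = "numeric"))

setValidity("PanningRound", function(object) {
  if (object@roundIndex < 1L) return("roundIndex must be >= 1")
  if (object@elutedTargetTiter < 0 || object@elutedControlTiter < 0)
    return("titers must be non-negative")
  TRUE
})

#' @param roundIndex,targetConcentration,elutedTargetTiter,elutedControlTiter
#'   see slots.
#' @rdname PanningRound-class
#' @export
panningRound <- function(roundIndex, targetConcentration,
                         elutedTargetTiter, elutedControlTiter) {
  obj <- new("PanningRound", roundIndex = as.integer(roundIndex),
             targetConcentration = targetConcentration,
             elutedTargetTiter = elutedTargetTiter,
             elutedControlTiter = elutedControlTiter)
  validObject(obj)
  obj
}

#' Enrichment ratio of a panning round
#'
#' The selection-performance parameter: phage recovered from the target sort
#' divided by background phage recovered from the negative-control sort.
#' A zero control titer makes the ratio unbounded; an `Inf` sentinel with an
#' attribute flag is returned rather than an error.
#'
#' @param round a [PanningRound-class], or target titer when `control` given.
#' @param control control titer (when `round` is numeric).
#' @return dimensionless ratio; `Inf` with attribute `unbounded = TRUE` when
#'   the control titer is zero.
#' @examples
#' enrichmentRatio(1e6, 1e4)  # 100
#' @export
enrichmentRatio <- function(round, control = NULL) {
  if (is(round, "PanningRound")) {
    target <- round@elutedTargetTiter
    control <- round@elutedControlTiter
  } else target <- round
  stopifnot(target >= 0, control >= 0)
  if (control == 0) {
    out <- Inf
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  target / control
}

#' Panning stringency presets
#'
#' Target-concentration schedules (nM) per selection round. Two schedules
#' are shipped; they reflect two printed descriptions of the same selection
#' and neither is asserted as canonical.
#'
#' @param preset `"results-schedule"` (100, 50, 25 nM) or
#'   `"methods-schedule"` (100, 20, 4 nM).
#' @return named numeric vector of concentrations, one per round.
#' @export
panningSchedule <- function(preset = c("results-schedule",
                                       "methods-schedule")) {
  preset <- match.arg(preset)
  conc <- switch(preset,
                 "results-schedule" = c(100, 50, 25),
                 "methods-schedule" = c(100, 20, 4))
  setNames(conc, paste0("round", seq_along(conc)))
}

#' Phage-ELISA plate
#'
#' OD450 matrix of clones x targets with per-target blank wells.
#'
#' @slot od450 numeric matrix, rows = clones, columns = targets.
#' @slot blanks numeric matrix of blank ODs (rows = blank replicates,
#'   columns = targets).
#' @name ElisaPlate-class
#' @aliases ElisaPlate
#' @exportClass ElisaPlate
setClass("ElisaPlate", representation(od450 = "matrix", blanks = "matrix"))

setValidity("ElisaPlate", function(object) {
  if (any(object@od450 < 0) || any(object@blanks < 0))
    return("ODs must be non-negative")
  if (ncol(object@blanks) != ncol(object@od450))
    return("blanks must cover every target")
  if (nrow(object@blanks) < 1L) return("each target needs >= 1 blank well")
  TRUE
})

#' @param od450,blanks see slots.
#' @rdname ElisaPlate-class
#' @export
elisaPlate <- function(od450, blanks) {
  obj <- new("ElisaPlate", od450 = as.matrix(od450),
             blanks = as.matrix(blanks))
  validObject(obj)
  obj
}

#' Read an ELISA plate CSV
#'
#' Layout: one row per clone plus reserved `BLANK` rows, one column per
#' target; first column holds the clone name.
#'
#' @param path CSV path.
#' @return An [ElisaPlate-class].
#' @export
readElisaPlate <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  is_blank <- toupper(ids) == "BLANK"
  if (!any(is_blank)) stop("plate has no BLANK rows", call. = FALSE)
  elisaPlate(m[!is_blank, , drop = FALSE], m[is_blank, , drop = FALSE])
}

#' Phage-ELISA specificity of one clone
#'
#' Subtracts each target's blank mean from the clone's ODs (clipping
#' negatives to zero), calls the clone a binder of the primary target when
#' its signal exceeds `k` blank standard deviations, and reports the
#' specificity index: primary-target signal over the strongest off-target
#' signal (`Inf` sentinel when all off-targets are zero).
#'
#' @param plate an [ElisaPlate-class].
#' @param clone clone (row) name.
#' @param primaryTarget primary target (column) name.
#' @param k binder-call threshold in blank standard deviations (default 3).
#' @return list with `signal` (named, background-subtracted), `specificity`
#'   (index), `binder` (logical call).
#' @export
elisaSpecificity <- function(plate, clone, primaryTarget, k = 3) {
  stopifnot(is(plate, "ElisaPlate"))
  if (!clone %in% rownames(plate@od450))
    stop(sprintf("unknown clone '%s'", clone), call. = FALSE)
  if (!primaryTarget %in% colnames(plate@od450))
    stop(sprintf("primary target '%s' not on plate", primaryTarget),
         call. = FALSE)
  bl_mean <- colMeans(plate@blanks)
  bl_sd <- apply(plate@blanks, 2, sd)
  if (nrow(plate@blanks) == 1L) bl_sd[] <- 0
  sig <- pmax(plate@od450[clone, ] - bl_mean, 0)
  others <- sig[setdiff(names(sig), primaryTarget)]
  idx <- if (length(others) == 0 || max(others) == 0) Inf else
    unname(sig[primaryTarget] / max(others))
  list(signal = sig,
       specificity = idx,
       binder = unname(sig[primaryTarget] > k * bl_sd[primaryTarget]))
}
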