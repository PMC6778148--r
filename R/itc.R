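#' Isothermal titration calorimetry experiment
#'
#' Injection geometry and per-injection heats of an ITC titration. The
#' standard scheme is a single small pre-injection (discarded from fits,
#' as its heat is perturbed by diffusion across the syringe tip) followed
#' by the working injections: by default 0.5 uL + 29 x 1 uL.
#'
#' @slot cellConc macromolecule concentration in the cell, Mt (M).
#' @slot syringeConc titrant concentration in the syringe, Xt0 (M).
#' @slot cellVolume cell volume V0 (L).
#' @slot injectionVolumes per-injection volumes (L), pre-injection first.
#' @slot heats per-injection heats (ucal), aligned with volumes; empty for
#'   a bare geometry used in simulation.
#' @slot temperature analysis temperature (degrees C).
#' @slot preInjections number of leading injections excluded from fits.
#' @name ItcExperiment-class
#' @aliases ItcExperiment
#' @exportClass ItcExperiment
setClass("ItcExperiment", representation(
  cellConc = "numeric", syringeConc = "numeric", cellVolume = "numeric",
  injectionVolumes = "numeric", heats = "numeric", temperature = "numeric",
  preInjections = "integer"))

setValidity("ItcExperiment", function(object) {
  if (object@cellVolume <= 0) return("cell volume must be positive")
  if (any(object@injectionVolumes <= 0))
    return("injection volumes must be positive")
  if (length(object@heats) &&
      length(object@heats) != length(object@injectionVolumes))
    return("heats must align with injection volumes")
  TRUE
})

setMethod("show", "ItcExperiment", function(object) {
  cat(sprintf(
    "ItcExperiment: cell %.3g M / syringe %.3g M, V0 %.3g L, %d injections (%d pre), %s\n",
    object@cellConc, object@syringeConc, object@cellVolume,
    length(object@injectionVolumes), object@preInjections,
    if (length(object@heats)) "with heats" else "geometry only"))
})

#' @rdname ItcExperiment-class
#' @param cellConc,syringeConc,cellVolume,injectionVolumes,heats,temperature,preInjections
#'   see slots; the default injection scheme is 0.5 uL followed by
#'   29 x 1 uL into a 200 uL cell.
#' @export
itcExperiment <- function(cellConc, syringeConc,
                          injectionVolumes = c(0.5e-6, rep(1e-6, 29)),
                          heats = numeric(0), cellVolume = 200e-6,
                          temperature = 25, preInjections = 1L) {
  obj <- new("ItcExperiment", cellConc = cellConc, syringeConc = syringeConc,
             cellVolume = cellVolume, injectionVolumes = injectionVolumes,
             heats = heats, temperature = temperature,
             preInjections = as.integer(preInjections))
  validObject(obj)
  obj
}

# post-injection total concentrations with the midpoint displaced-volume
# correction; d = cumulative injected volume
.itc_concentrations <- function(exp) {
  d <- cumsum(exp@injectionVolumes)
  V0 <- exp@cellVolume
  phi <- 1 / (1 + d / (2 * V0))
  list(Mt = exp@cellConc * (1 - d / (2 * V0)) * phi,
       Xt = exp@syringeConc * (d / V0) * phi,
       d = d)
}

# bound-complex concentration for n identical independent sites
.itc_bound <- function(N, KD, Mt, Xt) {
  s <- Xt + N * Mt + KD
  # stable form of the smaller quadratic root
  2 * N * Mt * Xt / (s + sqrt(pmax(s^2 - 4 * N * Mt * Xt, 0)))
}

#' One-set-of-sites ITC isotherm
#'
#' Per-injection heats for a binding model of `N` independent and identical
#' sites. The cumulative heat content after injection `i` is
#' `Q_i = V0 dH [MX]_i` with the bound-complex concentration from the
#' quadratic mass balance at the diluted totals; the measured heat of
#' injection `i` applies the midpoint displaced-volume correction
#' `dQ_i = Q_i - Q_{i-1} + (v_i/V0)(Q_i + Q_{i-1})/2`.
#'
#' @param N stoichiometry (> 0).
#' @param KD dissociation constant (M, > 0).
#' @param dH binding enthalpy (kcal/mol).
#' @param experiment an [ItcExperiment-class] (geometry; heats ignored).
#' @return numeric vector of per-injection heats (ucal), aligned with the
#'   experiment's injection volumes (pre-injection included).
#' @export
itcIsotherm <- function(N, KD, dH, experiment) {
  assert_scalar_number(N, "N", lower = 0, strict_lower = TRUE)
  assert_scalar_number(KD, "KD", lower = 0, strict_lower = TRUE)
  stopifnot(is(experiment, "ItcExperiment"))
  cc <- .itc_concentrations(experiment)
  MX <- .itc_bound(N, KD, cc$Mt, cc$Xt)
  V0 <- experiment@cellVolume
  Q <- V0 * (dH * 1000) * MX          # cal
  v <- experiment@injectionVolumes
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (v / V0) * (Q + Qprev) / 2
  dQ * 1e6                            # ucal
}

#' Heats normalized per mole of injectant
#'
#' @param experiment an [ItcExperiment-class].
#' @param heats per-injection heats (ucal); default the experiment's own.
#' @return kcal per mole of injected titrant, one value per injection.
#' @export
normalizedHeats <- function(experiment, heats = experiment@heats) {
  mol <- experiment@injectionVolumes * experiment@syringeConc
  (heats * 1e-6) / mol / 1000
}

#' Fit the one-set-of-sites binding model to an ITC isotherm
#'
#' Least squares on the heats normalized per mole of injectant (the
#' Wiseman plot), excluding the pre-injection(s), fitting stoichiometry N,
#' dissociation constant KD and enthalpy dH. Trust-region
#' Levenberg-Marquardt from a deterministic set of starting points
#' (N around 1, KD log-spaced below the cell concentration, dH from the
#' initial plateau). The Wiseman c-value `c = N Mt / KD` is reported;
#' values outside [0.1, 1e4] trigger an unreliable-fit warning (the
#' isotherm shape no longer constrains KD well), not a failure.
#'
#' @param experiment an [ItcExperiment-class] carrying heats (ucal).
#' @return list with `N`, `KD` (M), `dH` (kcal/mol), `cValue`,
#'   `reliable` (logical), `residualNorm` (kcal/mol).
#' @export
fitItc <- function(experiment) {
  stopifnot(is(experiment, "ItcExperiment"))
  if (!length(experiment@heats)) stop("experiment has no heats",
                                      call. = FALSE)
  use <- seq_along(experiment@heats) > experiment@preInjections
  if (sum(use) < 10) stop("need >= 10 usable injections", call. = FALSE)
  ndh_obs <- normalizedHeats(experiment)[use]
  model_ndh <- function(N, KD, dH)
    normalizedHeats(experiment, itcIsotherm(N, KD, dH, experiment))[use]
  resid_fn <- function(p) ndh_obs - model_ndh(10^p[1], 10^p[2], p[3])
  dh0 <- ndh_obs[1]
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  Mt <- experiment@cellConc
  best <- NULL
  for (n0 in c(0.5, 1, 2)) {
    for (kd0 in Mt / c(10, 100, 1000)) {
      p0 <- c(log10(n0), log10(kd0), dh0)
      fit <- tryCatch(
        minpack.lm::nls.lm(p0, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- sum(fit$fvec^2)
      if (is.null(best) || ssr < best$ssr)
        best <- list(par = fit$par, ssr = ssr)
    }
  }
  if (is.null(best)) stop("ITC fit failed from every start", call. = FALSE)
  N <- 10^best$par[1]; KD <- 10^best$par[2]; dH <- best$par[3]
  cval <- N * Mt / KD
  reliable <- cval >= 0.1 && cval <= 1e4
  if (!reliable)
    warning(sprintf(
      "c-value %.3g outside [0.1, 1e4]: KD poorly constrained", cval),
      call. = FALSE)
  list(N = N, KD = KD, dH = dH, cValue = cval, reliable = reliable,
       residualNorm = sqrt(best$ssr / sum(use)))
}
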