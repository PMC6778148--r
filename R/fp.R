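#' Fluorescence polarization titration
#'
#' Direct titration of a fixed concentration of fluorescent tracer peptide
#' with increasing receptor: polarization (mP) rises from the free-tracer
#' floor to the bound-tracer ceiling as the bound fraction grows.
#'
#' @slot receptorConc receptor concentrations (M, >= 0).
#' @slot polarization measured polarization (mP).
#' @slot tracerConc tracer concentration Lt (M, > 0); 50 nM is the standard
#'   working concentration.
#' @name FpTitration-class
#' @aliases FpTitration
#' @exportClass FpTitration
setClass("FpTitration", representation(
  receptorConc = "numeric", polarization = "numeric",
  tracerConc = "numeric"))

setValidity("FpTitration", function(object) {
  if (any(object@receptorConc < 0))
    return("receptor concentrations must be >= 0")
  if (object@tracerConc <= 0) return("tracer concentration must be > 0")
  if (length(object@receptorConc) != length(object@polarization))
    return("concentration/polarization length mismatch")
  TRUE
})

#' @rdname FpTitration-class
#' @param receptorConc,polarization,tracerConc see slots.
#' @export
fpTitration <- function(receptorConc, polarization, tracerConc = 50e-9) {
  obj <- new("FpTitration", receptorConc = receptorConc,
             polarization = polarization, tracerConc = tracerConc)
  validObject(obj)
  obj
}

#' Competition binding curve
#'
#' Signal versus competitor concentration at fixed receptor and tracer,
#' with the tracer affinity known and constrained.
#'
#' @slot competitorConc competitor concentrations (M).
#' @slot signal measured signal (mP, or percent bound for densitometry).
#' @slot receptorConc total receptor Rt (M).
#' @slot tracerConc total tracer Lt (M).
#' @slot tracerKd tracer dissociation constant (M).
#' @name CompetitionCurve-class
#' @aliases CompetitionCurve
#' @exportClass CompetitionCurve
setClass("CompetitionCurve", representation(
  competitorConc = "numeric", signal = "numeric", receptorConc = "numeric",
  tracerConc = "numeric", tracerKd = "numeric"))

setValidity("CompetitionCurve", function(object) {
  if (object@receptorConc <= 0 || object@tracerConc <= 0 ||
      object@tracerKd <= 0)
    return("constants must be positive")
  if (any(object@competitorConc < 0))
    return("competitor concentrations must be >= 0")
  if (length(object@competitorConc) != length(object@signal))
    return("concentration/signal length mismatch")
  TRUE
})

#' @rdname CompetitionCurve-class
#' @param competitorConc,signal,receptorConc,tracerConc,tracerKd see slots.
#' @export
competitionCurve <- function(competitorConc, signal, receptorConc,
                             tracerConc, tracerKd) {
  obj <- new("CompetitionCurve", competitorConc = competitorConc,
             signal = signal, receptorConc = receptorConc,
             tracerConc = tracerConc, tracerKd = tracerKd)
  validObject(obj)
  obj
}

#' Depletion-corrected bound fraction of the tracer
#'
#' Exact two-component mass balance: with total tracer Lt and total
#' receptor Rt, the bound tracer fraction is
#' `FB = ((KD + Lt + Rt) - sqrt((KD + Lt + Rt)^2 - 4 Lt Rt)) / (2 Lt)`.
#' In the `Lt -> 0` limit this reduces to the hyperbola `Rt / (Rt + KD)`.
#'
#' @param KD dissociation constant (M).
#' @param Rt total receptor (M), may be a vector.
#' @param Lt total tracer (M).
#' @return bound fraction in [0, 1].
#' @export
fpBoundFraction <- function(KD, Rt, Lt) {
  s <- KD + Lt + Rt
  # stable form of the smaller quadratic root (avoids cancellation when
  # the bound complex is far from half the total)
  2 * Rt / (s + sqrt(pmax(s^2 - 4 * Lt * Rt, 0)))
}

#' Direct FP fit (apparent KD)
#'
#' Fits `mP = P_free + (P_bound - P_free) FB` with the depletion-corrected
#' quadratic bound fraction, over log-scaled KD and (optionally) the two
#' plateaus. Gross non-monotonicity of the data produces a warning, not an
#' error.
#'
#' @param titration an [FpTitration-class] with >= 4 receptor
#'   concentrations.
#' @param fitPlateaus fit `P_free`/`P_bound` (default) or pin them to the
#'   data extremes.
#' @return list with `KD` (M), `pFree`, `pBound` (mP), `residualNorm`.
#' @export
fpDirectFit <- function(titration, fitPlateaus = TRUE) {
  stopifnot(is(titration, "FpTitration"))
  Rt <- titration@receptorConc
  mp <- titration@polarization
  Lt <- titration@tracerConc
  if (length(Rt) < 4) stop("need >= 4 receptor concentrations",
                           call. = FALSE)
  ord <- order(Rt)
  if (sum(diff(mp[ord]) < 0) > length(mp) / 2)
    warning("polarization grossly non-monotone in receptor concentration",
            call. = FALSE)
  pf0 <- min(mp); pb0 <- max(mp)
  half <- pf0 + 0.5 * (pb0 - pf0)
  kd0 <- Rt[ord][which.min(abs(mp[ord] - half))]
  if (kd0 <= 0) kd0 <- median(Rt[Rt > 0])
  resid_fn <- function(p) {
    fb <- fpBoundFraction(10^p[1], Rt, Lt)
    if (fitPlateaus) mp - (p[2] + (p[3] - p[2]) * fb)
    else mp - (pf0 + (pb0 - pf0) * fb)
  }
  best <- NULL
  for (f in c(0.1, 1, 10)) {
    p0 <- c(log10(kd0 * f), pf0, pb0)
    if (!fitPlateaus) p0 <- p0[1]
    fit <- tryCatch(minpack.lm::nls.lm(p0, fn = resid_fn),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par,
                                                      ssr = ssr)
  }
  if (is.null(best)) stop("FP fit failed", call. = FALSE)
  list(KD = 10^best$par[1],
       pFree = if (fitPlateaus) best$par[2] else pf0,
       pBound = if (fitPlateaus) best$par[3] else pb0,
       residualNorm = sqrt(best$ssr / length(mp)))
}

#' Exact ternary competition equilibrium
#'
#' Free receptor concentration when one receptor species binds both a
#' tracer (KD `kdTracer`) and a competitor (KD `ki`): the mass balance is a
#' cubic in free receptor, solved by the trigonometric closed form; the
#' bound tracer follows as `Lt [R] / (kdTracer + [R])`.
#'
#' @param Rt,Lt,It total receptor, tracer, competitor (M); `It` may be a
#'   vector.
#' @param kdTracer,ki dissociation constants (M).
#' @return list with `freeReceptor` (M) and `tracerBoundFraction`, each
#'   along `It`.
#' @export
competitionEquilibrium <- function(Rt, Lt, It, kdTracer, ki) {
  stopifnot(Rt > 0, Lt > 0, kdTracer > 0, ki > 0, all(It >= 0))
  KA <- kdTracer; KB <- ki
  a <- KA + KB + Lt + It - Rt
  b <- KB * (Lt - Rt) + KA * (It - Rt) + KA * KB
  cc <- -KA * KB * Rt
  q <- pmax(a^2 - 3 * b, .Machine$double.xmin)
  arg <- (-2 * a^3 + 9 * a * b - 27 * cc) / (2 * sqrt(q^3))
  arg <- pmin(1, pmax(-1, arg))
  theta <- acos(arg)
  R <- -a / 3 + (2 / 3) * sqrt(q) * cos(theta / 3)
  R <- pmax(R, 0)
  # two Newton steps on the mass balance polish the trigonometric root to
  # machine precision across extreme parameter ratios
  for (k in 1:2) {
    f <- R * (1 + Lt / (KA + R) + It / (KB + R)) - Rt
    fp <- 1 + Lt * KA / (KA + R)^2 + It * KB / (KB + R)^2
    R <- pmax(R - f / fp, 0)
  }
  list(freeReceptor = R, tracerBoundFraction = R / (KA + R))
}

#' Competitive FP fit (exact KI)
#'
#' Fits the exact ternary equilibrium (cubic in free receptor) to a
#' polarization-versus-competitor curve with the receptor, tracer and
#' tracer-KD constants constrained, returning the competitor inhibition
#' constant KI. A curve whose dynamic range is too small to constrain KI
#' (flat within noise) is reported as a lower bound only.
#'
#' @param curve a [CompetitionCurve-class] (signal in mP).
#' @return list with `KI` (M), `pFree`, `pBound`, `residualNorm`,
#'   `kiLowerBoundOnly` (logical).
#' @export
fpCompetitionKi <- function(curve) {
  stopifnot(is(curve, "CompetitionCurve"))
  It <- curve@competitorConc
  mp <- curve@signal
  Rt <- curve@receptorConc; Lt <- curve@tracerConc; KdT <- curve@tracerKd
  fb <- function(ki) competitionEquilibrium(Rt, Lt, It, KdT,
                                            ki)$tracerBoundFraction
  pf0 <- min(mp); pb0 <- max(mp)
  flat <- (pb0 - pf0) < 0.02 * max(abs(mp))
  resid_fn <- function(p) mp - (p[2] + (p[3] - p[2]) * fb(10^p[1]))
  best <- NULL
  for (ki0 in KdT * c(0.01, 1, 100)) {
    p0 <- c(log10(ki0), pb0, pf0)  # signal falls as competitor rises
    fit <- tryCatch(minpack.lm::nls.lm(p0, fn = resid_fn),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par,
                                                      ssr = ssr)
  }
  if (is.null(best)) stop("competition fit failed", call. = FALSE)
  list(KI = 10^best$par[1], pFree = best$par[3], pBound = best$par[2],
       residualNorm = sqrt(best$ssr / length(mp)),
       kiLowerBoundOnly = flat)
}

#' Pull-down competition Ki (one site, Cheng-Prusoff)
#'
#' Densitometry analogue of the Prism "One site - Fit Ki" model: the signal,
#' normalized so the zero-competitor lane reads 100 percent, follows a
#' four-parameter logistic in log10 competitor whose midpoint is tied to
#' the inhibition constant by the Cheng-Prusoff relation
#' `IC50 = Ki (1 + [tracer]/KD_tracer)`; top and bottom plateaus are
#' fitted, tracer concentration and tracer KD are fixed constants.
#'
#' @param curve a [CompetitionCurve-class]; `signal` is band intensity
#'   (arbitrary units or percent), `tracerConc`/`tracerKd` the constrained
#'   constants. Requires >= 4 nonzero competitor levels.
#' @return list with `Ki` (M), `IC50` (M), `top`, `bottom` (percent),
#'   `residualNorm`.
#' @export
pulldownKi <- function(curve) {
  stopifnot(is(curve, "CompetitionCurve"))
  It <- curve@competitorConc
  y <- curve@signal
  if (sum(It > 0) < 4) stop("need >= 4 competitor levels", call. = FALSE)
  if (any(It == 0)) {
    y <- 100 * y / mean(y[It == 0])
    keep <- It > 0
    It <- It[keep]; y <- y[keep]
  }
  shift <- 1 + curve@tracerConc / curve@tracerKd  # Cheng-Prusoff factor
  x <- log10(It)
  resid_fn <- function(p) {
    ic50 <- 10^p[1] * shift
    y - (p[3] + (p[2] - p[3]) / (1 + 10^(x - log10(ic50))))
  }
  ki0 <- 10^median(x) / shift
  best <- NULL
  for (f in c(0.01, 1, 100)) {
    p0 <- c(log10(ki0 * f), max(y), min(y))
    fit <- tryCatch(minpack.lm::nls.lm(p0, fn = resid_fn),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par,
                                                      ssr = ssr)
  }
  if (is.null(best)) stop("pull-down fit failed", call. = FALSE)
  ki <- 10^best$par[1]
  list(Ki = ki, IC50 = ki * shift, top = best$par[2], bottom = best$par[3],
       residualNorm = sqrt(best$ssr / length(y)))
}

#' Effective concentration of a tethered binding module
#'
#' For a fusion of two binding modules joined by a linker, the apparent
#' local concentration each module presents to its site:
#' `C_eff = (KD_A x KD_B) / KD_fusion`. Strong avidity (fusion KD far below
#' the product of the module KDs) corresponds to effective concentrations
#' in the mM range.
#'
#' @param kdA,kdB dissociation constants of the isolated modules (M).
#' @param kdFusion dissociation constant of the tethered fusion (M).
#' @return effective concentration (M).
#' @examples
#' effectiveConcentration(1e-6, 1e-6, 1e-9)  # 1e-3 M = 1 mM
#' @export
effectiveConcentration <- function(kdA, kdB, kdFusion) {
  assert_scalar_number(kdA, "kdA", lower = 0, strict_lower = TRUE)
  assert_scalar_number(kdB, "kdB", lower = 0, strict_lower = TRUE)
  assert_scalar_number(kdFusion, "kdFusion", lower = 0, strict_lower = TRUE)
  kdA * kdB / kdFusion
}
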