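#' Single-cycle kinetics sensorgram
#'
#' Response-vs-time record of a single-cycle kinetics SPR run: sequential
#' analyte injections at ascending concentrations without regeneration, each
#' association phase followed by a short dissociation, the last by a long
#' one.
#'
#' @slot data data.frame with columns `time` (s), `response` (RU),
#'   `phase` (`"association"`/`"dissociation"`), `conc` (M, 0 in
#'   dissociation), `segment` (integer).
#' @slot ligandDensity immobilized ligand level (RU), `NA` when unknown.
#' @name Sensorgram-class
#' @aliases Sensorgram
#' @exportClass Sensorgram
setClass("Sensorgram", representation(data = "data.frame",
                                      ligandDensity = "numeric"))

setValidity("Sensorgram", function(object) {
  d <- object@data
  need <- c("time", "response", "phase", "conc", "segment")
  if (!all(need %in% names(d)))
    return(paste("data needs columns:", paste(need, collapse = ", ")))
  for (s in unique(d$segment)) {
    t <- d$time[d$segment == s]
    if (any(diff(t) <= 0)) return("times must strictly increase per segment")
  }
  if (any(d$conc[d$phase == "association"] <= 0))
    return("association concentrations must be positive")
  TRUE
})

setMethod("show", "Sensorgram", function(object) {
  d <- object@data
  conc <- sort(unique(d$conc[d$phase == "association"]))
  cat(sprintf(
    "Sensorgram: %d points, %d segments, %d concentration(s) (%.3g-%.3g M)\n",
    nrow(d), length(unique(d$segment)), length(conc), min(conc), max(conc)))
})

#' @describeIn Sensorgram-class underlying data.frame.
#' @param x a `Sensorgram`.
#' @export
sensorgramData <- function(x) x@data

#' @rdname Sensorgram-class
#' @param data,ligandDensity see slots.
#' @export
sensorgram <- function(data, ligandDensity = NA_real_) {
  obj <- new("Sensorgram", data = as.data.frame(data),
             ligandDensity = ligandDensity)
  validObject(obj)
  obj
}

# evaluate the 1:1 Langmuir piecewise closed form over a segment table.
# segments: data.frame(segment, phase, conc, start, end); returns function of
# (kon, koff, Rmax) giving responses at `times` (vector aligned with segs_of)
.sck_model <- function(times, seg_of, segments) {
  function(kon, koff, Rmax) {
    out <- numeric(length(times))
    R0 <- 0
    for (i in seq_len(nrow(segments))) {
      sg <- segments[i, ]
      idx <- which(seg_of == sg$segment)
      tt <- times[idx] - sg$start
      if (sg$phase == "association") {
        keq <- kon * sg$conc + koff
        Req <- kon * sg$conc * Rmax / keq
        out[idx] <- Req + (R0 - Req) * exp(-keq * tt)
        R0 <- Req + (R0 - Req) * exp(-keq * (sg$end - sg$start))
      } else {
        out[idx] <- R0 * exp(-koff * tt)
        R0 <- R0 * exp(-koff * (sg$end - sg$start))
      }
    }
    out
  }
}

.sck_segments <- function(d) {
  segs <- unique(d$segment)
  do.call(rbind, lapply(segs, function(s) {
    dd <- d[d$segment == s, ]
    data.frame(segment = s, phase = dd$phase[1], conc = dd$conc[1],
               start = min(dd$time), end = max(dd$time))
  }))
}

#' Simulate a single-cycle kinetics sensorgram
#'
#' Closed-form 1:1 Langmuir response. During association at analyte
#' concentration C, `R(t) = Req + (R0 - Req) exp(-(kon C + koff) t)` with
#' `Req = kon C Rmax / (kon C + koff)`; during dissociation
#' `R(t) = R0 exp(-koff t)`. Segments chain continuously: the default
#' injection plan is five twofold-ascending concentrations, 120 s contact
#' and 70 s dissociation each, with the final dissociation extended to
#' 600 s.
#'
#' @param kon association rate constant (1/(M s), > 0).
#' @param koff dissociation rate constant (1/s, > 0).
#' @param Rmax surface capacity (RU, > 0).
#' @param concentrations analyte concentrations (M) in injection order;
#'   default five twofold-ascending steps up to `topConc`.
#' @param topConc top analyte concentration (M) for the default plan.
#' @param contactTime,dissocTime,finalDissoc phase durations (s).
#' @param dt sampling interval (s).
#' @param ligandDensity optional immobilized level (RU) stored as metadata.
#' @return A [Sensorgram-class].
#' @examples
#' sg <- simulateSck(1e5, 0.01, 50, topConc = 1e-6)
#' @export
simulateSck <- function(kon, koff, Rmax, concentrations = NULL,
                        topConc = 1e-6, contactTime = 120, dissocTime = 70,
                        finalDissoc = 600, dt = 1, ligandDensity = NA_real_) {
  for (p in c("kon", "koff", "Rmax"))
    assert_scalar_number(get(p), p, lower = 0, strict_lower = TRUE)
  if (is.null(concentrations))
    concentrations <- topConc / 2^(4:0)
  stopifnot(all(concentrations > 0))
  rows <- list()
  t0 <- 0
  seg <- 0L
  for (i in seq_along(concentrations)) {
    seg <- seg + 1L
    tt <- seq(0, contactTime, by = dt)
    rows[[length(rows) + 1L]] <- data.frame(
      time = t0 + tt, phase = "association", conc = concentrations[i],
      segment = seg)
    t0 <- t0 + contactTime
    seg <- seg + 1L
    dur <- if (i == length(concentrations)) finalDissoc else dissocTime
    tt <- seq(0, dur, by = dt)
    rows[[length(rows) + 1L]] <- data.frame(
      time = t0 + tt, phase = "dissociation", conc = 0, segment = seg)
    t0 <- t0 + dur
  }
  d <- do.call(rbind, rows)
  segs <- .sck_segments(d)
  d$response <- .sck_model(d$time, d$segment, segs)(kon, koff, Rmax)
  sensorgram(d, ligandDensity)
}

#' Kinetic fit of a 1:1 Langmuir model
#'
#' @slot kon,koff,Rmax fitted parameters (1/(M s), 1/s, RU).
#' @slot KD `koff / kon` (M), stored as exactly that quotient.
#' @slot residualNorm root-mean-square residual (RU).
#' @slot biphasic logical; systematic residual structure flagged by a
#'   runs test (data not described by a single exponential phase).
#' @slot converged optimizer convergence.
#' @name KineticFit-class
#' @aliases KineticFit
#' @exportClass KineticFit
setClass("KineticFit", representation(
  kon = "numeric", koff = "numeric", Rmax = "numeric", KD = "numeric",
  residualNorm = "numeric", biphasic = "logical", converged = "logical"))

setValidity("KineticFit", function(object) {
  if (object@kon <= 0 || object@koff <= 0 || object@Rmax <= 0)
    return("parameters must be positive")
  if (!identical(object@KD, object@koff / object@kon))
    return("KD must equal koff/kon exactly")
  TRUE
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(
    "KineticFit: kon %.4g /M/s, koff %.4g /s, KD %.4g M, Rmax %.3g RU%s\n",
    object@kon, object@koff, object@KD, object@Rmax,
    if (object@biphasic) " [biphasic residuals]" else ""))
})

# Wald-Wolfowitz runs test z-statistic on residual signs
.runs_z <- function(r) {
  s <- sign(r)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(0)
  (runs - mu) / sqrt(v)
}

#' Globally fit single-cycle kinetics
#'
#' Nonlinear least squares of the 1:1 Langmuir model over the whole
#' sensorgram (all association and dissociation segments simultaneously),
#' with the bulk refractive-index contribution fixed at 0 and mass transport
#' ignored (transfer constant fixed at 1e8, i.e. kinetics-limited). The
#' optimizer is trust-region Levenberg-Marquardt over log-scaled
#' parameters, restarted from 8 deterministic initial points log-spaced
#' around method-of-moments guesses (dissociation tail slope for koff,
#' response ceiling for Rmax).
#'
#' Sensorgrams whose residuals show strong systematic sign structure
#' (runs test) are flagged `biphasic` -- such data are not described by a
#' single 1:1 phase and the fit should not be interpreted quantitatively.
#'
#' @param sg a [Sensorgram-class] with at least two association segments.
#' @return A [KineticFit-class].
#' @export
fitSck <- function(sg) {
  stopifnot(is(sg, "Sensorgram"))
  d <- sg@data
  if (sum(tapply(d$phase, d$segment, function(p) p[1]) == "association") < 2)
    stop("need >= 2 association segments", call. = FALSE)
  segs <- .sck_segments(d)
  model <- .sck_model(d$time, d$segment, segs)
  obs <- d$response
  # method-of-moments starting guesses
  lastd <- segs$segment[segs$phase == "dissociation"]
  lastd <- lastd[length(lastd)]
  dd <- d[d$segment == lastd & d$response > 1e-6 * max(abs(obs)), ]
  koff0 <- 0.01
  if (nrow(dd) >= 3) {
    sl <- unname(coef(lm(log(dd$response) ~ dd$time))[2])
    if (is.finite(sl) && sl < 0) koff0 <- -sl
  }
  Rmax0 <- 1.5 * max(obs)
  topC <- max(segs$conc)
  kon0 <- koff0 / topC
  starts <- rbind(
    c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
    c(1, 1), c(-1, -1), c(0.5, -0.5))
  resid_fn <- function(p) obs - model(10^p[1], 10^p[2], 10^p[3])
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log10(kon0) + starts[i, 1], log10(koff0) + starts[i, 2],
            log10(Rmax0))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = fit$par, ssr = ssr,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best))
    stop("kinetic fit failed from every start", call. = FALSE)
  kon <- 10^best$par[1]; koff <- 10^best$par[2]; Rmax <- 10^best$par[3]
  r <- resid_fn(best$par)
  rms <- sqrt(mean(r^2))
  biphasic <- rms > 5e-3 * Rmax && .runs_z(r) < -4
  new("KineticFit", kon = kon, koff = koff, Rmax = Rmax, KD = koff / kon,
      residualNorm = rms, biphasic = biphasic, converged = best$converged)
}

#' Steady-state (equilibrium) affinity fit
#'
#' Least-squares fit of the one-site binding hyperbola
#' `Req(C) = Rmax C / (KD + C)` to equilibrium responses.
#'
#' @param concentrations analyte concentrations (M), length >= 3.
#' @param responses equilibrium responses (RU).
#' @return list with `KD` (M), `Rmax` (RU), `residualNorm`.
#' @examples
#' C <- 10^seq(-8, -5, length.out = 8)
#' fitSteadyState(C, 50 * C / (330e-9 + C))$KD
#' @export
fitSteadyState <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 3)
    stop("need >= 3 concentrations", call. = FALSE)
  if (var(responses) == 0)
    stop("degenerate data: all responses equal", call. = FALSE)
  resid_fn <- function(p)
    responses - 10^p[2] * concentrations / (10^p[1] + concentrations)
  best <- NULL
  for (kd0 in unname(quantile(concentrations, c(0.1, 0.5, 0.9)))) {
    p0 <- c(log10(kd0), log10(max(responses) * 1.2))
    fit <- tryCatch(minpack.lm::nls.lm(p0, fn = resid_fn),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) stop("steady-state fit failed", call. = FALSE)
  list(KD = 10^best$par[1], Rmax = 10^best$par[2],
       residualNorm = sqrt(best$ssr / length(responses)))
}

#' Theoretical surface capacity
#'
#' Maximum analyte-binding capacity of an SPR surface:
#' `Rmax = density x (MW_analyte / MW_ligand) x valence`. Comparing this
#' with the fitted experimental Rmax is a standard sanity check on a 1:1
#' interpretation.
#'
#' @param ligandDensity immobilized ligand level (RU).
#' @param mwLigand,mwAnalyte molecular weights (same units).
#' @param valence analyte binding sites per ligand.
#' @return theoretical Rmax in RU.
#' @examples
#' theoreticalRmax(74, 10000, 10000)  # 74
#' @export
theoreticalRmax <- function(ligandDensity, mwLigand, mwAnalyte, valence = 1) {
  assert_scalar_number(ligandDensity, "ligandDensity", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(mwLigand, "mwLigand", lower = 0, strict_lower = TRUE)
  assert_scalar_number(mwAnalyte, "mwAnalyte", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(valence, "valence", lower = 0, strict_lower = TRUE)
  ligandDensity * (mwAnalyte / mwLigand) * valence
}
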