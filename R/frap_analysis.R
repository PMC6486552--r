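## FRAP inference: recovery-phase extraction, ensemble averaging, the
## combined photobleach-corrected recovery fit used in vitro,
##     I(t) = a*exp(-t/tau_b) + I0*(1 - exp(-t/tau)),
## and the two-step in-vivo procedure (single-exponential fit to unpulsed
## control cells, pointwise correction, then a pure-recovery fit).

#' Normalize a trace to its pre-pulse steady state
#'
#' Divides intensities by the mean over frames before the first pulse
#' (after baseline subtraction), the convention used for "normalized
#' intensity" throughout: the pre-pulse steady state is 1.
#'
#' @param trace an [IntensityTrace-class] with at least one pulse time.
#' @param baseline additive offset to subtract first.
#' @return the normalized [IntensityTrace-class].
#' @export
normalizeTrace <- function(trace, baseline = 0) {
    stopIfNot(length(trace@pulseTimes) >= 1,
              "no pulse times; cannot locate the pre-pulse window")
    pre <- trace@t < min(trace@pulseTimes)
    stopIfNot(any(pre), "no frames before the first pulse")
    ref <- mean(trace@I[pre] - baseline)
    stopIfNot(is.finite(ref) && ref > 0, "non-positive pre-pulse level")
    trace@I <- (trace@I - baseline) / ref
    if (length(trace@sem)) trace@sem <- trace@sem / ref
    trace
}

#' Detect FRAP pulse frames from a trace
#'
#' A pulse frame is a >80% single-frame drop relative to the running
#' pre-drop level.
#'
#' @param trace an [IntensityTrace-class].
#' @param dropFraction minimal fractional single-frame drop.
#' @return numeric vector of detected pulse times (possibly empty).
#' @export
detectPulses <- function(trace, dropFraction = 0.8) {
    I <- trace@I; t <- trace@t
    n <- length(I)
    if (n < 4) return(numeric(0))
    lev <- vapply(seq_len(n), function(m)
        mean(I[max(1, m - 5):max(1, m - 1)]), numeric(1))
    scale <- max(abs(lev))
    hits <- which(lev - I > dropFraction * pmax(lev, 0.2 * scale) &
                      lev > 0.3 * scale)
    ## keep the first frame of each drop run
    if (length(hits)) hits <- hits[c(TRUE, diff(hits) > 2)]
    t[hits]
}

#' Extract aligned post-pulse recovery phases
#'
#' Splits a trace at its FRAP pulses (from metadata, or detected as >80%
#' single-frame intensity drops when `trace@pulseTimes` is empty), re-zeroes
#' each phase to its pulse time and truncates it at the next pulse. Empty
#' phases (pulse at the last frame) are excluded with a warning.
#'
#' @param trace an [IntensityTrace-class].
#' @param maxPhases keep at most this many phases (the convention is to
#'   average the first three).
#' @return list of [IntensityTrace-class] phases (times start at the first
#'   frame after the pulse).
#' @export
extractRecoveryPhases <- function(trace, maxPhases = Inf) {
    pulses <- trace@pulseTimes
    if (!length(pulses)) pulses <- detectPulses(trace)
    if (!length(pulses)) {
        cand <- order(diff(c(trace@I[1], trace@I)))[1:3]
        stop("no FRAP pulse found; steepest candidate frames: ",
             paste(sort(cand), collapse = ", "))
    }
    pulses <- sort(pulses)
    phases <- list()
    for (i in seq_along(pulses)) {
        if (length(phases) >= maxPhases) break
        lo <- pulses[i]
        hi <- if (i < length(pulses)) pulses[i + 1] else Inf
        sel <- trace@t > lo & trace@t < hi
        if (!any(sel)) {
            warning("empty recovery phase after pulse at t = ", lo,
                    " excluded")
            next
        }
        phases[[length(phases) + 1L]] <-
            intensityTrace(trace@t[sel] - lo, trace@I[sel],
                           spotId = paste0(trace@spotId, "_phase",
                                           length(phases) + 1L),
                           frameInterval = trace@frameInterval)
    }
    phases
}

#' Average recovery phases onto a common time base
#'
#' Linear interpolation of every phase onto the time grid of the shortest
#' one, then pointwise mean and SEM with equal weight per phase.
#'
#' @param phases list of [IntensityTrace-class] (>= 2).
#' @param tolFraction phases whose frame interval differs from the common
#'   base by more than this fraction are an error.
#' @return an [IntensityTrace-class] with `sem` filled and
#'   `nTraces = length(phases)`.
#' @export
averageTraces <- function(phases, tolFraction = 0.25) {
    stopIfNot(length(phases) >= 2, "need >= 2 phases to average")
    dts <- vapply(phases, function(p) p@frameInterval, numeric(1))
    dt <- median(dts)
    stopIfNot(all(abs(dts - dt) <= tolFraction * dt),
              "phase time bases differ beyond tolerance")
    tEnd <- min(vapply(phases, function(p) max(p@t), numeric(1)))
    grid <- seq(dt, tEnd, by = dt)
    mat <- vapply(phases, function(p)
        approx(p@t, p@I, xout = grid, rule = 2)$y,
        numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    mu <- rowMeans(mat)
    sem <- apply(mat, 1, sd) / sqrt(length(phases))
    intensityTrace(grid, mu, spotId = "mean", frameInterval = dt,
                   sem = sem, nTraces = length(phases))
}

## Initial values for the combined recovery fit, per the documented scheme:
## tau from time-to-half-recovery / ln 2, tau_b from the tail slope, a from
## I(0), I0 from the plateau.
eq1Start <- function(t, I) {
    plateau <- mean(tail(I, max(3, round(length(I) / 5))))
    I0 <- max(plateau, 0.05)
    half <- which(I >= I0 / 2)[1]
    tau <- if (is.na(half)) max(t) / 2 else max(t[half], t[2]) / log(2)
    tail3 <- seq(floor(2 * length(t) / 3), length(t))
    slope <- coef(lm(I[tail3] ~ t[tail3]))[[2]]
    tauB <- if (slope < -1e-6) min(I0 / abs(slope), 20 * max(t)) else
        10 * max(t)
    a <- max(I[1], 0.02)
    list(a = a, tauB = tauB, I0 = I0, tau = max(tau, t[1]))
}

#' Combined photobleach-corrected FRAP recovery fit
#'
#' Nonlinear least squares (Levenberg-Marquardt, all-positive bounds) of
#' \deqn{I(t) = a e^{-t/\tau_b} + I_0 (1 - e^{-t/\tau})}
#' to an averaged, pre-pulse-normalized recovery trace. Standard errors
#' come from the Jacobian; an optional bootstrap over contributing phases
#' can be attached via [bootstrapTau()]. Fits with a vanishing bleach
#' amplitude are re-fit without the bleach term and flagged
#' `"tauB_unidentifiable"`; fits where `tau` and `tauB` differ by <20% are
#' flagged `"near_degenerate"`; parameters at their bounds are flagged
#' `"at_bound"`.
#'
#' @param meanTrace an [IntensityTrace-class], normalized so the pre-pulse
#'   steady state is 1 and `t = 0` at the pulse.
#' @param weights optional per-point weights (e.g. `1/sem^2`).
#' @return A [RecoveryFit-class].
#' @export
fitRecoveryEq1 <- function(meanTrace, weights = NULL) {
    t <- meanTrace@t; I <- meanTrace@I
    stopIfNot(length(t) >= 8, "recovery trace too short to fit")
    st <- eq1Start(t, I)
    w <- if (is.null(weights)) rep(1, length(t)) else weights
    oneFit <- function(start) tryCatch(
        minpack.lm::nlsLM(
            I ~ a * exp(-t / tauB) + I0 * (1 - exp(-t / tau)),
            start = start, weights = w,
            lower = c(a = 0, tauB = 1e-3, I0 = 0, tau = 1e-3),
            upper = c(a = Inf, tauB = 1e5, I0 = Inf, tau = 1e4),
            control = nls.control(maxiter = 200, warnOnly = TRUE)),
        error = function(e) e)
    ## multi-start on tauB: the (a, tauB) pair rides a shallow valley when
    ## tauB is close to tau, so a single start can stall off-optimum
    fit <- NULL
    for (tb0 in unique(c(st$tauB, st$tau * c(0.5, 1, 2), 10 * max(t)))) {
        cand <- oneFit(modifyList(st, list(tauB = tb0)))
        if (inherits(cand, "error")) next
        if (is.null(fit) ||
            sum(residuals(cand)^2) < sum(residuals(fit)^2) - 1e-12)
            fit <- cand
    }
    flags <- character(0)
    cf <- if (is.null(fit)) NULL else coef(fit)
    if (is.null(cf) || cf[["a"]] < 0.05 * max(cf[["I0"]], 1e-6)) {
        ## a vanishing bleach amplitude makes the (a, tauB) pair
        ## unidentifiable (singular Jacobian): drop the bleach term and
        ## re-fit the pure recovery
        flags <- c(flags, "tauB_unidentifiable")
        fit <- tryCatch(
            minpack.lm::nlsLM(I ~ I0 * (1 - exp(-t / tau)),
                              start = st[c("I0", "tau")], weights = w,
                              lower = c(I0 = 0, tau = 1e-3),
                              control = nls.control(maxiter = 200,
                                                    warnOnly = TRUE)),
            error = function(e) e)
        if (inherits(fit, "error"))
            stop("recovery fit did not converge; initialization was: ",
                 paste(names(st), signif(unlist(st), 3), sep = "=",
                       collapse = ", "))
        cf <- c(a = 0, tauB = NA_real_, coef(fit))
    }
    se <- tryCatch({
        s <- sqrt(diag(vcov(fit)))
        full <- c(a = NA_real_, tauB = NA_real_, I0 = NA_real_,
                  tau = NA_real_)
        full[names(s)] <- s
        full
    }, error = function(e)
        c(a = NA_real_, tauB = NA_real_, I0 = NA_real_, tau = NA_real_))
    if (is.finite(cf[["tauB"]]) &&
        abs(cf[["tau"]] - cf[["tauB"]]) < 0.2 * cf[["tau"]])
        flags <- c(flags, "near_degenerate")
    if (cf[["tau"]] <= 2e-3 || cf[["tau"]] >= 9e3)
        flags <- c(flags, "at_bound")
    new("RecoveryFit", a = unname(cf[["a"]]), tauB = unname(cf[["tauB"]]),
        I0 = unname(cf[["I0"]]), tau = unname(cf[["tau"]]), se = se,
        tauBoot = numeric(0), rss = sum(residuals(fit)^2),
        nTraces = meanTrace@nTraces, flags = flags)
}

#' Bootstrap the exchange time over contributing phases
#'
#' Resamples phases with replacement, re-averages and re-fits, attaching
#' the bootstrap draws of `tau` to the fit.
#'
#' @param phases list of [IntensityTrace-class] recovery phases.
#' @param fitFun fitting function for an averaged trace (default
#'   [fitRecoveryEq1()]); for the two-step route pass a closure around
#'   [bleachCorrectAndFit()].
#' @param B number of resamples.
#' @param seed RNG seed.
#' @return numeric vector of bootstrap `tau` draws (failures dropped).
#' @export
bootstrapTau <- function(phases, fitFun = fitRecoveryEq1, B = 200,
                         seed = 1L) {
    draws <- withSeed(seed, {
        vapply(seq_len(B), function(b) {
            idx <- sample(length(phases), replace = TRUE)
            tryCatch(exchangeTime(fitFun(averageTraces(phases[idx]))),
                     error = function(e) NA_real_)
        }, numeric(1))
    })
    draws[is.finite(draws)]
}

#' Fit the imaging-photobleach lifetime from unpulsed control cells
#'
#' Averages the control-cell traces (normalized to their initial level) and
#' fits a single-exponential decay `A*exp(-t/tauB)`. A rising control is an
#' error; a flat control returns `tauB = Inf` flagged `"no_bleaching"`.
#'
#' @param controlTraces list of [IntensityTrace-class] from >= 2 unpulsed
#'   cells.
#' @return A [BleachControlFit-class].
#' @export
fitBleachControl <- function(controlTraces) {
    stopIfNot(length(controlTraces) >= 2, "need >= 2 control cells")
    norm <- lapply(controlTraces, function(tr) {
        ref <- mean(head(tr@I, 3))
        intensityTrace(tr@t, tr@I / ref, spotId = tr@spotId,
                       frameInterval = tr@frameInterval)
    })
    avg <- averageTraces(norm)
    t <- avg@t; I <- avg@I
    slope <- coef(lm(I ~ t))[[2]]
    relSlope <- slope * max(t) / mean(I)
    if (relSlope > 0.05)
        stop("control intensity increases over time: invalid control")
    if (relSlope > -0.01) {
        return(new("BleachControlFit", tauB = Inf, amplitude = mean(I),
                   se = c(tauB = NA_real_, A = NA_real_),
                   nCells = length(controlTraces), flags = "no_bleaching"))
    }
    fit <- minpack.lm::nlsLM(I ~ A * exp(-t / tauB),
                             start = list(A = I[1],
                                          tauB = max(-1 / (slope / mean(I)),
                                                     t[2])),
                             lower = c(A = 0, tauB = 1e-3),
                             control = nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))),
                   error = function(e) c(A = NA_real_, tauB = NA_real_))
    new("BleachControlFit", tauB = cf[["tauB"]], amplitude = cf[["A"]],
        se = c(tauB = unname(se[["tauB"]]), A = unname(se[["A"]])),
        nCells = length(controlTraces), flags = character(0))
}

#' Two-step photobleach-corrected recovery fit (in vivo)
#'
#' Divides the averaged FRAP trace pointwise by the fitted control decay
#' `exp(-t/tauB)` and fits the pure recovery `I0*(1 - exp(-t/tau))`. This
#' is the in-vivo procedure, distinct from the combined single-step fit of
#' [fitRecoveryEq1()]. Correction factors above `maxGain` (late times,
#' strong bleaching) are truncated with a warning. With a flat control
#' (`tauB = Inf`) the correction is the identity.
#'
#' @param meanTrace averaged normalized FRAP trace, `t = 0` at the pulse.
#' @param controlFit a [BleachControlFit-class].
#' @param maxGain maximal correction factor retained.
#' @return A [RecoveryFit-class] (with `a = 0`, `tauB` from the control).
#' @export
bleachCorrectAndFit <- function(meanTrace, controlFit, maxGain = 10) {
    stopIfNot(is(controlFit, "BleachControlFit"), "controlFit invalid")
    t <- meanTrace@t
    gain <- exp(t / controlFit@tauB)
    keep <- gain <= maxGain
    if (!all(keep))
        warning("bleach correction exceeds ", maxGain,
                "x at late times; trace truncated at t = ",
                signif(max(t[keep]), 3), " s")
    t <- t[keep]
    I <- meanTrace@I[keep] * gain[keep]
    st <- eq1Start(t, I)
    fit <- minpack.lm::nlsLM(I ~ I0 * (1 - exp(-t / tau)),
                             start = st[c("I0", "tau")],
                             lower = c(I0 = 0, tau = 1e-3),
                             control = nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))),
                   error = function(e) c(I0 = NA_real_, tau = NA_real_))
    new("RecoveryFit", a = 0, tauB = controlFit@tauB, I0 = cf[["I0"]],
        tau = cf[["tau"]],
        se = c(a = NA_real_, tauB = unname(controlFit@se[["tauB"]]),
               I0 = unname(se[["I0"]]), tau = unname(se[["tau"]])),
        tauBoot = numeric(0), rss = sum(residuals(fit)^2),
        nTraces = meanTrace@nTraces, flags = "two_step")
}
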