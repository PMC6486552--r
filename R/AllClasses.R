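#' @import methods
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the fork/SSB exchange model
#'
#' Holds every kinetic, photophysical and imaging parameter of the stochastic
#' replisome simulation. Exchange of fork-bound SSB tetramers with the
#' solution pool follows a pseudo-first-order law
#' \eqn{k_{ex}(c) = k_{intr} + k_{fac} c}, so the ground-truth exchange time
#' is \eqn{\tau = 1/k_{ex}}. Internal transfer of a tetramer displaced by the
#' lagging-strand polymerase succeeds with probability
#' \eqn{p_{int} = s/(s + c)} (competition constant `pIntScale` = \eqn{s});
#' with `pIntScale = Inf` every displaced tetramer transfers internally.
#'
#' Photobleaching: `tauB` is the per-dye bleach lifetime under continuous
#' illumination. Acquisition may be stroboscopic: only a fraction
#' `exposure/frameInterval` of wall time is illuminated, so the wall-clock
#' bleach rate is `exposure/(frameInterval * tauB)`.
#'
#' @slot vMean,vSd mean and between-replisome spread of the replication rate
#'   (bp/s).
#' @slot cSSB solution SSB tetramer concentration (nM).
#' @slot kFac facilitated exchange rate constant (nM^-1 s^-1).
#' @slot kIntr intrinsic, concentration-independent exchange rate (s^-1).
#' @slot pIntScale competition constant for internal transfer (nM); `Inf`
#'   disables displacement loss.
#' @slot lengthTable named numeric, concentration (nM, names) to mean
#'   Okazaki-fragment length (knt). Interpolated log-linearly in
#'   concentration. The default top entry is 100 nM: the source gel assigns
#'   2.8 knt to its highest-concentration lane, which the running text calls
#'   200 nM but the figure legend calls 100 nM; the legend value is used.
#' @slot footprintNt nucleotides occluded per tetramer (nt).
#' @slot labeledFraction fraction of solution tetramers carrying dye.
#' @slot dyesMean mean number of dyes per labelled tetramer (in \[1, 2\]).
#' @slot tauB per-dye photobleach lifetime under continuous illumination (s).
#' @slot exposure illuminated time per frame (s); equal to `frameInterval`
#'   for continuous imaging.
#' @slot frameInterval acquisition interval (s).
#' @slot unitBrightness intensity per bright dye (AU).
#' @slot baseline additive background (AU).
#' @slot noiseSd per-frame Gaussian noise (AU).
#' @slot pulseTimes FRAP pulse times (s).
#' @slot duration simulated time (s).
#' @slot seed integer RNG seed; recorded in all outputs.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    vMean = "numeric", vSd = "numeric",
    cSSB = "numeric", kFac = "numeric", kIntr = "numeric",
    pIntScale = "numeric",
    lengthTable = "numeric", footprintNt = "numeric",
    labeledFraction = "numeric", dyesMean = "numeric",
    tauB = "numeric", exposure = "numeric", frameInterval = "numeric",
    unitBrightness = "numeric", baseline = "numeric", noiseSd = "numeric",
    pulseTimes = "numeric", duration = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msgs <- character(0)
    chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
    chk(object@vMean >= 0, "vMean must be >= 0")
    chk(object@vSd >= 0, "vSd must be >= 0")
    chk(object@cSSB >= 0, "cSSB must be non-negative")
    chk(object@kFac >= 0 && object@kIntr >= 0, "rate constants must be >= 0")
    chk(object@pIntScale > 0, "pIntScale must be > 0 (Inf allowed)")
    chk(length(object@lengthTable) >= 1 && all(object@lengthTable > 0),
        "lengthTable must be non-empty with positive lengths")
    chk(!is.null(names(object@lengthTable)) &&
            all(suppressWarnings(as.numeric(names(object@lengthTable))) > 0),
        "lengthTable names must be positive concentrations")
    chk(object@footprintNt >= 1, "footprintNt must be >= 1")
    chk(object@labeledFraction >= 0 && object@labeledFraction <= 1,
        "labeledFraction must be in [0, 1]")
    chk(object@dyesMean >= 1 && object@dyesMean <= 2,
        "dyesMean must be in [1, 2]")
    chk(object@tauB > 0, "tauB must be > 0")
    chk(object@frameInterval > 0, "frameInterval must be > 0")
    chk(object@exposure > 0 && object@exposure <= object@frameInterval,
        "exposure must be in (0, frameInterval]")
    chk(object@duration > 0, "duration must be > 0")
    chk(all(object@pulseTimes >= 0 & object@pulseTimes <= object@duration),
        "pulseTimes must lie within [0, duration]")
    chk(object@noiseSd >= 0, "noiseSd must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param vMean,vSd replication rate mean and spread (bp/s).
#' @param cSSB SSB concentration (nM).
#' @param kFac,kIntr exchange-law constants (see [SimConfig-class]).
#' @param pIntScale internal-transfer competition constant (nM).
#' @param lengthTable named numeric mapping concentration (nM) to mean
#'   Okazaki length (knt).
#' @param footprintNt per-tetramer site size (nt).
#' @param labeledFraction fraction of labelled tetramers.
#' @param dyesMean mean dyes per labelled tetramer.
#' @param tauB continuous-illumination photobleach lifetime (s).
#' @param exposure illuminated time per frame (s).
#' @param frameInterval frame interval (s).
#' @param unitBrightness,baseline,noiseSd imaging model (AU).
#' @param pulseTimes FRAP pulse times (s).
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(cSSB = 10, duration = 60)
#' effectiveExchangeRate(cfg)
#' @export
simConfig <- function(vMean = 750, vSd = 70, cSSB = 10,
                      kFac = 0.0033, kIntr = 0.01, pIntScale = 20,
                      lengthTable = defaultLengthTable(),
                      footprintNt = 35, labeledFraction = 1,
                      dyesMean = 1.5, tauB = 9.5,
                      exposure = frameInterval, frameInterval = 0.5,
                      unitBrightness = 1, baseline = 0, noiseSd = 2,
                      pulseTimes = numeric(0), duration = 120, seed = 1L) {
    new("SimConfig", vMean = vMean, vSd = vSd, cSSB = cSSB, kFac = kFac,
        kIntr = kIntr, pIntScale = pIntScale, lengthTable = lengthTable,
        footprintNt = footprintNt, labeledFraction = labeledFraction,
        dyesMean = dyesMean, tauB = tauB, exposure = exposure,
        frameInterval = frameInterval, unitBrightness = unitBrightness,
        baseline = baseline, noiseSd = noiseSd, pulseTimes = pulseTimes,
        duration = duration, seed = as.integer(seed))
}

#' Default concentration-to-length table for Okazaki fragments
#'
#' Mean Okazaki-fragment lengths (knt) measured by gel densitometry at four
#' SSB concentrations. The highest-concentration entry is recorded under
#' 100 nM (the figure-legend value; the running text of the source calls the
#' same lane 200 nM).
#'
#' @return Named numeric vector (names are concentrations in nM).
#' @export
defaultLengthTable <- function() {
    c("2" = 1.4, "10" = 1.5, "20" = 2.0, "100" = 2.8)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:",
        sprintf("v = %g +/- %g bp/s, c = %g nM", object@vMean, object@vSd,
                object@cSSB), "\n")
    cat(sprintf("  exchange: k_intr = %g /s, k_fac = %g /nM/s (tau = %.3g s)",
                object@kIntr, object@kFac,
                1 / (object@kIntr + object@kFac * object@cSSB)), "\n")
    cat(sprintf("  p_int scale = %g nM, footprint = %g nt, mean OF = %.3g knt",
                object@pIntScale, object@footprintNt,
                okazakiMeanLength(object)), "\n")
    cat(sprintf("  imaging: tau_b = %g s, exposure %g s / frame %g s, %d pulses",
                object@tauB, object@exposure, object@frameInterval,
                length(object@pulseTimes)), "\n")
    cat(sprintf("  duration = %g s, seed = %d", object@duration,
                object@seed), "\n")
})

## ---------------------------------------------------------------------------
## ReplisomeSim
## ---------------------------------------------------------------------------

#' Result of one simulated replisome
#'
#' @slot config the [SimConfig-class] used.
#' @slot v realized replication rate (bp/s).
#' @slot cycles data.frame of Okazaki cycles: `start`, `end` (s),
#'   `length_nt`, `demand` (tetramers).
#' @slot ledger per-tetramer event history: `id`, `origin`
#'   (initial/solution), `bind_time`, `release_time` (NA if still bound),
#'   `fate` (internal_transfer / solution_exchange / retained_at_end /
#'   bleached_in_place), `exit_channel` (exchange / displaced / none),
#'   `n_transfers`, `labeled`, `n_dyes`, `dye1_bleach`, `dye2_bleach`
#'   (wall-clock bleach times, Inf = never).
#' @slot pulses FRAP pulse times already applied to the ledger (s).
#' @slot groundTruth list: realized `v`, `mean_of_knt`, `k_ex`, `tau_true`.
#' @exportClass ReplisomeSim
setClass("ReplisomeSim", representation(
    config = "SimConfig", v = "numeric", cycles = "data.frame",
    ledger = "data.frame", pulses = "numeric", groundTruth = "list"))

setMethod("show", "ReplisomeSim", function(object) {
    cat(sprintf("ReplisomeSim: %d tetramers over %d cycles, v = %.0f bp/s\n",
                nrow(object@ledger), nrow(object@cycles), object@v))
    cat(sprintf("  ground truth: k_ex = %.4g /s (tau = %.3g s), mean OF = %.3g knt\n",
                object@groundTruth$k_ex, object@groundTruth$tau_true,
                object@groundTruth$mean_of_knt))
    if (length(object@pulses))
        cat("  FRAP pulses at:", paste(signif(object@pulses, 4),
                                       collapse = ", "), "s\n")
})

#' @describeIn ReplisomeSim-class tetramer event ledger accessor.
#' @param x a `ReplisomeSim`.
#' @export
tetramerLedger <- function(x) x@ledger

#' @describeIn ReplisomeSim-class ground-truth parameter accessor.
#' @export
groundTruth <- function(x) x@groundTruth

## ---------------------------------------------------------------------------
## IntensityTrace
## ---------------------------------------------------------------------------

#' Time-stamped fluorescence intensity of one spot or focus
#'
#' @slot t frame times (s), strictly increasing.
#' @slot I intensities (AU).
#' @slot sem optional per-point standard errors (length 0 or length(t)).
#' @slot spotId identifier.
#' @slot pulseTimes known FRAP pulse times (s).
#' @slot frameInterval nominal frame interval (s).
#' @slot nTraces number of traces averaged into this one (1 for raw).
#' @exportClass IntensityTrace
setClass("IntensityTrace", representation(
    t = "numeric", I = "numeric", sem = "numeric", spotId = "character",
    pulseTimes = "numeric", frameInterval = "numeric", nTraces = "integer"))

setValidity("IntensityTrace", function(object) {
    msgs <- character(0)
    if (length(object@t) != length(object@I))
        msgs <- c(msgs, "t and I must have equal length")
    if (length(object@t) > 1 && any(diff(object@t) <= 0))
        msgs <- c(msgs, "t must be strictly increasing")
    if (any(!is.finite(object@I)))
        msgs <- c(msgs, "I must be finite")
    if (length(object@sem) && length(object@sem) != length(object@t))
        msgs <- c(msgs, "sem must be empty or match t")
    if (length(msgs)) msgs else TRUE
})

#' Construct an intensity trace
#' @param t,I time (s) and intensity (AU) vectors.
#' @param spotId identifier.
#' @param pulseTimes known pulse times (s).
#' @param frameInterval nominal frame interval (s); inferred from `t` if
#'   missing.
#' @param sem optional per-point SEM.
#' @param nTraces number of traces averaged in.
#' @return An [IntensityTrace-class].
#' @export
intensityTrace <- function(t, I, spotId = "spot", pulseTimes = numeric(0),
                           frameInterval = NULL, sem = numeric(0),
                           nTraces = 1L) {
    if (is.null(frameInterval))
        frameInterval <- if (length(t) > 1) median(diff(t)) else 1
    new("IntensityTrace", t = as.numeric(t), I = as.numeric(I), sem = sem,
        spotId = as.character(spotId), pulseTimes = pulseTimes,
        frameInterval = frameInterval, nTraces = as.integer(nTraces))
}

setMethod("show", "IntensityTrace", function(object) {
    cat(sprintf("IntensityTrace '%s': %d frames over %.3g s (N = %d)\n",
                object@spotId, length(object@t),
                diff(range(object@t)), object@nTraces))
})

#' Convert an intensity trace to a data.frame
#' @param x an [IntensityTrace-class].
#' @param ... unused.
#' @return data.frame with columns `t`, `I` (and `sem` when present).
#' @export
setMethod("as.data.frame", "IntensityTrace", function(x, ...) {
    df <- data.frame(t = x@t, I = x@I)
    if (length(x@sem)) df$sem <- x@sem
    df
})

## ---------------------------------------------------------------------------
## Fits
## ---------------------------------------------------------------------------

#' FRAP recovery fit
#'
#' Parameters of the photobleach-corrected recovery model
#' \deqn{I(t) = a e^{-t/\tau_b} + I_0 (1 - e^{-t/\tau})}
#' fitted to a (typically averaged, pre-pulse-normalized) recovery trace.
#' For the two-step in-vivo procedure `a` is 0 and `tauB` comes from the
#' control-cell fit.
#'
#' @slot a amplitude of the photobleaching component (AU).
#' @slot tauB photobleaching time (s).
#' @slot I0 steady-state fork/focus signal (AU).
#' @slot tau exchange time (s).
#' @slot se named numeric of standard errors (from the Jacobian).
#' @slot tauBoot bootstrap draws of tau (may be empty).
#' @slot rss residual sum of squares.
#' @slot nTraces number of traces behind the fitted curve.
#' @slot flags character flags (e.g. "tauB_unidentifiable",
#'   "near_degenerate", "two_step", "at_bound").
#' @exportClass RecoveryFit
setClass("RecoveryFit", representation(
    a = "numeric", tauB = "numeric", I0 = "numeric", tau = "numeric",
    se = "numeric", tauBoot = "numeric", rss = "numeric",
    nTraces = "integer", flags = "character"))

setMethod("show", "RecoveryFit", function(object) {
    cat(sprintf(
        "RecoveryFit: tau = %.3g +/- %.2g s, I0 = %.3g, a = %.3g, tau_b = %.3g s\n",
        object@tau, if ("tau" %in% names(object@se)) object@se[["tau"]] else NA,
        object@I0, object@a, object@tauB))
    if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                    collapse = ", "), "\n")
})

#' Exchange time accessor
#' @param fit a [RecoveryFit-class].
#' @return fitted exchange time (s).
#' @export
exchangeTime <- function(fit) fit@tau

#' Control-cell photobleach fit
#'
#' @slot tauB photobleaching lifetime (s); `Inf` when no decay is detected.
#' @slot amplitude fitted initial amplitude (AU).
#' @slot se named standard errors.
#' @slot nCells number of control cells averaged.
#' @slot flags character flags.
#' @exportClass BleachControlFit
setClass("BleachControlFit", representation(
    tauB = "numeric", amplitude = "numeric", se = "numeric",
    nCells = "integer", flags = "character"))

setMethod("show", "BleachControlFit", function(object) {
    cat(sprintf("BleachControlFit: tau_b = %.3g s from %d control cells\n",
                object@tauB, object@nCells))
})

## ---------------------------------------------------------------------------
## Okazaki analysis containers
## ---------------------------------------------------------------------------

#' Okazaki-fragment length sample
#'
#' @slot concentration SSB concentration (nM).
#' @slot lengths fragment lengths / inter-spot distances (knt).
#' @slot censorLimit detection (diffraction) limit below which distances are
#'   unobservable (knt).
#' @slot estimate list with `mean`, `ci` (2-vector), `n`, `method` once
#'   [fitExponentialLengths()] has run.
#' @exportClass OkazakiSample
setClass("OkazakiSample", representation(
    concentration = "numeric", lengths = "numeric", censorLimit = "numeric",
    estimate = "list"))

setValidity("OkazakiSample", function(object) {
    msgs <- character(0)
    if (any(object@lengths <= 0)) msgs <- c(msgs, "lengths must be > 0")
    if (object@censorLimit < 0) msgs <- c(msgs, "censorLimit must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn OkazakiSample-class constructor.
#' @param lengths fragment lengths (knt).
#' @param concentration SSB concentration (nM).
#' @param censorLimit detection limit (knt).
#' @export
okazakiSample <- function(lengths, concentration = NA_real_,
                          censorLimit = 0) {
    new("OkazakiSample", concentration = concentration,
        lengths = as.numeric(lengths), censorLimit = censorLimit,
        estimate = list())
}

setMethod("show", "OkazakiSample", function(object) {
    cat(sprintf("OkazakiSample: %d lengths at %g nM (censor %g knt)\n",
                length(object@lengths), object@concentration,
                object@censorLimit))
    if (length(object@estimate))
        cat(sprintf("  mean = %.3g knt (95%% CI %.3g-%.3g, %s)\n",
                    object@estimate$mean, object@estimate$ci[1],
                    object@estimate$ci[2], object@estimate$method))
})

#' Emulated alkaline-gel lane
#'
#' @slot lengthAxis bin centres (knt), log-spaced, monotone.
#' @slot raw raw densitometry profile: each fragment contributes intensity
#'   proportional to its length (stain scales with nucleotides).
#' @slot normalized profile after dividing intensity by length.
#' @slot mean,sd distribution mean and sd computed on the normalized profile
#'   (knt).
#' @slot ladder ladder band lengths used for calibration (knt).
#' @exportClass GelLane
setClass("GelLane", representation(
    lengthAxis = "numeric", raw = "numeric", normalized = "numeric",
    mean = "numeric", sd = "numeric", ladder = "numeric"))

setValidity("GelLane", function(object) {
    msgs <- character(0)
    if (any(object@normalized < 0)) msgs <- c(msgs, "normalized profile < 0")
    if (is.unsorted(object@lengthAxis))
        msgs <- c(msgs, "length axis must be monotone")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "GelLane", function(object) {
    cat(sprintf("GelLane: %d bins, normalized mean = %.3g +/- %.3g knt\n",
                length(object@lengthAxis), object@mean, object@sd))
})

## ---------------------------------------------------------------------------
## Trajectory analysis containers
## ---------------------------------------------------------------------------

#' Piecewise-linear segmentation of a fork trajectory
#'
#' @slot breakpoints interior breakpoint times (s).
#' @slot segments data.frame: `start`, `end` (s), `slope_bp_s`,
#'   `duration`, `rss`.
#' @slot residualVariance pooled residual variance (bp^2).
#' @exportClass SegmentedTrajectory
setClass("SegmentedTrajectory", representation(
    breakpoints = "numeric", segments = "data.frame",
    residualVariance = "numeric"))

setMethod("show", "SegmentedTrajectory", function(object) {
    cat(sprintf("SegmentedTrajectory: %d segment(s)\n",
                nrow(object@segments)))
    print(object@segments, row.names = FALSE, digits = 4)
})

#' Distribution of per-replisome replication rates
#'
#' @slot rates per-replisome rates (bp/s).
#' @slot mean,sd,sem Gaussian fit (maximum likelihood) and standard error of
#'   the mean (`sem = sd/sqrt(N)`).
#' @slot n number of contributing rates.
#' @slot nRejected non-finite inputs dropped.
#' @exportClass RateDistribution
setClass("RateDistribution", representation(
    rates = "numeric", mean = "numeric", sd = "numeric", sem = "numeric",
    n = "integer", nRejected = "integer"))

setMethod("show", "RateDistribution", function(object) {
    cat(sprintf("RateDistribution: %.0f +/- %.0f bp/s (mean +/- SEM, N = %d)\n",
                object@mean, object@sem, object@n))
})

## ---------------------------------------------------------------------------
## Rendering containers
## ---------------------------------------------------------------------------

#' Two-channel kymograph stack
#'
#' Kymographs are 2D images with rows = frames (time) and columns = position
#' along the stretched DNA (flow direction, origin at the tether).
#'
#' @slot dnaStain,ssb numeric matrices (frames x positions), intensities
#'   >= 0.
#' @slot pixelSize pixel size (nm).
#' @slot frameInterval frame interval (s).
#' @slot bpPerNm stretched-DNA conversion (bp/nm).
#' @slot seed seed recorded from the simulation.
#' @exportClass KymographStack
setClass("KymographStack", representation(
    dnaStain = "matrix", ssb = "matrix", pixelSize = "numeric",
    frameInterval = "numeric", bpPerNm = "numeric", seed = "integer"))

setValidity("KymographStack", function(object) {
    msgs <- character(0)
    if (!identical(dim(object@dnaStain), dim(object@ssb)))
        msgs <- c(msgs, "channels must share dimensions")
    if (min(object@dnaStain, object@ssb) < 0)
        msgs <- c(msgs, "intensities must be >= 0")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "KymographStack", function(object) {
    d <- dim(object@ssb)
    cat(sprintf(
        "KymographStack: %d frames x %d px (%g nm/px, %g s/frame, %g bp/nm)\n",
        d[1], d[2], object@pixelSize, object@frameInterval, object@bpPerNm))
})

## ---------------------------------------------------------------------------
## In-vivo scene
## ---------------------------------------------------------------------------

#' Simulated in-vivo FRAP field
#'
#' A field of cells, each with a finite cytosolic SSB-FP pool and 1-4
#' replisome foci. One focus may be FRAP-pulsed through a diffraction-limited
#' (500 nm FWHM) spot; the remaining cells are unpulsed controls for the
#' imaging-photobleach correction.
#'
#' @slot cells data.frame: `cell`, `cx`, `cy` (centre, nm), `ax`, `ay`
#'   (ellipse semi-axes, nm), `pool0` (initial pool tetramers), `pulsed`.
#' @slot foci data.frame: `cell`, `focus`, `x`, `y` (nm), `target`.
#' @slot focusTraces list of [IntensityTrace-class], one per focus (bright
#'   tetramer count plus noise).
#' @slot cellTraces list of [IntensityTrace-class], whole-cell integrated
#'   intensity, one per cell.
#' @slot pulse list: `time` (s), `x`, `y` (nm), `fwhm` (nm), `energy`.
#' @slot groundTruth list: `k_ex`, `tau_true`, `tau_b`, `focus_slots`,
#'   `pool0`.
#' @slot config the [SimConfig-class] used.
#' @exportClass InVivoScene
setClass("InVivoScene", representation(
    cells = "data.frame", foci = "data.frame", focusTraces = "list",
    cellTraces = "list", pulse = "list", groundTruth = "list",
    config = "SimConfig"))

setMethod("show", "InVivoScene", function(object) {
    cat(sprintf("InVivoScene: %d cells, %d foci, pulse at t = %g s\n",
                nrow(object@cells), nrow(object@foci),
                if (length(object@pulse)) object@pulse$time else NA))
})
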