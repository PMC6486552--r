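## Canned experiment templates: parameterized end-to-end drivers that
## mirror the imaging experiments (in-vitro FRAP concentration series,
## chase without solution SSB, in-vivo pinhole FRAP, replication-rate
## kymographs, Okazaki-length series). Each returns fitted results next to
## the generator's ground truth so parameter recovery can be checked.

#' Configuration for an in-vitro FRAP experiment
#'
#' FRAP acquisition is stroboscopic (12 ms exposure per 0.5 s frame), so
#' imaging photobleaching contributes less than 5% to the measured
#' replacement rate for exchange times up to ~20 s; the chase/continuous
#' protocol (see [chaseExperiment()]) uses full-duty illumination instead.
#' Displaced tetramers all transfer internally here (`pIntScale = Inf`), so
#' the solution-exchange channel is the only bright-influx path and the
#' ground-truth exchange time is exactly `1/effectiveExchangeRate(cfg)`.
#' Pulses are spaced at about 3.2 expected exchange times so each recovery
#' phase approaches its plateau; the first three phases are analyzed.
#'
#' @param cSSB SSB concentration (nM).
#' @param tauTrue optional injected ground-truth exchange time (s); when
#'   given, `kIntr = 1/tauTrue` and `kFac = 0`, otherwise the default
#'   exchange law applies.
#' @param seed integer seed.
#' @param nPhases number of recovery phases (pulses).
#' @return A [SimConfig-class].
#' @export
frapInVitroConfig <- function(cSSB, tauTrue = NULL, seed = 1L,
                              nPhases = 3L) {
    base <- simConfig(cSSB = cSSB, seed = seed)
    tau <- if (is.null(tauTrue)) 1 / effectiveExchangeRate(base) else
        tauTrue
    spacing <- max(3.2 * tau, 10)
    prePulse <- 10
    pulses <- prePulse + (seq_len(nPhases) - 1L) * spacing
    simConfig(cSSB = cSSB,
              kIntr = if (is.null(tauTrue)) 0.01 else 1 / tauTrue,
              kFac = if (is.null(tauTrue)) 0.0033 else 0,
              pIntScale = Inf, exposure = 0.012, frameInterval = 0.5,
              pulseTimes = pulses,
              duration = prePulse + nPhases * spacing, seed = seed)
}

#' In-vitro FRAP experiment: simulate, average recovery phases, fit
#'
#' Simulates `nReplisomes` forks with periodic FRAP pulses, normalizes each
#' trace to its pre-pulse steady state, pools the first `nPhases` recovery
#' phases of every replisome, averages them on a common time base and runs
#' the combined photobleach-corrected recovery fit.
#'
#' @inheritParams frapInVitroConfig
#' @param nReplisomes number of replisomes in the ensemble.
#' @param bootstrap number of bootstrap resamples for the exchange-time
#'   CI (0 to skip).
#' @return list: `fit` ([RecoveryFit-class]), `meanTrace`, `phases`,
#'   `groundTruth`.
#' @export
frapInVitroExperiment <- function(cSSB, tauTrue = NULL, nReplisomes = 24,
                                  seed = 1L, nPhases = 3L, bootstrap = 0) {
    cfg <- frapInVitroConfig(cSSB, tauTrue, seed, nPhases)
    sims <- simulateEnsemble(cfg, nReplisomes)
    phases <- unlist(lapply(sims, function(s) {
        tr <- normalizeTrace(emitIntensityTrace(s))
        extractRecoveryPhases(tr, maxPhases = nPhases)
    }), recursive = FALSE)
    mt <- averageTraces(phases)
    fit <- fitRecoveryEq1(mt)
    if (bootstrap > 0)
        fit@tauBoot <- bootstrapTau(phases, fitRecoveryEq1, B = bootstrap,
                                    seed = cfg@seed)
    list(fit = fit, meanTrace = mt, phases = phases, sims = sims,
         groundTruth = sims[[1]]@groundTruth)
}

#' Chase experiment: continuous imaging without solution SSB
#'
#' No SSB in solution and no intrinsic exchange: the initial SSB complement
#' is retained by internal transfer and the ensemble fork intensity decays
#' purely by photobleaching of the dyes, at the continuous-illumination
#' lifetime `tauB`. The ensemble-average decay is fitted with a single
#' exponential.
#'
#' @param nTraces number of replisomes.
#' @param seed integer seed.
#' @param tauB continuous-illumination bleach lifetime (s).
#' @param duration trace length (s).
#' @return list: `fit` ([BleachControlFit-class]), `sims`, `groundTruth`.
#' @export
chaseExperiment <- function(nTraces = 30, seed = 1L, tauB = 9.5,
                            duration = 40) {
    cfg <- simConfig(cSSB = 0, kIntr = 0, kFac = 0, tauB = tauB,
                     duration = duration, seed = seed)
    sims <- simulateEnsemble(cfg, nTraces)
    traces <- lapply(seq_along(sims), function(i)
        emitIntensityTrace(sims[[i]], spotId = paste0("fork", i)))
    fit <- fitBleachControl(traces)
    list(fit = fit, sims = sims,
         groundTruth = list(tau_b = tauB, k_ex = 0))
}

#' In-vivo FRAP experiment: two-step photobleach-corrected recovery
#'
#' Simulates `nPulsed` pinhole-FRAP fields plus pooled unpulsed control
#' cells, fits the control decay, normalizes and averages the pulsed-focus
#' recovery phases, applies the pointwise bleach correction and fits the
#' pure recovery.
#'
#' @param tauTrue ground-truth focus exchange time (s).
#' @param nPulsed pulsed foci.
#' @param nControl control cells.
#' @param seed integer seed.
#' @param tauB imaging bleach lifetime at visualization power (s).
#' @return list: `fit`, `controlFit`, `meanTrace`, `groundTruth`.
#' @export
inVivoExperiment <- function(tauTrue = 2.5, nPulsed = 29, nControl = 40,
                             seed = 1L, tauB = 20) {
    cfg <- simConfig(cSSB = 0, kIntr = 1 / tauTrue, kFac = 0, tauB = tauB,
                     frameInterval = 0.25, exposure = 0.25,
                     noiseSd = 1, pulseTimes = 2.5, duration = 25,
                     seed = seed)
    ens <- simulateInVivoEnsemble(cfg, nPulsed = nPulsed,
                                  nControl = nControl)
    ctrlFit <- fitBleachControl(ens$controlTraces)
    phases <- unlist(lapply(ens$frapTraces, function(tr)
        extractRecoveryPhases(normalizeTrace(tr), maxPhases = 1)),
        recursive = FALSE)
    mt <- averageTraces(phases)
    fit <- bleachCorrectAndFit(mt, ctrlFit)
    list(fit = fit, controlFit = ctrlFit, meanTrace = mt,
         groundTruth = ens$groundTruth)
}

#' Replication-rate experiment: kymographs, tracking, Gaussian rates
#'
#' Simulates an ensemble, renders each fork as a kymograph, tracks the SSB
#' spot, segments the trajectory into constant-slope pieces and pools the
#' duration-weighted mean slope per replisome into a Gaussian rate
#' distribution, reported as mean +/- SEM.
#'
#' @param n number of replisomes.
#' @param vMean,vSd ground-truth rate distribution (bp/s).
#' @param seed integer seed.
#' @param duration per-molecule observation (s).
#' @return list: `dist` ([RateDistribution-class]), `rates`,
#'   `groundTruth`.
#' @export
rateExperiment <- function(n = 71, vMean = 626, vSd = 73, seed = 1L,
                           duration = 60) {
    cfg <- simConfig(vMean = vMean, vSd = vSd, cSSB = 10,
                     duration = duration, seed = seed)
    sims <- simulateEnsemble(cfg, n)
    rates <- vapply(sims, function(s) {
        ky <- renderKymograph(s)
        series <- trackKymograph(ky, "ssb")
        seg <- segmentRates(series, bpPerPx = ky@bpPerNm * ky@pixelSize)
        with(seg@segments, sum(slope_bp_s * duration) / sum(duration))
    }, numeric(1))
    list(dist = rateDistribution(rates), rates = rates,
         groundTruth = list(v_mean = vMean, v_sd = vSd,
                            v_realized = vapply(sims, function(s) s@v,
                                                numeric(1))))
}

#' Okazaki-length experiment: spacing MLE and gel emulation per
#' concentration
#'
#' For each concentration, draws `n` fragment lengths at the configured
#' mean, lays SSB spots in the fragment gaps of synthetic product
#' molecules, estimates the mean by truncation-aware exponential MLE on
#' inter-spot spacings, emulates a gel lane from an independent sample of
#' the same size, and tabulates the concordance of the two estimators.
#'
#' @param concentrations SSB concentrations (nM).
#' @param n fragments per concentration and estimator.
#' @param seed integer seed.
#' @param censorLimit diffraction censoring limit (knt).
#' @param spotsPerMolecule spots laid per synthetic molecule.
#' @return list: `singleMol`, `gel` (data.frames), `comparison`,
#'   `samples`, `lanes`.
#' @export
okazakiExperiment <- function(concentrations = c(2, 10, 20, 100), n = 500,
                              seed = 1L, censorLimit = 0.5,
                              spotsPerMolecule = 6L) {
    cfg <- simConfig()
    seeds <- deriveSeeds(seed, length(concentrations))
    samples <- list(); lanes <- list()
    smRows <- list(); gelRows <- list()
    for (i in seq_along(concentrations)) {
        cc <- concentrations[i]
        mu <- okazakiMeanLength(cfg, cc)
        res <- withSeed(seeds[i], {
            gaps <- rexp(n, 1 / mu)
            nMol <- ceiling(n / (spotsPerMolecule - 1L))
            mol <- rep(seq_len(nMol), each = spotsPerMolecule - 1L)[
                seq_len(n)]
            spl <- split(gaps, mol)
            spots <- do.call(rbind, lapply(names(spl), function(mn)
                data.frame(molecule = mn,
                           position_knt = cumsum(c(0, spl[[mn]])))))
            gelLens <- rexp(n, 1 / mu)
            list(spots = spots, gelLens = gelLens)
        })
        smp <- spotSpacingLengths(res$spots, concentration = cc,
                                  censorLimit = censorLimit)
        smp <- fitExponentialLengths(smp, seed = seeds[i])
        lane <- emulateGelLane(res$gelLens)
        samples[[as.character(cc)]] <- smp
        lanes[[as.character(cc)]] <- lane
        smRows[[i]] <- data.frame(concentration = cc,
                                  mean = smp@estimate$mean,
                                  ci_lo = smp@estimate$ci[1],
                                  ci_hi = smp@estimate$ci[2],
                                  true_mean = mu)
        gelRows[[i]] <- data.frame(concentration = cc, mean = lane@mean,
                                   sd = lane@sd, true_mean = mu)
    }
    singleMol <- do.call(rbind, smRows)
    gel <- do.call(rbind, gelRows)
    list(singleMol = singleMol, gel = gel,
         comparison = compareEstimates(singleMol, gel),
         samples = samples, lanes = lanes)
}
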