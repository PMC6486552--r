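## Core stochastic simulation of SSB tetramer dynamics at a moving
## replication fork. The model is event-driven at the level of Okazaki
## cycles: within each cycle, fork-bound tetramers can be replaced from
## solution (Poisson, rate k_ex); at each completed cycle every bound
## tetramer is displaced by the lagging-strand polymerase and either
## transfers internally to new ssDNA behind the helicase (probability
## p_int) or leaves to solution. Exact event times are drawn, so sampled
## intensity traces carry no time-discretization bias.

#' Effective solution-exchange rate
#'
#' Pseudo-first-order facilitated exchange:
#' \eqn{k_{ex}(c) = k_{intr} + k_{fac} c}. Strictly increasing in the SSB
#' concentration whenever `kFac > 0`; the expected exchange time is
#' `1/effectiveExchangeRate(cfg)`.
#'
#' @param cfg a [SimConfig-class].
#' @return exchange rate (s^-1).
#' @examples
#' effectiveExchangeRate(simConfig(cSSB = 100)) # ~0.34/s, tau ~2.9 s
#' @export
effectiveExchangeRate <- function(cfg) {
    validObject(cfg)
    cfg@kIntr + cfg@kFac * cfg@cSSB
}

#' Internal-transfer probability at a given concentration
#'
#' Saturable competition between internal transfer and capture by solution
#' SSB: \eqn{p_{int} = s/(s + c)}. Equal to 1 when `pIntScale` is infinite
#' or the concentration is zero (chase conditions).
#'
#' @param cfg a [SimConfig-class].
#' @return probability in (0, 1].
#' @export
internalTransferProb <- function(cfg) {
    if (is.infinite(cfg@pIntScale)) return(1)
    cfg@pIntScale / (cfg@pIntScale + cfg@cSSB)
}

#' Mean Okazaki-fragment length at a concentration
#'
#' Log-linear interpolation of the configured concentration-to-length table;
#' concentrations outside the tabulated range are clamped to the nearest
#' entry (in particular, chase conditions at 0 nM use the lowest-
#' concentration length).
#'
#' @param cfg a [SimConfig-class].
#' @param conc concentration (nM); defaults to `cfg@cSSB`.
#' @return mean fragment length (knt).
#' @export
okazakiMeanLength <- function(cfg, conc = cfg@cSSB) {
    keys <- as.numeric(names(cfg@lengthTable))
    o <- order(keys)
    keys <- keys[o]; vals <- unname(cfg@lengthTable[o])
    if (length(keys) == 1L) return(vals)
    x <- log(pmin(pmax(conc, min(keys)), max(keys)))
    approx(log(keys), vals, xout = x, rule = 2)$y
}

#' Calibrate the exchange law against measured exchange times
#'
#' Least-squares fit of \eqn{\tau(c) = 1/(k_{intr} + k_{fac} c)} to a set of
#' (concentration, exchange time) pairs.
#'
#' @param tauByConc named numeric: exchange times (s), names are
#'   concentrations (nM).
#' @return list with `kIntr`, `kFac` and the fitted times.
#' @export
calibrateExchangeLaw <- function(tauByConc) {
    stopIfNot(length(tauByConc) >= 2, "need >= 2 (c, tau) pairs")
    c_ <- as.numeric(names(tauByConc))
    tau <- unname(tauByConc)
    fit <- minpack.lm::nlsLM(tau ~ 1 / (ki + kf * c_),
                             start = list(ki = 1 / max(tau), kf = 1e-3),
                             lower = c(0, 0))
    ki <- coef(fit)[["ki"]]; kf <- coef(fit)[["kf"]]
    list(kIntr = ki, kFac = kf, fitted = 1 / (ki + kf * c_),
         concentrations = c_)
}

## Draw dye complement for a cohort of n newly bound tetramers.
drawDyes <- function(n, cfg, bindTime) {
    labeled <- runif(n) < cfg@labeledFraction
    nDyes <- ifelse(labeled, 1L + (runif(n) < (cfg@dyesMean - 1)), 0L)
    duty <- cfg@exposure / cfg@frameInterval
    rate <- duty / cfg@tauB          # wall-clock bleach rate per dye
    d1 <- ifelse(nDyes >= 1L, bindTime + rexp(n, rate), NA_real_)
    d2 <- ifelse(nDyes >= 2L, bindTime + rexp(n, rate), NA_real_)
    list(labeled = labeled, nDyes = nDyes, d1 = d1, d2 = d2)
}

#' Simulate one replisome
#'
#' Runs the stochastic fork/SSB model: a per-replisome replication rate is
#' drawn from Gaussian(`vMean`, `vSd`); Okazaki-fragment lengths are i.i.d.
#' exponential with mean from the concentration-to-length table; exposed
#' lagging-strand ssDNA is tiled by tetramers (`footprintNt` each); each
#' bound tetramer is replaced from solution as a Poisson process with rate
#' [effectiveExchangeRate()]; at the end of every completed Okazaki cycle
#' each bound tetramer is displaced by the lagging-strand polymerase and
#' transfers internally with probability [internalTransferProb()], otherwise
#' leaves to solution. Any FRAP pulses in `cfg@pulseTimes` are applied to
#' the ledger. Fully reproducible under `cfg@seed`.
#'
#' @param cfg a [SimConfig-class].
#' @return A [ReplisomeSim-class].
#' @examples
#' sim <- simulateReplisome(simConfig(cSSB = 10, duration = 60))
#' head(tetramerLedger(sim))
#' @export
simulateReplisome <- function(cfg) {
    validObject(cfg)
    withSeed(cfg@seed, .simulateReplisome(cfg))
}

.simulateReplisome <- function(cfg) {
    kEx <- cfg@kIntr + cfg@kFac * cfg@cSSB
    pInt <- internalTransferProb(cfg)
    meanLnt <- 1000 * okazakiMeanLength(cfg)

    v <- if (cfg@vMean == 0) 0 else max(rnorm(1, cfg@vMean, cfg@vSd), 1)

    gt <- list(v = v, mean_of_knt = NA_real_, k_ex = kEx,
               tau_true = if (kEx > 0) 1 / kEx else Inf, seed = cfg@seed)

    if (v == 0) {
        sim <- new("ReplisomeSim", config = cfg, v = 0,
                   cycles = data.frame(start = numeric(0), end = numeric(0),
                                       length_nt = numeric(0),
                                       demand = integer(0)),
                   ledger = emptyLedger(), pulses = numeric(0),
                   groundTruth = gt)
        return(sim)
    }

    ## Okazaki cycle schedule (deterministic once lengths are drawn)
    lens <- numeric(0)
    while (sum(lens) / v < cfg@duration)
        lens <- c(lens, rexp(ceiling(cfg@duration * v / meanLnt) + 8,
                             1 / meanLnt))
    ends <- cumsum(lens) / v
    nCyc <- which(ends >= cfg@duration)[1]
    lens <- lens[seq_len(nCyc)]
    starts <- c(0, ends[seq_len(nCyc - 1)])
    ends <- pmin(ends[seq_len(nCyc)], cfg@duration)
    ## The fork maintains a steady Okazaki-scale SSB complement: the
    ## replication loop smooths per-fragment variation, so the slot count
    ## is set by the mean fragment length, not by each fragment's own.
    nSlots <- max(1L, as.integer(round(meanLnt / cfg@footprintNt)))
    demand <- rep(nSlots, nCyc)

    ## Ledger accumulators (grown in cohorts)
    acc <- new.env(parent = emptyenv())
    acc$origin <- character(0); acc$bind <- numeric(0)
    acc$labeled <- logical(0); acc$nDyes <- integer(0)
    acc$d1 <- numeric(0); acc$d2 <- numeric(0)
    acc$release <- numeric(0); acc$exit <- character(0)
    acc$transfers <- integer(0)

    addCohort <- function(n, t, origin) {
        if (n == 0L) return(integer(0))
        dye <- drawDyes(n, cfg, t)
        ids <- length(acc$bind) + seq_len(n)
        acc$origin <- c(acc$origin, rep(origin, n))
        acc$bind <- c(acc$bind, if (length(t) == 1L) rep(t, n) else t)
        acc$labeled <- c(acc$labeled, dye$labeled)
        acc$nDyes <- c(acc$nDyes, dye$nDyes)
        acc$d1 <- c(acc$d1, dye$d1)
        acc$d2 <- c(acc$d2, dye$d2)
        acc$release <- c(acc$release, rep(NA_real_, n))
        acc$exit <- c(acc$exit, rep("none", n))
        acc$transfers <- c(acc$transfers, rep(0L, n))
        ids
    }

    canRecruit <- cfg@cSSB > 0
    bound <- integer(0)          # ledger ids currently at the fork
    tExch <- numeric(0)          # absolute next solution-exchange times

    drawExch <- function(n, t)
        if (kEx > 0) t + rexp(n, kEx) else rep(Inf, n)

    for (i in seq_len(nCyc)) {
        sI <- starts[i]; eI <- ends[i]
        ## recruit up to demand (initial complement always assembles)
        deficit <- demand[i] - length(bound)
        if (deficit > 0L && (i == 1L || canRecruit)) {
            ids <- addCohort(deficit, sI,
                             if (i == 1L) "initial" else "solution")
            bound <- c(bound, ids)
            tExch <- c(tExch, drawExch(deficit, sI))
        }
        ## solution-exchange events within the cycle (chained replacements)
        repeat {
            due <- which(tExch < eI)
            if (!length(due)) break
            tDue <- tExch[due]
            acc$release[bound[due]] <- tDue
            acc$exit[bound[due]] <- "exchange"
            if (canRecruit) {
                ids <- addCohort(length(due), tDue, "solution")
                bound[due] <- ids
                tExch[due] <- drawExch(length(due), tDue)
            } else {
                bound <- bound[-due]
                tExch <- tExch[-due]
            }
        }
        ## polymerase displacement at the completed cycle boundary
        if (eI < cfg@duration && length(bound)) {
            stay <- runif(length(bound)) < pInt
            lost <- bound[!stay]
            if (length(lost)) {
                acc$release[lost] <- eI
                acc$exit[lost] <- "displaced"
            }
            acc$transfers[bound[stay]] <- acc$transfers[bound[stay]] + 1L
            bound <- bound[stay]
            tExch <- tExch[stay]
        }
    }

    fate <- ifelse(acc$exit != "none", "solution_exchange",
                   ifelse(acc$transfers > 0L, "internal_transfer",
                          "retained_at_end"))
    ledger <- data.frame(
        id = seq_along(acc$bind), origin = acc$origin,
        bind_time = acc$bind, release_time = acc$release,
        fate = fate, exit_channel = acc$exit, n_transfers = acc$transfers,
        labeled = acc$labeled, n_dyes = acc$nDyes,
        dye1_bleach = acc$d1, dye2_bleach = acc$d2,
        stringsAsFactors = FALSE)

    gt$mean_of_knt <- mean(lens) / 1000
    sim <- new("ReplisomeSim", config = cfg, v = v,
               cycles = data.frame(start = starts, end = ends,
                                   length_nt = lens, demand = demand),
               ledger = ledger, pulses = numeric(0), groundTruth = gt)
    for (tp in sort(cfg@pulseTimes)) sim <- applyFrapPulse(sim, tp)
    sim
}

emptyLedger <- function() {
    data.frame(id = integer(0), origin = character(0),
               bind_time = numeric(0), release_time = numeric(0),
               fate = character(0), exit_channel = character(0),
               n_transfers = integer(0), labeled = logical(0),
               n_dyes = integer(0), dye1_bleach = numeric(0),
               dye2_bleach = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate an ensemble of replisomes
#'
#' Runs [simulateReplisome()] `n` times with per-replisome sub-seeds derived
#' reproducibly from `cfg@seed`.
#'
#' @param cfg a [SimConfig-class].
#' @param n number of replisomes.
#' @return list of [ReplisomeSim-class] objects.
#' @export
simulateEnsemble <- function(cfg, n) {
    seeds <- deriveSeeds(cfg@seed, n)
    lapply(seq_len(n), function(i) {
        cfg@seed <- seeds[i]
        simulateReplisome(cfg)
    })
}

#' Exposed lagging-strand ssDNA at given times
#'
#' The exposed ssDNA at time t is the not-yet-synthesized part of the
#' current Okazaki fragment (the template already unwound by the helicase
#' but not yet copied by the lagging-strand polymerase).
#'
#' @param sim a [ReplisomeSim-class].
#' @param t times (s).
#' @return exposed ssDNA (nt), same length as `t`.
#' @export
exposedSsDNA <- function(sim, t) {
    if (nrow(sim@cycles) == 0L) return(rep(0, length(t)))
    i <- findInterval(t, sim@cycles$start)
    i[i < 1L] <- 1L
    pmax((sim@cycles$end[i] - t) * sim@v, 0)
}

#' Steady-state number of fork-bound tetramers
#'
#' Time-averaged exposed ssDNA divided by the per-tetramer footprint,
#' i.e. the mean Okazaki-scale SSB coverage of the fork.
#'
#' @param x a [SimConfig-class] (simulated internally) or a
#'   [ReplisomeSim-class].
#' @return expected tetramer count (dimensionless).
#' @export
steadyStateTetramers <- function(x) {
    sim <- if (is(x, "SimConfig")) simulateReplisome(x) else x
    tm <- seq(0, sim@config@duration, by = sim@config@frameInterval)
    mean(exposedSsDNA(sim, tm)) / sim@config@footprintNt
}

#' Apply a FRAP pulse to a simulated replisome
#'
#' Marks every dye on every fork-bound tetramer as bleached at `tPulse`.
#' The solution pool remains bright (in vitro, flow replenishes the pool).
#'
#' @param sim a [ReplisomeSim-class].
#' @param tPulse pulse time (s), inside the simulation window.
#' @return the modified [ReplisomeSim-class].
#' @export
applyFrapPulse <- function(sim, tPulse) {
    stopIfNot(tPulse >= 0 && tPulse <= sim@config@duration,
              "tPulse outside the simulation window")
    led <- sim@ledger
    if (nrow(led)) {
        bnd <- led$bind_time <= tPulse &
            (is.na(led$release_time) | led$release_time > tPulse)
        led$dye1_bleach[bnd] <- pmin(led$dye1_bleach[bnd], tPulse)
        led$dye2_bleach[bnd] <- pmin(led$dye2_bleach[bnd], tPulse)
        ## tetramers that never transferred, stayed to the end, and whose
        ## whole dye complement was killed by this pulse
        dark <- bnd & led$fate == "retained_at_end" & led$labeled &
            (is.na(led$dye1_bleach) | led$dye1_bleach <= tPulse) &
            (is.na(led$dye2_bleach) | led$dye2_bleach <= tPulse)
        led$fate[dark] <- "bleached_in_place"
    }
    sim@ledger <- led
    sim@pulses <- sort(c(sim@pulses, tPulse))
    sim
}

#' Count bright dyes on fork-bound tetramers at given times
#'
#' @param sim a [ReplisomeSim-class].
#' @param t times (s).
#' @return integer vector of bright-dye counts.
#' @export
brightDyeCount <- function(sim, t) {
    led <- sim@ledger
    if (!nrow(led)) return(rep(0L, length(t)))
    relEnd <- ifelse(is.na(led$release_time), Inf, led$release_time)
    starts <- c(led$bind_time[led$n_dyes >= 1L],
                led$bind_time[led$n_dyes >= 2L])
    ends <- c(pmin(relEnd, led$dye1_bleach)[led$n_dyes >= 1L],
              pmin(relEnd, led$dye2_bleach)[led$n_dyes >= 2L])
    ## a dye is bright at t if it bound at or before t and neither bleached
    ## nor left before (or at) t
    findInterval(t, sort(starts)) - findInterval(t, sort(ends))
}

#' Emit the fluorescence intensity trace of a simulated replisome
#'
#' Per frame, intensity = (bright dyes on fork-bound tetramers) x
#' `unitBrightness` + `baseline` + Gaussian noise. Dye bleaching during
#' illumination is already encoded in the ledger's per-dye bleach times.
#'
#' @param sim a [ReplisomeSim-class].
#' @param noiseFree logical; suppress the additive Gaussian noise.
#' @param spotId trace identifier.
#' @return An [IntensityTrace-class].
#' @export
emitIntensityTrace <- function(sim, noiseFree = FALSE, spotId = "fork") {
    cfg <- sim@config
    tm <- seq(cfg@frameInterval, cfg@duration, by = cfg@frameInterval)
    bright <- brightDyeCount(sim, tm)
    I <- bright * cfg@unitBrightness + cfg@baseline
    if (!noiseFree && cfg@noiseSd > 0)
        I <- I + withSeed(cfg@seed + 1L, rnorm(length(I), 0, cfg@noiseSd))
    intensityTrace(tm, I, spotId = spotId, pulseTimes = sim@pulses,
                   frameInterval = cfg@frameInterval)
}
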