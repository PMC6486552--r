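test_that("effective exchange rate follows the pseudo-first-order law", {
    expect_equal(effectiveExchangeRate(
        simConfig(cSSB = 0, kIntr = 0, kFac = 0.0033)), 0)
    ## default calibration at 100 nM lands on the fast exchange regime
    k100 <- effectiveExchangeRate(simConfig(cSSB = 100))
    expect_equal(k100, 0.34, tolerance = 0.01)
    expect_equal(1 / k100, 2.9, tolerance = 0.02)
    ## strictly increasing in concentration
    ks <- vapply(c(0, 2, 10, 20, 100, 300),
                 function(cc) effectiveExchangeRate(simConfig(cSSB = cc)),
                 numeric(1))
    expect_true(all(diff(ks) > 0))
    expect_error(simConfig(cSSB = -5), "non-negative")
})

test_that("exchange waiting times match a Monte-Carlo exponential oracle", {
    cfg <- simConfig(cSSB = 2)
    k <- effectiveExchangeRate(cfg)     # 0.0166/s -> tau ~60 s
    expect_equal(1 / k, 60, tolerance = 0.01)
    mc <- withSeed(99, mean(rexp(1e5, k)))
    expect_equal(mc, 1 / k, tolerance = 0.01)
})

test_that("exchange-law calibration recovers constants from clean data", {
    c_ <- c(2, 10, 20, 100)
    tau <- 1 / (0.02 + 0.004 * c_)
    cal <- calibrateExchangeLaw(setNames(tau, c_))
    expect_equal(cal$kIntr, 0.02, tolerance = 1e-4)
    expect_equal(cal$kFac, 0.004, tolerance = 1e-4)
})

test_that("Okazaki mean lengths interpolate log-linearly and clamp", {
    cfg <- simConfig()
    expect_equal(okazakiMeanLength(cfg, 2), 1.4)
    expect_equal(okazakiMeanLength(cfg, 100), 2.8)
    expect_equal(okazakiMeanLength(cfg, 0), 1.4)    # clamped (chase)
    expect_equal(okazakiMeanLength(cfg, 500), 2.8)  # clamped above
    mid <- okazakiMeanLength(cfg, sqrt(10 * 20))    # log-midpoint
    expect_equal(mid, (1.5 + 2.0) / 2, tolerance = 1e-9)
})

test_that("chase conditions conserve the initial tetramer complement", {
    cfg <- simConfig(cSSB = 0, kIntr = 0, kFac = 0, duration = 60,
                     seed = 42)
    sim <- simulateReplisome(cfg)
    led <- tetramerLedger(sim)
    expect_true(all(led$origin == "initial"))
    expect_true(all(is.na(led$release_time)))
    expect_true(all(led$fate %in% c("internal_transfer",
                                    "retained_at_end")))
    expect_false(any(led$fate == "solution_exchange"))
    ## replisome keeps replicating after the complement is fixed
    expect_gt(nrow(sim@cycles), 5)
})

test_that("a stalled replisome initiates no Okazaki fragments", {
    sim <- simulateReplisome(simConfig(vMean = 0, vSd = 0))
    expect_equal(nrow(sim@cycles), 0)
    expect_equal(nrow(tetramerLedger(sim)), 0)
    expect_equal(steadyStateTetramers(sim), 0)
})

test_that("simulation is bitwise reproducible under a fixed seed", {
    cfg <- simConfig(cSSB = 10, duration = 40, seed = 7,
                     pulseTimes = c(15, 30))
    s1 <- simulateReplisome(cfg)
    s2 <- simulateReplisome(cfg)
    expect_identical(tetramerLedger(s1), tetramerLedger(s2))
    expect_identical(s1@cycles, s2@cycles)
    t1 <- emitIntensityTrace(s1)
    t2 <- emitIntensityTrace(s2)
    expect_identical(t1@I, t2@I)
})

test_that("empirical exchange-event rate matches the configured rate", {
    ## ~10^4 tetramer-seconds at k_ex = 0.1/s
    cfg <- simConfig(cSSB = 10, kIntr = 0, kFac = 0.01, pIntScale = Inf,
                     duration = 120, seed = 5)
    sims <- simulateEnsemble(cfg, 3)
    events <- 0; exposure <- 0
    for (s in sims) {
        led <- tetramerLedger(s)
        events <- events + sum(led$exit_channel == "exchange")
        ends <- ifelse(is.na(led$release_time), cfg@duration,
                       led$release_time)
        exposure <- exposure + sum(ends - led$bind_time)
    }
    expect_gt(exposure, 1e4)
    expect_equal(events / exposure, 0.1, tolerance = 0.03)
})

test_that("steady-state coverage matches the renewal-process oracle", {
    cfg <- simConfig(cSSB = 2, duration = 300, seed = 3)
    sim <- simulateReplisome(cfg)
    cov <- steadyStateTetramers(sim)
    ## renewal identity on the realized cycles: time-averaged remaining
    ## ssDNA equals sum(L^2) / (2 sum(L))
    L <- sim@cycles$length_nt
    expect_equal(cov, sum(L^2) / (2 * sum(L)) / cfg@footprintNt,
                 tolerance = 0.02)
    ## and the identity itself against a snapshot Monte-Carlo oracle at
    ## 10^4 cycles: for exponential lengths the time-average equals the
    ## plain mean
    muNt <- 1000 * okazakiMeanLength(cfg)
    oracle <- withSeed(77, {
        Lmc <- rexp(1e4, 1 / muNt)
        u <- runif(1e4)
        sum((Lmc * (1 - u)) * Lmc) / sum(Lmc) / cfg@footprintNt
    })
    expect_equal(oracle, muNt / cfg@footprintNt, tolerance = 0.05)
    ## worked arithmetic: 1225 nt of exposed ssDNA at 35 nt per tetramer
    expect_equal(1225 / 35, 35)
})

test_that("a FRAP pulse darkens the fork and recovery follows 1-exp(-kt)", {
    tauTrue <- 5
    cfg <- frapInVitroConfig(cSSB = 10, tauTrue = tauTrue, seed = 1,
                             nPhases = 1L)
    cfg@noiseSd <- 0
    tPulse <- cfg@pulseTimes[1]
    sims <- simulateEnsemble(cfg, 60)
    ## immediately after the pulse the fork is dark
    darkAt <- vapply(sims, function(s) brightDyeCount(s, tPulse),
                     integer(1))
    expect_true(all(darkAt == 0))
    ## analytic recovery-curve oracle at several delays
    for (dlt in c(2, 5, 10)) {
        bright <- vapply(sims, function(s)
            brightDyeCount(s, tPulse + dlt), integer(1))
        pre <- vapply(sims, function(s)
            brightDyeCount(s, tPulse - 0.5), integer(1))
        expect_equal(mean(bright) / mean(pre),
                     1 - exp(-dlt / tauTrue), tolerance = 0.12)
    }
    ## pulsing before any binding is a no-op on an empty fork
    cfg0 <- simConfig(vMean = 0, vSd = 0, pulseTimes = numeric(0))
    sim0 <- simulateReplisome(cfg0)
    expect_silent(applyFrapPulse(sim0, 1))
    ## out-of-window pulses are rejected
    expect_error(applyFrapPulse(sims[[1]], cfg@duration + 10), "window")
})

test_that("intensity traces follow the ledger bookkeeping exactly", {
    cfg <- simConfig(cSSB = 10, duration = 30, noiseSd = 0, seed = 2,
                     pulseTimes = 15)
    sim <- simulateReplisome(cfg)
    tr <- emitIntensityTrace(sim, noiseFree = TRUE)
    ## independent tally straight off the ledger
    led <- tetramerLedger(sim)
    tally <- vapply(tr@t, function(tt) {
        n <- 0
        for (i in seq_len(nrow(led))) {
            endT <- if (is.na(led$release_time[i])) Inf else
                led$release_time[i]
            if (led$bind_time[i] > tt || endT <= tt) next
            for (d in c(led$dye1_bleach[i], led$dye2_bleach[i]))
                if (!is.na(d) && d > tt) n <- n + 1
        }
        n
    }, numeric(1))
    expect_equal(tr@I, tally * cfg@unitBrightness + cfg@baseline)
    expect_equal(sum(tr@I), sum(tally))
})

test_that("a lone never-bleaching dye gives a constant trace", {
    cfg <- simConfig(cSSB = 0, kIntr = 0, kFac = 0, vMean = 200, vSd = 0,
                     lengthTable = c("2" = 0.035), footprintNt = 35,
                     labeledFraction = 1, dyesMean = 1, tauB = 1e9,
                     noiseSd = 0, duration = 20, seed = 1)
    tr <- emitIntensityTrace(simulateReplisome(cfg), noiseFree = TRUE)
    expect_equal(unique(tr@I), 1)
})

test_that("ensemble chase decay follows the photobleach lifetime", {
    ch <- chaseExperiment(nTraces = 25, seed = 11, tauB = 9.5)
    expect_equal(ch$fit@tauB, 9.5, tolerance = 0.05)
})
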