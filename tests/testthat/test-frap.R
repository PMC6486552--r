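test_that("recovery phases align to pulses and re-zero", {
    t <- seq(0.5, 90, 0.5)
    pulses <- c(20, 45, 70)
    I <- rep(1, length(t))
    for (p in pulses) {
        post <- t > p & t <= p + 24.5
        I[post] <- pmin(I[post], 1 - exp(-(t[post] - p) / 8))
    }
    tr <- intensityTrace(t, I, pulseTimes = pulses)
    ph <- extractRecoveryPhases(tr)
    expect_length(ph, 3)
    for (p in ph) {
        expect_lt(p@I[1], 0.1)         # starts near zero
        expect_equal(p@t[1], 0.5)      # re-zeroed to the pulse
    }
    ## a pulse at the very last frame leaves an empty phase
    trLast <- intensityTrace(t, I, pulseTimes = c(20, t[length(t)]))
    expect_warning(phL <- extractRecoveryPhases(trLast), "empty")
    expect_length(phL, 1)
})

test_that("pulses are detected from the intensity drop when metadata is
          missing", {
    agree <- vapply(1:25, function(seed) {
        tauTrue <- 6
        cfg <- frapInVitroConfig(10, tauTrue, seed = seed, nPhases = 3L)
        sim <- simulateReplisome(cfg)
        tr <- normalizeTrace(emitIntensityTrace(sim))
        found <- detectPulses(intensityTrace(tr@t, tr@I))
        length(found) == 3 &&
            all(abs(found - cfg@pulseTimes) <= cfg@frameInterval)
    }, logical(1))
    expect_true(all(agree))
    ## no pulse at all is an error listing candidates
    flat <- intensityTrace(seq(0.5, 30, 0.5), rep(1, 60))
    expect_error(extractRecoveryPhases(flat), "candidate")
})

test_that("averaging uses a common time base with per-point SEM", {
    t <- seq(0.5, 20, 0.5)
    p1 <- intensityTrace(t, rep(0, length(t)))
    p2 <- intensityTrace(t, rep(2, length(t)))
    avg <- averageTraces(list(p1, p2))
    expect_true(all(avg@I == 1))
    expect_equal(avg@nTraces, 2L)
    avgSame <- averageTraces(list(p2, p2, p2))
    expect_true(all(avgSame@I == 2))
    expect_true(all(avgSame@sem == 0))
    ## law of large numbers against the analytic curve
    tau <- 5
    phases <- lapply(1:800, function(s)
        intensityTrace(t, 1 - exp(-t / tau) +
                           withSeed(s, rnorm(length(t), 0, 0.2))))
    avgN <- averageTraces(phases)
    expect_true(all(abs(avgN@I - (1 - exp(-t / tau))) <=
                        3 * pmax(avgN@sem, 1e-6)))
    ## incompatible time bases are rejected
    pBad <- intensityTrace(seq(1, 20, 1), rep(1, 20))
    expect_error(averageTraces(list(p1, pBad)), "tolerance")
})

test_that("the combined fit recovers clean parameters to 6 significant
          figures", {
    tr <- makeEq1Trace(a = 0.3, tauB = 9.5, I0 = 1, tau = 10)
    fit <- fitRecoveryEq1(tr)
    expect_equal(fit@a, 0.3, tolerance = 1e-6)
    expect_equal(fit@tauB, 9.5, tolerance = 1e-6)
    expect_equal(fit@I0, 1, tolerance = 1e-6)
    expect_equal(fit@tau, 10, tolerance = 1e-6)
    expect_true(all(is.finite(fit@se)))
})

test_that("a vanishing bleach amplitude is flagged, tau still recovered", {
    tr <- makeEq1Trace(a = 0, tauB = 3, I0 = 1, tau = 8)
    fit <- fitRecoveryEq1(tr)
    expect_true("tauB_unidentifiable" %in% fit@flags)
    expect_equal(fit@tau, 8, tolerance = 1e-4)
    expect_equal(fit@a, 0)
})

test_that("near-degenerate exponential pairs are flagged", {
    tr <- makeEq1Trace(a = 0.5, tauB = 10.5, I0 = 1, tau = 10)
    fit <- fitRecoveryEq1(tr)
    expect_true("near_degenerate" %in% fit@flags)
})

test_that("NLS agrees with the profiled grid-search oracle on noisy data", {
    tr <- makeEq1Trace(a = 0.3, tauB = 9.5, I0 = 1, tau = 10,
                       noiseSd = 0.05, seed = 42)
    fit <- fitRecoveryEq1(tr)
    gs <- gridSearchEq1(tr@t, tr@I)
    ## within one grid step of the exhaustive optimum
    expect_lt(abs(log(fit@tau / gs$tau)), log(gs$tauStep))
    expect_lte(fit@rss, gs$rss + 1e-9)
})

test_that("control-cell bleach fitting recovers the lifetime", {
    t <- seq(0.25, 25, 0.25)
    clean <- lapply(1:3, function(i) intensityTrace(t, exp(-t / 9.5)))
    fit <- fitBleachControl(clean)
    expect_equal(fit@tauB, 9.5, tolerance = 1e-6)
    ## constant control: no bleaching, flagged, infinite lifetime
    const <- lapply(1:2, function(i) intensityTrace(t, rep(3, length(t))))
    fitC <- fitBleachControl(const)
    expect_true(is.infinite(fitC@tauB))
    expect_true("no_bleaching" %in% fitC@flags)
    ## rising control is invalid
    rising <- lapply(1:2, function(i) intensityTrace(t, 1 + 0.05 * t))
    expect_error(fitBleachControl(rising), "invalid control")
    ## noisy controls at the experimental N recover within 5%
    ok <- vapply(1:10, function(seed) {
        tr <- lapply(1:40, function(i)
            intensityTrace(t, exp(-t / 20) +
                               withSeed(seed * 100 + i,
                                        rnorm(length(t), 0, 0.05))))
        abs(fitBleachControl(tr)@tauB / 20 - 1) < 0.05
    }, logical(1))
    expect_gte(mean(ok), 0.9)
})

test_that("two-step correction undoes a known bleach exactly", {
    t <- seq(0.25, 25, 0.25)
    tau <- 2.5; tauB <- 5
    tr <- intensityTrace(t, (1 - exp(-t / tau)) * exp(-t / tauB),
                         nTraces = 29L)
    ctrl <- fitBleachControl(lapply(1:2, function(i)
        intensityTrace(t, exp(-t / tauB))))
    expect_warning(fit <- bleachCorrectAndFit(tr, ctrl), "truncated")
    expect_equal(fit@tau, 2.5, tolerance = 1e-6)
    expect_true("two_step" %in% fit@flags)
    ## flat control: correction is the identity
    ctrlFlat <- fitBleachControl(lapply(1:2, function(i)
        intensityTrace(t, rep(1, length(t)))))
    trPure <- intensityTrace(t, 1 - exp(-t / tau))
    fit2 <- bleachCorrectAndFit(trPure, ctrlFlat)
    expect_equal(fit2@tau, 2.5, tolerance = 1e-6)
    ## corrected asymptote matches I0 on noise-free input
    expect_lt(abs((1 - exp(-max(t) / tau)) / fit2@I0 - 1), 0.05)
})

test_that("two-step and combined fits agree within joint CIs", {
    ## recovery (tau 2.5 s) and imaging bleach (tau_b 20 s) well
    ## separated, as in the in-vivo regime
    res <- vapply(1:20, function(seed) {
        t <- seq(0.25, 25, 0.25)
        tau <- 2.5; tauB <- 20
        I <- (1 - exp(-t / tau)) * exp(-t / tauB) +
            withSeed(seed, rnorm(length(t), 0, 0.02))
        ctrl <- fitBleachControl(lapply(1:2, function(i)
            intensityTrace(t, exp(-t / tauB))))
        twoStep <- bleachCorrectAndFit(intensityTrace(t, I), ctrl)
        comb <- fitRecoveryEq1(intensityTrace(t, I))
        c(twoStep@tau, comb@tau, twoStep@se[["tau"]], comb@se[["tau"]])
    }, numeric(4))
    joint <- 1.96 * sqrt(res[3, ]^2 + res[4, ]^2)
    agree <- abs(res[1, ] - res[2, ]) <= joint
    expect_gte(mean(agree[is.finite(joint)]), 0.9)
    expect_equal(median(res[1, ]), 2.5, tolerance = 0.05)
})

test_that("parameter recovery holds at the experimental trace counts", {
    ## tau 2.9/10/20 s at N = 18/24/20 replisomes, a few seeds each
    cases <- list(c(2.9, 18), c(10, 24), c(20, 20))
    for (cs in cases) {
        taus <- vapply(1:5, function(s)
            exchangeTime(frapInVitroExperiment(
                cSSB = 10, tauTrue = cs[1], nReplisomes = cs[2],
                seed = s)$fit), numeric(1))
        expect_lt(abs(median(taus) / cs[1] - 1), 0.15)
    }
})
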