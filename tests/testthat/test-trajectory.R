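test_that("spot detection handles blank, single and paired spots", {
    blank <- matrix(10, 40, 80)
    expect_equal(nrow(detectSpots(blank)), 0)
    ## single spot, SNR 10: centroid within 0.2 px
    fr <- gaussianSpotFrame(x0 = 50.3, y0 = 20.7, amp = 100, noiseSd = 10,
                            seed = 2)
    sp <- detectSpots(fr)
    expect_equal(nrow(sp), 1)
    expect_lt(abs(sp$x - 50.3), 0.2)
    expect_lt(abs(sp$y - 20.7), 0.2)
    ## two spots 10 px apart resolve; 1 px apart merge
    fr2 <- gaussianSpotFrame(x0 = 40, y0 = 20, noiseSd = 0) +
        gaussianSpotFrame(x0 = 50, y0 = 20, bg = 0, noiseSd = 0)
    expect_equal(nrow(detectSpots(fr2)), 2)
    fr1 <- gaussianSpotFrame(x0 = 40, y0 = 20, noiseSd = 0) +
        gaussianSpotFrame(x0 = 41, y0 = 20, bg = 0, noiseSd = 0)
    expect_equal(nrow(detectSpots(fr1)), 1)
    ## saturated frames warn but still return positions
    frS <- fr; frS[21, 51] <- 65535
    expect_warning(spS <- detectSpots(frS, satLevel = 65535), "satur")
    expect_gte(nrow(spS), 1)
})

test_that("segmentation recovers single-slope tracks", {
    t <- seq(0.5, 60, 0.5)
    bpPerPx <- 3.6 * 160
    seg <- segmentRates(data.frame(t = t, position_px = 626 * t / bpPerPx),
                        bpPerPx)
    expect_equal(nrow(seg@segments), 1)
    expect_equal(seg@segments$slope_bp_s, 626, tolerance = 1e-8)
    segFlat <- segmentRates(data.frame(t = t, position_px = rep(5, 120)),
                            bpPerPx)
    expect_equal(nrow(segFlat@segments), 1)
    expect_equal(segFlat@segments$slope_bp_s, 0)
    ## short series fall back to a single segment
    segShort <- segmentRates(data.frame(t = t[1:6],
                                        position_px = t[1:6]), bpPerPx)
    expect_equal(nrow(segShort@segments), 1)
})

test_that("changepoint matches the exhaustive two-piece oracle", {
    bpPerPx <- 3.6 * 160
    t <- seq(0.5, 60, 0.5)
    for (seed in c(1, 2, 3)) {
        pos <- ifelse(t <= 30, 500 * t, 500 * 30 + 800 * (t - 30)) /
            bpPerPx
        pos <- pos + withSeed(seed, rnorm(length(t), 0, 1))
        seg <- segmentRates(data.frame(t = t, position_px = pos), bpPerPx)
        expect_equal(nrow(seg@segments), 2)
        bOracle <- exhaustiveTwoPiece(t, pos)
        bFit <- which(t == seg@breakpoints[1])
        expect_lte(abs(bFit - (bOracle + 1)), 2)   # within 2 frames
        expect_equal(sort(seg@segments$slope_bp_s), c(500, 800),
                     tolerance = 0.05)
    }
})

test_that("segments respect the minimum length and tile the window", {
    t <- seq(0.5, 90, 0.5)
    withSeed(4, {
        pos <- cumsum(rnorm(length(t), 0.5, 0.8))
    })
    seg <- segmentRates(data.frame(t = t, position_px = pos), 576,
                        minSegmentSec = 5)
    expect_true(all(seg@segments$duration >= 5 - 0.5))
    expect_equal(seg@segments$start[1], t[1])
    expect_equal(seg@segments$end[nrow(seg@segments)], t[length(t)])
    if (nrow(seg@segments) > 1)
        expect_equal(seg@segments$start[-1],
                     head(seg@segments$end, -1) + 0.5)
})

test_that("rate pooling fits a Gaussian and reports mean +/- SEM", {
    rates <- withSeed(10, rnorm(71, 626, 73))
    d <- rateDistribution(rates)
    expect_equal(d@n, 71L)
    expect_equal(d@sem, d@sd / sqrt(71))
    expect_lt(abs(d@mean - 626), 2 * d@sem + 1e-9)
    ## Gaussian MLE equals the arithmetic moments
    expect_equal(d@mean, mean(rates))
    expect_equal(d@sd, sd(rates))
    ## degenerate and invalid inputs
    dSame <- rateDistribution(rep(700, 6))
    expect_equal(dSame@sd, 0)
    expect_equal(dSame@mean, 700)
    expect_message(dBad <- rateDistribution(c(rnorm(10, 600, 10), NaN,
                                              Inf)), "rejected")
    expect_equal(dBad@nRejected, 2L)
})

test_that("rate estimation is unbiased across SNR levels", {
    for (ub in c(0.4, 4)) {      # spot amplitude scale: low and high SNR
        cfg <- simConfig(vMean = 700, vSd = 0, cSSB = 10, duration = 50,
                         unitBrightness = ub, seed = 12)
        rates <- vapply(simulateEnsemble(cfg, 6), function(s) {
            ky <- renderKymograph(s)
            seg <- segmentRates(trackKymograph(ky, "ssb"),
                                bpPerPx = ky@bpPerNm * ky@pixelSize)
            with(seg@segments, sum(slope_bp_s * duration) / sum(duration))
        }, numeric(1))
        expect_lt(abs(mean(rates) / 700 - 1), 0.02)
    }
})

test_that("focus co-localization counts neighbours within the radius", {
    A <- data.frame(x = runif(20, 0, 5000), y = runif(20, 0, 2000))
    expect_equal(colocalizeFoci(A, A)$fraction, 1)
    B <- data.frame(x = A$x + 5000 + 300, y = A$y)
    expect_equal(colocalizeFoci(A, B)$fraction, 0)
    ## constructed scene: 67 of 100 foci given a partner within 250 nm
    withSeed(7, {
        A <- data.frame(x = seq(0, by = 2000, length.out = 100), y = 0,
                        cell = rep(1:10, each = 10))
        hit <- sample(100, 67)
        B <- data.frame(x = A$x[hit] + runif(67, -100, 100),
                        y = runif(67, -100, 100))
    })
    res <- colocalizeFoci(A, B)
    expect_equal(res$fraction, 0.67)
    expect_equal(nrow(res$perCell), 10)
    expect_equal(mean(res$perCell$fraction), 0.67, tolerance = 1e-9)
    ## empty input yields an explicit no-data marker
    expect_message(resE <- colocalizeFoci(A[0, ], B), "undefined")
    expect_true(is.na(resE$fraction))
})
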