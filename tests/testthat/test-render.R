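test_that("a (nearly) stationary fork renders as a horizontal line", {
    cfg <- simConfig(vMean = 1, vSd = 0, cSSB = 0, kIntr = 0, kFac = 0,
                     tauB = 1e9, noiseSd = 0, duration = 30, seed = 1)
    ky <- renderKymograph(simulateReplisome(cfg), noiseFree = TRUE)
    peaks <- apply(ky@ssb, 1, which.max)
    expect_equal(length(unique(peaks)), 1)
    expect_true(all(ky@ssb[cbind(seq_len(nrow(ky@ssb)), peaks)] > 0))
})

test_that("the rendered spot advances at the configured slope", {
    ## 626 bp/s over 3.6 bp/nm and 160 nm pixels -> 1.09 px/s
    cfg <- simConfig(vMean = 626, vSd = 0, cSSB = 10, tauB = 1e9,
                     noiseSd = 0, duration = 60, seed = 2)
    ky <- renderKymograph(simulateReplisome(cfg), noiseFree = TRUE)
    series <- trackKymograph(ky, "ssb")
    fit <- lm(position_px ~ t, data = series)
    slopeTrue <- 626 / (3.6 * 160)
    expect_equal(coef(fit)[[2]], slopeTrue, tolerance = 0.02)
    ## within 1 px over the full 60 s window
    expect_lt(abs(coef(fit)[[2]] - slopeTrue) * 60, 1)
})

test_that("noise-free frames conserve flux: sum = amplitude x PSF integral", {
    cfg <- simConfig(vMean = 750, vSd = 0, cSSB = 10, tauB = 1e9,
                     noiseSd = 0, duration = 20, seed = 3)
    sim <- simulateReplisome(cfg)
    ky <- renderKymograph(sim, noiseFree = TRUE)
    amp <- brightDyeCount(sim, seq(0.5, 20, 0.5))
    sigPx <- 120 / 160
    for (m in c(5, 20, 39)) {
        expect_equal(sum(ky@ssb[m, ]), amp[m] * sigPx * sqrt(2 * pi),
                     tolerance = 1e-3)
    }
})

test_that("background noise matches the configured read-noise variance", {
    cfg <- simConfig(vMean = 500, vSd = 0, cSSB = 10, duration = 120,
                     seed = 4)
    ky <- renderKymograph(simulateReplisome(cfg), readSd = 3)
    ## far field: early frames, columns the spot has not yet reached
    bg <- ky@ssb[1:60, 40:ncol(ky@ssb)]
    bg <- bg[bg > 0]           # negatives were clipped at 0
    n <- min(length(bg), 1e4)
    bg <- bg[seq_len(n)]
    ## clipping halves the distribution; compare upper-tail spread
    s2 <- mean(bg^2)            # E[X^2 | X>0] for N(0, 3^2) is 9
    stat <- n * s2 / 9
    expect_gt(pchisq(stat, n, lower.tail = FALSE), 0.005)
    expect_gt(pchisq(stat, n, lower.tail = TRUE), 0.005)
})

test_that("kymographs round-trip through 16-bit TIFF with sidecar", {
    cfg <- simConfig(vMean = 500, vSd = 0, duration = 20, seed = 5)
    ky <- renderKymograph(simulateReplisome(cfg))
    dir <- tempfile()
    writeKymographTiff(ky, dir)
    ky2 <- readKymographTiff(dir)
    expect_equal(ky2@pixelSize, ky@pixelSize)
    expect_equal(ky2@frameInterval, ky@frameInterval)
    expect_equal(ky2@bpPerNm, ky@bpPerNm)
    expect_equal(ky2@seed, ky@seed)
    quant <- max(ky@ssb) / 65535
    expect_lt(max(abs(ky2@ssb - ky@ssb)), quant * 1.01)
    expect_lt(max(abs(ky2@dnaStain - ky@dnaStain)),
              max(ky@dnaStain) / 65535 * 1.01)
})

test_that("render-then-track recovers fork position within 1 px RMS", {
    cfg <- simConfig(vMean = 750, vSd = 0, cSSB = 10, duration = 40,
                     seed = 6)
    sim <- simulateReplisome(cfg)
    ky <- renderKymograph(sim)          # with noise, SNR >= 5
    series <- trackKymograph(ky, "ssb")
    truth <- sim@v * series$t / ky@bpPerNm / ky@pixelSize
    rms <- sqrt(mean((series$position_px - truth)^2))
    expect_lt(rms, 1)
})

test_that("cell movies show a local pulse and a bleaching control", {
    cfg <- simConfig(cSSB = 0, kIntr = 1 / 2.5, kFac = 0, tauB = 20,
                     frameInterval = 0.25, exposure = 0.25, noiseSd = 0,
                     pulseTimes = 2.5, duration = 20, seed = 9)
    sc <- simulateInVivoScene(cfg, nCells = 2)
    mv <- renderCellMovie(sc, noiseFree = TRUE)
    tm <- sc@focusTraces[[1]]@t
    pf <- which(tm >= sc@pulse$time)[1]
    tgt <- which(sc@foci$target)
    px <- round(sc@foci$x[tgt] / mv$meta$pixel_size_nm)
    py <- round(sc@foci$y[tgt] / mv$meta$pixel_size_nm)
    win <- function(m, cx, cy, r = 3)
        sum(m[(cy - r):(cy + r), (cx - r):(cx + r)])
    pre <- mv$frames[, , pf - 1]; post <- mv$frames[, , pf]
    cellOfTgt <- sc@foci$cell[tgt]
    cl <- sc@cells[cellOfTgt, ]
    cellWin <- function(m) {
        xs <- round((cl$cx + c(-1, 1) * cl$ax) / mv$meta$pixel_size_nm)
        ys <- round((cl$cy + c(-1, 1) * cl$ay) / mv$meta$pixel_size_nm)
        sum(m[max(ys[1], 1):ys[2], max(xs[1], 1):xs[2]])
    }
    ## focus component (background-subtracted) collapses at the pulse
    ## frame; the whole-cell sum keeps >= 85% of its intensity
    cellMask <- function(cl, m) {
        xs <- (seq_len(ncol(m)) - 0.5) * mv$meta$pixel_size_nm
        ys <- (seq_len(nrow(m)) - 0.5) * mv$meta$pixel_size_nm
        outer(ys, xs, function(y, x)
            ((x - cl$cx) / cl$ax)^2 + ((y - cl$cy) / cl$ay)^2 <= 0.9)
    }
    bgPerPx <- function(m, cl) median(m[cellMask(cl, m)])
    focusComp <- function(m, cl) win(m, px, py) - 49 * bgPerPx(m, cl)
    expect_lt(focusComp(post, cl), 0.25 * focusComp(pre, cl))
    expect_gte(cellWin(post) / cellWin(pre), 0.85)
    ## with exchange off the kill is complete up to PSF tails
    cfg0 <- cfg; cfg0@kIntr <- 0
    sc0 <- simulateInVivoScene(cfg0, nCells = 2)
    mv0 <- renderCellMovie(sc0, noiseFree = TRUE)
    tgt0 <- which(sc0@foci$target)
    px0 <- round(sc0@foci$x[tgt0] / mv0$meta$pixel_size_nm)
    py0 <- round(sc0@foci$y[tgt0] / mv0$meta$pixel_size_nm)
    pre0 <- mv0$frames[, , pf - 1]; post0 <- mv0$frames[, , pf]
    cl0 <- sc0@cells[sc0@foci$cell[tgt0], ]
    f0pre <- win(pre0, px0, py0) - 49 * bgPerPx(pre0, cl0)
    f0post <- win(post0, px0, py0) - 49 * bgPerPx(post0, cl0)
    expect_lt(f0post, 0.05 * f0pre)
    ## zero-foci scene renders as pure background
    sc2 <- sc
    mv2 <- renderCellMovie(
        local({ s <- sc; s@foci <- s@foci[0, ];
                s@groundTruth$focus_bright <-
                    s@groundTruth$focus_bright[0, , drop = FALSE]; s }),
        noiseFree = TRUE)
    expect_true(all(apply(mv2$frames, 3, max) <=
                        max(sc@groundTruth$pool_bright) ))
    ## control-cell total intensity decays at the configured lifetime
    ctrl <- which(!sc@cells$pulsed)[1]
    fit <- fitBleachControl(sc@cellTraces[rep(ctrl, 2)])
    expect_equal(fit@tauB, 20, tolerance = 0.05)
})
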