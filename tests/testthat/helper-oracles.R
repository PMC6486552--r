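## Independent oracles and small generators used across the suite.

## The combined recovery model, written out directly.
eq1Curve <- function(t, a, tauB, I0, tau) {
    a * exp(-t / tauB) + I0 * (1 - exp(-t / tau))
}

makeEq1Trace <- function(a = 0.3, tauB = 9.5, I0 = 1, tau = 10,
                         dt = 0.5, tEnd = 60, noiseSd = 0, seed = 1) {
    t <- seq(dt, tEnd, by = dt)
    I <- eq1Curve(t, a, tauB, I0, tau)
    if (noiseSd > 0) I <- I + withSeed(seed, rnorm(length(t), 0, noiseSd))
    intensityTrace(t, I, frameInterval = dt)
}

## Grid-search oracle for the combined fit: (tau, tauB) on log grids, with
## the linear parameters (a, I0) profiled out exactly by least squares.
gridSearchEq1 <- function(t, I, nGrid = 50,
                          tauRange = c(1, 100), tauBRange = c(1, 1000)) {
    taus <- exp(seq(log(tauRange[1]), log(tauRange[2]),
                    length.out = nGrid))
    tauBs <- exp(seq(log(tauBRange[1]), log(tauBRange[2]),
                     length.out = nGrid))
    best <- list(rss = Inf)
    for (tau in taus) {
        rec <- 1 - exp(-t / tau)
        for (tauB in tauBs) {
            X <- cbind(exp(-t / tauB), rec)
            cf <- tryCatch(qr.coef(qr(X), I), error = function(e) NULL)
            if (is.null(cf) || anyNA(cf)) next
            cf <- pmax(cf, 0)                   # honour the bounds
            rss <- sum((I - X %*% cf)^2)
            if (rss < best$rss)
                best <- list(rss = rss, tau = tau, tauB = tauB,
                             a = cf[1], I0 = cf[2])
        }
    }
    best$tauStep <- taus[2] / taus[1]
    best
}

## Exhaustive two-piece least-squares changepoint (the oracle for the
## penalized segmentation).
exhaustiveTwoPiece <- function(t, y, minLen = 3) {
    n <- length(t)
    rss <- rep(Inf, n)
    for (b in seq(minLen, n - minLen)) {
        r1 <- sum(lm(y[1:b] ~ t[1:b])$residuals^2)
        r2 <- sum(lm(y[(b + 1):n] ~ t[(b + 1):n])$residuals^2)
        rss[b] <- r1 + r2
    }
    which.min(rss)
}

## Draw a synthetic 2D Gaussian spot on a constant background.
gaussianSpotFrame <- function(nr = 40, nc = 80, x0 = 50.3, y0 = 20.7,
                              amp = 100, sigma = 1.2, bg = 10,
                              noiseSd = 0, seed = 1) {
    xs <- seq_len(nc) - 1
    ys <- seq_len(nr) - 1
    img <- bg + amp * outer(ys, xs, function(y, x)
        exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2)))
    if (noiseSd > 0)
        img <- img + withSeed(seed, rnorm(length(img), 0, noiseSd))
    img
}
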