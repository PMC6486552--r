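## In-vivo variant of the exchange model: each cell carries a finite
## cytosolic pool of labelled SSB (bright fraction tracked per frame),
## 1-4 replisome foci exchange tetramers with that pool, imaging
## photobleaching applies to every dye in the field, and a
## diffraction-limited FRAP pulse (Gaussian spot, 500 nm FWHM) bleaches
## only dyes under the spot. Unpulsed cells are the photobleach controls.

cellGeometry <- function(nCells, ax = 2000, ay = 600, pitch = 5500) {
    ncol <- ceiling(sqrt(nCells))
    idx <- seq_len(nCells) - 1L
    data.frame(cell = seq_len(nCells),
               cx = (idx %% ncol) * pitch + pitch / 2,
               cy = (idx %/% ncol) * (2.5 * ay + 1500) + 1.5 * ay,
               ax = ax, ay = ay)
}

## Fraction of a uniformly distributed cytosolic dye population lying under
## a Gaussian spot centred at (px, py) -- fixed-grid quadrature over the
## cell ellipse.
spotOverlapFraction <- function(cell, px, py, sigma) {
    gx <- seq(-cell$ax, cell$ax, length.out = 41)
    gy <- seq(-cell$ay, cell$ay, length.out = 17)
    gr <- expand.grid(x = gx, y = gy)
    inside <- (gr$x / cell$ax)^2 + (gr$y / cell$ay)^2 <= 1
    gr <- gr[inside, ]
    g <- exp(-((gr$x + cell$cx - px)^2 + (gr$y + cell$cy - py)^2) /
                 (2 * sigma^2))
    mean(g)
}

#' Simulate an in-vivo FRAP field
#'
#' Builds a field of `nCells` cells (ellipses), each with a finite cytosolic
#' pool of labelled SSB and 1-4 replisome foci, and propagates bright-dye
#' counts frame by frame: focus occupants exchange with the cell's pool at
#' [effectiveExchangeRate()], every bright dye photobleaches at the imaging
#' bleach rate `exposure/(frameInterval*tauB)`, and at `cfg@pulseTimes[1]`
#' a FRAP pulse bleaches dyes with probability
#' `energy * exp(-r^2/(2*sigma^2))` around `frapTarget`. With
#' `pulseEnergy = 0` the movie is identical to an unpulsed movie under the
#' same seed.
#'
#' @param cfg a [SimConfig-class]; `cSSB`/`kIntr`/`kFac` set the focus
#'   exchange rate, `tauB` (with the duty cycle) the imaging bleach rate,
#'   `pulseTimes` the single pulse time (empty for no pulse).
#' @param nCells number of cells (>= 2, so at least one control remains).
#' @param frapTarget pulse centre `c(x, y)` in nm, or `NULL` for the first
#'   focus of cell 1. Must lie inside a cell.
#' @param poolSize cytosolic pool per cell (tetramers).
#' @param focusSlots tetramers per replisome focus.
#' @param fwhm pulse spot full width at half maximum (nm).
#' @param pulseEnergy peak bleach probability scale (0 disables the pulse).
#' @return An [InVivoScene-class].
#' @export
simulateInVivoScene <- function(cfg, nCells = 3, frapTarget = NULL,
                                poolSize = 1200, focusSlots = 30,
                                fwhm = 500, pulseEnergy = 1) {
    validObject(cfg)
    stopIfNot(nCells >= 2, "need nCells >= 2 (at least one control cell)")
    withSeed(cfg@seed, .simulateInVivoScene(cfg, nCells, frapTarget,
                                            poolSize, focusSlots, fwhm,
                                            pulseEnergy))
}

.simulateInVivoScene <- function(cfg, nCells, frapTarget, poolSize,
                                 focusSlots, fwhm, pulseEnergy) {
    cells <- cellGeometry(nCells)
    cells$pool0 <- poolSize

    foci <- do.call(rbind, lapply(seq_len(nCells), function(i) {
        nf <- sample(1:4, 1)
        data.frame(cell = i, focus = seq_len(nf),
                   x = cells$cx[i] + runif(nf, -0.7, 0.7) * cells$ax[i],
                   y = cells$cy[i] + runif(nf, -0.3, 0.3) * cells$ay[i])
    }))

    if (is.null(frapTarget)) {
        frapTarget <- c(foci$x[1], foci$y[1])
    } else {
        inAny <- any(((frapTarget[1] - cells$cx) / cells$ax)^2 +
                         ((frapTarget[2] - cells$cy) / cells$ay)^2 <= 1)
        stopIfNot(inAny, "frapTarget lies outside every cell")
    }
    sigma <- fwhm / (2 * sqrt(2 * log(2)))

    dt <- cfg@frameInterval
    tm <- seq(dt, cfg@duration, by = dt)
    nFr <- length(tm)
    kEx <- cfg@kIntr + cfg@kFac * cfg@cSSB
    kB <- (cfg@exposure / cfg@frameInterval) / cfg@tauB
    pX <- 1 - exp(-kEx * dt)
    pB <- 1 - exp(-kB * dt)
    tPulse <- if (length(cfg@pulseTimes)) cfg@pulseTimes[1] else NA_real_
    pulseFrame <- if (is.na(tPulse)) NA_integer_ else
        which(tm >= tPulse)[1]
    ## the pulse fires between the previous readout and this frame's
    ## update, so traces record it at the preceding frame time
    tPulseRec <- if (is.na(tPulse)) NA_real_ else tm[pulseFrame] - dt

    nFoci <- nrow(foci)
    poolBright <- rep(poolSize, nCells)
    focusBright <- rep(focusSlots, nFoci)  # start fully bright
    fb <- matrix(0L, nFoci, nFr)
    pbm <- matrix(0L, nCells, nFr)

    doPulse <- function() {
        if (pulseEnergy <= 0) return(invisible())
        r2 <- (foci$x - frapTarget[1])^2 + (foci$y - frapTarget[2])^2
        g <- pmin(1, pulseEnergy * exp(-r2 / (2 * sigma^2)))
        focusBright <<- rbinom(nFoci, focusBright, 1 - g)
        for (i in seq_len(nCells)) {
            f <- pmin(1, pulseEnergy *
                          spotOverlapFraction(cells[i, ], frapTarget[1],
                                              frapTarget[2], sigma))
            poolBright[i] <<- rbinom(1, poolBright[i], 1 - f)
        }
    }

    for (m in seq_len(nFr)) {
        if (!is.na(pulseFrame) && m == pulseFrame) doPulse()
        ## imaging bleach on pools
        poolBright <- rbinom(nCells, poolBright, 1 - pB)
        ## focus turnover + bleach
        cellOf <- foci$cell
        poolFrac <- poolBright[cellOf] / poolSize
        exBright <- rbinom(nFoci, focusBright, pX)
        dark <- focusSlots - focusBright
        exDark <- rbinom(nFoci, dark, pX)
        stayBright <- rbinom(nFoci, focusBright - exBright, 1 - pB)
        arrBright <- rbinom(nFoci, exBright + exDark, pmin(poolFrac, 1))
        focusBright <- stayBright + arrBright
        ## bookkeeping swap with the pool (bright leave to pool, arrivals
        ## drawn from it)
        dPool <- vapply(seq_len(nCells), function(i)
            sum(exBright[cellOf == i]) - sum(arrBright[cellOf == i]),
            numeric(1))
        poolBright <- pmax(poolBright + dPool, 0)
        fb[, m] <- focusBright
        pbm[, m] <- poolBright
    }

    mkTrace <- function(I, id) {
        if (cfg@noiseSd > 0) I <- I + rnorm(length(I), 0, cfg@noiseSd)
        intensityTrace(tm, I * cfg@unitBrightness + cfg@baseline,
                       spotId = id,
                       pulseTimes = if (is.na(tPulseRec)) numeric(0) else
                           tPulseRec,
                       frameInterval = dt)
    }
    focusTraces <- lapply(seq_len(nFoci), function(j)
        mkTrace(fb[j, ], sprintf("cell%d_focus%d", foci$cell[j],
                                 foci$focus[j])))
    cellTraces <- lapply(seq_len(nCells), function(i) {
        tot <- pbm[i, ] + colSums(fb[foci$cell == i, , drop = FALSE])
        mkTrace(tot, sprintf("cell%d", i))
    })

    d2 <- (foci$x - frapTarget[1])^2 + (foci$y - frapTarget[2])^2
    foci$target <- seq_len(nFoci) == which.min(d2)
    pulsedCell <- foci$cell[foci$target]
    cells$pulsed <- !is.na(tPulse) & pulseEnergy > 0 &
        cells$cell == pulsedCell

    new("InVivoScene", cells = cells, foci = foci,
        focusTraces = focusTraces, cellTraces = cellTraces,
        pulse = list(time = tPulse, x = frapTarget[1], y = frapTarget[2],
                     fwhm = fwhm, energy = pulseEnergy),
        groundTruth = list(k_ex = kEx,
                           tau_true = if (kEx > 0) 1 / kEx else Inf,
                           tau_b_wall = 1 / kB, focus_slots = focusSlots,
                           pool0 = poolSize, focus_bright = fb,
                           pool_bright = pbm, seed = cfg@seed),
        config = cfg)
}

#' Simulate an ensemble of in-vivo FRAP experiments
#'
#' Each pulsed focus is an independent small field (one pulsed cell plus
#' unpulsed neighbours); whole-cell traces of unpulsed cells across fields
#' are pooled as photobleach controls.
#'
#' @param cfg a [SimConfig-class] (see [simulateInVivoScene()]).
#' @param nPulsed number of pulsed foci.
#' @param nControl number of control cells to pool.
#' @param ... forwarded to [simulateInVivoScene()].
#' @return list with `frapTraces` (target-focus [IntensityTrace-class]s),
#'   `controlTraces` (whole-cell traces of unpulsed cells) and
#'   `groundTruth`.
#' @export
simulateInVivoEnsemble <- function(cfg, nPulsed = 29, nControl = 40, ...) {
    perField <- max(2L, ceiling(nControl / nPulsed) + 1L)
    seeds <- deriveSeeds(cfg@seed, nPulsed)
    frap <- vector("list", nPulsed)
    ctrl <- list()
    gt <- NULL
    for (i in seq_len(nPulsed)) {
        cfg@seed <- seeds[i]
        sc <- simulateInVivoScene(cfg, nCells = perField, ...)
        frap[[i]] <- sc@focusTraces[[which(sc@foci$target)]]
        ctrl <- c(ctrl, sc@cellTraces[!sc@cells$pulsed])
        if (is.null(gt)) gt <- sc@groundTruth[c("k_ex", "tau_true",
                                                "tau_b_wall")]
    }
    list(frapTraces = frap, controlTraces = ctrl[seq_len(nControl)],
         groundTruth = gt)
}
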