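## Spot detection, kymograph tracking, piecewise-linear rate segmentation
## and focus co-localization. Detection is threshold-based (median + k*MAD)
## with subpixel refinement by intensity-weighted centroid; segmentation is
## BIC-penalized piecewise linear regression solved exactly by dynamic
## programming. Positions are 0-based pixels, converted to bp only through
## an explicit bp-per-pixel factor.

#' Detect diffraction-limited spots in a 2D frame
#'
#' Local maxima above `median + k * MAD` of the frame, refined to subpixel
#' positions by background-subtracted intensity-weighted centroid in a
#' window of `2*halfWin + 1` pixels. Spots closer than about one PSF width
#' merge into one detection (documented resolution limit).
#'
#' @param frame numeric matrix (row = y, column = x).
#' @param k MAD multiplier for the detection threshold.
#' @param halfWin centroid window half-width (px).
#' @param satLevel optional saturation level; saturated frames raise a
#'   warning but positions are still returned.
#' @return data.frame with 0-based subpixel `x`, `y` and peak `intensity`;
#'   zero rows for a blank frame.
#' @export
detectSpots <- function(frame, k = 5, halfWin = 3, satLevel = NULL) {
    if (!is.null(satLevel) && any(frame >= satLevel))
        warning("saturated pixels in frame; positions may be biased")
    bg <- median(frame)
    thr <- bg + k * mad(frame)
    nr <- nrow(frame); nc <- ncol(frame)
    cand <- which(frame > thr, arr.ind = TRUE)
    if (!nrow(cand))
        return(data.frame(x = numeric(0), y = numeric(0),
                          intensity = numeric(0)))
    isMax <- vapply(seq_len(nrow(cand)), function(i) {
        r <- cand[i, 1]; c <- cand[i, 2]
        rr <- max(1, r - 1):min(nr, r + 1)
        cc <- max(1, c - 1):min(nc, c + 1)
        frame[r, c] >= max(frame[rr, cc])
    }, logical(1))
    cand <- cand[isMax, , drop = FALSE]
    out <- lapply(seq_len(nrow(cand)), function(i) {
        r <- cand[i, 1]; c <- cand[i, 2]
        rr <- max(1, r - halfWin):min(nr, r + halfWin)
        cc <- max(1, c - halfWin):min(nc, c + halfWin)
        w <- pmax(frame[rr, cc, drop = FALSE] - bg, 0)
        sw <- sum(w)
        data.frame(x = sum(t(w) * (cc - 1)) / sw,
                   y = sum(w * (rr - 1)) / sw,
                   intensity = frame[r, c])
    })
    res <- do.call(rbind, out)
    ## collapse duplicate maxima that refined to (nearly) the same centroid
    res <- res[order(-res$intensity), ]
    keep <- rep(TRUE, nrow(res))
    for (i in seq_len(nrow(res))) {
        if (!keep[i]) next
        d <- sqrt((res$x - res$x[i])^2 + (res$y - res$y[i])^2)
        keep[d < 2 & seq_len(nrow(res)) > i] <- FALSE
    }
    res <- res[keep, ]
    rownames(res) <- NULL
    res
}

## 1D spot detection along one kymograph row.
detectSpots1d <- function(profile, k = 5, halfWin = 3) {
    bg <- median(profile)
    thr <- bg + k * mad(profile)
    pk <- which.max(profile)
    if (profile[pk] <= thr) return(NA_real_)
    idx <- max(1, pk - halfWin):min(length(profile), pk + halfWin)
    w <- pmax(profile[idx] - bg, 0)
    sum(w * (idx - 1)) / sum(w)
}

#' Track the fork spot through a kymograph
#'
#' Per-frame 1D detection in the chosen channel (the fork is assumed to be
#' the brightest persistent spot), linked frame-to-frame by nearest
#' neighbour with a maximum step; frames without a detection inherit the
#' previous position (marked `detected = FALSE`).
#'
#' @param stack a [KymographStack-class].
#' @param channel `"ssb"` or `"dnaStain"` (for the DNA channel the tracked
#'   feature is the product edge, i.e. the steepest intensity drop).
#' @param k detection threshold (MADs above the median).
#' @param maxStepPx maximum allowed frame-to-frame step (px).
#' @return data.frame (`t`, `position_px`, `intensity`, `detected`).
#' @export
trackKymograph <- function(stack, channel = c("ssb", "dnaStain"), k = 5,
                           maxStepPx = 3) {
    channel <- match.arg(channel)
    img <- slot(stack, channel)
    nFr <- nrow(img)
    pos <- rep(NA_real_, nFr)
    det <- rep(FALSE, nFr)
    for (m in seq_len(nFr)) {
        p <- if (channel == "ssb") {
            detectSpots1d(img[m, ], k = k)
        } else {
            edgeFromProfile(img[m, ])
        }
        if (!is.na(p) && (m == 1 || is.na(pos[m - 1]) ||
                          abs(p - pos[m - 1]) <= maxStepPx)) {
            pos[m] <- p
            det[m] <- TRUE
        } else {
            pos[m] <- if (m > 1) pos[m - 1] else p
        }
    }
    col <- pmin(pmax(round(pos) + 1, 1), ncol(img))
    data.frame(t = seq_len(nFr) * stack@frameInterval, position_px = pos,
               intensity = img[cbind(seq_len(nFr), col)],
               detected = det)
}

## Product edge (half-maximum crossing) of a DNA-stain profile.
edgeFromProfile <- function(profile) {
    top <- median(profile[profile > max(profile) / 2])
    if (!is.finite(top) || top <= 0) return(NA_real_)
    below <- which(profile < top / 2)
    if (!length(below)) return(length(profile) - 1)
    e <- below[1]
    if (e == 1) return(0)
    ## linear interpolation across the crossing
    (e - 2) + (profile[e - 1] - top / 2) / (profile[e - 1] - profile[e])
}

#' Segment a fork trajectory into constant-rate pieces
#'
#' Exact dynamic-programming minimization of total residual sum of squares
#' plus a BIC-style penalty per additional segment; slopes are reported in
#' bp/s through the explicit `bpPerPx` conversion. Segments never get
#' shorter than `minSegmentSec` and partition the observation window.
#'
#' @param series data.frame with `t` (s) and `position_px`.
#' @param bpPerPx base pairs per pixel.
#' @param minSegmentSec minimum segment duration (s).
#' @param penaltyScale multiplier on the `sigma^2 * log(n)` per-breakpoint
#'   penalty.
#' @return A [SegmentedTrajectory-class].
#' @export
segmentRates <- function(series, bpPerPx, minSegmentSec = 5,
                         penaltyScale = 4) {
    t <- series$t
    y <- series$position_px
    n <- length(t)
    stopIfNot(n >= 2, "need at least 2 frames")
    if (n < max(10, ceiling(minSegmentSec / median(diff(t))))) {
        fit <- lm(y ~ t)
        seg <- data.frame(start = t[1], end = t[n],
                          slope_bp_s = coef(fit)[[2]] * bpPerPx,
                          duration = t[n] - t[1],
                          rss = sum(fit$residuals^2))
        return(new("SegmentedTrajectory", breakpoints = numeric(0),
                   segments = seg,
                   residualVariance = var(fit$residuals) * bpPerPx^2))
    }
    dt <- median(diff(t))
    minLen <- max(2L, ceiling(minSegmentSec / dt))
    ## O(1) segment RSS via cumulative sums
    cx <- cumsum(t); cy <- cumsum(y)
    cxx <- cumsum(t^2); cyy <- cumsum(y^2); cxy <- cumsum(t * y)
    segRss <- function(i, j) {       # fit on points i..j
        m <- j - i + 1
        sx <- cx[j] - if (i > 1) cx[i - 1] else 0
        sy <- cy[j] - if (i > 1) cy[i - 1] else 0
        sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
        syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
        sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
        vxx <- sxx - sx^2 / m
        vxy <- sxy - sx * sy / m
        vyy <- syy - sy^2 / m
        max(vyy - if (vxx > 0) vxy^2 / vxx else 0, 0)
    }
    sigma2 <- max(var(diff(y)) / 2, 1e-12)   # noise scale from differences
    lambda <- penaltyScale * sigma2 * log(n)
    best <- rep(Inf, n + 1); best[1] <- -lambda  # first segment unpenalized
    prev <- integer(n)
    for (j in seq_len(n)) {
        if (j < minLen) next
        for (i in seq_len(j - minLen + 1)) {
            if (j - i + 1 < minLen && !(i == 1 && j == n)) next
            val <- best[i] + segRss(i, j) + lambda
            if (val < best[j + 1]) {
                best[j + 1] <- val
                prev[j] <- i
            }
        }
    }
    ## backtrack
    bounds <- integer(0)
    j <- n
    while (j >= 1) {
        i <- prev[j]
        bounds <- c(i, bounds)
        j <- i - 1
    }
    starts <- bounds
    ends <- c(bounds[-1] - 1L, n)
    segs <- do.call(rbind, lapply(seq_along(starts), function(s) {
        i <- starts[s]; j <- ends[s]
        fit <- lm(y[i:j] ~ t[i:j])
        data.frame(start = t[i], end = t[j],
                   slope_bp_s = coef(fit)[[2]] * bpPerPx,
                   duration = t[j] - t[i], rss = sum(fit$residuals^2))
    }))
    rv <- sum(segs$rss) / max(n - 2 * nrow(segs), 1) * bpPerPx^2
    new("SegmentedTrajectory",
        breakpoints = if (length(starts) > 1) t[starts[-1]] else numeric(0),
        segments = segs, residualVariance = rv)
}

#' Pool per-replisome rates and fit a Gaussian
#'
#' Maximum-likelihood Gaussian fit (sample mean and sd) with the standard
#' error of the mean, reported as mean +/- SEM. Non-finite rates are
#' rejected and counted.
#'
#' @param rates numeric vector of rates (bp/s).
#' @return A [RateDistribution-class].
#' @export
rateDistribution <- function(rates) {
    bad <- !is.finite(rates)
    if (any(bad)) message(sum(bad), " non-finite rate(s) rejected")
    r <- rates[!bad]
    stopIfNot(length(r) >= 5, "need >= 5 finite rates")
    new("RateDistribution", rates = r, mean = mean(r), sd = sd(r),
        sem = sd(r) / sqrt(length(r)), n = length(r),
        nRejected = as.integer(sum(bad)))
}

#' Fraction of A-foci co-localized with B-foci
#'
#' A focus in `fociA` counts as co-localized when any `fociB` focus lies
#' within `radiusNm`. With a `cell` column, per-cell fractions are also
#' returned.
#'
#' @param fociA,fociB data.frames with `x`, `y` (nm) and optionally `cell`.
#' @param radiusNm co-localization radius (nm); default 250 nm, about the
#'   diffraction limit.
#' @return list with `fraction` (pooled; `NA` with zero A-foci), `n`, and
#'   `perCell` (data.frame, possibly empty).
#' @export
colocalizeFoci <- function(fociA, fociB, radiusNm = 250) {
    if (!nrow(fociA)) {
        message("no A-foci: co-localization undefined")
        return(list(fraction = NA_real_, n = 0L,
                    perCell = data.frame(cell = integer(0),
                                         fraction = numeric(0))))
    }
    hit <- vapply(seq_len(nrow(fociA)), function(i) {
        if (!nrow(fociB)) return(FALSE)
        any(sqrt((fociB$x - fociA$x[i])^2 +
                     (fociB$y - fociA$y[i])^2) <= radiusNm)
    }, logical(1))
    perCell <- if (!is.null(fociA$cell)) {
        agg <- tapply(hit, fociA$cell, mean)
        data.frame(cell = as.integer(names(agg)),
                   fraction = as.numeric(agg))
    } else {
        data.frame(cell = integer(0), fraction = numeric(0))
    }
    list(fraction = mean(hit), n = nrow(fociA), perCell = perCell)
}
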