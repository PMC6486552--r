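## Rendering of simulator output into image data: two-channel
## rolling-circle kymographs (DNA stain + labelled SSB) and in-vivo cell
## movies. Optics are a Gaussian PSF; noise is EMCCD-like (Poisson shot +
## Gaussian read). Defaults: 160 nm pixels, PSF sigma 120 nm, and a
## stretched-DNA conversion of 3.6 bp/nm (500 nm of stretched product
## corresponds to ~1800 bp).

#' Render a two-channel kymograph of a simulated replisome
#'
#' The DNA-stain channel draws the stretched product as a line from the
#' tether (x = 0) to the fork at `synthesized bp / bpPerNm / pixelSize`;
#' the SSB channel places a diffraction-limited Gaussian spot at the fork
#' with amplitude taken from the simulated bright-dye count.
#'
#' @param sim a [ReplisomeSim-class].
#' @param pixelSize pixel size (nm).
#' @param bpPerNm stretched-DNA conversion (bp/nm).
#' @param psfSigmaNm PSF standard deviation (nm).
#' @param dnaAmp DNA-stain intensity per pixel of dsDNA (photons).
#' @param readSd Gaussian read-noise sd (photons).
#' @param noiseFree suppress shot and read noise.
#' @param maxWidthPx canvas limit; longer trajectories are truncated with a
#'   warning.
#' @return A [KymographStack-class] (rows = frames, columns = position).
#' @export
renderKymograph <- function(sim, pixelSize = 160, bpPerNm = 3.6,
                            psfSigmaNm = 120, dnaAmp = 50, readSd = 3,
                            noiseFree = FALSE, maxWidthPx = 2048) {
    cfg <- sim@config
    tm <- seq(cfg@frameInterval, cfg@duration, by = cfg@frameInterval)
    posPx <- sim@v * tm / bpPerNm / pixelSize
    sigPx <- psfSigmaNm / pixelSize
    width <- ceiling(max(posPx) + 4 * sigPx + 2)
    if (width > maxWidthPx) {
        warning(sprintf(
            "trajectory exceeds canvas (%d px): truncated to %d px",
            width, maxWidthPx))
        width <- maxWidthPx
    }
    amp <- brightDyeCount(sim, tm) * cfg@unitBrightness
    x <- seq_len(width) - 1
    dna <- matrix(0, length(tm), width)
    ssb <- matrix(0, length(tm), width)
    for (m in seq_along(tm)) {
        frac <- pmin(pmax(posPx[m] - x, 0), 1)  # partial terminal pixel
        dna[m, ] <- dnaAmp * frac
        ssb[m, ] <- amp[m] * exp(-(x - posPx[m])^2 / (2 * sigPx^2))
    }
    if (!noiseFree) {
        withSeed(cfg@seed + 2L, {
            dna[] <- rpois(length(dna), dna) + rnorm(length(dna), 0, readSd)
            ssb[] <- rpois(length(ssb), ssb) + rnorm(length(ssb), 0, readSd)
        })
        dna[dna < 0] <- 0
        ssb[ssb < 0] <- 0
    }
    new("KymographStack", dnaStain = dna, ssb = ssb, pixelSize = pixelSize,
        frameInterval = cfg@frameInterval, bpPerNm = bpPerNm,
        seed = cfg@seed)
}

#' Write a kymograph stack as 16-bit TIFF files plus a JSON sidecar
#'
#' One TIFF per channel (`<prefix>_dna.tif`, `<prefix>_ssb.tif`), 16-bit
#' unsigned, values scaled by a per-channel factor recorded in
#' `<prefix>_meta.json` together with pixel size, frame interval,
#' bp-per-nm conversion and seed, so the stack round-trips losslessly to
#' 16-bit quantization.
#'
#' @param stack a [KymographStack-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the sidecar path.
#' @export
writeKymographTiff <- function(stack, dir, prefix = "kymo") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    scl <- vapply(list(stack@dnaStain, stack@ssb),
                  function(m) max(m, 1), numeric(1))
    tiff::writeTIFF(stack@dnaStain / scl[1],
                    file.path(dir, paste0(prefix, "_dna.tif")),
                    bits.per.sample = 16)
    tiff::writeTIFF(stack@ssb / scl[2],
                    file.path(dir, paste0(prefix, "_ssb.tif")),
                    bits.per.sample = 16)
    meta <- list(pixel_size_nm = stack@pixelSize,
                 frame_interval_s = stack@frameInterval,
                 bp_per_nm = stack@bpPerNm, seed = stack@seed,
                 scale_dna = scl[1], scale_ssb = scl[2])
    writeJsonAtomic(meta, file.path(dir, paste0(prefix, "_meta.json")))
    invisible(file.path(dir, paste0(prefix, "_meta.json")))
}

#' Read a kymograph stack written by [writeKymographTiff()]
#' @param dir directory holding the TIFFs and sidecar.
#' @param prefix file-name prefix.
#' @return A [KymographStack-class].
#' @export
readKymographTiff <- function(dir, prefix = "kymo") {
    meta <- jsonlite::read_json(file.path(dir, paste0(prefix,
                                                      "_meta.json")),
                                simplifyVector = TRUE)
    dna <- tiff::readTIFF(file.path(dir, paste0(prefix, "_dna.tif"))) *
        meta$scale_dna
    ssb <- tiff::readTIFF(file.path(dir, paste0(prefix, "_ssb.tif"))) *
        meta$scale_ssb
    new("KymographStack", dnaStain = dna, ssb = ssb,
        pixelSize = meta$pixel_size_nm,
        frameInterval = meta$frame_interval_s, bpPerNm = meta$bp_per_nm,
        seed = as.integer(meta$seed))
}

#' Render an in-vivo scene as an image stack
#'
#' Per frame: uniform cytosolic background inside each cell ellipse scaled
#' by the cell's bright pool, Gaussian PSFs at focus positions with
#' amplitudes from the simulated bright counts, optional EMCCD-like noise.
#'
#' @param scene an [InVivoScene-class].
#' @param pixelSize pixel size (nm).
#' @param psfSigmaNm PSF sd (nm).
#' @param photonsPerTetramer total flux per bright tetramer, identical for
#'   cytosolic and focus-bound molecules (focus PSFs are normalized to
#'   unit integral), so whole-cell pixel sums track the bright-molecule
#'   count.
#' @param noiseFree suppress noise.
#' @return list with `frames` (array height x width x nframes) and `meta`.
#' @export
renderCellMovie <- function(scene, pixelSize = 100, psfSigmaNm = 120,
                            photonsPerTetramer = 10, noiseFree = FALSE) {
    cells <- scene@cells; foci <- scene@foci
    gt <- scene@groundTruth
    w <- ceiling((max(cells$cx + cells$ax) + 1000) / pixelSize)
    h <- ceiling((max(cells$cy + cells$ay) + 1000) / pixelSize)
    nFr <- ncol(gt$focus_bright)
    xs <- (seq_len(w) - 0.5) * pixelSize
    ys <- (seq_len(h) - 0.5) * pixelSize
    masks <- lapply(seq_len(nrow(cells)), function(i) {
        mx <- outer(ys, xs, function(y, x)
            ((x - cells$cx[i]) / cells$ax[i])^2 +
                ((y - cells$cy[i]) / cells$ay[i])^2 <= 1)
        list(mask = mx, areaPx = max(sum(mx), 1L))
    })
    sigPx <- psfSigmaNm / pixelSize
    psf <- lapply(seq_len(nrow(foci)), function(j) {
        g <- outer(ys, xs, function(y, x)
            exp(-((x - foci$x[j])^2 + (y - foci$y[j])^2) /
                    (2 * psfSigmaNm^2)))
        g / (2 * pi * sigPx^2)           # unit integral in pixel units
    })
    frames <- array(0, dim = c(h, w, nFr))
    for (m in seq_len(nFr)) {
        img <- matrix(0, h, w)
        for (i in seq_len(nrow(cells))) {
            dens <- gt$pool_bright[i, m] * photonsPerTetramer /
                masks[[i]]$areaPx
            img <- img + masks[[i]]$mask * dens
        }
        for (j in seq_len(nrow(foci)))
            img <- img + gt$focus_bright[j, m] * photonsPerTetramer *
                psf[[j]]
        frames[, , m] <- img
    }
    if (!noiseFree) {
        withSeed(scene@config@seed + 3L, {
            frames[] <- rpois(length(frames), frames) +
                rnorm(length(frames), 0, 2)
        })
        frames[frames < 0] <- 0
    }
    list(frames = frames,
         meta = list(pixel_size_nm = pixelSize,
                     frame_interval_s = scene@config@frameInterval,
                     pulse = scene@pulse, seed = scene@config@seed))
}

#' Write an image stack as a multi-page 16-bit TIFF with a JSON sidecar
#' @param frames array (h x w x nframes).
#' @param path output TIFF path; sidecar written next to it.
#' @param meta list of metadata for the sidecar.
#' @return invisibly, `path`.
#' @export
writeTiffStack <- function(frames, path, meta = list()) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    scl <- max(frames, 1)
    pages <- lapply(seq_len(dim(frames)[3]),
                    function(m) frames[, , m] / scl)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    meta$scale <- scl
    writeJsonAtomic(meta, sub("\\.tiff?$", "_meta.json", path))
    invisible(path)
}
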