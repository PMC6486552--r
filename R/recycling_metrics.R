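## Headline recycling quantities assembled from fitted primitives: how many
## Okazaki-fragment synthesis cycles one exchange time spans, the per-cycle
## retained fraction, and SSB stoichiometry from spot intensities.

#' Okazaki cycles per exchange time
#'
#' The exchange time divided by the time to synthesize one Okazaki fragment
#' (`L_of / v`): the number of fragment synthesis cycles supported by the
#' same pool of fork-bound SSB.
#'
#' @param tau exchange time (s).
#' @param lOfKnt mean Okazaki-fragment length (knt).
#' @param vBpS replication rate (bp/s).
#' @return number of cycles (dimensionless).
#' @examples
#' cyclesPerExchange(20, 1.4, 750)   # ~10.7 cycles at low SSB
#' cyclesPerExchange(2.5, 1.5, 1000) # ~1.7 cycles in vivo
#' @export
cyclesPerExchange <- function(tau, lOfKnt, vBpS) {
    stopIfNot(all(c(tau, lOfKnt, vBpS) > 0),
              "tau, lOfKnt and vBpS must all be > 0")
    tau / (lOfKnt * 1000 / vBpS)
}

#' Fraction of fork-bound SSB retained over one Okazaki cycle
#'
#' For exponential replacement at rate `1/tau`, the fraction of the bound
#' population surviving one fragment time is
#' `exp(-t_of/tau) = exp(-1/n_cycles)`.
#'
#' @inheritParams cyclesPerExchange
#' @return retained fraction in (0, 1).
#' @export
retainedFractionPerCycle <- function(tau, lOfKnt, vBpS) {
    exp(-1 / cyclesPerExchange(tau, lOfKnt, vBpS))
}

#' Build one recycling summary row
#'
#' @inheritParams cyclesPerExchange
#' @param concentration SSB concentration (nM).
#' @return one-row data.frame: `concentration`, `tau_exch`, `L_of`, `v`,
#'   `t_of`, `n_cycles`, `retained_fraction_per_cycle`. `NA` exchange times
#'   propagate as `NA` (explicit missing-value semantics; never
#'   interpolated).
#' @export
recyclingSummary <- function(tau, lOfKnt, vBpS, concentration = NA_real_) {
    if (is.na(tau)) {
        return(data.frame(concentration = concentration,
                          tau_exch = NA_real_, L_of = lOfKnt, v = vBpS,
                          t_of = lOfKnt * 1000 / vBpS,
                          n_cycles = NA_real_,
                          retained_fraction_per_cycle = NA_real_))
    }
    n <- cyclesPerExchange(tau, lOfKnt, vBpS)
    data.frame(concentration = concentration, tau_exch = tau,
               L_of = lOfKnt, v = vBpS, t_of = lOfKnt * 1000 / vBpS,
               n_cycles = n, retained_fraction_per_cycle = exp(-1 / n))
}

#' SSB stoichiometry from spot intensity
#'
#' Divides a spot's intensity by the calibrated single-tetramer intensity
#' (from single-step bleaching plateaus) and converts to an occluded-ssDNA
#' footprint at the configured site size.
#'
#' @param spotIntensity spot intensity (AU).
#' @param unitIntensity single-tetramer intensity (AU), > 0.
#' @param footprintNt nucleotides occluded per tetramer.
#' @return list: `nTetramers`, `footprintNt` (total occluded ssDNA, nt).
#' @examples
#' countTetramers(35, 1) # 35 tetramers, 1225 nt: slightly more than 1 kb
#' @export
countTetramers <- function(spotIntensity, unitIntensity,
                           footprintNt = 35) {
    stopIfNot(unitIntensity > 0, "unitIntensity must be > 0")
    stopIfNot(spotIntensity >= 0, "spotIntensity must be >= 0")
    n <- spotIntensity / unitIntensity
    list(nTetramers = n, footprintNt = n * footprintNt)
}

#' Per-concentration recycling report
#'
#' One [recyclingSummary()] row per concentration plus a monotonicity check
#' of the exchange time versus concentration (faster exchange at higher
#' SSB). Missing exchange times are carried as `NA` rows.
#'
#' @param fits data.frame: `concentration`, `tau` (`NA` allowed), `L_of`
#'   (knt), `v` (bp/s). Replication rates show no significant concentration
#'   dependence, so a single shared `v` may be recycled across rows.
#' @return list with `table` and `tauMonotoneDecreasing` (`NA` when fewer
#'   than two finite exchange times).
#' @export
concentrationSeriesReport <- function(fits) {
    stopIfNot(all(c("concentration", "tau", "L_of", "v") %in% names(fits)),
              "fits needs concentration, tau, L_of, v columns")
    ord <- order(fits$concentration)
    fits <- fits[ord, ]
    tab <- do.call(rbind, lapply(seq_len(nrow(fits)), function(i)
        recyclingSummary(fits$tau[i], fits$L_of[i], fits$v[i],
                         fits$concentration[i])))
    fin <- is.finite(tab$tau_exch)
    mono <- if (sum(fin) >= 2) all(diff(tab$tau_exch[fin]) < 0) else NA
    list(table = tab, tauMonotoneDecreasing = mono)
}
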