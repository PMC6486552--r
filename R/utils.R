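#' @importFrom stats rnorm rexp runif rbinom rpois approx lm coef median mad
#'   var sd quantile setNames complete.cases vcov nls.control predict
#' @importFrom utils head tail read.csv write.csv packageVersion
#'   modifyList
NULL

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so seeded helpers do not perturb the global
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

## Derive a reproducible vector of sub-seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopIfNot <- function(cond, msg) {
    if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## Atomic file writes: write to a temp file in the same directory, then rename.
atomicWrite <- function(writer, path) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    writer(tmp)
    file.rename(tmp, path)
    invisible(path)
}

writeCsvAtomic <- function(df, path) {
    atomicWrite(function(tmp) write.csv(df, tmp, row.names = FALSE), path)
}

writeJsonAtomic <- function(x, path) {
    atomicWrite(function(tmp) {
        jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null", na = "null")
    }, path)
}
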