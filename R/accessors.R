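## Accessor generics and methods, plus show() methods, for the S4 containers.

#' @rdname RawTrace-class
#' @param object,x a package object.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname RawTrace-class
#' @export
setMethod("nSamples", "RawTrace", function(x) length(x@current))

#' Trace samples, sampling rate and filter cutoff
#'
#' @param x a [RawTrace-class].
#' @return `traceCurrent()` the numeric sample vector (pA);
#'   `samplingRate()` the sampling frequency (Hz); `filterCutoff()` the
#'   acquisition low-pass cutoff (Hz); `traceTime()` the sample times (s).
#' @export
traceCurrent <- function(x) x@current

#' @rdname traceCurrent
#' @export
samplingRate <- function(x) x@samplingRate

#' @rdname traceCurrent
#' @export
filterCutoff <- function(x) x@filterCutoff

#' @rdname traceCurrent
#' @export
traceTime <- function(x) (seq_along(x@current) - 1L) / x@samplingRate

setMethod("show", "RawTrace", function(object) {
    cat(sprintf(
        "RawTrace: %d samples @ %g Hz (%.3f s), f_c = %g Hz, range [%.3g, %.3g] pA\n",
        length(object@current), object@samplingRate,
        length(object@current) / object@samplingRate, object@filterCutoff,
        min(object@current), max(object@current)))
})

## ---- DwellSequence --------------------------------------------------------

#' Dwell-sequence accessors
#'
#' @param x a [DwellSequence-class].
#' @return `dwellStates()` / `dwellDurations()` the per-event state and
#'   duration vectors; `recordDuration()` the total record time
#'   \eqn{T_m} (s); `nOpen()` / `nClosed()` event counts; `openTime()` /
#'   `closedTime()` summed dwell times (s); `dwellEvents()` a data.frame
#'   with columns `state`, `start_s`, `duration_s`.
#' @export
dwellStates <- function(x) x@states

#' @rdname dwellStates
#' @export
dwellDurations <- function(x) x@durations

#' @rdname dwellStates
#' @export
recordDuration <- function(x) sum(x@durations)

#' @rdname dwellStates
#' @export
nOpen <- function(x) sum(x@states == "open")

#' @rdname dwellStates
#' @export
nClosed <- function(x) sum(x@states == "closed")

#' @rdname dwellStates
#' @export
openTime <- function(x) sum(x@durations[x@states == "open"])

#' @rdname dwellStates
#' @export
closedTime <- function(x) sum(x@durations[x@states == "closed"])

#' @rdname dwellStates
#' @export
dwellEvents <- function(x) {
    data.frame(state = x@states,
               start_s = cumsum(c(0, x@durations[-length(x@durations)])),
               duration_s = x@durations)
}

setMethod("show", "DwellSequence", function(object) {
    cat(sprintf(
        "DwellSequence: %d events (%d open, %d closed), T_m = %.4g s, P_o = %.4g\n",
        length(object@states), nOpen(object), nClosed(object),
        recordDuration(object),
        if (recordDuration(object) > 0) openProbability(object) else NA_real_))
})

## ---- HillFit --------------------------------------------------------------

#' Hill-fit accessors
#'
#' @param x a [HillFit-class].
#' @return `hillKd()`, `hillN()`, `hillAmplitude()` the fitted parameters;
#'   `hillSe()` their standard errors; `isFlagged()` whether the fit was
#'   flagged for attention.
#' @export
hillKd <- function(x) x@kd

#' @rdname hillKd
#' @export
hillN <- function(x) x@n

#' @rdname hillKd
#' @export
hillAmplitude <- function(x) x@amplitude

#' @rdname hillKd
#' @export
hillSe <- function(x) x@se

#' @rdname hillKd
#' @export
isFlagged <- function(x) x@flagged

setMethod("show", "HillFit", function(object) {
    cat(sprintf(
        "HillFit: K_d = %.4g (se %.3g), n = %.3g (se %.3g), amplitude = %.4g (se %.3g)\n",
        object@kd, object@se[["kd"]], object@n, object@se[["n"]],
        object@amplitude, object@se[["amplitude"]]))
    if (!object@converged) cat("  [optimizer did not converge]\n")
    if (object@flagged) cat("  [flagged: ", object@flagReason, "]\n", sep = "")
})

## ---- PoSurface ------------------------------------------------------------

#' Surface accessors
#'
#' @param x a [PoSurface-class].
#' @return `surfaceData()` the long-format data.frame; `surfaceTruth()`
#'   the generator ground truth (empty list for measured data).
#' @export
surfaceData <- function(x) x@data

#' @rdname surfaceData
#' @export
surfaceTruth <- function(x) x@truth

setMethod("show", "PoSurface", function(object) {
    d <- object@data
    cat(sprintf(
        "PoSurface: %d observations, %d PIP2 doses x %d Galpha(i3) doses, %s\n",
        nrow(d), length(unique(d$pip2_uM)), length(unique(d$gai3_uM)),
        if (length(object@truth)) "with generator truth" else "measured"))
})

## ---- ThreeCubeSet / BleedConstants ---------------------------------------

#' Intensity lookup for a three-cube set
#'
#' @param x a [ThreeCubeSet-class].
#' @param cube one of `"CFP"`, `"YFP"`, `"FRET"`.
#' @param specimen one of `"D"`, `"A"`, `"DA"`.
#' @return The stored background-corrected intensity (may be `NA`).
#' @export
intensity <- function(x, cube, specimen) {
    x@intensities[match.arg(cube, .CUBES), match.arg(specimen, .SPECIMENS)]
}

setMethod("show", "ThreeCubeSet", function(object) {
    cat("ThreeCubeSet (rows: cube, cols: specimen):\n")
    print(object@intensities)
})

#' Bleed-constant accessors
#'
#' @param x a [BleedConstants-class].
#' @return The requested bleed-through ratio.
#' @export
rd1 <- function(x) x@rd1

#' @rdname rd1
#' @export
rd2 <- function(x) x@rd2

#' @rdname rd1
#' @export
ra1 <- function(x) x@ra1

setMethod("show", "BleedConstants", function(object) {
    cat(sprintf("BleedConstants: R_D1 = %.4g, R_D2 = %.4g, R_A1 = %.4g\n",
                object@rd1, object@rd2, object@ra1))
    if (any(is.finite(object@dispersion)))
        cat(sprintf("  per-cell sd: R_D1 %.3g, R_D2 %.3g, R_A1 %.3g\n",
                    object@dispersion[["rd1"]], object@dispersion[["rd2"]],
                    object@dispersion[["ra1"]]))
})

## ---- ParticleTable --------------------------------------------------------

#' Particle-table accessors
#'
#' @param x a [ParticleTable-class].
#' @return `particleData()` the per-subunit data.frame; `symmetryOrder()`
#'   the cyclic symmetry order S; `nParticles()` the number of distinct
#'   original particles.
#' @export
particleData <- function(x) x@data

#' @rdname particleData
#' @export
symmetryOrder <- function(x) x@symmetryOrder

#' @rdname particleData
#' @export
nParticles <- function(x) length(unique(x@data$particle_id))

setMethod("show", "ParticleTable", function(object) {
    cat(sprintf("ParticleTable: %d rows, %d original particles, C%d symmetry\n",
                nrow(object@data), nParticles(object), object@symmetryOrder))
})

## ---- StructureModel / SuperpositionResult --------------------------------

#' Structure accessors
#'
#' @param x a [StructureModel-class].
#' @return `atomData()` the atom data.frame; `atomCoords()` the n x 3
#'   coordinate matrix (Angstrom); `nAtoms()` the atom count.
#' @export
atomData <- function(x) x@atoms

#' @rdname atomData
#' @export
atomCoords <- function(x) as.matrix(x@atoms[, c("x", "y", "z")])

#' @rdname atomData
#' @export
nAtoms <- function(x) nrow(x@atoms)

setMethod("show", "StructureModel", function(object) {
    a <- object@atoms
    cat(sprintf("StructureModel: %d atoms, %d chains (%s), %d residues\n",
                nrow(a), length(unique(a$chain)),
                paste(sort(unique(a$chain)), collapse = ","),
                nrow(unique(a[, c("chain", "resno", "insert")]))))
})

#' Superposition accessors
#'
#' @param x a [SuperpositionResult-class].
#' @return `superpositionRmsd()` the residual RMSD (Angstrom);
#'   `superpositionRotation()` / `superpositionTranslation()` the rigid
#'   transform mapping mobile onto reference coordinates.
#' @export
superpositionRmsd <- function(x) x@rmsd

#' @rdname superpositionRmsd
#' @export
superpositionRotation <- function(x) x@rotation

#' @rdname superpositionRmsd
#' @export
superpositionTranslation <- function(x) x@translation

setMethod("show", "SuperpositionResult", function(object) {
    cat(sprintf(
        "SuperpositionResult: RMSD = %.4g A over %d atoms, rotation angle = %.3g deg\n",
        object@rmsd, object@nAtoms, rotationAngle(object)))
})
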