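#' @import methods
NULL

## ---------------------------------------------------------------------------
## Single-channel containers
## ---------------------------------------------------------------------------

#' Raw single-channel current trace
#'
#' A uniformly sampled current trace from an excised-patch recording (or a
#' simulation of one), together with the acquisition metadata the idealizer
#' needs: the sampling rate and the cut-off frequency of the low-pass filter
#' applied during acquisition.
#'
#' @slot current numeric vector of current samples, in pA.
#' @slot samplingRate sampling frequency, in Hz.
#' @slot filterCutoff low-pass filter cut-off frequency \eqn{f_c}, in Hz.
#'
#' @seealso [rawTrace()], [idealizeTrace()], [simulateGatingTrace()]
#' @export
setClass("RawTrace",
    representation(
        current      = "numeric",
        samplingRate = "numeric",
        filterCutoff = "numeric"
    )
)

setValidity("RawTrace", function(object) {
    msg <- NULL
    if (length(object@current) < 1L || !all(is.finite(object@current)))
        msg <- c(msg, "'current' must be a non-empty finite numeric vector")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
        msg <- c(msg, "'samplingRate' must be a single positive number")
    if (length(object@filterCutoff) != 1L || object@filterCutoff <= 0)
        msg <- c(msg, "'filterCutoff' must be a single positive number")
    if (is.null(msg) && object@samplingRate <= 2 * object@filterCutoff)
        msg <- c(msg, "'samplingRate' must exceed twice 'filterCutoff' (Nyquist)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RawTrace
#'
#' @param current numeric vector of current samples (pA).
#' @param samplingRate sampling frequency (Hz).
#' @param filterCutoff acquisition low-pass cut-off frequency (Hz).
#' @return A [RawTrace-class] object.
#' @examples
#' tr <- rawTrace(c(0, 0, -2, -2, 0), samplingRate = 10000, filterCutoff = 1000)
#' nSamples(tr)
#' @export
rawTrace <- function(current, samplingRate, filterCutoff) {
    new("RawTrace", current = as.numeric(current),
        samplingRate = as.numeric(samplingRate),
        filterCutoff = as.numeric(filterCutoff))
}

#' Idealized dwell sequence
#'
#' The result of idealizing a single-channel trace: an alternating sequence
#' of open and closed sojourns with their durations.  The record duration
#' \eqn{T_m} equals the sum of all dwell durations.
#'
#' @slot states character vector, each element \code{"open"} or
#'   \code{"closed"}; states strictly alternate.
#' @slot durations numeric vector of dwell durations in seconds, positive,
#'   parallel to \code{states}.
#'
#' @seealso [dwellSequence()], [openProbability()], [idealizeTrace()]
#' @export
setClass("DwellSequence",
    representation(
        states    = "character",
        durations = "numeric"
    )
)

setValidity("DwellSequence", function(object) {
    msg <- NULL
    if (length(object@states) != length(object@durations))
        msg <- c(msg, "'states' and 'durations' must have equal length")
    if (!all(object@states %in% c("open", "closed")))
        msg <- c(msg, "states must be 'open' or 'closed'")
    if (length(object@durations) && !all(object@durations > 0))
        msg <- c(msg, "all durations must be positive")
    n <- length(object@states)
    if (n > 1L && any(object@states[-1L] == object@states[-n]))
        msg <- c(msg, "states must strictly alternate")
    if (is.null(msg)) TRUE else msg
})

#' Construct a DwellSequence
#'
#' @param states character vector of \code{"open"}/\code{"closed"} states.
#' @param durations numeric vector of dwell durations (s).
#' @return A [DwellSequence-class] object.
#' @examples
#' dw <- dwellSequence(c("closed", "open", "closed"), c(1, 0.5, 2.5))
#' openProbability(dw)
#' @export
dwellSequence <- function(states, durations) {
    new("DwellSequence", states = as.character(states),
        durations = as.numeric(durations))
}

## ---------------------------------------------------------------------------
## Dose-response containers
## ---------------------------------------------------------------------------

#' Hill-equation fit result
#'
#' Parameters of the Hill equation
#' \eqn{P(x) = A \, x^n / (K_d^n + x^n)} fitted to dose-response data:
#' the apparent dissociation constant \eqn{K_d}, the Hill coefficient
#' \eqn{n} and the amplitude \eqn{A}, with standard errors, a convergence
#' flag, and a quality flag raised when the fit is non-identifiable or the
#' fitted \eqn{K_d} lies far outside the dosed range.
#'
#' @slot kd apparent dissociation constant (same units as the doses).
#' @slot n Hill coefficient (dimensionless).
#' @slot amplitude maximal response (fraction, for normalized data).
#' @slot se named numeric vector of standard errors (\code{kd}, \code{n},
#'   \code{amplitude}; \code{NA} for fixed or non-estimable parameters).
#' @slot converged logical, did the optimizer converge.
#' @slot flagged logical, fit requires manual attention.
#' @slot flagReason character, why the fit was flagged (\code{""} if not).
#'
#' @seealso [fitHill()], [predictHill()]
#' @export
setClass("HillFit",
    representation(
        kd         = "numeric",
        n          = "numeric",
        amplitude  = "numeric",
        se         = "numeric",
        converged  = "logical",
        flagged    = "logical",
        flagReason = "character"
    )
)

setValidity("HillFit", function(object) {
    msg <- NULL
    for (s in c("kd", "n", "amplitude"))
        if (length(slot(object, s)) != 1L)
            msg <- c(msg, sprintf("'%s' must be a single number", s))
    if (is.null(msg) && is.finite(object@kd) && object@kd <= 0)
        msg <- c(msg, "'kd' must be positive")
    if (is.null(msg) && is.finite(object@n) && object@n <= 0)
        msg <- c(msg, "'n' must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Two-ligand open-probability surface
#'
#' Normalized open probability measured over a grid of two ligand
#' concentrations (the membrane cofactor PIP2 and the G-protein subunit
#' Galpha(i3)), in long format with optional replicates.  When built by the
#' synthetic generator the ground-truth per-column Hill parameters are
#' carried in \code{truth}.
#'
#' @slot data data.frame with columns \code{pip2_uM}, \code{gai3_uM},
#'   \code{replicate}, \code{po_norm}.
#' @slot truth list of ground-truth generation parameters (empty for
#'   measured data).
#'
#' @seealso [poSurface()], [fitSurface()], [simulateHillSurface()]
#' @export
setClass("PoSurface",
    representation(
        data  = "data.frame",
        truth = "list"
    )
)

setValidity("PoSurface", function(object) {
    msg <- NULL
    need <- c("pip2_uM", "gai3_uM", "replicate", "po_norm")
    if (!all(need %in% names(object@data)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(object@data)), collapse = ", ")))
    else {
        if (nrow(object@data) == 0L)
            msg <- c(msg, "surface has no rows")
        po <- object@data$po_norm
        if (!all(is.finite(po)) || any(po < 0) || any(po > 1 + 1e-9))
            msg <- c(msg, "'po_norm' values must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a PoSurface
#'
#' @param data data.frame with columns \code{pip2_uM}, \code{gai3_uM},
#'   \code{replicate}, \code{po_norm}.
#' @param truth optional list of ground-truth parameters.
#' @return A [PoSurface-class] object.
#' @export
poSurface <- function(data, truth = list()) {
    if (!"replicate" %in% names(data)) data$replicate <- 1L
    new("PoSurface", data = as.data.frame(data), truth = truth)
}

## ---------------------------------------------------------------------------
## Three-cube FRET containers
## ---------------------------------------------------------------------------

.CUBES     <- c("CFP", "YFP", "FRET")
.SPECIMENS <- c("D", "A", "DA")

#' Three-cube FRET intensity set
#'
#' Background-corrected fluorescence intensities \eqn{S_{CUBE}(SPECIMEN)}
#' for filter cubes CFP, YFP and FRET measured on donor-only (D),
#' acceptor-only (A) and double-labelled (DA) specimens.  Entries not
#' measured are \code{NA}; each computation checks that the entries it
#' needs are present.
#'
#' @slot intensities 3 x 3 numeric matrix, rows \code{CFP,YFP,FRET},
#'   columns \code{D,A,DA}; non-negative or \code{NA}.
#'
#' @seealso [threeCubeSet()], [bleedConstants()], [fretRatio()],
#'   [simulateThreeCube()]
#' @export
setClass("ThreeCubeSet",
    representation(intensities = "matrix")
)

setValidity("ThreeCubeSet", function(object) {
    m <- object@intensities
    msg <- NULL
    if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
        msg <- c(msg, "'intensities' must be a 3 x 3 numeric matrix")
    else {
        if (!identical(rownames(m), .CUBES) || !identical(colnames(m), .SPECIMENS))
            msg <- c(msg, "dimnames must be CFP/YFP/FRET x D/A/DA")
        if (any(m < 0, na.rm = TRUE))
            msg <- c(msg, "intensities must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a ThreeCubeSet
#'
#' @param intensities 3 x 3 numeric matrix (rows \code{CFP,YFP,FRET},
#'   columns \code{D,A,DA}), or a named list/vector of entries like
#'   \code{FRET.D = 30}.
#' @return A [ThreeCubeSet-class] object.
#' @examples
#' s <- threeCubeSet(c(CFP.D = 100, YFP.D = 6, FRET.D = 30))
#' intensity(s, "FRET", "D")
#' @export
threeCubeSet <- function(intensities) {
    m <- matrix(NA_real_, 3L, 3L, dimnames = list(.CUBES, .SPECIMENS))
    if (is.matrix(intensities)) {
        m[rownames(intensities), colnames(intensities)] <- intensities
    } else {
        v <- unlist(intensities)
        parts <- strsplit(names(v), ".", fixed = TRUE)
        for (i in seq_along(v))
            m[parts[[i]][1L], parts[[i]][2L]] <- v[[i]]
    }
    new("ThreeCubeSet", intensities = m)
}

#' Bleed-through constants for three-cube FRET
#'
#' The three cross-talk ratios determined from single-fluorophore control
#' cells: \eqn{R_{D1} = S_{FRET}(D)/S_{CFP}(D)},
#' \eqn{R_{D2} = S_{YFP}(D)/S_{CFP}(D)} and
#' \eqn{R_{A1} = S_{FRET}(A)/S_{YFP}(A)}.
#'
#' @slot rd1,rd2,ra1 bleed-through ratios (dimensionless, positive).
#' @slot dispersion named numeric vector of per-cell standard deviations
#'   when constants were averaged over several control cells (\code{NA}
#'   for a single cell).
#'
#' @seealso [bleedConstants()]
#' @export
setClass("BleedConstants",
    representation(
        rd1 = "numeric", rd2 = "numeric", ra1 = "numeric",
        dispersion = "numeric"
    )
)

setValidity("BleedConstants", function(object) {
    v <- c(object@rd1, object@rd2, object@ra1)
    if (length(v) != 3L || !all(is.finite(v)) || !all(v > 0))
        "rd1, rd2 and ra1 must be single positive numbers"
    else TRUE
})

## ---------------------------------------------------------------------------
## Particle-occupancy containers
## ---------------------------------------------------------------------------

#' Symmetry-expanded cryo-EM particle table
#'
#' Per-subunit particle metadata after point-group symmetry expansion: each
#' original particle contributes one row per asymmetric unit (subunit),
#' carrying the focused-classification class assignment used to score that
#' subunit as ligand-bound or unbound.  Extra metadata columns (poses,
#' micrograph paths, ...) are passed through untouched so that files can be
#' round-tripped.
#'
#' @slot data data.frame with at least \code{particle_id} (opaque key of the
#'   original, un-expanded particle), \code{subunit_index} (0-based, below
#'   \code{symmetryOrder}) and \code{class_id} (integer focused-class label).
#' @slot symmetryOrder the cyclic symmetry order S (4 for a C4 channel).
#'
#' @seealso [particleTable()], [readStar()], [sortParticles()],
#'   [simulateParticleTable()]
#' @export
setClass("ParticleTable",
    representation(
        data          = "data.frame",
        symmetryOrder = "integer"
    )
)

setValidity("ParticleTable", function(object) {
    msg <- NULL
    need <- c("particle_id", "subunit_index", "class_id")
    if (!all(need %in% names(object@data)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(object@data)), collapse = ", ")))
    if (length(object@symmetryOrder) != 1L || object@symmetryOrder < 1L)
        msg <- c(msg, "'symmetryOrder' must be a single integer >= 1")
    if (is.null(msg) && nrow(object@data) &&
        (any(object@data$subunit_index < 0L) ||
         any(object@data$subunit_index >= object@symmetryOrder)))
        msg <- c(msg, "'subunit_index' must lie in [0, symmetryOrder)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a ParticleTable
#'
#' @param data data.frame with columns \code{particle_id},
#'   \code{subunit_index}, \code{class_id} plus arbitrary pass-through
#'   columns.
#' @param symmetryOrder cyclic symmetry order S (default 4).
#' @return A [ParticleTable-class] object.
#' @export
particleTable <- function(data, symmetryOrder = 4L) {
    data$subunit_index <- as.integer(data$subunit_index)
    data$class_id <- as.integer(data$class_id)
    new("ParticleTable", data = as.data.frame(data),
        symmetryOrder = as.integer(symmetryOrder))
}

## ---------------------------------------------------------------------------
## Structure containers
## ---------------------------------------------------------------------------

#' Atomic structure model
#'
#' A flat atom table sufficient for superposition, interface-area and
#' domain-rotation analysis: chain, residue, atom name, element, Cartesian
#' coordinates and a van der Waals radius per atom.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{insert}, \code{elety} (atom name), \code{element},
#'   \code{x}, \code{y}, \code{z}, \code{radius}.
#'
#' @seealso [structureModel()], [readStructure()], [selectAtoms()],
#'   [superposeStructures()], [buriedInterfaceArea()]
#' @export
setClass("StructureModel",
    representation(atoms = "data.frame")
)

setValidity("StructureModel", function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "resid", "insert", "elety", "element",
              "x", "y", "z", "radius")
    msg <- NULL
    if (!all(need %in% names(a)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(a)), collapse = ", ")))
    else {
        if (nrow(a) < 1L)
            msg <- c(msg, "model contains no atoms")
        if (nrow(a) && !all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
            msg <- c(msg, "coordinates must be finite")
        if (nrow(a) && !all(a$radius > 0))
            msg <- c(msg, "radii must be positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a StructureModel
#'
#' @param atoms data.frame of atoms; missing \code{resid}, \code{insert},
#'   \code{elety} or \code{element} columns are filled with defaults and a
#'   missing \code{radius} column is assigned from the built-in van der
#'   Waals table (see [vdwRadius()]).
#' @return A [StructureModel-class] object.
#' @export
structureModel <- function(atoms) {
    atoms <- as.data.frame(atoms)
    if (is.null(atoms$resid))   atoms$resid   <- "UNK"
    if (is.null(atoms$insert))  atoms$insert  <- ""
    if (is.null(atoms$elety))   atoms$elety   <- "CA"
    if (is.null(atoms$element)) atoms$element <- "C"
    if (is.null(atoms$radius))  atoms$radius  <- vdwRadius(atoms$element)
    new("StructureModel", atoms = atoms)
}

#' Rigid superposition result
#'
#' Optimal least-squares rigid transform (Kabsch) mapping a mobile onto a
#' reference point set, the residual RMSD and the number of atom pairs
#' used.  The transform maps mobile coordinates \eqn{x} to
#' \eqn{R x + t}.
#'
#' @slot rotation 3 x 3 proper rotation matrix (determinant +1).
#' @slot translation length-3 translation vector (Angstrom).
#' @slot rmsd root-mean-square deviation after superposition (Angstrom).
#' @slot nAtoms number of atom pairs used.
#'
#' @seealso [superposeStructures()], [rotationAngle()]
#' @export
setClass("SuperpositionResult",
    representation(
        rotation    = "matrix",
        translation = "numeric",
        rmsd        = "numeric",
        nAtoms      = "integer"
    )
)

setValidity("SuperpositionResult", function(object) {
    msg <- NULL
    R <- object@rotation
    if (!identical(dim(R), c(3L, 3L)))
        msg <- c(msg, "'rotation' must be 3 x 3")
    else {
        if (max(abs(crossprod(R) - diag(3))) > 1e-6)
            msg <- c(msg, "'rotation' must be orthonormal")
        if (abs(det(R) - 1) > 1e-6)
            msg <- c(msg, "'rotation' must be proper (det = +1)")
    }
    if (length(object@translation) != 3L)
        msg <- c(msg, "'translation' must have length 3")
    if (length(object@rmsd) != 1L || object@rmsd < 0)
        msg <- c(msg, "'rmsd' must be a single non-negative number")
    if (is.null(msg)) TRUE else msg
})
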