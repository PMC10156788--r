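## Synthetic-data generators.  Each generator emits data with the exact
## statistical structure the corresponding analysis stage assumes, together
## with its ground truth, so every stage of the pipeline can be validated
## without external downloads.  All generators are deterministic under a
## fixed seed.

#' Simulate a single-channel gating trace
#'
#' Two-state (closed <-> open) continuous-time Markov gating: exponential
#' waiting times with the given opening (C->O) and closing (O->C) rates are
#' drawn until the requested duration is covered, the state path is sampled
#' at `samplingRate`, scaled by the unitary current, and Gaussian noise
#' low-pass filtered at `filterCutoff` (the digital analogue of the
#' recording Bessel filter) is added.  The closed level is 0 pA.  The true
#' dwell sequence is returned alongside the trace so idealization can be
#' scored event by event.
#'
#' Generating the continuous-time path first and sampling it afterwards
#' avoids discretization bias for dwells near the dead time.  The default
#' acquisition settings (10 kHz sampling, 1 kHz cut-off) are the standard
#' excised inside-out configuration; the default unitary current of -2 pA
#' and post-filter noise SD of 0.25 pA are typical of such patches.
#'
#' @param openingRate C->O transition rate (per second), positive.
#' @param closingRate O->C transition rate (per second), positive.
#' @param unitaryCurrent open-channel current relative to closed (pA);
#'   negative for inward current.
#' @param noiseSd standard deviation of the additive noise after
#'   filtering (pA).
#' @param samplingRate sampling frequency (Hz); must be at least twice
#'   `filterCutoff` and at least five times each gating rate.
#' @param filterCutoff noise low-pass cut-off frequency (Hz).
#' @param duration record length (s).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return List with components `trace` ([RawTrace-class]), `dwells` (the
#'   true [DwellSequence-class]), `levels` (true closed/open levels) and
#'   `pOpen` (the stationary open probability
#'   `openingRate / (openingRate + closingRate)`).
#' @examples
#' sim <- simulateGatingTrace(20, 30, duration = 2, seed = 1)
#' sim$pOpen
#' openProbability(sim$dwells)
#' @export
simulateGatingTrace <- function(openingRate, closingRate,
                                unitaryCurrent = -2, noiseSd = 0.25,
                                samplingRate = 10000, filterCutoff = 1000,
                                duration = 10, seed = NULL) {
    if (!is.finite(openingRate) || openingRate <= 0 ||
        !is.finite(closingRate) || closingRate <= 0)
        stop("gating rates must be positive and finite")
    if (duration <= 0) stop("'duration' must be positive")
    if (samplingRate < 2 * filterCutoff)
        stop("'samplingRate' must be at least twice 'filterCutoff'")
    if (max(openingRate, closingRate) > samplingRate / 5)
        stop("gating rates too fast for 'samplingRate': mean dwell must ",
             "span at least 5 sample periods")
    if (noiseSd < 0) stop("'noiseSd' must be non-negative")
    if (!is.null(seed)) set.seed(seed)

    pOpen <- openingRate / (openingRate + closingRate)
    startOpen <- stats::runif(1) < pOpen

    ## exponential waiting times until the duration is covered
    states <- logical(0); durs <- numeric(0)
    chunk <- max(16L, ceiling(2 * duration *
                              (1 / (1 / openingRate + 1 / closingRate))))
    total <- 0
    open <- startOpen
    while (total < duration) {
        nc <- ceiling(chunk / 2)
        dC <- stats::rexp(nc, openingRate)   # closed sojourns
        dO <- stats::rexp(nc, closingRate)   # open sojourns
        d <- if (open) as.vector(rbind(dO, dC)) else as.vector(rbind(dC, dO))
        s <- if (open) rep(c(TRUE, FALSE), nc) else rep(c(FALSE, TRUE), nc)
        states <- c(states, s); durs <- c(durs, d)
        total <- total + sum(d)
        open <- !s[length(s)]
    }
    cum <- cumsum(durs)
    last <- which(cum >= duration)[1L]
    durs <- durs[seq_len(last)]
    states <- states[seq_len(last)]
    durs[last] <- durs[last] - (cum[last] - duration)   # truncate to duration
    keep <- durs > 0
    durs <- durs[keep]; states <- states[keep]

    ## sample the state path
    n <- round(duration * samplingRate)
    t <- (seq_len(n) - 1L) / samplingRate
    idx <- findInterval(t, cumsum(durs)) + 1L
    idx[idx > length(durs)] <- length(durs)
    signal <- ifelse(states[idx], unitaryCurrent, 0)

    if (noiseSd > 0) {
        gain <- .kernelNoiseGain(gaussianKernel(filterCutoff, samplingRate))
        noise <- gaussianFilter(stats::rnorm(n, 0, noiseSd / gain),
                                filterCutoff, samplingRate)
        signal <- signal + noise
    }

    list(trace  = rawTrace(signal, samplingRate, filterCutoff),
         dwells = dwellSequence(ifelse(states, "open", "closed"), durs),
         levels = c(closed = 0, open = unitaryCurrent),
         pOpen  = pOpen)
}

## ---------------------------------------------------------------------------

#' Canonical occupancy-pattern vocabulary for a C4 ring
#'
#' The six distinguishable ways 0-4 ligands can decorate a four-fold ring,
#' up to cyclic rotation: none, one, two adjacent (`"2-cis"`), two opposite
#' (`"2-trans"`), three, four.
#'
#' @return Character vector of the six canonical labels.
#' @export
occupancyPatternLabels <- function() c("0", "1", "2-cis", "2-trans", "3", "4")

## representative bound-flag tuple for each canonical C4 pattern
.patternTuple <- function(label) {
    switch(label,
        "0"       = c(FALSE, FALSE, FALSE, FALSE),
        "1"       = c(TRUE,  FALSE, FALSE, FALSE),
        "2-cis"   = c(TRUE,  TRUE,  FALSE, FALSE),
        "2-trans" = c(TRUE,  FALSE, TRUE,  FALSE),
        "3"       = c(TRUE,  TRUE,  TRUE,  FALSE),
        "4"       = c(TRUE,  TRUE,  TRUE,  TRUE),
        stop("unknown pattern label: ", label))
}

#' Simulate a symmetry-expanded particle table
#'
#' Draws an occupancy pattern for each original particle from the given
#' pattern frequencies, applies a uniformly random rotational phase (so
#' canonicalization is genuinely exercised), and expands each particle to
#' `symmetryOrder` per-subunit rows.  Bound subunits receive one of two
#' bound focused-class ids (1, 2) and unbound subunits one of two unbound
#' ids (3, 4), mirroring a focused 3D classification with two strong- and
#' two weak-density classes.  RELION-style metadata columns (image name,
#' coordinates, Euler angles with the in-plane symmetry offsets of
#' 360/S degrees) are generated so the table can be written to and
#' re-derived from a STAR file.
#'
#' @param nParticles number of original particles.
#' @param freqs named numeric vector of pattern frequencies over (a subset
#'   of) [occupancyPatternLabels()]; non-negative, summing to 1.
#' @param symmetryOrder cyclic symmetry order (default 4; the pattern
#'   vocabulary is defined for 4).
#' @param seed integer seed.
#' @return A [ParticleTable-class] whose data carry, besides the required
#'   keys, the truth column `tqBoundTruth` and RELION metadata columns.
#' @examples
#' pt <- simulateParticleTable(10, c("1" = 0.5, "4" = 0.5), seed = 1)
#' nrow(particleData(pt))   # 40
#' @export
simulateParticleTable <- function(nParticles, freqs, symmetryOrder = 4L,
                                  seed = NULL) {
    S <- as.integer(symmetryOrder)
    if (S != 4L)
        stop("the canonical pattern vocabulary is defined for symmetryOrder 4")
    if (is.null(names(freqs)) || !all(names(freqs) %in% occupancyPatternLabels()))
        stop("'freqs' must be named with canonical pattern labels")
    if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
        stop("'freqs' must be non-negative and sum to 1")
    if (!is.null(seed)) set.seed(seed)

    labels <- sample(names(freqs), nParticles, replace = TRUE, prob = freqs)
    phase  <- sample.int(S, nParticles, replace = TRUE) - 1L
    baseRot <- stats::runif(nParticles, -180, 180)
    tilt <- stats::runif(nParticles, 0, 180)
    psi  <- stats::runif(nParticles, -180, 180)
    cx <- sample.int(4096L, nParticles, replace = TRUE)
    cy <- sample.int(4096L, nParticles, replace = TRUE)
    img <- sprintf("%06d@job/particles.mrcs", seq_len(nParticles))

    rows <- vector("list", nParticles)
    for (i in seq_len(nParticles)) {
        tup <- .patternTuple(labels[i])
        tup <- tup[((seq_len(S) - 1L + phase[i]) %% S) + 1L]  # random phase
        cls <- ifelse(tup, sample(c(1L, 2L), S, replace = TRUE),
                           sample(c(3L, 4L), S, replace = TRUE))
        rot <- ((baseRot[i] + (seq_len(S) - 1L) * 360 / S + 180) %% 360) - 180
        rows[[i]] <- data.frame(
            particle_id   = paste(img[i], cx[i], cy[i], sep = "/"),
            subunit_index = seq_len(S) - 1L,
            class_id      = cls,
            tqBoundTruth  = tup,
            rlnImageName  = img[i],
            rlnCoordinateX = cx[i], rlnCoordinateY = cy[i],
            rlnAngleRot = rot, rlnAngleTilt = tilt[i], rlnAnglePsi = psi[i],
            rlnClassNumber = cls)
    }
    particleTable(do.call(rbind, rows), S)
}

## ---------------------------------------------------------------------------

#' Simulate a two-ligand Hill-form open-probability surface
#'
#' For each Galpha(i3) concentration a Hill curve in [PIP2] with its own
#' apparent \eqn{K_d}, Hill coefficient and amplitude is evaluated on the
#' PIP2 grid, Gaussian noise is added, and the result is clipped to
#' `[0, 1]`.  With `noiseSd = 0` the surface is exactly Hill-form, so
#' fitting it back recovers the truth to optimizer precision.
#'
#' Defaults emulate the dose ranges of an excised-patch titration: PIP2
#' doses spanning 0.5-50 uM and Galpha(i3) concentrations from 0.07 to
#' 14.6 uM, with the apparent K_d for PIP2 falling from 23.3 to 10.2 uM as
#' Galpha(i3) rises.
#'
#' @param kd per-column apparent K_d for PIP2 (uM); recycled along
#'   `gai3Conc`.
#' @param hillN per-column Hill coefficient; recycled.
#' @param amplitude per-column amplitude (fraction of the global maximum,
#'   in (0, 1]); recycled.
#' @param pip2Conc PIP2 dose grid (uM), non-empty.
#' @param gai3Conc Galpha(i3) concentration grid (uM), non-empty.
#' @param noiseSd additive noise SD (fraction of the normalized response).
#' @param replicates replicate observations per grid point.
#' @param seed integer seed.
#' @return A [PoSurface-class]; `surfaceTruth()` returns the generation
#'   parameters.
#' @export
simulateHillSurface <- function(kd = c(23.3, 18, 13, 10.2),
                                hillN = 1.5, amplitude = 1,
                                pip2Conc = c(0.5, 1, 2, 5, 10, 16, 30, 50),
                                gai3Conc = c(0.07, 0.73, 2.92, 14.6),
                                noiseSd = 0, replicates = 1L, seed = NULL) {
    if (length(pip2Conc) == 0L || length(gai3Conc) == 0L)
        stop("concentration grids must be non-empty")
    nG <- length(gai3Conc)
    kd <- rep_len(kd, nG); hillN <- rep_len(hillN, nG)
    amplitude <- rep_len(amplitude, nG)
    if (any(kd <= 0) || any(hillN <= 0))
        stop("'kd' and 'hillN' must be positive")
    if (any(amplitude <= 0) || any(amplitude > 1))
        stop("'amplitude' must lie in (0, 1]")
    if (replicates < 1L) stop("'replicates' must be >= 1")
    if (!is.null(seed)) set.seed(seed)

    g <- expand.grid(replicate = seq_len(replicates), pip2_uM = pip2Conc,
                     gai3_uM = gai3Conc, KEEP.OUT.ATTRS = FALSE)
    j <- match(g$gai3_uM, gai3Conc)
    mu <- amplitude[j] * g$pip2_uM^hillN[j] /
          (kd[j]^hillN[j] + g$pip2_uM^hillN[j])
    po <- mu + if (noiseSd > 0) stats::rnorm(nrow(g), 0, noiseSd) else 0
    g$po_norm <- pmin(1, pmax(0, po))
    poSurface(g[, c("pip2_uM", "gai3_uM", "replicate", "po_norm")],
              truth = list(kd = kd, hillN = hillN, amplitude = amplitude,
                           gai3Conc = gai3Conc, noiseSd = noiseSd))
}

## ---------------------------------------------------------------------------

#' Simulate a three-cube FRET intensity set
#'
#' Inverts the three-cube measurement model: given an intrinsic FRET
#' efficiency `E`, a bound fraction `Ab` and the bleed-through constants,
#' it emits intensities for donor-only (D), acceptor-only (A) and
#' double-labelled (DA) specimens such that running the bleed-constant,
#' FRET-ratio and effective-efficiency calculations on the noiseless
#' output recovers the constants and \eqn{E_{EFF} = E \cdot A_b} exactly.
#'
#' The DA donor signal is quenched by the transferred fraction
#' (\eqn{S_{CFP}(DA) = d (1 - E A_b)}); the DA acceptor channels combine
#' donor bleed-through with direct acceptor excitation, and the FRET-cube
#' signal carries the sensitized emission
#' \eqn{R_{A1} a \cdot FR} with \eqn{FR = 1 + E A_b / \epsilon}.
#'
#' @param efficiency intrinsic FRET efficiency E in `[0, 1]`.
#' @param boundFraction fraction A_b of acceptor-tagged molecules bound to
#'   donor-tagged ones, in `[0, 1]`.
#' @param rd1,rd2,ra1 ground-truth bleed constants (positive); defaults are
#'   typical CFP/YFP filter-set values.
#' @param extinctionRatio ratio of YFP to CFP molar extinction at the FRET
#'   cube's excitation (default 0.079 for an ECFP/EYFP pair).
#' @param donorBrightness,acceptorBrightness direct-excitation intensities
#'   of the two fluorophores (arbitrary units).
#' @param noiseSd multiplicative noise SD (fraction of each intensity).
#' @param seed integer seed.
#' @return A [ThreeCubeSet-class] with all nine entries populated.
#' @examples
#' s <- simulateThreeCube(0.5, 1)
#' k <- bleedConstants(s)
#' effectiveEfficiency(fretRatio(s, k))   # 0.5
#' @export
simulateThreeCube <- function(efficiency, boundFraction = 1,
                              rd1 = 0.32, rd2 = 0.06, ra1 = 0.11,
                              extinctionRatio = 0.079,
                              donorBrightness = 1000,
                              acceptorBrightness = 1000,
                              noiseSd = 0, seed = NULL) {
    if (efficiency < 0 || efficiency > 1)
        stop("'efficiency' must lie in [0, 1]")
    if (boundFraction < 0 || boundFraction > 1)
        stop("'boundFraction' must lie in [0, 1]")
    if (any(c(rd1, rd2, ra1, extinctionRatio) <= 0))
        stop("bleed constants and extinction ratio must be positive")
    if (!is.null(seed)) set.seed(seed)

    d <- donorBrightness; a <- acceptorBrightness
    eEff <- efficiency * boundFraction
    fr <- 1 + eEff / extinctionRatio
    dDA <- d * (1 - eEff)
    m <- matrix(c(
        ## D           A          DA
        d,             0,         dDA,                 # CFP cube
        rd2 * d,       a,         rd2 * dDA + a,       # YFP cube
        rd1 * d,       ra1 * a,   rd1 * dDA + ra1 * a * fr   # FRET cube
    ), nrow = 3L, byrow = TRUE, dimnames = list(.CUBES, .SPECIMENS))
    if (noiseSd > 0)
        m <- pmax(0, m * (1 + stats::rnorm(length(m), 0, noiseSd)))
    new("ThreeCubeSet", intensities = m)
}

## ---------------------------------------------------------------------------

#' Rotation matrix from an axis and angle
#'
#' Rodrigues' formula for the proper rotation of `angle` degrees about
#' `axis` (normalized internally).
#'
#' @param angle rotation angle in degrees.
#' @param axis length-3 axis vector (need not be unit length).
#' @return 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(angle, axis = c(0, 0, 1)) {
    stopifnot(length(axis) == 3L, sum(axis^2) > 0)
    a <- axis / sqrt(sum(axis^2))
    th <- angle * pi / 180
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## random pseudo-atom cloud used by the structure fixtures
.randomCloud <- function(n, spread = 20, chain = "A", element = "C") {
    xyz <- matrix(stats::runif(3L * n, -spread, spread), ncol = 3L)
    structureModel(data.frame(
        chain = chain, resno = seq_len(n), resid = "GLY", insert = "",
        elety = "CA", element = element,
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]))
}

#' Structure fixture: a point set and its copy under a known rigid motion
#'
#' Generates a random pseudo-atom cloud and a copy transformed by the
#' rotation `angle` about `axis` plus `translation`, with optional
#' coordinate noise.  The returned true transform lets superposition and
#' domain-rotation analyses be scored exactly.
#'
#' @param nAtoms number of pseudo-atoms (>= 3).
#' @param angle rotation angle (degrees).
#' @param axis rotation axis (length 3).
#' @param translation translation vector (Angstrom).
#' @param noiseSd per-coordinate Gaussian noise SD on the copy (Angstrom).
#' @param spread half-width of the uniform cube the cloud is drawn from.
#' @param seed integer seed.
#' @return List with `reference` and `mobile` ([StructureModel-class]) and
#'   the true `rotation` and `translation` mapping reference onto mobile.
#' @export
syntheticRotatedCopy <- function(nAtoms = 100, angle = 0, axis = c(0, 0, 1),
                                 translation = c(0, 0, 0), noiseSd = 0,
                                 spread = 20, seed = NULL) {
    if (nAtoms < 3L) stop("need at least 3 atoms for a non-degenerate fixture")
    if (!is.null(seed)) set.seed(seed)
    ref <- .randomCloud(nAtoms, spread)
    if (stats::sd(atomCoords(ref)[, 1]) == 0)
        stop("degenerate (coincident) point set")
    R <- rotationMatrix(angle, axis)
    xyz <- atomCoords(ref) %*% t(R) +
           matrix(translation, nAtoms, 3L, byrow = TRUE)
    if (noiseSd > 0) xyz <- xyz + stats::rnorm(3L * nAtoms, 0, noiseSd)
    mob <- ref
    mob@atoms$x <- xyz[, 1L]; mob@atoms$y <- xyz[, 2L]; mob@atoms$z <- xyz[, 3L]
    list(reference = ref, mobile = mob,
         rotation = R, translation = as.numeric(translation))
}

#' Structure fixture: a two-body complex at controlled separation
#'
#' Two compact pseudo-atom clusters (chains A and B) whose centers sit a
#' known distance apart along the x axis, for interface-area analyses with
#' known contact geometry: separating the bodies beyond
#' `2 * (clusterRadius + maxAtomRadius + 2 * probe)` guarantees zero
#' buried area.
#'
#' @param separation center-to-center distance (Angstrom).
#' @param nAtomsPerBody atoms per cluster.
#' @param clusterRadius radius of the ball each cluster is drawn in.
#' @param seed integer seed.
#' @return A [StructureModel-class] with chains `A` and `B`.
#' @export
syntheticTwoBodyComplex <- function(separation, nAtomsPerBody = 30,
                                    clusterRadius = 5, seed = NULL) {
    if (separation < 0) stop("'separation' must be non-negative")
    if (!is.null(seed)) set.seed(seed)
    ball <- function(n, r) {
        m <- matrix(stats::rnorm(3L * n), ncol = 3L)
        m <- m / sqrt(rowSums(m^2)) * r * stats::runif(n)^(1 / 3)
        m
    }
    a <- ball(nAtomsPerBody, clusterRadius)
    b <- ball(nAtomsPerBody, clusterRadius)
    b[, 1L] <- b[, 1L] + separation
    structureModel(data.frame(
        chain = rep(c("A", "B"), each = nAtomsPerBody),
        resno = c(seq_len(nAtomsPerBody), seq_len(nAtomsPerBody)),
        resid = "GLY", insert = "", elety = "CA", element = "C",
        x = c(a[, 1L], b[, 1L]), y = c(a[, 2L], b[, 2L]),
        z = c(a[, 3L], b[, 3L])))
}
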