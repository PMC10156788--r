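## Three-cube FRET: bleed-through constants, FRET ratio, effective
## efficiency, the intensity acceptance gate, and FRET-distance conversion.
## All intensities are assumed background-corrected; an optional per-cube
## background can be subtracted on entry.

.need <- function(set, cube, specimen) {
    v <- intensity(set, cube, specimen)
    if (is.na(v))
        stop("required intensity S_", cube, "(", specimen, ") is missing")
    v
}

#' Subtract a per-cube background from a three-cube set
#'
#' @param set a [ThreeCubeSet-class].
#' @param background named numeric vector of per-cube backgrounds
#'   (names among `CFP`, `YFP`, `FRET`), subtracted from every specimen;
#'   results are floored at 0.
#' @return A background-corrected [ThreeCubeSet-class].
#' @export
subtractBackground <- function(set, background) {
    stopifnot(is(set, "ThreeCubeSet"))
    m <- set@intensities
    for (cube in intersect(names(background), .CUBES))
        m[cube, ] <- pmax(0, m[cube, ] - background[[cube]])
    new("ThreeCubeSet", intensities = m)
}

#' Bleed-through constants from single-fluorophore controls
#'
#' Computes \eqn{R_{D1} = S_{FRET}(D)/S_{CFP}(D)},
#' \eqn{R_{D2} = S_{YFP}(D)/S_{CFP}(D)} from donor-only cells and
#' \eqn{R_{A1} = S_{FRET}(A)/S_{YFP}(A)} from acceptor-only cells.  When
#' several control cells are supplied the per-cell ratios are averaged and
#' their dispersion reported.
#'
#' @param donorOnly a [ThreeCubeSet-class] (or list of them) providing the
#'   D-specimen entries; defaults to `acceptorOnly` so one fully populated
#'   set can serve as both controls.
#' @param acceptorOnly a [ThreeCubeSet-class] (or list) providing the
#'   A-specimen entries; defaults to `donorOnly`.
#' @return A [BleedConstants-class].
#' @examples
#' s <- threeCubeSet(c(CFP.D = 100, YFP.D = 6, FRET.D = 30,
#'                     YFP.A = 200, FRET.A = 22))
#' bleedConstants(s)   # R_D1 = 0.3, R_D2 = 0.06, R_A1 = 0.11
#' @export
bleedConstants <- function(donorOnly, acceptorOnly = donorOnly) {
    dsets <- if (is(donorOnly, "ThreeCubeSet")) list(donorOnly) else donorOnly
    asets <- if (is(acceptorOnly, "ThreeCubeSet")) list(acceptorOnly) else acceptorOnly
    ratio <- function(set, cubeNum, cubeDen, specimen) {
        den <- .need(set, cubeDen, specimen)
        if (den == 0)
            stop("zero denominator: S_", cubeDen, "(", specimen, ") = 0")
        .need(set, cubeNum, specimen) / den
    }
    rd1s <- vapply(dsets, ratio, numeric(1), "FRET", "CFP", "D")
    rd2s <- vapply(dsets, ratio, numeric(1), "YFP",  "CFP", "D")
    ra1s <- vapply(asets, ratio, numeric(1), "FRET", "YFP", "A")
    disp <- c(rd1 = if (length(rd1s) > 1L) stats::sd(rd1s) else NA_real_,
              rd2 = if (length(rd2s) > 1L) stats::sd(rd2s) else NA_real_,
              ra1 = if (length(ra1s) > 1L) stats::sd(ra1s) else NA_real_)
    new("BleedConstants", rd1 = mean(rd1s), rd2 = mean(rd2s),
        ra1 = mean(ra1s), dispersion = disp)
}

#' FRET ratio from a double-labelled specimen
#'
#' The fractional increase in acceptor emission due to FRET:
#' \deqn{FR = \frac{F_{AD}}{F_A} =
#'   \frac{S_{FRET}(DA) - R_{D1} S_{CFP}(DA)}
#'        {R_{A1}\,[S_{YFP}(DA) - R_{D2} S_{CFP}(DA)]}}
#' A non-positive denominator means the specimen has no measurable direct
#' acceptor signal and is an error.
#'
#' @param da a [ThreeCubeSet-class] with the DA-specimen entries present.
#' @param k a [BleedConstants-class].
#' @return The FRET ratio (dimensionless; 1 in the absence of FRET).
#' @export
fretRatio <- function(da, k) {
    stopifnot(is(da, "ThreeCubeSet"), is(k, "BleedConstants"))
    sFret <- .need(da, "FRET", "DA")
    sCfp  <- .need(da, "CFP",  "DA")
    sYfp  <- .need(da, "YFP",  "DA")
    den <- k@ra1 * (sYfp - k@rd2 * sCfp)
    if (den <= 0)
        stop("non-positive denominator: direct acceptor signal ",
             "S_YFP(DA) - R_D2 * S_CFP(DA) must be positive")
    (sFret - k@rd1 * sCfp) / den
}

#' Effective FRET efficiency from the FRET ratio
#'
#' \eqn{E_{EFF} = E \cdot A_b = (FR - 1) \cdot
#' [\epsilon_{YFP}(440)/\epsilon_{CFP}(440)]}: the product of the
#' intrinsic efficiency and the bound fraction of the acceptor-tagged
#' (limiting) moiety.  The default extinction-coefficient ratio of 0.079
#' is appropriate for an ECFP/EYFP pair excited through a 440-nm-band
#' FRET cube.  A negative result (FR < 1) is passed through with a
#' warning, since it indicates a measurement inconsistency rather than an
#' invalid input.
#'
#' @param fr FRET ratio.
#' @param extinctionRatio YFP/CFP molar extinction ratio at the FRET-cube
#'   excitation (positive).
#' @return Effective FRET efficiency (fraction).
#' @examples
#' effectiveEfficiency(2)   # 0.079
#' @export
effectiveEfficiency <- function(fr, extinctionRatio = 0.079) {
    if (extinctionRatio <= 0) stop("'extinctionRatio' must be positive")
    e <- (fr - 1) * extinctionRatio
    if (any(e < 0))
        warning("FR < 1 gives a negative effective efficiency")
    e
}

#' Fluorophore intensity acceptance gate
#'
#' A cell enters the FRET cohort only when its donor and acceptor
#' expression levels are comparable: strictly
#' \eqn{0.5 < I_{CFP}/I_{YFP} < 2.0}.  Values exactly on a bound are
#' rejected.
#'
#' @param iCfp,iYfp fluorophore intensities (positive).
#' @param bounds the open interval for the ratio (default `c(0.5, 2)`).
#' @return Logical: accept the cell.
#' @export
intensityGate <- function(iCfp, iYfp, bounds = c(0.5, 2)) {
    if (any(iCfp <= 0) || any(iYfp <= 0))
        stop("intensities must be positive")
    r <- iCfp / iYfp
    r > bounds[1] & r < bounds[2]
}

#' Fluorophore separation from FRET efficiency
#'
#' Inverts the Foerster relation: \eqn{r = R_0 (1/E - 1)^{1/6}}.  The
#' Foerster radius must be supplied by the user (it depends on the
#' fluorophore pair, orientation factor and medium; about 49-50 A is
#' typical for ECFP/EYFP).
#'
#' @param efficiency intrinsic FRET efficiency in `(0, 1]`.
#' @param r0 Foerster radius (Angstrom), positive.
#' @return Separation in Angstrom (0 when `efficiency` is 1).
#' @examples
#' fretDistance(0.5, 50)   # = R0
#' @export
fretDistance <- function(efficiency, r0) {
    if (any(efficiency <= 0) || any(efficiency > 1))
        stop("'efficiency' must lie in (0, 1]")
    if (r0 <= 0) stop("'r0' must be positive")
    r0 * (1 / efficiency - 1)^(1 / 6)
}

#' Full three-cube FRET analysis of one cell
#'
#' Convenience wrapper: checks the intensity gate on the DA specimen
#' (CFP- vs YFP-cube intensities), computes the FRET ratio with the given
#' or internally derived bleed constants, and converts to effective
#' efficiency.
#'
#' @param set a [ThreeCubeSet-class] with the DA entries (and, if `k` is
#'   not supplied, the single-fluorophore entries too).
#' @param k optional [BleedConstants-class]; derived from `set` when
#'   omitted.
#' @param extinctionRatio see [effectiveEfficiency()].
#' @return List with `fr`, `eEff`, `gated` (did the cell pass the gate)
#'   and `constants`.
#' @export
fretAnalysis <- function(set, k = NULL, extinctionRatio = 0.079) {
    if (is.null(k)) k <- bleedConstants(set)
    fr <- fretRatio(set, k)
    list(fr = fr,
         eEff = effectiveEfficiency(fr, extinctionRatio),
         gated = intensityGate(.need(set, "CFP", "DA"),
                               .need(set, "YFP", "DA")),
         constants = k)
}
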