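## Hill fitting of dose-response data, the two-ligand normalized-Po
## surface, and the amplification-ratio analysis.

#' Normalize open probabilities to the maximum-condition response
#'
#' Divides each open probability by the open probability measured in the
#' same patch under the maximal-stimulation condition (the condition used
#' to elicit the patch's maximum response), yielding normalized values
#' comparable across patches.  Values exceeding 1 (possible with noise)
#' are reported in the `"clipped"` attribute and clipped.
#'
#' @param po numeric vector of open probabilities.
#' @param maxPo the same-patch maximum-condition open probability
#'   (positive).
#' @return Normalized values in `[0, 1]` with attribute `"clipped"` (count
#'   of values that exceeded 1 before clipping).
#' @export
normalizePo <- function(po, maxPo) {
    if (!is.numeric(maxPo) || length(maxPo) != 1L || maxPo <= 0)
        stop("'maxPo' must be a single positive number")
    v <- po / maxPo
    nClip <- sum(v > 1)
    out <- pmin(v, 1)
    attr(out, "clipped") <- nClip
    out
}

#' Evaluate a Hill curve
#'
#' @param fit a [HillFit-class] (or anything with `hillKd`, `hillN`,
#'   `hillAmplitude` accessors).
#' @param x doses at which to evaluate.
#' @return `amplitude * x^n / (kd^n + x^n)`.
#' @export
predictHill <- function(fit, x) {
    hillAmplitude(fit) * x^hillN(fit) / (hillKd(fit)^hillN(fit) + x^hillN(fit))
}

#' Fit the Hill equation to dose-response data
#'
#' Nonlinear least squares of
#' \eqn{P(x) = A \, x^n / (K_d^n + x^n)} by the Levenberg-Marquardt
#' algorithm with box constraints, initialized at the geometric mean of
#' the doses (\eqn{K_d}), \eqn{n = 1} and the maximum response
#' (\eqn{A}) - a robust starting point for log-spaced doses.  Residuals
#' are taken on the linear response scale.  The fit is flagged (not
#' errored) when the responses are constant (non-identifiable), the
#' optimizer fails, or the fitted \eqn{K_d} lies more than 100-fold
#' outside the dosed range.
#'
#' @param conc dose vector (uM), positive.
#' @param response response vector (fraction), parallel to `conc`;
#'   replicates are supplied as repeated doses.
#' @param fixN optional fixed Hill coefficient; when given, only
#'   \eqn{K_d} and \eqn{A} are estimated.
#' @param fixAmplitude optional fixed amplitude.
#' @param weights optional per-observation weights for weighted least
#'   squares.
#' @return A [HillFit-class].
#' @examples
#' x <- c(0.1, 0.3, 1, 3, 10)
#' y <- x^2.3 / (0.91^2.3 + x^2.3)
#' fitHill(x, y)   # recovers K_d = 0.91, n = 2.3
#' @export
fitHill <- function(conc, response, fixN = NULL, fixAmplitude = NULL,
                    weights = NULL) {
    stopifnot(length(conc) == length(response))
    if (any(conc <= 0)) stop("doses must be positive")
    nDistinct <- length(unique(conc))
    minDoses <- if (is.null(fixN)) 3L else 2L
    if (nDistinct < minDoses)
        stop("need at least ", minDoses, " distinct doses")

    blank <- c(kd = NA_real_, n = NA_real_, amplitude = NA_real_)
    if (stats::sd(response) == 0)
        return(new("HillFit", kd = NA_real_, n = if (is.null(fixN)) NA_real_ else fixN,
                   amplitude = response[1L], se = blank,
                   converged = FALSE, flagged = TRUE,
                   flagReason = "constant responses: K_d and n not identifiable"))

    start <- list(kd = exp(mean(log(conc))))
    lower <- c(kd = min(conc) * 1e-6)
    upper <- c(kd = max(conc) * 1e6)
    if (is.null(fixN)) {
        start$n <- 1; lower <- c(lower, n = 0.05); upper <- c(upper, n = 20)
    }
    if (is.null(fixAmplitude)) {
        start$amplitude <- max(response)
        lower <- c(lower, amplitude = 1e-6)
        upper <- c(upper, amplitude = 10)
    }
    form <- response ~ amplitude * conc^n / (kd^n + conc^n)
    dat <- data.frame(conc = conc, response = response)
    if (!is.null(fixN)) dat$n <- fixN
    if (!is.null(fixAmplitude)) dat$amplitude <- fixAmplitude

    args <- list(form, data = dat, start = start, lower = lower,
                 upper = upper,
                 control = minpack.lm::nls.lm.control(
                     maxiter = 200, ftol = 1e-14, ptol = 1e-14))
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
    if (inherits(fit, "error"))
        return(new("HillFit", kd = NA_real_,
                   n = if (is.null(fixN)) NA_real_ else fixN,
                   amplitude = if (is.null(fixAmplitude)) NA_real_ else fixAmplitude,
                   se = blank, converged = FALSE, flagged = TRUE,
                   flagReason = paste("optimizer failed:", conditionMessage(fit))))

    cf <- stats::coef(fit)
    se <- blank
    sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (!is.null(sm)) se[rownames(sm)] <- sm[, "Std. Error"]
    kd <- unname(cf[["kd"]])
    nHat <- if (is.null(fixN)) unname(cf[["n"]]) else fixN
    amp <- if (is.null(fixAmplitude)) unname(cf[["amplitude"]]) else fixAmplitude
    flagged <- FALSE; reason <- ""
    if (kd > max(conc) * 100 || kd < min(conc) / 100) {
        flagged <- TRUE
        reason <- "fitted K_d more than 100-fold outside the dosed range"
    }
    new("HillFit", kd = kd, n = nHat, amplitude = amp, se = se,
        converged = TRUE, flagged = flagged, flagReason = reason)
}

#' Fit a two-ligand open-probability surface column by column
#'
#' Performs an independent Hill fit of normalized open probability versus
#' [PIP2] for each Galpha(i3) concentration and tabulates the apparent
#' \eqn{K_d^{PIP2}} trend across Galpha(i3), together with a monotonicity
#' report: a falling trend means Galpha(i3) increases the channel's PIP2
#' sensitivity.  Columns whose fit fails are flagged and excluded from the
#' trend.
#'
#' @param surface a [PoSurface-class].
#' @param fixN optional Hill coefficient shared by all columns.
#' @param fixAmplitude optional fixed amplitude.
#' @return List with `fits` (named list of [HillFit-class], one per
#'   Galpha(i3) concentration), `trend` (data.frame `gai3_uM`, `kd_pip2`,
#'   `kd_se`, `n`, `amplitude`, `flagged`) and `monotone` (`TRUE` when
#'   \eqn{K_d^{PIP2}} is non-increasing in Galpha(i3) over the unflagged
#'   columns).
#' @export
fitSurface <- function(surface, fixN = NULL, fixAmplitude = NULL) {
    stopifnot(is(surface, "PoSurface"))
    d <- surfaceData(surface)
    gai3 <- sort(unique(d$gai3_uM))
    fits <- vector("list", length(gai3))
    names(fits) <- as.character(gai3)
    for (i in seq_along(gai3)) {
        sub <- d[d$gai3_uM == gai3[i], ]
        if (length(unique(sub$pip2_uM)) < 3L)
            stop("need >= 3 PIP2 doses per Galpha(i3) concentration")
        fits[[i]] <- fitHill(sub$pip2_uM, sub$po_norm,
                             fixN = fixN, fixAmplitude = fixAmplitude)
    }
    trend <- data.frame(
        gai3_uM  = gai3,
        kd_pip2  = vapply(fits, hillKd, numeric(1)),
        kd_se    = vapply(fits, function(f) hillSe(f)[["kd"]], numeric(1)),
        n        = vapply(fits, hillN, numeric(1)),
        amplitude = vapply(fits, hillAmplitude, numeric(1)),
        flagged  = vapply(fits, isFlagged, logical(1)))
    ok <- !trend$flagged & is.finite(trend$kd_pip2)
    monotone <- if (sum(ok) >= 2L) all(diff(trend$kd_pip2[ok]) <= 0) else NA
    list(fits = fits, trend = trend, monotone = monotone)
}

#' Amplification-ratio curve between two Hill fits
#'
#' The fold increase in open probability contributed by the activator:
#' the fitted dose-response curve at the highest activator concentration
#' divided by the curve at the lowest, evaluated at the requested doses.
#' Points where the denominator falls below `floorFrac` of the global
#' maximum response are masked (`NA` ratio) to avoid the numerical
#' singularity as the denominator tends to zero at low dose.
#'
#' For two fits sharing `n` and amplitude the ratio is
#' \eqn{(K_{lo}^n + x^n)/(K_{hi}^n + x^n)}: monotone non-increasing with
#' limit 1 at high dose and \eqn{(K_{lo}/K_{hi})^n} at low dose.
#'
#' @param fitLo [HillFit-class] at the lowest activator concentration.
#' @param fitHi [HillFit-class] at the highest activator concentration.
#' @param evalPoints doses (uM) at which to evaluate the ratio; the
#'   canonical choices for a PIP2 titration are 5, 16 and 50 uM.
#' @param floorFrac denominator floor as a fraction of the global maximum
#'   response (default 0.01).
#' @return data.frame with columns `dose`, `lo`, `hi`, `ratio`, `masked`.
#'   Errors if every point is masked.
#' @export
amplificationCurve <- function(fitLo, fitHi, evalPoints = c(5, 16, 50),
                               floorFrac = 0.01) {
    stopifnot(is(fitLo, "HillFit"), is(fitHi, "HillFit"))
    if (any(evalPoints <= 0)) stop("'evalPoints' must be positive doses")
    if (isFlagged(fitLo) || isFlagged(fitHi))
        stop("both fits must be valid (unflagged)")
    lo <- predictHill(fitLo, evalPoints)
    hi <- predictHill(fitHi, evalPoints)
    floorVal <- floorFrac * max(hillAmplitude(fitLo), hillAmplitude(fitHi))
    masked <- lo < floorVal
    ratio <- ifelse(masked, NA_real_, hi / lo)
    if (all(masked))
        stop("denominator below the floor at every evaluation point")
    data.frame(dose = evalPoints, lo = lo, hi = hi,
               ratio = ratio, masked = masked)
}
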