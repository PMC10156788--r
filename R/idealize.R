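## Single-channel idealization by the half-amplitude (50%) rule with a
## filter-derived dead time, and the derived quantities: open probability,
## windowed stationarity check, membrane potential and unitary i-V slope
## conductances.

#' Dead time of a low-pass filtered recording
#'
#' The shortest transition resolvable after low-pass filtering,
#' \eqn{\tau_{dead} = 1/(2\pi f_c)}.  Candidate events briefer than this
#' are ignored during idealization.  For the usual 1 kHz cut-off this is
#' 0.159 ms (~0.16 ms).
#'
#' @param fc low-pass cut-off frequency (Hz), positive.
#' @return Dead time in seconds.
#' @examples
#' deadTime(1000) * 1000   # ms
#' @export
deadTime <- function(fc) {
    if (!is.numeric(fc) || length(fc) != 1L || !is.finite(fc) || fc <= 0)
        stop("'fc' must be a single positive frequency in Hz")
    1 / (2 * pi * fc)
}

#' Assign closed and open current levels from an all-point histogram
#'
#' Builds an all-point amplitude density of the trace, locates its modes,
#' and returns the two dominant ones as the closed and open levels.  The
#' closed level is the mode at the trace's modal baseline (the tallest
#' peak, since a single channel spends the plurality of samples at one
#' level in typical records); the open level is the next-tallest mode.  If
#' the histogram is unimodal (no resolvable open events) the open level is
#' returned as `NA` and downstream idealization yields a single all-closed
#' dwell.
#'
#' Levels may always be supplied manually to [idealizeTrace()], mirroring
#' the practice of verifying level assignment by eye.
#'
#' @param trace a [RawTrace-class].
#' @param nGrid number of density grid points.
#' @return Named numeric vector `c(closed = ..., open = ...)`; `open` is
#'   `NA` for a unimodal histogram.
#' @export
assignLevels <- function(trace, nGrid = 512L) {
    stopifnot(is(trace, "RawTrace"))
    x <- trace@current
    if (length(unique(x)) == 1L)
        return(c(closed = x[1L], open = NA_real_))
    d <- stats::density(x, n = nGrid)
    y <- d$y
    ## interior local maxima
    peak <- which(y[-c(1L, length(y))] > y[-c(length(y) - 1L, length(y))] &
                  y[-c(1L, length(y))] >= y[-c(1L, 2L)]) + 1L
    if (length(peak) == 0L)
        peak <- which.max(y)
    ## discard bumps under 1% of the main peak: histogram noise, not a level
    peak <- peak[y[peak] >= 0.01 * max(y[peak])]
    peak <- peak[order(y[peak], decreasing = TRUE)]
    if (length(peak) < 2L)
        return(c(closed = d$x[peak[1L]], open = NA_real_))
    c(closed = d$x[peak[1L]], open = d$x[peak[2L]])
}

## merge runs shorter than minLen samples into their surroundings, always
## removing the currently shortest sub-dead-time run first
.mergeShortRuns <- function(lengths, values, minLen) {
    repeat {
        k <- length(lengths)
        if (k <= 1L) break
        short <- which(lengths < minLen)
        if (length(short) == 0L) break
        j <- short[which.min(lengths[short])]
        if (j == 1L) {
            lengths[2L] <- lengths[2L] + lengths[1L]
            lengths <- lengths[-1L]; values <- values[-1L]
        } else if (j == k) {
            lengths[k - 1L] <- lengths[k - 1L] + lengths[k]
            lengths <- lengths[-k]; values <- values[-k]
        } else {
            lengths[j - 1L] <- lengths[j - 1L] + lengths[j] + lengths[j + 1L]
            lengths <- lengths[-c(j, j + 1L)]
            values <- values[-c(j, j + 1L)]
        }
    }
    list(lengths = lengths, values = values)
}

#' Idealize a trace by the 50% rule
#'
#' Thresholds the trace at the midpoint of the closed and open levels; the
#' channel is scored open whenever the signal is on the open side of the
#' threshold.  Samples falling exactly on the threshold keep the preceding
#' state.  Candidate events shorter than the dead time are merged into the
#' surrounding dwell (shortest first), implementing the rule that signal
#' changes briefer than \eqn{1/(2\pi f_c)} are ignored.  The transition
#' count before and after dead-time merging is attached as attribute
#' `"transitionReport"` so that automated records replace eyeball
#' verification.
#'
#' @param trace a [RawTrace-class].
#' @param levels named numeric vector `c(closed=, open=)`; defaults to
#'   [assignLevels()] on the trace.  An `NA` open level yields one
#'   all-closed dwell.
#' @param dead dead time in seconds; defaults to
#'   `deadTime(filterCutoff(trace))`.
#' @return A [DwellSequence-class].  `recordDuration()` of the result
#'   equals the trace duration exactly.
#' @examples
#' tr <- rawTrace(rep(c(0, -2, 0), c(40, 50, 40)), 1e4, 1e3)
#' idealizeTrace(tr, levels = c(closed = 0, open = -2))
#' @export
idealizeTrace <- function(trace, levels = assignLevels(trace),
                          dead = deadTime(filterCutoff(trace))) {
    stopifnot(is(trace, "RawTrace"), dead >= 0)
    if (!all(c("closed", "open") %in% names(levels)))
        stop("'levels' must be a named vector with elements 'closed' and 'open'")
    x  <- trace@current
    fs <- trace@samplingRate
    n  <- length(x)
    if (is.na(levels[["open"]]))
        return(dwellSequence("closed", n / fs))
    if (levels[["open"]] == levels[["closed"]])
        stop("open and closed levels must differ")
    thr <- (levels[["closed"]] + levels[["open"]]) / 2
    s   <- sign(levels[["open"]] - levels[["closed"]])
    v   <- s * (x - thr)
    st  <- integer(n)            # 1 = open, 0 = closed
    st[v > 0] <- 1L
    ties <- which(v == 0)
    if (length(ties)) {          # exact threshold: carry the previous state
        for (i in ties) st[i] <- if (i == 1L) 0L else st[i - 1L]
    }
    r <- rle(st)
    nTransRaw <- length(r$lengths) - 1L
    minLen <- dead * fs - sqrt(.Machine$double.eps)
    m <- .mergeShortRuns(r$lengths, r$values, minLen)
    dw <- dwellSequence(ifelse(m$values == 1L, "open", "closed"),
                        m$lengths / fs)
    attr(dw, "transitionReport") <- c(raw = nTransRaw,
                                      retained = length(m$lengths) - 1L,
                                      mergedOut = nTransRaw - (length(m$lengths) - 1L))
    dw
}

#' Open probability of a dwell sequence
#'
#' \eqn{P_o = \sum_i \tau_{o,i} / T_m}: the summed open dwell times over
#' the record duration.
#'
#' @param dwells a [DwellSequence-class].
#' @return Open probability in `[0, 1]`.
#' @examples
#' openProbability(dwellSequence(c("closed", "open"), c(3, 1)))  # 0.25
#' @export
openProbability <- function(dwells) {
    stopifnot(is(dwells, "DwellSequence"))
    Tm <- recordDuration(dwells)
    if (length(dwells@states) == 0L || Tm <= 0)
        stop("empty dwell sequence: T_m must be positive")
    openTime(dwells) / Tm
}

#' Windowed open-probability consistency check
#'
#' Splits the record into windows of the given length and reports, for
#' each, the ratio of the window's open probability to the whole-record
#' open probability and whether it falls in the 95-105% consistency band
#' used to confirm stationarity of a displayed segment.
#'
#' @param dwells a [DwellSequence-class].
#' @param window window length in seconds (default 30); must not exceed
#'   the record duration.
#' @param step spacing of window starts (default `window`:
#'   non-overlapping tiling).
#' @param band acceptance band for the ratio (default `c(0.95, 1.05)`).
#' @return data.frame with columns `start_s`, `end_s`, `window_po`,
#'   `ratio`, `pass`; the whole-record `P_o` is attached as attribute
#'   `"recordPo"`.
#' @export
windowConsistency <- function(dwells, window = 30, step = window,
                              band = c(0.95, 1.05)) {
    stopifnot(is(dwells, "DwellSequence"), window > 0, step > 0)
    Tm <- recordDuration(dwells)
    if (window > Tm + 1e-12)
        stop("'window' is longer than the record (", signif(Tm, 4), " s)")
    po <- openProbability(dwells)
    dur <- dwells@durations
    ends <- cumsum(dur)
    starts <- ends - dur
    isOpen <- dwells@states == "open"
    w0 <- seq(0, Tm - window, by = step)
    wpo <- vapply(w0, function(a) {
        ov <- pmax(0, pmin(ends, a + window) - pmax(starts, a))
        sum(ov[isOpen]) / window
    }, numeric(1))
    ratio <- wpo / po
    out <- data.frame(start_s = w0, end_s = w0 + window,
                      window_po = wpo, ratio = ratio,
                      pass = ratio > band[1] & ratio < band[2])
    attr(out, "recordPo") <- po
    out
}

#' Membrane potential of an excised inside-out patch
#'
#' \eqn{V_{mem} = V_{rev} - V_{cmd}}.  A liquid-junction potential below
#' 3 mV in magnitude is neglected; larger LJPs are subtracted
#' (\eqn{V_{mem} = V_{rev} - V_{cmd} - LJP}), with the LJP expressed as
#' bath minus pipette potential.
#'
#' @param vRev reversal potential (mV).
#' @param vCmd command potential applied by the amplifier (mV).
#' @param ljp liquid-junction potential (mV); default 0.
#' @param ljpThreshold magnitude below which the LJP is neglected
#'   (default 3 mV).
#' @return Membrane potential in mV.
#' @examples
#' membranePotential(0, -60)          # +60 mV
#' membranePotential(0, -60, ljp = 2) # unchanged: |LJP| < 3 mV
#' @export
membranePotential <- function(vRev, vCmd, ljp = 0, ljpThreshold = 3) {
    v <- vRev - vCmd
    ifelse(abs(ljp) < ljpThreshold, v, v - ljp)
}

#' Slope conductances from a unitary i-V relation
#'
#' Fits ordinary least-squares lines separately to the negative and
#' positive driving-force branches of a unitary current-voltage relation
#' (the curve is doubly rectifying, so a single line would not describe
#' it).  Points at zero driving force belong to neither branch, and points
#' whose unitary current is indistinguishable from baseline can be
#' excluded explicitly.
#'
#' @param vMem membrane potentials (mV).
#' @param current unitary currents (pA), parallel to `vMem`.
#' @param exclude optional logical or integer index of points to drop
#'   (e.g. potentials where the open level could not be resolved from the
#'   baseline).
#' @return List with elements `negative` and `positive`; each is either
#'   `NULL` (branch omitted, with a warning, when it has fewer than two
#'   points) or a list with `slope_pS`, `slopeSe_pS`, `intercept_pA` and
#'   `n`.
#' @examples
#' v <- c(-100, -60, -40, 40, 60, 100)
#' unitaryIV(v, 0.05 * v)   # both slopes 50 pS
#' @export
unitaryIV <- function(vMem, current, exclude = NULL) {
    stopifnot(length(vMem) == length(current))
    keep <- rep(TRUE, length(vMem))
    if (!is.null(exclude)) keep[exclude] <- FALSE
    vMem <- vMem[keep]; current <- current[keep]
    fitBranch <- function(sel, name) {
        if (sum(sel) < 2L) {
            warning("fewer than 2 points on the ", name,
                    " branch; branch omitted")
            return(NULL)
        }
        fit <- stats::lm(current[sel] ~ vMem[sel])
        ## summary.lm warns on exactly linear data; the fit itself is fine
        co <- suppressWarnings(summary(fit)$coefficients)
        list(slope_pS = unname(co[2L, 1L]) * 1000,          # pA/mV -> pS
             slopeSe_pS = unname(co[2L, 2L]) * 1000,
             intercept_pA = unname(co[1L, 1L]),
             n = sum(sel))
    }
    list(negative = fitBranch(vMem < 0, "negative"),
         positive = fitBranch(vMem > 0, "positive"))
}

## ---------------------------------------------------------------------------
## Plain-text I/O
## ---------------------------------------------------------------------------

#' Read and write traces and dwell tables as CSV
#'
#' Traces are exchanged as two-column CSV (`time_s`, `current_pA`) with a
#' header; dwell tables as three-column CSV (`state`, `start_s`,
#' `duration_s`).
#'
#' @param path file path.
#' @param filterCutoff acquisition low-pass cutoff (Hz) for the trace
#'   (metadata not stored in the CSV).
#' @param samplingRate optional sampling rate (Hz); inferred from the
#'   `time_s` column when omitted.
#' @return `readTraceCsv()` a [RawTrace-class]; `readDwellCsv()` a
#'   [DwellSequence-class]; the writers return the path invisibly.
#' @export
readTraceCsv <- function(path, filterCutoff, samplingRate = NULL) {
    d <- utils::read.csv(path)
    if (!all(c("time_s", "current_pA") %in% names(d)))
        stop("trace CSV must have columns 'time_s' and 'current_pA'")
    if (is.null(samplingRate)) {
        dt <- diff(d$time_s)
        if (length(dt) == 0L || any(dt <= 0))
            stop("cannot infer sampling rate from 'time_s'")
        samplingRate <- 1 / stats::median(dt)
    }
    rawTrace(d$current_pA, samplingRate, filterCutoff)
}

#' @rdname readTraceCsv
#' @param trace a [RawTrace-class] to write.
#' @export
writeTraceCsv <- function(trace, path) {
    utils::write.csv(
        data.frame(time_s = traceTime(trace), current_pA = traceCurrent(trace)),
        path, row.names = FALSE)
    invisible(path)
}

#' @rdname readTraceCsv
#' @param dwells a [DwellSequence-class] to write.
#' @export
writeDwellCsv <- function(dwells, path) {
    utils::write.csv(dwellEvents(dwells), path, row.names = FALSE)
    invisible(path)
}

#' @rdname readTraceCsv
#' @export
readDwellCsv <- function(path) {
    d <- utils::read.csv(path)
    dwellSequence(d$state, d$duration_s)
}

#' Summary of an idealized record
#'
#' Compact record of the idealization outcome, suitable for JSON
#' serialization: open probability, event counts, record duration and the
#' dead time used.
#'
#' @param dwells a [DwellSequence-class].
#' @param dead dead time used (s).
#' @return Named list with `P_o`, `n_o`, `n_c`, `T_m_s`, `dead_time_ms`.
#' @export
idealizationSummary <- function(dwells, dead) {
    list(P_o = openProbability(dwells),
         n_o = nOpen(dwells), n_c = nClosed(dwells),
         T_m_s = recordDuration(dwells),
         dead_time_ms = dead * 1000)
}
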