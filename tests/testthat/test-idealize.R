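test_that("dead time follows the filter closed form", {
    expect_equal(deadTime(1000) * 1000, 0.1591549, tolerance = 1e-6)
    expect_equal(deadTime(500) * 1000, 0.3183099, tolerance = 1e-6)
    expect_lt(deadTime(1e9), 1e-9)          # vanishes for a fast filter
    expect_error(deadTime(0), "positive")
    expect_error(deadTime(-100), "positive")
})

test_that("all-point histogram finds the two levels of a square wave", {
    x <- rep(c(0, -2), times = c(700, 300))
    lv <- assignLevels(rawTrace(x, 10000, 1000))
    expect_equal(lv[["closed"]], 0, tolerance = 0.2)
    expect_equal(lv[["open"]], -2, tolerance = 0.2)
    ## flat trace: no open level
    lv0 <- assignLevels(rawTrace(rep(1.5, 100), 10000, 1000))
    expect_identical(lv0[["open"]], NA_real_)
    expect_equal(lv0[["closed"]], 1.5)
})

test_that("levels recovered from a noisy simulated trace match the truth", {
    sim <- simulateGatingTrace(30, 30, duration = 10, noiseSd = 0.25,
                               seed = 3)
    lv <- assignLevels(sim$trace)
    expect_equal(lv[["closed"]], 0, tolerance = 0.25)
    expect_equal(lv[["open"]], -2, tolerance = 0.25)
})

test_that("a noiseless square pulse idealizes to one open event", {
    fs <- 10000
    x <- rep(c(0, -2, 0), times = c(100, 50, 100))   # 5 ms pulse
    dw <- idealizeTrace(rawTrace(x, fs, 1000),
                        levels = c(closed = 0, open = -2))
    expect_identical(dwellStates(dw), c("closed", "open", "closed"))
    expect_equal(dwellDurations(dw)[2], 50 / fs)
    expect_equal(recordDuration(dw), length(x) / fs)
})

test_that("sub-dead-time blips are merged into the surrounding dwell", {
    fs <- 10000
    ## 0.1 ms blip (1 sample) inside a closed stretch; dead time 0.16 ms
    x <- rep(0, 400); x[200] <- -2
    dw <- idealizeTrace(rawTrace(x, fs, 1000),
                        levels = c(closed = 0, open = -2),
                        dead = deadTime(1000))
    expect_identical(dwellStates(dw), "closed")
    expect_equal(recordDuration(dw), 400 / fs)
    rep_ <- attr(dw, "transitionReport")
    expect_identical(unname(rep_["mergedOut"]), 2L)
    ## the same blip survives with dead time 0
    dw0 <- idealizeTrace(rawTrace(x, fs, 1000),
                         levels = c(closed = 0, open = -2), dead = 0)
    expect_identical(dwellStates(dw0), c("closed", "open", "closed"))
})

test_that("samples exactly at threshold keep the previous state", {
    fs <- 10000
    x <- c(0, 0, -1, -2, -2, -1, 0)   # threshold is -1
    dw <- idealizeTrace(rawTrace(x, fs, 1000),
                        levels = c(closed = 0, open = -2), dead = 0)
    expect_identical(dwellStates(dw), c("closed", "open", "closed"))
    expect_equal(dwellDurations(dw) * fs, c(3, 3, 1))
})

test_that("idealization is invariant under a sign flip of the trace", {
    sim <- simulateGatingTrace(30, 40, duration = 5, seed = 9)
    dw1 <- idealizeTrace(sim$trace, levels = c(closed = 0, open = -2))
    tr2 <- rawTrace(-traceCurrent(sim$trace), samplingRate(sim$trace),
                    filterCutoff(sim$trace))
    dw2 <- idealizeTrace(tr2, levels = c(closed = 0, open = 2))
    expect_identical(dwellStates(dw1), dwellStates(dw2))
    expect_equal(dwellDurations(dw1), dwellDurations(dw2))
})

test_that("noiseless idealization reproduces the generator dwells", {
    sim <- simulateGatingTrace(20, 30, duration = 30, noiseSd = 0, seed = 5)
    dw <- idealizeTrace(sim$trace, levels = sim$levels)
    dead <- deadTime(1000)
    truthLong <- sum(dwellDurations(sim$dwells) >= dead)
    idealLong <- length(dwellStates(dw))
    ## every resolvable (>= dead time) true event should be recovered;
    ## sampling can merge rare sub-dead-time pairs, so allow 5% slack
    expect_gt(idealLong / truthLong, 0.95)
    expect_lt(idealLong / truthLong, 1.05)
    expect_equal(openProbability(dw), openProbability(sim$dwells),
                 tolerance = 0.01)
})

test_that("open probability is the open-time fraction", {
    dw <- dwellSequence(c("closed", "open", "closed", "open"),
                        c(2, 0.6, 1, 0.4))
    expect_equal(openProbability(dw), 0.25)
    expect_equal(openTime(dw) + closedTime(dw), recordDuration(dw))
    expect_equal(openProbability(dwellSequence("closed", 3)), 0)
    expect_error(openProbability(dwellSequence(character(0), numeric(0))),
                 "empty")
})

test_that("window consistency flags non-stationary records", {
    sim <- simulateGatingTrace(40, 40, duration = 120, noiseSd = 0, seed = 2)
    wc <- windowConsistency(sim$dwells, window = 30)
    expect_gt(mean(wc$pass), 0.5)           # stationary: most windows pass
    ## silent second half
    bad <- dwellSequence(c("closed", "open", "closed"), c(10, 20, 30))
    wcBad <- windowConsistency(bad, window = 30, step = 30)
    expect_false(all(wcBad$pass))
    ## window equal to the record: ratio exactly 1
    wc1 <- windowConsistency(bad, window = 60)
    expect_equal(wc1$ratio, 1)
    expect_error(windowConsistency(bad, window = 120), "longer")
})

test_that("membrane potential handles the LJP rule", {
    expect_equal(membranePotential(0, -60), 60)
    expect_equal(membranePotential(0, -60, ljp = 2),
                 membranePotential(0, -60))
    expect_equal(membranePotential(0, -60, ljp = 5), 55)
    expect_equal(membranePotential(-20, -20), 0)
})

test_that("unitary i-V slopes are fitted per branch", {
    v <- c(-100, -80, -60, -40, 40, 60, 80, 100)
    iv <- unitaryIV(v, 0.05 * v)
    expect_equal(iv$negative$slope_pS, 50, tolerance = 1e-9)
    expect_equal(iv$positive$slope_pS, 50, tolerance = 1e-9)
    ## noisy line: slope within 3 fitted standard errors
    set.seed(4)
    i2 <- 0.04 * v + rnorm(length(v), 0, 0.05)
    iv2 <- unitaryIV(v, i2)
    expect_lt(abs(iv2$negative$slope_pS - 40), 3 * iv2$negative$slopeSe_pS)
    ## baseline-indistinguishable points excluded from a branch
    v3 <- c(-100, -60, 0, 20, 60, 100)
    iv3 <- unitaryIV(v3, c(-5, -3, 0, 0, 2.4, 4), exclude = v3 %in% c(0, 20))
    expect_identical(iv3$positive$n, 2L)
    expect_warning(unitaryIV(c(-60, 40, 60), c(-3, 2, 3)), "negative branch")
})

test_that("trace and dwell CSV round trips preserve values", {
    sim <- simulateGatingTrace(20, 30, duration = 0.5, seed = 6)
    tf <- tempfile(fileext = ".csv")
    writeTraceCsv(sim$trace, tf)
    tr2 <- readTraceCsv(tf, filterCutoff = 1000)
    expect_equal(traceCurrent(tr2), traceCurrent(sim$trace), tolerance = 1e-9)
    expect_equal(samplingRate(tr2), 10000, tolerance = 1e-6)
    df <- tempfile(fileext = ".csv")
    writeDwellCsv(sim$dwells, df)
    dw2 <- readDwellCsv(df)
    expect_equal(dwellDurations(dw2), dwellDurations(sim$dwells),
                 tolerance = 1e-9)
    s <- idealizationSummary(sim$dwells, deadTime(1000))
    expect_named(s, c("P_o", "n_o", "n_c", "T_m_s", "dead_time_ms"))
    unlink(c(tf, df))
})
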