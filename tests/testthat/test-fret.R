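test_that("bleed constants are the single-fluorophore intensity ratios", {
    s <- threeCubeSet(c(CFP.D = 100, YFP.D = 6, FRET.D = 30,
                        YFP.A = 200, FRET.A = 22))
    k <- bleedConstants(s)
    expect_equal(rd1(k), 0.3)
    expect_equal(rd2(k), 0.06)
    expect_equal(ra1(k), 0.11)
    ## per-cell averaging with dispersion
    s2 <- threeCubeSet(c(CFP.D = 50, YFP.D = 4, FRET.D = 16,
                         YFP.A = 100, FRET.A = 12))
    k2 <- bleedConstants(list(s, s2), list(s, s2))
    expect_equal(rd1(k2), mean(c(0.3, 0.32)))
    expect_false(is.na(k2@dispersion[["rd1"]]))
    ## degenerate acceptor-only cell
    s0 <- threeCubeSet(c(YFP.A = 0, FRET.A = 5))
    expect_error(bleedConstants(s, s0), "zero denominator")
})

test_that("the noiseless three-cube round trip is exact", {
    for (E in c(0, 0.1, 0.5, 0.9, 1)) {
        for (Ab in c(0.3, 0.7, 1)) {
            for (eps in c(0.05, 0.079, 0.2)) {
                s <- simulateThreeCube(E, Ab, rd1 = 0.4, rd2 = 0.08,
                                       ra1 = 0.15, extinctionRatio = eps,
                                       donorBrightness = 812,
                                       acceptorBrightness = 1930)
                k <- bleedConstants(s)
                expect_equal(rd1(k), 0.4, tolerance = 1e-12)
                expect_equal(rd2(k), 0.08, tolerance = 1e-12)
                expect_equal(ra1(k), 0.15, tolerance = 1e-12)
                fr <- fretRatio(s, k)
                eEff <- suppressWarnings(effectiveEfficiency(fr, eps))
                expect_equal(eEff, E * Ab, tolerance = 1e-12)
            }
        }
    }
})

test_that("FR is 1 without FRET and matches a prescribed ratio", {
    s0 <- simulateThreeCube(0, 1)
    expect_equal(fretRatio(s0, bleedConstants(s0)), 1, tolerance = 1e-12)
    ## truth FR = 1.8  <=>  E_EFF = 0.8 * 0.079
    s <- simulateThreeCube(0.8 * 0.079, 1)
    expect_equal(fretRatio(s, bleedConstants(s)), 1.8, tolerance = 1e-12)
})

test_that("FR is invariant under global rescaling of the DA intensities", {
    s <- simulateThreeCube(0.4, 0.9)
    k <- bleedConstants(s)
    m <- s@intensities
    m[, "DA"] <- m[, "DA"] * 3.7
    s2 <- new("ThreeCubeSet", intensities = m)
    expect_equal(fretRatio(s2, k), fretRatio(s, k), tolerance = 1e-12)
})

test_that("degenerate DA specimens are caught", {
    k <- new("BleedConstants", rd1 = 0.3, rd2 = 0.06, ra1 = 0.11,
             dispersion = c(rd1 = NA_real_, rd2 = NA_real_, ra1 = NA_real_))
    ## null numerator: S_FRET(DA) = R_D1 * S_CFP(DA)
    sNull <- threeCubeSet(c(CFP.DA = 100, YFP.DA = 500, FRET.DA = 30))
    expect_equal(fretRatio(sNull, k), 0)
    ## acceptor-signal deficit
    sBad <- threeCubeSet(c(CFP.DA = 100, YFP.DA = 6, FRET.DA = 30))
    expect_error(fretRatio(sBad, k), "acceptor")
    sMiss <- threeCubeSet(c(CFP.DA = 100))
    expect_error(fretRatio(sMiss, k), "missing")
})

test_that("effective efficiency is affine in FR", {
    expect_equal(effectiveEfficiency(1), 0)
    expect_equal(effectiveEfficiency(2), 0.079)
    frs <- seq(1, 5, by = 0.5)
    es <- effectiveEfficiency(frs)
    expect_equal(diff(es) / diff(frs), rep(0.079, length(frs) - 1))
    expect_warning(effectiveEfficiency(0.8), "negative")
})

test_that("the intensity gate is strict at both bounds", {
    expect_true(intensityGate(100, 100))
    expect_false(intensityGate(40, 100))     # ratio 0.4
    expect_false(intensityGate(200, 100))    # exactly 2.0
    expect_false(intensityGate(50, 100))     # exactly 0.5
    expect_true(intensityGate(199.9, 100))
    expect_error(intensityGate(0, 100), "positive")
})

test_that("FRET distance inverts the Foerster relation", {
    expect_equal(fretDistance(0.5, 50), 50)
    expect_equal(fretDistance(1, 50), 0)
    expect_lt(fretDistance(1 - 1e-12, 50), 0.6)   # sixth-root approach to 0
    expect_equal(fretDistance(0.1, 50), 50 * 9^(1 / 6), tolerance = 1e-12)
    expect_error(fretDistance(0, 50), "efficiency")
    expect_error(fretDistance(1.2, 50), "efficiency")
    expect_error(fretDistance(0.5, -1), "positive")
})

test_that("the per-cell wrapper gates and reports consistently", {
    s <- simulateThreeCube(0.5, 1)
    out <- fretAnalysis(s)
    expect_equal(out$eEff, 0.5, tolerance = 1e-12)
    expect_type(out$gated, "logical")
    ## background subtraction restores a shifted specimen
    sShift <- new("ThreeCubeSet", intensities = s@intensities + 50)
    sBack <- subtractBackground(sShift, c(CFP = 50, YFP = 50, FRET = 50))
    expect_equal(sBack@intensities, s@intensities, tolerance = 1e-12)
})
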