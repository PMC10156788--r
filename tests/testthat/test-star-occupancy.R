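test_that("pattern classification matches the cyclic-gap oracle on all 16 tuples", {
    tuples <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
    labels <- apply(tuples, 1L, function(fl) as.character(classifyPattern(fl)))
    oracle <- apply(tuples, 1L, oraclePattern4)
    expect_identical(labels, oracle)
    ## class sizes from exhaustive enumeration
    expect_identical(as.integer(table(labels)[occupancyPatternLabels()]),
                     c(1L, 4L, 4L, 2L, 4L, 1L))
})

test_that("classification is rotation invariant and canonical", {
    base <- c(TRUE, TRUE, TRUE, FALSE)
    labs <- vapply(0:3, function(r)
        as.character(classifyPattern(base[((0:3 + r) %% 4) + 1])), character(1))
    expect_identical(labs, rep("3", 4))
    ## canonical tuples agree with the binary-value oracle for S = 5 and 6
    for (S in 5:6) {
        tuples <- expand.grid(rep(list(c(FALSE, TRUE)), S))
        for (i in seq_len(nrow(tuples))) {
            fl <- as.logical(tuples[i, ])
            expect_identical(attr(classifyPattern(fl), "canonical"),
                             oracleCanonical(fl))
        }
    }
    expect_error(classifyPattern(c(TRUE, FALSE), symOrder = 4), "length")
})

test_that("the particle generator honours counts, patterns and phases", {
    pt <- simulateParticleTable(10, c("4" = 1), seed = 1)
    d <- particleData(pt)
    expect_identical(nrow(d), 40L)
    expect_true(all(d$tqBoundTruth))
    expect_true(all(d$class_id %in% 1:2))
    ## trans particles have bound flags at opposite subunits after any shift
    ptT <- simulateParticleTable(50, c("2-trans" = 1), seed = 2)
    dT <- particleData(ptT)
    for (pid in unique(dT$particle_id)) {
        fl <- dT$tqBoundTruth[dT$particle_id == pid][
            order(dT$subunit_index[dT$particle_id == pid]) ]
        expect_identical(oraclePattern4(fl), "2-trans")
    }
    ## pose offsets are multiples of 90 degrees
    offs <- (dT$rlnAngleRot - rep(dT$rlnAngleRot[dT$subunit_index == 0L],
                                  each = 4L)) %% 360
    expect_true(all(abs(offs - round(offs / 90) * 90) < 1e-9))
    expect_error(simulateParticleTable(5, c("1" = 0.4, "3" = 0.4)), "sum to 1")
    expect_error(simulateParticleTable(5, c(a = 1)), "canonical")
})

test_that("STAR files round trip and report malformed input", {
    pt <- simulateParticleTable(30, c("1" = 0.4, "2-cis" = 0.3, "3" = 0.3),
                                seed = 4)
    f <- tempfile(fileext = ".star")
    writeStar(pt, f)
    pt2 <- readStar(f)
    d1 <- particleData(pt); d2 <- particleData(pt2)
    expect_identical(nrow(d2), nrow(d1))
    expect_identical(d2$particle_id, d1$particle_id)
    expect_identical(d2$subunit_index, d1$subunit_index)
    expect_identical(d2$class_id, d1$class_id)
    expect_equal(d2$rlnAngleRot, d1$rlnAngleRot, tolerance = 1e-10)
    ## write -> read -> write -> read is stable
    f2 <- tempfile(fileext = ".star")
    writeStar(pt2, f2)
    d3 <- particleData(readStar(f2))
    expect_equal(d3$rlnAngleRot, d2$rlnAngleRot, tolerance = 1e-12)
    ## malformed header and rows are reported with a line number
    bad <- tempfile(fileext = ".star")
    writeLines(c("data_particles", "loop_", "_rlnImageName #1",
                 "not a tag or row count", "1@a.mrcs extra"), bad)
    expect_error(readStar(bad), "line")
    writeLines(c("data_particles", "loop_"), bad)
    expect_error(readStar(bad), "header")
    noimg <- tempfile(fileext = ".star")
    writeLines(c("data_particles", "loop_", "_rlnClassNumber #1", "1"), noimg)
    expect_error(readStar(noimg), "rlnImageName")
    unlink(c(f, f2, bad, noimg))
})

test_that("symmetry expansion and deduplication are inverse", {
    orig <- data.frame(rlnImageName = sprintf("%03d@s.mrcs", 1:7),
                       rlnCoordinateX = 1:7 * 10, rlnCoordinateY = 1:7 * 11,
                       rlnAngleRot = seq(-150, 150, length.out = 7))
    ex <- symmetryExpand(orig, 4)
    expect_identical(nrow(particleData(ex)), 28L)
    offs <- (particleData(ex)$rlnAngleRot -
             rep(orig$rlnAngleRot, each = 4)) %% 360
    expect_true(all(abs(offs - round(offs / 90) * 90) < 1e-9))
    dd <- deduplicateParticles(ex)
    expect_identical(nrow(dd), 7L)
    expect_equal(sort(dd$rlnCoordinateX), orig$rlnCoordinateX)
})

test_that("sorting recovers generator frequencies and conserves particles", {
    freqs <- c("1" = 0.5, "4" = 0.5)
    pt <- simulateParticleTable(4000, freqs, seed = 10)
    srt <- sortParticles(pt, boundClasses = c(1, 2))
    expect_identical(sum(srt$summary$count) + length(srt$excluded),
                     nParticles(pt))
    expect_lt(abs(sum(srt$summary$fraction) - 1), 1e-12)
    for (lb in names(freqs)) {
        p <- freqs[[lb]]
        phat <- srt$summary$fraction[srt$summary$pattern == lb]
        expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 4000))
    }
    ## all-unbound table
    pt0 <- simulateParticleTable(100, c("0" = 1), seed = 11)
    srt0 <- sortParticles(pt0, boundClasses = c(1, 2))
    expect_equal(srt0$summary$fraction[srt0$summary$pattern == "0"], 1)
    ## integrity: a particle with a missing row is excluded, not repaired
    d <- particleData(pt0)
    dBroken <- d[-1L, ]
    srtB <- sortParticles(particleTable(dBroken, 4L), boundClasses = c(1, 2))
    expect_identical(length(srtB$excluded), 1L)
    expect_identical(srtB$nParticles, 99L)
    ## class-map validation
    expect_error(sortParticles(pt0, boundClasses = 1:2, unboundClasses = 2:4),
                 "disjoint")
    expect_error(sortParticles(pt0, boundClasses = 1L, unboundClasses = 3L),
                 "not covered")
})

test_that("per-pattern STAR files contain the sorted originals", {
    pt <- simulateParticleTable(60, c("1" = 0.5, "2-trans" = 0.25,
                                      "3" = 0.25), seed = 12)
    srt <- sortParticles(pt, boundClasses = c(1, 2))
    outDir <- tempfile("patterns")
    paths <- writePatternStars(srt, outDir)
    expect_identical(sort(names(paths)),
                     sort(srt$summary$pattern[srt$summary$count > 0]))
    expect_true(file.exists(attr(paths, "summary")))
    for (lb in names(paths)) {
        sub <- readStar(paths[[lb]], symOrder = 1)
        cnt <- srt$summary$count[srt$summary$pattern == lb]
        expect_identical(nParticles(sub), as.integer(cnt))
        ## re-sorting the expanded rows of just these particles gives a
        ## single pattern
        keep <- particleData(pt)$particle_id %in%
            particleData(sub)$particle_id
        srt2 <- sortParticles(particleTable(particleData(pt)[keep, ], 4L),
                              boundClasses = c(1, 2))
        expect_identical(srt2$summary$pattern[srt2$summary$count > 0], lb)
    }
    unlink(outDir, recursive = TRUE)
})
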