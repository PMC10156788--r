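fixturePdb <- system.file("extdata", "synthetic_tripeptide.pdb",
                          package = "trpcquant")
fixtureCif <- system.file("extdata", "synthetic_tripeptide.cif",
                          package = "trpcquant")

test_that("PDB and mmCIF readers agree on the synthetic fixture", {
    m <- readStructure(fixturePdb)
    expect_identical(nAtoms(m), 12L)
    expect_equal(atomCoords(m)[1, ], c(x = 11.104, y = 6.134, z = -6.504))
    expect_identical(sort(unique(atomData(m)$chain)), c("A", "B"))
    expect_equal(atomData(m)$radius[1], 1.55)   # nitrogen
    mc <- suppressWarnings(readStructure(fixtureCif))
    expect_equal(atomCoords(mc), atomCoords(m), tolerance = 1e-9)
    expect_identical(atomData(mc)$elety, atomData(m)$elety)
})

test_that("missing element symbols are inferred from atom names", {
    ## a minimal PDB without element columns
    f <- tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
        "ATOM      2  CB  GLY A   1       1.500   0.000   0.000  1.00  0.00",
        "END"), f)
    expect_warning(m <- readStructure(f), "inferred")
    expect_identical(atomData(m)$element, c("C", "C"))
    unlink(f)
})

test_that("atom selection filters and rejects empty results", {
    m <- readStructure(fixturePdb)
    ca <- selectAtoms(m, elety = "CA")
    expect_identical(nAtoms(ca), 3L)
    expect_identical(nAtoms(selectAtoms(m, chain = "B")), 4L)
    expect_identical(nAtoms(selectAtoms(m, chain = "A", resno = 1)), 4L)
    expect_error(selectAtoms(m, chain = "Z"), "no atoms")
})

test_that("superposition recovers known rigid transforms", {
    ## identity
    fx0 <- syntheticRotatedCopy(40, angle = 0, seed = 1)
    expect_lt(superpositionRmsd(
        superposeStructures(fx0$mobile, fx0$reference)), 1e-10)
    ## 30-degree rotation + translation + 0.1 A coordinate noise
    fx <- syntheticRotatedCopy(100, angle = 30, axis = c(1, 1, 0),
                               translation = c(4, -3, 2), noiseSd = 0.1,
                               seed = 2)
    sp <- superposeStructures(fx$reference, fx$mobile)
    expect_equal(rotationAngle(sp), 30, tolerance = 0.5)
    ## rmsd at the noise level: per-atom 3D rms is sqrt(3) * 0.1
    expect_gt(superpositionRmsd(sp), 0.1)
    expect_lt(superpositionRmsd(sp), 0.26)
})

test_that("RMSD is symmetric and invariant under rigid pre-transforms", {
    fx <- syntheticRotatedCopy(60, angle = 25, noiseSd = 0.2, seed = 3)
    r1 <- superpositionRmsd(superposeStructures(fx$mobile, fx$reference))
    r2 <- superpositionRmsd(superposeStructures(fx$reference, fx$mobile))
    expect_equal(r1, r2, tolerance = 1e-9)
    pre <- transformStructure(fx$mobile, rotationMatrix(77, c(0, 1, 2)),
                              c(10, 0, -5))
    r3 <- superpositionRmsd(superposeStructures(pre, fx$reference))
    expect_equal(r3, r1, tolerance = 1e-9)
})

test_that("superposition agrees with the bio3d reference implementation", {
    fx <- syntheticRotatedCopy(50, angle = 40, translation = c(1, 2, 3),
                               noiseSd = 0.3, seed = 4)
    sp <- superposeStructures(fx$mobile, fx$reference)
    fixed <- as.vector(t(atomCoords(fx$reference)))
    mobile <- as.vector(t(atomCoords(fx$mobile)))
    xyz <- suppressWarnings(bio3d::fit.xyz(fixed, mobile))
    rmsdRef <- sqrt(mean(colSums(matrix((xyz - fixed)^2, nrow = 3))))
    expect_equal(superpositionRmsd(sp), rmsdRef, tolerance = 1e-6)
})

test_that("degenerate superpositions error", {
    line <- structureModel(data.frame(chain = "A", resno = 1:5,
                                      x = 1:5, y = 0, z = 0))
    expect_error(superposeStructures(line, line), "collinear")
    two <- structureModel(data.frame(chain = "A", resno = 1:2,
                                     x = c(0, 1), y = c(0, 1), z = c(0, 2)))
    expect_error(superposeStructures(two, two), "3 paired")
})

test_that("Shrake-Rupley SASA matches sphere closed forms", {
    probe <- 1.4
    one <- structureModel(data.frame(chain = "A", resno = 1,
                                     x = 0, y = 0, z = 0, element = "C"))
    R <- 1.7 + probe
    expect_equal(attr(shrakeRupleySasa(one), "total"), 4 * pi * R^2,
                 tolerance = 1e-9)
    ## two-sphere buried area against the analytic cap, within 2%
    for (d in c(2, 3, 4, 5)) {
        other <- structureModel(data.frame(chain = "B", resno = 1,
                                           x = d, y = 0, z = 0,
                                           element = "C"))
        ba <- buriedInterfaceArea(one, other, nPoints = 960)
        expect_equal(ba$buriedPerSide, oracleSphereCap(R, d),
                     tolerance = 0.02)
        ## symmetry in the two groups
        ba2 <- buriedInterfaceArea(other, one, nPoints = 960)
        expect_equal(ba2$buriedPerSide, ba$buriedPerSide, tolerance = 1e-9)
    }
})

test_that("SASA converges with the point count", {
    cx <- syntheticTwoBodyComplex(6, nAtomsPerBody = 20, seed = 5)
    t1 <- attr(shrakeRupleySasa(cx, nPoints = 960), "total")
    t2 <- attr(shrakeRupleySasa(cx, nPoints = 1920), "total")
    expect_lt(abs(t2 - t1) / t2, 0.005)
})

test_that("buried area is non-negative and falls with separation", {
    prev <- Inf
    for (sep in c(4, 8, 12, 40)) {
        cx <- syntheticTwoBodyComplex(sep, nAtomsPerBody = 15, seed = 6)
        ba <- buriedInterfaceArea(selectAtoms(cx, chain = "A"),
                                  selectAtoms(cx, chain = "B"),
                                  nPoints = 480)
        expect_gte(ba$buriedPerSide, -1e-9)
        expect_lte(ba$buriedPerSide, prev + 1e-9)
        prev <- ba$buriedPerSide
    }
    ## beyond any possible contact the buried area is exactly zero
    far <- syntheticTwoBodyComplex(40, nAtomsPerBody = 15, seed = 6)
    ba <- buriedInterfaceArea(selectAtoms(far, chain = "A"),
                              selectAtoms(far, chain = "B"))
    expect_equal(ba$buriedPerSide, 0)
    expect_error(buriedInterfaceArea(selectAtoms(far, chain = "A"),
                                     selectAtoms(far, chain = "A")),
                 "overlap")
})

test_that("domain rotation recovers constructed screw motions", {
    ## identical models: no rotation
    fx0 <- syntheticRotatedCopy(50, angle = 0, seed = 7)
    dr0 <- domainRotation(fx0$reference, fx0$reference,
                          fx0$reference, fx0$reference)
    expect_lt(dr0$angle, 1e-6)
    ## 45-degree rotation about z plus 5 A translation down the axis
    fx <- syntheticRotatedCopy(80, angle = 45, axis = c(0, 0, 1),
                               translation = c(0, 0, 5), seed = 8)
    dr <- domainRotation(fx$reference, fx$reference,
                         fx$reference, fx$mobile, axis = c(0, 0, 1))
    expect_equal(dr$angle, 45, tolerance = 0.1)
    expect_equal(dr$twist, 45, tolerance = 0.1)
    expect_equal(dr$translationAlongAxis, 5, tolerance = 0.01)
    expect_equal(abs(dr$axis[3]), 1, tolerance = 1e-6)
    ## sign convention: opposite rotation gives a negative twist
    fxN <- syntheticRotatedCopy(80, angle = -8, axis = c(0, 0, 1), seed = 9)
    drN <- domainRotation(fxN$reference, fxN$reference,
                          fxN$reference, fxN$mobile, axis = c(0, 0, 1))
    expect_equal(drN$twist, -8, tolerance = 0.1)
    expect_equal(drN$angle, 8, tolerance = 0.1)
})
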