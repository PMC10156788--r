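## Structural comparison metrics: coordinate input via bio3d, atom
## selection, Kabsch superposition RMSD, Shrake-Rupley solvent-accessible
## surface area and buried interface area, and domain rotation angles.

## Bondi-style van der Waals radii (Angstrom); metals use ionic-context
## values common in SASA implementations.
.VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
          FE = 1.80, ZN = 1.39, CA = 2.31, MG = 1.73, "NA" = 2.27,
          K = 2.75, MN = 1.73, CU = 1.40, CO = 1.80, NI = 1.63)
.VDW_DEFAULT <- 1.70

#' Van der Waals radius lookup
#'
#' The built-in Bondi-style radius table used when structures are read;
#' unknown elements fall back to 1.70 Angstrom (carbon).
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii (Angstrom).
#' @examples
#' vdwRadius(c("C", "N", "O", "Zn"))
#' @export
vdwRadius <- function(element) {
    r <- .VDW[toupper(trimws(element))]
    r[is.na(r)] <- .VDW_DEFAULT
    unname(r)
}

## infer an element symbol from a PDB atom name (digits stripped, first
## alphabetic character; handles names like "1HB1", "CA", "OXT")
.elementFromName <- function(elety) {
    s <- gsub("[^A-Za-z]", "", elety)
    toupper(substr(s, 1L, 1L))
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses coordinates with bio3d (`read.pdb` / `read.cif`, chosen by file
#' extension), resolves alternate locations by keeping the highest
#' occupancy, infers missing element symbols from atom names (with a
#' warning), and assigns van der Waals radii from the built-in table.
#'
#' @param path path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param removeWaters drop water residues (HOH/WAT/DOD); default `TRUE`.
#' @return A [StructureModel-class].
#' @export
readStructure <- function(path, removeWaters = TRUE) {
    ext <- tolower(tools::file_ext(path))
    pdb <- tryCatch(
        if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
        else bio3d::read.pdb(path),
        error = function(e) stop("cannot parse '", path, "': ",
                                 conditionMessage(e)))
    a <- pdb$atom
    if (removeWaters)
        a <- a[!a$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
    ## altloc policy: highest occupancy per (chain, resno, insert, elety)
    alt <- a$alt
    if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
        occ <- a$o; occ[is.na(occ)] <- 1
        key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
        a <- a[order(key, -occ), , drop = FALSE]
        a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety,
                                 sep = "\r")), , drop = FALSE]
    }
    elem <- a$elesy
    if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
    bad <- is.na(elem) | trimws(elem) == ""
    if (any(bad)) {
        warning(sum(bad), " atoms lack an element symbol; ",
                "inferred from atom names")
        elem[bad] <- .elementFromName(a$elety[bad])
    }
    ins <- a$insert
    ins[is.na(ins)] <- ""
    ch <- a$chain
    ch[is.na(ch)] <- ""
    structureModel(data.frame(
        chain = ch, resno = a$resno, resid = a$resid, insert = ins,
        elety = a$elety, element = trimws(elem),
        x = a$x, y = a$y, z = a$z,
        radius = vdwRadius(elem)))
}

#' Select atoms from a structure
#'
#' Subsets a model by chain, residue number, residue name, atom name
#' and/or element; omitted predicates match everything.  An empty result
#' is an error, since every downstream analysis needs at least one atom.
#'
#' @param model a [StructureModel-class].
#' @param chain,resno,resid,elety,element optional vectors of admissible
#'   values (e.g. `chain = c("A","B")`, `resno = 1:100`, `elety = "CA"`).
#' @return The selected [StructureModel-class].
#' @export
selectAtoms <- function(model, chain = NULL, resno = NULL, resid = NULL,
                        elety = NULL, element = NULL) {
    stopifnot(is(model, "StructureModel"))
    a <- model@atoms
    keep <- rep(TRUE, nrow(a))
    if (!is.null(chain))   keep <- keep & a$chain %in% chain
    if (!is.null(resno))   keep <- keep & a$resno %in% resno
    if (!is.null(resid))   keep <- keep & a$resid %in% resid
    if (!is.null(elety))   keep <- keep & a$elety %in% elety
    if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
    if (!any(keep)) stop("selection resolves to no atoms")
    out <- model
    out@atoms <- a[keep, , drop = FALSE]
    rownames(out@atoms) <- NULL
    out
}

## Kabsch: proper rotation R and translation t minimizing ||R p + t - q||
.kabsch <- function(P, Q) {
    pc <- colMeans(P); qc <- colMeans(Q)
    P0 <- sweep(P, 2L, pc); Q0 <- sweep(Q, 2L, qc)
    sv <- svd(crossprod(P0, Q0))     # t(P0) %*% Q0
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    resid <- P0 %*% t(R) - Q0
    list(rotation = R, translation = as.numeric(qc - R %*% pc),
         rmsd = sqrt(mean(rowSums(resid^2))))
}

#' Optimal rigid superposition of two structures
#'
#' Pairs atoms between mobile and reference by chain, residue number,
#' insertion code and atom name (atoms missing in either model are
#' dropped and counted), then computes the least-squares optimal proper
#' rotation and translation (Kabsch algorithm via singular value
#' decomposition) and the residual RMSD.  At least three non-collinear
#' atom pairs are required.
#'
#' @param mobile,reference [StructureModel-class] objects; apply
#'   [selectAtoms()] first to restrict the comparison (e.g. to C-alpha
#'   atoms of the channel chains).
#' @param pairBy columns used to match atoms (default chain, residue
#'   number, insertion code and atom name).
#' @return A [SuperpositionResult-class]; the number of unpaired atoms is
#'   attached as attribute `"dropped"`.
#' @examples
#' fx <- syntheticRotatedCopy(50, angle = 30, translation = c(5, 0, 0),
#'                            seed = 1)
#' superposeStructures(fx$mobile, fx$reference)   # RMSD ~ 0
#' @export
superposeStructures <- function(mobile, reference,
                                pairBy = c("chain", "resno", "insert",
                                           "elety")) {
    stopifnot(is(mobile, "StructureModel"), is(reference, "StructureModel"))
    keyOf <- function(m) do.call(paste, c(m@atoms[pairBy], sep = "\r"))
    km <- keyOf(mobile); kr <- keyOf(reference)
    common <- intersect(km, kr)
    if (anyDuplicated(km[km %in% common]) ||
        anyDuplicated(kr[kr %in% common]))
        stop("atom pairing is ambiguous: duplicated keys (",
             paste(pairBy, collapse = "/"), ")")
    if (length(common) < 3L)
        stop("need at least 3 paired atoms; found ", length(common))
    P <- atomCoords(mobile)[match(common, km), , drop = FALSE]
    Q <- atomCoords(reference)[match(common, kr), , drop = FALSE]
    sv <- svd(sweep(Q, 2L, colMeans(Q)))$d
    if (sv[2L] < 1e-8 * max(sv[1L], 1))
        stop("paired atoms are collinear; superposition is degenerate")
    k <- .kabsch(P, Q)
    res <- new("SuperpositionResult", rotation = k$rotation,
               translation = k$translation, rmsd = k$rmsd,
               nAtoms = length(common))
    attr(res, "dropped") <- (length(km) - length(common)) +
                            (length(kr) - length(common))
    res
}

#' Apply a superposition (or any rigid transform) to a structure
#'
#' @param model a [StructureModel-class].
#' @param rotation 3 x 3 rotation matrix, or a
#'   [SuperpositionResult-class] (whose translation is then used too).
#' @param translation length-3 vector (ignored when `rotation` is a
#'   superposition result).
#' @return The transformed [StructureModel-class].
#' @export
transformStructure <- function(model, rotation, translation = c(0, 0, 0)) {
    stopifnot(is(model, "StructureModel"))
    if (is(rotation, "SuperpositionResult")) {
        translation <- rotation@translation
        rotation <- rotation@rotation
    }
    xyz <- atomCoords(model) %*% t(rotation)
    xyz <- sweep(xyz, 2L, as.numeric(translation), `+`)
    model@atoms$x <- xyz[, 1L]; model@atoms$y <- xyz[, 2L]
    model@atoms$z <- xyz[, 3L]
    model
}

#' Rotation angle (and axis) of a rigid transform
#'
#' @param x a [SuperpositionResult-class] or a 3 x 3 rotation matrix.
#' @return `rotationAngle()`: the rotation angle in degrees, in
#'   `[0, 180]`.  `rotationAxis()`: the unit rotation axis (sign chosen
#'   so the angle is positive by the right-hand rule); `NA` for the
#'   identity.
#' @export
rotationAngle <- function(x) {
    R <- if (is(x, "SuperpositionResult")) x@rotation else x
    acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' @rdname rotationAngle
#' @export
rotationAxis <- function(x) {
    R <- if (is(x, "SuperpositionResult")) x@rotation else x
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
    v / nv
}

## ---------------------------------------------------------------------------
## Shrake-Rupley solvent-accessible surface area
## ---------------------------------------------------------------------------

## deterministic near-uniform points on the unit sphere (golden spiral)
.spherePoints <- function(n) {
    i <- seq_len(n) - 1L
    z <- (2 * i + 1) / n - 1
    r <- sqrt(pmax(0, 1 - z^2))
    th <- i * pi * (3 - sqrt(5))
    cbind(r * cos(th), r * sin(th), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic point-sampling SASA: each atom's van der Waals sphere is
#' inflated by the probe radius and covered with a deterministic
#' golden-spiral point set; the accessible fraction is the fraction of
#' points outside every neighbouring inflated sphere.
#'
#' @param model a [StructureModel-class] (radii are taken from its atom
#'   table).
#' @param probe solvent probe radius (Angstrom; 1.4 for water).
#' @param nPoints test points per atom (default 960; doubling changes
#'   totals by well under 1%).
#' @return Numeric vector of per-atom areas (Angstrom^2) with the total
#'   as attribute `"total"`.
#' @export
shrakeRupleySasa <- function(model, probe = 1.4, nPoints = 960L) {
    stopifnot(is(model, "StructureModel"), probe >= 0, nPoints >= 12L)
    xyz <- atomCoords(model)
    rad <- model@atoms$radius + probe
    n <- nrow(xyz)
    sph <- .spherePoints(as.integer(nPoints))
    areas <- numeric(n)
    maxR <- max(rad)
    for (i in seq_len(n)) {
        d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
        nb <- which(d2 < (rad[i] + maxR)^2 & seq_len(n) != i)
        nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
        pts <- sweep(sph * rad[i], 2L, xyz[i, ], `+`)
        free <- rep(TRUE, nPoints)
        for (j in nb) {
            if (!any(free)) break
            dd <- (pts[free, 1L] - xyz[j, 1L])^2 +
                  (pts[free, 2L] - xyz[j, 2L])^2 +
                  (pts[free, 3L] - xyz[j, 3L])^2
            free[free] <- dd >= rad[j]^2
        }
        areas[i] <- 4 * pi * rad[i]^2 * sum(free) / nPoints
    }
    attr(areas, "total") <- sum(areas)
    areas
}

#' Buried solvent-accessible interface area between two atom groups
#'
#' Computes the Shrake-Rupley SASA of group A alone, group B alone and
#' the combined complex, and returns the per-side buried area
#' \eqn{(SASA_A + SASA_B - SASA_{AB})/2} - the convention under which a
#' "contact surface" is one face of the buried interface - together with
#' the total change in SASA.  The groups must not share atoms.
#'
#' @param groupA,groupB disjoint [StructureModel-class] objects (use
#'   [selectAtoms()] to carve them out of a complex).
#' @param probe solvent probe radius (Angstrom).
#' @param nPoints Shrake-Rupley points per atom.
#' @return List with `buriedPerSide`, `buriedTotal`, `sasaA`, `sasaB`,
#'   `sasaComplex` (all Angstrom^2).
#' @examples
#' cx <- syntheticTwoBodyComplex(50, seed = 1)   # far apart: no contact
#' buriedInterfaceArea(selectAtoms(cx, chain = "A"),
#'                     selectAtoms(cx, chain = "B"))$buriedPerSide
#' @export
buriedInterfaceArea <- function(groupA, groupB, probe = 1.4,
                                nPoints = 960L) {
    stopifnot(is(groupA, "StructureModel"), is(groupB, "StructureModel"))
    keyOf <- function(m) paste(m@atoms$chain, m@atoms$resno,
                               m@atoms$insert, m@atoms$elety,
                               m@atoms$x, m@atoms$y, m@atoms$z, sep = "\r")
    if (length(intersect(keyOf(groupA), keyOf(groupB))))
        stop("groups overlap: they must not share atoms")
    sa <- attr(shrakeRupleySasa(groupA, probe, nPoints), "total")
    sb <- attr(shrakeRupleySasa(groupB, probe, nPoints), "total")
    both <- structureModel(rbind(groupA@atoms, groupB@atoms))
    sab <- attr(shrakeRupleySasa(both, probe, nPoints), "total")
    list(buriedPerSide = (sa + sb - sab) / 2,
         buriedTotal = sa + sb - sab,
         sasaA = sa, sasaB = sb, sasaComplex = sab)
}

## ---------------------------------------------------------------------------
## Domain rotation between two conformations
## ---------------------------------------------------------------------------

## unit quaternion (w, x, y, z) from a rotation matrix
.quaternion <- function(R) {
    tr <- sum(diag(R))
    if (tr > 0) {
        s <- sqrt(tr + 1) * 2
        q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
               (R[2, 1] - R[1, 2]) / s)
    } else {
        i <- which.max(diag(R))
        j <- i %% 3L + 1L; k <- j %% 3L + 1L
        s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
        q <- numeric(4)
        q[1] <- (R[k, j] - R[j, k]) / s
        q[i + 1L] <- s / 4
        q[j + 1L] <- (R[j, i] + R[i, j]) / s
        q[k + 1L] <- (R[k, i] + R[i, k]) / s
    }
    q / sqrt(sum(q^2))
}

#' Rotation of a domain between two conformational classes
#'
#' Quantifies how a structural domain moves between two models of the
#' same molecule: the models are first brought into a common frame by
#' superposing the (assumed rigid) frame selection of B onto that of A;
#' the optimal rigid transform then mapping A's domain onto B's
#' frame-aligned domain is decomposed into a rotation angle, a rotation
#' axis and the domain-centroid translation.  When a reference axis is
#' supplied (e.g. the channel's four-fold axis) the twist about that axis
#' and the translation along it are reported as well; the sign of the
#' twist follows the right-hand rule about the supplied axis.
#'
#' @param frameA,frameB frame selections ([StructureModel-class]) of the
#'   two models (e.g. the transmembrane domain).
#' @param domainA,domainB domain selections of the two models (e.g. the
#'   coiled-coil domain).
#' @param axis optional length-3 reference axis.
#' @return List with `angle` (degrees), `axis` (unit vector, the
#'   transform's own rotation axis), `translation` (domain-centroid
#'   displacement vector, Angstrom), and, when a reference axis is given,
#'   `twist` (degrees about it) and `translationAlongAxis` (Angstrom,
#'   positive along the supplied direction).  The frame alignment is
#'   returned as `frameSuperposition`.
#' @examples
#' fx <- syntheticRotatedCopy(60, angle = 45, axis = c(0, 0, 1), seed = 2)
#' dr <- domainRotation(fx$reference, fx$reference, fx$reference,
#'                      fx$mobile, axis = c(0, 0, 1))
#' dr$angle   # 45
#' @export
domainRotation <- function(frameA, frameB, domainA, domainB, axis = NULL) {
    supF <- superposeStructures(frameB, frameA)   # B -> A frame
    domB <- transformStructure(domainB, supF)
    supD <- superposeStructures(domainA, domB)    # A domain -> aligned B domain
    R <- supD@rotation
    cA <- colMeans(atomCoords(domainA))
    cB <- colMeans(atomCoords(domB))
    out <- list(angle = rotationAngle(R), axis = rotationAxis(R),
                translation = cB - cA, domainRmsd = supD@rmsd,
                frameSuperposition = supF)
    if (!is.null(axis)) {
        stopifnot(length(axis) == 3L)
        a <- axis / sqrt(sum(axis^2))
        q <- .quaternion(R)
        out$twist <- 2 * atan2(sum(q[2:4] * a), q[1]) * 180 / pi
        out$translationAlongAxis <- sum((cB - cA) * a)
    }
    out
}
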