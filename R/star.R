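## RELION-dialect STAR particle tables: reading, writing, symmetry
## expansion, occupancy-pattern canonicalization under cyclic symmetry,
## and the particle-sorting stage that turns focused-class assignments
## into per-pattern particle files.

.starNumFormat <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.12g", x)
    else as.character(x)
}

#' Read a RELION-dialect particle STAR file
#'
#' Parses the first `data_` block containing a `loop_` of `_rln` columns
#' (preferring a block named `data_particles`), keeps every column for
#' round-tripping, and derives the keys the occupancy sorter needs:
#'
#' * `particle_id` - the original-particle key, built from the image name
#'   plus micrograph coordinates (when present), so symmetry-expanded
#'   duplicates of one particle share a key;
#' * `subunit_index` - recovered by binning each row's in-plane rotation
#'   offset, relative to the first row of its particle, into multiples of
#'   360/S degrees; falls back to within-particle row order when angles
#'   are absent or do not bin cleanly;
#' * `class_id` - from `_rlnClassNumber` (`NA` when absent).
#'
#' @param path STAR file path.
#' @param symOrder cyclic symmetry order S; `NULL` (default) infers it
#'   from the maximal number of rows sharing one particle key.
#' @return A [ParticleTable-class].
#' @export
readStar <- function(path, symOrder = NULL) {
    lines <- readLines(path, warn = FALSE)
    stripped <- trimws(lines)
    dataAt <- grep("^data_", stripped)
    if (length(dataAt) == 0L)
        stop("no data block found in ", path)
    pref <- dataAt[stripped[dataAt] == "data_particles"]
    start <- if (length(pref)) pref[1L] else dataAt[1L]
    loopAt <- which(stripped == "loop_" & seq_along(stripped) > start)
    if (length(loopAt) == 0L)
        stop("no loop_ found in block '", stripped[start], "'")
    i <- loopAt[1L] + 1L
    cols <- character(0)
    while (i <= length(stripped) && startsWith(stripped[i], "_")) {
        if (!grepl("^_\\S+(\\s+#\\d+)?$", stripped[i]))
            stop("malformed loop header at line ", i, ": ", stripped[i])
        cols <- c(cols, sub("^_(\\S+).*$", "\\1", stripped[i]))
        i <- i + 1L
    }
    if (length(cols) == 0L)
        stop("empty loop header at line ", loopAt[1L])
    rows <- list(); rowLine <- integer(0)
    while (i <= length(stripped) && nzchar(stripped[i]) &&
           !startsWith(stripped[i], "data_")) {
        if (!startsWith(stripped[i], "#")) {
            f <- strsplit(stripped[i], "\\s+")[[1L]]
            if (length(f) != length(cols))
                stop("line ", i, ": expected ", length(cols),
                     " fields, found ", length(f))
            rows[[length(rows) + 1L]] <- f
            rowLine <- c(rowLine, i)
        }
        i <- i + 1L
    }
    if (length(rows) == 0L)
        stop("no data rows in loop at line ", loopAt[1L])
    m <- do.call(rbind, rows)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- cols
    for (j in seq_along(df))
        df[[j]] <- utils::type.convert(df[[j]], as.is = TRUE)

    if (!"rlnImageName" %in% cols)
        stop("missing required column: rlnImageName")
    key <- df$rlnImageName
    if (all(c("rlnCoordinateX", "rlnCoordinateY") %in% cols))
        key <- paste(key, df$rlnCoordinateX, df$rlnCoordinateY, sep = "/")
    df$particle_id <- key
    df$class_id <- if ("rlnClassNumber" %in% cols)
        as.integer(df$rlnClassNumber) else NA_integer_

    grp <- split(seq_len(nrow(df)), key)
    if (is.null(symOrder))
        symOrder <- max(lengths(grp))
    step <- 360 / symOrder
    sub <- integer(nrow(df))
    for (idx in grp) {
        k <- NULL
        if ("rlnAngleRot" %in% cols) {
            off <- (df$rlnAngleRot[idx] - df$rlnAngleRot[idx[1L]]) %% 360
            k <- as.integer(round(off / step)) %% symOrder
            if (anyDuplicated(k) || any(abs(off - round(off / step) * step) > 1))
                k <- NULL                      # offsets do not bin cleanly
        }
        if (is.null(k)) k <- seq_along(idx) - 1L
        sub[idx] <- k
    }
    df$subunit_index <- sub
    particleTable(df, symOrder)
}

#' Write a particle table as a RELION-dialect STAR file
#'
#' Emits a `data_particles` block with a `loop_` over every `rln` column
#' of the table (derived keys are not written; they are re-derived on
#' read).  Floating-point values are printed with 12 significant digits
#' so a read-write-read cycle preserves values.
#'
#' @param pt a [ParticleTable-class] or plain data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeStar <- function(pt, path) {
    df <- if (is(pt, "ParticleTable")) particleData(pt) else pt
    cols <- grep("^rln", names(df), value = TRUE)
    if (length(cols) == 0L)
        stop("no rln* metadata columns to write")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("", "data_particles", "", "loop_",
                 sprintf("_%s #%d", cols, seq_along(cols))), con)
    body <- vapply(cols, function(cn) .starNumFormat(df[[cn]]),
                   character(nrow(df)))
    if (nrow(df) == 1L) body <- matrix(body, nrow = 1L)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Symmetry-expand original particle rows
#'
#' Replicates each original particle into S per-subunit rows with
#' subunit indices 0..S-1 and in-plane rotation offsets of 360/S degrees
#' added to `rlnAngleRot` (wrapped to \[-180, 180)).
#'
#' @param original a data.frame with one row per original particle (or a
#'   [ParticleTable-class], from which subunit-0 rows are taken).
#' @param symOrder cyclic symmetry order S (default 4).
#' @return A [ParticleTable-class] with `S * nrow(original)` rows.
#' @export
symmetryExpand <- function(original, symOrder = 4L) {
    S <- as.integer(symOrder)
    df <- if (is(original, "ParticleTable")) {
        d <- particleData(original)
        d[d$subunit_index == 0L, , drop = FALSE]
    } else as.data.frame(original)
    n <- nrow(df)
    out <- df[rep(seq_len(n), each = S), , drop = FALSE]
    out$subunit_index <- rep(seq_len(S) - 1L, n)
    if ("rlnAngleRot" %in% names(out))
        out$rlnAngleRot <- ((out$rlnAngleRot +
                             out$subunit_index * 360 / S + 180) %% 360) - 180
    if (is.null(out$particle_id)) {
        key <- out$rlnImageName
        if (all(c("rlnCoordinateX", "rlnCoordinateY") %in% names(out)))
            key <- paste(key, out$rlnCoordinateX, out$rlnCoordinateY, sep = "/")
        out$particle_id <- key
    }
    if (is.null(out$class_id)) out$class_id <- NA_integer_
    rownames(out) <- NULL
    particleTable(out, S)
}

#' Collapse a symmetry-expanded table back to original particles
#'
#' Inverse of [symmetryExpand()]: keeps one row (subunit 0) per original
#' particle.
#'
#' @param pt a [ParticleTable-class].
#' @return data.frame of original-particle rows.
#' @export
deduplicateParticles <- function(pt) {
    stopifnot(is(pt, "ParticleTable"))
    d <- particleData(pt)
    d <- d[order(d$particle_id, d$subunit_index), , drop = FALSE]
    out <- d[!duplicated(d$particle_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Canonical occupancy pattern of a ring of bound flags
#'
#' Canonicalizes a tuple of per-subunit bound flags under cyclic rotation
#' (the point group of the ring) by taking the lexicographically minimal
#' rotation.  Reflections are deliberately not applied: the symmetry is
#' cyclic (C_S), not dihedral - for binary patterns on a 4-ring mirroring
#' happens to change nothing, but for general S it would.
#'
#' For S = 4 the label vocabulary is `"0"`, `"1"`, `"2-cis"` (two bound
#' subunits adjacent), `"2-trans"` (opposite), `"3"`, `"4"`; for other S
#' the label is the bound count followed by the canonical binary tuple.
#'
#' @param flags logical vector of per-subunit bound flags (length S).
#' @param symOrder expected length (default `length(flags)`).
#' @return The canonical label (character), with the canonical logical
#'   tuple in attribute `"canonical"`.
#' @examples
#' classifyPattern(c(TRUE, FALSE, TRUE, FALSE))   # "2-trans"
#' classifyPattern(c(FALSE, TRUE, TRUE, FALSE))   # "2-cis"
#' @export
classifyPattern <- function(flags, symOrder = length(flags)) {
    S <- as.integer(symOrder)
    if (length(flags) != S)
        stop("'flags' must have length ", S)
    flags <- as.logical(flags)
    if (anyNA(flags)) stop("'flags' must not contain NA")
    rots <- vapply(seq_len(S) - 1L, function(r)
        paste(as.integer(flags[((seq_len(S) - 1L + r) %% S) + 1L]),
              collapse = ""), character(1))
    canonStr <- min(rots)
    canon <- as.logical(as.integer(strsplit(canonStr, "")[[1L]]))
    nb <- sum(flags)
    label <- if (S == 4L) {
        if (nb == 2L) {
            adjacent <- any(flags & flags[c(2:4, 1)])
            if (adjacent) "2-cis" else "2-trans"
        } else as.character(nb)
    } else paste0(nb, ":", canonStr)
    structure(label, canonical = canon)
}

#' Sort symmetry-expanded particles into occupancy patterns
#'
#' The metadata-level particle-sorting stage: groups the table's rows by
#' original particle, maps each subunit's focused-class id to a bound
#' flag, canonicalizes the per-particle pattern under cyclic rotation,
#' removes the symmetry-expanded duplicates, and reports per-pattern
#' particle sets and fractions.  Particles that do not have exactly S
#' rows with distinct subunit indices are excluded (not repaired) and
#' counted in the integrity report; fractions are over the included
#' particles and sum to 1.
#'
#' @param pt a [ParticleTable-class].
#' @param boundClasses integer class ids whose subunits count as
#'   ligand-bound.
#' @param unboundClasses integer class ids counting as unbound; defaults
#'   to all observed classes not in `boundClasses`.  The two sets must be
#'   disjoint and jointly cover every observed class id.
#' @return List of class `"occupancySort"` with elements `patterns`
#'   (named list of data.frames of original, un-expanded particle rows),
#'   `summary` (data.frame `pattern`, `count`, `fraction`), `nParticles`
#'   (included count) and `excluded` (particle ids failing the integrity
#'   check).
#' @examples
#' pt <- simulateParticleTable(200, c("1" = 0.5, "4" = 0.5), seed = 7)
#' srt <- sortParticles(pt, boundClasses = c(1, 2))
#' srt$summary
#' @export
sortParticles <- function(pt, boundClasses, unboundClasses = NULL) {
    stopifnot(is(pt, "ParticleTable"))
    S <- symmetryOrder(pt)
    d <- particleData(pt)
    observed <- sort(unique(d$class_id))
    boundClasses <- as.integer(boundClasses)
    if (is.null(unboundClasses))
        unboundClasses <- setdiff(observed, boundClasses)
    unboundClasses <- as.integer(unboundClasses)
    if (length(intersect(boundClasses, unboundClasses)))
        stop("bound and unbound class sets must be disjoint")
    uncovered <- setdiff(observed, c(boundClasses, unboundClasses))
    if (length(uncovered))
        stop("observed class ids not covered by the class map: ",
             paste(uncovered, collapse = ", "))

    d <- d[order(d$particle_id, d$subunit_index), , drop = FALSE]
    grp <- split(seq_len(nrow(d)), d$particle_id)
    ok <- vapply(grp, function(idx)
        length(idx) == S && !anyDuplicated(d$subunit_index[idx]),
        logical(1))
    excluded <- names(grp)[!ok]
    grp <- grp[ok]

    labels <- vapply(grp, function(idx)
        as.character(classifyPattern(d$class_id[idx] %in% boundClasses, S)),
        character(1))
    firstRow <- vapply(grp, `[`, integer(1), 1L)   # subunit-0 representative

    allLabels <- if (S == 4L) occupancyPatternLabels() else sort(unique(labels))
    counts <- table(factor(labels, levels = allLabels))
    n <- length(grp)
    patterns <- lapply(allLabels, function(lb) {
        out <- d[firstRow[labels == lb], , drop = FALSE]
        rownames(out) <- NULL
        out
    })
    names(patterns) <- allLabels
    structure(list(
        patterns = patterns,
        summary = data.frame(pattern = allLabels,
                             count = as.integer(counts),
                             fraction = if (n > 0) as.numeric(counts) / n
                                        else rep(NA_real_, length(allLabels))),
        nParticles = n,
        excluded = excluded), class = "occupancySort")
}

#' @export
print.occupancySort <- function(x, ...) {
    cat("Occupancy sort:", x$nParticles, "particles")
    if (length(x$excluded))
        cat(" (", length(x$excluded), " excluded by integrity check)", sep = "")
    cat("\n")
    print(x$summary, row.names = FALSE)
    invisible(x)
}

#' Write one STAR file per occupancy pattern
#'
#' Writes the original (un-expanded) particle rows of each non-empty
#' pattern to `particles_<pattern>.star` under `outDir`, plus a
#' `summary.csv` of counts and fractions.  Empty patterns produce no file
#' but stay in the summary with count 0.
#'
#' @param sorted an `"occupancySort"` result from [sortParticles()].
#' @param outDir output directory (created if absent).
#' @return Named character vector of written STAR paths, invisibly; the
#'   summary path is attached as attribute `"summary"`.
#' @export
writePatternStars <- function(sorted, outDir) {
    stopifnot(inherits(sorted, "occupancySort"))
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    paths <- character(0)
    for (lb in names(sorted$patterns)) {
        rows <- sorted$patterns[[lb]]
        if (nrow(rows) == 0L) next
        p <- file.path(outDir, paste0("particles_", lb, ".star"))
        writeStar(rows, p)
        paths[lb] <- p
    }
    sp <- file.path(outDir, "summary.csv")
    utils::write.csv(sorted$summary, sp, row.names = FALSE)
    attr(paths, "summary") <- sp
    invisible(paths)
}
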