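## Independent oracles used to freeze expected values.  These deliberately
## use different mechanics from the package implementations.

## Occupancy-pattern oracle for a 4-ring: label from the bound positions'
## cyclic gap, not from rotation canonicalization.
oraclePattern4 <- function(flags) {
    pos <- which(flags)
    nb <- length(pos)
    if (nb == 2L) {
        gap <- (pos[2L] - pos[1L]) %% 4L
        if (gap == 2L) "2-trans" else "2-cis"
    } else as.character(nb)
}

## Canonical-tuple oracle for general S: minimal binary integer value over
## all rotations (most-significant bit first).
oracleCanonical <- function(flags) {
    S <- length(flags)
    vals <- vapply(seq_len(S) - 1L, function(r) {
        rot <- flags[((seq_len(S) - 1L + r) %% S) + 1L]
        sum(as.integer(rot) * 2^((S - 1L):0))
    }, numeric(1))
    best <- which.min(vals)
    flags[((seq_len(S) - 1L + (best - 1L)) %% S) + 1L]
}

## Closed-form single-metal / single-chelator equilibrium: bound complex B
## solves K (Mt - B)(Lt - B) = B, the smaller root of
## K B^2 - (K Mt + K Lt + 1) B + K Mt Lt = 0.
oracleFreeMetal <- function(Mt, Lt, K) {
    a <- K; b <- -(K * Mt + K * Lt + 1); cc <- K * Mt * Lt
    B <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
    Mt - B
}

## Analytic buried area for two equal probe-inflated spheres of radius R
## at center distance d < 2R: one spherical cap of height h = R - d/2 is
## buried on each sphere.
oracleSphereCap <- function(R, d) 2 * pi * R * (R - d / 2)

## Stationary open probability of the two-state gating scheme.
oracleStationaryPo <- function(opening, closing) opening / (opening + closing)
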