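## Chelator equilibrium solver: free divalent-cation concentrations in
## buffered recording solutions, in the spirit of the MaxChelator family of
## calculators.

#' Default apparent EGTA stability constants
#'
#' Apparent (conditional) 1:1 association constants for Ca-EGTA and
#' Mg-EGTA at pH 7.2, 22 degrees C, ionic strength 0.15 M, as
#' \eqn{\log_{10} K'} with K' in 1/M.  These are MaxChelator-lineage
#' values: NIST absolute stability constants (log K about 10.5-10.7 for
#' Ca-EGTA, about 5.4 for Mg-EGTA) minus the EGTA protonation correction
#' \eqn{\log \alpha_H \approx 3.8}-3.9 at pH 7.2.  Published apparent
#' constants at these conditions span roughly a factor of two (the
#' apparent Ca-EGTA K_d is variously quoted between about 100 and 200 nM),
#' so the table is user-overridable in [bufferRecipe()].
#'
#' The defaults correspond to apparent dissociation constants of 180 nM
#' (Ca-EGTA) and 24 mM (Mg-EGTA).
#'
#' @return data.frame with columns `metal`, `chelator`, `logKapp`.
#' @export
egtaConstants <- function() {
    data.frame(metal = c("Ca", "Mg"), chelator = "EGTA",
               logKapp = c(log10(1 / 180e-9), log10(1 / 24e-3)))
}

#' Describe a buffered solution recipe
#'
#' Total concentrations of metals and chelators plus the apparent
#' stability constants linking them, ready for [freeIonConcentrations()].
#' Only the 1:1 metal-chelator complexes are modelled; the constants must
#' already be conditional on the recipe's pH, temperature and ionic
#' strength (see [egtaConstants()]).
#'
#' @param metals named numeric vector of total metal concentrations (mM),
#'   e.g. `c(Ca = 7.13, Mg = 3.31)`.
#' @param chelators named numeric vector of total chelator concentrations
#'   (mM), e.g. `c(EGTA = 10)`.
#' @param constants data.frame with columns `metal`, `chelator`,
#'   `logKapp` (apparent association constants, 1/M).  Pairs absent from
#'   the table do not bind.
#' @param pH,temperature recorded for documentation only; the constants
#'   are assumed already conditional on them.
#' @return A list of class `"bufferRecipe"`.
#' @examples
#' insideOutBath <- bufferRecipe(c(Ca = 7.13, Mg = 3.31), c(EGTA = 10))
#' freeIonConcentrations(insideOutBath)
#' @export
bufferRecipe <- function(metals, chelators, constants = egtaConstants(),
                         pH = 7.2, temperature = 22) {
    if (is.null(names(metals)) || is.null(names(chelators)))
        stop("'metals' and 'chelators' must be named vectors")
    if (any(metals < 0) || any(chelators < 0))
        stop("total concentrations must be non-negative")
    need <- c("metal", "chelator", "logKapp")
    if (!all(need %in% names(constants)))
        stop("'constants' must have columns metal, chelator, logKapp")
    if (any(!is.finite(constants$logKapp)))
        stop("'logKapp' values must be finite")
    structure(list(metals = metals, chelators = chelators,
                   constants = constants, pH = pH,
                   temperature = temperature),
              class = "bufferRecipe")
}

#' Apparent stability constant from an absolute constant and pKa values
#'
#' Converts an absolute (pH-independent) 1:1 stability constant into the
#' apparent constant at a given pH by dividing out the ligand protonation
#' polynomial: \eqn{\log K' = \log K - \log \alpha_H} with
#' \eqn{\alpha_H = 1 + \sum_k \prod_{j \le k} [H^+]/K_{a,j}}.
#'
#' @param logK absolute log10 association constant (1/M).
#' @param pKa vector of ligand protonation pKa values, most basic first
#'   (for EGTA near physiological pH the first two, about 9.4-9.5 and
#'   8.8-8.9, dominate).
#' @param pH solution pH.
#' @return Apparent log10 association constant.
#' @export
apparentStabilityConstant <- function(logK, pKa, pH) {
    h <- 10^(-pH)
    ka <- 10^(-pKa)
    terms <- cumprod(h / ka)
    logK - log10(1 + sum(terms))
}

#' Solve chelator equilibria for free ion concentrations
#'
#' Solves the coupled 1:1 metal-chelator mass-action equilibria by damped
#' fixed-point iteration on the free chelator concentrations:
#' \deqn{[M_i]_{free} = \frac{[M_i]_{tot}}{1 + \sum_j K_{ij} [L_j]_{free}},
#'       \qquad
#'       [L_j]_{free} = \frac{[L_j]_{tot}}{1 + \sum_i K_{ij} [M_i]_{free}}}
#' iterated to a relative tolerance of 1e-10 (mass conservation holds to
#' better than 1e-12 relative at convergence).
#'
#' @param recipe a [bufferRecipe()].
#' @param tol relative convergence tolerance.
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   residuals.
#' @return List with `freeMetals` (mM, named), `freeChelators` (mM,
#'   named), `bound` (metals x chelators matrix of complex concentrations,
#'   mM) and `residual` (largest relative mass-conservation error).
#' @examples
#' # no chelator binding: free equals total
#' r <- bufferRecipe(c(Ca = 2), c(EGTA = 0))
#' freeIonConcentrations(r)$freeMetals
#' @export
freeIonConcentrations <- function(recipe, tol = 1e-10, maxIter = 10000L) {
    stopifnot(inherits(recipe, "bufferRecipe"))
    tm <- recipe$metals / 1000      # mM -> M
    tl <- recipe$chelators / 1000
    K <- matrix(0, length(tm), length(tl),
                dimnames = list(names(tm), names(tl)))
    for (r in seq_len(nrow(recipe$constants))) {
        mi <- recipe$constants$metal[r]; lj <- recipe$constants$chelator[r]
        if (mi %in% rownames(K) && lj %in% colnames(K))
            K[mi, lj] <- 10^recipe$constants$logKapp[r]
    }
    freeM <- function(L) tm / (1 + as.numeric(K %*% L))

    ## damped fixed point on the free chelator concentrations
    L <- tl
    damp <- 0.5
    for (it in seq_len(maxIter)) {
        Lnew <- tl / (1 + as.numeric(crossprod(K, freeM(L))))
        delta <- max(abs(Lnew - L) / pmax(tl, .Machine$double.xmin))
        L <- damp * L + (1 - damp) * Lnew
        if (delta < tol) break
        if (it == maxIter) {
            res <- .freeIonResidual(tm, tl, K, freeM(L), L)
            stop("equilibrium iteration did not converge; largest relative ",
                 "residual = ", signif(res, 3))
        }
    }

    ## Newton polish on the chelator-conservation residual, driving mass
    ## conservation to machine precision
    act <- which(tl > 0)
    Fres <- function(L) (L * (1 + as.numeric(crossprod(K, freeM(L)))) - tl)[act]
    for (nit in if (length(act)) seq_len(50L) else integer(0)) {
        f0 <- Fres(L)
        if (max(abs(f0) / tl[act]) < 1e-15) break
        J <- matrix(0, length(act), length(act))
        for (k in seq_along(act)) {
            h <- pmax(L[act[k]], tl[act[k]]) * 1e-7
            Lp <- L; Lp[act[k]] <- Lp[act[k]] + h
            J[, k] <- (Fres(Lp) - f0) / h
        }
        step <- tryCatch(solve(J, f0), error = function(e) NULL)
        if (is.null(step)) break
        L[act] <- pmax(L[act] - step, 0)
    }

    M <- freeM(L)
    bound <- K * outer(M, L)        # [M_i L_j] = K_ij [M_i][L_j]
    list(freeMetals = M * 1000, freeChelators = L * 1000,
         bound = bound * 1000,
         residual = .freeIonResidual(tm, tl, K, M, L))
}

.freeIonResidual <- function(tm, tl, K, M, L) {
    bound <- K * outer(M, L)
    rm <- abs(M + rowSums(bound) - tm) / pmax(tm, .Machine$double.xmin)
    rl <- abs(L + colSums(bound) - tl) / pmax(tl, .Machine$double.xmin)
    max(rm, rl, 0)
}
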