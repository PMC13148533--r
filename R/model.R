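#' Expected MLD of a single HGT event
#'
#' A mobile element of length L that disseminated across a genus set along a
#' tree of total branch length `tau` (in mutation-rate time units) leaves an
#' exponential match length distribution: `m(r | tau) = L * tau^2 *
#' exp(-tau * r)`.
#'
#' @param L Element length (bp).
#' @param tau Total tree length (mutation-rate units), `>= 0`.
#' @param r Match length grid (bp), positive.
#'
#' @return Density values (matches per bp) on the `r` grid.
#' @examples
#' mldSingleEvent(1e4, 0.01, 500) # exp(-5)
#' @export
mldSingleEvent <- function(L, tau, r) {
    if (L <= 0) stop("L must be positive")
    if (tau < 0) stop("tau must be non-negative")
    if (any(r <= 0)) stop("r must be positive")
    L * tau^2 * exp(-tau * r)
}

#' MLD from a tree-length density (Laplace-transform relation)
#'
#' When HGT is frequent, the total tree length tau of the event that placed a
#' given element has a continuous density P(tau), and the MLD is
#' `m(r) = L * integral( tau^2 exp(-r tau) P(tau) dtau )`, i.e. L times the
#' second derivative of the Laplace transform of P evaluated at r.
#'
#' @param P A function of tau: the tree-length density. Must integrate to 1
#'   over `support` (checked to 1%).
#' @param L Mobilome length (bp).
#' @param r Match length grid (bp).
#' @param support Integration support of P (default `c(0, Inf)`).
#' @param relTol Relative quadrature tolerance.
#'
#' @return Density values on the `r` grid, by adaptive quadrature.
#' @examples
#' # exponential P(tau) with rate lambda has closed form 2*L*lambda/(r+lambda)^3
#' mldFromDensity(function(t) 100 * exp(-100 * t), L = 1e4, r = 100)
#' @export
mldFromDensity <- function(P, L, r, support = c(0, Inf), relTol = 1e-9) {
    if (!is.function(P)) stop("P must be a function of tau")
    if (L <= 0) stop("L must be positive")
    if (any(r <= 0)) stop("r must be positive")
    norm <- stats::integrate(P, support[1], support[2],
                             rel.tol = relTol)$value
    if (abs(norm - 1) > 0.01)
        stop("P is not normalized (integral = ", signif(norm, 6), ")")
    # integrate in u = r * tau: the exp(-u) kernel keeps the integrand at
    # O(1) scale for every r, where the raw tau integrand concentrates in a
    # boundary layer of width 1/r that adaptive quadrature can miss
    vapply(r, function(ri) {
        L / ri^3 * stats::integrate(function(u) {
            u^2 * exp(-u) * P(u / ri)
        }, support[1] * ri, support[2] * ri, rel.tol = relTol)$value
    }, numeric(1))
}

# Nested sum over ordered transfer pairs with progressive recipient
# exclusion, on the sub-matrix of rates restricted to the genus set.
# exclusion = "shrinking": both donor and recipient of step k are drawn from
# the set minus all previous recipients (coincides with the enumeration of
# dissemination scenarios whose donors already carry the element, under
# rank-1 symmetric rates). exclusion = "recipient_only": donors are drawn
# from the full set, only recipients shrink.
nestedRateSum <- function(rho, exclusion = c("shrinking", "recipient_only")) {
    exclusion <- match.arg(exclusion)
    n <- nrow(rho)
    shrinking <- exclusion == "shrinking"
    bits <- bitwShiftL(1L, seq_len(n) - 1L)
    memo <- rep(NA_real_, bitwShiftL(1L, n)) # keyed by recipient-set bitmask
    recur <- function(mask, members) {
        if (length(members) == 1L) return(1)
        hit <- memo[mask]
        if (!is.na(hit)) return(hit)
        total <- 0
        for (j in members) {
            rest <- members[members != j]
            donors <- if (shrinking) rest else seq_len(n)[-j]
            total <- total + sum(rho[donors, j]) *
                recur(mask - bits[j], rest)
        }
        memo[mask] <<- total
        total
    }
    recur(sum(bits), seq_len(n))
}

#' Direct-transfer asymptotic MLD
#'
#' Large-r MLD of a genus set s when transfers occur only within the set:
#' `m_s^d(r) = Ld * (n-2)! / r^(n+1) * S`, with S the nested sum over ordered
#' transfer pairs with progressive recipient exclusion (n = |s|). The log-log
#' slope is exactly `-(n+1)`.
#'
#' @param network A [TaxonNetwork-class].
#' @param set Character vector of n >= 2 genus labels, all in the network.
#' @param r Match length grid (bp).
#' @param exclusion Index-exclusion convention of the nested sum:
#'   `"shrinking"` (default; donors and recipients both drawn from the
#'   shrinking set, validated against the stochastic simulator) or
#'   `"recipient_only"`.
#'
#' @return Density values on the `r` grid.
#' @examples
#' net <- TaxonNetwork(c("A", "B"), gamma = c(1, 1), Ld = 1)
#' directMLD(net, c("A", "B"), r = 10) # (rho_AB + rho_BA) / r^3 = 2e-3
#' @export
directMLD <- function(network, set, r,
                      exclusion = c("shrinking", "recipient_only")) {
    exclusion <- match.arg(exclusion)
    stopifnot(is(network, "TaxonNetwork"))
    n <- length(set)
    if (n < 2) stop("need a set of at least two genera")
    idx <- match(set, network@taxa)
    if (anyNA(idx)) stop("set contains taxa absent from the network")
    if (any(r <= 0)) stop("r must be positive")
    rho <- rates(network)[idx, idx, drop = FALSE]
    S <- nestedRateSum(rho, exclusion)
    network@Ld * factorial(n - 2) * S / r^(n + 1)
}

#' Hub-mediated asymptotic MLD
#'
#' Large-r MLD contribution of an unobserved hub (index 0) connected to every
#' genus of the set with rates `rho0i = hubGamma * gamma[i]`:
#' `m_s^h(r) = 2 * Lh / (n (n+1) r^(n+2)) * prod(rho0i)` in bidirectional
#' mode; a common-source hub (no rates towards the hub) gives half of that.
#' The log-log slope is exactly `-(n+2)`.
#'
#' @inheritParams directMLD
#'
#' @return Density values on the `r` grid. With no hub configured, zeros are
#'   returned with attribute `noHub = TRUE`.
#' @examples
#' net <- TaxonNetwork(c("A", "B"), gamma = c(1, 1), hubGamma = 1,
#'                     Lh = 1)
#' hubMLD(net, c("A", "B"), r = 10) # 2 / (2 * 3 * 10^4)
#' @export
hubMLD <- function(network, set, r) {
    stopifnot(is(network, "TaxonNetwork"))
    n <- length(set)
    if (n < 2) stop("need a set of at least two genera")
    idx <- match(set, network@taxa)
    if (anyNA(idx)) stop("set contains taxa absent from the network")
    if (any(r <= 0)) stop("r must be positive")
    if (!length(network@hubGamma)) {
        out <- rep(0, length(r))
        attr(out, "noHub") <- TRUE
        return(out)
    }
    if (!length(network@gamma))
        stop("hub MLD needs rank-1 transferabilities")
    rho0 <- network@hubGamma * network@gamma[idx]
    pref <- 2 * network@Lh * prod(rho0) / (n * (n + 1))
    if (network@hubMode == "common_source") pref <- pref / 2
    pref / r^(n + 2)
}

#' Complete model MLD curve
#'
#' Pointwise sum of the direct-transfer and hub-mediated asymptotics,
#' `m_s(r) = m_s^d(r) + m_s^h(r)`, packaged as a [ModelCurve-class]. The
#' observed power-law exponent of a set therefore interpolates between
#' `n + 1` (direct transfers dominate) and `n + 2` (hub dominates), crossing
#' over where the two components are equal.
#'
#' @inheritParams directMLD
#'
#' @return A [ModelCurve-class].
#' @export
totalMLD <- function(network, set, r,
                     exclusion = c("shrinking", "recipient_only")) {
    d <- directMLD(network, set, r, exclusion = exclusion)
    h <- as.numeric(hubMLD(network, set, r))
    new("ModelCurve", genusSet = as.character(set), r = as.numeric(r),
        mDirect = d, mHub = h, mTotal = d + h)
}

#' Write a model curve as TSV
#'
#' Columns `r`, `m_direct`, `m_hub`, `m_total`.
#'
#' @param curve A [ModelCurve-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
    utils::write.table(
        data.frame(r = curve@r, m_direct = curve@mDirect,
                   m_hub = curve@mHub, m_total = curve@mTotal),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Model bookkeeping: number of MLDs and free parameters
#'
#' A network over n genera yields `2^n - n - 1` genus-set MLDs (all subsets
#' of size >= 2) which are fitted jointly with `n + 3` free parameters (n
#' transferabilities, the hub transferability, and the two mobilome sizes
#' Ld and Lh). For n = 8: 247 MLDs, 11 parameters.
#'
#' @param n Number of genera (>= 2).
#' @return An integer count.
#' @examples
#' countMLDs(8) # 247
#' countParams(8) # 11
#' @export
countMLDs <- function(n) {
    if (n < 2) stop("n must be >= 2")
    as.integer(2^n - n - 1)
}

#' @rdname countMLDs
#' @export
countParams <- function(n) {
    if (n < 2) stop("n must be >= 2")
    as.integer(n + 3)
}
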