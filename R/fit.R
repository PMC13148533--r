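# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

#' Fit configuration
#'
#' Settings of the joint network fit: the trimming fraction of the robust
#' objective, log10 bounds of the searched parameters, the budget of the
#' seeded population-based global stage and the local refinement, and the
#' model conventions.
#'
#' @param trim Fraction of worst bins dropped per genus set (default 0.15).
#' @param gammaBounds log10 bounds for transferabilities (default
#'   `c(-6, 2)`).
#' @param LBounds log10 bounds for mobilome sizes (default `c(2, 8)`).
#' @param popSize,generations Differential-evolution population size and
#'   generation count of the global stage.
#' @param F,CR Differential-evolution mutation weight and crossover rate.
#' @param localMaxit Iteration cap of the L-BFGS-B refinement.
#' @param hubMode Hub convention, see [TaxonNetwork()].
#' @param exclusion Nested-sum convention, see [directMLD()].
#'
#' @return A validated list of class `FitConfig`.
#' @export
fitConfig <- function(trim = 0.15, gammaBounds = c(-6, 2),
                      LBounds = c(2, 8), popSize = 40, generations = 150,
                      F = 0.8, CR = 0.9, localMaxit = 500,
                      hubMode = c("bidirectional", "common_source"),
                      exclusion = c("shrinking", "recipient_only")) {
    if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
    if (!all(is.finite(c(gammaBounds, LBounds))))
        stop("bounds must be finite")
    structure(list(trim = trim, gammaBounds = gammaBounds,
                   LBounds = LBounds, popSize = popSize,
                   generations = generations, F = F, CR = CR,
                   localMaxit = localMaxit,
                   hubMode = match.arg(hubMode),
                   exclusion = match.arg(exclusion)),
              class = "FitConfig")
}

# populated-bin data of one MLD: centers and log10 densities
populatedBins <- function(mld) {
    keep <- rawCounts(mld) > 0
    list(r = binCenters(mld)[keep], logd = log10(mldDensity(mld)[keep]))
}

# Model log10 density for one set from raw parameters (rank-1 + hub),
# avoiding S4 construction in the optimizer's hot path.
modelLogDensity <- function(r, setIdx, gamma, gamma0, Ld, Lh, hubMode,
                            exclusion) {
    n <- length(setIdx)
    g <- gamma[setIdx]
    rho <- outer(g, g)
    diag(rho) <- 0
    S <- nestedRateSum(rho, exclusion)
    md <- Ld * factorial(n - 2) * S / r^(n + 1)
    ph <- 2 * Lh * gamma0^n * prod(g) / (n * (n + 1))
    if (hubMode == "common_source") ph <- ph / 2
    log10(md + ph / r^(n + 2))
}

# worst (trimmable) penalty for bins where the model density is zero
.zeroModelPenalty <- 1e6

#' Trimmed mean squared log-difference objective
#'
#' For every genus set and every populated bin, the squared difference of
#' log10 empirical and log10 model density is computed; per set, the largest
#' `floor(trim * B)` squared residuals are dropped, and the mean of all
#' retained residuals across all sets is returned. Bins where the model
#' density vanishes receive a large, trimmable penalty and are flagged.
#'
#' @param network A [TaxonNetwork-class] (rank-1 mode with hub).
#' @param mlds List of [MLD-class] objects, each carrying its genus set.
#' @param trim Trimming fraction per set (default 0.15).
#' @param exclusion Nested-sum convention, see [directMLD()].
#'
#' @return The scalar objective; attribute `flagged` counts zero-model bins.
#' @export
mldObjective <- function(network, mlds, trim = 0.15,
                         exclusion = c("shrinking", "recipient_only")) {
    exclusion <- match.arg(exclusion)
    stopifnot(is(network, "TaxonNetwork"))
    gamma0 <- if (length(network@hubGamma)) network@hubGamma else 0
    sets <- lapply(mlds, function(m) match(genusSet(m), network@taxa))
    if (anyNA(unlist(sets)))
        stop("an MLD genus set contains taxa absent from the network")
    data <- lapply(mlds, populatedBins)
    res <- objectiveCore(data, sets, network@gamma, gamma0, network@Ld,
                         network@Lh, network@hubMode, exclusion, trim)
    out <- res$value
    attr(out, "flagged") <- res$flagged
    out
}

objectiveCore <- function(data, sets, gamma, gamma0, Ld, Lh, hubMode,
                          exclusion, trim) {
    retained <- numeric(0)
    flagged <- 0L
    for (k in seq_along(data)) {
        d <- data[[k]]
        if (!length(d$r)) next
        lm <- modelLogDensity(d$r, sets[[k]], gamma, gamma0, Ld, Lh,
                              hubMode, exclusion)
        sq <- (d$logd - lm)^2
        bad <- !is.finite(sq)
        if (any(bad)) {
            sq[bad] <- .zeroModelPenalty
            flagged <- flagged + sum(bad)
        }
        drop <- floor(trim * length(sq))
        if (drop > 0)
            sq <- sort(sq, decreasing = TRUE)[-seq_len(drop)]
        retained <- c(retained, sq)
    }
    if (!length(retained)) stop("no populated bins in any MLD")
    list(value = mean(retained), flagged = flagged)
}

# Bounded differential evolution (DE/rand/1/bin) over a box; the global
# stage of the fit. Seeded by the caller; returns the best parameter vector.
deOptim <- function(fn, lower, upper, popSize, generations, F = 0.8,
                    CR = 0.9) {
    d <- length(lower)
    pop <- matrix(stats::runif(popSize * d, lower, upper),
                  nrow = popSize, byrow = TRUE)
    fit <- apply(pop, 1, fn)
    for (gen in seq_len(generations)) {
        for (i in seq_len(popSize)) {
            idx <- sample(setdiff(seq_len(popSize), i), 3)
            trial <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
            cross <- stats::runif(d) < CR
            cross[sample.int(d, 1)] <- TRUE
            trial <- ifelse(cross, trial, pop[i, ])
            trial <- pmin(pmax(trial, lower), upper)
            ftrial <- fn(trial)
            if (ftrial <= fit[i]) {
                pop[i, ] <- trial
                fit[i] <- ftrial
            }
        }
    }
    best <- which.min(fit)
    list(par = pop[best, ], value = fit[best])
}

#' Jointly fit the HGT network to a collection of MLDs
#'
#' Fits the `n + 3` free parameters (per-genus transferabilities, hub
#' transferability, direct and hub mobilome sizes) of the rank-1 network
#' model to all supplied genus-set MLDs by minimizing the trimmed mean
#' squared log-difference, searching log10 parameter space with a seeded,
#' bounded differential-evolution stage followed by L-BFGS-B refinement.
#'
#' @param mlds List of [MLD-class] objects (each must carry its genus set).
#' @param taxa Character vector of the n genera being modelled.
#' @param config A [fitConfig()] list.
#' @param seed Integer seed; identical seeds give identical results.
#'
#' @return A [FitResult-class].
#' @export
fitNetwork <- function(mlds, taxa, config = fitConfig(), seed = 1) {
    stopifnot(inherits(config, "FitConfig"))
    n <- length(taxa)
    if (n < 2) stop("need at least two taxa")
    sets <- lapply(mlds, function(m) match(genusSet(m), taxa))
    if (anyNA(unlist(sets)))
        stop("an MLD genus set contains taxa absent from 'taxa'")
    data <- lapply(mlds, populatedBins)
    if (!any(vapply(data, function(d) length(d$r) > 0, logical(1))))
        stop("all MLDs are empty; nothing to fit")

    d <- n + 3L # log10: gamma_1..n, gamma0, Ld, Lh
    lower <- c(rep(config$gammaBounds[1], n + 1), rep(config$LBounds[1], 2))
    upper <- c(rep(config$gammaBounds[2], n + 1), rep(config$LBounds[2], 2))
    fn <- function(theta) {
        p <- 10^theta
        objectiveCore(data, sets, p[seq_len(n)], p[n + 1], p[n + 2],
                      p[n + 3], config$hubMode, config$exclusion,
                      config$trim)$value
    }
    res <- withSeed(seed, {
        glob <- deOptim(fn, lower, upper, config$popSize,
                        config$generations, config$F, config$CR)
        loc <- stats::optim(glob$par, fn, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = config$localMaxit))
        list(glob = glob, loc = loc)
    })
    best <- if (res$loc$value <= res$glob$value) res$loc$par else res$glob$par
    p <- 10^best
    net <- TaxonNetwork(taxa = taxa, gamma = p[seq_len(n)],
                        hubGamma = p[n + 1], Ld = p[n + 2], Lh = p[n + 3],
                        hubMode = config$hubMode)
    resid <- lapply(seq_along(mlds), function(k) {
        dk <- data[[k]]
        if (!length(dk$r)) return(numeric(0))
        lm <- modelLogDensity(dk$r, sets[[k]], p[seq_len(n)], p[n + 1],
                              p[n + 2], p[n + 3], config$hubMode,
                              config$exclusion)
        (dk$logd - lm)^2
    })
    names(resid) <- vapply(mlds, function(m)
        paste(genusSet(m), collapse = ","), character(1))
    new("FitResult", network = net,
        objective = fn(best),
        residuals = resid,
        convergence = list(globalValue = res$glob$value,
                           localValue = res$loc$value,
                           localConvergence = res$loc$convergence,
                           generations = config$generations,
                           popSize = config$popSize),
        seed = as.integer(seed))
}

#' Fit an exponential mixture to an episodic MLD
#'
#' Rare, episodic transfer produces an MLD that is a sum of a few
#' exponential components `A_k * exp(-tau_k * r)` (one per dissemination
#' event). The mixture is fitted by least squares on log10 densities of the
#' populated bins, with multistart over seeded restarts and log-spaced
#' initial rates. Crossover lengths, where consecutive components (ordered
#' by decreasing rate) are equal, are `log(A_k / A_{k+1}) /
#' (tau_k - tau_{k+1})`.
#'
#' @param mld An [MLD-class] with more than `2 K` populated bins.
#' @param K Number of exponential components.
#' @param trim Trimming fraction of the objective (default 0 for mixtures).
#' @param restarts Number of seeded multistart restarts (default 10).
#' @param seed Integer seed.
#'
#' @return An [ExpMixture-class].
#' @export
fitExpMixture <- function(mld, K, trim = 0, restarts = 10, seed = 1) {
    if (K < 1) stop("K must be >= 1")
    d <- populatedBins(mld)
    B <- length(d$r)
    if (B <= 2 * K)
        stop("K = ", K, " too large for ", B, " populated bins")
    obj <- function(theta) {
        A <- 10^theta[seq_len(K)]
        tau <- 10^theta[K + seq_len(K)]
        lm <- log10(colSums(A * exp(-outer(tau, d$r))))
        sq <- (d$logd - lm)^2
        sq[!is.finite(sq)] <- .zeroModelPenalty
        drop <- floor(trim * length(sq))
        if (drop > 0) sq <- sort(sq, decreasing = TRUE)[-seq_len(drop)]
        mean(sq)
    }
    rmin <- min(d$r)
    rmax <- max(d$r)
    best <- NULL
    withSeed(seed, {
        for (j in seq_len(restarts)) {
            ltau <- seq(log10(1 / rmax), log10(1 / rmin), length.out = K)
            ltau <- ltau + stats::rnorm(K, sd = if (j == 1) 0 else 0.25)
            # anchor each component near the data at the length it should
            # dominate: A = dens(anchor) * exp(tau * anchor)
            anchors <- stats::quantile(d$r, probs = rev(seq_len(K)) /
                                                (K + 1), names = FALSE)
            ld <- stats::approx(d$r, d$logd, xout = anchors, rule = 2)$y
            lA <- ld + 10^ltau * anchors / log(10) - log10(K)
            fit <- stats::optim(c(lA, ltau), obj, method = "Nelder-Mead",
                                control = list(maxit = 5000,
                                               reltol = 1e-12))
            fit <- stats::optim(fit$par, obj, method = "BFGS",
                                control = list(maxit = 1000,
                                               reltol = 1e-14))
            if (is.null(best) || fit$value < best$value) best <- fit
        }
    })
    A <- 10^best$par[seq_len(K)]
    tau <- 10^best$par[K + seq_len(K)]
    ord <- order(tau, decreasing = TRUE)
    A <- A[ord]
    tau <- tau[ord]
    cross <- if (K > 1)
        log(A[-K] / A[-1]) / (tau[-K] - tau[-1]) else numeric(0)
    new("ExpMixture", amplitudes = A, rates = tau, crossovers = cross)
}

#' Evaluate an exponential mixture
#'
#' @param mixture An [ExpMixture-class].
#' @param r Match lengths (bp).
#' @return `sum_k A_k * exp(-tau_k * r)` on the grid.
#' @export
evalMixture <- function(mixture, r) {
    colSums(mixture@amplitudes * exp(-outer(mixture@rates, r)))
}
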