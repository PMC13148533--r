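#' Construct a simulation configuration
#'
#' @param network A [TaxonNetwork-class]; every taxon is simulated as a real
#'   node (an unobserved hub is simply a taxon left out of `genusSets`).
#' @param L Mobilome length per taxon (bp).
#' @param Le Element length (bp); `L` must be a multiple of `Le`. Elements
#'   transfer as units, so each bp is overwritten at the per-bp rate.
#' @param Tend Simulated duration in mutation-rate time units (mu = 1).
#' @param minLen Minimum match length extracted (bp). On random backgrounds
#'   of length L the longest spurious match is around `log4(L^2)` bp, so
#'   keep `minLen` comfortably above that (>= 25 for L = 1e5).
#' @param replicates Number of independent replicates whose match lengths
#'   are pooled.
#' @param genusSets List of character vectors: observed taxon sets whose
#'   shared matches are extracted. Defaults to the full taxon set.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @param eventCap Cap on transfer events per replicate (resource guard).
#'
#' @return A [SimConfig-class].
#' @export
simConfig <- function(network, L = 1e5, Le = 5e3, Tend = 0.5, minLen = 25,
                      replicates = 1, genusSets = list(taxa(network)),
                      seed = 1, eventCap = 1e6) {
    new("SimConfig", network = network, L = as.numeric(L),
        Le = as.numeric(Le), Tend = as.numeric(Tend),
        minLen = as.numeric(minLen), replicates = as.integer(replicates),
        genusSets = genusSets, seed = as.integer(seed),
        eventCap = as.numeric(eventCap))
}

# apply dt time units of neutral substitution (rate 1 per bp) to an
# integer-coded sequence; Poisson number of events, uniform positions,
# uniform shift to one of the 3 other bases
mutateSequence <- function(s, dt) {
    nm <- stats::rpois(1, length(s) * dt)
    if (nm > 0) {
        pos <- sample.int(length(s), nm, replace = TRUE)
        shift <- sample.int(3L, nm, replace = TRUE)
        s[pos] <- (s[pos] + shift) %% 4L
    }
    s
}

intToDNA <- function(v) paste(c("A", "C", "G", "T")[v + 1L], collapse = "")

#' Stochastic sequence-level simulation of HGT on a taxon network
#'
#' Gillespie-style forward simulation: each taxon starts with an independent
#' uniform-random mobilome of `L` bp partitioned into elements of `Le` bp;
#' element e transfers from taxon i to taxon j at rate `rho[i,j]` (the
#' donor's current element sequence overwrites the recipient's), and every
#' base of every taxon substitutes at rate 1 (to one of the other three
#' bases, uniformly). At the end of each replicate the maximal exact matches
#' shared by every requested taxon set are extracted and their lengths
#' pooled over replicates.
#'
#' @param config A [SimConfig-class].
#' @param forcedEvents Optional `data.frame(time, donor, recipient, element)`
#'   replacing the stochastic transfer process by a fixed event list (for
#'   controlled experiments); stochastic transfers are then disabled.
#'
#' @return A [SimResult-class].
#' @export
simulateHGT <- function(config, forcedEvents = NULL) {
    stopifnot(is(config, "SimConfig"))
    net <- config@network
    nt <- length(net@taxa)
    rateM <- rates(net)
    nel <- as.integer(config@L / config@Le)
    Le <- as.integer(config@Le)
    L <- as.integer(config@L)

    pairs <- which(rateM > 0, arr.ind = TRUE)
    pairRates <- rateM[pairs] * nel # element-transfer rate per directed edge
    totRate <- sum(pairRates)
    useForced <- !is.null(forcedEvents)
    if (useForced) {
        forcedEvents <- forcedEvents[order(forcedEvents$time), , drop = FALSE]
        if (any(forcedEvents$time < 0 | forcedEvents$time > config@Tend))
            stop("forced event times must lie in [0, Tend]")
    }

    allEvents <- list()
    pooled <- stats::setNames(
        rep(list(numeric(0)), length(config@genusSets)),
        vapply(config@genusSets, paste, character(1), collapse = ","))
    lastSeqs <- NULL

    withSeed(config@seed, {
        for (rep_ in seq_len(config@replicates)) {
            seqs <- lapply(seq_len(nt), function(i)
                sample(0:3, L, replace = TRUE))
            t <- 0
            nev <- 0L
            forcedIdx <- 1L
            repeat {
                if (useForced) {
                    if (forcedIdx > nrow(forcedEvents)) break
                    tNext <- forcedEvents$time[forcedIdx]
                    di <- match(forcedEvents$donor[forcedIdx], net@taxa)
                    ri <- match(forcedEvents$recipient[forcedIdx], net@taxa)
                    el <- forcedEvents$element[forcedIdx]
                    forcedIdx <- forcedIdx + 1L
                } else {
                    if (totRate <= 0) break
                    tNext <- t + stats::rexp(1, totRate)
                    if (tNext > config@Tend) break
                    k <- sample.int(nrow(pairs), 1, prob = pairRates)
                    di <- pairs[k, 1]
                    ri <- pairs[k, 2]
                    el <- sample.int(nel, 1)
                }
                nev <- nev + 1L
                if (nev > config@eventCap)
                    stop("transfer event cap exceeded; lower the rates, ",
                         "the duration, or raise eventCap")
                for (i in seq_len(nt))
                    seqs[[i]] <- mutateSequence(seqs[[i]], tNext - t)
                span <- ((el - 1L) * Le + 1L):(el * Le)
                seqs[[ri]][span] <- seqs[[di]][span]
                allEvents[[length(allEvents) + 1L]] <- data.frame(
                    replicate = rep_, time = tNext,
                    donor = net@taxa[di], recipient = net@taxa[ri],
                    element = el, stringsAsFactors = FALSE)
                t <- tNext
            }
            for (i in seq_len(nt))
                seqs[[i]] <- mutateSequence(seqs[[i]], config@Tend - t)
            gs <- GenomeSet(
                stats::setNames(vapply(seqs, intToDNA, character(1)),
                                net@taxa),
                taxon = net@taxa)
            for (si in seq_along(config@genusSets)) {
                len <- matchLengths(gs, config@genusSets[[si]],
                                    minLen = config@minLen)
                pooled[[si]] <- c(pooled[[si]], len)
            }
            lastSeqs <- gs@sequences
        }
    })

    events <- if (length(allEvents)) do.call(rbind, allEvents)
              else data.frame(replicate = integer(0), time = numeric(0),
                              donor = character(0), recipient = character(0),
                              element = integer(0))
    new("SimResult", sequences = lastSeqs, events = events,
        matchLengths = pooled, config = config)
}

#' Generate synthetic MLDs from the analytic model
#'
#' Fast generative counterpart of the full simulator: for each genus set the
#' model curve is evaluated on the standard geometric bin grid, converted to
#' expected counts per bin (density x bin width x comparisons x scale), and
#' Poisson counts are drawn. The `countsScale` factor acts like additional
#' genome comparisons, so the returned densities converge to the model curve
#' as the scale grows.
#'
#' @param network A [TaxonNetwork-class] (rank-1 mode).
#' @param genusSets List of character vectors (subsets of the network taxa,
#'   each of size >= 2).
#' @param rMin Lower length cutoff (bp) of the grid.
#' @param nDecades Number of decades the grid spans (default 3).
#' @param countsScale Expected-count multiplier (default 1).
#' @param seed Integer seed.
#' @param binsPerDecade Bins per decade (default 20).
#' @param nComparisons Genome comparisons per set (default 1). Ignored when
#'   `genomesPerGenus` is given.
#' @param genomesPerGenus Optional number of genomes per genus (scalar or
#'   named vector over the network taxa); the comparisons of a set s are
#'   then the product k1 k2 ... kn over its genera, as for real
#'   collections.
#' @param noise Draw Poisson counts (default). With `noise = FALSE`,
#'   expected counts are rounded instead (near-noise-free at high counts).
#' @param exclusion Nested-sum convention, see [directMLD()].
#'
#' @return A list of [MLD-class] objects, one per genus set.
#' @export
generateSyntheticMLDs <- function(network, genusSets, rMin = 1000,
                                  nDecades = 3, countsScale = 1, seed = 1,
                                  binsPerDecade = 20, nComparisons = 1,
                                  genomesPerGenus = NULL, noise = TRUE,
                                  exclusion = c("shrinking",
                                                "recipient_only")) {
    exclusion <- match.arg(exclusion)
    nbin <- as.integer(nDecades * binsPerDecade)
    edges <- (rMin - 0.5) * 10^(seq(0L, nbin) / binsPerDecade)
    centers <- sqrt(edges[-length(edges)] * edges[-1])
    widths <- diff(edges)
    if (!is.null(genomesPerGenus) && is.null(names(genomesPerGenus)))
        genomesPerGenus <- stats::setNames(
            rep(genomesPerGenus, length.out = length(taxa(network))),
            taxa(network))
    withSeed(seed, {
        lapply(genusSets, function(s) {
            comp <- if (is.null(genomesPerGenus)) nComparisons
                    else prod(genomesPerGenus[s])
            curve <- totalMLD(network, s, centers, exclusion = exclusion)
            expected <- curve@mTotal * widths * comp * countsScale
            counts <- if (noise) stats::rpois(length(expected), expected)
                      else as.integer(round(expected))
            effComp <- comp * countsScale
            new("MLD", genusSet = as.character(s), rMin = as.numeric(rMin),
                binsPerDecade = as.integer(binsPerDecade),
                binEdges = edges, binCenters = centers,
                rawCounts = as.integer(counts),
                density = counts / widths / effComp,
                nComparisons = effComp)
        })
    })
}
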