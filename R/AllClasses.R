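#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' A collection of genomes with taxon labels
#'
#' Holds one or more genome sequences together with the genus (taxon) each
#' genome belongs to and an optional replicon tag (chromosome/plasmid,
#' passthrough metadata). Genome identifiers are the names of the underlying
#' [Biostrings::DNAStringSet].
#'
#' @slot sequences A [Biostrings::DNAStringSet]; names are genome ids.
#' @slot taxon Character vector, one genus label per genome.
#' @slot replicon Character vector, one tag per genome (may be `NA`).
#'
#' @export
setClass("GenomeSet",
    representation(
        sequences = "DNAStringSet",
        taxon = "character",
        replicon = "character"
    )
)

setValidity("GenomeSet", function(object) {
    n <- length(object@sequences)
    ids <- names(object@sequences)
    msg <- character()
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        msg <- c(msg, "every genome needs a non-empty id")
    if (anyDuplicated(ids))
        msg <- c(msg, "genome ids must be unique")
    if (length(object@taxon) != n)
        msg <- c(msg, "one taxon label per genome required")
    if (anyNA(object@taxon) || any(object@taxon == ""))
        msg <- c(msg, "taxon labels must be non-empty")
    if (length(object@replicon) != n)
        msg <- c(msg, "one replicon tag per genome required (NA allowed)")
    if (n > 0 && any(Biostrings::width(object@sequences) < 1))
        msg <- c(msg, "sequences must have length >= 1")
    if (length(msg)) msg else TRUE
})

#' Log-binned, per-comparison-normalized match length distribution
#'
#' The match length distribution (MLD) of a genus set s is the number of
#' maximal exact matches of length r per comparison of one genome from each
#' genus in s, binned on a geometric grid and normalized per bp of bin width
#' and per genome comparison.
#'
#' @slot genusSet Character vector of genus labels (may be empty for
#'   anonymous length samples).
#' @slot rMin Minimum match length (bp) entering the distribution.
#' @slot binsPerDecade Number of geometric bins per decade (default 20).
#' @slot binEdges Numeric vector of bin edges, strictly increasing, at
#'   `(rMin - 0.5) * 10^(k / binsPerDecade)`.
#' @slot binCenters Geometric means of adjacent edges.
#' @slot rawCounts Integer match counts per bin.
#' @slot density Matches per bp per comparison:
#'   `rawCounts / diff(binEdges) / nComparisons`.
#' @slot nComparisons Number of genome comparisons (product of per-genus
#'   genome counts).
#'
#' @export
setClass("MLD",
    representation(
        genusSet = "character",
        rMin = "numeric",
        binsPerDecade = "integer",
        binEdges = "numeric",
        binCenters = "numeric",
        rawCounts = "integer",
        density = "numeric",
        nComparisons = "numeric"
    )
)

setValidity("MLD", function(object) {
    msg <- character()
    nb <- length(object@rawCounts)
    if (length(object@binEdges) != (if (nb == 0) 0L else nb + 1L))
        msg <- c(msg, "need one more edge than bins (or none when empty)")
    if (nb > 0 && any(diff(object@binEdges) <= 0))
        msg <- c(msg, "bin edges must be strictly increasing")
    if (length(object@binCenters) != nb || length(object@density) != nb)
        msg <- c(msg, "centers/density must have one value per bin")
    if (object@nComparisons < 1)
        msg <- c(msg, "nComparisons must be >= 1")
    if (nb > 0) {
        dens <- object@rawCounts / diff(object@binEdges) / object@nComparisons
        if (max(abs(dens - object@density)) > 1e-8 * max(dens, 1e-300))
            msg <- c(msg, "density must equal rawCounts/binWidth/nComparisons")
    }
    if (length(msg)) msg else TRUE
})

#' HGT network over a set of taxa
#'
#' Nodes are taxa (genera); edge weights are effective per-bp horizontal
#' transfer rates in units of the mutation rate (time units with mu = 1).
#' In rank-1 mode every taxon i carries a transferability `gamma[i]` and the
#' directed rate is `rho[i,j] = gamma[i] * gamma[j]` (symmetric). A general
#' non-negative rate matrix with zero diagonal may be supplied instead.
#' An optional unobserved hub with transferability `hubGamma` mediates
#' indirect transfers; `hubMode` selects bidirectional exchange with the hub
#' or a common-source hub (rates towards the hub all zero).
#'
#' @slot taxa Character vector of taxon (genus) labels.
#' @slot gamma Per-taxon transferabilities (length 0 in general-matrix mode).
#' @slot hubGamma Hub transferability (length 0 if no hub).
#' @slot Ld Size (bp) of the directly exchanged mobilome.
#' @slot Lh Size (bp) of the hub-routed mobilome.
#' @slot rateMatrix Directed rate matrix (0 x 0 in rank-1 mode).
#' @slot hubMode `"bidirectional"` or `"common_source"`.
#'
#' @export
setClass("TaxonNetwork",
    representation(
        taxa = "character",
        gamma = "numeric",
        hubGamma = "numeric",
        Ld = "numeric",
        Lh = "numeric",
        rateMatrix = "matrix",
        hubMode = "character"
    )
)

setValidity("TaxonNetwork", function(object) {
    msg <- character()
    n <- length(object@taxa)
    if (n < 1 || anyDuplicated(object@taxa))
        msg <- c(msg, "need at least one uniquely named taxon")
    rank1 <- length(object@gamma) > 0
    if (rank1) {
        if (length(object@gamma) != n)
            msg <- c(msg, "one gamma per taxon required")
        if (any(object@gamma < 0))
            msg <- c(msg, "gamma must be non-negative")
    } else if (nrow(object@rateMatrix) > 0) {
        if (!all(dim(object@rateMatrix) == c(n, n)))
            msg <- c(msg, "rateMatrix must be n x n")
        else {
            if (any(object@rateMatrix < 0))
                msg <- c(msg, "rates must be non-negative")
            if (any(diag(object@rateMatrix) != 0))
                msg <- c(msg, "rateMatrix diagonal must be zero")
        }
    } else {
        msg <- c(msg, "supply either gamma (rank-1 mode) or rateMatrix")
    }
    if (length(object@hubGamma) > 1 || (length(object@hubGamma) == 1 &&
        object@hubGamma < 0))
        msg <- c(msg, "hubGamma must be a single non-negative value (or absent)")
    if (length(object@Ld) != 1 || object@Ld < 0)
        msg <- c(msg, "Ld must be a single non-negative length")
    if (length(object@Lh) != 1 || object@Lh < 0)
        msg <- c(msg, "Lh must be a single non-negative length")
    if (!object@hubMode %in% c("bidirectional", "common_source"))
        msg <- c(msg, "hubMode must be 'bidirectional' or 'common_source'")
    if (length(msg)) msg else TRUE
})

#' Predicted model MLD curve for one genus set
#'
#' Direct-transfer, hub-mediated and total model densities evaluated on a
#' grid of match lengths. The total is the pointwise sum of the two
#' components; the direct component scales as `r^-(n+1)` and the hub
#' component as `r^-(n+2)` for a set of n genera.
#'
#' @slot genusSet Genus labels of the set.
#' @slot r Match-length grid (bp).
#' @slot mDirect,mHub,mTotal Densities (matches per bp per comparison).
#'
#' @export
setClass("ModelCurve",
    representation(
        genusSet = "character",
        r = "numeric",
        mDirect = "numeric",
        mHub = "numeric",
        mTotal = "numeric"
    )
)

setValidity("ModelCurve", function(object) {
    msg <- character()
    k <- length(object@r)
    if (length(object@mDirect) != k || length(object@mHub) != k ||
        length(object@mTotal) != k)
        msg <- c(msg, "component lengths must match the r grid")
    if (any(object@mDirect < 0) || any(object@mHub < 0))
        msg <- c(msg, "densities must be non-negative")
    if (k > 0 && max(abs(object@mTotal - (object@mDirect + object@mHub))) >
        1e-12 * max(object@mTotal, 1e-300))
        msg <- c(msg, "mTotal must equal mDirect + mHub pointwise")
    if (length(msg)) msg else TRUE
})

#' Result of a joint network fit
#'
#' @slot network The fitted [TaxonNetwork-class].
#' @slot objective Trimmed mean squared log10 difference at the optimum.
#' @slot residuals Named list (per genus set) of per-bin squared log10
#'   residuals at the optimum.
#' @slot convergence List of diagnostics (generations, local fit info, seed).
#' @slot seed Integer seed the fit was run with.
#'
#' @export
setClass("FitResult",
    representation(
        network = "TaxonNetwork",
        objective = "numeric",
        residuals = "list",
        convergence = "list",
        seed = "integer"
    )
)

#' Exponential mixture fitted to an episodic MLD
#'
#' Each component `A_k * exp(-tau_k * r)` corresponds to a single transfer
#' event whose dissemination tree has total length `tau_k` (amplitude
#' `A_k = L_k * tau_k^2`). Components are ordered by decreasing rate, so the
#' last component dominates at large r; crossovers are the match lengths at
#' which consecutive components have equal density.
#'
#' @slot amplitudes Component amplitudes `A_k`.
#' @slot rates Component decay rates `tau_k`, strictly decreasing.
#' @slot crossovers Crossover lengths between consecutive components
#'   (length K - 1).
#'
#' @export
setClass("ExpMixture",
    representation(
        amplitudes = "numeric",
        rates = "numeric",
        crossovers = "numeric"
    )
)

setValidity("ExpMixture", function(object) {
    msg <- character()
    K <- length(object@rates)
    if (length(object@amplitudes) != K)
        msg <- c(msg, "one amplitude per rate required")
    if (any(object@rates <= 0) || any(object@amplitudes <= 0))
        msg <- c(msg, "amplitudes and rates must be positive")
    if (K > 1 && any(diff(object@rates) >= 0))
        msg <- c(msg, "rates must be strictly decreasing")
    if (length(object@crossovers) != max(K - 1, 0))
        msg <- c(msg, "need one crossover per consecutive component pair")
    if (length(msg)) msg else TRUE
})

#' Configuration of a stochastic HGT simulation
#'
#' @slot network A [TaxonNetwork-class]; a hub, if present in the dynamics,
#'   is simply one of the taxa (typically excluded from observed sets).
#' @slot L Mobilome length per taxon (bp).
#' @slot Le Element length (bp); the mobilome is partitioned into L/Le
#'   elements that transfer as units.
#' @slot Tend Duration in mutation-rate time units.
#' @slot minLen Minimum match length extracted (bp).
#' @slot replicates Number of independent replicates pooled.
#' @slot genusSets List of character vectors: the observed taxon sets whose
#'   match lengths are extracted.
#' @slot seed Integer seed.
#' @slot eventCap Hard cap on the number of transfer events per replicate.
#'
#' @export
setClass("SimConfig",
    representation(
        network = "TaxonNetwork",
        L = "numeric",
        Le = "numeric",
        Tend = "numeric",
        minLen = "numeric",
        replicates = "integer",
        genusSets = "list",
        seed = "integer",
        eventCap = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@L < 1 || object@Le < 1 || object@L %% object@Le != 0)
        msg <- c(msg, "L must be a positive multiple of Le")
    if (object@Tend <= 0) msg <- c(msg, "Tend must be positive")
    if (object@minLen < 2) msg <- c(msg, "minLen must be >= 2")
    if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
    bad <- vapply(object@genusSets, function(s) {
        !is.character(s) || length(s) < 2 || !all(s %in% object@network@taxa)
    }, logical(1))
    if (any(bad))
        msg <- c(msg, "each genus set needs >= 2 taxa present in the network")
    if (length(msg)) msg else TRUE
})

#' Result of a stochastic HGT simulation
#'
#' @slot sequences Final genome sequences of the last replicate.
#' @slot events Data frame of transfer events over all replicates
#'   (replicate, time, donor, recipient, element).
#' @slot matchLengths Named list, one numeric vector of pooled match lengths
#'   per requested genus set.
#' @slot config The [SimConfig-class] the simulation was run with.
#'
#' @export
setClass("SimResult",
    representation(
        sequences = "DNAStringSet",
        events = "data.frame",
        matchLengths = "list",
        config = "SimConfig"
    )
)
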