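#' @include AllClasses.R
NULL

#' Accessors for hgtnet classes
#'
#' Small accessor generics so that slot access never appears in user code:
#' `genomeIds`, `taxa`, `replicons` for [GenomeSet-class]; `binCenters`,
#' `binEdges`, `rawCounts`, `mldDensity`, `nComparisons`, `genusSet`, `rMin`
#' for [MLD-class]; `gammas`, `hubGamma`, `mobilomeSizes`, `rates`, `hubMode`
#' for [TaxonNetwork-class]; `crossovers`, `mixtureRates`, `amplitudes` for
#' [ExpMixture-class]; `fittedNetwork`, `objectiveValue` for
#' [FitResult-class]; `matchLengths`, `eventLog` for [SimResult-class].
#'
#' @param x An object of the documented class.
#' @return The corresponding slot content (a copy; objects are immutable).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("replicons", function(x) standardGeneric("replicons"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))
#' @rdname accessors
#' @export
setGeneric("mldDensity", function(x) standardGeneric("mldDensity"))
#' @rdname accessors
#' @export
setGeneric("nComparisons", function(x) standardGeneric("nComparisons"))
#' @rdname accessors
#' @export
setGeneric("genusSet", function(x) standardGeneric("genusSet"))
#' @rdname accessors
#' @export
setGeneric("rMin", function(x) standardGeneric("rMin"))
#' @rdname accessors
#' @export
setGeneric("gammas", function(x) standardGeneric("gammas"))
#' @rdname accessors
#' @export
setGeneric("hubGamma", function(x) standardGeneric("hubGamma"))
#' @rdname accessors
#' @export
setGeneric("hubMode", function(x) standardGeneric("hubMode"))
#' @rdname accessors
#' @export
setGeneric("mobilomeSizes", function(x) standardGeneric("mobilomeSizes"))
#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))
#' @rdname accessors
#' @export
setGeneric("crossovers", function(x) standardGeneric("crossovers"))
#' @rdname accessors
#' @export
setGeneric("mixtureRates", function(x) standardGeneric("mixtureRates"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("fittedNetwork", function(x) standardGeneric("fittedNetwork"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("matchLengths", function(x, ...) standardGeneric("matchLengths"))
#' @rdname accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

## GenomeSet -----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("genomeIds", "GenomeSet", function(x) names(x@sequences))
#' @rdname accessors
#' @export
setMethod("taxa", "GenomeSet", function(x) {
    stats::setNames(x@taxon, names(x@sequences))
})
#' @rdname accessors
#' @export
setMethod("replicons", "GenomeSet", function(x) {
    stats::setNames(x@replicon, names(x@sequences))
})
#' @rdname accessors
#' @export
setMethod("taxa", "TaxonNetwork", function(x) x@taxa)

setMethod("show", "GenomeSet", function(object) {
    cat("GenomeSet with", length(object@sequences), "genome(s) from",
        length(unique(object@taxon)), "taxa\n")
    if (length(object@sequences) > 0) {
        tab <- table(object@taxon)
        cat("  genomes per taxon:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
        cat("  total length:", sum(Biostrings::width(object@sequences)),
            "bp\n")
    }
})

## MLD ------------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("binCenters", "MLD", function(x) x@binCenters)
#' @rdname accessors
#' @export
setMethod("binEdges", "MLD", function(x) x@binEdges)
#' @rdname accessors
#' @export
setMethod("rawCounts", "MLD", function(x) x@rawCounts)
#' @rdname accessors
#' @export
setMethod("mldDensity", "MLD", function(x) x@density)
#' @rdname accessors
#' @export
setMethod("nComparisons", "MLD", function(x) x@nComparisons)
#' @rdname accessors
#' @export
setMethod("genusSet", "MLD", function(x) x@genusSet)
#' @rdname accessors
#' @export
setMethod("rMin", "MLD", function(x) x@rMin)
#' @rdname accessors
#' @export
setMethod("genusSet", "ModelCurve", function(x) x@genusSet)

setMethod("show", "MLD", function(object) {
    cat("MLD", if (length(object@genusSet))
        paste0("[", paste(object@genusSet, collapse = ","), "]") else "",
        "\n")
    cat("  rMin:", object@rMin, "bp;", length(object@rawCounts), "bins (",
        object@binsPerDecade, "per decade );",
        sum(object@rawCounts), "matches over", object@nComparisons,
        "comparison(s)\n")
})

## TaxonNetwork ---------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("gammas", "TaxonNetwork", function(x) {
    if (length(x@gamma)) stats::setNames(x@gamma, x@taxa) else x@gamma
})
#' @rdname accessors
#' @export
setMethod("hubGamma", "TaxonNetwork", function(x) x@hubGamma)
#' @rdname accessors
#' @export
setMethod("hubMode", "TaxonNetwork", function(x) x@hubMode)
#' @rdname accessors
#' @export
setMethod("mobilomeSizes", "TaxonNetwork", function(x) {
    c(Ld = x@Ld, Lh = x@Lh)
})

#' @describeIn accessors Directed per-bp transfer-rate matrix; in rank-1 mode
#'   this is `outer(gamma, gamma)` with a zero diagonal.
#' @export
setMethod("rates", "TaxonNetwork", function(x) {
    if (length(x@gamma)) {
        m <- outer(x@gamma, x@gamma)
        diag(m) <- 0
        dimnames(m) <- list(x@taxa, x@taxa)
        m
    } else {
        m <- x@rateMatrix
        dimnames(m) <- list(x@taxa, x@taxa)
        m
    }
})

setMethod("show", "TaxonNetwork", function(object) {
    cat("TaxonNetwork with", length(object@taxa), "taxa",
        if (length(object@gamma)) "(rank-1 transferabilities)"
        else "(general rate matrix)", "\n")
    if (length(object@gamma))
        cat("  gamma:", paste(object@taxa,
            signif(object@gamma, 4), sep = "=", collapse = ", "), "\n")
    if (length(object@hubGamma))
        cat("  hub: gamma0 =", signif(object@hubGamma, 4),
            paste0("(", object@hubMode, ")"), "\n")
    cat("  mobilome: Ld =", signif(object@Ld, 4), "bp, Lh =",
        signif(object@Lh, 4), "bp\n")
})

setMethod("show", "ModelCurve", function(object) {
    cat("ModelCurve [", paste(object@genusSet, collapse = ","), "] over",
        length(object@r), "grid points, r in [",
        min(object@r), ",", max(object@r), "]\n")
})

## Fit objects ----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("fittedNetwork", "FitResult", function(x) x@network)
#' @rdname accessors
#' @export
setMethod("objectiveValue", "FitResult", function(x) x@objective)

setMethod("show", "FitResult", function(object) {
    cat("FitResult: objective =", signif(object@objective, 6),
        "( seed", object@seed, ")\n")
    show(object@network)
})

#' @rdname accessors
#' @export
setMethod("crossovers", "ExpMixture", function(x) x@crossovers)
#' @rdname accessors
#' @export
setMethod("mixtureRates", "ExpMixture", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("amplitudes", "ExpMixture", function(x) x@amplitudes)

setMethod("show", "ExpMixture", function(object) {
    cat("ExpMixture with", length(object@rates), "component(s)\n")
    for (k in seq_along(object@rates))
        cat(sprintf("  A=%.4g  tau=%.4g\n", object@amplitudes[k],
            object@rates[k]))
    if (length(object@crossovers))
        cat("  crossovers:", paste(signif(object@crossovers, 6),
            collapse = ", "), "bp\n")
})

## Simulation -----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("matchLengths", "SimResult", function(x, ...) x@matchLengths)
#' @rdname accessors
#' @export
setMethod("eventLog", "SimResult", function(x) x@events)

setMethod("show", "SimResult", function(object) {
    cat("SimResult:", object@config@replicates, "replicate(s),",
        nrow(object@events), "transfer events\n")
    for (nm in names(object@matchLengths))
        cat("  ", nm, ": ", length(object@matchLengths[[nm]]),
            " matches >= ", object@config@minLen, " bp\n", sep = "")
})
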