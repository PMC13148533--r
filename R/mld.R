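#' Bin match lengths into a normalized MLD
#'
#' Logarithmic binning with `binsPerDecade` points per decade: bin edges sit
#' at `(rMin - 0.5) * 10^(k / binsPerDecade)` for k = 0, 1, 2, ... until the
#' largest length is covered (the half-integer offset reflects that match
#' lengths are integers). Bin centers are the geometric means of adjacent
#' edges. The density is the count per bp of bin width per genome comparison.
#'
#' @param lengths Numeric vector of match lengths (bp), all `>= rMin`.
#' @param rMin Minimum length (bp) of the distribution.
#' @param binsPerDecade Bins per decade (default 20).
#' @param nComparisons Number of genome comparisons the matches were pooled
#'   over (the product k1 k2 ... kn; default 1).
#' @param genusSet Optional genus labels carried along as metadata.
#'
#' @return An [MLD-class]. An empty `lengths` vector yields an MLD with zero
#'   bins.
#' @examples
#' mld <- binMLD(c(1000, 1100), rMin = 1000)
#' mldDensity(mld)[1] # 2 / (999.5 * (10^0.05 - 1))
#' @export
binMLD <- function(lengths, rMin, binsPerDecade = 20, nComparisons = 1,
                   genusSet = character()) {
    if (nComparisons < 1) stop("nComparisons must be >= 1")
    if (rMin <= 0.5) stop("rMin must exceed 0.5")
    lengths <- as.numeric(lengths)
    if (anyNA(lengths)) stop("lengths must not contain NA")
    if (length(lengths) == 0) {
        return(new("MLD", genusSet = as.character(genusSet),
                   rMin = as.numeric(rMin),
                   binsPerDecade = as.integer(binsPerDecade),
                   binEdges = numeric(0), binCenters = numeric(0),
                   rawCounts = integer(0), density = numeric(0),
                   nComparisons = as.numeric(nComparisons)))
    }
    if (any(lengths < rMin)) stop("all lengths must be >= rMin")
    e0 <- rMin - 0.5
    nbin <- ceiling(binsPerDecade * log10(max(lengths) / e0))
    nbin <- max(nbin, 1L)
    edges <- e0 * 10^(seq(0L, nbin) / binsPerDecade)
    # guard against max(lengths) landing exactly on the last edge
    while (max(lengths) >= edges[length(edges)]) {
        nbin <- nbin + 1L
        edges <- e0 * 10^(seq(0L, nbin) / binsPerDecade)
    }
    counts <- as.integer(
        table(cut(lengths, breaks = edges, right = FALSE,
                  labels = FALSE, include.lowest = FALSE))
        [as.character(seq_len(nbin))])
    counts[is.na(counts)] <- 0L
    centers <- sqrt(edges[-length(edges)] * edges[-1])
    dens <- counts / diff(edges) / nComparisons
    new("MLD", genusSet = as.character(genusSet), rMin = as.numeric(rMin),
        binsPerDecade = as.integer(binsPerDecade),
        binEdges = edges, binCenters = centers,
        rawCounts = counts, density = dens,
        nComparisons = as.numeric(nComparisons))
}

#' Method-of-moments power-law exponent estimator
#'
#' For a Pareto tail with density proportional to `r^-alpha` above `rMin`,
#' the mean is `rMin * (alpha - 1) / (alpha - 2)`. Inverting this with
#' `m = mean(lengths) / rMin` gives the moments estimator
#' `alpha = (2 m - 1) / (m - 1)`.
#'
#' @param lengths Match lengths (bp), all `>= rMin`.
#' @param rMin Lower cutoff (bp).
#'
#' @return The estimate `alpha` (a single number). A warning is raised when
#'   the estimate falls at or below 2 (the fitted law would have no finite
#'   mean).
#' @examples
#' estimateAlphaMoments(c(1500, 2500), rMin = 1000) # mean 2*rMin -> alpha 3
#' @export
estimateAlphaMoments <- function(lengths, rMin) {
    lengths <- as.numeric(lengths)
    if (!length(lengths)) stop("no lengths supplied")
    if (any(lengths < rMin)) stop("all lengths must be >= rMin")
    m <- mean(lengths) / rMin
    if (m <= 1) stop("mean must exceed rMin for the moments estimator")
    alpha <- (2 * m - 1) / (m - 1)
    if (alpha <= 2)
        warning("estimated alpha <= 2: the fitted law has no finite mean")
    alpha
}

#' Read and write MLD files
#'
#' An MLD is serialized as a TSV (`bin_center`, `bin_lo`, `bin_hi`,
#' `raw_count`, `density`) plus a JSON sidecar `<path>.json` carrying the
#' metadata (`genus_set`, `r_min`, `bins_per_decade`, `n_comparisons`).
#'
#' @param mld An [MLD-class].
#' @param path TSV file path (sidecar written next to it).
#'
#' @return `writeMLD` returns `path` invisibly; `readMLD` the reconstructed
#'   [MLD-class].
#' @export
writeMLD <- function(mld, path) {
    nb <- length(rawCounts(mld))
    tab <- data.frame(
        bin_center = binCenters(mld),
        bin_lo = if (nb) binEdges(mld)[-(nb + 1)] else numeric(0),
        bin_hi = if (nb) binEdges(mld)[-1] else numeric(0),
        raw_count = rawCounts(mld),
        density = mldDensity(mld)
    )
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- list(genus_set = genusSet(mld), r_min = rMin(mld),
                 bins_per_decade = mld@binsPerDecade,
                 n_comparisons = nComparisons(mld))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeMLD
#' @export
readMLD <- function(path) {
    tab <- utils::read.delim(path)
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    edges <- if (nrow(tab)) c(tab$bin_lo, tab$bin_hi[nrow(tab)])
             else numeric(0)
    new("MLD",
        genusSet = as.character(meta$genus_set %||% character()),
        rMin = as.numeric(meta$r_min),
        binsPerDecade = as.integer(meta$bins_per_decade),
        binEdges = edges, binCenters = as.numeric(tab$bin_center),
        rawCounts = as.integer(tab$raw_count),
        density = as.numeric(tab$density),
        nComparisons = as.numeric(meta$n_comparisons))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
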