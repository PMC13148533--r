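#' Intersect pairwise matches into multi-genus matches
#'
#' Given pairwise matches of one reference genome against one partner genome
#' per other genus, projects every match to its interval on the reference and
#' returns the maximal intervals covered by at least one interval from every
#' partner (position-wise AND over the reference). Because exact identity is
#' transitive, these intervals are exactly the regions identical across all
#' genomes.
#'
#' @param pairwise Named list (name = partner genus) of pairwise match
#'   `data.frame`s as produced by [pairMatches()]; all must share the same
#'   reference genome in `genome_a` and have a single partner genome each.
#' @param minLen Minimum multi-match length (bp).
#' @param refGenus Genus label of the reference genome.
#'
#' @return A `data.frame` with columns `genus_set` (comma-joined, reference
#'   genus first), `genomes` (comma-joined ids, reference first), `ref_start`,
#'   `ref_end` (0-based half-open on the reference) and `length`.
#' @examples
#' b <- data.frame(genome_a = "r", genome_b = "b1",
#'                 start_a = 100, start_b = 0, length = 500)
#' cc <- data.frame(genome_a = "r", genome_b = "c1",
#'                  start_a = 300, start_b = 0, length = 600)
#' intersectToMultiMatch(list(B = b, C = cc), minLen = 200, refGenus = "A")
#' @export
intersectToMultiMatch <- function(pairwise, minLen = 1000, refGenus = "ref") {
    if (!length(pairwise) || is.null(names(pairwise)))
        stop("pairwise must be a named list (partner genus -> matches)")
    refs <- unique(unlist(lapply(pairwise, function(m) unique(m$genome_a))))
    if (length(refs) > 1)
        stop("all match lists must be anchored on the same reference genome")
    refGenome <- if (length(refs)) refs else NA_character_
    partnerGenomes <- vapply(pairwise, function(m) {
        g <- unique(m$genome_b)
        if (length(g) > 1)
            stop("one partner genome per genus expected")
        if (length(g)) g else NA_character_
    }, character(1))

    ranges <- lapply(pairwise, function(m) {
        if (!nrow(m)) return(IRanges::IRanges())
        IRanges::reduce(IRanges::IRanges(start = m$start_a + 1L,
                                         width = m$length))
    })
    common <- Reduce(IRanges::intersect, ranges)
    common <- common[IRanges::width(common) >= minLen]

    data.frame(
        genus_set = rep(paste(c(refGenus, names(pairwise)), collapse = ","),
                        length(common)),
        genomes = rep(paste(c(refGenome, partnerGenomes), collapse = ","),
                      length(common)),
        ref_start = IRanges::start(common) - 1L,
        ref_end = IRanges::end(common),
        length = IRanges::width(common),
        stringsAsFactors = FALSE
    )
}

#' Regions shared across all genera of a set
#'
#' Enumerates, for every combination of one genome per genus (anchored in
#' turn on each genome of the first genus as reference), the maximal regions
#' identical across all chosen genomes, by intersecting pairwise maximal
#' exact matches on the reference. Duplicate intervals arising from different
#' genome combinations are kept: the per-comparison normalization by
#' k1 k2 ... kn accounts for the number of combinations.
#'
#' @param genomes A [GenomeSet-class].
#' @param genusSet Character vector of n >= 2 genus labels; the first genus
#'   anchors the reference.
#' @param minLen Minimum match length (bp).
#' @param revComp Passed to [findMaximalExactMatches()].
#'
#' @return For n = 2, a pairwise match table over all genome combinations
#'   (one row per occurrence pair); for n > 2 a multi-match table as in
#'   [intersectToMultiMatch()], pooled over combinations.
#' @export
multiMatches <- function(genomes, genusSet, minLen = 1000, revComp = FALSE) {
    stopifnot(is(genomes, "GenomeSet"))
    genusSet <- as.character(genusSet)
    if (length(genusSet) < 2) stop("need at least two genera")
    tx <- taxa(genomes)
    absent <- setdiff(genusSet, tx)
    if (length(absent))
        stop("genera not in the collection: ", paste(absent, collapse = ", "))
    byGenus <- lapply(genusSet, function(g) genomeIds(genomes)[tx == g])
    names(byGenus) <- genusSet

    cache <- new.env(parent = emptyenv())
    getPair <- function(idA, idB) {
        key <- paste(idA, idB, sep = "\r")
        if (!is.null(cache[[key]])) return(cache[[key]])
        m <- pairMatches(genomes, idA, idB, minLen = minLen,
                         revComp = revComp)
        cache[[key]] <- m
        m
    }

    if (length(genusSet) == 2) {
        combos <- expand.grid(a = byGenus[[1]], b = byGenus[[2]],
                              stringsAsFactors = FALSE)
        out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
            getPair(combos$a[i], combos$b[i])
        }))
        rownames(out) <- NULL
        return(out)
    }

    partnerGenera <- genusSet[-1]
    partnerCombos <- expand.grid(byGenus[partnerGenera],
                                 stringsAsFactors = FALSE)
    res <- list()
    for (ref in byGenus[[1]]) {
        for (i in seq_len(nrow(partnerCombos))) {
            pw <- lapply(partnerGenera, function(g) {
                getPair(ref, partnerCombos[i, g])
            })
            names(pw) <- partnerGenera
            res[[length(res) + 1L]] <- intersectToMultiMatch(
                pw, minLen = minLen, refGenus = genusSet[1])
        }
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' @describeIn accessors Pooled match lengths (bp) of a genus set in a
#'   [GenomeSet-class]: pairwise occurrence-pair lengths for n = 2, lengths
#'   of intersected multi-genus regions for n > 2.
#' @param genusSet,minLen,revComp See [multiMatches()].
#' @export
setMethod("matchLengths", "GenomeSet",
    function(x, genusSet, minLen = 1000, revComp = FALSE) {
        mm <- multiMatches(x, genusSet, minLen = minLen, revComp = revComp)
        as.numeric(mm$length)
    })

#' Write a multi-match table
#'
#' TSV with columns `genus_set`, `genomes` (comma-joined), `ref_start`,
#' `ref_end` (0-based half-open) and `length`.
#'
#' @param multimatches Output of [multiMatches()] (n > 2 form).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeMultiMatches <- function(multimatches, path) {
    utils::write.table(multimatches, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
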