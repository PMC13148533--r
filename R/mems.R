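#' Find maximal exact matches between two sequences
#'
#' Enumerates every maximal exact match (MEM) of length at least `minLen`
#' between two sequences: identical substrings that cannot be extended on
#' either side without hitting a sequence boundary or a mismatch. Every
#' occurrence pair of a repeated maximal substring is reported (each genome
#' comparison contributes to the MLD), unless `perOccurrencePair = FALSE`.
#'
#' Internally a suffix array over the concatenation (with a sentinel
#' separator) is built and cross-sequence suffix pairs with a sufficiently
#' long common prefix and differing preceding characters are emitted.
#' Non-ACGT symbols are treated as universal mismatches: they terminate
#' matches and never match anything, so runs of N cannot fake identity.
#'
#' @param a,b Sequences: character scalars, [Biostrings::DNAString] or
#'   length-1 [Biostrings::DNAStringSet] objects.
#' @param minLen Minimum match length in bp (default 1000, the analysis
#'   threshold that excludes conserved-sequence matches; simulations on
#'   random backgrounds can use much smaller values).
#' @param revComp Also search `a` against the reverse complement of `b`
#'   (default `FALSE`: forward strand only).
#' @param perOccurrencePair Report every occurrence pair (default). If
#'   `FALSE`, matches sharing the same substring content are collapsed to
#'   one record.
#'
#' @return A `data.frame` with columns `start_a`, `start_b` (0-based
#'   offsets), `length` (bp) and `strand` (`"+"` or `"-"`; for `"-"`,
#'   `start_b` refers to the reverse-complemented `b`).
#' @examples
#' findMaximalExactMatches("ACGTACGTAA", "TTACGTACGG", minLen = 4)
#' @export
findMaximalExactMatches <- function(a, b, minLen = 1000, revComp = FALSE,
                                    perOccurrencePair = TRUE) {
    a <- as.character(a)
    b <- as.character(b)
    if (length(a) != 1L || length(b) != 1L)
        stop("a and b must be single sequences")
    if (nchar(a) < 1 || nchar(b) < 1)
        stop("sequences must be non-empty")
    if (minLen < 2) stop("minLen must be >= 2")
    am <- maskSequence(a, "X")
    run1 <- function(bseq, strand) {
        bm <- maskSequence(bseq, "Y")
        m <- .memFinderCpp(am, bm, as.integer(minLen))
        m <- as.data.frame(m)
        if (nrow(m)) m$strand <- strand else m$strand <- character(0)
        m
    }
    out <- run1(b, "+")
    if (revComp) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(b)))
        out <- rbind(out, run1(rc, "-"))
    }
    if (!perOccurrencePair && nrow(out)) {
        key <- vapply(seq_len(nrow(out)), function(i) {
            substr(a, out$start_a[i] + 1L, out$start_a[i] + out$length[i])
        }, character(1))
        out <- out[!duplicated(key), , drop = FALSE]
    }
    out <- out[order(out$start_a, out$start_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Maximal exact matches between two genomes of a GenomeSet
#'
#' Thin wrapper around [findMaximalExactMatches()] that resolves genome ids
#' and attaches them to the output (the pairwise match table format).
#'
#' @param genomes A [GenomeSet-class].
#' @param idA,idB Genome ids.
#' @inheritParams findMaximalExactMatches
#'
#' @return A `data.frame` with columns `genome_a`, `genome_b`, `start_a`,
#'   `start_b`, `length`, `strand`.
#' @export
pairMatches <- function(genomes, idA, idB, minLen = 1000, revComp = FALSE,
                        perOccurrencePair = TRUE) {
    m <- findMaximalExactMatches(getSequence(genomes, idA),
                                 getSequence(genomes, idB),
                                 minLen = minLen, revComp = revComp,
                                 perOccurrencePair = perOccurrencePair)
    cbind(data.frame(genome_a = rep(idA, nrow(m)),
                     genome_b = rep(idB, nrow(m)),
                     stringsAsFactors = FALSE), m)
}

#' Read and write pairwise match tables
#'
#' TSV with columns `genome_a`, `genome_b`, `start_a`, `start_b`, `length`
#' (and `strand` if present). Coordinates are 0-based half-open; setting
#' `oneBased = TRUE` in the writer converts starts to 1-based for
#' compatibility with 1-based tools, and the reader's `oneBased = TRUE`
#' undoes it.
#'
#' @param matches A pairwise match `data.frame` (see [pairMatches()]).
#' @param path File path.
#' @param oneBased Convert coordinates to/from 1-based (default `FALSE`).
#'
#' @return `writeMatches` returns `path` invisibly; `readMatches` returns the
#'   match `data.frame` with 0-based coordinates.
#' @export
writeMatches <- function(matches, path, oneBased = FALSE) {
    m <- matches
    if (oneBased) {
        m$start_a <- m$start_a + 1L
        m$start_b <- m$start_b + 1L
    }
    utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatches
#' @export
readMatches <- function(path, oneBased = FALSE) {
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (oneBased) {
        m$start_a <- m$start_a - 1L
        m$start_b <- m$start_b - 1L
    }
    m
}
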