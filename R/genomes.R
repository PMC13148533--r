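#' Construct a GenomeSet
#'
#' @param sequences A named [Biostrings::DNAStringSet] or a named character
#'   vector of genome sequences. Names are genome ids.
#' @param taxon Character vector of genus labels, one per genome (recycled if
#'   length 1).
#' @param replicon Optional character vector of replicon tags
#'   (chromosome/plasmid); defaults to `NA`.
#'
#' @return A [GenomeSet-class].
#' @examples
#' gs <- GenomeSet(c(g1 = "ACGTACGT", g2 = "TTACGTAC"),
#'                 taxon = c("A", "B"))
#' genomeIds(gs)
#' @export
GenomeSet <- function(sequences, taxon,
                      replicon = rep(NA_character_, length(sequences))) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(sequences)
    if (length(taxon) == 1L)
        taxon <- rep(taxon, length(sequences))
    new("GenomeSet", sequences = sequences,
        taxon = as.character(taxon),
        replicon = as.character(replicon))
}

#' Read genomes from FASTA with a taxon manifest
#'
#' The FASTA record id (first whitespace-delimited token of the header) is
#' the genome id. The manifest is a tab-separated file with a header line and
#' columns `genome_id`, `taxon` and optionally `replicon_tag`.
#'
#' @param fasta Path to a (multi-record) FASTA file.
#' @param manifest Path to the two/three-column TSV manifest.
#'
#' @return A [GenomeSet-class].
#' @export
readGenomes <- function(fasta, manifest) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    need <- c("genome_id", "taxon")
    if (!all(need %in% names(man)))
        stop("manifest needs columns 'genome_id' and 'taxon'")
    missing <- setdiff(names(seqs), man$genome_id)
    if (length(missing))
        stop("manifest is missing genomes: ", paste(missing, collapse = ", "))
    idx <- match(names(seqs), man$genome_id)
    repl <- if ("replicon_tag" %in% names(man)) man$replicon_tag[idx]
            else rep(NA_character_, length(seqs))
    GenomeSet(seqs, taxon = man$taxon[idx], replicon = repl)
}

#' Per-genus genome counts and their product
#'
#' The number of genome comparisons for a genus set s with k1, ..., kn
#' genomes per genus is the product k1 * k2 * ... * kn; the MLD of the set is
#' normalized by this number.
#'
#' @param genomes A [GenomeSet-class].
#' @param genusSet Character vector of genus labels.
#'
#' @return A list with elements `genusSet`, `counts` (named per-genus genome
#'   counts) and `total` (their product).
#' @examples
#' gs <- GenomeSet(c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT"),
#'                 taxon = c("A", "A", "B"))
#' countComparisons(gs, c("A", "B"))$total # 2
#' @export
countComparisons <- function(genomes, genusSet) {
    stopifnot(is(genomes, "GenomeSet"))
    tx <- taxa(genomes)
    absent <- setdiff(genusSet, tx)
    if (length(absent))
        stop("genera not in the collection: ", paste(absent, collapse = ", "))
    counts <- vapply(genusSet, function(g) sum(tx == g), numeric(1))
    list(genusSet = genusSet, counts = counts, total = prod(counts))
}

# Uppercase and mask non-ACGT symbols with `mask`, which must be chosen so
# masked positions can never match the partner sequence (universal
# mismatch). IUPAC ambiguity codes are masked; anything else (gaps, stray
# symbols) is an input error.
maskSequence <- function(x, mask) {
    x <- toupper(x)
    if (grepl("[^ACGTRYSWKMBDHVN]", x))
        stop("sequence contains symbols outside the DNA alphabet")
    gsub("[^ACGT]", mask, x)
}

getSequence <- function(genomes, id) {
    i <- match(id, genomeIds(genomes))
    if (is.na(i)) stop("unknown genome id: ", id)
    as.character(genomes@sequences[[i]])
}
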