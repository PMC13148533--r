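# Independent oracles and small generators used across the tests.

randDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# O(L^2) brute-force maximal exact match oracle: walk every diagonal of the
# comparison matrix and extract maximal runs of equality. Independent of the
# suffix-array implementation.
bruteMEMs <- function(a, b, minLen) {
    av <- strsplit(toupper(a), "")[[1]]
    bv <- strsplit(toupper(b), "")[[1]]
    ok <- c("A", "C", "G", "T")
    na <- length(av)
    nb <- length(bv)
    out <- list()
    for (d in (-(nb - 1)):(na - 1)) {
        i0 <- max(1L, 1L + d)
        i1 <- min(na, nb + d)
        if (i1 - i0 + 1 < minLen) next
        ia <- i0:i1
        ib <- ia - d
        eq <- av[ia] == bv[ib] & av[ia] %in% ok & bv[ib] %in% ok
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values & r$lengths >= minLen)
        for (h in hit) {
            out[[length(out) + 1L]] <- data.frame(
                start_a = ia[starts[h]] - 1L,
                start_b = ib[starts[h]] - 1L,
                length = r$lengths[h])
        }
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(start_a = integer(0), start_b = integer(0),
                           length = integer(0))
    res[order(res$start_a, res$start_b), , drop = FALSE]
}

# normalize a match table for comparison
matchKey <- function(m) {
    m <- m[order(m$start_a, m$start_b), c("start_a", "start_b", "length")]
    rownames(m) <- NULL
    m
}

# continuous Pareto sampler with density ~ r^-alpha above rmin
rpareto <- function(n, alpha, rmin) {
    rmin * stats::runif(n)^(-1 / (alpha - 1))
}

# splice `segment` into `host` at 1-based position `at` (overwrite)
plantSegment <- function(host, segment, at) {
    paste0(substr(host, 1, at - 1), segment,
           substr(host, at + nchar(segment), nchar(host)))
}

allSubsets <- function(taxa, minSize = 2) {
    unlist(lapply(minSize:length(taxa), function(k)
        utils::combn(taxa, k, simplify = FALSE)), recursive = FALSE)
}
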