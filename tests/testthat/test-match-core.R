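test_that("MEM finder agrees with the brute-force diagonal oracle", {
    # worked example: two overlapping maximal matches
    got <- findMaximalExactMatches("ACGTACGTAA", "TTACGTACGG", minLen = 4)
    exp <- bruteMEMs("ACGTACGTAA", "TTACGTACGG", 4)
    expect_equal(matchKey(got), matchKey(exp))
    expect_true(any(got$start_a == 0 & got$start_b == 2 & got$length == 7))

    # randomized pairs with planted shared segments
    set.seed(71)
    for (i in 1:12) {
        la <- sample(300:1500, 1)
        lb <- sample(300:1500, 1)
        a <- randDNA(la)
        b <- randDNA(lb)
        if (i %% 2 == 0) {
            seg <- substr(a, 11, 10 + sample(40:120, 1))
            b <- plantSegment(b, seg, sample(seq_len(lb - nchar(seg)), 1))
        }
        ml <- sample(c(8L, 10L, 15L), 1)
        expect_equal(matchKey(findMaximalExactMatches(a, b, minLen = ml)),
                     matchKey(bruteMEMs(a, b, ml)),
                     info = paste("pair", i))
    }
})

test_that("identical sequences give a single full-length match", {
    set.seed(5)
    s <- randDNA(5000)
    m <- findMaximalExactMatches(s, s, minLen = 1000)
    expect_equal(nrow(m), 1L)
    expect_equal(m$start_a, 0L)
    expect_equal(m$start_b, 0L)
    expect_equal(m$length, 5000L)
})

test_that("independent random 100 kb sequences share no 1 kb match", {
    set.seed(9)
    m <- findMaximalExactMatches(randDNA(1e5), randDNA(1e5), minLen = 1000)
    expect_equal(nrow(m), 0L)
})

test_that("reported matches are identical, maximal, and symmetric", {
    set.seed(23)
    a <- randDNA(800)
    b <- plantSegment(randDNA(800), substr(a, 101, 250), 301)
    m <- findMaximalExactMatches(a, b, minLen = 10)
    expect_gt(nrow(m), 0)
    for (k in seq_len(nrow(m))) {
        sa <- m$start_a[k]; sb <- m$start_b[k]; len <- m$length[k]
        expect_identical(substr(a, sa + 1, sa + len),
                         substr(b, sb + 1, sb + len))
        # left extension breaks identity (or hits a boundary)
        if (sa > 0 && sb > 0)
            expect_false(substr(a, sa, sa) == substr(b, sb, sb))
        # right extension breaks identity (or hits a boundary)
        ea <- sa + len; eb <- sb + len
        if (ea < nchar(a) && eb < nchar(b))
            expect_false(substr(a, ea + 1, ea + 1) ==
                         substr(b, eb + 1, eb + 1))
    }
    # role swap returns the same matches with coordinates exchanged
    mswap <- findMaximalExactMatches(b, a, minLen = 10)
    expect_equal(matchKey(data.frame(start_a = mswap$start_b,
                                     start_b = mswap$start_a,
                                     length = mswap$length)),
                 matchKey(m))
})

test_that("non-ACGT symbols terminate matches on both sides", {
    a <- "ACGTACGTNNACGTACGT"
    b <- "ACGTACGTNNACGTACGT"
    m <- findMaximalExactMatches(a, b, minLen = 4)
    # the N run must not bridge the two 8 bp halves, nor match itself
    expect_gt(nrow(m), 0)
    expect_true(all(m$length <= 8))
    covers_n <- (m$start_a < 10 & m$start_a + m$length > 8) |
                (m$start_b < 10 & m$start_b + m$length > 8)
    expect_false(any(covers_n))
    expect_equal(matchKey(m), matchKey(bruteMEMs(a, b, 4)))
})

test_that("reverse-complement matches are found only when asked", {
    set.seed(31)
    a <- randDNA(600)
    seg <- substr(a, 201, 320)
    rcseg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    b <- plantSegment(randDNA(600), rcseg, 101)
    fwd <- findMaximalExactMatches(a, b, minLen = 50)
    expect_equal(nrow(fwd), 0L)
    both <- findMaximalExactMatches(a, b, minLen = 50, revComp = TRUE)
    expect_equal(both$strand, "-")
    expect_true(any(both$length >= 120))
})

test_that("occurrence pairs of a repeated substring can be collapsed", {
    set.seed(41)
    seg <- randDNA(60)
    a <- paste0(randDNA(100), seg, randDNA(100), seg, randDNA(100))
    b <- paste0(randDNA(50), seg, randDNA(50))
    m <- findMaximalExactMatches(a, b, minLen = 30)
    expect_equal(nrow(m), 2L) # both occurrence pairs reported by default
    m1 <- findMaximalExactMatches(a, b, minLen = 30,
                                  perOccurrencePair = FALSE)
    expect_equal(nrow(m1), 1L)
})

test_that("MEM finder rejects degenerate input", {
    expect_error(findMaximalExactMatches("", "ACGT", minLen = 2),
                 "non-empty")
    expect_error(findMaximalExactMatches("ACGT", "ACGT", minLen = 1),
                 "minLen")
    expect_error(findMaximalExactMatches("AC-GT", "ACGT", minLen = 2),
                 "alphabet")
})

test_that("interval intersection yields shared multi-genus regions", {
    pw <- function(starts, lengths, partner) {
        data.frame(genome_a = "r", genome_b = partner,
                   start_a = starts, start_b = 0, length = lengths)
    }
    one <- intersectToMultiMatch(
        list(B = pw(100, 500, "b1"), C = pw(300, 600, "c1")),
        minLen = 200, refGenus = "A")
    expect_equal(one$ref_start, 300)
    expect_equal(one$ref_end, 600)
    expect_equal(one$length, 300)
    expect_equal(one$genus_set, "A,B,C")

    none <- intersectToMultiMatch(
        list(B = pw(0, 500, "b1"), C = pw(600, 300, "c1")),
        minLen = 100, refGenus = "A")
    expect_equal(nrow(none), 0L)

    two <- intersectToMultiMatch(
        list(B = pw(c(0, 450), c(400, 550), "b1"),
             C = pw(200, 600, "c1")),
        minLen = 100, refGenus = "A")
    expect_equal(two$ref_start, c(200, 450))
    expect_equal(two$ref_end, c(400, 800))

    bad <- list(B = pw(0, 500, "b1"),
                C = data.frame(genome_a = "other", genome_b = "c1",
                               start_a = 0, start_b = 0, length = 500))
    expect_error(intersectToMultiMatch(bad, minLen = 100), "same reference")
})

test_that("multi-genus regions occur verbatim in every partner genome", {
    set.seed(57)
    ref <- randDNA(3000)
    core <- substr(ref, 1001, 1800) # 800 bp shared by everyone
    gB <- plantSegment(randDNA(3000), substr(ref, 801, 2000), 401)
    gC <- plantSegment(randDNA(3000), core, 2101)
    gs <- GenomeSet(c(r1 = ref, b1 = gB, c1 = gC),
                    taxon = c("A", "B", "C"))
    mm <- multiMatches(gs, c("A", "B", "C"), minLen = 300)
    expect_gt(nrow(mm), 0)
    for (k in seq_len(nrow(mm))) {
        seg <- substr(ref, mm$ref_start[k] + 1, mm$ref_end[k])
        expect_true(grepl(seg, gB, fixed = TRUE))
        expect_true(grepl(seg, gC, fixed = TRUE))
    }
    # lengths reported by the accessor match the table
    expect_equal(matchLengths(gs, c("A", "B", "C"), minLen = 300),
                 as.numeric(mm$length))
})

test_that("comparison counting is the product of per-genus genome counts", {
    seqs <- stats::setNames(replicate(7, randDNA(50)), paste0("g", 1:7))
    gs <- GenomeSet(seqs, taxon = c("A", "A", "A", "B", "B", "B", "B"))
    cc <- countComparisons(gs, c("A", "B"))
    expect_equal(unname(cc$counts), c(3, 4))
    expect_equal(cc$total, 12)
    one <- GenomeSet(stats::setNames(replicate(3, randDNA(50)),
                                     c("x", "y", "z")),
                     taxon = c("A", "B", "C"))
    expect_equal(countComparisons(one, c("A", "B", "C"))$total, 1)
    eight <- GenomeSet(stats::setNames(replicate(16, randDNA(30)),
                                       paste0("g", 1:16)),
                       taxon = rep(LETTERS[1:8], each = 2))
    expect_equal(countComparisons(eight, LETTERS[1:8])$total, 256)
    expect_error(countComparisons(gs, c("A", "Z")), "not in the collection")
})

test_that("match tables round-trip through TSV including 1-based mode", {
    set.seed(3)
    a <- randDNA(400)
    b <- plantSegment(randDNA(400), substr(a, 51, 150), 201)
    gs <- GenomeSet(c(x = a, y = b), taxon = c("A", "B"))
    m <- pairMatches(gs, "x", "y", minLen = 40)
    f <- tempfile(fileext = ".tsv")
    writeMatches(m, f, oneBased = TRUE)
    back <- readMatches(f, oneBased = TRUE)
    expect_equal(back$start_a, m$start_a)
    expect_equal(back$start_b, m$start_b)
    raw <- utils::read.delim(f)
    expect_equal(raw$start_a, m$start_a + 1L)
})
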