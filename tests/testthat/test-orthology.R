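makeGenes <- function(ids, species, ranks = seq_along(ids),
                      proteins = rep("MKVLAAGG", length(ids))) {
    data.frame(gene_id = ids, species = species, chromosome = "chr1",
               start = ranks * 3000L, end = ranks * 3000L + 1000L,
               strand = "+", rank = ranks, protein = proteins)
}

makeHits <- function(q, s, bitscore = 100) {
    data.frame(qseqid = q, sseqid = s, pident = 100, length = 8L,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 8L,
               sstart = 1L, send = 8L, evalue = 0, bitscore = bitscore)
}

test_that("identical gene orders form a single full-length block", {
    gA <- makeGenes(paste0("A", 1:5), "A")
    gB <- makeGenes(paste0("B", 1:5), "B")
    hits <- makeHits(gA$gene_id, gB$gene_id)
    bl <- detectCollinearBlocks(gA, gB, hits)
    expect_length(bl, 1L)
    expect_identical(bl[[1]]$size, 5L)
    expect_identical(bl[[1]]$orientation, 1L)
})

test_that("a reversed middle segment becomes its own block, flanks none", {
    gA <- makeGenes(paste0("A", 1:5), "A")
    gB <- makeGenes(paste0("B", 1:5), "B", ranks = c(1L, 4L, 3L, 2L, 5L))
    hits <- makeHits(gA$gene_id, gB$gene_id)
    bl <- detectCollinearBlocks(gA, gB, hits)
    expect_length(bl, 1L)
    expect_identical(bl[[1]]$orientation, -1L)
    expect_identical(sort(bl[[1]]$pairs$geneA), c("A2", "A3", "A4"))
})

test_that("unknown gene ids in hits are rejected", {
    gA <- makeGenes("A1", "A"); gB <- makeGenes("B1", "B")
    expect_error(detectCollinearBlocks(gA, gB, makeHits("A1", "Bxx")),
                 "unknown gene")
})

test_that("planted inversions are recovered exactly, none spurious", {
    toy <- simulateToyGenomes(100, nInversions = 2, seed = 31)
    bl <- detectCollinearBlocks(toy$genesA, toy$genesB, toy$hits)
    revBlocks <- Filter(function(b) b$orientation == -1L, bl)
    expect_length(revBlocks, 2L)
    planted <- lapply(toy$registry$inversions, function(seg)
        sort(toy$genesA$gene_id[seg]))
    found <- lapply(revBlocks, function(b) sort(b$pairs$geneA))
    expect_setequal(vapply(found, paste, character(1), collapse = ","),
                    vapply(planted, paste, character(1), collapse = ","))
    # every true ortholog pair sits in at least one block
    inBlocks <- unique(unlist(lapply(bl, function(b) b$pairs$geneA)))
    expect_setequal(inBlocks, toy$genesA$gene_id)
})

test_that("pair parsing applies the four rules in order", {
    gA <- makeGenes(paste0("A", 1:5), "A")
    gB <- makeGenes(paste0("B", 1:5), "B")
    hits <- makeHits(gA$gene_id, gB$gene_id)
    bl <- detectCollinearBlocks(gA, gB, hits)

    # rule 1: identity at the threshold is retained
    pairs <- resolveOrthologPairs(bl, hits, gA, gB,
                                  identityFun = function(a, b) 96)
    expect_identical(nrow(pairs), 5L)

    # low identity with no better rival is still retained
    pairs <- resolveOrthologPairs(bl, hits, gA, gB,
                                  identityFun = function(a, b) 90)
    expect_identical(nrow(pairs), 5L)

    # rule 2: low identity + strictly better rival hit removes the pair
    hits2 <- rbind(hits, makeHits("A2", "B4", bitscore = 500))
    bl2 <- detectCollinearBlocks(gA, gB, hits2)
    pairs2 <- resolveOrthologPairs(bl2, hits2, gA, gB,
                                   identityFun = function(a, b) 90)
    expect_false(any(pairs2$geneA == "A2" & pairs2$geneB == "B2"))
    # ...but an equal-bitscore rival does not ("better" is strict)
    hits3 <- rbind(hits, makeHits("A2", "B4", bitscore = 100))
    pairs3 <- resolveOrthologPairs(detectCollinearBlocks(gA, gB, hits3),
                                   hits3, gA, gB,
                                   identityFun = function(a, b) 90)
    expect_true(any(pairs3$geneA == "A2" & pairs3$geneB == "B2"))
})

test_that("a gene in two blocks keeps only the larger block's pair", {
    # genome A: 3-gene run on chr1 and 7-gene run on chr2; gene A1 pairs
    # with B1 in both (duplicated anchor via an extra hit)
    gA <- rbind(makeGenes(paste0("A", 1:3), "A"),
                makeGenes(paste0("A", 4:10), "A"))
    gA$chromosome <- rep(c("chr1", "chr2"), c(3, 7))
    gA$rank <- c(1:3, 1:7)
    gB <- rbind(makeGenes(paste0("B", 1:3), "B"),
                makeGenes(paste0("B", 4:10), "B"))
    gB$chromosome <- rep(c("chr1", "chr2"), c(3, 7))
    gB$rank <- c(1:3, 1:7)
    hits <- makeHits(gA$gene_id, gB$gene_id)
    bl <- detectCollinearBlocks(gA, gB, hits)
    sizes <- vapply(bl, `[[`, integer(1), "size")
    expect_setequal(sizes, c(3L, 7L))
    # force the same pair (A1,B1) to appear in both blocks
    blDup <- bl
    small <- which(sizes == 3L); big <- which(sizes == 7L)
    blDup[[big]]$pairs <- rbind(blDup[[big]]$pairs, blDup[[small]]$pairs[1, ])
    blDup[[big]]$size <- nrow(blDup[[big]]$pairs)
    pairs <- resolveOrthologPairs(blDup, hits, gA, gB,
                                  identityFun = function(a, b) 100)
    a1 <- pairs[pairs$geneA == "A1", ]
    expect_identical(nrow(a1), 1L)
    expect_identical(a1$blockSize, 8L)  # the larger block won
})

test_that("tandem duplicates remove their pairs", {
    toy <- simulateToyGenomes(30, nTandem = 2, seed = 13)
    bl <- detectCollinearBlocks(toy$genesA, toy$genesB, toy$hits)
    pairs <- resolveOrthologPairs(bl, toy$hits, toy$genesA, toy$genesB,
                                  identityFun = function(a, b) 100)
    parents <- sub("d$", "", toy$registry$tandemGenes)
    expect_false(any(pairs$geneB %in%
                     c(parents, toy$registry$tandemGenes)))
    expect_identical(nrow(pairs), 28L)
    expect_identical(anyDuplicated(pairs$geneA), 0L)
    expect_identical(anyDuplicated(pairs$geneB), 0L)
})

test_that("the default identity uses a global alignment", {
    # 9/10 identical residues under a gapless global alignment
    expect_equal(globalPercentIdentity("MKVLAAGGHH", "MKVLAAGGHY"), 90)
    expect_equal(globalPercentIdentity("MKVL", "MKVL"), 100)
})

test_that("families are the human-pivot intersection of three pair lists", {
    hc <- data.frame(geneA = paste0("H", 1:100),
                     geneB = paste0("C", 1:100))
    hg <- data.frame(geneA = paste0("H", 1:100),
                     geneB = paste0("G", 1:100))
    hb <- data.frame(geneA = paste0("H", 11:100),
                     geneB = paste0("B", 11:100))  # 10 lost in gibbon
    fam <- assembleFamilies(hc, hg, hb)
    expect_identical(nrow(fam), 90L)
    expect_identical(attr(fam, "attrition")[["Gibbon"]], 10L)
    expect_false("H5" %in% fam$Human)
    # duplicated human gene violates the 1:1 precondition
    bad <- rbind(hc, data.frame(geneA = "H1", geneB = "C999"))
    expect_error(assembleFamilies(bad, hg, hb), "not 1:1")
})

test_that("raising minGenes never increases the number of blocks", {
    toy <- simulateToyGenomes(60, nInversions = 2, seed = 41)
    nBlocks <- vapply(2:6, function(mg)
        length(detectCollinearBlocks(toy$genesA, toy$genesB, toy$hits,
                                     minGenes = mg)), integer(1L))
    expect_true(all(diff(nBlocks) <= 0L))
})

test_that("fully collinear genomes with high identity yield every gene", {
    toy <- simulateToyGenomes(40, seed = 8)
    bl <- detectCollinearBlocks(toy$genesA, toy$genesB, toy$hits)
    pairs <- resolveOrthologPairs(bl, toy$hits, toy$genesA, toy$genesB)
    expect_identical(nrow(pairs), 40L)
    expect_true(all(pairs$identity == 100))
})

test_that("gene tables and hit tables round-trip through disk", {
    toy <- simulateToyGenomes(15, seed = 6)
    gf <- tempfile(fileext = ".tsv"); hf <- tempfile(fileext = ".tsv")
    writeGeneTable(toy$genesA, gf)
    writeBlastTab(toy$hits, hf)
    back <- readGeneTable(gf, species = "A")
    expect_identical(back$gene_id, toy$genesA$gene_id)
    expect_identical(back$rank, toy$genesA$rank)
    hitsBack <- readBlastHits(hf)
    expect_identical(hitsBack$qseqid, toy$hits$qseqid)
    expect_equal(hitsBack$bitscore, toy$hits$bitscore)
})
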