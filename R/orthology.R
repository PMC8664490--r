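#' Detect collinear (syntenic) blocks between two gene orders
#'
#' Deterministic anchor chaining on gene ranks. Homology hits between the two
#' genomes are the anchors; within each chromosome pair the anchors are
#' sorted by query rank and scanned once per orientation. A chain extends
#' from one anchor to the next while both genomes advance by at most
#' `maxGap + 1` ranks in the chain's orientation (forward in the query,
#' forward or backward in the subject); a violating anchor closes the chain
#' and starts a new one. Chains with fewer than `minGenes` anchors are
#' discarded. An anchor may belong to one chain per orientation, so blocks
#' from the two orientations can overlap; such overlaps are resolved by
#' [resolveOrthologPairs()].
#'
#' @param genesA,genesB gene data frames with columns `gene_id`,
#'   `chromosome`, `rank` (see [readGeneTable()]).
#' @param hits homology hit data frame with columns `qseqid`, `sseqid`,
#'   `bitscore` (12-column BLAST tabular accepted). Hits may be given in
#'   either direction; they are normalised to A-vs-B.
#' @param minGenes minimum number of collinear gene pairs per block.
#' @param maxGap maximum number of intervening genes between consecutive
#'   pairs of a block, in either genome.
#' @return List of blocks; each is a list with `pairs` (data frame `geneA`,
#'   `geneB`, `rankA`, `rankB`), `size`, `orientation` (+1/-1), `chromA`,
#'   `chromB`.
#' @examples
#' toy <- simulateToyGenomes(20, seed = 1)
#' length(detectCollinearBlocks(toy$genesA, toy$genesB, toy$hits))
#' @export
detectCollinearBlocks <- function(genesA, genesB, hits, minGenes = 3L,
                                  maxGap = 2L) {
    known <- c(genesA$gene_id, genesB$gene_id)
    bad <- setdiff(unique(c(hits$qseqid, hits$sseqid)), known)
    if (length(bad))
        stop("hits reference unknown gene id(s): ",
             paste(head(bad, 5L), collapse = ", "))

    ## normalise hits to A-query / B-subject anchors
    fwd <- hits[hits$qseqid %in% genesA$gene_id &
                hits$sseqid %in% genesB$gene_id, c("qseqid", "sseqid")]
    rev_ <- hits[hits$qseqid %in% genesB$gene_id &
                 hits$sseqid %in% genesA$gene_id, c("sseqid", "qseqid")]
    names(rev_) <- c("qseqid", "sseqid")
    anchors <- unique(rbind(fwd, rev_))
    if (!nrow(anchors)) return(list())

    ia <- match(anchors$qseqid, genesA$gene_id)
    ib <- match(anchors$sseqid, genesB$gene_id)
    anchors <- data.frame(geneA = anchors$qseqid, geneB = anchors$sseqid,
                          chromA = genesA$chromosome[ia],
                          rankA = genesA$rank[ia],
                          chromB = genesB$chromosome[ib],
                          rankB = genesB$rank[ib])

    blocks <- list()
    maxStep <- maxGap + 1L
    for (key in unique(paste(anchors$chromA, anchors$chromB))) {
        grp <- anchors[paste(anchors$chromA, anchors$chromB) == key, ,
                       drop = FALSE]
        grp <- grp[order(grp$rankA, grp$rankB), , drop = FALSE]
        for (orientation in c(1L, -1L)) {
            chain <- integer(0)
            flush <- function(chain) {
                if (length(chain) >= minGenes) {
                    pr <- grp[chain, c("geneA", "geneB", "rankA", "rankB")]
                    rownames(pr) <- NULL
                    blocks[[length(blocks) + 1L]] <<-
                        list(pairs = pr, size = nrow(pr),
                             orientation = orientation,
                             chromA = grp$chromA[1L], chromB = grp$chromB[1L])
                }
            }
            for (i in seq_len(nrow(grp))) {
                if (length(chain)) {
                    last <- chain[length(chain)]
                    dA <- grp$rankA[i] - grp$rankA[last]
                    dB <- orientation * (grp$rankB[i] - grp$rankB[last])
                    ## a second hit of an already-chained gene (rank step 0
                    ## in either genome) cannot extend the chain but must
                    ## not sever it either: skip it
                    if (dA == 0L || dB == 0L) next
                    ok <- dA <= maxStep && dB >= 1L && dB <= maxStep
                } else ok <- FALSE
                if (ok) chain <- c(chain, i)
                else { flush(chain); chain <- i }
            }
            flush(chain)
        }
    }
    blocks
}

#' Global-alignment percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap opening 10 and gap
#' extension 0.5, reporting identical positions per alignment column
#' (including gap columns in the denominator). This is the identity used to
#' vet syntenic gene pairs.
#'
#' @param seqA,seqB amino-acid strings.
#' @param pidType denominator convention passed to [Biostrings::pid()];
#'   `"PID1"` divides by the alignment length.
#' @return Percent identity in \[0, 100\].
#' @export
globalPercentIdentity <- function(seqA, seqB, pidType = "PID1") {
    aln <- pairwiseAlignment(AAStringSet(seqA), AAStringSet(seqB),
                             type = "global",
                             substitutionMatrix = "BLOSUM62",
                             gapOpening = 10, gapExtension = 0.5)
    pid(aln, type = pidType)
}

## Tandem duplicates: two hits from one query to same-species genes at
## adjacent ranks (same chromosome, rank distance <= maxDist).
findTandemDuplicates <- function(hits, genes, maxDist = 1L) {
    sub <- hits[hits$sseqid %in% genes$gene_id, , drop = FALSE]
    tandem <- character(0)
    for (q in unique(sub$qseqid)) {
        s <- unique(sub$sseqid[sub$qseqid == q])
        if (length(s) < 2L) next
        i <- match(s, genes$gene_id)
        ch <- genes$chromosome[i]; rk <- genes$rank[i]
        for (a in seq_along(s)[-length(s)])
            for (b in (a + 1L):length(s))
                if (ch[a] == ch[b] && abs(rk[a] - rk[b]) <= maxDist)
                    tandem <- c(tandem, s[a], s[b])
    }
    unique(tandem)
}

#' Resolve collinear gene pairs into 1:1 ortholog pairs
#'
#' Applies the four parsing rules to the candidate pairs of the collinear
#' blocks, in order: (1) a pair with global-alignment identity at or above
#' `identityThreshold` is retained outright; (2) otherwise the pair is
#' dropped if either member has a strictly higher bitscore hit to a
#' different gene of the other species; (3) a gene occurring in pairs of
#' more than one block keeps only the pair in the larger block (gene-pair
#' count; ties keep the first encountered and are flagged); (4) pairs
#' containing a tandem duplicate (two same-species hits from one query at
#' adjacent ranks) are dropped. The result is 1:1 within the species pair.
#'
#' @param blocks block list from [detectCollinearBlocks()].
#' @param hits homology hit data frame (used for rules 2 and 4).
#' @param genesA,genesB gene data frames; `protein` columns supply the
#'   default identity computation, ranks supply tandem detection.
#' @param identityFun function(seqA, seqB) -> percent identity; defaults to
#'   [globalPercentIdentity()]. A failure on any candidate aborts with the
#'   offending pair named.
#' @param identityThreshold retention threshold, percent (default 95).
#' @param tandemMaxDist maximum rank distance defining a tandem duplicate.
#' @return Data frame of retained pairs: `geneA`, `geneB`, `blockSize`,
#'   `identity`, `tieFlagged`.
#' @export
resolveOrthologPairs <- function(blocks, hits, genesA, genesB,
                                 identityFun = NULL,
                                 identityThreshold = 95,
                                 tandemMaxDist = 1L) {
    if (!length(blocks))
        return(data.frame(geneA = character(0), geneB = character(0),
                          blockSize = integer(0), identity = numeric(0),
                          tieFlagged = logical(0)))
    if (is.null(identityFun))
        identityFun <- function(a, b) globalPercentIdentity(a, b)

    cand <- do.call(rbind, lapply(seq_along(blocks), function(i) {
        p <- blocks[[i]]$pairs
        data.frame(geneA = p$geneA, geneB = p$geneB, blockId = i,
                   blockSize = blocks[[i]]$size)
    }))
    ## a pair may sit in several blocks; keep one row per (pair, block)
    cand <- unique(cand)

    ## rule 1: identity; computed once per distinct gene pair
    pairKey <- paste(cand$geneA, cand$geneB)
    uniqPairs <- !duplicated(pairKey)
    ident <- setNames(rep(NA_real_, sum(uniqPairs)), pairKey[uniqPairs])
    for (k in which(uniqPairs)) {
        a <- genesA$protein[match(cand$geneA[k], genesA$gene_id)]
        b <- genesB$protein[match(cand$geneB[k], genesB$gene_id)]
        ident[pairKey[k]] <- tryCatch(identityFun(a, b), error = function(e)
            stop("identity computation failed for pair ", cand$geneA[k],
                 " / ", cand$geneB[k], ": ", conditionMessage(e),
                 call. = FALSE))
    }
    cand$identity <- ident[pairKey]

    ## rule 2: for pairs below threshold, drop if either gene has a strictly
    ## better bitscore hit to a different gene of the other species
    bestOther <- function(gene, partner, otherGenes) {
        h <- hits[(hits$qseqid == gene & hits$sseqid %in% otherGenes) |
                  (hits$sseqid == gene & hits$qseqid %in% otherGenes), ,
                  drop = FALSE]
        other <- ifelse(h$qseqid == gene, h$sseqid, h$qseqid)
        pairScore <- suppressWarnings(max(h$bitscore[other == partner], -Inf))
        rivalScore <- suppressWarnings(max(h$bitscore[other != partner], -Inf))
        rivalScore > pairScore
    }
    low <- which(cand$identity < identityThreshold)
    dropRule2 <- logical(nrow(cand))
    for (k in low) {
        dropRule2[k] <- bestOther(cand$geneA[k], cand$geneB[k],
                                  genesB$gene_id) ||
                        bestOther(cand$geneB[k], cand$geneA[k],
                                  genesA$gene_id)
    }
    cand <- cand[!dropRule2, , drop = FALSE]

    ## rule 3: gene in pairs of two blocks -> keep pair in the larger block
    ## (iterate by descending block size, first encountered wins; ties flagged)
    cand <- cand[order(-cand$blockSize, cand$blockId), , drop = FALSE]
    seenA <- character(0); seenB <- character(0)
    keep <- logical(nrow(cand)); tie <- logical(nrow(cand))
    sizeOfA <- list(); sizeOfB <- list()
    for (k in seq_len(nrow(cand))) {
        a <- cand$geneA[k]; b <- cand$geneB[k]
        if (a %in% seenA || b %in% seenB) {
            tiedA <- a %in% seenA && identical(sizeOfA[[a]], cand$blockSize[k])
            tiedB <- b %in% seenB && identical(sizeOfB[[b]], cand$blockSize[k])
            if (tiedA || tiedB) {
                prev <- which(keep & (cand$geneA == a | cand$geneB == b))
                tie[prev] <- TRUE
            }
            next
        }
        keep[k] <- TRUE
        seenA <- c(seenA, a); seenB <- c(seenB, b)
        sizeOfA[[a]] <- cand$blockSize[k]; sizeOfB[[b]] <- cand$blockSize[k]
    }
    cand$tieFlagged <- tie
    cand <- cand[keep, , drop = FALSE]

    ## rule 4: drop pairs containing a tandem duplicate
    tandem <- c(findTandemDuplicates(hits, genesA, tandemMaxDist),
                findTandemDuplicates(hits, genesB, tandemMaxDist))
    cand <- cand[!(cand$geneA %in% tandem | cand$geneB %in% tandem), ,
                 drop = FALSE]

    rownames(cand) <- NULL
    cand[, c("geneA", "geneB", "blockSize", "identity", "tieFlagged")]
}

#' Assemble four-species ortholog families from human-pivot pair lists
#'
#' Intersects three 1:1 pair lists (human vs chimpanzee, gorilla, gibbon) on
#' the human gene id; a family is formed only when the human gene has an
#' ortholog in all three lists. Attrition per species is recorded as an
#' attribute.
#'
#' @param pairsHC,pairsHG,pairsHB pair data frames from
#'   [resolveOrthologPairs()], with the human gene in `geneA`.
#' @return Data frame with columns `Human`, `Chimpanzee`, `Gorilla`,
#'   `Gibbon`; attribute `attrition` counts human genes present in some but
#'   not all lists.
#' @export
assembleFamilies <- function(pairsHC, pairsHG, pairsHB) {
    for (nm in c("pairsHC", "pairsHG", "pairsHB")) {
        p <- get(nm)
        if (anyDuplicated(p$geneA) || anyDuplicated(p$geneB))
            stop(nm, " is not 1:1: duplicated gene id")
    }
    common <- Reduce(intersect, list(pairsHC$geneA, pairsHG$geneA,
                                     pairsHB$geneA))
    fam <- data.frame(
        Human = common,
        Chimpanzee = pairsHC$geneB[match(common, pairsHC$geneA)],
        Gorilla = pairsHG$geneB[match(common, pairsHG$geneA)],
        Gibbon = pairsHB$geneB[match(common, pairsHB$geneA)])
    allHuman <- unique(c(pairsHC$geneA, pairsHG$geneA, pairsHB$geneA))
    attr(fam, "attrition") <- c(
        Chimpanzee = length(setdiff(allHuman, pairsHC$geneA)),
        Gorilla = length(setdiff(allHuman, pairsHG$geneA)),
        Gibbon = length(setdiff(allHuman, pairsHB$geneA)))
    fam
}
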