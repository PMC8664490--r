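#' Simulate a pair of toy genomes with planted synteny features
#'
#' Builds two single-chromosome gene orders related by a known permutation:
#' genome B starts as a copy of genome A's order, then `nInversions`
#' non-overlapping segments (3-6 genes each) are reversed, and `nTandem`
#' genes receive an adjacent duplicate copy in B. Every true ortholog pair
#' gets a strong homology hit; each tandem duplicate gets a weaker hit from
#' the same query, so it is detectable by the adjacent-rank rule. The planted
#' feature registry is returned for assertions.
#'
#' @param nGenes number of genes (>= 10).
#' @param nInversions number of reversed segments planted in genome B.
#' @param nTandem number of tandem duplicates planted in genome B.
#' @param seed RNG seed.
#' @param proteinLength length of the random protein assigned to each
#'   ortholog group (identical across the pair, so pairwise identity is 100).
#' @return A list with `genesA` and `genesB` (data frames with columns
#'   `gene_id`, `species`, `chromosome`, `start`, `end`, `strand`, `rank`,
#'   `protein`), `hits` (12-column BLAST-tabular data frame), and `registry`
#'   (`truePairs`, `inversions` as a list of A-rank vectors, `tandemGenes`).
#' @examples
#' toy <- simulateToyGenomes(20, nInversions = 1, seed = 3)
#' toy$registry$inversions
#' @export
simulateToyGenomes <- function(nGenes, nInversions = 0, nTandem = 0,
                               seed = 1, proteinLength = 60L) {
    if (nGenes < 10L)
        stop("nGenes must be >= 10")
    if (nInversions * 6L + nTandem > nGenes)
        stop("planted feature counts exceed what ", nGenes, " genes can hold")
    withSeed(seed, {
        idsA <- sprintf("A%04d", seq_len(nGenes))
        idsB <- sprintf("B%04d", seq_len(nGenes))
        prots <- vapply(seq_len(nGenes), function(i)
            paste0(sample(Biostrings::AA_STANDARD, proteinLength,
                          replace = TRUE), collapse = ""), character(1L))

        ## order of B expressed as indices into the ortholog groups
        ordB <- seq_len(nGenes)
        strandB <- rep("+", nGenes)
        inversions <- list()
        if (nInversions > 0L) {
            ## carve non-overlapping segments from a shuffled partition
            avail <- rep(TRUE, nGenes)
            for (k in seq_len(nInversions)) {
                segLen <- sample(3:6, 1L)
                starts <- which(vapply(seq_len(nGenes - segLen + 1L),
                    function(s) all(avail[s:(s + segLen - 1L)]), logical(1L)))
                if (!length(starts))
                    stop("could not place inversion ", k,
                         "; reduce nInversions")
                s <- sample(starts, 1L)
                seg <- s:(s + segLen - 1L)
                ordB[seg] <- rev(ordB[seg])
                strandB[seg] <- "-"
                ## guard genes so segments stay non-overlapping and non-adjacent
                avail[max(1L, s - 1L):min(nGenes, s + segLen)] <- FALSE
                inversions[[k]] <- seg
            }
        }

        tandemOf <- integer(0)
        if (nTandem > 0L) {
            eligible <- setdiff(seq_len(nGenes), unlist(inversions))
            tandemOf <- sort(sample(eligible, nTandem))
        }

        genesA <- data.frame(gene_id = idsA, species = "A",
                             chromosome = "chrA1",
                             start = (seq_len(nGenes) - 1L) * 3000L + 1L,
                             end = (seq_len(nGenes) - 1L) * 3000L + 1000L,
                             strand = "+", rank = seq_len(nGenes),
                             protein = prots)

        ## build B gene list in B order, inserting tandem copies
        bRows <- list()
        for (pos in seq_len(nGenes)) {
            grp <- ordB[pos]
            bRows[[length(bRows) + 1L]] <-
                list(gene_id = idsB[grp], group = grp, strand = strandB[pos])
            if (grp %in% tandemOf)
                bRows[[length(bRows) + 1L]] <-
                    list(gene_id = paste0(idsB[grp], "d"), group = grp,
                         strand = strandB[pos])
        }
        nB <- length(bRows)
        genesB <- data.frame(
            gene_id = vapply(bRows, `[[`, character(1L), "gene_id"),
            species = "B", chromosome = "chrB1",
            start = (seq_len(nB) - 1L) * 3000L + 1L,
            end = (seq_len(nB) - 1L) * 3000L + 1000L,
            strand = vapply(bRows, `[[`, character(1L), "strand"),
            rank = seq_len(nB),
            protein = prots[vapply(bRows, `[[`, integer(1L), "group")])

        ## homology hits: true pair (strong) + duplicate (slightly weaker)
        hit <- function(q, s, bits, pident)
            data.frame(qseqid = q, sseqid = s, pident = pident,
                       length = proteinLength, mismatch = 0L, gapopen = 0L,
                       qstart = 1L, qend = proteinLength, sstart = 1L,
                       send = proteinLength, evalue = 1e-30, bitscore = bits)
        hits <- do.call(rbind, c(
            lapply(seq_len(nGenes), function(i)
                hit(idsA[i], idsB[i], 500, 100)),
            lapply(tandemOf, function(i)
                hit(idsA[i], paste0(idsB[i], "d"), 450, 98))))

        list(genesA = genesA, genesB = genesB, hits = hits,
             registry = list(
                 truePairs = data.frame(geneA = idsA, geneB = idsB),
                 inversions = inversions,
                 tandemGenes = paste0(idsB[tandemOf], "d")))
    })
}

#' Write a toy genome as a GFF3-like gene table and hits as BLAST tabular
#'
#' @param genes gene table as produced by [simulateToyGenomes()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writeGeneTable <- function(genes, path) {
    gff <- data.frame(seqid = genes$chromosome, source = "apeClock",
                      type = "gene", start = genes$start, end = genes$end,
                      score = ".", strand = genes$strand, phase = ".",
                      attributes = paste0("ID=", genes$gene_id))
    write.table(gff, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeGeneTable
#' @param hits 12-column hit table.
#' @export
writeBlastTab <- function(hits, path) {
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a GFF3-like gene table written by [writeGeneTable()]
#'
#' Gene rank along each chromosome is assigned by start coordinate.
#'
#' @param path TSV path.
#' @param species species label to attach.
#' @return Gene data frame with `gene_id`, `species`, `chromosome`, `start`,
#'   `end`, `strand`, `rank`.
#' @export
readGeneTable <- function(path, species = NA_character_) {
    gff <- read.delim(path, header = FALSE,
                      col.names = c("seqid", "source", "type", "start",
                                    "end", "score", "strand", "phase",
                                    "attributes"))
    gff <- gff[gff$type == "gene", , drop = FALSE]
    id <- sub("^.*ID=([^;]+).*$", "\\1", gff$attributes)
    genes <- data.frame(gene_id = id, species = species,
                        chromosome = gff$seqid, start = gff$start,
                        end = gff$end, strand = gff$strand)
    genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
    genes$rank <- ave(seq_len(nrow(genes)), genes$chromosome,
                      FUN = seq_along)
    rownames(genes) <- NULL
    genes
}

#' @rdname readGeneTable
#' @export
readBlastHits <- function(path) {
    read.delim(path, header = FALSE,
               col.names = c("qseqid", "sseqid", "pident", "length",
                             "mismatch", "gapopen", "qstart", "qend",
                             "sstart", "send", "evalue", "bitscore"))
}
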