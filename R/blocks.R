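## Convert a 4-sequence alignment into a character matrix (4 x L).
msaMatrix <- function(msa) {
    if (is.matrix(msa)) {
        if (nrow(msa) != 4L) stop("alignment must have exactly 4 sequences")
        if (is.null(rownames(msa))) rownames(msa) <- .SPECIES
        return(msa)
    }
    if (is.character(msa)) msa <- AAStringSet(msa)
    if (length(msa) != 4L) stop("alignment must have exactly 4 sequences")
    w <- Biostrings::width(msa)
    if (length(unique(w)) != 1L)
        stop("aligned sequences must have equal lengths")
    m <- t(vapply(as.character(msa), function(s)
        strsplit(s, "", fixed = TRUE)[[1L]], character(w[1L])))
    rownames(m) <- if (is.null(names(msa))) .SPECIES else names(msa)
    m
}

#' Reduce a family alignment to its gap-free conserved blocks
#'
#' Re-implementation of the conserved-block filter applied to every family
#' alignment, with the parameter set used throughout the package: with four
#' sequences and conserved/flanking minima equal to the sequence number, a
#' column is conserved iff all four residues are identical and non-gap.
#' Any column containing a gap is removed and splits the alignment. Within
#' each gap-free segment, maximal runs of more than `maxNonconservedRun`
#' consecutive non-conserved columns are removed entirely and split the
#' segment further. Segment ends are trimmed so that every block starts and
#' ends on a conserved column, and blocks shorter than `minBlock` columns
#' are discarded. The surviving columns, concatenated, form the alignment
#' overlap `L`.
#'
#' @param msa the aligned family: an `AAStringSet` of four equal-width
#'   sequences, a character vector of four aligned strings, or a 4-row
#'   character matrix. Gap symbol `-`.
#' @param minBlock minimum block length in columns (default 10).
#' @param maxNonconservedRun longest run of consecutive non-conserved
#'   columns allowed inside a block (default 2).
#' @param familyId identifier stored in the result.
#' @return A \linkS4class{FilteredAlignment}. Families where no block
#'   survives have `L == 0` (non-overlapping) and are excluded from all
#'   downstream statistics.
#' @examples
#' msa <- c(H = paste(rep("A", 50), collapse = ""),
#'          C = paste(rep("A", 50), collapse = ""),
#'          G = paste(rep("A", 50), collapse = ""),
#'          B = paste(rep("A", 50), collapse = ""))
#' alignmentOverlap(filterBlocks(msa))
#' @export
filterBlocks <- function(msa, minBlock = 10L, maxNonconservedRun = 2L,
                         familyId = "family") {
    m <- msaMatrix(msa)
    L0 <- ncol(m)
    letters_ok <- c(Biostrings::AA_STANDARD, "-")
    if (!all(m %in% letters_ok))
        stop("alignment contains symbols outside the 20 amino acids + gap")

    isGap <- colSums(m == "-") > 0L
    conserved <- !isGap &
        m[1L, ] == m[2L, ] & m[2L, ] == m[3L, ] & m[3L, ] == m[4L, ]

    keep <- logical(L0)
    ## segments between gap columns
    segId <- cumsum(isGap)
    for (seg in split(which(!isGap), segId[!isGap])) {
        cons <- conserved[seg]
        ## remove non-conserved runs longer than maxNonconservedRun,
        ## splitting the segment at every removed run
        r <- rle(cons)
        bad <- !r$values & r$lengths > maxNonconservedRun
        badCol <- rep(bad, r$lengths)
        pieces <- split(seq_along(cons)[!badCol],
                        cumsum(badCol)[!badCol])
        for (p in pieces) {
            ## trim to conserved boundaries
            cs <- cons[p]
            if (!any(cs)) next
            p <- p[min(which(cs)):max(which(cs))]
            if (length(p) >= minBlock)
                keep[seg[p]] <- TRUE
        }
    }

    keptCols <- which(keep)
    blocks <- if (length(keptCols)) {
        breaks <- which(diff(keptCols) != 1L)
        IRanges(start = keptCols[c(1L, breaks + 1L)],
                end = keptCols[c(breaks, length(keptCols))])
    } else IRanges()

    seqs <- AAStringSet(apply(m[, keptCols, drop = FALSE], 1L, paste0,
                              collapse = ""))
    if (length(keptCols) == 0L)
        seqs <- AAStringSet(rep("", 4L))
    names(seqs) <- rownames(m)
    shortest <- as.integer(min(rowSums(m != "-")))
    L <- length(keptCols)
    new("FilteredAlignment", familyId = familyId, seqs = seqs,
        keptColumns = keptCols, blocks = blocks, L = L,
        shortestLen = shortest,
        saturation = alignmentSaturation(L, shortest))
}

#' Alignment saturation
#'
#' Percentage of the shortest ortholog retained in the filtered alignment:
#' `100 * L / shortestLen`, reported to two decimals. A gapless alignment
#' can never exceed the shortest sequence, so `L > shortestLen` is an
#' invariant violation.
#'
#' @param L alignment overlap (number of kept columns).
#' @param shortestLen length in residues of the shortest unaligned ortholog.
#' @return Saturation percentage, rounded to 2 decimals.
#' @examples
#' alignmentSaturation(171, 176)  # 97.16
#' @export
alignmentSaturation <- function(L, shortestLen) {
    if (shortestLen < 1L) stop("shortestLen must be >= 1")
    if (L < 0L) stop("L must be non-negative")
    if (L > shortestLen)
        stop("alignment overlap (", L, ") exceeds the shortest sequence (",
             shortestLen, "): gapless alignment invariant violated")
    round(100 * L / shortestLen, 2L)
}

#' Length variation within an ortholog family
#'
#' Maximum length difference per 100 residues of the shortest ortholog:
#' `100 * (longest - shortest) / shortest`, computed on ungapped sequence
#' lengths.
#'
#' @param seqs the four ortholog sequences: `AAStringSet`, character vector,
#'   or anything accepted by [msaMatrix] conventions. Gap characters are not
#'   counted.
#' @return Per-100-residue length difference.
#' @examples
#' lengthVariation(c("AAAA", "AAAA", "AAAA", "AAAAA"))  # 25
#' @export
lengthVariation <- function(seqs) {
    if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
    lens <- vapply(seqs, function(s)
        nchar(gsub("-", "", s, fixed = TRUE)), integer(1L))
    if (any(lens == 0L)) stop("empty sequence in family")
    100 * (max(lens) - min(lens)) / min(lens)
}
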