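#' Classify gap-free four-residue alignment columns into site patterns
#'
#' Each column of a filtered (gap-free) four-taxon alignment falls into
#' exactly one of ten mutually exclusive categories, determined by which of
#' the six pairwise identities among (human, chimpanzee, gorilla, gibbon)
#' hold:
#' \describe{
#'   \item{identical}{all four residues equal.}
#'   \item{Human/Chimpanzee/Gorilla/Gibbon}{species-specific substitution:
#'     exactly three residues equal, the named species differs (one
#'     substitution on that tip branch).}
#'   \item{Internal}{human = chimpanzee, gorilla = gibbon, the two pairs
#'     differ: one substitution on the internal human+chimp branch.}
#'   \item{inconsistent_2state}{two states paired against the species tree
#'     (human = gorilla with chimp = gibbon, or human = gibbon with
#'     chimp = gorilla).}
#'   \item{consistent_3state}{three states whose single identical pair is
#'     human+chimp or gorilla+gibbon (requires two events, consistent with
#'     the tree).}
#'   \item{inconsistent_3state}{three states whose identical pair crosses
#'     the human+chimp split.}
#'   \item{no_identity}{four distinct residues (at least three independent
#'     events; hypermutable site).}
#' }
#' Only the species-specific and Internal categories count as
#' branch-specific substitutions.
#'
#' `classifyColumn` classifies a single column; `classifyColumns` classifies
#' all columns of a 4 x L matrix (or \linkS4class{FilteredAlignment}) at
#' once.
#'
#' @param h,c_,g,b single residues for human, chimpanzee, gorilla, gibbon.
#' @return `classifyColumn`: one of [siteCategories()].
#' @examples
#' classifyColumn("A", "A", "T", "T")  # "Internal"
#' classifyColumn("V", "A", "A", "A")  # "Human"
#' @export
classifyColumn <- function(h, c_, g, b) {
    res <- c(h, c_, g, b)
    if (any(!res %in% Biostrings::AA_STANDARD))
        stop("classifyColumn requires four standard amino-acid residues ",
             "(gap-free)")
    classifyColumns(matrix(res, nrow = 4L))[1L]
}

#' @rdname classifyColumn
#' @param x 4 x L character matrix of residues (rows human, chimpanzee,
#'   gorilla, gibbon), or a \linkS4class{FilteredAlignment}.
#' @return `classifyColumns`: character vector of length L of category
#'   codes.
#' @export
classifyColumns <- function(x) {
    if (is(x, "FilteredAlignment")) x <- msaMatrix(x@seqs)
    if (!is.matrix(x) || nrow(x) != 4L)
        stop("expected a 4 x L residue matrix")
    if (ncol(x) == 0L) return(character(0))
    if (any(!x %in% Biostrings::AA_STANDARD))
        stop("columns must be gap-free standard amino acids; run ",
             "filterBlocks() first")
    h <- x[1L, ]; cc <- x[2L, ]; g <- x[3L, ]; b <- x[4L, ]
    hc <- h == cc; hg <- h == g; hb <- h == b
    cg <- cc == g; cb <- cc == b; gb <- g == b
    nEq <- hc + hg + hb + cg + cb + gb

    out <- character(ncol(x))
    out[nEq == 6L] <- "identical"
    ## exactly three equal: the lone species names the branch
    sel <- nEq == 3L
    out[sel & cg & cb] <- "Human"        # triple c,g,b
    out[sel & hg & hb] <- "Chimpanzee"   # triple h,g,b
    out[sel & hc & hb] <- "Gorilla"      # triple h,c,b
    out[sel & hc & hg] <- "Gibbon"       # triple h,c,g
    ## two disjoint pairs
    sel <- nEq == 2L
    out[sel & hc & gb] <- "Internal"
    out[sel & ((hg & cb) | (hb & cg))] <- "inconsistent_2state"
    ## one pair, three states
    sel <- nEq == 1L
    out[sel & (hc | gb)] <- "consistent_3state"
    out[sel & !(hc | gb)] <- "inconsistent_3state"
    out[nEq == 0L] <- "no_identity"
    out
}

#' Count branch-specific substitutions in a filtered family alignment
#'
#' Tallies every kept column's site-pattern category and derives the
#' per-branch substitution counts: tip branches count their
#' species-specific columns, the internal branch counts
#' human=chimpanzee / gorilla=gibbon columns, and the gibbon count
#' implicitly contains the deeper internal branch. Inconsistent,
#' consistent-three-state and no-identity columns contribute zero to every
#' branch (a branch-specific site has exactly one substitution in its
#' column).
#'
#' @param filtered a \linkS4class{FilteredAlignment} (or 4 x L residue
#'   matrix).
#' @param familyId identifier; defaults to the alignment's.
#' @return A \linkS4class{FamilyCounts}.
#' @examples
#' fam <- simulateFamily(simulationParams(seed = 5), 1)
#' countFamily(filterBlocks(fam$msa, familyId = fam$familyId))
#' @export
countFamily <- function(filtered, familyId = NULL) {
    if (is(filtered, "FilteredAlignment")) {
        if (is.null(familyId)) familyId <- filtered@familyId
        L <- filtered@L
        codes <- classifyColumns(filtered)
    } else {
        if (is.null(familyId)) familyId <- "family"
        codes <- classifyColumns(msaMatrix(filtered))
        L <- length(codes)
    }
    tab <- table(factor(codes, levels = .CATEGORIES))
    catCounts <- setNames(as.integer(tab), .CATEGORIES)
    counts <- catCounts[.BRANCHES]
    new("FamilyCounts", familyId = familyId, counts = counts,
        categoryCounts = catCounts, L = as.integer(L),
        N = as.integer(sum(counts)))
}

#' Expected number of no-identity (hypermutable) sites
#'
#' A no-identity column requires at least three independent substitution
#' events, so its expected count under independence is the product of the
#' three largest per-site branch rates and the number of aligned sites:
#' `r1 * r2 * r3 * L`.
#'
#' @param r1,r2,r3 per-site substitution rates of the three fastest
#'   lineages.
#' @param L number of aligned sites.
#' @return Expected number of no-identity sites.
#' @examples
#' expectedNoIdentity(0.0134, 0.0036, 0.0036, 7313620)  # ~1.27
#' @export
expectedNoIdentity <- function(r1, r2, r3, L) {
    rates <- c(r1, r2, r3)
    if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
        stop("rates must be in [0, 1]")
    if (L < 0) stop("L must be non-negative")
    r1 * r2 * r3 * L
}

#' Report families containing no-identity (hypermutable) columns
#'
#' Lists families with at least one no-identity column. More than one such
#' column in a single family is a hint of misalignment, so that case raises
#' a data-quality warning (not an error).
#'
#' @param countsList list of \linkS4class{FamilyCounts}.
#' @return Data frame `familyId`, `noIdentitySites` for affected families.
#' @export
hypermutableFamilies <- function(countsList) {
    n <- vapply(countsList, function(x)
        x@categoryCounts[["no_identity"]], integer(1L))
    ids <- vapply(countsList, familyId, character(1L))
    out <- data.frame(familyId = ids[n > 0L], noIdentitySites = n[n > 0L])
    if (any(out$noIdentitySites > 1L))
        warning("family with more than one no-identity column: ",
                paste(out$familyId[out$noIdentitySites > 1L],
                      collapse = ", "),
                " (possible misalignment)")
    rownames(out) <- NULL
    out
}
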