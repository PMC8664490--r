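#' Simulation parameters for synthetic ortholog families
#'
#' Holds the per-branch per-site substitution probabilities and the family-,
#' episodic- and indel-level knobs of the four-taxon sequence simulator. The
#' default branch rates are the genome-wide per-site substitution frequencies
#' of the ape dataset (% substitutions per site / 100): Human 0.0027,
#' Chimpanzee 0.0026, Internal 0.0009, Gorilla 0.0036, Gibbon 0.0134 (the
#' gibbon branch absorbing the deeper internal branch).
#'
#' @slot branchRates named numeric(5), per-site substitution probability per
#'   branch, each in \[0, 1\].
#' @slot familyShape shape of the gamma distribution (mean fixed at 1) from
#'   which the per-family rate multiplier is drawn; `Inf` disables family rate
#'   heterogeneity (multiplier identically 1).
#' @slot nFamilies number of families to generate.
#' @slot lengthRange integer(2), min/max ancestral protein length (residues).
#' @slot episodicFraction fraction of families receiving a rate shift.
#' @slot episodicBranch branch receiving the shift (one of [apeBranches()]).
#' @slot episodicFold multiplicative rate factor (> 0) on the shifted branch.
#' @slot indelRate per-site probability that a deletion run starts in one
#'   randomly chosen species.
#' @slot seed master RNG seed; per-family seeds are derived from it.
#' @export
setClass("SimulationParams",
    representation(branchRates = "numeric", familyShape = "numeric",
                   nFamilies = "integer", lengthRange = "integer",
                   episodicFraction = "numeric", episodicBranch = "character",
                   episodicFold = "numeric", indelRate = "numeric",
                   seed = "integer"))

setValidity("SimulationParams", function(object) {
    msg <- character()
    r <- object@branchRates
    if (length(r) != 5L || !identical(names(r), .BRANCHES))
        msg <- c(msg, "branchRates must be named numeric(5) in apeBranches() order")
    if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
        msg <- c(msg, "branchRates must be finite and in [0, 1]")
    if (length(object@familyShape) != 1L || is.na(object@familyShape) ||
        object@familyShape <= 0)
        msg <- c(msg, "familyShape must be a single positive number (Inf allowed)")
    if (object@nFamilies < 0L)
        msg <- c(msg, "nFamilies must be >= 0")
    lr <- object@lengthRange
    if (length(lr) != 2L || any(lr < 1L) || lr[1] > lr[2])
        msg <- c(msg, "lengthRange must be c(min, max) with 1 <= min <= max")
    if (object@episodicFraction < 0 || object@episodicFraction > 1)
        msg <- c(msg, "episodicFraction must be in [0, 1]")
    if (!(object@episodicBranch %in% c(NA_character_, .BRANCHES)))
        msg <- c(msg, "episodicBranch must be NA or one of apeBranches()")
    if (!is.finite(object@episodicFold) || object@episodicFold <= 0)
        msg <- c(msg, "episodicFold must be > 0")
    if (!is.finite(object@indelRate) || object@indelRate < 0 ||
        object@indelRate > 1)
        msg <- c(msg, "indelRate must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Gap-free conserved-block alignment of one ortholog family
#'
#' Result of [filterBlocks()]: the concatenation of all gap-free conserved
#' blocks of a four-sequence family alignment. `L`, the alignment overlap, is
#' the number of kept columns and the denominator of every per-site statistic.
#'
#' @slot familyId family identifier.
#' @slot seqs `AAStringSet` of the four filtered (gap-free) sequences.
#' @slot keptColumns integer vector of kept column indices (1-based, on the
#'   input alignment, ascending).
#' @slot blocks `IRanges` of the retained blocks in input-alignment
#'   coordinates.
#' @slot L alignment overlap: number of kept columns.
#' @slot shortestLen length in residues of the shortest ungapped input
#'   sequence.
#' @slot saturation alignment saturation, `100 * L / shortestLen`, percent.
#' @export
setClass("FilteredAlignment",
    representation(familyId = "character", seqs = "AAStringSet",
                   keptColumns = "integer", blocks = "IRanges",
                   L = "integer", shortestLen = "integer",
                   saturation = "numeric"))

setValidity("FilteredAlignment", function(object) {
    msg <- character()
    if (length(object@seqs) != 4L)
        msg <- c(msg, "seqs must contain exactly four sequences")
    w <- Biostrings::width(object@seqs)
    if (length(unique(w)) > 1L || (length(w) && w[1] != object@L))
        msg <- c(msg, "filtered sequences must all have width L")
    if (object@L != length(object@keptColumns))
        msg <- c(msg, "L must equal the number of kept columns")
    if (object@L != sum(IRanges::width(object@blocks)))
        msg <- c(msg, "L must equal the summed block widths")
    if (object@L > 0 &&
        any(grepl("-", as.character(object@seqs), fixed = TRUE)))
        msg <- c(msg, "filtered sequences must be gap-free")
    if (object@saturation < 0 || object@saturation > 100)
        msg <- c(msg, "saturation must be in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Per-branch substitution counts of one family
#'
#' Result of [countFamily()]: the number of branch-specific substitutions on
#' each of the five branches, the total `N`, the alignment overlap `L`, and
#' the tally of every site-pattern category. Only species-specific columns
#' (one substituted species) and internal-branch columns (human=chimpanzee
#' differing from gorilla=gibbon) contribute to branch counts; inconsistent,
#' consistent three-state and no-identity columns are tallied but contribute
#' zero to every branch.
#'
#' @slot familyId family identifier.
#' @slot counts named integer(5): branch-specific substitutions per branch.
#' @slot categoryCounts named integer over [siteCategories()]; sums to `L`.
#' @slot L alignment overlap.
#' @slot N total branch-specific substitutions, `sum(counts)`.
#' @export
setClass("FamilyCounts",
    representation(familyId = "character", counts = "integer",
                   categoryCounts = "integer", L = "integer", N = "integer"))

setValidity("FamilyCounts", function(object) {
    msg <- character()
    if (!identical(names(object@counts), .BRANCHES))
        msg <- c(msg, "counts must be named in apeBranches() order")
    if (any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (object@N != sum(object@counts))
        msg <- c(msg, "N must equal sum(counts)")
    if (object@N > object@L)
        msg <- c(msg, "N cannot exceed L")
    if (!identical(names(object@categoryCounts), .CATEGORIES))
        msg <- c(msg, "categoryCounts must be named by siteCategories()")
    if (sum(object@categoryCounts) != object@L)
        msg <- c(msg, "category counts must sum to L")
    if (length(msg)) msg else TRUE
})

#' Mean tree: average Poisson-corrected branch lengths across families
#'
#' The null reference tree of the RF deviation test: the arithmetic mean of
#' the Poisson-corrected length of each branch over all families with at
#' least one branch-specific substitution. Zero-substitution families are
#' excluded and counted separately.
#'
#' @slot pcbar named numeric(5): mean PC length per branch.
#' @slot nFamiliesUsed number of families entering the means (N >= 1).
#' @slot nZeroFamilies number of excluded zero-substitution families.
#' @export
setClass("MeanTree",
    representation(pcbar = "numeric", nFamiliesUsed = "integer",
                   nZeroFamilies = "integer"))

setValidity("MeanTree", function(object) {
    msg <- character()
    if (!identical(names(object@pcbar), .BRANCHES))
        msg <- c(msg, "pcbar must be named in apeBranches() order")
    if (any(object@pcbar < 0))
        msg <- c(msg, "mean PC lengths must be non-negative")
    if (object@nFamiliesUsed < 1L)
        msg <- c(msg, "mean tree requires at least one substituted family")
    if (length(msg)) msg else TRUE
})

#' Multinomial simulation null for one value of N
#'
#' Result of [simulateNull()]: the empirical marginal distribution of the
#' per-branch substitution count over `S` multinomial draws of size `N`,
#' where the probability of an event falling on a branch equals the branch's
#' relative length. Cached per distinct `N` and shared across families.
#'
#' @slot N total branch-specific substitutions of the families served.
#' @slot S number of simulation replicates.
#' @slot probs named numeric(5), branch probabilities (sum to 1).
#' @slot marginalCounts integer matrix `(N + 1) x 5`: row `k` holds the
#'   number of replicates with `k - 1` events on each branch.
#' @slot seed RNG seed used for the draws.
#' @export
setClass("SimulationNull",
    representation(N = "integer", S = "integer", probs = "numeric",
                   marginalCounts = "matrix", seed = "integer"))

setValidity("SimulationNull", function(object) {
    msg <- character()
    if (object@N < 1L) msg <- c(msg, "N must be >= 1")
    if (object@S < 1L) msg <- c(msg, "S must be >= 1")
    if (abs(sum(object@probs) - 1) > 1e-9)
        msg <- c(msg, "probs must sum to 1")
    if (!identical(dim(object@marginalCounts),
                   c(object@N + 1L, 5L)))
        msg <- c(msg, "marginalCounts must be (N + 1) x 5")
    if (any(colSums(object@marginalCounts) != object@S))
        msg <- c(msg, "each branch marginal must account for all S replicates")
    if (length(msg)) msg else TRUE
})
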