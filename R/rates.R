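#' Relative branch lengths from per-branch substitution totals
#'
#' Each branch's relative length is its share of the total branch-specific
#' substitutions: `total_b / sum(totals)`. The five proportions sum to 1
#' before any rounding.
#'
#' @param totals numeric(5) of per-branch substitution totals, in
#'   [apeBranches()] order (names optional).
#' @return Named numeric(5) of proportions summing to 1.
#' @examples
#' relativeBranchLengths(c(19815, 18818, 6279, 26026, 97830))
#' @export
relativeBranchLengths <- function(totals) {
    totals <- checkBranchVector(totals, "totals")
    if (any(totals < 0)) stop("totals must be non-negative")
    s <- sum(totals)
    if (s < 1) stop("relative branch lengths undefined for all-zero totals")
    totals / s
}

#' Percent substitutions per site
#'
#' `100 * n / L`. For the total rate, `n` counts all substituted sites; for
#' a branch-specific rate, `n` counts only that branch's branch-specific
#' sites. Vectorised over `n`.
#'
#' @param n number of substituted sites.
#' @param L alignment overlap (>= 1).
#' @return Percentage(s).
#' @examples
#' pctSubsPerSite(13, 171)  # 7.602...
#' @export
pctSubsPerSite <- function(n, L) {
    if (any(L < 1)) stop("L must be >= 1 (zero-overlap families are excluded)")
    if (any(n < 0) || any(n > L)) stop("n must be in [0, L]")
    100 * n / L
}

#' Poisson-corrected branch length
#'
#' Corrects the per-site substitution proportion for multiple hits:
#' `-ln(1 - n/L)`. Undefined at `n == L` (saturated branch); such families
#' are excluded upstream with an explicit error. Vectorised over `n`.
#'
#' @param n substitutions on the branch.
#' @param L alignment overlap.
#' @return PC branch length(s); always `>= n/L`.
#' @examples
#' pcBranchLength(1, 100)  # 0.010050...
#' @export
pcBranchLength <- function(n, L) {
    if (any(L < 1)) stop("L must be >= 1")
    if (any(n < 0)) stop("n must be non-negative")
    if (any(n >= L))
        stop("branch saturated (n = L = ", L,
             "): Poisson-corrected length undefined")
    -log(1 - n / L)
}

#' Poisson-corrected tree of one family
#'
#' The five PC branch lengths of a family and their sum (the PC tree
#' length).
#'
#' @param counts a \linkS4class{FamilyCounts}.
#' @return Named numeric(5) of PC lengths with attribute `treeLength`.
#' @export
familyTree <- function(counts) {
    stopifnot(is(counts, "FamilyCounts"))
    pc <- pcBranchLength(counts@counts, counts@L)
    attr(pc, "treeLength") <- sum(pc)
    pc
}

#' Mean tree across substituted families
#'
#' Arithmetic mean of each branch's PC length over all families with at
#' least one branch-specific substitution. Zero-substitution families carry
#' no tree information and are excluded (their number is recorded).
#'
#' @param countsList list of \linkS4class{FamilyCounts}.
#' @return A \linkS4class{MeanTree}.
#' @export
meanTree <- function(countsList) {
    Ns <- vapply(countsList, totalSubstitutions, integer(1L))
    eligible <- countsList[Ns >= 1L]
    if (!length(eligible))
        stop("mean tree requires at least one family with a substitution")
    pcs <- vapply(eligible, familyTree, numeric(5L))
    new("MeanTree", pcbar = setNames(rowMeans(pcs), .BRANCHES),
        nFamiliesUsed = length(eligible),
        nZeroFamilies = sum(Ns == 0L))
}

#' Aggregate branch statistics table
#'
#' Dataset-level summary in the conventional layout: branch time, total
#' substitutions, relative branch length (4 decimals), % substitutions per
#' site (2 decimals) and % per site per Mya (3 decimals, computed from the
#' full-precision per-site rate). Internally everything is computed at full
#' precision; only the reported columns are rounded.
#'
#' @param totals numeric(5) per-branch substitution totals.
#' @param L total alignment overlap across families.
#' @param branchTimes named numeric(5) of branch durations in Mya
#'   (default [apeBranchTimes()]).
#' @return Data frame with one row per branch.
#' @examples
#' branchStatsTable(c(19815, 18818, 6279, 26026, 97830), 7313620)
#' @export
branchStatsTable <- function(totals, L, branchTimes = apeBranchTimes()) {
    totals <- checkBranchVector(totals, "totals")
    branchTimes <- checkBranchVector(branchTimes, "branchTimes")
    rel <- relativeBranchLengths(totals)
    pct <- pctSubsPerSite(totals, L)
    data.frame(branch = .BRANCHES,
               timeMya = branchTimes,
               totalSubs = as.integer(totals),
               relativeLength = round(rel, 4L),
               pctPerSite = round(pct, 2L),
               pctPerSiteMya = round(pct / branchTimes, 3L),
               row.names = NULL)
}
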