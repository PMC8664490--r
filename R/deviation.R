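#' Branch-length-aware RF score of a family against the mean tree
#'
#' Sum over the five branches of the absolute difference between the
#' family's Poisson-corrected branch length and the mean tree's:
#' `sum(|PC_b - PCbar_b|)`. Zero means the family diverged exactly at the
#' average rate. This is an L1 distance, hence a metric on branch-length
#' vectors.
#'
#' @param pc named numeric(5) of family PC branch lengths (from
#'   [familyTree()]).
#' @param mean a \linkS4class{MeanTree} or named numeric(5).
#' @return Non-negative RF score.
#' @examples
#' rfScore(c(Human = 0.004, Chimpanzee = 0.003, Internal = 0.001,
#'           Gorilla = 0.004, Gibbon = 0.015),
#'         c(Human = 0.003, Chimpanzee = 0.003, Internal = 0.001,
#'           Gorilla = 0.004, Gibbon = 0.015))  # 0.001
#' @export
rfScore <- function(pc, mean) {
    pc <- checkBranchVector(pc, "pc")
    pcbar <- if (is(mean, "MeanTree")) mean@pcbar
             else checkBranchVector(mean, "mean")
    sum(abs(pc - pcbar))
}

#' Bootstrap variance of a family's RF score
#'
#' Column bootstrap of the family's filtered alignment: each replicate
#' resamples the L kept columns with replacement, reclassifies them,
#' recomputes the five PC branch lengths and the RF score against the fixed
#' mean tree. Because the RF score depends on the columns only through the
#' per-branch counts, the resample is drawn as a multinomial over the
#' family's per-category column frequencies, which is distributionally
#' identical to resampling column indices. Replicates in which any branch
#' count reaches L (PC undefined) are discarded and counted; if more than
#' 10\% of replicates are discarded the family is aborted.
#'
#' @param filtered a \linkS4class{FilteredAlignment} with `L >= 1`, or a
#'   \linkS4class{FamilyCounts}.
#' @param mean a \linkS4class{MeanTree} (held fixed across replicates).
#' @param B number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return List with `zbar` (mean replicate RF score), `V` (sample variance
#'   with the B - 1 denominator), `nDiscarded`, `B`.
#' @export
bootstrapRFVariance <- function(filtered, mean, B = 1000L, seed = 1L) {
    counts <- if (is(filtered, "FamilyCounts")) filtered
              else countFamily(filtered)
    L <- counts@L
    if (L < 1L) stop("bootstrap requires L >= 1")
    pcbar <- if (is(mean, "MeanTree")) mean@pcbar
             else checkBranchVector(mean, "mean")
    ## six resampling classes: the five branches + everything else
    p <- c(counts@counts, other = L - counts@N) / L
    reps <- withSeed(seed, rmultinom(B, L, p))
    branchReps <- reps[seq_len(5L), , drop = FALSE]
    saturated <- apply(branchReps, 2L, max) >= L
    nDiscarded <- sum(saturated)
    if (nDiscarded > 0.1 * B)
        stop("family ", counts@familyId, ": ", nDiscarded, " of ", B,
             " bootstrap replicates saturated a branch; aborting")
    kept <- branchReps[, !saturated, drop = FALSE]
    z <- colSums(abs(-log(1 - kept / L) - pcbar))
    list(zbar = mean(z), V = if (length(z) > 1L) var(z) else 0,
         nDiscarded = nDiscarded, B = as.integer(B))
}

#' Z-test of RF scores with FDR correction
#'
#' For each family, `Z = z / sqrt(V)` with `z` the observed RF score and
#' `V` its bootstrap variance; the two-sided normal p-value tests whether
#' the family's divergence differs from the mean tree. Benjamini-Hochberg
#' adjustment is applied across all testable families. Degenerate families
#' with `V == 0` get `p = 1` when `z == 0` (indistinguishable from the
#' mean) and are flagged untestable otherwise.
#'
#' @param results data frame with columns `familyId`, `z`, `V`.
#' @param fdrAlpha FDR level for the `significant` flag (default 0.05).
#' @return The input with columns `Z`, `p`, `q`, `untestable`,
#'   `significant` appended.
#' @export
rfZTest <- function(results, fdrAlpha = 0.05) {
    stopifnot(all(c("familyId", "z", "V") %in% names(results)))
    Z <- ifelse(results$V > 0, results$z / sqrt(results$V), 0)
    p <- ifelse(results$V > 0, 2 * pnorm(-abs(Z)),
                ifelse(results$z == 0, 1, NA_real_))
    untestable <- results$V == 0 & results$z > 0
    q <- rep(NA_real_, length(p))
    q[!untestable] <- p.adjust(p[!untestable], method = "BH")
    results$Z <- Z
    results$p <- p
    results$q <- q
    results$untestable <- untestable
    results$significant <- !untestable & !is.na(q) & q < fdrAlpha
    results
}

#' Multinomial simulation null for N branch-specific substitutions
#'
#' Draws `S` multinomial samples of size `N` over the five branches, with
#' the probability of an event falling on a branch equal to the branch's
#' relative length, and tabulates the marginal count distribution per
#' branch. The null depends only on `N` (the probabilities are fixed per
#' run), so it is built once per distinct `N` and shared by all families
#' with that many substitutions.
#'
#' @param N total branch-specific substitutions (>= 1).
#' @param probs named numeric(5) branch probabilities summing to 1
#'   (typically [relativeBranchLengths()] of the dataset totals).
#' @param S number of replicates (default 100000).
#' @param seed RNG seed.
#' @return A \linkS4class{SimulationNull}.
#' @examples
#' null <- simulateNull(10, c(Human = 0.1174, Chimpanzee = 0.1115,
#'                            Internal = 0.0372, Gorilla = 0.1542,
#'                            Gibbon = 0.5797), S = 1000, seed = 1)
#' @export
simulateNull <- function(N, probs, S = 100000L, seed = 1L) {
    if (N < 1L) stop("no null is constructed for N = 0")
    probs <- checkBranchVector(probs, "probs")
    if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
    draws <- withSeed(seed, rmultinom(S, N, probs))
    marg <- vapply(seq_len(5L), function(b)
        tabulate(draws[b, ] + 1L, nbins = N + 1L), integer(N + 1L))
    colnames(marg) <- .BRANCHES
    new("SimulationNull", N = as.integer(N), S = as.integer(S),
        probs = probs, marginalCounts = marg, seed = as.integer(seed))
}

#' Two-tailed rank test of each branch's count against the simulation null
#'
#' For each branch, the empirical two-tailed p-value of observing the
#' family's branch count or a more extreme one under the null:
#' `p = min(1, 2 * min(Pr[X <= n], Pr[X >= n]))`, the observed value
#' included in both tails. A branch is flagged significant when
#' `p < alpha / nBranchesTested` (the Bonferroni-adjusted threshold, 0.01
#' at the defaults). Direction is the sign of `n - N * p_b`. Families with
#' `N == 0` are skipped with all p-values 1.
#'
#' @param counts a \linkS4class{FamilyCounts}.
#' @param null the \linkS4class{SimulationNull} for this family's `N`
#'   (ignored when `N == 0`).
#' @param nBranchesTested number of branches tested per family (Bonferroni
#'   divisor, default 5).
#' @param alpha unadjusted significance level (default 0.05).
#' @return Data frame with one row per branch: `familyId`, `branch`, `n`,
#'   `expected`, `p`, `direction`, `significant`.
#' @export
branchDeviationTest <- function(counts, null = NULL, nBranchesTested = 5L,
                                alpha = 0.05) {
    stopifnot(is(counts, "FamilyCounts"))
    threshold <- alpha / nBranchesTested
    if (counts@N == 0L) {
        return(data.frame(familyId = counts@familyId, branch = .BRANCHES,
                          n = 0L, expected = 0, p = 1,
                          direction = "none", significant = FALSE))
    }
    stopifnot(is(null, "SimulationNull"))
    if (null@N != counts@N)
        stop("null was built for N = ", null@N, ", family has N = ",
             counts@N)
    N <- counts@N; S <- null@S
    p <- expected <- numeric(5L); direction <- character(5L)
    for (b in seq_len(5L)) {
        n <- counts@counts[b]
        m <- null@marginalCounts[, b]
        lower <- sum(m[seq_len(n + 1L)]) / S
        upper <- sum(m[(n + 1L):(N + 1L)]) / S
        p[b] <- min(1, 2 * min(lower, upper))
        expected[b] <- N * null@probs[b]
        direction[b] <- if (n > expected[b]) "faster"
                        else if (n < expected[b]) "slower" else "none"
    }
    data.frame(familyId = counts@familyId, branch = .BRANCHES,
               n = as.integer(counts@counts), expected = expected, p = p,
               direction = direction, significant = p < threshold)
}

#' Run the branch deviation test over a whole dataset
#'
#' Builds (and caches) one simulation null per distinct value of `N`
#' observed among the families, then applies [branchDeviationTest()] to
#' each family. Null probabilities default to the relative branch lengths
#' of the dataset's aggregate substitution totals.
#'
#' @param countsList list of \linkS4class{FamilyCounts}.
#' @param probs branch probabilities; `NULL` (default) derives them from
#'   the aggregate totals of `countsList`.
#' @param S simulation replicates per null (default 100000).
#' @param nBranchesTested,alpha see [branchDeviationTest()].
#' @param seed master seed; each null's seed is derived from it and `N`.
#' @return Data frame of per-family per-branch test rows.
#' @export
datasetDeviationTests <- function(countsList, probs = NULL, S = 100000L,
                                  nBranchesTested = 5L, alpha = 0.05,
                                  seed = 1L) {
    if (is.null(probs)) {
        totals <- Reduce(`+`, lapply(countsList, branchCounts))
        probs <- relativeBranchLengths(totals)
    } else probs <- checkBranchVector(probs, "probs")
    Ns <- vapply(countsList, totalSubstitutions, integer(1L))
    cache <- new.env(parent = emptyenv())
    for (N in sort(unique(Ns[Ns >= 1L])))
        assign(as.character(N),
               simulateNull(N, probs, S = S, seed = deriveSeed(seed, N)),
               envir = cache)
    do.call(rbind, lapply(seq_along(countsList), function(i) {
        null <- if (Ns[i] >= 1L) get(as.character(Ns[i]), envir = cache)
                else NULL
        branchDeviationTest(countsList[[i]], null,
                            nBranchesTested = nBranchesTested,
                            alpha = alpha)
    }))
}

#' Summarise deviation tests per branch and branch combination
#'
#' Counts families deviating on exactly one branch (per branch and
#' direction) and families deviating on several branches (per combination
#' label), in the layout of a lower/higher-than-expected summary table.
#'
#' @param devTests data frame from [datasetDeviationTests()].
#' @return Data frame `branches`, `lower`, `higher` (counts of families).
#' @export
summaryDeviationTable <- function(devTests) {
    sig <- devTests[devTests$significant, , drop = FALSE]
    if (!nrow(sig))
        return(data.frame(branches = character(0), lower = integer(0),
                          higher = integer(0)))
    perFam <- split(sig, sig$familyId)
    singles <- Filter(function(d) nrow(d) == 1L, perFam)
    multis <- Filter(function(d) nrow(d) > 1L, perFam)
    out <- data.frame(branches = .BRANCHES,
                      lower = vapply(.BRANCHES, function(b) sum(vapply(
                          singles, function(d) d$branch == b &
                              d$direction == "slower", logical(1L))),
                          integer(1L)),
                      higher = vapply(.BRANCHES, function(b) sum(vapply(
                          singles, function(d) d$branch == b &
                              d$direction == "faster", logical(1L))),
                          integer(1L)))
    if (length(multis)) {
        combos <- vapply(multis, function(d)
            paste(sort(d$branch), collapse = ","), character(1L))
        dirs <- vapply(multis, function(d)
            if (all(d$direction == "faster")) "higher"
            else if (all(d$direction == "slower")) "lower" else "mixed",
            character(1L))
        for (cmb in unique(combos)) {
            out <- rbind(out, data.frame(
                branches = cmb,
                lower = sum(combos == cmb & dirs == "lower"),
                higher = sum(combos == cmb & dirs == "higher")))
        }
        nMixed <- sum(dirs == "mixed")
        if (nMixed)
            out <- rbind(out, data.frame(branches = "opposite directions",
                                         lower = NA_integer_,
                                         higher = nMixed))
    }
    rownames(out) <- NULL
    out
}
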