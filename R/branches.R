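## Branch order used throughout: the four tips plus the internal branch
## subtending Human+Chimpanzee. The deeper internal branch (human+chimp+gorilla
## ancestor) is unresolvable without an outgroup and is absorbed into Gibbon.
.BRANCHES <- c("Human", "Chimpanzee", "Internal", "Gorilla", "Gibbon")
.SPECIES <- c("Human", "Chimpanzee", "Gorilla", "Gibbon")

## Site-pattern categories for a gap-free four-residue column. The five branch
## names double as the branch-specific categories.
.CATEGORIES <- c("identical", .BRANCHES, "inconsistent_2state",
                 "consistent_3state", "inconsistent_3state", "no_identity")

#' Branch and species names of the four-taxon ape tree
#'
#' The fixed branch order used by every table and vector in the package:
#' Human, Chimpanzee, Internal (the branch subtending human+chimpanzee),
#' Gorilla, Gibbon. The gibbon branch implicitly contains the deeper internal
#' branch, which cannot be separated without an outgroup.
#'
#' @return `apeBranches()`: character vector of the five branch names.
#' @export
apeBranches <- function() .BRANCHES

#' @rdname apeBranches
#' @return `apeSpecies()`: character vector of the four species names.
#' @export
apeSpecies <- function() .SPECIES

#' @rdname apeBranches
#' @return `siteCategories()`: character vector of the ten site-pattern
#'   category codes assigned by [classifyColumn()].
#' @export
siteCategories <- function() .CATEGORIES

#' Default branch times of the ape tree
#'
#' Divergence-time configuration profile (millions of years) for the five
#' branches, taken from the TimeTree consensus ages of the ape splits. These
#' are configuration inputs for per-Mya rate normalisation, not estimates made
#' by this package.
#'
#' @return Named numeric vector of branch durations in Mya, in
#'   [apeBranches()] order.
#' @export
apeBranchTimes <- function() {
    setNames(c(6.65, 6.65, 2.41, 9.06, 31.24), .BRANCHES)
}

## Deterministic derivation of per-unit seeds from a master seed; doubles are
## exact well beyond 2^46 so the arithmetic below never loses precision.
deriveSeed <- function(master, index) {
    as.integer((as.numeric(master) * 48271 + as.numeric(index) * 2246822519 +
                3141592653) %% 2147483647)
}

## Run code under a locally seeded RNG without disturbing the caller's stream.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

## Internal: named five-vector check
checkBranchVector <- function(x, what = "branch vector") {
    if (length(x) != 5L)
        stop(what, " must have length 5 (", paste(.BRANCHES, collapse = ", "),
             ")", call. = FALSE)
    if (is.null(names(x)))
        names(x) <- .BRANCHES
    if (!all(.BRANCHES %in% names(x)))
        stop(what, " must be named with ", paste(.BRANCHES, collapse = ", "),
             call. = FALSE)
    x[.BRANCHES]
}
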