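#' Construct simulation parameters
#'
#' Constructor for \linkS4class{SimulationParams}. Defaults reproduce a
#' clock-like four-taxon ape dataset: branch rates equal to the genome-wide
#' per-site substitution frequencies (Human 0.0027, Chimpanzee 0.0026,
#' Internal 0.0009, Gorilla 0.0036, Gibbon 0.0134), moderate family-rate
#' heterogeneity (gamma shape 2, mean 1), no episodic shifts and no indels.
#'
#' @param branchRates named numeric(5) of per-site substitution
#'   probabilities, in [apeBranches()] order.
#' @param familyShape gamma shape of the per-family rate multiplier
#'   (mean 1); `Inf` fixes the multiplier at 1.
#' @param nFamilies number of families.
#' @param lengthRange integer(2), min/max ancestral protein length.
#' @param episodicFraction fraction of families given a rate shift.
#' @param episodicBranch branch receiving the shift.
#' @param episodicFold multiplicative factor (> 0) applied to the shifted
#'   branch's rate in flagged families.
#' @param indelRate per-site probability that a single-species deletion run
#'   (geometric length, mean 3) starts at a column.
#' @param seed master RNG seed.
#' @return A validated \linkS4class{SimulationParams} object.
#' @examples
#' simulationParams(nFamilies = 10, seed = 1)
#' @export
simulationParams <- function(branchRates = c(Human = 0.0027,
                                             Chimpanzee = 0.0026,
                                             Internal = 0.0009,
                                             Gorilla = 0.0036,
                                             Gibbon = 0.0134),
                             familyShape = 2, nFamilies = 100,
                             lengthRange = c(100L, 1000L),
                             episodicFraction = 0,
                             episodicBranch = NA_character_,
                             episodicFold = 1, indelRate = 0, seed = 1) {
    br <- checkBranchVector(branchRates, "branchRates")
    new("SimulationParams", branchRates = br,
        familyShape = as.numeric(familyShape),
        nFamilies = as.integer(nFamilies),
        lengthRange = as.integer(lengthRange),
        episodicFraction = as.numeric(episodicFraction),
        episodicBranch = as.character(episodicBranch),
        episodicFold = as.numeric(episodicFold),
        indelRate = as.numeric(indelRate), seed = as.integer(seed))
}

## Replace each residue with a uniformly chosen different one of the 19
## alternatives. `cur` is a character vector of standard amino-acid letters.
substituteResidues <- function(cur) {
    alpha <- Biostrings::AA_STANDARD
    pos <- match(cur, alpha)
    step <- sample.int(length(alpha) - 1L, length(cur), replace = TRUE)
    alpha[((pos - 1L + step) %% length(alpha)) + 1L]
}

#' Simulate one four-taxon ortholog family with ground truth
#'
#' Draws an ancestral protein and evolves it along the five branches of the
#' tree ((Human,Chimpanzee)Internal,Gorilla,Gibbon). Each column x branch
#' receives an independent substitution event with probability
#' `rate_b * multiplier * fold` (the fold only on the episodic branch of
#' flagged families). An event on the internal branch replaces the human and
#' chimpanzee residues identically; tip events replace that tip's current
#' residue with a uniformly chosen different one, so multiple hits on one
#' column produce inconsistent and no-identity patterns naturally. The
#' gibbon branch rate implicitly contains the deeper internal branch.
#' Optionally, single-species deletion runs (geometric length, mean 3) are
#' written as gap characters, yielding the aligned family as a multiple
#' sequence aligner would emit it.
#'
#' @param params a \linkS4class{SimulationParams} object.
#' @param familyIndex integer index; together with `params@seed` it
#'   determines the family's private RNG stream.
#' @param episodic logical; whether this family carries the episodic shift.
#' @return A list with elements
#'   \describe{
#'     \item{familyId}{`"FAM<index>"`.}
#'     \item{msa}{`AAStringSet` of the four aligned sequences (with `-` for
#'       deleted residues), named `"<Species>|<gene id>"`.}
#'     \item{truth}{ground truth: `events` (5 x L logical matrix of
#'       per-branch events), `trueCounts` (columns hit by exactly one
#'       branch, per branch), `columnEvents` (number of branch events per
#'       column), `multiplier`, `episodic`, `episodicBranch`.}
#'   }
#' @examples
#' fam <- simulateFamily(simulationParams(seed = 7), 1)
#' fam$truth$trueCounts
#' @export
simulateFamily <- function(params, familyIndex, episodic = FALSE) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    withSeed(deriveSeed(params@seed, familyIndex), {
        len <- if (params@lengthRange[1] == params@lengthRange[2])
            params@lengthRange[1]
        else sample(params@lengthRange[1]:params@lengthRange[2], 1L)
        anc <- sample(Biostrings::AA_STANDARD, len, replace = TRUE)
        mult <- if (is.finite(params@familyShape))
            rgamma(1L, shape = params@familyShape, rate = params@familyShape)
        else 1
        rates <- params@branchRates * mult
        if (isTRUE(episodic) && !is.na(params@episodicBranch))
            rates[params@episodicBranch] <-
                rates[params@episodicBranch] * params@episodicFold
        rates <- pmin(rates, 1)

        events <- matrix(FALSE, nrow = 5L, ncol = len,
                         dimnames = list(.BRANCHES, NULL))
        for (b in .BRANCHES)
            events[b, ] <- runif(len) < rates[b]

        seqs <- matrix(rep(anc, 4L), nrow = 4L, byrow = TRUE,
                       dimnames = list(.SPECIES, NULL))
        ## internal branch first: one shared replacement for human + chimp
        idx <- which(events["Internal", ])
        if (length(idx)) {
            repl <- substituteResidues(anc[idx])
            seqs["Human", idx] <- repl
            seqs["Chimpanzee", idx] <- repl
        }
        ## then each tip, replacing its current residue
        for (sp in .SPECIES) {
            idx <- which(events[sp, ])
            if (length(idx))
                seqs[sp, idx] <- substituteResidues(seqs[sp, idx])
        }

        colEvents <- colSums(events)
        trueCounts <- setNames(integer(5L), .BRANCHES)
        for (b in .BRANCHES)
            trueCounts[b] <- sum(events[b, ] & colEvents == 1L)

        ## single-species deletion runs
        if (params@indelRate > 0) {
            starts <- which(runif(len) < params@indelRate)
            for (j in starts) {
                sp <- sample(.SPECIES, 1L)
                runLen <- rgeom(1L, 1 / 3) + 1L
                seqs[sp, j:min(j + runLen - 1L, len)] <- "-"
            }
        }

        famId <- sprintf("FAM%05d", familyIndex)
        msa <- AAStringSet(apply(seqs, 1L, paste0, collapse = ""))
        names(msa) <- sprintf("%s|%s_%s", .SPECIES, famId,
                              c("H", "C", "G", "B"))
        list(familyId = famId, msa = msa,
             truth = list(events = events, trueCounts = trueCounts,
                          columnEvents = colEvents, multiplier = mult,
                          episodic = isTRUE(episodic),
                          episodicBranch = if (isTRUE(episodic))
                              params@episodicBranch else NA_character_))
    })
}

#' Simulate a dataset of ortholog families
#'
#' Generates `params@nFamilies` families with [simulateFamily()]. Episodic
#' flags are assigned to a random subset of size
#' `round(episodicFraction * nFamilies)` drawn from the master seed, and each
#' family has a private seed derived from the master seed and its index, so
#' the dataset is reproducible family-by-family.
#'
#' @param params a \linkS4class{SimulationParams} object.
#' @return List of family objects as returned by [simulateFamily()].
#' @examples
#' fams <- simulateDataset(simulationParams(nFamilies = 3, seed = 2))
#' length(fams)
#' @export
simulateDataset <- function(params) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    n <- params@nFamilies
    if (n == 0L) return(list())
    flagged <- logical(n)
    nEp <- round(params@episodicFraction * n)
    if (nEp > 0L)
        flagged[withSeed(deriveSeed(params@seed, 0L), sample.int(n, nEp))] <-
            TRUE
    lapply(seq_len(n), function(i)
        simulateFamily(params, i, episodic = flagged[i]))
}

#' Write a simulated family as FASTA and its ground truth as TSV
#'
#' @param family a family object from [simulateFamily()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the FASTA path.
#' @export
writeFamilyFasta <- function(family, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, paste0(family$familyId, ".fa"))
    writeXStringSet(family$msa, path)
    tr <- family$truth
    truthDf <- data.frame(family_id = family$familyId, branch = .BRANCHES,
                          true_count = as.integer(tr$trueCounts),
                          multiplier = tr$multiplier, episodic = tr$episodic,
                          episodic_branch = tr$episodicBranch)
    write.table(truthDf, file.path(dir, paste0(family$familyId, ".truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
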