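#' Read per-family aligned FASTA files
#'
#' Reads every `*.fa`/`*.fasta` file in a directory as one four-sequence
#' family alignment. Record ids are expected as `"<Species>|<gene id>"`;
#' sequences are reordered to Human, Chimpanzee, Gorilla, Gibbon when the
#' species labels are recognisable, and taken in file order otherwise.
#'
#' @param dir directory of aligned FASTA files.
#' @return Named list of `AAStringSet` alignments, one per family (file
#'   base name).
#' @export
readFamilyAlignments <- function(dir) {
    files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (!length(files)) stop("no FASTA files found in ", dir)
    out <- lapply(files, function(f) {
        msa <- readAAStringSet(f)
        if (length(msa) != 4L)
            stop(f, ": expected 4 sequences, found ", length(msa))
        sp <- sub("\\|.*$", "", names(msa))
        if (all(.SPECIES %in% sp)) msa <- msa[match(.SPECIES, sp)]
        msa
    })
    names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
    out
}

#' Pipeline configuration
#'
#' Assembles the configuration for [runPipeline()]. Synthetic mode
#' generates families with [simulateDataset()]; real mode reads per-family
#' alignments from `alignmentDir`.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param simParams \linkS4class{SimulationParams} (synthetic mode).
#' @param alignmentDir directory of per-family aligned FASTA (real mode).
#' @param outDir output directory for report tables and the run log.
#' @param branchTimes named numeric(5) branch durations in Mya.
#' @param minBlock,maxNonconservedRun block-filter settings.
#' @param bootstrapReps RF bootstrap replicates per family.
#' @param simReps multinomial simulation replicates per distinct N.
#' @param alpha unadjusted significance level of the deviation test.
#' @param fdrAlpha FDR level of the RF Z-test.
#' @param nBranchesTested Bonferroni divisor of the deviation test.
#' @param topK candidates reported per branch and direction.
#' @param runRF,runDeviation switches for the two test stages.
#' @param seed master seed for the stochastic stages.
#' @return A list of class `"apeClockConfig"`.
#' @export
pipelineConfig <- function(mode = c("synthetic", "real"), simParams = NULL,
                           alignmentDir = NULL, outDir = tempfile("apeClock"),
                           branchTimes = apeBranchTimes(), minBlock = 10L,
                           maxNonconservedRun = 2L, bootstrapReps = 1000L,
                           simReps = 100000L, alpha = 0.05,
                           fdrAlpha = 0.05, nBranchesTested = 5L,
                           topK = 5L, runRF = TRUE, runDeviation = TRUE,
                           seed = 1L) {
    mode <- match.arg(mode)
    if (mode == "synthetic" && is.null(simParams))
        stop("synthetic mode requires simParams")
    if (mode == "real" && is.null(alignmentDir))
        stop("real mode requires alignmentDir")
    structure(list(mode = mode, simParams = simParams,
                   alignmentDir = alignmentDir, outDir = outDir,
                   branchTimes = checkBranchVector(branchTimes,
                                                   "branchTimes"),
                   minBlock = as.integer(minBlock),
                   maxNonconservedRun = as.integer(maxNonconservedRun),
                   bootstrapReps = as.integer(bootstrapReps),
                   simReps = as.integer(simReps), alpha = alpha,
                   fdrAlpha = fdrAlpha,
                   nBranchesTested = as.integer(nBranchesTested),
                   topK = as.integer(topK), runRF = runRF,
                   runDeviation = runDeviation, seed = as.integer(seed)),
              class = "apeClockConfig")
}

writeTsv <- function(df, dir, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes alignment filtering, site classification, branch statistics,
#' the mean tree, the RF bootstrap Z-test, the multinomial deviation test
#' and candidate ranking, writing every stage's table as TSV into the
#' output directory together with a run log that records family attrition
#' (zero-overlap families, bootstrap saturation aborts, untestable
#' families).
#'
#' @param config an `apeClockConfig` from [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of the stage tables: `families`, `siteCounts`,
#'   `branchStats`, `familyTrees`, `rfTests`, `deviationTests`,
#'   `deviationSummary`, `candidates`, plus `attrition`.
#' @examples
#' cfg <- pipelineConfig(simParams = simulationParams(nFamilies = 5,
#'                                                    seed = 1),
#'                       bootstrapReps = 50, simReps = 1000,
#'                       outDir = tempfile())
#' res <- runPipeline(cfg, quiet = TRUE)
#' res$branchStats
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "apeClockConfig"))
    if (!dir.exists(config$outDir))
        dir.create(config$outDir, recursive = TRUE)
    logPath <- file.path(config$outDir, "run_log.txt")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon))
    logLine <- function(...) {
        msg <- paste0(...)
        writeLines(msg, logCon)
        if (!quiet) message(msg)
    }

    ## stage 1: obtain family alignments
    if (config$mode == "synthetic") {
        logLine("stage simulate: generating ",
                config$simParams@nFamilies, " families")
        fams <- simulateDataset(config$simParams)
        msas <- lapply(fams, `[[`, "msa")
        names(msas) <- vapply(fams, `[[`, character(1L), "familyId")
    } else {
        logLine("stage read: loading alignments from ", config$alignmentDir)
        msas <- readFamilyAlignments(config$alignmentDir)
    }

    ## stage 2: block filtering
    filtered <- lapply(names(msas), function(id)
        filterBlocks(msas[[id]], minBlock = config$minBlock,
                     maxNonconservedRun = config$maxNonconservedRun,
                     familyId = id))
    names(filtered) <- names(msas)
    famTable <- do.call(rbind, lapply(filtered, function(f)
        data.frame(familyId = f@familyId, L = f@L,
                   shortestLen = f@shortestLen, saturation = f@saturation,
                   nBlocks = length(f@blocks),
                   blockSpans = paste(sprintf("%d-%d",
                       IRanges::start(f@blocks), IRanges::end(f@blocks)),
                       collapse = ";"))))
    nonOverlap <- names(filtered)[vapply(filtered, function(f) f@L == 0L,
                                         logical(1L))]
    logLine("stage filter: ", length(filtered), " families, ",
            length(nonOverlap), " non-overlapping removed")
    usable <- filtered[setdiff(names(filtered), nonOverlap)]

    ## stage 3: site classification and counts
    countsList <- lapply(usable, countFamily)
    siteTable <- do.call(rbind, lapply(countsList, function(x)
        cbind(data.frame(familyId = x@familyId, L = x@L, N = x@N),
              as.data.frame(as.list(x@counts)),
              as.data.frame(as.list(
                  x@categoryCounts[setdiff(.CATEGORIES, .BRANCHES)])))))
    logLine("stage classify: ", length(countsList), " families counted")

    ## families with a fully saturated branch (n_b = L) have no defined PC
    ## length; exclude them with a logged error rather than clamping
    saturatedIds <- names(countsList)[vapply(countsList, function(x)
        any(x@counts >= x@L) && x@L > 0L, logical(1L))]
    if (length(saturatedIds)) {
        logLine("stage classify: ", length(saturatedIds),
                " families excluded (saturated branch, PC undefined)")
        countsList <- countsList[setdiff(names(countsList), saturatedIds)]
    }

    ## stage 4: aggregate branch statistics
    totals <- Reduce(`+`, lapply(countsList, branchCounts))
    Lsum <- sum(vapply(countsList, alignmentOverlap, integer(1L)))
    branchStats <- if (sum(totals) >= 1)
        branchStatsTable(totals, Lsum, config$branchTimes)
    else {
        logLine("stage rates: no substitutions in dataset; ",
                "rate table has zero totals and no tests are run")
        data.frame(branch = .BRANCHES, timeMya = config$branchTimes,
                   totalSubs = 0L, relativeLength = NA_real_,
                   pctPerSite = 0, pctPerSiteMya = 0, row.names = NULL)
    }

    ## stage 5: family trees + mean tree + RF test
    rfTests <- NULL; familyTrees <- NULL
    attrition <- data.frame(familyId = nonOverlap,
                            stage = rep("filter", length(nonOverlap)),
                            reason = rep("no overlapping block",
                                         length(nonOverlap)))
    if (length(saturatedIds))
        attrition <- rbind(attrition, data.frame(
            familyId = saturatedIds, stage = "classify",
            reason = "saturated branch (n = L)"))
    canTest <- sum(totals) >= 1 &&
        sum(vapply(countsList, totalSubstitutions, integer(1L)) >= 1L) > 0
    if (canTest) {
        mt <- meanTree(countsList)
        familyTrees <- do.call(rbind, lapply(countsList, function(x) {
            pc <- familyTree(x)
            cbind(data.frame(familyId = x@familyId),
                  as.data.frame(as.list(setNames(pc,
                      paste0("PC_", .BRANCHES)))),
                  data.frame(treeLength = sum(pc)))
        }))
        if (config$runRF) {
            logLine("stage rf: bootstrapping ", length(countsList),
                    " families, B = ", config$bootstrapReps)
            rfRows <- lapply(countsList, function(x) {
                bt <- tryCatch(
                    bootstrapRFVariance(x, mt, B = config$bootstrapReps,
                                        seed = deriveSeed(config$seed,
                                            match(x@familyId,
                                                  names(countsList)))),
                    error = function(e) e)
                if (inherits(bt, "error"))
                    return(data.frame(familyId = x@familyId, z = NA_real_,
                                      V = NA_real_, failed = TRUE))
                data.frame(familyId = x@familyId,
                           z = rfScore(familyTree(x), mt), V = bt$V,
                           failed = FALSE)
            })
            rfDf <- do.call(rbind, rfRows)
            failedIds <- rfDf$familyId[rfDf$failed]
            if (length(failedIds))
                attrition <- rbind(attrition, data.frame(
                    familyId = failedIds, stage = "rf",
                    reason = "bootstrap saturation"))
            rfTests <- rfZTest(rfDf[!rfDf$failed,
                                    c("familyId", "z", "V")],
                               fdrAlpha = config$fdrAlpha)
            logLine("stage rf: ", sum(rfTests$significant),
                    " families significant at FDR ", config$fdrAlpha)
        }
    }

    ## stage 6: multinomial deviation test
    devTests <- NULL; devSummary <- NULL; candidates <- NULL
    if (canTest && config$runDeviation) {
        logLine("stage deviation: simulation null, S = ", config$simReps)
        devTests <- datasetDeviationTests(countsList, S = config$simReps,
                                          nBranchesTested =
                                              config$nBranchesTested,
                                          alpha = config$alpha,
                                          seed = config$seed)
        devSummary <- summaryDeviationTable(devTests)
        candidates <- rbind(
            rankCandidates(devTests, countsList, topK = config$topK,
                           direction = "faster"),
            rankCandidates(devTests, countsList, topK = config$topK,
                           direction = "slower"))
        logLine("stage deviation: ",
                length(unique(devTests$familyId[devTests$significant])),
                " families with a deviating branch")
    }

    tables <- list(families = famTable, siteCounts = siteTable,
                   branchStats = branchStats, familyTrees = familyTrees,
                   rfTests = rfTests, deviationTests = devTests,
                   deviationSummary = devSummary, candidates = candidates,
                   attrition = attrition)
    for (nm in names(tables))
        if (!is.null(tables[[nm]]))
            writeTsv(tables[[nm]], config$outDir,
                     paste0(gsub("([A-Z])", "_\\L\\1", nm, perl = TRUE),
                            ".tsv"))
    logLine("pipeline complete: tables written to ", config$outDir)
    invisible(tables)
}

#' Rank candidate families by branch-specific substitution rate
#'
#' Per branch, the `topK` families flagged significant in the requested
#' direction, sorted by descending branch-specific % substitutions per
#' site. The `comment` column is left empty for downstream manual
#' annotation.
#'
#' @param devTests data frame from [datasetDeviationTests()].
#' @param countsList list of \linkS4class{FamilyCounts} providing L and
#'   saturation denominators.
#' @param topK number of candidates per branch (default 5).
#' @param direction `"faster"` or `"slower"`.
#' @return Data frame `branch`, `familyId`, `pctPerSite`, `n`, `L`,
#'   `direction`, `comment`, sorted within branch.
#' @export
rankCandidates <- function(devTests, countsList, topK = 5L,
                           direction = c("faster", "slower")) {
    direction <- match.arg(direction)
    Ls <- setNames(vapply(countsList, alignmentOverlap, integer(1L)),
                   vapply(countsList, familyId, character(1L)))
    sig <- devTests[devTests$significant &
                    devTests$direction == direction, , drop = FALSE]
    out <- lapply(.BRANCHES, function(b) {
        d <- sig[sig$branch == b, , drop = FALSE]
        if (!nrow(d)) return(NULL)
        d$L <- Ls[d$familyId]
        d$pctPerSite <- round(pctSubsPerSite(d$n, d$L), 2L)
        d <- d[order(-d$pctPerSite), , drop = FALSE]
        d <- head(d, topK)
        data.frame(branch = b, familyId = d$familyId,
                   pctPerSite = d$pctPerSite, n = d$n, L = d$L,
                   direction = direction, comment = "")
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(branch = character(0), familyId = character(0),
                          pctPerSite = numeric(0), n = integer(0),
                          L = integer(0), direction = character(0),
                          comment = character(0))
    rownames(out) <- NULL
    out
}
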