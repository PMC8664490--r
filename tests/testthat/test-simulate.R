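test_that("zero rates give four identical sequences and zero true counts", {
    p <- simulationParams(branchRates = setNames(rep(0, 5), apeBranches()),
                          lengthRange = c(200L, 200L), indelRate = 0,
                          seed = 11)
    fam <- simulateFamily(p, 1)
    seqs <- as.character(fam$msa)
    expect_length(unique(unname(seqs)), 1L)
    expect_true(all(fam$truth$trueCounts == 0L))
    # downstream: the pipeline sees no substitutions at all
    counts <- countFamily(filterBlocks(fam$msa))
    expect_identical(totalSubstitutions(counts), 0L)
    expect_identical(unname(categoryCounts(counts)[["identical"]]), 200L)
})

test_that("single-branch event count follows its binomial law", {
    rates <- setNames(rep(0, 5), apeBranches())
    rates["Gibbon"] <- 0.01
    p <- simulationParams(branchRates = rates, familyShape = Inf,
                          lengthRange = c(10000L, 10000L), seed = 3)
    fam <- simulateFamily(p, 1)
    expected <- 10000 * 0.01
    tol <- 3 * sqrt(10000 * 0.01 * 0.99)
    expect_lt(abs(fam$truth$trueCounts[["Gibbon"]] - expected), tol)
    expect_true(all(fam$truth$trueCounts[setdiff(apeBranches(),
                                                 "Gibbon")] == 0L))
})

test_that("an episodic fold multiplies the expected event count", {
    rates <- setNames(rep(0, 5), apeBranches())
    rates["Human"] <- 0.01
    p <- simulationParams(branchRates = rates, familyShape = Inf,
                          lengthRange = c(1000L, 1000L),
                          episodicBranch = "Human", episodicFold = 5,
                          seed = 21)
    base <- vapply(1:300, function(i)
        simulateFamily(p, i, episodic = FALSE)$truth$trueCounts[["Human"]],
        integer(1L))
    shifted <- vapply(1:300, function(i)
        simulateFamily(p, i, episodic = TRUE)$truth$trueCounts[["Human"]],
        integer(1L))
    expect_lt(abs(mean(shifted) / mean(base) - 5), 0.5)
})

test_that("datasets are reproducible and per-family streams independent", {
    p <- simulationParams(nFamilies = 5, lengthRange = c(50L, 120L),
                          indelRate = 0.01, seed = 99)
    d1 <- simulateDataset(p)
    d2 <- simulateDataset(p)
    expect_identical(lapply(d1, function(f) as.character(f$msa)),
                     lapply(d2, function(f) as.character(f$msa)))
    expect_identical(lapply(d1, `[[`, "truth"), lapply(d2, `[[`, "truth"))
    # empty dataset
    expect_identical(simulateDataset(simulationParams(nFamilies = 0)),
                     list())
})

test_that("aggregate relative branch lengths recover the clock shares", {
    p <- simulationParams(branchRates = clockRates, familyShape = Inf,
                          nFamilies = 800, lengthRange = c(500L, 500L),
                          seed = 17)
    fams <- simulateDataset(p)
    counts <- lapply(fams, function(f)
        countFamily(filterBlocks(f$msa, familyId = f$familyId)))
    totals <- Reduce(`+`, lapply(counts, branchCounts))
    rel <- relativeBranchLengths(totals)
    expected <- c(0.1174, 0.1115, 0.0372, 0.1542, 0.5797)
    # multinomial sampling error on ~9000 events is well under 0.02
    expect_true(all(abs(rel - expected) < 0.02))
})

test_that("true counts converge to L * rate and internal events pair H with C", {
    p <- simulationParams(branchRates = clockRates, familyShape = Inf,
                          nFamilies = 200, lengthRange = c(400L, 400L),
                          seed = 5)
    fams <- simulateDataset(p)
    tc <- Reduce(`+`, lapply(fams, function(f) f$truth$trueCounts))
    L <- 200 * 400
    for (b in apeBranches()) {
        expected <- L * clockRates[[b]]
        se <- sqrt(L * clockRates[[b]] * (1 - clockRates[[b]]))
        # true counts exclude multi-hit columns, a small downward leak
        leak <- expected * sum(clockRates[-match(b, apeBranches())])
        expect_lt(abs(tc[[b]] - expected), 3 * se + 2 * leak)
    }
    # every sole internal event yields the Internal column pattern
    for (f in fams[1:20]) {
        sole <- f$truth$events["Internal", ] & f$truth$columnEvents == 1L
        if (!any(sole)) next
        m <- apeClock:::msaMatrix(f$msa)
        expect_true(all(m[1, sole] == m[2, sole]))
        expect_true(all(m[3, sole] == m[4, sole]))
        expect_true(all(m[1, sole] != m[3, sole]))
    }
})

test_that("invalid simulation parameters are rejected", {
    expect_error(simulationParams(branchRates = c(Human = 1.2,
        Chimpanzee = 0, Internal = 0, Gorilla = 0, Gibbon = 0)),
        "0, 1")
    expect_error(simulationParams(episodicFold = 0), "episodicFold")
    expect_error(simulationParams(lengthRange = c(0L, 10L)), "lengthRange")
})

test_that("toy genomes plant the promised features", {
    toy <- simulateToyGenomes(50, nInversions = 0, nTandem = 0, seed = 2)
    expect_identical(toy$genesB$gene_id,
                     sub("^A", "B", toy$genesA$gene_id))
    expect_true(all(diff(toy$genesA$start) > 0))
    expect_length(toy$registry$inversions, 0L)

    toy2 <- simulateToyGenomes(50, nTandem = 1, seed = 7)
    dup <- toy2$registry$tandemGenes
    expect_length(dup, 1L)
    parent <- sub("d$", "", dup)
    # the duplicate sits at a rank adjacent to its parent
    rk <- toy2$genesB$rank[match(c(parent, dup), toy2$genesB$gene_id)]
    expect_identical(abs(diff(rk)), 1L)
    # exactly one query has hits to two co-located genes
    multi <- table(toy2$hits$qseqid)
    expect_identical(sum(multi == 2L), 1L)

    expect_error(simulateToyGenomes(5), ">= 10")
    expect_error(simulateToyGenomes(12, nInversions = 3), "exceed")
})
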