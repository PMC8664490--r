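mkTree <- function(...) setNames(c(...), apeBranches())

test_that("the RF score is the L1 distance to the mean tree", {
    a <- mkTree(0.004, 0.003, 0.001, 0.004, 0.015)
    m <- mkTree(0.003, 0.003, 0.001, 0.004, 0.015)
    expect_identical(rfScore(a, a), 0)
    expect_equal(rfScore(a, m), 0.001)
    expect_identical(rfScore(a, m), rfScore(m, a))
})

test_that("the RF score satisfies the metric axioms", {
    withr::with_seed(2, {
        for (i in 1:50) {
            x <- mkTree(runif(5, 0, 0.05))
            y <- mkTree(runif(5, 0, 0.05))
            z <- mkTree(runif(5, 0, 0.05))
            expect_gte(rfScore(x, y), 0)
            expect_equal(rfScore(x, y), rfScore(y, x))
            expect_lte(rfScore(x, z), rfScore(x, y) + rfScore(y, z) + 1e-12)
        }
    })
})

test_that("bootstrap variance is deterministic and degenerates sensibly", {
    mt <- new("MeanTree", pcbar = mkTree(0.003, 0.003, 0.001, 0.004, 0.015),
              nFamiliesUsed = 10L, nZeroFamilies = 0L)
    fam <- countFamily(msaWithColumns(200,
        list(`3` = c("V", "A", "A", "A"), `9` = c("A", "A", "A", "W"),
             `40` = c("A", "A", "T", "T"))), familyId = "f")
    b1 <- bootstrapRFVariance(fam, mt, B = 500, seed = 7)
    b2 <- bootstrapRFVariance(fam, mt, B = 500, seed = 7)
    expect_identical(b1, b2)
    expect_gt(b1$V, 0)
    # an all-identical family has a point-mass bootstrap: V = 0
    ident <- countFamily(identicalMSA(100), familyId = "ident")
    bid <- bootstrapRFVariance(ident, mt, B = 200, seed = 1)
    expect_identical(bid$V, 0)
})

test_that("B = 1000 variance agrees with an independent larger-B run", {
    withr::with_seed(31, {
        p <- simulationParams(branchRates = clockRates * 4,
                              familyShape = Inf,
                              lengthRange = c(500L, 500L), seed = 57)
        fam <- simulateFamily(p, 1)
        counts <- countFamily(filterBlocks(fam$msa))
        mt <- new("MeanTree",
                  pcbar = mkTree(-log(1 - clockRates * 4)),
                  nFamiliesUsed = 100L, nZeroFamilies = 0L)
        vSmall <- bootstrapRFVariance(counts, mt, B = 1000, seed = 5)$V
        vBig <- bootstrapRFVariance(counts, mt, B = 10000, seed = 91)$V
        expect_lt(abs(vSmall - vBig) / vBig, 0.1)
    })
})

test_that("the Z-test handles ordinary, null and degenerate families", {
    df <- data.frame(familyId = c("a", "b", "c", "d"),
                     z = c(0, 0.00196, 0.01, 0),
                     V = c(1e-6, 1e-6, 0, 0))
    res <- rfZTest(df)
    expect_identical(res$Z[1], 0)
    expect_identical(res$p[1], 1)
    expect_equal(res$Z[2], 1.96)
    expect_equal(res$p[2], 0.04999579, tolerance = 1e-6)
    expect_true(res$untestable[3])
    expect_true(is.na(res$p[3]))
    expect_identical(res$p[4], 1)  # V = 0 but z = 0: at the mean exactly
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
    # hand trace: sorted p times n/i gives (0.04, 0.04, 0.0533, 0.8) after
    # the step-up monotonisation, so exactly the first two pass at 0.05
    # (p3 = 0.04 exceeds its step-up threshold 3/4 * 0.05 = 0.0375)
    zs <- c(2.5758293, 2.3263479, 2.0537489, 0.2533471)  # p two-sided
    df <- data.frame(familyId = letters[1:4],
                     z = zs * 1e-3, V = rep(1e-6, 4))
    res <- rfZTest(df)
    expect_equal(res$p, c(0.01, 0.02, 0.04, 0.8), tolerance = 1e-6)
    expect_equal(res$q, c(0.04, 0.04, 0.053333333, 0.8),
                 tolerance = 1e-6)
    expect_identical(res$significant, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the simulation null reproduces known marginals", {
    # N = 1: a Bernoulli event lands on branch b with probability p_b
    null1 <- simulateNull(1, clockProbs, S = 20000, seed = 3)
    freq <- null1@marginalCounts[2, ] / null1@S
    expect_true(all(abs(freq - clockProbs) <
                    3 * sqrt(clockProbs * (1 - clockProbs) / null1@S)))
    # degenerate probabilities put every event on one branch
    probs1 <- setNames(c(1, 0, 0, 0, 0), apeBranches())
    nullD <- simulateNull(7, probs1, S = 500, seed = 1)
    expect_identical(unname(nullD@marginalCounts[8, "Human"]), 500L)
    expect_identical(sum(nullD@marginalCounts[, "Gibbon"][1]), 500L)
    # determinism
    expect_identical(simulateNull(5, clockProbs, S = 1000, seed = 9),
                     simulateNull(5, clockProbs, S = 1000, seed = 9))
    expect_error(simulateNull(0, clockProbs), "N = 0")
})

test_that("marginals match the exact binomial within Monte-Carlo error", {
    for (N in c(5, 30)) {
        null <- simulateNull(N, clockProbs, S = 100000, seed = N)
        for (b in seq_len(5)) {
            empCdf <- cumsum(null@marginalCounts[, b]) / null@S
            exactCdf <- pbinom(0:N, N, clockProbs[b])
            expect_lt(max(abs(empCdf - exactCdf)), 0.01)
        }
    }
})

test_that("the branch deviation test caps, directs and thresholds correctly", {
    # a count at the null centre is not extreme: doubling caps p at 1
    probs <- setNames(rep(0.2, 5), apeBranches())
    null <- simulateNull(10, probs, S = 50000, seed = 2)
    # a family with exactly 2 substitutions per branch (N = 10)
    cols <- list()
    pats <- list(Human = c("V", "A", "A", "A"),
                 Chimpanzee = c("A", "V", "A", "A"),
                 Internal = c("V", "V", "A", "A"),
                 Gorilla = c("A", "A", "V", "A"),
                 Gibbon = c("A", "A", "A", "V"))
    k <- 1
    for (b in names(pats)) for (r in 1:2) {
        cols[[as.character(k)]] <- pats[[b]]; k <- k + 3
    }
    fam <- countFamily(msaWithColumns(60, cols), familyId = "even")
    expect_identical(unname(branchCounts(fam)), rep(2L, 5))
    res <- branchDeviationTest(fam, null)
    expect_true(all(res$p == 1))
    expect_true(all(res$direction == "none"))

    # all N events on the slowest branch: p at the simulation floor
    colsH <- setNames(lapply(1:50, function(j) c("V", "A", "A", "A")),
                      as.character(seq(1, 148, 3)))
    famH <- countFamily(msaWithColumns(160, colsH), familyId = "fastH")
    nullT <- simulateNull(50, clockProbs, S = 100000, seed = 4)
    resH <- branchDeviationTest(famH, nullT)
    hRow <- resH[resH$branch == "Human", ]
    expect_lte(hRow$p, 2 / nullT@S)
    expect_identical(hRow$direction, "faster")
    expect_true(hRow$significant)
    # the Bonferroni-adjusted threshold at defaults is alpha/5 = 0.01
    expect_identical(resH$significant, resH$p < 0.05 / 5)

    # N = 0 families are skipped with all p = 1
    zero <- countFamily(identicalMSA(40), familyId = "z")
    resZ <- branchDeviationTest(zero)
    expect_true(all(resZ$p == 1) && !any(resZ$significant))
})

test_that("dataset-level tests cache one null per distinct N", {
    p <- simulationParams(nFamilies = 20, lengthRange = c(200L, 200L),
                          seed = 67)
    counts <- lapply(simulateDataset(p), function(f)
        countFamily(filterBlocks(f$msa, familyId = f$familyId)))
    res <- datasetDeviationTests(counts, S = 2000, seed = 8)
    expect_identical(nrow(res), 20L * 5L)
    expect_true(all(res$p >= 0 & res$p <= 1))
    # determinism of the whole battery
    res2 <- datasetDeviationTests(counts, S = 2000, seed = 8)
    expect_identical(res, res2)
})

test_that("the deviation summary splits singles from combinations", {
    dev <- data.frame(
        familyId = c("f1", "f1", "f1", "f1", "f1",
                     "f2", "f2", "f2", "f2", "f2"),
        branch = rep(apeBranches(), 2),
        n = 1L, expected = 1, p = 1,
        direction = "none", significant = FALSE)
    dev$p[dev$familyId == "f1" & dev$branch == "Gibbon"] <- 0.001
    dev$direction[dev$familyId == "f1" & dev$branch == "Gibbon"] <- "faster"
    dev$significant[dev$familyId == "f1" & dev$branch == "Gibbon"] <- TRUE
    dev$significant[dev$familyId == "f2" &
                    dev$branch %in% c("Human", "Gibbon")] <- TRUE
    dev$direction[dev$familyId == "f2" & dev$branch == "Human"] <- "faster"
    dev$direction[dev$familyId == "f2" & dev$branch == "Gibbon"] <- "slower"
    s <- summaryDeviationTable(dev)
    expect_identical(s$higher[s$branches == "Gibbon"], 1L)
    expect_identical(s$higher[s$branches == "opposite directions"], 1L)
})
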