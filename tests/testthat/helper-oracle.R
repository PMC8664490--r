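# Independent, naive re-derivation of the site-pattern rules used as an
# oracle against the vectorised classifier. Works from the residue
# multiset, not from pairwise-identity bit patterns.
oracleClassify <- function(h, c_, g, b) {
    r <- c(h, c_, g, b)
    tab <- table(r)
    if (length(tab) == 1L) return("identical")
    if (length(tab) == 4L) return("no_identity")
    if (length(tab) == 2L && max(tab) == 3L) {
        lone <- names(tab)[tab == 1L]
        return(c("Human", "Chimpanzee", "Gorilla", "Gibbon")[r == lone])
    }
    if (length(tab) == 2L) {  # 2 + 2
        if (r[1] == r[2]) return("Internal")  # implies r[3] == r[4]
        return("inconsistent_2state")
    }
    # three states: locate the single repeated residue
    paired <- names(tab)[tab == 2L]
    idx <- which(r == paired)
    if (identical(idx, c(1L, 2L)) || identical(idx, c(3L, 4L)))
        "consistent_3state" else "inconsistent_3state"
}

# An all-identical four-sequence alignment of n columns.
identicalMSA <- function(n, residue = "A") {
    setNames(rep(strrep(residue, n), 4L),
             c("Human", "Chimpanzee", "Gorilla", "Gibbon"))
}

# Build a 4 x n matrix alignment, then overwrite selected columns.
msaWithColumns <- function(n, columns) {
    m <- matrix("A", nrow = 4L, ncol = n,
                dimnames = list(c("Human", "Chimpanzee", "Gorilla",
                                  "Gibbon"), NULL))
    for (j in names(columns)) m[, as.integer(j)] <- columns[[j]]
    m
}

# Genome-wide clock quantities of the ape dataset, used across tests.
clockTotals <- c(Human = 19815, Chimpanzee = 18818, Internal = 6279,
                  Gorilla = 26026, Gibbon = 97830)
clockProbs <- clockTotals / sum(clockTotals)
clockRates <- c(Human = 0.0027, Chimpanzee = 0.0026, Internal = 0.0009,
                 Gorilla = 0.0036, Gibbon = 0.0134)
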