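test_that("trimInterval reproduces the cumulative-error recurrence", {
    expect_equal(trimInterval(rep(0.01, 10)), c(1L, 10L))
    expect_equal(trimInterval(rep(0.9, 3)), integer(0))
    ## hand-simulated: s = (0, 0.04, 0.08, 0)
    expect_equal(trimInterval(c(0.5, 0.01, 0.01, 0.5)), c(2L, 3L))
    expect_error(trimInterval(numeric(0)), "non-empty")
    expect_error(trimInterval(c(0.2, 1.3)), "\\[0,1\\]")
})

test_that("trimInterval agrees with the step-by-step oracle", {
    set.seed(202)
    for (i in 1:300) {
        L <- sample(20:150, 1)
        e <- 10^(-sample(2:40, L, replace = TRUE) / 10)
        expect_identical(trimInterval(e), oracleTrim(e))
    }
})

test_that("trimmed reads respect length and ambiguity rules", {
    p <- trimParams()
    ## qualities: Q2 -> e=0.63 (bad), Q30 -> e=0.001 (good)
    bad <- "#"; good <- "?"
    mkq <- function(pattern) paste(pattern, collapse = "")
    ## 19 good bases flanked by bad ones: retained run too short
    r1 <- qsReadsQual(paste(rep("A", 25), collapse = ""),
                      mkq(c(rep(bad, 3), rep(good, 19), rep(bad, 3))))
    expect_length(trimReads(r1, p), 0)
    ## 20 good bases: exactly the minimum, kept
    r2 <- qsReadsQual(paste(rep("A", 26), collapse = ""),
                      mkq(c(rep(bad, 3), rep(good, 20), rep(bad, 3))))
    expect_length(trimReads(r2, p), 1)
    expect_equal(Biostrings::width(trimReads(r2, p)), 20)
    ## 3 Ns in the retained part: discarded; 2 Ns: kept
    s3 <- paste(c(rep("A", 10), rep("N", 3), rep("A", 17)), collapse = "")
    r3 <- qsReads(s3, "?")
    expect_length(trimReads(r3, p), 0)
    s4 <- paste(c(rep("A", 10), rep("N", 2), rep("A", 18)), collapse = "")
    expect_length(trimReads(qsReads(s4, "?"), p), 1)
})

test_that("pair trimming breaks pairs into orphans correctly", {
    good <- paste(rep("?", 30), collapse = "")
    bad <- paste(rep("#", 30), collapse = "")
    seqs <- replicate(4, randomSeq(30))
    pr <- PairedReads(
        qsReadsQual(seqs[c(1, 2)], c(good, good)),
        qsReadsQual(seqs[c(3, 4)], c(good, bad)))
    out <- trimReads(pr)
    expect_equal(length(out$pairs), 1)
    expect_equal(length(out$orphans), 1)
    expect_identical(unname(as.character(out$orphans)), seqs[2])
})

test_that("duplicate removal is pair-exact, order-keeping and idempotent", {
    a <- randomSeq(40); b <- randomSeq(40); c <- randomSeq(40)
    pr <- pairedReadsFrom(c(a, a, a), c(b, b, c))
    out <- removeDuplicates(pr)
    expect_equal(length(out$pairs), 2)        # (a,b) collapsed, (a,c) kept
    expect_identical(names(mate1(out$pairs))[1], "r0001")
    twice <- removeDuplicates(out$pairs, out$orphans)
    expect_identical(as.character(mate1(twice$pairs)),
                     as.character(mate1(out$pairs)))
    orph <- qsReads(c(a, a, b))
    expect_equal(length(removeDuplicates(pr[0], orph)$orphans), 2)
})

test_that("length-keep filter is strictly greater-than and balances", {
    seqs <- c(randomSeq(50), randomSeq(60), randomSeq(45), randomSeq(100))
    pr <- pairedReadsFrom(seqs[c(1, 2)], seqs[c(4, 3)])
    out <- lengthKeepFilter(pr, minLenKeep = 50L)
    ## pair 1: mate1 is exactly 50 -> removed, mate2 (100) orphaned
    ## pair 2: mate2 is 45 -> removed, mate1 (60) orphaned
    expect_equal(length(out$pairs), 0)
    expect_equal(length(out$orphans), 2)
    expect_setequal(unname(as.character(out$orphans)), seqs[c(2, 4)])
    allLong <- pairedReadsFrom(c(randomSeq(100)), c(randomSeq(100)))
    keptAll <- lengthKeepFilter(allLong, minLenKeep = 50L)
    expect_equal(length(keptAll$pairs), 1)
})

test_that("qc accounting conserves reads through every stage", {
    set.seed(203)
    n <- 120
    seqs1 <- replicate(n, randomSeq(80))
    seqs2 <- replicate(n, randomSeq(80))
    ## inject duplicates and low-quality tails
    seqs1[11:20] <- seqs1[1:10]; seqs2[11:20] <- seqs2[1:10]
    quals <- replicate(2 * n, rawToChar(as.raw(
        33 + sample(c(2, 30, 38), 80, replace = TRUE,
                    prob = c(0.2, 0.3, 0.5)))))
    pr <- PairedReads(qsReadsQual(seqs1, quals[1:n]),
                      qsReadsQual(seqs2, quals[(n + 1):(2 * n)]))
    res <- qcReads(pr)
    rep <- res$report
    expect_equal(as.numeric(rep["sum", ]),
                 as.numeric(rep["pairs", ] + rep["orphans", ]))
    expect_equal(rep["pairs", "raw"], 2 * n)
    ## pairs only shrink; orphan gains come from broken pairs
    expect_true(all(diff(as.numeric(rep["pairs", ])) <= 0))
    expect_lte(rep["orphans", "trimmed"] - rep["orphans", "raw"],
               (rep["pairs", "raw"] - rep["pairs", "trimmed"]) / 2)
    expect_equal(2 * length(res$pairs) + length(res$orphans),
                 rep["sum", "dup_keep"])
})

test_that("subsampling is seeded, partition-exact and uniform", {
    pr <- pairedReadsFrom(replicate(10, randomSeq(60)),
                          replicate(10, randomSeq(60)))
    all <- subsamplePairs(pr, 10, seed = 1)
    expect_equal(length(all$selected), 10)
    expect_equal(length(all$unselected), 0)
    none <- subsamplePairs(pr, 0, seed = 1)
    expect_equal(length(none$selected), 0)
    expect_error(subsamplePairs(pr, 11, seed = 1), "between 0 and")

    s1 <- subsamplePairs(pr, 4, seed = 42)
    s2 <- subsamplePairs(pr, 4, seed = 42)
    expect_identical(names(mate1(s1$selected)), names(mate1(s2$selected)))
    ## selected + unselected partition the input
    expect_setequal(c(names(mate1(s1$selected)),
                      names(mate1(s1$unselected))),
                    names(mate1(pr)))
    ## frequency of selection under n=1 is uniform (binomial oracle,
    ## trial count scaled down for runtime; 3 sigma band)
    trials <- 2000
    counts <- table(vapply(seq_len(trials), function(i)
        names(mate1(subsamplePairs(pr, 1, seed = i)$selected)),
        character(1)))
    p <- 0.1
    sigma <- sqrt(p * (1 - p) / trials)
    expect_true(all(abs(counts / trials - p) < 3 * sigma + 1e-9))
})
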