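test_that("pairwise identity follows the shorter-sequence convention", {
    set.seed(401)
    s <- randomSeq(200)
    expect_equal(pairwiseIdentity(s, s), 1)
    expect_equal(pairwiseIdentity(s, mutateSeq(s, 50)), 199 / 200)
    long <- paste0(randomSeq(100), s, randomSeq(100))
    expect_equal(pairwiseIdentity(s, long), 1)     # containment
    expect_equal(pairwiseIdentity(long, s), 1)     # symmetric
    ## reverse complement is recognized
    expect_equal(pairwiseIdentity(s, revcomp(s)), 1)
    s300 <- randomSeq(300)
    expect_equal(pairwiseIdentity(s300, mutateSeq(s300, c(10, 60, 110,
                                                          160, 210, 260))),
                 0.98)
    expect_error(pairwiseIdentity("", s), "non-empty")
})

test_that("clustering collapses duplicates and containments", {
    set.seed(402)
    base <- randomSeq(500)
    seqs <- Biostrings::DNAStringSet(c(
        a = base, b = base,                       # exact duplicate
        c = substr(base, 100, 249),               # 150 bp containment
        d = randomSeq(400),
        e = revcomp(substr(base, 1, 300))))       # rc containment
    out <- clusterTranscripts(seqs)
    expect_setequal(names(out), c("a", "d"))
    cl <- S4Vectors::metadata(out)$clusters
    expect_equal(sort(cl$member[cl$representative == "a"]),
                 c("a", "b", "c", "e"))
})

test_that("sequences below the identity threshold are both retained", {
    set.seed(403)
    s <- randomSeq(300)
    other <- mutateSeq(s, c(10, 60, 110, 160, 210, 260))  # identity 0.98
    out <- clusterTranscripts(Biostrings::DNAStringSet(c(x = s, y = other)))
    expect_setequal(names(out), c("x", "y"))
})

test_that("clustering matches the alignment-only oracle and is idempotent", {
    set.seed(404)
    truth <- replicate(12, randomSeq(sample(220:400, 1)))
    seqs <- character(0)
    for (s in truth) {
        seqs <- c(seqs, s)
        if (runif(1) < 0.6) seqs <- c(seqs, mutateSeq(s, sample(50:150, 2)))
        if (runif(1) < 0.4)
            seqs <- c(seqs, substr(s, 5, sample(230:280, 1)))
        if (runif(1) < 0.3) seqs <- c(seqs, revcomp(s))
    }
    names(seqs) <- sprintf("q%03d", seq_along(seqs))
    dss <- Biostrings::DNAStringSet(seqs)
    out <- clusterTranscripts(dss)
    expect_identical(names(out),
                     names(seqs)[oracleCluster(seqs, 0.99, 200L)])
    ## idempotence
    again <- clusterTranscripts(out)
    expect_identical(as.character(again), as.character(out))
    ## no retained pair above the threshold, output subset of input
    kept <- as.character(out)
    if (length(kept) > 1) {
        for (i in seq_len(length(kept) - 1))
            for (j in (i + 1):length(kept))
                expect_lte(pairwiseIdentity(kept[i], kept[j]), 0.99)
    }
    expect_true(all(names(out) %in% names(dss)))
})

test_that("every removed sequence has a longer retained representative", {
    set.seed(405)
    base <- replicate(8, randomSeq(sample(250:450, 1)))
    seqs <- c(base, vapply(base[1:5], function(s)
        substr(s, 1, 240), character(1)))
    names(seqs) <- sprintf("m%02d", seq_along(seqs))
    out <- clusterTranscripts(Biostrings::DNAStringSet(seqs))
    cl <- S4Vectors::metadata(out)$clusters
    removed <- cl[cl$representative != cl$member, ]
    for (r in seq_len(nrow(removed))) {
        repSeq <- seqs[removed$representative[r]]
        memSeq <- seqs[removed$member[r]]
        expect_gte(nchar(repSeq), nchar(memSeq))
        expect_gt(pairwiseIdentity(repSeq, memSeq), 0.99)
    }
})
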