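test_that("exact and reverse-complement substrings map end-to-end", {
    set.seed(501)
    tx <- randomDnaSet(5, 400, 800, "t")
    txc <- as.character(tx)
    r1 <- substr(txc[2], 101, 200)
    r2 <- revcomp(substr(txc[4], 51, 150))
    res <- mapReads(c(r1, r2), tx)
    h <- as.data.frame(hits(res))
    expect_equal(nrow(h), 2)
    expect_equal(h$transcript, c("t0002", "t0004"))
    expect_equal(h$pos, c(101L, 51L))
    expect_equal(h$strand, c("+", "-"))
    expect_equal(h$mismatches, c(0L, 0L))
})

test_that("the mismatch budget is a hard cap", {
    set.seed(502)
    tx <- randomDnaSet(3, 500, 500, "t")
    read <- substr(as.character(tx)[1], 201, 300)
    ok <- mutateSeq(read, c(10, 30, 50, 70))       # 4 mismatches: allowed
    bad <- mutateSeq(read, c(10, 30, 50, 70, 90))  # 5 > floor(0.04*100)
    res <- mapReads(c(ok, bad), tx)
    h <- as.data.frame(hits(res))
    expect_equal(h$read, 1L)
    expect_equal(h$mismatches, 4L)
    expect_false(oracleMapped(bad, tx, 4L))        # oracle concurs
})

test_that("error-free simulated reads all map; foreign reads do not", {
    cfg <- simConfig(nTranscripts = 50, seed = 503, baseErrorRate = 0)
    sim <- simulateTranscriptome(cfg)
    rd <- simulateReads(sim$transcripts, sim$weights, 1000, cfg)
    expect_equal(rmbtPercent(mapReads(rd$reads, sim$transcripts)), 100)
    foreign <- simulateTranscriptome(simConfig(nTranscripts = 20,
                                               seed = 901,
                                               baseErrorRate = 0))
    rdF <- simulateReads(foreign$transcripts, foreign$weights, 500,
                         simConfig(seed = 901, baseErrorRate = 0))
    expect_lte(rmbtPercent(mapReads(rdF$reads, sim$transcripts)), 0.1)
})

test_that("mapping agrees with the all-offsets scanner under errors", {
    set.seed(504)
    tx <- randomDnaSet(10, 300, 1200, "t")
    txc <- as.character(tx)
    reads <- character(200)
    for (i in seq_len(200)) {
        ti <- sample(10, 1)
        st <- sample(nchar(txc[ti]) - 99, 1)
        r <- substr(txc[ti], st, st + 99)
        nmut <- sample(0:6, 1)             # straddles the 4-mismatch cap
        if (nmut > 0) r <- mutateSeq(r, sample(100, nmut))
        if (runif(1) < 0.5) r <- revcomp(r)
        reads[i] <- r
    }
    res <- mapReads(reads, tx)
    mapped <- seq_along(reads) %in% hits(res)$read
    oracle <- vapply(reads, oracleMapped, logical(1),
                     transcripts = tx, mm = 4L, USE.NAMES = FALSE)
    expect_identical(mapped, oracle)
    ## reported loci are genuine: re-check mismatch counts directly
    h <- as.data.frame(hits(res))
    for (r in seq_len(nrow(h))) {
        q <- if (h$strand[r] == "+") reads[h$read[r]] else
            revcomp(reads[h$read[r]])
        seg <- substr(txc[h$transcript[r]], h$pos[r], h$pos[r] + 99)
        expect_equal(sum(charToRaw(q) != charToRaw(seg)), h$mismatches[r])
        expect_lte(h$mismatches[r], 4L)
    }
})

test_that("rmbt percentage is invariant to read and transcript order", {
    set.seed(505)
    tx <- randomDnaSet(8, 300, 600, "t")
    txc <- as.character(tx)
    reads <- c(vapply(1:30, function(i) {
        ti <- sample(8, 1)
        st <- sample(nchar(txc[ti]) - 79, 1)
        substr(txc[ti], st, st + 79)
    }, character(1)), replicate(10, randomSeq(80)))
    p1 <- rmbtPercent(mapReads(reads, tx))
    p2 <- rmbtPercent(mapReads(rev(reads), tx[sample(8)]))
    expect_equal(p1, p2)
    expect_equal(p1, 100 * 30 / 40)
})

test_that("rmbt percentage handles the degenerate cases", {
    tx <- Biostrings::DNAStringSet(c(t1 = randomSeq(300)))
    allHit <- mapReads(substr(as.character(tx), 10, 109), tx)
    expect_equal(rmbtPercent(allHit), 100)
    noHit <- mapReads(randomSeq(100), tx)
    expect_equal(rmbtPercent(noHit), 0)
    expect_error(rmbtPercent(mapReads(character(0), tx)), "no reads")
})

test_that("SAM adapter counts primary mapped records", {
    sam <- c("@HD\tVN:1.6",
             "@SQ\tSN:t1\tLN:500",
             "r1\t0\tt1\t10\t42\t100M\t*\t0\t0\tACGT\tIIII",
             "r2\t16\tt1\t60\t42\t100M\t*\t0\t0\tACGT\tIIII",
             "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII",
             "r1\t256\tt1\t99\t0\t100M\t*\t0\t0\tACGT\tIIII")
    f <- tempfile(fileext = ".sam")
    writeLines(sam, f)
    res <- readSamMapped(f)
    expect_equal(nReads(res), 3L)
    expect_equal(rmbtPercent(res), 100 * 2 / 3)
    expect_equal(as.data.frame(hits(res))$strand, c("+", "-"))
})
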