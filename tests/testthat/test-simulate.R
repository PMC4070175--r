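test_that("transcriptome simulation is seed-deterministic and bounded", {
    cfg <- simConfig(nTranscripts = 10, seed = 701)
    a <- simulateTranscriptome(cfg)
    b <- simulateTranscriptome(cfg)
    expect_identical(as.character(a$transcripts),
                     as.character(b$transcripts))
    expect_identical(a$weights, b$weights)
    expect_true(all(Biostrings::width(a$transcripts) >= 200))
    expect_true(all(Biostrings::width(a$transcripts) <= 10000))
    expect_equal(sum(a$weights), 1, tolerance = 1e-12)
    c <- simulateTranscriptome(simConfig(nTranscripts = 10, seed = 702))
    expect_false(identical(as.character(a$transcripts),
                           as.character(c$transcripts)))
})

test_that("error-free reads are exact fragments of their transcripts", {
    cfg <- simConfig(nTranscripts = 8, seed = 703, baseErrorRate = 0)
    sim <- simulateTranscriptome(cfg)
    rd <- simulateReads(sim$transcripts, sim$weights, 400, cfg)
    expect_equal(length(rd$reads), 400)
    txc <- as.character(sim$transcripts)
    tr <- rd$truth
    r1 <- unname(as.character(as(mate1(rd$reads), "DNAStringSet")))
    r2 <- unname(as.character(as(mate2(rd$reads), "DNAStringSet")))
    for (i in seq_len(50)) {
        tx <- unname(txc[tr$transcript[i]])
        expect_identical(r1[i], substr(tx, tr$frag_start[i],
                                       tr$frag_start[i] + 99))
        e <- tr$frag_start[i] + tr$insert[i] - 1
        expect_identical(r2[i], revcomp(substr(tx, e - 99, e)))
    }
    ## insert sizes respect the truncation contract
    expect_true(all(tr$insert >= 100))
    expect_true(all(tr$insert <= Biostrings::width(
        sim$transcripts)[match(tr$transcript,
                               names(sim$transcripts))]))
})

test_that("errors carry low quality and determinism holds end to end", {
    cfg <- simConfig(nTranscripts = 5, seed = 704, baseErrorRate = 0.02)
    sim <- simulateTranscriptome(cfg)
    rd1 <- simulateReads(sim$transcripts, sim$weights, 200, cfg)
    rd2 <- simulateReads(sim$transcripts, sim$weights, 200, cfg)
    expect_identical(as.character(mate1(rd1$reads)),
                     as.character(mate1(rd2$reads)))
    txc <- as.character(sim$transcripts)
    r1 <- unname(as.character(as(mate1(rd1$reads), "DNAStringSet")))
    q1 <- as.character(Biostrings::quality(mate1(rd1$reads)))
    tr <- rd1$truth
    ## wherever the read deviates from its source fragment, quality is low
    mismAt <- function(i) {
        frag <- substr(txc[tr$transcript[i]], tr$frag_start[i],
                       tr$frag_start[i] + 99)
        which(charToRaw(r1[i]) != charToRaw(frag))
    }
    found <- FALSE
    for (i in seq_len(200)) {
        mm <- mismAt(i)
        if (!length(mm)) next
        found <- TRUE
        qual <- utf8ToInt(q1[i]) - 33L
        expect_true(all(qual[mm] == 12L))
        expect_true(all(qual[-mm] == 38L))
    }
    expect_true(found)
})

test_that("expression weights drive read counts (goodness of fit)", {
    tx <- Biostrings::DNAStringSet(c(hi = randomSeq(1000),
                                     lo = randomSeq(1000)))
    cfg <- simConfig(nTranscripts = 2, seed = 705, baseErrorRate = 0)
    rd <- simulateReads(tx, c(hi = 0.9, lo = 0.1), 10000, cfg)
    counts <- table(factor(rd$truth$transcript, levels = c("hi", "lo")))
    p <- stats::chisq.test(counts, p = c(0.9, 0.1))$p.value
    expect_gt(p, 0.001)
})

test_that("tool profiles corrupt assemblies as configured", {
    cfg <- simConfig(nTranscripts = 10, seed = 706)
    sim <- simulateTranscriptome(cfg)
    clean <- simulateToolAssemblies(
        sim$transcripts,
        list(pure = toolProfile(fragmentationRate = 0, dropoutRate = 0,
                                noiseContigs = 0, substitutionRate = 0)),
        seed = 706)
    expect_identical(unname(as.character(clean$assemblies$pure)),
                     unname(as.character(sim$transcripts)))
    onlyNoise <- simulateToolAssemblies(
        sim$transcripts,
        list(none = toolProfile(dropoutRate = 1, noiseContigs = 5)),
        seed = 706)
    expect_equal(length(onlyNoise$assemblies$none), 5)
    expect_true(all(onlyNoise$truth$source == "noise"))
})

test_that("forced fragmentation is reversible by consensus merging", {
    tmpl <- Biostrings::DNAStringSet(c(tx00001 = randomSeq(1000)))
    frag <- simulateToolAssemblies(
        tmpl, list(f = toolProfile(fragmentationRate = 1, dropoutRate = 0,
                                   noiseContigs = 0, substitutionRate = 0)),
        seed = 707)
    expect_gte(length(frag$assemblies$f), 2)
    m <- mergeAssemblies(list(frag$assemblies$f),
                         mergeParams(minTools = 1))
    expect_equal(length(contigs(m)), 1)
    cons <- unname(as.character(contigs(m)))
    t0 <- unname(as.character(tmpl))
    expect_true(cons == t0 || cons == revcomp(t0))
})
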