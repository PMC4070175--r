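test_that("findOverlap detects dovetail, containment and orientation", {
    set.seed(601)
    x <- randomSeq(200); y <- randomSeq(60); z <- randomSeq(180)
    a <- paste0(x, y)
    b <- paste0(y, z)
    ov <- findOverlap(a, b)
    expect_equal(ov$length, 60)
    expect_equal(ov$identity, 1)
    expect_equal(ov$orientation, 1)
    expect_equal(ov$offset, 200)
    expect_equal(ov$type, "dovetail")

    inner <- substr(a, 50, 149)
    ovc <- findOverlap(a, inner)
    expect_equal(ovc$type, "containment")
    expect_equal(ovc$offset, 49)
    expect_equal(ovc$identity, 1)

    ovr <- findOverlap(a, revcomp(b))
    expect_equal(ovr$orientation, -1)
    expect_equal(ovr$length, 60)
})

test_that("random unrelated sequences yield no qualifying overlap", {
    set.seed(602)
    hits <- 0
    for (i in 1:300) {
        if (!is.null(findOverlap(randomSeq(300), randomSeq(300))))
            hits <- hits + 1
    }
    expect_equal(hits, 0)
})

test_that("identical contigs from three tools merge with full provenance", {
    set.seed(603)
    s <- randomSeq(500)
    mk <- function(tool) Assembly(
        Biostrings::DNAStringSet(c(c1 = s)), tool, 31)
    m <- mergeAssemblies(list(mk("A"), mk("B"), mk("C")))
    expect_equal(length(contigs(m)), 1)
    expect_equal(nrow(provenance(m)), 3)
    expect_equal(unname(nTools(m)), 3L)
    expect_identical(unname(as.character(contigs(m))), s)
})

test_that("fragments from a template merge into the template consensus", {
    set.seed(604)
    tmpl <- randomSeq(900)
    fragA <- substr(tmpl, 1, 520)             # tool A: left piece
    fragB <- substr(tmpl, 461, 900)           # tool B: right piece (60 ov)
    whole <- revcomp(tmpl)                    # tool C: contains both
    asms <- list(
        Assembly(Biostrings::DNAStringSet(c(f = fragA)), "A", 21),
        Assembly(Biostrings::DNAStringSet(c(f = fragB)), "B", 21),
        Assembly(Biostrings::DNAStringSet(c(f = whole)), "C", 21))
    m <- mergeAssemblies(asms)
    expect_equal(length(contigs(m)), 1)
    expect_equal(unname(nTools(m)), 3L)
    cons <- unname(as.character(contigs(m)))
    expect_true(cons == tmpl || cons == revcomp(tmpl))
})

test_that("non-overlapping contigs stay singlets and conservation holds", {
    set.seed(605)
    asms <- list(
        Assembly(randomDnaSet(5, 300, 400, "a"), "A", 21),
        Assembly(randomDnaSet(4, 300, 400, "b"), "B", 21))
    m <- mergeAssemblies(asms)
    expect_equal(length(contigs(m)), 9)
    expect_equal(nrow(provenance(m)), 9)     # constituent conservation
    expect_true(all(nTools(m) == 1))
    ## every input contig appears exactly once
    expect_equal(anyDuplicated(provenance(m)$constituent_id), 0L)
})

test_that("robust filter counts tools, not assemblies, and is monotone", {
    set.seed(606)
    s <- randomSeq(400)
    asms <- list(
        Assembly(Biostrings::DNAStringSet(c(c1 = s)), "A", 21),
        Assembly(Biostrings::DNAStringSet(c(c1 = s)), "A", 35),  # same tool
        Assembly(Biostrings::DNAStringSet(c(c1 = s)), "B", 21),
        Assembly(Biostrings::DNAStringSet(c(c1 = randomSeq(300))), "C", 21))
    m <- mergeAssemblies(asms)
    ## merged contig has constituents from assemblies A/21, A/35, B/21:
    ## two distinct tools only
    expect_equal(length(contigs(robustFilter(m, 2))), 1)
    expect_equal(length(contigs(robustFilter(m, 3))), 0)
    ## min_tools = 1 keeps everything; monotone decreasing
    expect_equal(length(contigs(robustFilter(m, 1))), length(contigs(m)))
    sizes <- vapply(1:4, function(k)
        length(contigs(robustFilter(m, k))), integer(1))
    expect_true(all(diff(sizes) <= 0))
    ## strict mode requires every input assembly
    expect_equal(length(contigs(robustFilter(m, strict = TRUE))), 0)
})

test_that("simulated multi-tool assemblies yield noise-free robust sets", {
    cfg <- simConfig(nTranscripts = 30, seed = 607)
    sim <- simulateTranscriptome(cfg)
    pr <- list(t1 = toolProfile(), t2 = toolProfile(), t3 = toolProfile())
    ta <- simulateToolAssemblies(sim$transcripts, pr, seed = 607)
    m <- mergeAssemblies(unname(ta$assemblies))
    rb <- robustFilter(m, 3)
    src <- setNames(ta$truth$source,
                    paste(ta$truth$tool, "sim", ta$truth$contig_id,
                          sep = "_"))
    pv <- as.data.frame(provenance(rb))
    expect_false(any(src[pv$constituent_id] == "noise"))
    recovered <- unique(src[pv$constituent_id])
    expect_gte(length(setdiff(recovered, "noise")) /
               length(sim$transcripts), 0.95)
    ## total conservation across the unfiltered merge
    expect_equal(nrow(provenance(m)), sum(vapply(ta$assemblies, length,
                                                 integer(1))))
})
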