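## shared fixtures and independent oracles, all built in code

randomSeq <- function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

randomDnaSet <- function(n, minLen, maxLen, prefix = "s") {
    lens <- sample(minLen:maxLen, n, replace = TRUE)
    x <- Biostrings::DNAStringSet(vapply(lens, randomSeq, character(1)))
    names(x) <- sprintf("%s%04d", prefix, seq_len(n))
    x
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

mutateSeq <- function(s, positions) {
    ch <- strsplit(s, "")[[1]]
    for (p in positions)
        ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
}

## literal simulation of the cumulative-error trimming recurrence:
## walk base by base, clamp at zero, track last argmax and run start
oracleTrim <- function(e, limit = 0.05) {
    s <- 0
    best <- 0
    end <- 0L
    runStart <- 0L
    start <- 0L
    for (i in seq_along(e)) {
        s <- s + (limit - e[i])
        if (s <= 0) {
            s <- max(0, s)
            runStart <- 0L
        } else if (runStart == 0L) {
            runStart <- i
        }
        if (s > 0 && s >= best) {
            best <- s
            end <- i
            start <- runStart
        }
    }
    if (end == 0L) integer(0) else c(start, end)
}

## sort-descending-and-accumulate N50
oracleN50 <- function(lengths) {
    s <- sort(lengths, decreasing = TRUE)
    tot <- sum(s)
    acc <- 0
    for (x in s) {
        acc <- acc + x
        if (acc >= tot / 2) return(x)
    }
}

## all-offsets end-to-end scan: is there any gapless full-length placement
## of the read (either strand) with at most mm mismatches?
oracleMapped <- function(read, transcripts, mm) {
    pats <- c(read, revcomp(read))
    for (p in pats) {
        hits <- Biostrings::vcountPattern(p, transcripts, max.mismatch = mm,
                                          with.indels = FALSE)
        if (any(hits > 0)) return(TRUE)
    }
    FALSE
}

## build a QualityScaledDNAStringSet from sequences and a quality char
qsReads <- function(seqs, qualChar = "I", ids = NULL) {
    quals <- vapply(nchar(seqs), function(L)
        paste(rep(qualChar, L), collapse = ""), character(1))
    x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs),
        Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
    names(x) <- if (is.null(ids)) sprintf("r%04d", seq_along(seqs)) else ids
    x
}

qsReadsQual <- function(seqs, quals, ids = NULL) {
    x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs),
        Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
    names(x) <- if (is.null(ids)) sprintf("r%04d", seq_along(seqs)) else ids
    x
}

pairedReadsFrom <- function(seqs1, seqs2, qualChar = "I") {
    PairedReads(qsReads(seqs1, qualChar), qsReads(seqs2, qualChar))
}

## greedy longest-first clustering oracle using only pairwiseIdentity
oracleCluster <- function(seqs, threshold, minLenKeep) {
    ord <- order(-nchar(seqs))
    reps <- integer(0)
    for (i in ord) {
        dup <- FALSE
        for (r in reps) {
            if (pairwiseIdentity(seqs[i], seqs[r]) > threshold) {
                dup <- TRUE
                break
            }
        }
        if (!dup) reps <- c(reps, i)
    }
    sort(reps[nchar(seqs[reps]) > minLenKeep])
}
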