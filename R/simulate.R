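## Seeded synthetic ground truth: transcriptomes with expression weights,
## paired-end reads with an error/quality model, and corrupted multi-tool
## assemblies. Everything is deterministic under a fixed seed and every
## simulation emits its ground-truth map.

#' Configuration for the read simulator
#'
#' Defaults state the emulated protocol: 100 bp paired-end reads from
#' cDNA fragments with insert size about 305 +/- 30 bp, transcript lengths
#' log-normal truncated to [200, 10000] bp, log-normal expression weights
#' (coverage varies with expression), and a small uniform substitution
#' error rate.
#'
#' @param nTranscripts number of transcripts.
#' @param lengthMeanlog,lengthSdlog log-normal parameters of transcript
#'   length (defaults 7 and 0.6, median about 1.1 kb).
#' @param lengthRange truncation interval for lengths (bp).
#' @param exprSdlog sd-log of the log-normal expression weights (mean-log
#'   0; default 1.5, a wide dynamic range).
#' @param readLen read length in bp (default 100).
#' @param insertMean,insertSd insert size distribution (defaults 305, 30).
#' @param baseErrorRate per-base substitution probability (default 0.005).
#' @param seed integer seed driving all randomness.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nTranscripts = 500L, lengthMeanlog = 7,
                      lengthSdlog = 0.6, lengthRange = c(200L, 10000L),
                      exprSdlog = 1.5, readLen = 100L, insertMean = 305,
                      insertSd = 30, baseErrorRate = 0.005, seed = 1L) {
    stopifnot(nTranscripts >= 1, lengthRange[1] >= 1,
              lengthRange[2] >= lengthRange[1], readLen >= 1,
              insertMean >= readLen, insertSd >= 0,
              baseErrorRate >= 0, baseErrorRate <= 1)
    structure(list(nTranscripts = as.integer(nTranscripts),
                   lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
                   lengthRange = as.integer(lengthRange),
                   exprSdlog = exprSdlog, readLen = as.integer(readLen),
                   insertMean = insertMean, insertSd = insertSd,
                   baseErrorRate = baseErrorRate, seed = as.integer(seed)),
              class = "SimConfig")
}

#' Assembly-corruption profile for one simulated tool
#'
#' @param fragmentationRate probability a transcript is emitted as two or
#'   more overlapping fragments rather than whole.
#' @param dropoutRate probability a transcript is missing entirely.
#' @param noiseContigs number of tool-private random contigs.
#' @param substitutionRate per-base substitution rate in emitted contigs.
#' @return A validated list of class \code{"ToolProfile"}.
#' @export
toolProfile <- function(fragmentationRate = 0.3, dropoutRate = 0,
                        noiseContigs = 20L, substitutionRate = 0.002) {
    stopifnot(fragmentationRate >= 0, fragmentationRate <= 1,
              dropoutRate >= 0, dropoutRate <= 1, noiseContigs >= 0,
              substitutionRate >= 0, substitutionRate <= 1)
    structure(list(fragmentationRate = fragmentationRate,
                   dropoutRate = dropoutRate,
                   noiseContigs = as.integer(noiseContigs),
                   substitutionRate = substitutionRate),
              class = "ToolProfile")
}

.rtruncLnorm <- function(n, meanlog, sdlog, lo, hi) {
    out <- integer(0)
    while (length(out) < n) {
        x <- round(rlnorm(n, meanlog, sdlog))
        out <- c(out, x[x >= lo & x <= hi])
    }
    as.integer(out[seq_len(n)])
}

.substitute <- function(seqs, rate) {
    if (rate <= 0) return(list(seqs = seqs, errPos = vector("list",
                                                            length(seqs))))
    errPos <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        L <- nchar(seqs[i])
        hit <- which(runif(L) < rate)
        errPos[[i]] <- hit
        if (length(hit)) {
            ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
            for (p in hit)
                ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
            seqs[i] <- paste(ch, collapse = "")
        }
    }
    list(seqs = seqs, errPos = errPos)
}

#' Simulate a ground-truth transcriptome with expression weights
#'
#' Sequences are i.i.d. uniform over \{A,C,G,T\} at log-normal lengths
#' truncated to \code{config$lengthRange}; expression weights are
#' log-normal, normalized to sum to one.
#'
#' @param config a [simConfig()] list.
#' @return \code{list(transcripts, weights)}: a named \code{DNAStringSet}
#'   (\code{tx00001}, ...) and a parallel numeric weight vector.
#' @export
simulateTranscriptome <- function(config = simConfig()) {
    .withSeed(config$seed, {
        lens <- .rtruncLnorm(config$nTranscripts, config$lengthMeanlog,
                             config$lengthSdlog, config$lengthRange[1],
                             config$lengthRange[2])
        seqs <- .randomDna(lens)
        wts <- rlnorm(config$nTranscripts, 0, config$exprSdlog)
        wts <- wts / sum(wts)
        tx <- DNAStringSet(seqs)
        names(tx) <- sprintf("tx%05d", seq_along(tx))
        list(transcripts = tx, weights = setNames(wts, names(tx)))
    })
}

#' Simulate paired-end reads from a weighted transcriptome
#'
#' Fragments are drawn from transcripts with probability proportional to
#' weight times the number of eligible start positions; the insert length
#' is normal (\code{insertMean}, \code{insertSd}) rounded and truncated to
#' [readLen, transcript length]. Mate 1 is the fragment's 5' read; mate 2
#' is the reverse complement of its 3' read. Substitution errors occur at
#' \code{baseErrorRate}; quality strings are constant high quality (Q38)
#' except at error positions (Q12), so trimming has signal to act on.
#' Transcripts shorter than the read length are excluded with a warning.
#'
#' @param transcripts named \code{DNAStringSet}.
#' @param weights numeric weights parallel to \code{transcripts}.
#' @param nPairs number of read pairs (> 0).
#' @param config a [simConfig()] list (read length, insert model, error
#'   rate, seed).
#' @return \code{list(reads, truth)}: a \linkS4class{PairedReads} and a
#'   data.frame (\code{read_id}, \code{transcript}, \code{frag_start},
#'   \code{insert}) of fragment ground truth.
#' @export
simulateReads <- function(transcripts, weights, nPairs,
                          config = simConfig()) {
    nPairs <- as.integer(nPairs)
    if (nPairs <= 0L) stop("nPairs must be positive", call. = FALSE)
    txLen <- width(transcripts)
    ok <- txLen >= config$readLen
    if (!all(ok)) {
        warning(sum(!ok), " transcripts shorter than the read length ",
                "were excluded")
        transcripts <- transcripts[ok]
        weights <- weights[ok]
        txLen <- txLen[ok]
    }
    txChr <- as.character(transcripts)
    .withSeed(config$seed + 1L, {
        p <- weights * (txLen - config$readLen + 1)
        tIdx <- sample.int(length(txChr), nPairs, replace = TRUE,
                           prob = p / sum(p))
        ins <- pmin(pmax(round(rnorm(nPairs, config$insertMean,
                                     config$insertSd)),
                         config$readLen), txLen[tIdx])
        start <- floor(runif(nPairs) * (txLen[tIdx] - ins + 1)) + 1L
        r1 <- substring(txChr[tIdx], start, start + config$readLen - 1L)
        r2 <- .rcChar(substring(txChr[tIdx], start + ins - config$readLen,
                                start + ins - 1L))
        e1 <- .substitute(r1, config$baseErrorRate)
        e2 <- .substitute(r2, config$baseErrorRate)
        qual <- function(errs) vapply(errs, function(pp) {
            q <- rep(38L, config$readLen)
            q[pp] <- 12L
            rawToChar(as.raw(q + 33L))
        }, character(1))
        ids <- sprintf("read%07d", seq_len(nPairs))
        mk <- function(sq, ql) {
            x <- QualityScaledDNAStringSet(DNAStringSet(sq),
                                           PhredQuality(BStringSet(ql)))
            names(x) <- ids
            x
        }
        list(reads = PairedReads(mk(e1$seqs, qual(e1$errPos)),
                                 mk(e2$seqs, qual(e2$errPos))),
             truth = data.frame(read_id = ids,
                                transcript = names(transcripts)[tIdx],
                                frag_start = start, insert = ins))
    })
}

#' Simulate per-tool corrupted assemblies of a known transcriptome
#'
#' Per tool: each transcript is dropped with probability
#' \code{dropoutRate}; otherwise it is emitted whole or, with probability
#' \code{fragmentationRate}, as two overlapping fragments (overlap at
#' least 50 bp), with substitution errors at \code{substitutionRate}.
#' \code{noiseContigs} tool-private random contigs are appended. The
#' ground-truth map (contig to source transcript, or "noise") is returned
#' alongside the labeled assemblies.
#'
#' @param transcripts named \code{DNAStringSet} of true transcripts.
#' @param profiles named list of [toolProfile()] lists; names are tool
#'   names.
#' @param seed integer seed.
#' @param minFragOverlap minimum overlap between fragments of a split
#'   transcript (default 50 bp).
#' @return \code{list(assemblies, truth)}: a list of
#'   \linkS4class{Assembly} (k label "sim") and a data.frame
#'   (\code{tool}, \code{contig_id}, \code{source}).
#' @export
simulateToolAssemblies <- function(transcripts, profiles, seed = 1L,
                                   minFragOverlap = 50L) {
    stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
    txChr <- as.character(transcripts)
    txLen <- nchar(txChr)
    .withSeed(seed + 2L, {
        assemblies <- list()
        truth <- list()
        for (tool in names(profiles)) {
            pr <- profiles[[tool]]
            outSeq <- character(0)
            outSrc <- character(0)
            for (ti in seq_along(txChr)) {
                if (runif(1) < pr$dropoutRate) next
                L <- txLen[ti]
                frag <- runif(1) < pr$fragmentationRate &&
                        L >= 2L * minFragOverlap + 2L
                if (frag) {
                    ov <- minFragOverlap +
                        sample.int(max(1L, min(30L, L - 2L * minFragOverlap)),
                                   1L) - 1L
                    cut <- sample.int(L - ov - 1L, 1L)
                    pieces <- c(substring(txChr[ti], 1L, cut + ov),
                                substring(txChr[ti], cut + 1L, L))
                } else {
                    pieces <- txChr[ti]
                }
                outSeq <- c(outSeq, pieces)
                outSrc <- c(outSrc, rep(names(txChr)[ti], length(pieces)))
            }
            outSeq <- .substitute(outSeq, pr$substitutionRate)$seqs
            if (pr$noiseContigs > 0L) {
                nl <- .rtruncLnorm(pr$noiseContigs, 6.2, 0.4, 250L, 2000L)
                outSeq <- c(outSeq, .randomDna(nl))
                outSrc <- c(outSrc, rep("noise", pr$noiseContigs))
            }
            ids <- sprintf("c%05d", seq_along(outSeq))
            ctg <- DNAStringSet(outSeq)
            names(ctg) <- ids
            assemblies[[tool]] <- Assembly(ctg, tool = tool, k = "sim")
            truth[[tool]] <- data.frame(tool = tool, contig_id = ids,
                                        source = outSrc)
        }
        list(assemblies = assemblies, truth = do.call(rbind, truth))
    })
}
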