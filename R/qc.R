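## Read quality control: cumulative-error quality trimming, ambiguity and
## length filters, duplicate removal, and seeded subsampling, with
## per-stage read accounting.

#' Parameters for read trimming and filtering
#'
#' Defaults follow the workflow's stated settings: trim limit 0.05, at most
#' 2 ambiguous bases, minimum post-trim length 20, and a strict > 50 bp
#' keep filter applied after duplicate removal.
#'
#' @param limit error-probability threshold of the trimmer, in (0,1).
#' @param maxAmbiguous maximum number of 'N' bases tolerated in a trimmed
#'   read.
#' @param minLenPostTrim minimum retained length after trimming (bp).
#' @param minLenKeep reads must be strictly longer than this (bp) to be
#'   kept in the final filter.
#' @return A validated list of class \code{"TrimParams"}.
#' @export
trimParams <- function(limit = 0.05, maxAmbiguous = 2L,
                       minLenPostTrim = 20L, minLenKeep = 50L) {
    stopifnot(limit > 0, limit < 1, maxAmbiguous >= 0,
              minLenPostTrim >= 1, minLenKeep >= 1)
    structure(list(limit = limit,
                   maxAmbiguous = as.integer(maxAmbiguous),
                   minLenPostTrim = as.integer(minLenPostTrim),
                   minLenKeep = as.integer(minLenKeep)),
              class = "TrimParams")
}

#' Quality-trim interval of a read from base error probabilities
#'
#' Implements cumulative-error trimming: for each base the error
#' probability is subtracted from \code{limit}; the running total of
#' (limit - error) is clamped at zero whenever it becomes negative. The
#' retained part of the read starts at the first position of the final
#' positive run and ends at the running total's maximum. If the maximum is
#' attained several times the last such position is used (retaining more
#' sequence); if the running total never becomes positive the read is
#' discarded.
#'
#' The clamped recursion \eqn{s_i = \max(0, s_{i-1} + (limit - e_i))} is
#' evaluated through the equivalent closed form
#' \eqn{s_i = c_i - \min(0, \min_{j \le i} c_j)} with
#' \eqn{c_i = \sum_{j \le i} (limit - e_j)}.
#'
#' @param errorProbs numeric vector of per-base error probabilities in
#'   [0,1].
#' @param limit trim threshold (default 0.05).
#' @return Integer vector \code{c(start, end)} (1-based, inclusive), or
#'   \code{integer(0)} if the whole read is discarded.
#' @examples
#' trimInterval(rep(0.01, 10))            # whole read: c(1, 10)
#' trimInterval(c(0.5, 0.01, 0.01, 0.5))  # c(2, 3)
#' trimInterval(rep(0.9, 3))              # integer(0)
#' @export
trimInterval <- function(errorProbs, limit = 0.05) {
    if (length(errorProbs) == 0L)
        stop("errorProbs must be non-empty", call. = FALSE)
    if (any(errorProbs < 0 | errorProbs > 1))
        stop("error probabilities must lie in [0,1]", call. = FALSE)
    cs <- cumsum(limit - errorProbs)
    s <- cs - pmin(0, cummin(cs))
    m <- max(s)
    if (m <= 0) return(integer(0))
    end <- max(which(s == m))
    zeros <- which(s[seq_len(end)] <= 0)
    start <- if (length(zeros)) max(zeros) + 1L else 1L
    c(as.integer(start), as.integer(end))
}

## trim a QualityScaledDNAStringSet; returns list(reads = kept trimmed
## reads, kept = logical over the input)
.trimSet <- function(reads, params) {
    n <- length(reads)
    if (n == 0L) return(list(reads = reads, kept = logical(0)))
    qints <- .qualityInts(reads)
    iv <- vapply(qints, function(q) {
        r <- trimInterval(10^(-q / 10), params$limit)
        if (length(r)) r else c(0L, -1L)
    }, integer(2))
    kept <- iv[2L, ] - iv[1L, ] + 1L >= params$minLenPostTrim
    trimmed <- .sliceQualityScaled(reads[kept],
                                   start = iv[1L, kept], end = iv[2L, kept])
    nN <- alphabetFrequency(as(trimmed, "DNAStringSet"))[, "N", drop = TRUE]
    ok <- nN <= params$maxAmbiguous
    kept[kept] <- ok
    list(reads = trimmed[ok], kept = kept)
}

#' Quality-trim reads
#'
#' Applies [trimInterval()] to every read (using its Phred qualities),
#' discards reads whose retained part is shorter than
#' \code{params$minLenPostTrim} or contains more than
#' \code{params$maxAmbiguous} 'N' bases. For paired input, a pair whose two
#' mates survive stays a pair; if exactly one mate survives it becomes an
#' orphan.
#'
#' @param x a \linkS4class{PairedReads} or
#'   \code{QualityScaledDNAStringSet}.
#' @param params a [trimParams()] list.
#' @return For paired input, \code{list(pairs, orphans)}; for single-end
#'   input, the trimmed \code{QualityScaledDNAStringSet}.
#' @export
setGeneric("trimReads", function(x, params = trimParams())
    standardGeneric("trimReads"))

#' @rdname trimReads
#' @export
setMethod("trimReads", "QualityScaledDNAStringSet", function(x, params) {
    .trimSet(x, params)$reads
})

#' @rdname trimReads
#' @export
setMethod("trimReads", "PairedReads", function(x, params) {
    t1 <- .trimSet(x@r1, params)
    t2 <- .trimSet(x@r2, params)
    both <- t1$kept & t2$kept
    pairs <- PairedReads(t1$reads[both[t1$kept]], t2$reads[both[t2$kept]])
    orphans <- c(t1$reads[(t1$kept & !t2$kept)[t1$kept]],
                 t2$reads[(t2$kept & !t1$kept)[t2$kept]])
    list(pairs = pairs, orphans = orphans)
})

#' Remove duplicate read pairs and orphan reads
#'
#' A pair is a duplicate of an earlier pair when the ordered sequence tuple
#' (mate1, mate2) matches exactly; an orphan is a duplicate on exact
#' sequence match. The first occurrence in input order is kept. No
#' reverse-complement collapsing and no quality comparison; the operation
#' is idempotent.
#'
#' @param pairs a \linkS4class{PairedReads}.
#' @param orphans a \code{QualityScaledDNAStringSet} (may be empty).
#' @return \code{list(pairs, orphans)} with duplicates removed.
#' @export
removeDuplicates <- function(pairs, orphans = .emptyReads()) {
    keyP <- paste(as.character(pairs@r1), as.character(pairs@r2), sep = "|")
    keepP <- !duplicated(keyP)
    keepO <- !duplicated(as.character(orphans))
    list(pairs = pairs[keepP], orphans = orphans[keepO])
}

#' Keep only reads strictly longer than a threshold
#'
#' Reads of length exactly \code{minLenKeep} are removed (strict
#' inequality). A pair with one failing mate is broken: the surviving mate
#' becomes an orphan.
#'
#' @param pairs a \linkS4class{PairedReads}.
#' @param orphans a \code{QualityScaledDNAStringSet}.
#' @param minLenKeep length threshold in bp (default 50).
#' @return \code{list(pairs, orphans)}.
#' @export
lengthKeepFilter <- function(pairs, orphans = .emptyReads(),
                             minLenKeep = 50L) {
    ok1 <- width(pairs@r1) > minLenKeep
    ok2 <- width(pairs@r2) > minLenKeep
    both <- ok1 & ok2
    newOrphans <- c(pairs@r1[ok1 & !ok2], pairs@r2[ok2 & !ok1])
    list(pairs = pairs[both],
         orphans = c(orphans[width(orphans) > minLenKeep], newOrphans))
}

#' Run the full read QC chain with per-stage accounting
#'
#' Stages, in the fixed order trim -> duplicate removal -> length-keep
#' filter, with a report mirroring the standard accounting table: rows
#' pairs / orphans / sum, columns raw, trimmed, after-duplicate-removal
#' (all) and after the strict > \code{minLenKeep} bp filter. Counts are
#' numbers of reads (a pair contributes 2).
#'
#' @param pairs a \linkS4class{PairedReads} of raw read pairs.
#' @param orphans optional raw single reads.
#' @param params a [trimParams()] list.
#' @return \code{list(pairs, orphans, report)}; \code{report} is a
#'   data.frame with rows \code{pairs}, \code{orphans}, \code{sum}.
#' @export
qcReads <- function(pairs, orphans = .emptyReads(), params = trimParams()) {
    counts <- function(p, o) c(pairs = 2L * length(p), orphans = length(o))
    raw <- counts(pairs, orphans)
    tr <- trimReads(pairs, params)
    trOrph <- c(tr$orphans, trimReads(orphans, params))
    trimmed <- counts(tr$pairs, trOrph)
    dd <- removeDuplicates(tr$pairs, trOrph)
    dup <- counts(dd$pairs, dd$orphans)
    lf <- lengthKeepFilter(dd$pairs, dd$orphans, params$minLenKeep)
    fin <- counts(lf$pairs, lf$orphans)
    report <- data.frame(
        raw = c(raw, sum(raw)),
        trimmed = c(trimmed, sum(trimmed)),
        dup_all = c(dup, sum(dup)),
        dup_keep = c(fin, sum(fin)),
        row.names = c("pairs", "orphans", "sum"))
    list(pairs = lf$pairs, orphans = lf$orphans, report = report)
}

#' Seeded random subsample of read pairs without replacement
#'
#' Selects a uniformly random subset of \code{n} pairs and returns both the
#' selection and its complement (e.g. for mapping the unselected reads back
#' to an assembly of the selected ones). Deterministic for a fixed seed;
#' the generator (Mersenne-Twister) is recorded in the result.
#'
#' @param pairs a \linkS4class{PairedReads}.
#' @param n number of pairs to select, \code{0 <= n <= length(pairs)}.
#' @param seed integer RNG seed.
#' @return \code{list(selected, unselected, seed, algorithm)}; selected and
#'   unselected preserve input order and partition the input.
#' @export
subsamplePairs <- function(pairs, n, seed) {
    n <- as.integer(n)
    if (n < 0L || n > length(pairs))
        stop("n must be between 0 and the number of pairs (", length(pairs),
             ")", call. = FALSE)
    idx <- .withSeed(seed, sample.int(length(pairs), n))
    sel <- sort(idx)
    unsel <- setdiff(seq_len(length(pairs)), sel)
    list(selected = pairs[sel], unselected = pairs[unsel],
         seed = as.integer(seed), algorithm = "Mersenne-Twister")
}
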