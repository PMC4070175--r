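## Reads-mapped-back-to-transcripts validation: an auditable ungapped
## end-to-end mapper (seed-and-extend over a k-mer index) standing in for
## an external end-to-end aligner, plus a SAM adapter for external output.

#' Parameters for end-to-end read mapping
#'
#' @param seedLength maximum seed width for the k-mer index (default 22).
#'   The effective width is lowered when needed so that a read with the
#'   full mismatch budget still must contain one exact seed (pigeonhole
#'   over \code{floor(maxMismatchRate * len) + 1} disjoint seeds), keeping
#'   candidate generation exhaustive.
#' @param maxMismatchRate maximum mismatches as a fraction of read length
#'   (default 0.04); the per-read budget is
#'   \code{floor(maxMismatchRate * len)}.
#' @return A validated list of class \code{"MappingParams"}.
#' @export
mappingParams <- function(seedLength = 22L, maxMismatchRate = 0.04) {
    stopifnot(seedLength >= 10, maxMismatchRate >= 0, maxMismatchRate < 0.5)
    structure(list(seedLength = as.integer(seedLength),
                   maxMismatchRate = maxMismatchRate),
              class = "MappingParams")
}

.readsAsCharacter <- function(reads) {
    if (is(reads, "PairedReads"))
        c(as.character(as(reads@r1, "DNAStringSet")),
          as.character(as(reads@r2, "DNAStringSet")))
    else if (is.character(reads)) toupper(reads)
    else as.character(as(reads, "DNAStringSet"))
}

## exhaustive per-read scan, used for reads too short for seeding
.bruteHits <- function(read, txt, mmMax) {
    out <- list()
    pat <- DNAStringSet(c(read, .rcChar(read)))
    for (s in 1:2) {
        for (ti in seq_along(txt)) {
            m <- matchPattern(pat[[s]], DNAStringSet(txt[ti])[[1L]],
                              max.mismatch = mmMax, with.indels = FALSE)
            if (length(m))
                out[[length(out) + 1L]] <- data.frame(
                    transcript = names(txt)[ti],
                    pos = IRanges::start(m),
                    strand = c("+", "-")[s],
                    mismatches = vapply(as.character(m), function(x)
                        sum(charToRaw(x) != charToRaw(as.character(pat[[s]]))),
                        integer(1), USE.NAMES = FALSE))
        }
    }
    if (length(out)) do.call(rbind, out) else NULL
}

#' Map reads end-to-end against a transcript set
#'
#' A hit requires the full read to align without gaps or clipping, on
#' either strand, with at most \code{floor(maxMismatchRate * len)}
#' mismatches. Among a read's hits, the one with fewest mismatches wins;
#' ties go to the lexicographically first transcript id, then the smallest
#' position, then the + strand. Multi-mapping reads count once.
#'
#' @param reads a \linkS4class{PairedReads} (both mates counted singly), a
#'   \code{DNAStringSet}/\code{QualityScaledDNAStringSet}, or a character
#'   vector.
#' @param transcripts an \linkS4class{Assembly} or named
#'   \code{DNAStringSet}.
#' @param params a [mappingParams()] list.
#' @return A \linkS4class{MappingResult}.
#' @export
mapReads <- function(reads, transcripts, params = mappingParams()) {
    rchr <- .readsAsCharacter(reads)
    txt <- as.character(as(transcripts, "DNAStringSet"))
    if (is.null(names(txt)) || anyDuplicated(names(txt)))
        stop("transcripts must have unique names", call. = FALSE)
    nR <- length(rchr)
    empty <- DataFrame(read = integer(0), transcript = character(0),
                       pos = integer(0), strand = character(0),
                       mismatches = integer(0))
    if (nR == 0L || length(txt) == 0L)
        return(new("MappingResult", nReads = nR, hits = empty))

    lens <- nchar(rchr)
    mmBudget <- as.integer(floor(params$maxMismatchRate * lens))
    capW <- lens %/% (mmBudget + 1L)          # widest exhaustive seed
    seedable <- capW >= 8L
    W <- if (any(seedable)) max(8L, min(params$seedLength,
                                        min(capW[seedable]))) else 0L

    allHits <- list()

    if (any(seedable)) {
        kt <- .kmerTable(txt, W)
        data.table::setkey(kt, kmer)
        twidth <- nchar(txt)
        tnames <- names(txt)
        rIdx <- which(seedable)
        rcAll <- .rcChar(rchr[rIdx])
        for (L in unique(lens[rIdx])) {
            g <- rIdx[lens[rIdx] == L]
            mm <- mmBudget[g[1L]]
            q <- min(mm + 1L, L %/% W)
            starts <- 1L + (seq_len(q) - 1L) * W
            qseq <- c(rchr[g], rcAll[match(g, rIdx)])
            strand <- rep(c("+", "-"), each = length(g))
            qread <- rep(g, 2L)
            sd <- data.table::data.table(
                qi = rep(seq_along(qseq), each = q),
                spos = rep(starts, length(qseq)))
            sd[, kmer := substring(qseq[qi], spos, spos + W - 1L)]
            cand <- kt[sd, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
            if (nrow(cand) == 0L) next
            cand[, start := pos - spos + 1L]
            cand <- unique(cand[, .(qi, seq, start)])
            cand <- cand[start >= 1L & start + L - 1L <= twidth[seq]]
            if (nrow(cand) == 0L) next
            sub <- substring(txt[cand$seq], cand$start, cand$start + L - 1L)
            mmc <- .hammingVec(qseq[cand$qi], sub, L)
            ok <- mmc <= mm
            if (!any(ok)) next
            allHits[[length(allHits) + 1L]] <- data.table::data.table(
                read = qread[cand$qi[ok]],
                transcript = tnames[cand$seq[ok]],
                pos = cand$start[ok],
                strand = strand[cand$qi[ok]],
                mismatches = mmc[ok])
        }
    }

    for (i in which(!seedable)) {
        h <- .bruteHits(rchr[i], txt, mmBudget[i])
        if (!is.null(h))
            allHits[[length(allHits) + 1L]] <-
                data.table::data.table(read = i, h)
    }

    if (!length(allHits))
        return(new("MappingResult", nReads = nR, hits = empty))
    ht <- data.table::rbindlist(allHits)
    data.table::setorder(ht, read, mismatches, transcript, pos, strand)
    best <- ht[!duplicated(read)]
    new("MappingResult", nReads = nR,
        hits = DataFrame(read = best$read, transcript = best$transcript,
                         pos = best$pos, strand = best$strand,
                         mismatches = best$mismatches))
}

#' Percentage of reads mapped back to transcripts
#'
#' @param result a \linkS4class{MappingResult} from [mapReads()] or
#'   [readSamMapped()].
#' @return 100 * mapped / total, reads counted individually.
#' @export
rmbtPercent <- function(result) {
    stopifnot(is(result, "MappingResult"))
    if (result@nReads == 0L)
        stop("no reads in mapping result", call. = FALSE)
    100 * nrow(result@hits) / result@nReads
}

#' Import mapping status from a SAM file
#'
#' Adapter for using an external end-to-end mapper: primary records are
#' counted, and a read is mapped when FLAG bit 0x4 is unset. Secondary
#' (0x100) and supplementary (0x800) records are ignored.
#'
#' @param path path to a text SAM file.
#' @return A \linkS4class{MappingResult} (mismatch column is \code{NA}).
#' @export
readSamMapped <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            select = 1:4,
                            col.names = c("qname", "flag", "rname", "pos"),
                            colClasses = "character")
    dt <- dt[!startsWith(qname, "@")]
    dt[, flag := as.integer(flag)]
    dt <- dt[bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L]
    mapped <- dt[bitwAnd(flag, 0x4L) == 0L]
    new("MappingResult", nReads = nrow(dt),
        hits = DataFrame(read = which(bitwAnd(dt$flag, 0x4L) == 0L),
                         transcript = mapped$rname,
                         pos = as.integer(mapped$pos),
                         strand = ifelse(bitwAnd(mapped$flag, 0x10L) > 0L,
                                         "-", "+"),
                         mismatches = rep(NA_integer_, nrow(mapped))))
}
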