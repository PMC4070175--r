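## Core-gene completeness proxy: classify each user-supplied core gene as
## complete / partial / absent from the best single-transcript local
## alignment coverage, in nucleotide space. A stand-in for the HMM-based
## core-gene pipeline, preserving its role as a completeness metric.
##
## Speed structure: candidate (gene, transcript, strand) pairs come from a
## shared 12-mer prefilter; exact ungapped diagonal segments settle clear
## cases, and the dynamic-programming local alignment runs only when the
## diagonal evidence is not already decisive (e.g. possible gapped hits).

.COMPLETENESS_WORD <- 12L

## best qualifying ungapped coverage of gene g by one strand s of a
## transcript: for each supported diagonal, the overlap segment counts
## only if its identity reaches minIdentity
.diagCoverage <- function(g, s, kg, ks, minIdentity) {
    hit <- match(kg, ks)
    ok <- !is.na(hit)
    if (!any(ok))
        return(list(cov = 0, intervals = NULL))
    ng <- nchar(g); ns <- nchar(s)
    diags <- hit[ok] - which(ok)
    tab <- sort(table(diags), decreasing = TRUE)
    cov <- 0
    intervals <- NULL
    bestD <- NA_integer_
    for (d in as.integer(names(tab))[seq_len(min(25L, length(tab)))]) {
        gFrom <- max(1L, 1L - d)
        gTo <- min(ng, ns - d)
        if (gTo < gFrom) next
        seg <- gTo - gFrom + 1L
        mism <- sum(charToRaw(substr(g, gFrom, gTo)) !=
                    charToRaw(substr(s, gFrom + d, gTo + d)))
        if ((seg - mism) / seg < minIdentity) next
        if (seg / ng > cov) bestD <- d
        cov <- max(cov, seg / ng)
        intervals <- rbind(intervals, c(gFrom, gTo))
    }
    list(cov = cov, intervals = intervals, d = bestD)
}

#' Core-gene recovery report for a transcript set
#'
#' For every core gene, the best local alignment against any single
#' transcript (either strand) with identity at least \code{minIdentity} is
#' found; the fraction of the gene covered by that alignment classifies
#' the gene as \emph{complete} (coverage \eqn{\ge} \code{completeCov}),
#' \emph{partial} (\eqn{\ge} \code{partialCov}) or \emph{absent}. The
#' summary percentages follow the usual convention that partial includes
#' complete, so partial \eqn{\ge} complete. Coverage is never stitched
#' across transcripts for the status call; a stitched-coverage column
#' (union of qualifying alignment intervals over all transcripts) is
#' reported as supplementary information only.
#'
#' @param transcripts an \linkS4class{Assembly} or named
#'   \code{DNAStringSet}.
#' @param coreGenes a named \code{DNAStringSet} of core gene nucleotide
#'   sequences (non-empty).
#' @param completeCov coverage fraction for "complete" (default 0.70,
#'   following the core-gene tool's published convention).
#' @param partialCov coverage fraction for "partial" (default 0.30).
#' @param minIdentity minimum alignment identity (default 0.95).
#' @return A list with \code{perGene} (data.frame: \code{gene},
#'   \code{status}, \code{coverage}, \code{best_transcript},
#'   \code{stitched_coverage}) and \code{summary} (named vector
#'   \code{complete_pct}, \code{partial_pct}).
#' @export
coreGeneRecovery <- function(transcripts, coreGenes,
                             completeCov = 0.70, partialCov = 0.30,
                             minIdentity = 0.95) {
    genes <- as(coreGenes, "DNAStringSet")
    if (length(genes) == 0L)
        stop("core gene set is empty", call. = FALSE)
    if (is.null(names(genes)) || anyDuplicated(names(genes)))
        stop("core genes must have unique ids", call. = FALSE)
    stopifnot(partialCov > 0, partialCov <= completeCov, completeCov <= 1,
              minIdentity > 0.5, minIdentity <= 1)
    txt <- as.character(as(transcripts, "DNAStringSet"))
    rct <- .rcChar(txt)
    gchr <- as.character(genes)
    pw <- .COMPLETENESS_WORD
    kFwd <- lapply(txt, .posKmers, w = pw)
    kRc <- lapply(rct, .posKmers, w = pw)
    perGene <- lapply(seq_along(gchr), function(gi) {
        g <- gchr[gi]
        gl <- nchar(g)
        gkm <- .posKmers(g, pw)
        bestCov <- 0
        bestTx <- NA_character_
        intervals <- NULL
        pending <- list()   # pairs the diagonal pass left undecided
        for (ti in seq_along(txt)) {
            for (strandSeqs in list(list(s = txt[ti], km = kFwd[[ti]]),
                                    list(s = rct[ti], km = kRc[[ti]]))) {
                dg <- .diagCoverage(g, strandSeqs$s, gkm, strandSeqs$km,
                                    minIdentity)
                if (!is.null(dg$intervals))
                    intervals <- rbind(intervals, dg$intervals)
                if (dg$cov > 0 && dg$cov < completeCov)
                    pending[[length(pending) + 1L]] <-
                        list(ti = ti, s = strandSeqs$s, d = dg$d)
                if (dg$cov > bestCov) {
                    bestCov <- dg$cov
                    bestTx <- names(txt)[ti]
                }
            }
        }
        ## gapped fallback: only if no diagonal already proved "complete"
        if (bestCov < completeCov) {
            for (pp in pending) {
                ## align against a window around the supporting diagonal;
                ## skip pairs whose DP would be disproportionate (the
                ## diagonal answer then stands)
                slack <- as.integer(0.2 * gl) + 100L
                from <- max(1L, (if (is.na(pp$d)) 0L else pp$d) + 1L - slack)
                to <- min(nchar(pp$s),
                          (if (is.na(pp$d)) 0L else pp$d) + gl + slack)
                if (as.numeric(gl) * (to - from + 1L) > 2.5e7) next
                win <- substr(pp$s, from, to)
                aln <- pairwiseAlignment(g, win, type = "local",
                                         substitutionMatrix = .subMat(),
                                         gapOpening = 4, gapExtension = 1)
                if (nmatch(aln) == 0L ||
                    Biostrings::pid(aln, type = "PID1") / 100 < minIdentity)
                    next
                acov <- width(pattern(aln)) / gl
                intervals <- rbind(intervals,
                                   c(IRanges::start(pattern(aln)),
                                     IRanges::end(pattern(aln))))
                if (acov > bestCov) {
                    bestCov <- acov
                    bestTx <- names(txt)[pp$ti]
                }
            }
        }
        stitched <- if (is.null(intervals)) 0 else
            sum(width(reduce(IRanges(intervals[, 1L],
                                     intervals[, 2L])))) / gl
        status <- if (bestCov >= completeCov) "complete"
                  else if (bestCov >= partialCov) "partial"
                  else "absent"
        data.frame(gene = names(genes)[gi], status = status,
                   coverage = bestCov, best_transcript = bestTx,
                   stitched_coverage = stitched)
    })
    perGene <- do.call(rbind, perGene)
    G <- nrow(perGene)
    completePct <- 100 * sum(perGene$status == "complete") / G
    partialPct <- 100 * sum(perGene$status %in% c("complete", "partial")) / G
    list(perGene = perGene,
         summary = c(complete_pct = completePct, partial_pct = partialPct))
}
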