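## Assembly evaluation: N50, the seven-column statistics row, k-mer
## selection and k-sweep reporting.

#' N50 of a set of contig lengths
#'
#' The largest length L present in the input such that contigs of length
#' \eqn{\ge} L together cover at least half of the total assembly length.
#'
#' @param lengths positive integer vector of contig lengths.
#' @return The N50 length (integer).
#' @examples
#' n50(c(6, 5, 4, 3, 2))  # 5
#' @export
n50 <- function(lengths) {
    if (length(lengths) == 0L)
        stop("lengths must be non-empty", call. = FALSE)
    if (any(lengths <= 0))
        stop("lengths must be positive", call. = FALSE)
    s <- sort(as.numeric(lengths), decreasing = TRUE)
    i <- which(cumsum(s) >= sum(s) / 2)[1L]
    as.integer(s[i])
}

#' Evaluation statistics for one assembly
#'
#' Computes the length-based columns of the standard evaluation row over
#' the contigs strictly longer than \code{minLen} (200 bp by default,
#' matching "statistics based on non-redundant sequences greater than
#' 200 bp"): number of transcripts, total bp, mean length, N50, and the
#' number of transcripts strictly longer than \code{longThreshold} (1 kb).
#' The mapping-rate and completeness columns are filled by [rmbt()] and
#' [coreGeneRecovery()]; see [runPipeline()].
#'
#' @param assembly an \linkS4class{Assembly} or \code{DNAStringSet}.
#' @param minLen contigs must be strictly longer than this to be counted.
#' @param longThreshold threshold for the long-transcript count (strict >).
#' @return A one-row data.frame: \code{tool}, \code{k},
#'   \code{n_transcripts}, \code{total_bp}, \code{mean_len}, \code{n50},
#'   \code{n_long}.
#' @export
assemblyStats <- function(assembly, minLen = 200L, longThreshold = 1000L) {
    tool <- if (is(assembly, "Assembly")) assembly@tool else NA_character_
    k <- if (is(assembly, "Assembly")) assembly@k else NA_character_
    w <- width(assembly)[width(assembly) > minLen]
    if (length(w) == 0L)
        stop("no contigs longer than ", minLen, " bp", call. = FALSE)
    data.frame(tool = tool, k = k,
               n_transcripts = length(w),
               total_bp = sum(as.numeric(w)),
               mean_len = sum(as.numeric(w)) / length(w),
               n50 = n50(w),
               n_long = sum(w > longThreshold))
}

#' Select a single-k assembly by N50 under a total-length constraint
#'
#' Operationalizes "maximize the N50 value whilst keeping the total
#' assembly length as long as possible": among candidates whose total
#' length is at least \code{retention} times the largest candidate total,
#' the k with maximal N50 is chosen; ties go to the smaller k.
#'
#' @param candidates data.frame with columns \code{k} (numeric),
#'   \code{n50} and \code{total_bp}, one row per candidate assembly.
#' @param retention fraction f in (0,1] of the maximum total length that a
#'   candidate must retain to stay eligible (default 0.90).
#' @return The chosen k (numeric scalar).
#' @export
selectK <- function(candidates, retention = 0.90) {
    stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L,
              all(c("k", "n50", "total_bp") %in% colnames(candidates)),
              retention > 0, retention <= 1)
    eligible <- candidates[candidates$total_bp >=
                           retention * max(candidates$total_bp), ]
    best <- eligible[eligible$n50 == max(eligible$n50), ]
    min(best$k)
}

#' Per-k N50 and total-length table for a k-mer sweep
#'
#' @param perK data.frame with columns \code{k}, \code{n50},
#'   \code{total_bp}; k values must be unique.
#' @return The same data.frame sorted by ascending k.
#' @export
kSweepTable <- function(perK) {
    stopifnot(is.data.frame(perK), nrow(perK) >= 1L,
              all(c("k", "n50", "total_bp") %in% colnames(perK)))
    if (anyDuplicated(perK$k))
        stop("duplicate k values in sweep table", call. = FALSE)
    out <- perK[order(perK$k), c("k", "n50", "total_bp")]
    rownames(out) <- NULL
    out
}

#' Valid k-mer range for an assembly sweep
#'
#' Mirrors the cited guidance of sweeping odd k from 21 up to the mean read
#' length minus 10.
#'
#' @param meanReadLen mean read length in bp.
#' @return Integer vector of odd k values \code{21, 23, ...}.
#' @export
validKRange <- function(meanReadLen) {
    hi <- as.integer(floor(meanReadLen)) - 10L
    if (hi < 21L) return(integer(0))
    seq.int(21L, hi, by = 2L)
}
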