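#' @import methods
#' @importFrom Biostrings DNAStringSet QualityScaledDNAStringSet PhredQuality
#'   quality readDNAStringSet readQualityScaledDNAStringSet writeXStringSet
#'   reverseComplement pairwiseAlignment nmatch pattern subject width
#'   alphabetFrequency subseq vcountPattern matchPattern BStringSet
#'   nucleotideSubstitutionMatrix
#' @importFrom IRanges IRanges reduce
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats rnorm rlnorm runif setNames
#' @importFrom utils write.table
NULL

#' Paired sequencing reads with base qualities
#'
#' Container for a set of read pairs: two parallel
#' \link[Biostrings]{QualityScaledDNAStringSet} objects holding mate 1 and
#' mate 2. Position \code{i} of \code{r1} is paired with position \code{i}
#' of \code{r2}; id suffixes are never parsed.
#'
#' @slot r1 \code{QualityScaledDNAStringSet} of first mates.
#' @slot r2 \code{QualityScaledDNAStringSet} of second mates, same length.
#'
#' @seealso [readPairedFastq()], [trimReads()], [subsamplePairs()]
#' @export
setClass("PairedReads", representation(
    r1 = "QualityScaledDNAStringSet",
    r2 = "QualityScaledDNAStringSet"
))

setValidity("PairedReads", function(object) {
    if (length(object@r1) != length(object@r2))
        return("r1 and r2 must contain the same number of reads")
    TRUE
})

#' A transcript assembly labeled with its source
#'
#' A \link[Biostrings]{DNAStringSet} of contigs together with the label of
#' the producing tool and the k-mer value used ("MK" for a merged
#' multiple-k assembly, "merged" for a cross-tool consensus).
#'
#' @slot tool single character, name of the assembly tool.
#' @slot k single character, k-mer value or "MK"/"merged".
#' @export
setClass("Assembly",
    contains = "DNAStringSet",
    representation(tool = "character", k = "character"))

setValidity("Assembly", function(object) {
    msg <- NULL
    if (length(object@tool) != 1L || !nzchar(object@tool))
        msg <- c(msg, "'tool' must be a single non-empty string")
    if (length(object@k) != 1L)
        msg <- c(msg, "'k' must be a single string")
    if (length(object) && any(width(object) < 1L))
        msg <- c(msg, "contigs must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' Result of merging several assemblies into consensus contigs
#'
#' Holds the consensus contigs and, for every input contig, the merged
#' contig it was placed in (its provenance), so that the number of distinct
#' tools behind each consensus contig is decidable.
#'
#' @slot contigs \code{DNAStringSet} of consensus sequences (merged contigs
#'   and singlets).
#' @slot provenance \code{DataFrame} with one row per input contig:
#'   \code{merged_id}, \code{constituent_id}, \code{tool}, \code{k},
#'   \code{strand} (+1/-1 relative to the consensus) and \code{offset}
#'   (0-based placement of the oriented constituent on the consensus).
#' @export
setClass("MergedAssembly", representation(
    contigs = "DNAStringSet",
    provenance = "DataFrame"
))

setValidity("MergedAssembly", function(object) {
    need <- c("merged_id", "constituent_id", "tool", "k", "strand", "offset")
    if (!all(need %in% colnames(object@provenance)))
        return(paste("provenance must have columns:",
                     paste(need, collapse = ", ")))
    if (!all(object@provenance$merged_id %in% names(object@contigs)))
        return("every provenance merged_id must name a consensus contig")
    TRUE
})

#' Result of mapping reads end-to-end against transcripts
#'
#' @slot nReads total number of reads queried.
#' @slot hits \code{DataFrame} with one row per mapped read: \code{read},
#'   \code{transcript}, \code{pos} (1-based start on the transcript),
#'   \code{strand} ("+"/"-") and \code{mismatches}.
#' @export
setClass("MappingResult", representation(
    nReads = "integer",
    hits = "DataFrame"
))

setValidity("MappingResult", function(object) {
    if (nrow(object@hits) > object@nReads)
        return("more hits than reads")
    TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "PairedReads", function(object) {
    cat("PairedReads with", length(object@r1), "pairs\n")
    if (length(object@r1)) {
        w <- range(c(width(object@r1), width(object@r2)))
        cat("  read widths:", w[1], "-", w[2], "\n")
    }
})

setMethod("show", "Assembly", function(object) {
    cat("Assembly [", object@tool, ", k=", object@k, "]: ",
        length(object), " contigs, ", sum(width(object)), " bp\n", sep = "")
})

setMethod("show", "MergedAssembly", function(object) {
    nt <- nTools(object)
    cat("MergedAssembly:", length(object@contigs), "consensus contigs from",
        nrow(object@provenance), "constituents\n")
    cat("  tools per contig:",
        paste(names(table(nt)), table(nt), sep = ":", collapse = " "), "\n")
})

setMethod("show", "MappingResult", function(object) {
    cat("MappingResult:", nrow(object@hits), "of", object@nReads,
        sprintf("reads mapped (%.2f%%)\n",
                if (object@nReads) 100 * nrow(object@hits) / object@nReads
                else NA_real_))
})
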