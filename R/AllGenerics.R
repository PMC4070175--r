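#' Accessors for the core containers
#'
#' \code{mate1}/\code{mate2} return the two read sets of a
#' \linkS4class{PairedReads}; \code{toolName} and \code{kmerLabel} return an
#' \linkS4class{Assembly}'s source label; \code{contigs} and
#' \code{provenance} expose a \linkS4class{MergedAssembly}'s consensus
#' sequences and constituent table; \code{nTools} counts the distinct tools
#' behind each merged contig; \code{hits} and \code{nReads} expose a
#' \linkS4class{MappingResult}.
#'
#' @param x one of the package's S4 objects.
#' @return See details; accessors return the corresponding slot or a derived
#'   summary (for \code{nTools}, a named integer vector over merged contigs).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mate1", function(x) standardGeneric("mate1"))
#' @rdname accessors
#' @export
setGeneric("mate2", function(x) standardGeneric("mate2"))
#' @rdname accessors
#' @export
setGeneric("toolName", function(x) standardGeneric("toolName"))
#' @rdname accessors
#' @export
setGeneric("kmerLabel", function(x) standardGeneric("kmerLabel"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("nTools", function(x) standardGeneric("nTools"))
#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname accessors
#' @export
setMethod("mate1", "PairedReads", function(x) x@r1)
#' @rdname accessors
#' @export
setMethod("mate2", "PairedReads", function(x) x@r2)
#' @rdname accessors
#' @export
setMethod("toolName", "Assembly", function(x) x@tool)
#' @rdname accessors
#' @export
setMethod("kmerLabel", "Assembly", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("contigs", "MergedAssembly", function(x) x@contigs)
#' @rdname accessors
#' @export
setMethod("provenance", "MergedAssembly", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("nTools", "MergedAssembly", function(x) {
    pv <- x@provenance
    tab <- vapply(split(pv$tool, pv$merged_id),
                  function(t) length(unique(t)), integer(1))
    out <- setNames(integer(length(x@contigs)), names(x@contigs))
    out[names(tab)] <- tab
    out
})
#' @rdname accessors
#' @export
setMethod("hits", "MappingResult", function(x) x@hits)
#' @rdname accessors
#' @export
setMethod("nReads", "MappingResult", function(x) x@nReads)

#' Number of read pairs
#' @param x a \linkS4class{PairedReads}.
#' @export
setMethod("length", "PairedReads", function(x) length(x@r1))

#' Subset read pairs
#' @param x a \linkS4class{PairedReads}.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PairedReads", function(x, i, j, ..., drop = FALSE) {
    new("PairedReads", r1 = x@r1[i], r2 = x@r2[i])
})

#' Construct a PairedReads object
#'
#' @param r1,r2 \code{QualityScaledDNAStringSet} objects of equal length.
#' @return A \linkS4class{PairedReads}.
#' @export
PairedReads <- function(r1, r2) new("PairedReads", r1 = r1, r2 = r2)

#' Construct an Assembly
#'
#' @param seqs a \code{DNAStringSet} (or object coercible to one) of contigs.
#' @param tool name of the producing tool.
#' @param k k-mer value used (coerced to character), or "MK"/"merged".
#' @return An \linkS4class{Assembly}.
#' @examples
#' a <- Assembly(Biostrings::DNAStringSet(c(c1 = "ACGTACGTACGT")), "velvet", 31)
#' toolName(a)
#' @export
Assembly <- function(seqs, tool, k = "NA") {
    seqs <- as(seqs, "DNAStringSet")
    if (is.null(names(seqs)))
        names(seqs) <- paste0("contig", seq_along(seqs))
    new("Assembly", seqs, tool = as.character(tool), k = as.character(k))
}
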