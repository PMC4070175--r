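## Sequence I/O: FASTQ/FASTA via Biostrings, plus Phred decoding.
## The Biostrings FASTQ parser accepts some malformed records silently
## (e.g. a quality line shorter than its sequence), so reads are
## post-validated and failures re-diagnosed line by line.

.FASTQ_SCORING <- c(`33` = "phred", `64` = "illumina")

#' Convert Phred quality characters to error probabilities
#'
#' Decodes ASCII-encoded base qualities to error probabilities
#' \eqn{p = 10^{-Q/10}} with \eqn{Q = \mathrm{code}(c) - \mathrm{offset}}.
#'
#' @param qual character vector; each element may be a single quality
#'   character or a whole per-read quality string.
#' @param offset integer ASCII offset, 33 (default, modern Illumina) or 64.
#' @return If every element of \code{qual} has one character, a numeric
#'   vector of probabilities; otherwise a list of numeric vectors (one per
#'   input string).
#' @examples
#' phredErrorProb(c("!", "+", "I"))   # 1, 0.1, 1e-4
#' @export
phredErrorProb <- function(qual, offset = 33L) {
    stopifnot(is.character(qual))
    out <- lapply(qual, function(s) {
        codes <- utf8ToInt(s)
        if (any(codes < offset))
            stop("quality character below offset ", offset,
                 " (code ", min(codes), ")")
        10^(-(codes - offset) / 10)
    })
    if (all(nchar(qual) == 1L)) unlist(out) else out
}

## line-level scan used only after the fast parser fails or produces an
## inconsistent object; errors with the first offending record and line.
.diagnoseFastq <- function(path) {
    lines <- readLines(path, warn = FALSE)
    n <- length(lines)
    if (n == 0L) return(invisible(NULL))
    if (n %% 4L != 0L)
        stop("malformed FASTQ '", path, "': ", n,
             " lines is not a multiple of 4", call. = FALSE)
    nrec <- n %/% 4L
    bad <- function(what, i, line)
        stop("malformed FASTQ '", path, "': record ", i, " (line ", line,
             ") ", what, call. = FALSE)
    i <- which(!startsWith(lines[seq.int(1L, n, 4L)], "@"))[1L]
    if (!is.na(i)) bad("does not start with '@'", i, (i - 1L) * 4L + 1L)
    i <- which(!startsWith(lines[seq.int(3L, n, 4L)], "+"))[1L]
    if (!is.na(i)) bad("separator is not '+'", i, (i - 1L) * 4L + 3L)
    sq <- lines[seq.int(2L, n, 4L)]
    ql <- lines[seq.int(4L, n, 4L)]
    i <- which(nchar(sq) != nchar(ql))[1L]
    if (!is.na(i))
        bad(paste0("sequence length ", nchar(sq[i]),
                   " != quality length ", nchar(ql[i])),
            i, (i - 1L) * 4L + 2L)
    i <- which(grepl("[^ACGTNacgtn]", sq))[1L]
    if (!is.na(i))
        bad("has characters outside {A,C,G,T,N}", i, (i - 1L) * 4L + 2L)
    invisible(NULL)
}

.checkAlphabet <- function(x, what) {
    if (!length(x)) return(invisible(NULL))
    af <- colSums(alphabetFrequency(x))
    bad <- af[!names(af) %in% c("A", "C", "G", "T", "N")]
    if (any(bad > 0))
        stop(what, " contains characters outside {A,C,G,T,N}: ",
             paste(names(bad)[bad > 0], collapse = ", "), call. = FALSE)
    invisible(NULL)
}

#' Read a FASTQ file of quality-scaled reads
#'
#' Reads 4-line FASTQ (plain or gzip) into a
#' \link[Biostrings]{QualityScaledDNAStringSet}. Sequences are uppercased
#' and restricted to \{A,C,G,T,N\}; a malformed record triggers an error
#' naming the record and line. Quality encoding is fixed by
#' \code{phredOffset} (no auto-detection).
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @param phredOffset 33 (default) or 64.
#' @return A \code{QualityScaledDNAStringSet}.
#' @export
readFastq <- function(path, phredOffset = 33L) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    scoring <- .FASTQ_SCORING[as.character(phredOffset)]
    if (is.na(scoring)) stop("phredOffset must be 33 or 64")
    ## validate structure first: the fast parser accepts some malformed
    ## records silently (with memory-dependent results)
    .diagnoseFastq(path)
    x <- tryCatch(
        withCallingHandlers(
            readQualityScaledDNAStringSet(path, quality.scoring = scoring),
            warning = function(w) {
                ## the parser warns about its own internal metadata columns
                if (grepl("metadata columns", conditionMessage(w)))
                    invokeRestart("muffleWarning")
            }),
        error = function(e) {
            .diagnoseFastq(path)
            stop("failed to parse FASTQ '", path, "': ",
                 conditionMessage(e), call. = FALSE)
        })
    ok <- tryCatch({
        wq <- width(quality(x))
        invisible(as.character(quality(x)))
        all(width(x) == wq)
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) {
        .diagnoseFastq(path)
        stop("inconsistent FASTQ '", path,
             "': sequence/quality lengths differ", call. = FALSE)
    }
    .checkAlphabet(x, paste0("FASTQ '", path, "'"))
    S4Vectors::mcols(x) <- NULL
    x
}

#' Read paired FASTQ files
#'
#' Mates are paired by record order: record \code{i} of \code{path1} pairs
#' with record \code{i} of \code{path2}; id suffixes such as "/1" are not
#' interpreted.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @param phredOffset 33 (default) or 64.
#' @return A \linkS4class{PairedReads}.
#' @export
readPairedFastq <- function(path1, path2, phredOffset = 33L) {
    r1 <- readFastq(path1, phredOffset)
    r2 <- readFastq(path2, phredOffset)
    if (length(r1) != length(r2))
        stop("mate files differ in record count: ", length(r1), " vs ",
             length(r2), call. = FALSE)
    PairedReads(r1, r2)
}

#' Write quality-scaled reads as FASTQ
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param path output file; a ".gz" suffix triggers compression.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
    writeXStringSet(as(reads, "DNAStringSet"), path,
                    compress = endsWith(path, ".gz"),
                    format = "fastq", qualities = quality(reads))
    invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' Ids are truncated at the first whitespace (the usual FASTA convention);
#' sequences are validated against \{A,C,G,T,N\}.
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return A \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    x <- readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    .checkAlphabet(x, paste0("FASTA '", path, "'"))
    x
}

#' Write contigs as wrapped FASTA
#'
#' Round-trip safe: reading the written file reproduces ids and sequences
#' exactly. An empty set writes an empty file.
#'
#' @param seqs a \code{DNAStringSet} (or \linkS4class{Assembly}).
#' @param path output file; ".gz" triggers compression.
#' @param lineWidth bases per sequence line (default 60).
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, lineWidth = 60L) {
    seqs <- as(seqs, "DNAStringSet")
    if (length(seqs) && any(width(seqs) == 0L))
        stop("cannot write empty sequences", call. = FALSE)
    writeXStringSet(seqs, path, compress = endsWith(path, ".gz"),
                    width = max(1L, as.integer(lineWidth)))
    invisible(path)
}

## integer qualities as a plain list, one vector per read
.qualityInts <- function(reads) {
    as.list(as(quality(reads), "IntegerList"))
}
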