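## internal helpers shared across modules

## evaluate expr under a fixed RNG seed, restoring global RNG state after
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = env)
        on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
                    rm(".Random.seed", envir = env), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

## random uniform-composition DNA of given lengths (character vector)
.randomDna <- function(lengths) {
    vapply(lengths, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1))
}

.rcChar <- function(x) {
    vapply(chartr("ACGTN", "TGCAN", x), function(s)
        rawToChar(rev(charToRaw(s))), character(1), USE.NAMES = FALSE)
}

## per-position mismatch counts between two equal-width character vectors
.hammingVec <- function(a, b, L) {
    if (!length(a)) return(integer(0))
    d <- charToRaw(paste0(a, collapse = "")) !=
         charToRaw(paste0(b, collapse = ""))
    as.integer(colSums(matrix(d, nrow = L)))
}

## all k-mers of a character vector of sequences as a data.table
## (seq index, 1-based position, kmer); sequences shorter than k contribute
## nothing
.kmerTable <- function(seqs, k) {
    idx <- rep.int(seq_along(seqs), pmax(0L, nchar(seqs) - k + 1L))
    if (!length(idx))
        return(data.table::data.table(seq = integer(0), pos = integer(0),
                                      kmer = character(0)))
    pos <- unlist(lapply(pmax(0L, nchar(seqs) - k + 1L), seq_len),
                  use.names = FALSE)
    data.table::data.table(
        seq = idx, pos = pos,
        kmer = substring(seqs[idx], pos, pos + k - 1L))
}

.sliceQualityScaled <- function(x, start, end) {
    s <- as(x, "DNAStringSet")
    q <- as(quality(x), "BStringSet")
    S4Vectors::mcols(s) <- NULL
    S4Vectors::mcols(q) <- NULL
    QualityScaledDNAStringSet(subseq(s, start = start, end = end),
                              PhredQuality(subseq(q, start = start,
                                                  end = end)))
}

.emptyReads <- function() {
    QualityScaledDNAStringSet(DNAStringSet(), PhredQuality(character(0)))
}
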