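## Redundancy removal within one assembly: greedy longest-first identity
## clustering (cd-hit-est style) plus the strict > 200 bp keep rule.

#' Parameters for redundancy clustering
#'
#' @param identityThreshold sequences sharing more than this identity with
#'   a longer retained sequence are removed (default 0.99).
#' @param minLenKeep retained sequences must be strictly longer than this
#'   (default 200 bp).
#' @param wordSize word length of the shared-word prefilter used to skip
#'   hopeless alignments (default 10). The prefilter is a speed heuristic
#'   only: alignments are skipped only when a run-length bound proves that
#'   any pair above the identity threshold must share a word of this size,
#'   so results equal the exhaustive comparison.
#' @return A validated list of class \code{"ClusterParams"}.
#' @export
clusterParams <- function(identityThreshold = 0.99, minLenKeep = 200L,
                          wordSize = 10L) {
    stopifnot(identityThreshold > 0.5, identityThreshold <= 1,
              minLenKeep >= 1, wordSize >= 4)
    structure(list(identityThreshold = identityThreshold,
                   minLenKeep = as.integer(minLenKeep),
                   wordSize = as.integer(wordSize)),
              class = "ClusterParams")
}

.SUB_MAT <- NULL
.subMat <- function() {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    m
}

## global alignment of the shorter sequence within the longer one;
## matches / length(shorter), on the given strings as-is
.identityOneStrand <- function(shorter, longer) {
    aln <- pairwiseAlignment(shorter, longer, type = "global-local",
                             substitutionMatrix = .subMat(),
                             gapOpening = 2, gapExtension = 1)
    nmatch(aln) / nchar(shorter)
}

#' Pairwise identity of two transcripts
#'
#' Global-alignment match count divided by the length of the shorter
#' sequence, so a perfect containment scores 1. Both strands of \code{b}
#' are considered and the higher identity returned (de novo transcript
#' orientation is arbitrary).
#'
#' @param a,b character strings or \code{DNAString}s, non-empty.
#' @param bothStrands compare against the reverse complement of \code{b}
#'   as well (default TRUE).
#' @return Identity fraction in [0,1].
#' @export
pairwiseIdentity <- function(a, b, bothStrands = TRUE) {
    a <- as.character(a); b <- as.character(b)
    if (nchar(a) == 0L || nchar(b) == 0L)
        stop("sequences must be non-empty", call. = FALSE)
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    id <- .identityOneStrand(a, b)
    if (bothStrands && id < 1)
        id <- max(id, .identityOneStrand(a, .rcChar(b)))
    id
}

## fast lower bound on identity: best ungapped diagonal of the shorter
## sequence against one strand of the longer, matches / length(shorter)
.posKmers <- function(s, w) {
    n <- nchar(s)
    if (n < w) return(character(0))
    substring(s, seq_len(n - w + 1L), w:n)
}

.ungappedIdentityOne <- function(s, l, w = 8L, ks = NULL, kl = NULL) {
    ns <- nchar(s); nl <- nchar(l)
    if (ns < w || nl < w) return(list(id = 0, d = 0L))
    if (is.null(ks)) ks <- .posKmers(s, w)
    if (is.null(kl)) kl <- .posKmers(l, w)
    hit <- match(ks, kl)
    ok <- !is.na(hit)
    if (!any(ok)) return(list(id = 0, d = 0L))
    diags <- hit[ok] - which(ok)          # 0-based offset of s on l
    tab <- sort(table(diags), decreasing = TRUE)
    best <- 0; bestD <- 0L
    for (d in as.integer(names(tab))[seq_len(min(20L, length(tab)))]) {
        sFrom <- max(1L, 1L - d)
        sTo <- min(ns, nl - d)
        if (sTo < sFrom) next
        seg <- sTo - sFrom + 1L
        m <- seg - sum(charToRaw(substr(s, sFrom, sTo)) !=
                       charToRaw(substr(l, sFrom + d, sTo + d)))
        if (m / ns > best) { best <- m / ns; bestD <- d }
        if (best == 1) break
    }
    list(id = best, d = bestD)
}

## duplicate decision used by clustering: the ungapped diagonal bound
## settles clear cases; a banded alignment around the best diagonal
## decides only the borderline band just below the threshold, where
## gapped alignments could still push identity over it. a must be the
## shorter sequence when precomputed kmers are passed.
.identityExceeds <- function(a, b, threshold, margin = 0.05, w = 8L,
                             ka = NULL, kbF = NULL, kbR = NULL,
                             bR = NULL) {
    if (is.null(ka) && nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    if (is.null(bR)) bR <- .rcChar(b)
    orientations <- list(list(seq = b, km = kbF),
                         list(seq = bR, km = kbR))
    for (o in orientations) {
        u <- .ungappedIdentityOne(a, o$seq, w, ks = ka, kl = o$km)
        if (u$id > threshold) return(TRUE)
        if (u$id >= threshold - margin) {
            slack <- max(50L, as.integer(0.1 * nchar(a)))
            win <- substr(o$seq, max(1L, u$d + 1L - slack),
                          min(nchar(o$seq), u$d + nchar(a) + slack))
            if (.identityOneStrand(a, win) > threshold) return(TRUE)
        }
    }
    FALSE
}

.kmerSet <- function(seq, w) {
    n <- nchar(seq)
    if (n < w) return(character(0))
    unique(substring(seq, seq_len(n - w + 1L), w:n))
}

## TRUE when any pair (shorter length L) above threshold t must share an
## exact word of length w, so a shared-word miss proves identity <= t
.prefilterSafe <- function(L, t, w) {
    e <- ceiling((1 - t) * L) * 2 + 2   # generous edit allowance (gaps)
    floor((L - e) / (e + 1)) >= w
}

## minimum number of distinct shared words a pair above threshold t must
## exhibit: each of the <= e edits destroys at most w words of the shorter
## sequence's L - w + 1, halved again as slack for repeated words
.prefilterMinHits <- function(L, t, w) {
    e <- ceiling((1 - t) * L) * 2 + 2
    pmax(1L, as.integer((L - w + 1L - e * w) %/% 2L))
}

#' Remove redundant transcripts from an assembly
#'
#' Greedy longest-first clustering: contigs are visited in order of
#' decreasing length (input order breaks ties); a contig sharing more than
#' \code{identityThreshold} identity (per [pairwiseIdentity()], either
#' strand) with an already-retained representative is removed, otherwise it
#' becomes a representative. Finally, representatives not strictly longer
#' than \code{minLenKeep} are dropped. Deterministic and idempotent.
#'
#' @param assembly an \linkS4class{Assembly} or named \code{DNAStringSet}.
#' @param params a [clusterParams()] list.
#' @return An object of the same class as \code{assembly} containing the
#'   retained contigs (input order preserved), with a data.frame of
#'   cluster memberships (\code{representative}, \code{member}) in
#'   \code{metadata(x)$clusters}.
#' @export
clusterTranscripts <- function(assembly, params = clusterParams()) {
    seqs <- as.character(as(assembly, "DNAStringSet"))
    ids <- names(assembly)
    w <- params$wordSize
    t <- params$identityThreshold
    n <- length(seqs)
    lens <- nchar(seqs)
    rcs <- .rcChar(seqs)
    kFwd <- lapply(seqs, .posKmers, w = w)   # positional kmers, reused
    kRc <- lapply(rcs, .posKmers, w = w)     # for diagonals and prefilter

    ## candidate pairs from one global shared-word count (both strands);
    ## a pair above the identity threshold must share at least
    ## .prefilterMinHits distinct words of its shorter member
    mkKt <- function(klist) {
        ul <- lapply(klist, unique)
        data.table::data.table(
            seq = rep.int(seq_along(ul), lengths(ul)),
            kmer = unlist(ul, use.names = FALSE))
    }
    kt <- mkKt(kFwd)
    pairCounts <- function(x, y) {
        jj <- merge(x, y, by = "kmer", allow.cartesian = TRUE,
                    suffixes = c(".a", ".b"))
        jj <- jj[seq.a < seq.b]
        if (nrow(jj) == 0L) return(NULL)
        jj[, .(N = .N), by = .(i = seq.a, j = seq.b)]
    }
    pc <- data.table::rbindlist(c(list(pairCounts(kt, kt)),
                                  list(pairCounts(kt, mkKt(kRc)))))
    adj <- vector("list", n)
    if (!is.null(pc) && nrow(pc)) {
        pc <- pc[, .(N = max(N)), by = .(i, j)]
        pc <- pc[N >= .prefilterMinHits(pmin(lens[i], lens[j]), t, w)]
        for (r in seq_len(nrow(pc))) {
            adj[[pc$i[r]]] <- c(adj[[pc$i[r]]], pc$j[r])
            adj[[pc$j[r]]] <- c(adj[[pc$j[r]]], pc$i[r])
        }
    }

    ord <- order(-lens)                  # stable: ties keep input order
    repRank <- integer(n)                # insertion order of reps, 0 = no
    repIdx <- integer(0)
    memberOf <- integer(n)               # 0 = representative
    for (i in ord) {
        s <- seqs[i]
        cand <- if (.prefilterSafe(lens[i], t, w)) {
            nb <- adj[[i]][repRank[adj[[i]]] > 0L]
            nb[order(repRank[nb])]
        } else repIdx
        assigned <- 0L
        for (r in cand) {
            if (.identityExceeds(s, seqs[r], t, w = w, ka = kFwd[[i]],
                                 kbF = kFwd[[r]], kbR = kRc[[r]],
                                 bR = rcs[r])) {
                assigned <- r
                break
            }
        }
        if (assigned) {
            memberOf[i] <- assigned
        } else {
            repIdx <- c(repIdx, i)
            repRank[i] <- length(repIdx)
        }
    }
    keep <- sort(repIdx[nchar(seqs[repIdx]) > params$minLenKeep])
    clusters <- data.frame(
        representative = ids[ifelse(memberOf > 0L, memberOf,
                                    seq_along(seqs))],
        member = ids)
    out <- as(assembly, "DNAStringSet")[keep]
    if (is(assembly, "Assembly"))
        out <- new("Assembly", out, tool = assembly@tool, k = assembly@k)
    metadata(out)$clusters <- clusters
    out
}
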