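## Orchestration of the full workflow: QC -> subsample -> (external
## assemblies in) -> redundancy -> metrics / RMBT / completeness ->
## k selection -> consensus merge -> robust set, with TSV report bundling.
## All randomness flows from the single top-level seed.

#' Configuration for the full pipeline
#'
#' Bundles every module's parameters with the input paths. Every default
#' equals the workflow's stated value where one exists (trim limit 0.05,
#' min trimmed length 20, keep > 50 bp, keep transcripts > 200 bp, 99\%
#' redundancy identity, robust contigs from >= 3 tools).
#'
#' @param reads1,reads2 FASTQ paths for mate 1 / mate 2.
#' @param assemblies data.frame with columns \code{file}, \code{tool},
#'   \code{k}: one row per input assembly FASTA.
#' @param outDir output directory (created if needed).
#' @param coreGenes optional FASTA of core gene sequences (completeness
#'   columns are omitted when \code{NULL}).
#' @param subsampleN number of pairs for the assembly subsample; the
#'   complement is used for mapping validation.
#' @param seed top-level integer seed.
#' @param trim,cluster,mapping,merge parameter lists from [trimParams()],
#'   [clusterParams()], [mappingParams()], [mergeParams()].
#' @param retention k-selection total-length retention fraction.
#' @param completeCov,partialCov,minIdentity completeness thresholds.
#' @param rmbtMaxReads cap on the number of validation reads mapped per
#'   assembly (a seeded subsample of the unselected reads keeps desk-scale
#'   runs fast); \code{Inf} maps them all.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(reads1, reads2, assemblies, outDir,
                           coreGenes = NULL, subsampleN = 10000L,
                           seed = 1L, trim = trimParams(),
                           cluster = clusterParams(),
                           mapping = mappingParams(),
                           merge = mergeParams(), retention = 0.90,
                           completeCov = 0.70, partialCov = 0.30,
                           minIdentity = 0.95, rmbtMaxReads = 20000) {
    if (missing(assemblies) || is.null(assemblies) ||
        !is.data.frame(assemblies) || nrow(assemblies) == 0L)
        stop("configuration error: at least one labeled assembly is ",
             "required", call. = FALSE)
    stopifnot(all(c("file", "tool", "k") %in% colnames(assemblies)))
    paths <- c(reads1, reads2, assemblies$file, coreGenes)
    missingP <- paths[!file.exists(paths)]
    if (length(missingP))
        stop("configuration error: missing input file(s): ",
             paste(missingP, collapse = ", "), call. = FALSE)
    structure(list(reads1 = reads1, reads2 = reads2,
                   assemblies = assemblies, outDir = outDir,
                   coreGenes = coreGenes,
                   subsampleN = as.integer(subsampleN),
                   seed = as.integer(seed), trim = trim, cluster = cluster,
                   mapping = mapping, merge = merge, retention = retention,
                   completeCov = completeCov, partialCov = partialCov,
                   minIdentity = minIdentity, rmbtMaxReads = rmbtMaxReads),
              class = "PipelineConfig")
}

.writeTsv <- function(x, path, rowNames = FALSE) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = rowNames,
                col.names = TRUE)
    path
}

#' Run the full consensus-assembly evaluation pipeline
#'
#' Stages, in fixed order: read QC with accounting; seeded subsampling of
#' the surviving pairs; per-assembly redundancy removal and the
#' seven-column evaluation (length statistics, mapping-back rate of the
#' unselected reads, optional core-gene completeness); per-tool k
#' selection; consensus merging of the selected assemblies; robust-contig
#' filtering with re-applied redundancy and length rules; evaluation of
#' the robust set. Reports are written as TSV into \code{config$outDir};
#' re-running with an identical config and seed reproduces them
#' byte-identically.
#'
#' @param config a [pipelineConfig()] list.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the report data.frames (\code{qc},
#'   \code{metrics}, \code{ksweep}, \code{selected}), the
#'   \linkS4class{MergedAssembly} objects (\code{merged}, \code{robust})
#'   and the output file paths.
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(config$outDir, "pipeline.log")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon), add = TRUE)
    say <- function(...) {
        msg <- paste0(...)
        writeLines(msg, logCon)
        flush(logCon)
        if (!quiet) message(msg)
    }
    say("stage qc: trimming/duplicate/length filtering")
    say("  params: limit=", config$trim$limit, " maxN=",
        config$trim$maxAmbiguous, " minTrim=", config$trim$minLenPostTrim,
        " keep>", config$trim$minLenKeep, " bp")
    raw <- readPairedFastq(config$reads1, config$reads2)
    qc <- qcReads(raw, params = config$trim)
    qcPath <- .writeTsv(qc$report, file.path(config$outDir,
                                             "qc_report.tsv"),
                        rowNames = TRUE)

    say("stage subsample: n=", min(config$subsampleN, length(qc$pairs)),
        " seed=", config$seed, " (Mersenne-Twister)")
    sub <- subsamplePairs(qc$pairs,
                          min(config$subsampleN, length(qc$pairs)),
                          config$seed)

    valReads <- sub$unselected
    if (length(valReads) > 0 &&
        is.finite(config$rmbtMaxReads) &&
        length(valReads) > config$rmbtMaxReads %/% 2) {
        keep <- .withSeed(config$seed + 3L,
                          sort(sample.int(length(valReads),
                                          config$rmbtMaxReads %/% 2)))
        valReads <- valReads[keep]
        say("  rmbt validation reads capped at ", 2 * length(keep))
    }

    genes <- if (!is.null(config$coreGenes)) readFasta(config$coreGenes)

    say("stage assemblies: redundancy filtering (identity>",
        config$cluster$identityThreshold, ", keep>",
        config$cluster$minLenKeep, " bp)")
    asms <- lapply(seq_len(nrow(config$assemblies)), function(i) {
        a <- Assembly(readFasta(config$assemblies$file[i]),
                      tool = config$assemblies$tool[i],
                      k = config$assemblies$k[i])
        clusterTranscripts(a, config$cluster)
    })

    evalAsm <- function(asm, label) {
        say("stage metrics: ", label)
        row <- assemblyStats(asm, minLen = config$cluster$minLenKeep)
        row$rmbt_pct <- if (length(valReads) > 0)
            rmbtPercent(mapReads(valReads, asm, config$mapping))
        else NA_real_
        if (!is.null(genes)) {
            cg <- coreGeneRecovery(asm, genes, config$completeCov,
                                   config$partialCov, config$minIdentity)
            row$cegma_complete_pct <- cg$summary[["complete_pct"]]
            row$cegma_partial_pct <- cg$summary[["partial_pct"]]
        } else {
            row$cegma_complete_pct <- NA_real_
            row$cegma_partial_pct <- NA_real_
        }
        row
    }
    metrics <- do.call(rbind, lapply(asms, function(a)
        evalAsm(a, paste0(a@tool, " k=", a@k))))

    say("stage select-k: retention=", config$retention)
    ksweep <- NULL
    selected <- list()
    for (tool in unique(metrics$tool)) {
        rows <- metrics[metrics$tool == tool, ]
        if (nrow(rows) > 1L && !anyDuplicated(suppressWarnings(
                as.numeric(rows$k)))) {
            tab <- kSweepTable(data.frame(k = as.numeric(rows$k),
                                          n50 = rows$n50,
                                          total_bp = rows$total_bp))
            tab$tool <- tool
            ksweep <- rbind(ksweep, tab)
            kSel <- selectK(tab, config$retention)
        } else {
            kSel <- rows$k[1L]
        }
        say("  ", tool, ": selected k=", kSel)
        selected[[tool]] <- asms[[which(metrics$tool == tool &
                                        metrics$k == as.character(kSel))[1L]]]
    }

    say("stage merge: minOverlap=", config$merge$minOverlap, " identity>=",
        config$merge$minOverlapIdentity)
    merged <- mergeAssemblies(unname(selected), config$merge)
    say("stage robust: minTools=", config$merge$minTools)
    robust <- robustFilter(merged, config$merge$minTools)
    robustAsm <- clusterTranscripts(
        Assembly(contigs(robust), tool = "merged", k = "robust"),
        config$cluster)
    metrics <- rbind(metrics, evalAsm(robustAsm, "merged robust set"))

    paths <- list(
        qc = qcPath,
        metrics = .writeTsv(metrics, file.path(config$outDir,
                                               "metrics.tsv")),
        merged_fasta = writeFasta(contigs(merged),
                                  file.path(config$outDir, "merged.fasta")),
        robust_fasta = writeFasta(as(robustAsm, "DNAStringSet"),
                                  file.path(config$outDir, "robust.fasta")),
        provenance = .writeTsv(as.data.frame(provenance(merged)),
                               file.path(config$outDir, "provenance.tsv")),
        log = logPath)
    if (!is.null(ksweep))
        paths$ksweep <- .writeTsv(ksweep,
                                  file.path(config$outDir, "ksweep.tsv"))
    say("done: ", nrow(metrics), " assemblies evaluated; robust set has ",
        length(robustAsm), " contigs")
    invisible(list(qc = qc$report, metrics = metrics, ksweep = ksweep,
                   selected = names(selected), merged = merged,
                   robust = robustAsm, paths = paths))
}

#' Write a complete simulated dataset to disk
#'
#' Generates a ground-truth transcriptome, paired-end reads, per-tool
#' corrupted assemblies and a core-gene subset, and writes them as
#' FASTQ/FASTA plus truth TSVs, ready for [runPipeline()].
#'
#' @param dir output directory.
#' @param config a [simConfig()] list.
#' @param profiles named list of [toolProfile()] lists.
#' @param nPairs number of read pairs.
#' @param nCoreGenes number of transcripts re-used verbatim as the
#'   core-gene proxy set (default 30).
#' @return A list of the file paths (\code{reads1}, \code{reads2},
#'   \code{assemblies} data.frame, \code{coreGenes},
#'   \code{transcripts}, truth tables), plus the in-memory \code{truth}
#'   objects.
#' @export
simulateDataset <- function(dir, config = simConfig(),
                            profiles = list(
                                alpha = toolProfile(),
                                beta = toolProfile(),
                                gamma = toolProfile()),
                            nPairs = 50000L, nCoreGenes = 30L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateTranscriptome(config)
    rd <- simulateReads(sim$transcripts, sim$weights, nPairs, config)
    asm <- simulateToolAssemblies(sim$transcripts, profiles, config$seed)
    coreIdx <- .withSeed(config$seed + 4L,
                         sort(sample.int(length(sim$transcripts),
                                         min(nCoreGenes,
                                             length(sim$transcripts)))))
    genes <- sim$transcripts[coreIdx]
    names(genes) <- sub("^tx", "gene", names(genes))
    p <- function(f) file.path(dir, f)
    writeFasta(sim$transcripts, p("transcripts.fasta"))
    writeFastq(mate1(rd$reads), p("reads_1.fastq"))
    writeFastq(mate2(rd$reads), p("reads_2.fastq"))
    writeFasta(genes, p("core_genes.fasta"))
    asmFiles <- data.frame(
        file = vapply(names(asm$assemblies), function(t)
            writeFasta(asm$assemblies[[t]],
                       p(paste0("asm_", t, ".fasta"))), character(1)),
        tool = names(asm$assemblies),
        k = "sim", row.names = NULL)
    .writeTsv(rd$truth, p("read_truth.tsv"))
    .writeTsv(asm$truth, p("assembly_truth.tsv"))
    list(reads1 = p("reads_1.fastq"), reads2 = p("reads_2.fastq"),
         assemblies = asmFiles, coreGenes = p("core_genes.fasta"),
         transcripts = p("transcripts.fasta"),
         readTruth = rd$truth, assemblyTruth = asm$truth,
         weights = sim$weights)
}
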