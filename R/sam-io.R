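#' Write an AlignmentSet to SAM
#'
#' Emits a coordinate-sorted SAM file with \code{@SQ} headers (chromosome
#' lengths from \code{genome}) and \code{SA:Z:} tags on split alignments.
#' QUAL is written as \code{*}.
#'
#' @param reads an \linkS4class{AlignmentSet}.
#' @param genome named DNAStringSet or named vector of chromosome lengths.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(reads, genome, path) {
    aln <- alignments(reads)
    seqlens <- genomeSeqlengths(genome)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", names(seqlens), "\tLN:", seqlens),
             "@PG\tID:CircleSeqTools\tPN:CircleSeqTools")
    body <- character(0)
    if (nrow(aln)) {
        tags <- ifelse(is.na(aln$sa), "", paste0("\tSA:Z:", aln$sa))
        body <- paste0(aln$qname, "\t", aln$flag, "\t", aln$rname, "\t",
                       aln$pos, "\t", aln$mapq, "\t", aln$cigar, "\t",
                       aln$rnext, "\t", aln$pnext, "\t", aln$tlen, "\t",
                       aln$seq, "\t*", tags)
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a SAM file into an AlignmentSet
#'
#' Parsing goes through Rsamtools (SAM is converted to BAM with
#' \code{asBam}, then scanned), so any spec-conformant SAM is accepted.
#' The \code{SA} tag is retained for split-read junction calling.
#'
#' @param path SAM file path.
#' @return An \linkS4class{AlignmentSet}.
#' @export
readSam <- function(path) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "mrnm", "mpos", "isize", "seq"),
        tag = "SA")
    res <- Rsamtools::scanBam(bam, param = param)[[1]]
    n <- length(res$qname)
    sa <- res$tag$SA
    if (is.null(sa)) sa <- rep(NA_character_, n)
    aln <- data.frame(
        qname = res$qname,
        flag = as.integer(res$flag),
        rname = as.character(res$rname),
        pos = as.integer(res$pos),
        mapq = as.integer(res$mapq),
        cigar = res$cigar,
        rnext = as.character(res$mrnm),
        pnext = as.integer(res$mpos),
        tlen = as.integer(res$isize),
        seq = as.character(res$seq),
        sa = as.character(sa))
    AlignmentSet(aln)
}

#' Write circles to BED
#'
#' BED3+ in 0-based half-open coordinates; any metric metadata columns of
#' the GRanges are appended after the name column.
#'
#' @param gr circles as GRanges.
#' @param path output path.
#' @param trackName optional name column prefix.
#' @return \code{path}, invisibly.
#' @export
writeCircleBed <- function(gr, path, trackName = "circle") {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L,
                     end = end(gr))
    if (length(gr))
        df$name <- paste0(trackName, seq_along(gr))
    m <- as.data.frame(mcols(gr))
    if (ncol(m)) df <- cbind(df, m)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Per-sample summary table
#'
#' One row per sample: sample_id, group, n_unique circles, mapped reads and
#' EPM, written as TSV.
#'
#' @param samples list of \linkS4class{SampleCircleSet}.
#' @param path output TSV path (NULL to just return the data.frame).
#' @return data.frame of the summary, invisibly when written.
#' @export
writeSampleSummary <- function(samples, path = NULL) {
    df <- data.frame(
        sample_id = vapply(samples, sampleId, character(1)),
        group = vapply(samples, sampleGroup, character(1)),
        n_unique = vapply(samples, function(s) length(circles(s)), numeric(1)),
        mapped_reads = vapply(samples, mappedReads, numeric(1)),
        epm = vapply(samples, epm, numeric(1)))
    if (is.null(path)) return(df)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Round-trip a simulation configuration through YAML
#'
#' @param config a \linkS4class{SimConfig}.
#' @param path YAML file path.
#' @return \code{path} invisibly (write) / a \linkS4class{SimConfig} (read).
#' @export
writeSimConfig <- function(config, path) {
    sl <- slotNames(config)
    lst <- lapply(sl, function(s) {
        v <- slot(config, s)
        if (is.data.frame(v)) as.list(v) else v
    })
    names(lst) <- sl
    yaml::write_yaml(lst, path)
    invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
    lst <- yaml::read_yaml(path)
    lst$elementPlan <- as.data.frame(lst$elementPlan)
    lst$sizePeaks <- as.data.frame(lst$sizePeaks)
    args <- lst[intersect(names(lst), names(formals(simConfig)))]
    do.call(simConfig, args)
}
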