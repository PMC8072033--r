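## Readers/writers for the plain-text formats the pipeline touches (BED,
## bedGraph, FASTA, TSV TSS tables) plus the DHS-midpoint-to-promoter
## assignment. Coordinates are BED-style 0-based half-open on disk and GRanges
## 1-based closed in memory; rtracklayer handles the conversion. A light
## structural pre-scan gives line-numbered parse errors that the generic
## importers do not.

.contentLines <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED3+ file of genomic intervals
#'
#' Tolerates comment, `track` and `browser` lines. Malformed lines (fewer than
#' 3 tab-separated fields, non-numeric or negative coordinates, start >= end)
#' raise an error naming the offending line.
#'
#' @param path BED file path.
#' @return `GRanges` in input order (names from column 4 when present).
#' @export
readBed <- function(path) {
    cl <- .contentLines(path)
    if (!length(cl$lines))
        return(GRanges())
    fields <- strsplit(cl$lines, "\t", fixed = TRUE)
    for (k in seq_along(fields)) {
        f <- fields[[k]]
        where <- paste0("line ", cl$lineno[k], " of ", path)
        if (length(f) < 3)
            stop("BED parse error at ", where, ": fewer than 3 fields")
        s <- suppressWarnings(as.numeric(f[2]))
        e <- suppressWarnings(as.numeric(f[3]))
        if (is.na(s) || is.na(e))
            stop("BED parse error at ", where, ": non-numeric coordinate")
        if (s < 0 || s >= e)
            stop("BED parse error at ", where,
                 ": need 0 <= start < end, got [", f[2], ", ", f[3], ")")
    }
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(mcols(gr)$name)) names(gr) <- mcols(gr)$name
    gr
}

#' Write intervals as BED
#'
#' @param gr `GRanges` (names become the BED name column).
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
    if (is.null(names(gr)) && !is.null(mcols(gr)$region_id))
        names(gr) <- mcols(gr)$region_id
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read per-sample bedGraphs into a binned count array
#'
#' Every bedGraph interval must align to the `bin_size` grid (intervals
#' spanning several bins are split); off-grid or overlapping intervals are
#' errors naming the interval. Bins absent from a bedGraph are 0.
#'
#' @param paths named character vector of bedGraph paths (names = sample ids).
#' @param regions `GRanges` of equal-width windows.
#' @param bin_size bin width in bp.
#' @return numeric 3-d array, regions x samples x bins.
#' @export
readBedGraphMatrix <- function(paths, regions, bin_size) {
    if (is.null(names(paths)))
        names(paths) <- basename(paths)
    B <- unique(GenomicRanges::width(regions)) / bin_size
    if (length(B) != 1)
        stop("all regions must share one width")
    out <- array(0, dim = c(length(regions), length(paths), B),
                 dimnames = list(names(regions), names(paths), NULL))
    for (j in seq_along(paths)) {
        gr <- rtracklayer::import(paths[[j]], format = "bedGraph")
        st0 <- GenomicRanges::start(gr) - 1L
        en0 <- GenomicRanges::end(gr)
        off <- st0 %% bin_size != 0 | en0 %% bin_size != 0
        if (any(off)) {
            i <- which(off)[1]
            stop("off-grid bedGraph interval in ", paths[[j]], ": ",
                 GenomicRanges::seqnames(gr)[i], ":", st0[i], "-", en0[i])
        }
        ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
        if (length(ov)) {
            i <- queryHits(ov)[1]
            stop("overlapping bedGraph intervals in ", paths[[j]], " near ",
                 GenomicRanges::seqnames(gr)[i], ":", st0[i], "-", en0[i])
        }
        hits <- findOverlaps(gr, regions)
        if (!length(hits)) next
        for (h in seq_along(hits)) {
            qi <- queryHits(hits)[h]; ri <- subjectHits(hits)[h]
            rs0 <- GenomicRanges::start(regions)[ri] - 1L
            b0 <- (st0[qi] - rs0) / bin_size    # first covered bin, 0-based
            nb <- (en0[qi] - st0[qi]) / bin_size
            bins <- b0 + seq_len(nb)
            keep <- bins >= 1 & bins <= B
            out[ri, j, bins[keep]] <- GenomicRanges::score(gr)[qi]
        }
    }
    out
}

#' Read promoter sequences from FASTA
#'
#' Sequences are uppercased and RNA-style `U` is normalized to `T`.
#' Duplicate record ids are an error.
#'
#' @param path FASTA path.
#' @return named [Biostrings::DNAStringSet].
#' @export
readPromoterFasta <- function(path) {
    raw <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(raw))
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
    seqs <- chartr("u", "T", toupper(as.character(raw)))
    seqs <- chartr("U", "T", seqs)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Read a TSS table
#'
#' Expects tab-separated columns `gene_id`, `chrom`, `tss` (0-based bp) and
#' optionally `strand`. Comment lines starting with `#` are skipped. When a
#' gene has several TSS rows they are collapsed to one record per gene using
#' the 5'-most TSS (smallest coordinate on `+`, largest on `-`).
#'
#' @param path TSV path.
#' @return data.frame, one row per gene, ordered by gene_id.
#' @export
readTssTable <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("TSS table is missing column(s): ", paste(miss, collapse = ", "))
    if (is.null(df$strand)) df$strand <- "+"
    pick <- function(d) {
        i <- if (d$strand[1] == "-") which.max(d$tss) else which.min(d$tss)
        d[i, , drop = FALSE]
    }
    out <- do.call(rbind, lapply(split(df, df$gene_id), pick))
    rownames(out) <- NULL
    out[order(out$gene_id), , drop = FALSE]
}

#' Promoter windows from a TSS table
#'
#' Builds the symmetric promoter window `[TSS - flank, TSS + flank)`
#' (strand-independent) around each gene's TSS.
#'
#' @param tss data.frame as returned by [readTssTable()].
#' @param flank half-width in bp (default 1000, i.e. a 2-kb window).
#' @return `GRanges` with `gene_id` and `tss` metadata columns.
#' @export
promoterWindows <- function(tss, flank = 1000) {
    gr <- GRanges(tss$chrom,
                  IRanges(start = tss$tss - flank + 1L,
                          end = tss$tss + flank),
                  strand = if (is.null(tss$strand)) "*" else tss$strand,
                  gene_id = tss$gene_id, tss = tss$tss)
    names(gr) <- tss$gene_id
    gr
}

## 0-based midpoint of BED-style [s, e): floor((s + e) / 2)
.midpoint0 <- function(gr) {
    floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
}

#' Assign DHS regions to promoters by midpoint overlap
#'
#' A `(dhs_id, gene_id)` pair is emitted iff the DHS midpoint (0-based,
#' `floor((start + end) / 2)` of the BED interval) lies inside the half-open
#' promoter window `[TSS - flank, TSS + flank)`. A DHS may hit several genes
#' and vice versa. Output order is deterministic (by DHS, then gene).
#'
#' @param dhs `GRanges` of DHS windows (names or `region_id` used as ids).
#' @param promoters `GRanges` from [promoterWindows()].
#' @return data.frame with columns `dhs_id`, `gene_id` (possibly empty).
#' @export
assignDhsToPromoters <- function(dhs, promoters) {
    dhs_id <- names(dhs)
    if (is.null(dhs_id)) dhs_id <- mcols(dhs)$region_id
    if (is.null(dhs_id)) dhs_id <- as.character(seq_along(dhs))
    mid0 <- .midpoint0(dhs)
    midp <- GRanges(GenomicRanges::seqnames(dhs),
                    IRanges(start = mid0 + 1L, width = 1L))
    hits <- findOverlaps(midp, promoters, ignore.strand = TRUE)
    out <- data.frame(dhs_id = dhs_id[queryHits(hits)],
                      gene_id = mcols(promoters)$gene_id[subjectHits(hits)],
                      stringsAsFactors = FALSE)
    out <- out[order(out$dhs_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
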