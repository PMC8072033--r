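#' @import methods
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges findOverlaps
NULL

#' DHSProfileSet: binned cut-count profiles over fixed DHS windows
#'
#' Container for per-stage, per-replicate DNase-seq cut-count profiles over a
#' common set of fixed-width DHS windows. Extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with a three-dimensional
#' `counts` assay of dimension regions x samples x bins; `rowRanges()` holds
#' the DHS windows and `colData()` the sample sheet (`stage`, `replicate`,
#' `library_size`). The bin width in bp is kept in `metadata(x)$bin_size`.
#'
#' @slot ... inherited from `RangedSummarizedExperiment`.
#' @seealso [DHSProfileSet()], [normalizeRPM()], [regionProfiles()]
#' @export
setClass("DHSProfileSet", contains = "RangedSummarizedExperiment")

setValidity("DHSProfileSet", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        a <- assay(object, "counts")
        if (length(dim(a)) != 3L)
            msg <- c(msg, "assay 'counts' must be a 3-d array (regions x samples x bins)")
        else if (any(a < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    need <- c("stage", "replicate", "library_size")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData is missing column(s): ",
                             paste(miss, collapse = ", ")))
    bs <- metadata(object)$bin_size
    if (is.null(bs) || !is.numeric(bs) || length(bs) != 1L || bs <= 0)
        msg <- c(msg, "metadata(x)$bin_size must be a single positive number")
    else if ("counts" %in% assayNames(object) &&
             length(dim(assay(object, "counts"))) == 3L &&
             length(object) > 0L) {
        w <- unique(GenomicRanges::width(rowRanges(object)))
        if (length(w) != 1L)
            msg <- c(msg, "all DHS windows must have the same width")
        else if (w %% bs != 0 || w / bs != dim(assay(object, "counts"))[3L])
            msg <- c(msg, "window width / bin_size must equal the number of bins")
    }
    if ("library_size" %in% colnames(colData(object)) &&
        any(colData(object)$library_size <= 0))
        msg <- c(msg, "library sizes must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a DHSProfileSet
#'
#' @param counts 3-d integer array, regions x samples x bins.
#' @param regions `GRanges` of the DHS windows (one per row of `counts`);
#'   all windows must share one width, a whole multiple of `bin_size`.
#' @param stage character vector of stage labels, one per sample.
#' @param replicate integer replicate index per sample.
#' @param library_size mapped reads per sample (used for RPM normalization).
#' @param bin_size bin width in bp (default 20).
#' @return A [DHSProfileSet-class] object.
#' @examples
#' cfg <- simConfig(seed = 1)
#' truth <- plantedTruth(cfg, c(null = 3, high = 2))
#' x <- simulateDHSProfiles(cfg, truth)
#' x
#' @export
DHSProfileSet <- function(counts, regions, stage, replicate, library_size,
                          bin_size = 20) {
    stopifnot(length(dim(counts)) == 3L)
    n_samp <- dim(counts)[2L]
    if (length(stage) != n_samp || length(replicate) != n_samp ||
        length(library_size) != n_samp)
        stop("stage, replicate and library_size must have one entry per sample")
    if (any(library_size <= 0))
        stop("library sizes must be positive")
    sample_id <- dimnames(counts)[[2L]]
    if (is.null(sample_id)) sample_id <- paste(stage, replicate, sep = "_")
    cd <- DataFrame(stage = as.character(stage),
                    replicate = as.integer(replicate),
                    library_size = as.numeric(library_size),
                    row.names = sample_id)
    dimnames(counts)[1:2] <- list(names(regions), sample_id)
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = regions, colData = cd,
                               metadata = list(bin_size = bin_size))
    new("DHSProfileSet", se)
}

#' @describeIn DHSProfileSet bin width in bp.
#' @param x a `DHSProfileSet`.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setMethod("binSize", "DHSProfileSet", function(x) metadata(x)$bin_size)

#' @describeIn DHSProfileSet number of bins per window.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setMethod("nBins", "DHSProfileSet",
          function(x) dim(assay(x, "counts"))[3L])

#' @describeIn DHSProfileSet stage label per sample.
#' @export
setGeneric("sampleStages", function(x) standardGeneric("sampleStages"))

#' @export
setMethod("sampleStages", "DHSProfileSet",
          function(x) colData(x)$stage)

#' @describeIn DHSProfileSet mapped reads per sample.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @export
setMethod("librarySizes", "DHSProfileSet",
          function(x) colData(x)$library_size)

#' Reads-per-million normalization of cut-count profiles
#'
#' Scales every bin count by `1e6 / library_size` of its sample, matching the
#' usual "tag density per million mapped reads" display convention. The result
#' is stored as an `rpm` assay alongside `counts`.
#'
#' @param x a [DHSProfileSet-class].
#' @return `x` with an added `rpm` assay.
#' @export
setGeneric("normalizeRPM", function(x) standardGeneric("normalizeRPM"))

#' @export
setMethod("normalizeRPM", "DHSProfileSet", function(x) {
    libs <- librarySizes(x)
    if (any(libs <= 0)) stop("library sizes must be positive")
    a <- assay(x, "counts")
    scale <- 1e6 / libs
    rpm <- sweep(a, 2L, scale, `*`)
    assays(x)$rpm <- rpm
    x
})

#' Extract the replicate-by-bin profile matrix of one region
#'
#' @param x a [DHSProfileSet-class].
#' @param region region index or name.
#' @param stage optional stage label to subset samples.
#' @param assay_name `"counts"` or `"rpm"`.
#' @return numeric matrix, samples x bins.
#' @export
setGeneric("regionProfiles",
           function(x, region, stage = NULL, assay_name = "counts")
               standardGeneric("regionProfiles"))

#' @export
setMethod("regionProfiles", "DHSProfileSet",
          function(x, region, stage = NULL, assay_name = "counts") {
    a <- assay(x, assay_name)
    m <- a[region, , , drop = FALSE]
    m <- matrix(m, nrow = dim(a)[2L], ncol = dim(a)[3L],
                dimnames = list(colnames(x), NULL))
    if (!is.null(stage)) {
        keep <- sampleStages(x) == stage
        if (!any(keep)) stop("no samples with stage '", stage, "'")
        m <- m[keep, , drop = FALSE]
    }
    m
})

setMethod("show", "DHSProfileSet", function(object) {
    cat("DHSProfileSet with", nrow(object), "regions,",
        ncol(object), "samples,", nBins(object), "bins of",
        binSize(object), "bp\n")
    st <- table(sampleStages(object))
    cat("stages:", paste(sprintf("%s(%d)", names(st), st), collapse = ", "),
        "\n")
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
})
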