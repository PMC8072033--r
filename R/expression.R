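## RNA count filtering and the stage-pair log2 fold-changes used as
## classification gates. CPM = counts * 1e6 / column sum (edgeR convention,
## no between-sample normalization factors); the fold-change is taken on
## group-mean CPM with a 0.5 pseudocount so genes silent in the control do
## not produce infinite values.

.checkCountMatrix <- function(counts, samples) {
    if (!is.matrix(counts) || any(counts < 0))
        stop("counts must be a non-negative gene x sample matrix")
    if (!all(c("sample", "stage") %in% colnames(samples)))
        stop("sample sheet needs 'sample' and 'stage' columns")
    if (!setequal(colnames(counts), samples$sample))
        stop("sample sheet does not match count matrix columns")
    if (any(colSums(counts) == 0))
        stop("all-zero sample(s): ",
             paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
    invisible(TRUE)
}

#' Counts-per-million filter
#'
#' Retains genes with CPM >= `min_cpm` in at least `min_samples` samples
#' (`min_samples` defaults to the size of the smallest stage group in the
#' study design, 2). The sample set is unchanged.
#'
#' @param counts integer gene x sample matrix.
#' @param samples sample sheet data.frame (`sample`, `stage`, ...).
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples at or above the threshold.
#' @return the filtered count matrix.
#' @export
cpmFilter <- function(counts, samples, min_cpm = 1, min_samples = 2) {
    .checkCountMatrix(counts, samples)
    cpm <- edgeR::cpm(counts)
    keep <- rowSums(cpm >= min_cpm) >= min_samples
    counts[keep, , drop = FALSE]
}

.groupMeanCpm <- function(counts, samples, stage) {
    sel <- samples$sample[samples$stage == stage]
    if (!length(sel))
        stop("unknown or empty stage label: ", stage)
    cpm <- edgeR::cpm(counts)
    rowMeans(cpm[, sel, drop = FALSE])
}

#' Per-gene log2 fold-change between two stages
#'
#' `log2((mean CPM_a + pseudocount) / (mean CPM_b + pseudocount))`.
#'
#' @inheritParams cpmFilter
#' @param stage_a,stage_b stage labels (numerator, denominator).
#' @param pseudocount added to both group means on the CPM scale.
#' @return named numeric vector (one value per gene).
#' @export
log2FoldChange <- function(counts, samples, stage_a, stage_b,
                           pseudocount = 0.5) {
    .checkCountMatrix(counts, samples)
    ma <- .groupMeanCpm(counts, samples, stage_a)
    mb <- .groupMeanCpm(counts, samples, stage_b)
    log2((ma + pseudocount) / (mb + pseudocount))
}

#' Log2 fold-change table for the classification gates
#'
#' Computes the three stage pairs the dose-response gates use:
#' DN1 vs ctrl, DN2b vs ctrl and DN2b vs DN1.
#'
#' @inheritParams log2FoldChange
#' @return data.frame with columns `gene_id`, `lfc_DN1_ctrl`,
#'   `lfc_DN2b_ctrl`, `lfc_DN2b_DN1` and a `pseudocount` attribute.
#' @export
log2fcTable <- function(counts, samples, pseudocount = 0.5) {
    out <- data.frame(
        gene_id = rownames(counts),
        lfc_DN1_ctrl = log2FoldChange(counts, samples, "DN1", "ctrl",
                                      pseudocount),
        lfc_DN2b_ctrl = log2FoldChange(counts, samples, "DN2b", "ctrl",
                                       pseudocount),
        lfc_DN2b_DN1 = log2FoldChange(counts, samples, "DN2b", "DN1",
                                      pseudocount),
        row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "pseudocount") <- pseudocount
    out
}

#' Expression gates for dose-response classification
#'
#' The low-dose gate passes iff `log2FC(DN1, ctrl) >= threshold`; the
#' high-dose gate passes iff `log2FC(DN2b, ctrl) >= threshold` AND
#' `log2FC(DN2b, DN1) >= threshold` (both thresholds inclusive).
#'
#' @param lfc a [log2fcTable()] data.frame.
#' @param gate `"low"` or `"high"`.
#' @param threshold log2 fold-change cutoff (default 2).
#' @return named logical vector over genes.
#' @export
expressionGate <- function(lfc, gate = c("low", "high"), threshold = 2) {
    gate <- match.arg(gate)
    need <- if (gate == "low") "lfc_DN1_ctrl" else
        c("lfc_DN2b_ctrl", "lfc_DN2b_DN1")
    miss <- setdiff(need, colnames(lfc))
    if (length(miss))
        stop("missing stage pair(s) in log2FC table: ",
             paste(miss, collapse = ", "))
    res <- if (gate == "low") lfc$lfc_DN1_ctrl >= threshold
           else lfc$lfc_DN2b_ctrl >= threshold & lfc$lfc_DN2b_DN1 >= threshold
    stats::setNames(res, lfc$gene_id)
}
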