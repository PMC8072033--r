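## Dose-response classification of promoter DHS regions: combines per-stage
## accessibility calls, adjusted differential-accessibility p-values for the
## LSK~DN1 and DN1~DN2b transitions, and the expression gates into the
## low-dose-responsive I / II and high-dose-dependent classes.

.lookupBy <- function(df, key, values, cols) {
    i <- match(values, df[[key]])
    if (anyNA(i))
        stop("missing evidence for ", key, ": ",
             paste(unique(values[is.na(i)]), collapse = ", "))
    as.data.frame(df[i, cols, drop = FALSE])
}

#' Classify promoter DHS regions by Notch dose response
#'
#' Applies the dose-response criteria per (region, gene) pair:
#' \describe{
#'   \item{high}{LSK and DN1 inaccessible, DN2b accessible, adjusted
#'     DN1~DN2b p < `alpha`, high expression gate.}
#'   \item{low_I}{LSK inaccessible, DN1 accessible, adjusted LSK~DN1
#'     p < `alpha`, low expression gate.}
#'   \item{low_II}{LSK accessible, adjusted LSK~DN1 p < `alpha` with a
#'     positive DN1 - LSK mean-RPM effect, low expression gate.}
#' }
#' Predicates are evaluated in that order (they are mutually exclusive on the
#' accessibility flags); `unclassified` when none holds. All evidence used is
#' carried in the output.
#'
#' @param calls accessibility calls from [callAccessibility()] covering at
#'   least stages LSK, DN1 and DN2b.
#' @param diff_lsk_dn1 [diffAccessTest()] result for LSK vs DN1, with
#'   `p_adjusted` filled in.
#' @param diff_dn1_dn2b [diffAccessTest()] result for DN1 vs DN2b, with
#'   `p_adjusted` filled in.
#' @param gates data.frame with columns `gene_id`, `low`, `high` (from
#'   [expressionGate()]).
#' @param mapping data.frame `dhs_id`, `gene_id` pairs (from
#'   [assignDhsToPromoters()]).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return `DataFrame`, one row per (region, gene) pair: `gene_id`,
#'   `region_id`, `dose_class` and the evidence columns.
#' @export
classifyPromoters <- function(calls, diff_lsk_dn1, diff_dn1_dn2b, gates,
                              mapping, alpha = 0.05) {
    calls <- as.data.frame(calls)
    acc <- function(stage) {
        sub <- calls[calls$stage == stage, , drop = FALSE]
        if (!nrow(sub)) stop("missing accessibility calls for stage ", stage)
        .lookupBy(sub, "region_id", mapping$dhs_id, "accessible")[[1]]
    }
    acc_lsk <- acc("LSK"); acc_dn1 <- acc("DN1"); acc_dn2b <- acc("DN2b")
    ld <- .lookupBy(as.data.frame(diff_lsk_dn1), "region_id", mapping$dhs_id,
                    c("p_adjusted", "delta_mean_rpm"))
    dd <- .lookupBy(as.data.frame(diff_dn1_dn2b), "region_id", mapping$dhs_id,
                    c("p_adjusted", "delta_mean_rpm"))
    if (anyNA(ld$p_adjusted) || anyNA(dd$p_adjusted))
        stop("p_adjusted not filled in; run adjustEffectiveBonferroni first")
    gt <- .lookupBy(gates, "gene_id", mapping$gene_id, c("low", "high"))
    sig_ld <- ld$p_adjusted < alpha
    sig_dd <- dd$p_adjusted < alpha
    ## diff_lsk_dn1 effect is LSK - DN1; the DN1 gain is its negative
    delta_dn1 <- -ld$delta_mean_rpm
    is_high <- !acc_lsk & !acc_dn1 & acc_dn2b & sig_dd & gt$high
    is_low1 <- !acc_lsk & acc_dn1 & sig_ld & gt$low
    is_low2 <- acc_lsk & sig_ld & delta_dn1 > 0 & gt$low
    dose_class <- rep("unclassified", nrow(mapping))
    dose_class[is_low2] <- "low_II"
    dose_class[is_low1] <- "low_I"
    dose_class[is_high] <- "high"
    DataFrame(gene_id = mapping$gene_id, region_id = mapping$dhs_id,
              dose_class = dose_class,
              acc_LSK = acc_lsk, acc_DN1 = acc_dn1, acc_DN2b = acc_dn2b,
              p_adj_LSK_DN1 = ld$p_adjusted,
              p_adj_DN1_DN2b = dd$p_adjusted,
              delta_DN1_minus_LSK = delta_dn1,
              gate_low = gt$low, gate_high = gt$high)
}

#' Summarize dose-response classes
#'
#' Deduplicated gene lists per class plus the unions and cross-class
#' overlaps (a gene hit by several DHS regions counts once per class).
#'
#' @param classifications a [classifyPromoters()] result.
#' @return list with `class_genes` (named list of unique gene ids per
#'   class), `sizes`, `n_unique_low` (union of low_I and low_II),
#'   `n_unique_high`, and `overlaps` (pairwise gene-overlap counts).
#' @export
summarizeClasses <- function(classifications) {
    cls <- c("low_I", "low_II", "high")
    df <- as.data.frame(classifications)
    class_genes <- lapply(stats::setNames(cls, cls), function(k)
        sort(unique(df$gene_id[df$dose_class == k])))
    ov <- outer(cls, cls, Vectorize(function(a, b)
        length(intersect(class_genes[[a]], class_genes[[b]]))))
    dimnames(ov) <- list(cls, cls)
    list(class_genes = class_genes,
         sizes = vapply(class_genes, length, 0L),
         n_unique_low = length(union(class_genes$low_I, class_genes$low_II)),
         n_unique_high = length(class_genes$high),
         overlaps = ov)
}
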