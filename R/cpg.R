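## Promoter CpG content: observed/expected CpG ratio per 2-kb promoter and
## Mann-Whitney comparison of dose-class groups. Observed = count of CG
## dinucleotides on the forward strand (the result is strand-invariant since
## CG is its own reverse complement); expected = nC * nG / length. N bases
## count toward the length but not toward any base or dinucleotide count.

#' Observed/expected CpG ratio of promoter sequences
#'
#' @param sequences a [Biostrings::DNAStringSet] or character vector of
#'   A/C/G/T/N sequences (case-insensitive).
#' @return `DataFrame` with one row per sequence: `gene_id` (from names),
#'   `observed_cpg`, `n_c`, `n_g`, `length`, `expected_cpg` and `oe_ratio`
#'   (`NA` when the expected count is zero; such promoters are excluded
#'   downstream with a warning).
#' @examples
#' oeCpG(c(x = "CGCGCG", y = "ACGT"))
#' @export
oeCpG <- function(sequences) {
    ids <- names(sequences)
    if (!methods::is(sequences, "DNAStringSet")) {
        sequences <- toupper(as.character(sequences))
        if (any(nchar(sequences) == 0))
            stop("empty sequence")
        bad <- grepl("[^ACGTN]", sequences)
        if (any(bad))
            stop("non-IUPAC character in sequence(s): ",
                 paste(utils::head(which(bad)), collapse = ", "))
        sequences <- Biostrings::DNAStringSet(sequences)
    }
    if (any(Biostrings::width(sequences) == 0))
        stop("empty sequence")
    freq <- Biostrings::alphabetFrequency(sequences, baseOnly = TRUE)
    extra <- freq[, "other", drop = FALSE] -
        Biostrings::letterFrequency(sequences, "N")
    if (any(extra > 0))
        stop("non-IUPAC character in sequence(s): ",
             paste(utils::head(which(extra > 0)), collapse = ", "))
    observed <- Biostrings::vcountPattern("CG", sequences)
    n_c <- freq[, "C"]; n_g <- freq[, "G"]
    len <- Biostrings::width(sequences)
    expected <- n_c * n_g / len
    if (is.null(ids)) ids <- as.character(seq_along(sequences))
    DataFrame(gene_id = ids, observed_cpg = observed,
              n_c = unname(n_c), n_g = unname(n_g), length = len,
              expected_cpg = unname(expected),
              oe_ratio = ifelse(expected > 0, observed / expected, NA_real_))
}

#' Per-class mean observed/expected CpG ratio
#'
#' Arithmetic mean over defined ratios; undefined (NA) ratios are excluded
#' and counted.
#'
#' @param results an [oeCpG()] result.
#' @param classes named character vector or data.frame (`gene_id`, `class`)
#'   mapping genes to groups.
#' @return data.frame: `class`, `n`, `n_excluded`, `mean_oe`, `median_oe`.
#' @export
cpgGroupMeans <- function(results, classes) {
    if (is.data.frame(classes) || methods::is(classes, "DataFrame"))
        classes <- stats::setNames(classes$class, classes$gene_id)
    res <- as.data.frame(results)
    cl <- classes[res$gene_id]
    keep <- !is.na(cl)
    res <- res[keep, , drop = FALSE]; cl <- cl[keep]
    out <- lapply(split(res$oe_ratio, cl), function(v) {
        n_ex <- sum(is.na(v))
        v <- v[!is.na(v)]
        data.frame(n = length(v), n_excluded = n_ex,
                   mean_oe = mean(v), median_oe = stats::median(v))
    })
    if (any(vapply(out, function(d) d$n_excluded, 0L) > 0))
        warning("promoters with undefined o/e ratio were excluded")
    cbind(class = names(out), do.call(rbind, out), row.names = NULL)
}

#' Mann-Whitney comparison of two groups of o/e CpG ratios
#'
#' Two-sided by default. The exact distribution is used when
#' `n_a + n_b <= 16` and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param group_a,group_b numeric ratio vectors (NA entries are excluded
#'   with a warning).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact override the automatic exact/approximate choice.
#' @return list: `n_a`, `n_b`, group means and medians, `U` (the
#'   Mann-Whitney statistic for group A), `p`, `exact`.
#' @examples
#' mannWhitneyCpG(c(1, 2, 3), c(4, 5, 6))$p   # exact two-sided 0.1
#' @export
mannWhitneyCpG <- function(group_a, group_b,
                           alternative = c("two.sided", "less", "greater"),
                           exact = NULL) {
    alternative <- match.arg(alternative)
    drop_a <- sum(is.na(group_a)); drop_b <- sum(is.na(group_b))
    if (drop_a + drop_b > 0)
        warning("excluded ", drop_a + drop_b, " undefined ratio(s)")
    a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
    if (!length(a) || !length(b))
        stop("empty group after excluding undefined ratios")
    ties <- anyDuplicated(c(a, b)) > 0
    if (is.null(exact))
        exact <- (length(a) + length(b) <= 16) && !ties
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                           correct = TRUE))
    list(n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b),
         median_a = stats::median(a), median_b = stats::median(b),
         U = unname(wt$statistic), p = wt$p.value, exact = exact)
}
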