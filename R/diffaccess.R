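## Nonparametric spatial differential-accessibility test on binned RPM
## profiles over fixed DHS windows. Two scores: a Welch-standardized
## integrated squared difference of the per-bin condition means, either
## unsmoothed (robust to heteroscedastic error variance; the default) or with
## Nadaraya-Watson Gaussian kernel smoothing of the mean and variance curves.
## Null calibration is by replicate-label permutation; because only
## choose(nA + nB, nA) distinct assignments exist at 2-4 replicates, a
## continuous p-value is obtained by moment-matching a Gamma distribution to
## the permutation statistics pooled across all regions of a run (identity
## and complement assignments excluded), alongside the coarse empirical
## permutation p.

#' Nadaraya-Watson Gaussian kernel smoothing of a binned profile
#'
#' Smooths a profile with a Gaussian kernel of standard deviation
#' `bandwidth_bp` on the bp scale; a constant profile is preserved exactly
#' and as `bandwidth_bp -> 0` the output tends to the input.
#'
#' @param y numeric profile (one value per bin).
#' @param bandwidth_bp kernel SD in bp (default 150).
#' @param bin_size bin width in bp (default 20).
#' @return smoothed numeric vector, same length as `y`.
#' @export
smoothProfile <- function(y, bandwidth_bp = 150, bin_size = 20) {
    S <- .smoothOperator(length(y), bandwidth_bp, bin_size)
    as.numeric(S %*% y)
}

## row-stochastic smoothing matrix; s_i = sum_j K(x_i - x_j) y_j / sum_j K
.smoothOperator <- function(B, bandwidth_bp, bin_size) {
    if (bandwidth_bp <= 0) stop("bandwidth must be > 0")
    if (B < 2) stop("need at least 2 bins")
    x <- (seq_len(B) - 0.5) * bin_size
    K <- stats::dnorm(outer(x, x, "-") / bandwidth_bp)
    K / rowSums(K)
}

## Per-bin group summaries for a set of label assignments, vectorized.
## Y: pooled samples x bins; MA: assignments x samples membership (1 = group
## A). Returns assignments x bins matrices of means and Welch variance term.
.assignmentSummaries <- function(Y, MA) {
    nA <- rowSums(MA)[1]
    nB <- ncol(MA) - nA
    MB <- 1 - MA
    S1A <- MA %*% Y; S2A <- MA %*% (Y^2)
    S1B <- MB %*% Y; S2B <- MB %*% (Y^2)
    mA <- S1A / nA; mB <- S1B / nB
    vA <- pmax((S2A - nA * mA^2) / (nA - 1), 0)
    vB <- pmax((S2B - nB * mB^2) / (nB - 1), 0)
    list(mA = mA, mB = mB, W = vA / nA + vB / nB)
}

## Core quadratic form: mean over bins of squared mean difference over the
## floored Welch variance. Operates on assignments x bins matrices; smoothing
## operator S (or NULL) is applied to means and variances for the kn score.
.tsScore <- function(mA, mB, W, S = NULL) {
    if (!is.null(S)) {
        tS <- t(S)
        mA <- mA %*% tS; mB <- mB %*% tS; W <- W %*% tS
    }
    eps <- 0.5 * apply(W, 1, stats::median) + 1e-12
    rowMeans((mA - mB)^2 / (W + eps))
}

.checkGroups <- function(A, B) {
    if (!is.matrix(A) || !is.matrix(B) || ncol(A) != ncol(B))
        stop("A and B must be matrices with the same number of bins")
    if (nrow(A) < 2 || nrow(B) < 2)
        stop("need at least 2 replicates per condition")
}

#' Unsmoothed differential-accessibility score
#'
#' Welch-standardized integrated squared difference of per-bin condition
#' means: `(1/B) * sum_b (mean_A(b) - mean_B(b))^2 / (s2_A(b)/n_A +
#' s2_B(b)/n_B + eps)`, with a variance floor
#' `eps = 0.5 * median_b(Welch variance) + 1e-12` guarding bins with zero
#' replicate variance. Zero iff the condition means are identical; invariant
#' to swapping the two conditions; accommodates unequal error variance
#' between samples.
#'
#' @param A,B replicate x bin RPM profile matrices for the two conditions.
#' @return non-negative scalar score.
#' @export
tsDnun <- function(A, B) {
    .checkGroups(A, B)
    Y <- rbind(A, B)
    MA <- matrix(c(rep(1, nrow(A)), rep(0, nrow(B))), nrow = 1)
    s <- .assignmentSummaries(Y, MA)
    as.numeric(.tsScore(s$mA, s$mB, s$W))
}

#' Kernel-smoothed differential-accessibility score
#'
#' Same quadratic form as [tsDnun()] but computed on Nadaraya-Watson
#' smoothed condition-mean curves, with the per-bin Welch variance term
#' smoothed by the same kernel. Sensitive to peak-shape differences,
#' including pure positional shifts; equals [tsDnun()] in the
#' `bandwidth_bp -> 0` limit.
#'
#' @inheritParams tsDnun
#' @param bandwidth_bp Gaussian kernel SD in bp (default 150).
#' @param bin_size bin width in bp (default 20).
#' @return non-negative scalar score.
#' @export
tsKn <- function(A, B, bandwidth_bp = 150, bin_size = 20) {
    .checkGroups(A, B)
    S <- .smoothOperator(ncol(A), bandwidth_bp, bin_size)
    Y <- rbind(A, B)
    MA <- matrix(c(rep(1, nrow(A)), rep(0, nrow(B))), nrow = 1)
    s <- .assignmentSummaries(Y, MA)
    as.numeric(.tsScore(s$mA, s$mB, s$W, S))
}

## All (or max_perms Monte-Carlo) label assignments for nA-of-n pooled
## samples, as a membership matrix with the identity assignment in row 1.
.assignmentMatrix <- function(nA, nB, max_perms, exhaustive_only = FALSE) {
    n <- nA + nB
    n_total <- choose(n, nA)
    if (n_total < 2) stop("fewer than 2 distinct assignments")
    if (n_total <= max_perms || exhaustive_only) {
        idx <- utils::combn(n, nA)
        MA <- matrix(0, ncol(idx), n)
        MA[cbind(rep(seq_len(ncol(idx)), each = nA), as.vector(idx))] <- 1
        identity <- rep(c(1, 0), c(nA, nB))
        id_row <- which(apply(MA, 1, function(r) all(r == identity)))
        comp_row <- which(apply(MA, 1, function(r) all(r == 1 - identity)))
        ## put the identity first
        ord <- c(id_row, setdiff(seq_len(nrow(MA)), id_row))
        MA <- MA[ord, , drop = FALSE]
        comp_row <- match(comp_row, ord)
        list(MA = MA, exhaustive = TRUE, complement = comp_row)
    } else {
        MA <- matrix(0, max_perms + 1L, n)
        MA[1, seq_len(nA)] <- 1
        for (i in seq_len(max_perms) + 1L)
            MA[i, sample.int(n, nA)] <- 1
        list(MA = MA, exhaustive = FALSE, complement = NA_integer_)
    }
}

#' Permutation p-value for a differential-accessibility score
#'
#' Permutes condition labels across the pooled replicates. All
#' `choose(nA + nB, nA)` assignments are enumerated when that count does not
#' exceed `max_perms` and the p-value is `#[assignments with statistic >=
#' observed] / total` (identity included, so p > 0; ties count as >=).
#' Otherwise `max_perms` Monte-Carlo assignments are drawn and the add-one
#' estimator `(1 + #[>= observed]) / (1 + max_perms)` is used. Note that both
#' scores are invariant to swapping the two groups, so with a balanced design
#' the complement of the identity always ties with it and the smallest
#' attainable exhaustive p is `2 / total`.
#'
#' @inheritParams tsKn
#' @param statistic `"dnun"` or `"kn"`.
#' @param max_perms enumeration cutoff / Monte-Carlo size (default 10000).
#' @param seed optional seed for the Monte-Carlo branch.
#' @return list with `p_perm`, `n_permutations`, `exhaustive`, `observed`
#'   and the vector of permutation statistics `stats` (identity first).
#' @export
permutationPvalue <- function(A, B, statistic = c("dnun", "kn"),
                              max_perms = 10000, seed = NULL,
                              bandwidth_bp = 150, bin_size = 20) {
    statistic <- match.arg(statistic)
    .checkGroups(A, B)
    if (nrow(A) + nrow(B) < 4)
        stop("need at least 4 pooled replicates")
    if (!is.null(seed)) set.seed(seed)
    S <- if (statistic == "kn")
        .smoothOperator(ncol(A), bandwidth_bp, bin_size) else NULL
    asg <- .assignmentMatrix(nrow(A), nrow(B), max_perms)
    Y <- rbind(A, B)
    sm <- .assignmentSummaries(Y, asg$MA)
    stats <- .tsScore(sm$mA, sm$mB, sm$W, S)
    obs <- stats[1]
    tol <- 1e-12 * max(1, abs(obs))
    k <- sum(stats >= obs - tol)
    p <- if (asg$exhaustive) k / length(stats)
         else (1 + (k - 1)) / (1 + (length(stats) - 1))
    list(p_perm = p, n_permutations = length(stats) - !asg$exhaustive,
         exhaustive = asg$exhaustive, observed = obs, stats = stats,
         complement = asg$complement)
}

#' Region-wise differential accessibility between two stages
#'
#' For every region, computes both scores ([tsDnun()] and [tsKn()]) between
#' the replicate RPM profiles of `stage_a` and `stage_b`, the empirical
#' permutation p-value of the chosen statistic, and a continuous tail
#' p-value: a Gamma distribution is moment-matched to the permutation
#' statistics pooled across all regions (excluding, in the exhaustive case,
#' each region's identity assignment and its complement, which always equal
#' the observed score) and `p_value` is its upper tail at the observed score.
#' The pooled fit makes p-values with the resolution needed for Bonferroni
#' control available at replicate counts where per-region enumeration alone
#' cannot go below `2 / choose(nA + nB, nA)`.
#'
#' @param x a [DHSProfileSet-class] (RPM assay added on the fly if missing).
#' @param stage_a,stage_b stage labels to compare.
#' @param statistic score used for p-values: `"dnun"` (default) or `"kn"`.
#' @param bandwidth_bp kernel SD in bp for the kn score.
#' @param max_perms enumeration cutoff / Monte-Carlo size.
#' @param seed seed for any Monte-Carlo permutation draws.
#' @param p_method `"pooled_tail"` (default) or `"empirical"` to make
#'   `p_value` the coarse per-region permutation p instead.
#' @return `DataFrame` with one row per region: `region_id`, `stage_a`,
#'   `stage_b`, `ts_kn`, `ts_dnun`, `p_perm`, `p_value`, `p_adjusted` (NA
#'   until [adjustEffectiveBonferroni()]), `delta_mean_rpm`
#'   (mean RPM A - mean RPM B), `n_permutations`. The Gamma null parameters
#'   are recorded in `metadata()`.
#' @export
diffAccessTest <- function(x, stage_a, stage_b, statistic = c("dnun", "kn"),
                           bandwidth_bp = 150, max_perms = 10000,
                           seed = NULL,
                           p_method = c("pooled_tail", "empirical")) {
    statistic <- match.arg(statistic)
    p_method <- match.arg(p_method)
    if (!"rpm" %in% assayNames(x)) x <- normalizeRPM(x)
    for (s in c(stage_a, stage_b))
        if (sum(sampleStages(x) == s) < 2)
            stop("need at least 2 replicates for stage '", s, "'")
    if (!is.null(seed)) set.seed(seed)
    ia <- which(sampleStages(x) == stage_a)
    ib <- which(sampleStages(x) == stage_b)
    nA <- length(ia); nB <- length(ib)
    B <- nBins(x)
    S <- .smoothOperator(B, bandwidth_bp, binSize(x))
    asg <- .assignmentMatrix(nA, nB, max_perms)
    a <- assay(x, "rpm")
    n <- nrow(x)
    ts_kn <- ts_dnun <- p_perm <- delta <- obs <- numeric(n)
    pool <- vector("list", n)
    drop_rows <- if (asg$exhaustive) c(1L, asg$complement) else 1L
    for (i in seq_len(n)) {
        Y <- rbind(matrix(a[i, ia, ], nA, B), matrix(a[i, ib, ], nB, B))
        sm <- .assignmentSummaries(Y, asg$MA)
        st_dn <- .tsScore(sm$mA, sm$mB, sm$W)
        st_kn <- .tsScore(sm$mA, sm$mB, sm$W, S)
        st <- if (statistic == "dnun") st_dn else st_kn
        ts_dnun[i] <- st_dn[1]; ts_kn[i] <- st_kn[1]
        obs[i] <- st[1]
        tol <- 1e-12 * max(1, obs[i])
        k <- sum(st >= obs[i] - tol)
        p_perm[i] <- if (asg$exhaustive) k / length(st)
                     else (1 + (k - 1)) / length(st)
        pool[[i]] <- st[-drop_rows]
        delta[i] <- mean(sm$mA[1, ]) - mean(sm$mB[1, ])
    }
    pool <- unlist(pool)
    m <- mean(pool); v <- stats::var(pool)
    if (p_method == "pooled_tail" && is.finite(v) && v > 0 && m > 0) {
        shape <- m^2 / v; rate <- m / v
        p_value <- stats::pgamma(obs, shape = shape, rate = rate,
                                 lower.tail = FALSE)
        p_value <- pmin(1, pmax(p_value, .Machine$double.xmin))
        null_fit <- list(method = "pooled_gamma", shape = shape, rate = rate,
                         n_pool = length(pool))
    } else {
        p_value <- p_perm
        null_fit <- list(method = "empirical", n_pool = length(pool))
    }
    out <- DataFrame(region_id = rownames(x), stage_a = stage_a,
                     stage_b = stage_b, ts_kn = ts_kn, ts_dnun = ts_dnun,
                     p_perm = p_perm, p_value = p_value,
                     p_adjusted = NA_real_, delta_mean_rpm = delta,
                     n_permutations = nrow(asg$MA) - !asg$exhaustive)
    metadata(out) <- list(statistic = statistic, null_fit = null_fit,
                          n_a = nA, n_b = nB)
    out
}

#' Bonferroni adjustment on the effective number of tests
#'
#' Regions whose genomic intervals overlap are merged into clusters
#' (single-linkage); within a cluster the minimum p is the cluster p, the
#' effective number of tests is the number of clusters, and
#' `p_adjusted = min(1, cluster_p * n_clusters)` is assigned back to every
#' member region. With no overlapping regions this reduces to plain
#' Bonferroni.
#'
#' @param results a [diffAccessTest()] `DataFrame` (or any data.frame with
#'   `region_id` and a p column).
#' @param regions `GRanges` named by region id.
#' @param p_col which p column to adjust (default `"p_value"`).
#' @return `results` with `p_adjusted` filled in; the number of clusters is
#'   recorded in `metadata()$n_clusters` when the input carries metadata.
#' @export
adjustEffectiveBonferroni <- function(results, regions, p_col = "p_value") {
    ids <- results$region_id
    regions <- regions[ids]
    red <- GenomicRanges::reduce(regions, min.gapwidth = 0L,
                                 ignore.strand = TRUE)
    cl <- subjectHits(findOverlaps(regions, red))
    n_clusters <- length(red)
    p <- results[[p_col]]
    cluster_p <- tapply(p, cl, min)
    p_adj <- pmin(1, unname(cluster_p[as.character(cl)]) * n_clusters)
    results$p_adjusted <- p_adj
    if (is(results, "DataFrame"))
        metadata(results)$n_clusters <- n_clusters
    results
}

#' Per-stage accessibility calls
#'
#' If per-stage hotspot BEDs (as `GRanges`) are supplied, a region is called
#' accessible in a stage iff its midpoint falls inside a stage hotspot.
#' Otherwise a threshold rule is used: accessible iff the mean RPM per bin
#' over the central 1 kb of the window is at least `tau`; by default `tau` is
#' 3x a background estimate taken as the 25th percentile of the per-bin stage
#' mean RPM over all regions of that stage.
#'
#' @param x a [DHSProfileSet-class].
#' @param hotspots optional named list of `GRanges`, one per stage.
#' @param tau optional fixed RPM-per-bin threshold.
#' @param central_bp width of the central window used by the threshold rule.
#' @return `DataFrame`: `region_id`, `stage`, `accessible`, `mean_rpm`,
#'   `source` (`"hotspot_bed"` or `"threshold"`).
#' @export
callAccessibility <- function(x, hotspots = NULL, tau = NULL,
                              central_bp = 1000) {
    if (!"rpm" %in% assayNames(x)) x <- normalizeRPM(x)
    a <- assay(x, "rpm")
    stages <- unique(sampleStages(x))
    B <- nBins(x)
    cb <- round(central_bp / binSize(x))
    ctr <- seq_len(cb) + floor((B - cb) / 2)
    out <- vector("list", length(stages))
    mid0 <- .midpoint0(rowRanges(x))
    midp <- GRanges(GenomicRanges::seqnames(rowRanges(x)),
                    IRanges(start = mid0 + 1L, width = 1L))
    for (k in seq_along(stages)) {
        s <- stages[k]
        js <- which(sampleStages(x) == s)
        ## regions x bins stage-mean RPM
        sm <- apply(a[, js, , drop = FALSE], c(1, 3), mean)
        central_mean <- rowMeans(sm[, ctr, drop = FALSE])
        if (!is.null(hotspots)) {
            hs <- hotspots[[s]]
            if (is.null(hs))
                stop("no hotspot BED supplied for stage '", s, "'")
            acc <- overlapsAny(midp, hs, ignore.strand = TRUE)
            src <- "hotspot_bed"
        } else {
            tau_s <- if (!is.null(tau)) tau else
                3 * stats::quantile(sm, 0.25, names = FALSE)
            acc <- central_mean >= tau_s
            src <- "threshold"
        }
        out[[k]] <- DataFrame(region_id = rownames(x), stage = s,
                              accessible = acc, mean_rpm = central_mean,
                              source = src)
    }
    do.call(rbind, out)
}
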