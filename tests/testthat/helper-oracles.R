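## Independent oracles and small builders shared across tests.

## tiny default simulation used where only structure matters
tinyConfig <- function(...) simConfig(n_regions = 6, seed = 7,
                                      rna_background_genes = 50, ...)

## brute-force CpG scan over a character sequence (independent of oeCpG)
bruteCpG <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    L <- length(ch)
    obs <- sum(ch[-L] == "C" & ch[-1] == "G")
    nC <- sum(ch == "C"); nG <- sum(ch == "G")
    exp <- nC * nG / L
    list(observed = obs, n_c = nC, n_g = nG,
         ratio = if (exp > 0) obs / exp else NA_real_)
}

## brute-force two-sided Mann-Whitney p by full enumeration of group
## assignments (no ties assumed)
bruteMannWhitneyP <- function(a, b) {
    pooled <- c(a, b)
    na <- length(a)
    U <- function(x, y) sum(outer(x, y, ">")) # ties absent
    u_obs <- U(a, b)
    m <- length(pooled)
    combs <- utils::combn(m, na)
    us <- apply(combs, 2, function(i) U(pooled[i], pooled[-i]))
    mu <- na * (m - na) / 2
    mean(abs(us - mu) >= abs(u_obs - mu))
}

## brute-force DHS-to-promoter assignment on 0-based coordinates
bruteAssign <- function(dhs_df, tss_df, flank = 1000) {
    out <- NULL
    for (i in seq_len(nrow(dhs_df))) {
        mid <- floor((dhs_df$start[i] + dhs_df$end[i]) / 2)
        for (j in seq_len(nrow(tss_df))) {
            if (dhs_df$chrom[i] == tss_df$chrom[j] &&
                mid >= tss_df$tss[j] - flank && mid < tss_df$tss[j] + flank)
                out <- rbind(out, data.frame(dhs_id = dhs_df$id[i],
                                             gene_id = tss_df$gene_id[j]))
        }
    }
    if (is.null(out)) return(data.frame(dhs_id = character(),
                                        gene_id = character()))
    out <- out[order(out$dhs_id, out$gene_id), ]
    rownames(out) <- NULL
    out
}

## direct (unvectorized) evaluation of the unsmoothed score, written
## independently of the package internals
bruteTsDnun <- function(A, B) {
    B_bins <- ncol(A)
    num <- den <- numeric(B_bins)
    for (b in seq_len(B_bins)) {
        num[b] <- (mean(A[, b]) - mean(B[, b]))^2
        den[b] <- var(A[, b]) / nrow(A) + var(B[, b]) / nrow(B)
    }
    eps <- 0.5 * median(den) + 1e-12
    mean(num / (den + eps))
}

## replicate x bin Poisson profile matrix
poisProfiles <- function(n_rep, rate) {
    t(vapply(seq_len(n_rep), function(i) rpois(length(rate), rate),
             numeric(length(rate))))
}

gaussBump <- function(B = 200, bin = 20, center = 2000, sd = 200, amp = 5,
                      bg = 0.5) {
    x <- (seq_len(B) - 0.5) * bin
    bg + amp * exp(-(x - center)^2 / (2 * sd^2))
}
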