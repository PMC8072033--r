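test_that("RPM normalization scales by library size", {
    counts <- array(0L, c(1, 2, 4))
    counts[1, 1, ] <- c(5L, 0L, 3L, 0L)
    counts[1, 2, ] <- c(5L, 0L, 3L, 0L)
    regions <- GRanges("chr1", IRanges(1, 80))
    names(regions) <- "r1"
    x <- DHSProfileSet(counts, regions, stage = c("A", "B"),
                       replicate = c(1, 1), library_size = c(1e6, 2e6),
                       bin_size = 20)
    rpm <- assay(normalizeRPM(x), "rpm")
    expect_equal(rpm[1, 1, ], c(5, 0, 3, 0))     # count 5 at 1e6 -> 5 RPM
    expect_equal(rpm[1, 2, ], c(2.5, 0, 1.5, 0)) # count 3 at 2e6 -> 1.5

    ## doubling counts and libraries leaves RPM unchanged
    x2 <- DHSProfileSet(counts * 2L, regions, c("A", "B"), c(1, 1),
                        c(2e6, 4e6), bin_size = 20)
    expect_equal(assay(normalizeRPM(x2), "rpm"), rpm)
    expect_error(DHSProfileSet(counts, regions, c("A", "B"), c(1, 1),
                               c(1e6, 0), 20), "positive")
})

test_that("the kernel smoother preserves constants and localizes spikes", {
    expect_equal(smoothProfile(rep(3.5, 50)), rep(3.5, 50))
    ## delta spike -> symmetric bump, mass conserved within edge effects
    y <- rep(0, 101); y[51] <- 1
    s <- smoothProfile(y, bandwidth_bp = 150, bin_size = 20)
    expect_equal(s[51 - 1:10], s[51 + 1:10], tolerance = 1e-9)
    expect_equal(which.max(s), 51L)
    expect_equal(sum(s), 1, tolerance = 1e-3)
    ## bandwidth -> 0 limit returns the input
    expect_equal(smoothProfile(y, bandwidth_bp = 1e-3, bin_size = 20), y)
    expect_error(smoothProfile(y, bandwidth_bp = 0), "bandwidth")
})

test_that("the unsmoothed score matches direct formula evaluation", {
    ## identical replicate sets -> 0
    A <- matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE)
    expect_equal(tsDnun(A, A), 0)

    ## hand case: 2 bins, 2 replicates, zero within-group variance
    A2 <- matrix(c(1, 3, 1, 3), 2, 2, byrow = TRUE)
    B2 <- matrix(1, 2, 2)
    ## means differ by (0, 2), all variances 0, so eps = 1e-12 and the
    ## score is (1/2) * (0 + 4 / 1e-12)
    expect_equal(tsDnun(A2, B2), 0.5 * 4 / 1e-12, tolerance = 1e-6)

    set.seed(5)
    for (i in 1:10) {
        A <- matrix(rpois(3 * 20, 2), 3, 20)
        B <- matrix(rpois(3 * 20, 3), 3, 20)
        expect_equal(tsDnun(A, B), bruteTsDnun(A, B))
        ## exchangeability
        expect_equal(tsDnun(A, B), tsDnun(B, A))
        expect_equal(tsKn(A, B), tsKn(B, A))
        ## joint scale behavior: scaling data by 2 scales means by 2 and
        ## variances by 4; the score recomputed from 2y must agree
        expect_equal(tsDnun(2 * A, 2 * B), bruteTsDnun(2 * A, 2 * B))
    }
    expect_error(tsDnun(A[1, , drop = FALSE], B), "2 replicates")
})

test_that("the smoothed score detects positional shifts and has the right limit", {
    set.seed(11)
    rateA <- gaussBump(center = 1850)
    rateB <- gaussBump(center = 2150)            # pure 300-bp shift
    A <- poisProfiles(3, rateA); B <- poisProfiles(3, rateB)
    expect_gt(tsKn(A, B), 0)
    expect_equal(tsKn(A, A), 0)
    ## bandwidth -> 0 recovers the unsmoothed score
    expect_equal(tsKn(A, B, bandwidth_bp = 1e-4), tsDnun(A, B),
                 tolerance = 1e-9)
})

test_that("permutation p-values follow the exhaustive conventions", {
    set.seed(2)
    ## 2 vs 2: C(4,2) = 6 assignments enumerated; the complement always
    ## ties with the identity so a strongly separated case attains 2/6
    A <- matrix(c(10, 12, 11, 13), 2, 2) + matrix(rnorm(4, 0, .1), 2, 2)
    B <- matrix(rnorm(4, 0, .1), 2, 2)
    pv <- permutationPvalue(A, B)
    expect_equal(pv$n_permutations, 6)
    expect_true(pv$exhaustive)
    expect_equal(pv$p_perm, 2 / 6)
    expect_gte(pv$p_perm, 1 / 6)

    ## identical pooled data -> every assignment ties -> p = 1
    C <- matrix(5, 2, 3)
    expect_equal(permutationPvalue(C, C)$p_perm, 1)
})

test_that("permutation p-values are uniform on null regions", {
    set.seed(303)
    p <- replicate(400, {
        Y <- matrix(rpois(6 * 60, 0.5), 6, 60)
        permutationPvalue(Y[1:3, ], Y[4:6, ])$p_perm
    })
    ## discrete support is multiples of 0.1 at 3v3; P(p <= 0.1) = 0.1
    expect_lt(abs(mean(p <= 0.1) - 0.10), 0.03)
    expect_gte(min(p), 0.1)
})

test_that("region-wise testing separates planted regions from nulls", {
    cfg <- simConfig(n_regions = 60, seed = 19)
    truth <- plantedTruth(cfg, c(low_I = 10, null = 50))
    x <- normalizeRPM(simulateDHSProfiles(cfg, truth))
    res <- diffAccessTest(x, "LSK", "DN1", seed = 1)
    expect_s4_class(res, "DataFrame")
    planted <- truth$true_class == "low_I"
    expect_true(all(res$p_value[planted] < 1e-6))
    expect_gt(min(res$p_value[!planted]), 1e-4)
    ## planted peaks appear in DN1, so the LSK - DN1 effect is negative
    expect_true(all(res$delta_mean_rpm[planted] < 0))
    ## both scores reported, non-negative
    expect_true(all(res$ts_kn >= 0 & res$ts_dnun >= 0))
    ## empirical p floor at 2/20 for a symmetric statistic
    expect_gte(min(res$p_perm), 0.1)
})

test_that("effective-number Bonferroni merges overlapping regions", {
    gr <- GRanges("chr1", IRanges(start = c(1, 2001, 9001, 20001, 30001),
                                  end = c(4000, 6000, 13000, 24000, 34000)))
    names(gr) <- paste0("r", 1:5)
    res <- S4Vectors::DataFrame(region_id = names(gr),
                                p_value = c(0.01, 0.20, 0.03, 0.04, 0.02),
                                p_adjusted = NA_real_)
    adj <- adjustEffectiveBonferroni(res, gr)
    ## r1 and r2 overlap -> 4 clusters; cluster p = 0.01
    expect_equal(S4Vectors::metadata(adj)$n_clusters, 4)
    expect_equal(adj$p_adjusted[1], 0.04)
    expect_equal(adj$p_adjusted[2], 0.04)
    expect_equal(adj$p_adjusted[3], 0.03 * 4)

    ## no overlaps: plain Bonferroni, never decreasing
    gr2 <- GRanges("chr1", IRanges(start = c(1, 5001, 10001, 15001, 20001),
                                   width = 4000))
    names(gr2) <- paste0("q", 1:5)
    res2 <- S4Vectors::DataFrame(region_id = names(gr2),
                                 p_value = rep(0.01, 5),
                                 p_adjusted = NA_real_)
    adj2 <- adjustEffectiveBonferroni(res2, gr2)
    expect_equal(adj2$p_adjusted, rep(0.05, 5))
    expect_true(all(adj2$p_adjusted >= adj2$p_value))

    ## single region: p unchanged
    adj3 <- adjustEffectiveBonferroni(res2[1, ], gr2[1])
    expect_equal(adj3$p_adjusted, 0.01)

    ## order invariance
    perm <- c(3, 1, 5, 2, 4)
    adj4 <- adjustEffectiveBonferroni(res[perm, ], gr)
    expect_equal(adj4$p_adjusted, adj$p_adjusted[perm])
})

test_that("accessibility calls work from hotspots or the RPM threshold", {
    cfg <- simConfig(n_regions = 40, seed = 23)
    truth <- plantedTruth(cfg, c(high = 10, null = 30))
    x <- normalizeRPM(simulateDHSProfiles(cfg, truth))
    calls <- as.data.frame(callAccessibility(x))
    dn2b <- calls[calls$stage == "DN2b", ]
    planted <- truth$true_class == "high"
    expect_true(all(dn2b$accessible[planted]))      # peaks called open
    expect_true(all(!dn2b$accessible[!planted]))    # background closed
    lsk <- calls[calls$stage == "LSK", ]
    expect_true(all(!lsk$accessible))               # nothing open in LSK
    expect_true(all(calls$source == "threshold"))

    ## hotspot-BED mode: membership by midpoint
    hs <- rowRanges(x)[planted]
    calls2 <- as.data.frame(callAccessibility(
        x, hotspots = stats::setNames(rep(list(hs), 5),
                                      unique(sampleStages(x)))))
    dn2b2 <- calls2[calls2$stage == "DN2b", ]
    expect_equal(dn2b2$accessible, planted)
    expect_true(all(calls2$source == "hotspot_bed"))
})

test_that("planted peaks are called accessible under the default threshold", {
    cfg <- simConfig(n_regions = 500, seed = 29)
    truth <- plantedTruth(cfg, c(low_I = 100, null = 400))
    x <- normalizeRPM(simulateDHSProfiles(cfg, truth))
    calls <- as.data.frame(callAccessibility(x))
    dn1 <- calls[calls$stage == "DN1", ]
    hit <- mean(dn1$accessible[truth$true_class == "low_I"])
    expect_gte(hit, 0.99)
})
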