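## Synthetic-data generator: Poisson cut-count profiles over DHS windows,
## negative-binomial expression with planted log2FC, and promoter sequences
## with a tunable CpG observed/expected ratio. Ground truth is carried along
## so every downstream stage can be scored against what was planted.

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generator. Defaults mirror the study
#' conditions the pipeline targets: five conditions (LSK, DN1, DN2a, DN2b and
#' a no-Notch control), 4-kb DHS windows in 20-bp bins, 3 replicates per
#' stage, a per-bin Poisson background of 0.5 cuts with planted peaks at 10x
#' background amplitude, negative-binomial expression with a planted log2
#' fold-change of 3, and promoter CpG observed/expected targets of 0.43 for
#' high-dose genes versus 0.60 for low-dose genes (0.90 elsewhere).
#'
#' @param n_regions number of DHS windows.
#' @param region_length window width in bp; must be divisible by `bin_size`.
#' @param bin_size bin width in bp.
#' @param stages ordered condition labels.
#' @param replicates_per_stage DNase replicates per stage (2-4).
#' @param rna_replicates RNA replicates per stage (2-4).
#' @param library_sizes mapped reads per DNase sample; scalar recycled.
#' @param reference_library library size at which `background_rate` and
#'   `peak_amplitude` are expressed.
#' @param background_rate expected background cuts per bin.
#' @param peak_amplitude expected extra cuts per bin at the peak apex.
#' @param peak_width_sd Gaussian peak SD in bp.
#' @param shift_bp positional offset used by shift alternatives.
#' @param nb_dispersion negative-binomial dispersion of RNA counts (> 0).
#' @param planted_log2fc expression effect size planted for responsive genes.
#' @param rna_baseline baseline expression mean (counts).
#' @param rna_background_genes unlinked stage-flat filler genes added to the
#'   count matrix so planted effects are a realistically small fraction of
#'   each library (real stage transcriptomes have ~10k expressed genes; with
#'   only the DHS-linked genes, planted fold-changes would distort the
#'   per-sample totals and bias CPM fold-changes downward).
#' @param rna_mean_sdlog log-normal spread of background gene means.
#' @param target_cpg_oe named numeric: promoter CpG observed/expected targets
#'   for the `low`, `high` and `other` gene groups.
#' @param gc_content promoter GC fraction.
#' @param seed master seed; child streams for profiles, RNA and promoters are
#'   derived from it deterministically.
#' @return A `SimConfig` list.
#' @examples
#' cfg <- simConfig(n_regions = 10, seed = 42)
#' @export
simConfig <- function(n_regions = 60,
                      region_length = 4000,
                      bin_size = 20,
                      stages = c("LSK", "DN1", "DN2a", "DN2b", "ctrl"),
                      replicates_per_stage = 3,
                      rna_replicates = 3,
                      library_sizes = 1e6,
                      reference_library = 1e6,
                      background_rate = 0.5,
                      peak_amplitude = 5,
                      peak_width_sd = 200,
                      shift_bp = 300,
                      nb_dispersion = 0.1,
                      planted_log2fc = 3,
                      rna_baseline = 100,
                      rna_background_genes = 5000,
                      rna_mean_sdlog = 1,
                      target_cpg_oe = c(low = 0.60, high = 0.43, other = 0.90),
                      gc_content = 0.5,
                      seed = 1) {
    if (region_length %% bin_size != 0)
        stop("region_length must be divisible by bin_size")
    if (replicates_per_stage < 2 || rna_replicates < 2)
        stop("at least 2 replicates per stage are required")
    if (any(library_sizes <= 0))
        stop("library sizes must be positive")
    if (nb_dispersion <= 0)
        stop("nb_dispersion must be > 0")
    if (background_rate < 0 || peak_amplitude < 0 || peak_width_sd <= 0)
        stop("rates must be non-negative and peak_width_sd positive")
    if (any(target_cpg_oe < 0) || any(target_cpg_oe > 2))
        stop("target_cpg_oe must lie in [0, 2]")
    if (gc_content <= 0 || gc_content >= 1)
        stop("gc_content must lie in (0, 1)")
    if (!all(c("low", "high", "other") %in% names(target_cpg_oe)))
        stop("target_cpg_oe needs entries named 'low', 'high', 'other'")
    structure(list(n_regions = n_regions, region_length = region_length,
                   bin_size = bin_size, stages = stages,
                   replicates_per_stage = replicates_per_stage,
                   rna_replicates = rna_replicates,
                   library_sizes = library_sizes,
                   reference_library = reference_library,
                   background_rate = background_rate,
                   peak_amplitude = peak_amplitude,
                   peak_width_sd = peak_width_sd, shift_bp = shift_bp,
                   nb_dispersion = nb_dispersion,
                   planted_log2fc = planted_log2fc,
                   rna_baseline = rna_baseline,
                   rna_background_genes = rna_background_genes,
                   rna_mean_sdlog = rna_mean_sdlog,
                   target_cpg_oe = target_cpg_oe, gc_content = gc_content,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

## child RNG streams derived from the master seed, kept below 2^31
.childSeed <- function(config, offset)
    as.integer((as.numeric(config$seed) * 97 + offset) %% .Machine$integer.max)

#' Planted ground truth
#'
#' Lays out `n_regions` disjoint 4-kb DHS windows on a synthetic chromosome
#' (10-kb spacing), one gene per region with its TSS at the window midpoint,
#' and assigns each gene a true dose-response class that fixes its per-stage
#' peak amplitude/center, its planted expression fold-changes and its promoter
#' CpG target:
#' \describe{
#'   \item{null}{no peak anywhere, flat expression.}
#'   \item{low_I}{peak appears de novo in DN1 (absent in LSK/ctrl); low gate
#'     expression (DN1 and later stages up by `planted_log2fc`).}
#'   \item{low_II}{peak already present in LSK at `peak_amplitude`, doubled
#'     in height from DN1 on; low gate expression.}
#'   \item{high}{peak appears de novo in DN2b only; high gate expression
#'     (DN2b up by `planted_log2fc` over both ctrl and DN1).}
#'   \item{shift_only}{same peak in all stages but its center moves by
#'     `shift_bp` from DN1 on; flat expression.}
#'   \item{height_only}{peak doubles in height from DN1 on; flat expression.}
#' }
#'
#' @param config a [simConfig()] object.
#' @param n_per_class named integer vector over the classes above; classes not
#'   named get 0. The total overrides `config$n_regions`.
#' @return data.frame with one row per region/gene: coordinates, TSS,
#'   `true_class`, per-stage amplitude (`amp_<stage>`), center
#'   (`center_<stage>`) and accessibility flag (`acc_<stage>`), planted
#'   expression multipliers (`expr_<stage>`) and `cpg_target`.
#' @export
plantedTruth <- function(config, n_per_class = c(null = config$n_regions)) {
    classes <- c("null", "low_I", "low_II", "high", "shift_only", "height_only")
    bad <- setdiff(names(n_per_class), classes)
    if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
    cls <- rep(names(n_per_class), n_per_class)
    n <- length(cls)
    L <- config$region_length
    spacing <- max(10000, 2 * L)
    start0 <- (seq_len(n) - 1) * spacing          # 0-based starts
    mid <- L / 2
    amp <- config$peak_amplitude
    shift <- config$shift_bp
    lfc <- config$planted_log2fc
    stg <- config$stages

    truth <- data.frame(
        region_id = sprintf("region%04d", seq_len(n)),
        gene_id = sprintf("gene%04d", seq_len(n)),
        true_class = cls,
        chrom = "chrS1",
        start = start0,
        end = start0 + L,
        tss = start0 + L / 2,
        strand = rep(c("+", "-"), length.out = n),
        stringsAsFactors = FALSE)

    ampFor <- function(class, stage) {
        early <- stage %in% c("LSK", "ctrl")
        switch(class,
               null = 0,
               low_I = if (early) 0 else amp,
               low_II = if (early) amp else 2 * amp,
               high = if (stage == "DN2b") amp else 0,
               shift_only = amp,
               height_only = if (early) amp else 2 * amp)
    }
    ctrFor <- function(class, stage) {
        if (class == "shift_only" && !(stage %in% c("LSK", "ctrl")))
            mid + shift else mid
    }
    exprFor <- function(class, stage) {
        up <- 2^lfc
        switch(class,
               low_I = ,
               low_II = if (stage %in% c("DN1", "DN2a", "DN2b")) up else 1,
               high = if (stage %in% c("DN2a", "DN2b")) up else 1,
               1)
    }
    for (s in stg) {
        truth[[paste0("amp_", s)]] <- vapply(cls, ampFor, 0, stage = s)
        truth[[paste0("center_", s)]] <- vapply(cls, ctrFor, 0, stage = s)
        truth[[paste0("acc_", s)]] <- truth[[paste0("amp_", s)]] > 0
    }
    for (s in setdiff(stg, "LSK"))
        truth[[paste0("expr_", s)]] <- vapply(cls, exprFor, 0, stage = s)
    oe <- config$target_cpg_oe
    truth$cpg_target <- unname(
        oe[ifelse(cls %in% c("low_I", "low_II"), "low",
                  ifelse(cls == "high", "high", "other"))])
    truth
}

## expected cuts per bin for one region in one stage (reference library scale)
.rateProfile <- function(config, amp, center) {
    x <- (seq_len(config$region_length / config$bin_size) - 0.5) *
        config$bin_size
    config$background_rate +
        amp * exp(-(x - center)^2 / (2 * config$peak_width_sd^2))
}

#' Simulate binned DNase cut-count profiles
#'
#' Draws per-bin integer counts as Poisson with rate
#' `(background + amplitude * Gaussian bump(center, peak_width_sd))`, scaled
#' by `library_size / reference_library`. Null regions have identical rate
#' functions in every stage.
#'
#' @param config a [simConfig()] object.
#' @param truth a [plantedTruth()] table (one row per region).
#' @return A [DHSProfileSet-class].
#' @export
simulateDHSProfiles <- function(config, truth) {
    if (any(config$library_sizes <= 0))
        stop("library sizes must be positive")
    stg <- config$stages
    reps <- config$replicates_per_stage
    n_samp <- length(stg) * reps
    libs <- rep_len(config$library_sizes, n_samp)
    stage <- rep(stg, each = reps)
    replicate <- rep(seq_len(reps), times = length(stg))
    sample_id <- paste(stage, replicate, sep = "_")
    B <- config$region_length / config$bin_size
    n <- nrow(truth)

    set.seed(.childSeed(config, 101))
    counts <- array(0L, dim = c(n, n_samp, B),
                    dimnames = list(truth$region_id, sample_id, NULL))
    for (j in seq_len(n_samp)) {
        s <- stage[j]
        sc <- libs[j] / config$reference_library
        for (i in seq_len(n)) {
            rate <- .rateProfile(config, truth[[paste0("amp_", s)]][i],
                                 truth[[paste0("center_", s)]][i]) * sc
            counts[i, j, ] <- stats::rpois(B, rate)
        }
    }
    regions <- GRanges(truth$chrom,
                       IRanges(start = truth$start + 1L, end = truth$end),
                       region_id = truth$region_id)
    names(regions) <- truth$region_id
    DHSProfileSet(counts, regions, stage, replicate, libs,
                  bin_size = config$bin_size)
}

#' Simulate RNA-seq gene counts
#'
#' Negative-binomial counts with stage-dependent means
#' `rna_baseline * expr_<stage>` so planted genes meet (and null genes fail)
#' the log2 fold-change gates in expectation. RNA stages are DN1, DN2a, DN2b
#' and the no-Notch control (`ctrl`). On top of the truth-linked genes,
#' `rna_background_genes` stage-flat genes with log-normally spread baseline
#' means emulate the rest of the transcriptome, so library totals (and hence
#' CPM fold-changes) are not distorted by the planted effects.
#'
#' @inheritParams simulateDHSProfiles
#' @return list with `counts` (gene x sample integer matrix) and `samples`
#'   (data.frame: sample, stage, replicate).
#' @export
simulateRNACounts <- function(config, truth) {
    if (config$nb_dispersion <= 0)
        stop("nb_dispersion must be > 0")
    stg <- intersect(c("DN1", "DN2a", "DN2b", "ctrl"), config$stages)
    reps <- config$rna_replicates
    stage <- rep(stg, each = reps)
    replicate <- rep(seq_len(reps), times = length(stg))
    sample_id <- paste("rna", stage, replicate, sep = "_")
    n <- nrow(truth)
    nbg <- config$rna_background_genes
    set.seed(.childSeed(config, 202))
    bg_mu <- stats::rlnorm(nbg, meanlog = log(config$rna_baseline),
                           sdlog = config$rna_mean_sdlog)
    gene_id <- c(truth$gene_id,
                 if (nbg) sprintf("bg%05d", seq_len(nbg)))
    counts <- matrix(0L, n + nbg, length(sample_id),
                     dimnames = list(gene_id, sample_id))
    size <- 1 / config$nb_dispersion
    for (j in seq_along(sample_id)) {
        mu <- c(config$rna_baseline * truth[[paste0("expr_", stage[j])]],
                bg_mu)
        counts[, j] <- stats::rnbinom(n + nbg, mu = mu, size = size)
    }
    list(counts = counts,
         samples = data.frame(sample = sample_id, stage = stage,
                              replicate = replicate,
                              stringsAsFactors = FALSE))
}

## first-order transition matrix with stationary base composition pi
## (pC = pG = gc/2) and stationary CpG observed/expected ratio = target.
.cpgTransitionMatrix <- function(target, gc) {
    base <- c("A", "C", "G", "T")
    pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    names(pi) <- base
    piC <- pi[["C"]]; piG <- pi[["G"]]
    cC <- (1 - target * piG) / (1 - piG)       # row C, non-G scaling
    g <- 1 + piC * (1 - target) / (1 - piC)    # non-C rows, G scaling
    ci <- (1 - g * piG) / (1 - piG)            # non-C rows, non-G scaling
    if (target * piG > 1 || g * piG > 1 || cC < 0 || ci < 0)
        stop("target_cpg_oe ", target, " is incompatible with gc_content ", gc)
    Tm <- matrix(0, 4, 4, dimnames = list(base, base))
    for (b in base) {
        if (b == "C") {
            Tm[b, ] <- pi * cC
            Tm[b, "G"] <- target * piG
        } else {
            Tm[b, ] <- pi * ci
            Tm[b, "G"] <- g * piG
        }
    }
    Tm
}

## vectorized Markov sampling: n sequences of length L
.sampleMarkov <- function(n, L, Tm, pi) {
    cum <- t(apply(Tm, 1, cumsum))
    S <- matrix(1L, n, L)
    S[, 1] <- findInterval(stats::runif(n), cumsum(pi),
                           rightmost.closed = TRUE) + 1L
    for (j in seq_len(L)[-1]) {
        u <- stats::runif(n)
        prev <- S[, j - 1]
        S[, j] <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2]) +
            (u > cum[prev, 3])
    }
    S
}

#' Simulate 2-kb promoter sequences with tunable CpG content
#'
#' Generates one promoter per gene from a first-order dinucleotide Markov
#' chain whose stationary base composition matches `gc_content` and whose
#' stationary CpG observed/expected ratio matches the gene's `cpg_target`
#' (taken from the planted truth).
#'
#' @inheritParams simulateDHSProfiles
#' @param window promoter width in bp (default 2000; TSS +/- 1 kb).
#' @return list with `sequences` (named [Biostrings::DNAStringSet]),
#'   `tss` (data.frame gene_id/chrom/tss/strand) and `achieved_oe` (the
#'   realized observed/expected ratio per promoter).
#' @export
simulatePromoters <- function(config, truth, window = 2000) {
    base <- c("A", "C", "G", "T")
    gc <- config$gc_content
    pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    set.seed(.childSeed(config, 303))
    seqs <- character(nrow(truth))
    for (tgt in unique(truth$cpg_target)) {
        Tm <- .cpgTransitionMatrix(tgt, gc)
        idx <- which(truth$cpg_target == tgt)
        S <- .sampleMarkov(length(idx), window, Tm, pi)
        seqs[idx] <- apply(S, 1, function(r) paste(base[r], collapse = ""))
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- truth$gene_id
    res <- oeCpG(dna)
    list(sequences = dna,
         tss = data.frame(gene_id = truth$gene_id, chrom = truth$chrom,
                          tss = truth$tss, strand = truth$strand,
                          stringsAsFactors = FALSE),
         achieved_oe = stats::setNames(res$oe_ratio, truth$gene_id))
}

#' Simulate a complete linked dataset
#'
#' Convenience wrapper producing profiles, RNA counts and promoters from one
#' truth table (one promoter DHS per gene).
#'
#' @inheritParams plantedTruth
#' @return list with `config`, `truth`, `profiles`, `rna`, `promoters`.
#' @export
simulateDataset <- function(config, n_per_class = c(null = config$n_regions)) {
    truth <- plantedTruth(config, n_per_class)
    list(config = config,
         truth = truth,
         profiles = simulateDHSProfiles(config, truth),
         rna = simulateRNACounts(config, truth),
         promoters = simulatePromoters(config, truth))
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Writes `regions.bed`, one bedGraph of binned counts per DNase sample
#' (zero bins omitted), `promoters.fa`, `tss.tsv`, `rna_counts.tsv`,
#' `rna_samples.tsv`, `dnase_samples.tsv`, `truth.tsv` and `config.yaml`.
#' Everything round-trips losslessly through [readFixtures()].
#'
#' @param dataset a [simulateDataset()] bundle.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeFixtures <- function(dataset, out_dir) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", out_dir)
    x <- dataset$profiles
    files <- character()
    wtsv <- function(df, name) {
        p <- file.path(out_dir, name)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        p
    }
    ## regions
    bedp <- file.path(out_dir, "regions.bed")
    writeBed(rowRanges(x), bedp)
    files <- c(files, bedp)
    ## per-sample bedGraphs of binned counts
    a <- assay(x, "counts")
    bs <- binSize(x)
    st0 <- GenomicRanges::start(rowRanges(x)) - 1L
    chrom <- as.character(GenomicRanges::seqnames(rowRanges(x)))
    for (j in seq_len(ncol(x))) {
        p <- file.path(out_dir, paste0(colnames(x)[j], ".bedGraph"))
        con <- file(p, "w")
        writeLines(paste0("track type=bedGraph name=", colnames(x)[j]), con)
        for (i in seq_len(nrow(x))) {
            v <- a[i, j, ]
            nz <- which(v != 0)
            if (length(nz))
                writeLines(sprintf("%s\t%d\t%d\t%g", chrom[i],
                                   st0[i] + (nz - 1L) * bs,
                                   st0[i] + nz * bs, v[nz]), con)
        }
        close(con)
        files <- c(files, p)
    }
    files <- c(files,
               wtsv(data.frame(sample = colnames(x),
                               stage = sampleStages(x),
                               replicate = colData(x)$replicate,
                               library_size = librarySizes(x)),
                    "dnase_samples.tsv"),
               wtsv(cbind(gene_id = rownames(dataset$rna$counts),
                          as.data.frame(dataset$rna$counts)),
                    "rna_counts.tsv"),
               wtsv(dataset$rna$samples, "rna_samples.tsv"),
               wtsv(dataset$promoters$tss, "tss.tsv"),
               wtsv(dataset$truth, "truth.tsv"))
    fap <- file.path(out_dir, "promoters.fa")
    Biostrings::writeXStringSet(dataset$promoters$sequences, fap)
    files <- c(files, fap)
    cfgp <- file.path(out_dir, "config.yaml")
    cfg_out <- lapply(unclass(dataset$config), unclass)
    ## yaml drops names of atomic vectors; keep the per-group map
    cfg_out$target_cpg_oe <- as.list(cfg_out$target_cpg_oe)
    yaml::write_yaml(cfg_out, cfgp)
    files <- c(files, cfgp)
    invisible(files)
}

#' Read back a fixture directory written by [writeFixtures()]
#'
#' @param dir fixture directory.
#' @return list with `config`, `truth`, `profiles`, `rna`, `promoters`
#'   mirroring [simulateDataset()] output.
#' @export
readFixtures <- function(dir) {
    cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
    cfg_raw$target_cpg_oe <- unlist(cfg_raw$target_cpg_oe)
    config <- do.call(simConfig, cfg_raw)
    regions <- readBed(file.path(dir, "regions.bed"))
    samp <- utils::read.delim(file.path(dir, "dnase_samples.tsv"))
    paths <- stats::setNames(file.path(dir, paste0(samp$sample, ".bedGraph")),
                             samp$sample)
    counts <- readBedGraphMatrix(paths, regions, config$bin_size)
    profiles <- DHSProfileSet(counts, regions, samp$stage, samp$replicate,
                              samp$library_size, bin_size = config$bin_size)
    rna_tab <- utils::read.delim(file.path(dir, "rna_counts.tsv"),
                                 check.names = FALSE)
    rna_counts <- as.matrix(rna_tab[, -1, drop = FALSE])
    rownames(rna_counts) <- rna_tab$gene_id
    storage.mode(rna_counts) <- "integer"
    seqs <- readPromoterFasta(file.path(dir, "promoters.fa"))
    list(config = config,
         truth = utils::read.delim(file.path(dir, "truth.tsv")),
         profiles = profiles,
         rna = list(counts = rna_counts,
                    samples = utils::read.delim(
                        file.path(dir, "rna_samples.tsv"))),
         promoters = list(sequences = seqs,
                          tss = utils::read.delim(file.path(dir, "tss.tsv")),
                          achieved_oe = stats::setNames(
                              oeCpG(seqs)$oe_ratio, names(seqs))))
}
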