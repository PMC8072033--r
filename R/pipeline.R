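## End-to-end orchestration: simulate (or load) -> RPM normalization ->
## accessibility calls -> differential tests for the LSK~DN1 and DN1~DN2b
## transitions -> effective-number Bonferroni -> expression filter + gates ->
## DHS-to-promoter assignment -> dose-response classification -> promoter
## CpG comparison. Every stage output is a plain TSV/JSON so intermediates
## are diffable and individually re-consumable.

#' Pipeline configuration
#'
#' Bundles every pipeline threshold with its default: `alpha` 0.05,
#' `log2fc_threshold` 2, `min_cpm` 1, `min_samples` 2, `window` 2000 bp,
#' `bandwidth` 150 bp, `max_perms` 10000, statistic `"dnun"`.
#'
#' @param sim a [simConfig()] for simulate-mode input.
#' @param n_per_class planted class sizes (see [plantedTruth()]).
#' @param alpha adjusted-p significance threshold.
#' @param log2fc_threshold expression gate cutoff.
#' @param min_cpm,min_samples CPM filter parameters.
#' @param window promoter window width in bp.
#' @param bandwidth kernel SD in bp for the kn score.
#' @param max_perms permutation enumeration cutoff.
#' @param statistic `"dnun"` or `"kn"`.
#' @param out_dir optional directory for stage outputs and the manifest.
#' @param seed pipeline seed (defaults to the simulation seed).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           n_per_class = c(low_I = 20, low_II = 20,
                                           high = 20, null = 440),
                           alpha = 0.05, log2fc_threshold = 2,
                           min_cpm = 1, min_samples = 2, window = 2000,
                           bandwidth = 150, max_perms = 10000,
                           statistic = c("dnun", "kn"), out_dir = NULL,
                           seed = sim$seed) {
    structure(list(sim = sim, n_per_class = n_per_class, alpha = alpha,
                   log2fc_threshold = log2fc_threshold, min_cpm = min_cpm,
                   min_samples = min_samples, window = window,
                   bandwidth = bandwidth, max_perms = max_perms,
                   statistic = match.arg(statistic), out_dir = out_dir,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

.writeStage <- function(obj, name, out_dir, manifest) {
    if (is.null(out_dir)) return(manifest)
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(obj), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs[[name]] <- list(file = basename(p),
                                     rows = nrow(as.data.frame(obj)))
    manifest
}

#' Run the discovery pipeline end to end
#'
#' @param config a [pipelineConfig()].
#' @param dataset optional pre-built [simulateDataset()] bundle (for restarts
#'   and fixture-driven runs); simulated from `config$sim` when absent.
#' @return result bundle: `dataset`, `calls`, `diff_lsk_dn1`,
#'   `diff_dn1_dn2b`, `lfc`, `gates`, `mapping`, `classifications`,
#'   `summary`, `cpg`, `comparison`, `manifest`, `config`.
#' @export
runPipeline <- function(config, dataset = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (is.null(dataset)) {
        config$sim$seed <- config$seed
        dataset <- simulateDataset(config$sim, config$n_per_class)
    }
    out_dir <- config$out_dir
    if (!is.null(out_dir) && !dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("stage 'setup': cannot create ", out_dir)
    manifest <- list(seed = config$seed,
                     config = unclass(config)[setdiff(names(config),
                                                      c("sim", "out_dir"))],
                     sim_config = lapply(unclass(config$sim), unclass),
                     counts = list(), outputs = list())
    x <- normalizeRPM(dataset$profiles)
    manifest$counts$regions <- nrow(x)
    manifest$counts$dnase_samples <- ncol(x)

    calls <- callAccessibility(x)
    manifest <- .writeStage(calls, "accessibility_calls", out_dir, manifest)

    regions <- rowRanges(x)
    diff1 <- diffAccessTest(x, "LSK", "DN1", statistic = config$statistic,
                            bandwidth_bp = config$bandwidth,
                            max_perms = config$max_perms,
                            seed = .childSeed(config$sim, 401))
    diff1 <- adjustEffectiveBonferroni(diff1, regions)
    diff2 <- diffAccessTest(x, "DN1", "DN2b", statistic = config$statistic,
                            bandwidth_bp = config$bandwidth,
                            max_perms = config$max_perms,
                            seed = .childSeed(config$sim, 402))
    diff2 <- adjustEffectiveBonferroni(diff2, regions)
    manifest <- .writeStage(diff1, "diff_LSK_DN1", out_dir, manifest)
    manifest <- .writeStage(diff2, "diff_DN1_DN2b", out_dir, manifest)

    counts <- cpmFilter(dataset$rna$counts, dataset$rna$samples,
                        min_cpm = config$min_cpm,
                        min_samples = config$min_samples)
    manifest$counts$genes_prefilter <- nrow(dataset$rna$counts)
    manifest$counts$genes_postfilter <- nrow(counts)
    lfc <- log2fcTable(counts, dataset$rna$samples)
    gates <- data.frame(
        gene_id = lfc$gene_id,
        low = unname(expressionGate(lfc, "low", config$log2fc_threshold)),
        high = unname(expressionGate(lfc, "high", config$log2fc_threshold)))
    ## genes dropped by the CPM filter fail every gate
    dropped <- setdiff(rownames(dataset$rna$counts), gates$gene_id)
    if (length(dropped))
        gates <- rbind(gates, data.frame(gene_id = dropped, low = FALSE,
                                         high = FALSE))
    manifest <- .writeStage(lfc, "log2fc", out_dir, manifest)

    promoters <- promoterWindows(dataset$promoters$tss,
                                 flank = config$window / 2)
    mapping <- assignDhsToPromoters(regions, promoters)
    manifest$counts$promoter_dhs_pairs <- nrow(mapping)

    cls <- classifyPromoters(calls, diff1, diff2, gates, mapping,
                             alpha = config$alpha)
    manifest <- .writeStage(cls, "classifications", out_dir, manifest)
    summ <- summarizeClasses(cls)
    manifest$counts$class_sizes <- as.list(summ$sizes)

    cpg <- oeCpG(dataset$promoters$sequences)
    manifest <- .writeStage(cpg, "cpg", out_dir, manifest)
    df <- as.data.frame(cls)
    gene_class <- stats::setNames(df$dose_class, df$gene_id)
    low_genes <- union(summ$class_genes$low_I, summ$class_genes$low_II)
    high_genes <- summ$class_genes$high
    cpg_df <- as.data.frame(cpg)
    comparison <- NULL
    if (length(low_genes) && length(high_genes)) {
        comparison <- mannWhitneyCpG(
            cpg_df$oe_ratio[cpg_df$gene_id %in% high_genes],
            cpg_df$oe_ratio[cpg_df$gene_id %in% low_genes])
    }
    bundle <- list(dataset = dataset, calls = calls, diff_lsk_dn1 = diff1,
                   diff_dn1_dn2b = diff2, lfc = lfc, gates = gates,
                   mapping = mapping, classifications = cls, summary = summ,
                   cpg = cpg, comparison = comparison, manifest = manifest,
                   config = config)
    if (!is.null(out_dir)) {
        yaml::write_yaml(manifest$config, file.path(out_dir,
                                                    "effective_config.yaml"))
        jsonlite::write_json(makeReport(bundle),
                             file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    bundle
}

#' Summary report of a pipeline run
#'
#' Class sizes and overlaps, per-class promoter CpG means, the Mann-Whitney
#' comparison of high- versus low-dose promoters (omitted, with a note, when
#' a class is empty), and the effective configuration.
#'
#' @param bundle a [runPipeline()] result.
#' @return a nested list, JSON-ready.
#' @export
makeReport <- function(bundle) {
    summ <- bundle$summary
    cpg_df <- as.data.frame(bundle$cpg)
    low_genes <- union(summ$class_genes$low_I, summ$class_genes$low_II)
    high_genes <- summ$class_genes$high
    grp <- function(g) {
        v <- cpg_df$oe_ratio[cpg_df$gene_id %in% g]
        v <- v[!is.na(v)]
        if (length(v)) list(n = length(v), mean = mean(v),
                            median = stats::median(v)) else NULL
    }
    rep <- list(class_sizes = as.list(summ$sizes),
                n_unique_low = summ$n_unique_low,
                n_unique_high = summ$n_unique_high,
                overlaps = summ$overlaps,
                cpg = list(low = grp(low_genes), high = grp(high_genes)),
                config = bundle$manifest$config)
    if (is.null(bundle$comparison)) {
        rep$note <- "empty dose class; Mann-Whitney comparison omitted"
    } else {
        rep$mann_whitney <- list(U = bundle$comparison$U,
                                 p = bundle$comparison$p,
                                 n_high = bundle$comparison$n_a,
                                 n_low = bundle$comparison$n_b)
    }
    rep
}
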