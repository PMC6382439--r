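## End-to-end pipeline over the synthetic dataset: reproducible staged runs
## with a flat configuration, TSV/JSON artifacts and a machine-readable
## manifest. A thin command-line wrapper lives in inst/scripts/pipeline.R.

.PIPELINE_DEFAULTS <- list(
    seed = 1L,
    ## simulator
    n_cells_per_group = 150, n_switch_genes = 40, n_flat_genes = 80,
    n_marker_genes_per_group = 8, n_cellcycle_genes = 0,
    n_background_genes = 40, nb_dispersion = 0.5,
    library_size_log_mean = log(5000), library_size_log_sd = 0.3,
    dropout_extra = 0,
    doublet_rate = 0.05, gd_rate = 0.05, no_tcr_rate = 0.05,
    ## QC thresholds (the conventional droplet-data values)
    umi_min = 1000, umi_max = 15000, genes_min = 700, genes_max = 3500,
    ## markers / DE
    min_frac = 0.05, logfc_min = 0.25, alpha = 0.05,
    ## label transfer
    l1_strength = 1,
    ## trajectory
    q_latent = 6, gplvm_maxit = 300, n_variable_genes = 50,
    tissue_include = NULL, nlt_tissues = "NLT",
    ## switch kinetics
    min_cells = 30, min_abs_corr = 0.25, q_max = 0.05,
    ## cross-species demo
    n_orthologs = 300, n_paralog_swaps = 5)

#' Build a validated pipeline configuration
#'
#' Starts from the defaults (QC and testing thresholds at their
#' conventional values; simulator sizes at a desk-scale demonstration
#' setting) and applies overrides. Unknown keys are rejected.
#'
#' @param ... named overrides of the default keys.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
    over <- list(...)
    if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
        stop("all configuration entries must be named")
    }
    unknown <- setdiff(names(over), names(.PIPELINE_DEFAULTS))
    if (length(unknown)) {
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- .PIPELINE_DEFAULTS
    cfg[names(over)] <- over
    cfg$seed <- as.integer(cfg$seed)
    if (cfg$umi_min >= cfg$umi_max || cfg$genes_min >= cfg$genes_max) {
        stop("invalid thresholds: lower bounds must be below upper bounds")
    }
    cfg
}

.pipeSimConfig <- function(cfg) {
    simConfig(n_cells_per_group = cfg$n_cells_per_group,
              n_switch_genes = cfg$n_switch_genes,
              n_flat_genes = cfg$n_flat_genes,
              n_marker_genes_per_group = cfg$n_marker_genes_per_group,
              n_cellcycle_genes = cfg$n_cellcycle_genes,
              n_background_genes = cfg$n_background_genes,
              nb_dispersion = cfg$nb_dispersion,
              library_size_log_mean = cfg$library_size_log_mean,
              library_size_log_sd = cfg$library_size_log_sd,
              dropout_extra = cfg$dropout_extra,
              seed = cfg$seed)
}

#' Run pipeline stages on the bundled synthetic dataset
#'
#' Stages: `simulate` (counts + TCR + truth), `qc` (count and TCR filters,
#' normalisation), `markers` (cluster markers and NLT/LT signature score),
#' `transfer` (label-transfer demonstration on held-out cells),
#' `trajectory` (variable genes, GPLVM, adaptation-LV selection),
#' `kinetics` (switch-gene fits along the adaptation LV), `ordering`
#' (program activation times over the planted early/mid/late programs),
#' `xspecies` (cross-species marker comparison demo), or `all`. Each stage
#' writes TSV/JSON artifacts under `outdir` and depends on its upstream
#' stage's artifacts; a manifest records package version, seed and artifact
#' checksums.
#'
#' @param stage one of the stage names above.
#' @param config from [pipelineConfig()].
#' @param outdir output directory.
#' @return named list of the stage's main in-memory results, invisibly.
#' @export
runPipeline <- function(stage = c("all", "simulate", "qc", "markers",
                                  "transfer", "trajectory", "kinetics",
                                  "ordering", "xspecies"),
                        config = pipelineConfig(), outdir = tempfile()) {
    stage <- match.arg(stage)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stages <- if (stage == "all") {
        c("simulate", "qc", "markers", "transfer", "trajectory",
          "kinetics", "ordering", "xspecies")
    } else stage
    res <- list()
    for (s in stages) res <- .runStage(s, config, outdir, res)
    .writeManifest(config, outdir)
    invisible(res)
}

.need <- function(path, producer) {
    if (!file.exists(path)) {
        stop("missing upstream artifact '", basename(path),
             "'; run the '", producer, "' stage first")
    }
    path
}

.runStage <- function(s, cfg, outdir, res) {
    if (s == "simulate") {
        sce <- simulateTrajectoryDataset(.pipeSimConfig(cfg))
        tcr <- simulateTCRTable(sce, cfg$doublet_rate, cfg$gd_rate,
                                cfg$no_tcr_rate, seed = cfg$seed + 1)
        writeCounts10x(sce, file.path(outdir, "sim"))
        .writeTSV(geneTruth(sce), file.path(outdir, "gene_truth.tsv"))
        .writeTSV(tcr$chains, file.path(outdir, "tcr_chains.tsv"))
        .writeTSV(tcr$truth, file.path(outdir, "tcr_truth.tsv"))
        res$sce <- sce; res$tcr <- tcr$chains
    } else if (s == "qc") {
        if (is.null(res$sce)) {
            .need(file.path(outdir, "sim", "matrix.mtx"), "simulate")
            res$sce <- readCounts10x(file.path(outdir, "sim"))
            res$tcr <- readTCRTable(
                .need(file.path(outdir, "tcr_chains.tsv"), "simulate"))
        }
        qc <- qcReport(res$sce, res$tcr, cfg$umi_min, cfg$umi_max,
                       cfg$genes_min, cfg$genes_max)
        .writeTSV(qc$report, file.path(outdir, "qc_report.tsv"))
        res$qc <- logNormalize(qc$filtered)
    } else if (s == "markers") {
        sce <- .needQC(res)
        mk <- findClusterMarkers(sce, sce$group, min_frac = cfg$min_frac,
                                 logfc_min = cfg$logfc_min,
                                 alpha = cfg$alpha)
        .writeTSV(mk, file.path(outdir, "markers.tsv"))
        tru <- geneTruth(sce)
        nlt_sig <- tru$gene[(tru$class == "marker" &
                                 tru$owner == "NLT") %in% TRUE |
                            (tru$class == "switch" & tru$k > 0)]
        lt_sig <- tru$gene[(tru$class == "marker" &
                                tru$owner == "LT") %in% TRUE |
                           (tru$class == "switch" & tru$k < 0)]
        sc <- nltLtScore(mk, nlt_sig, lt_sig)
        .writeTSV(sc, file.path(outdir, "signature_scores.tsv"))
        res$markers <- mk; res$signature <- sc
    } else if (s == "transfer") {
        sce <- .needQC(res)
        n <- ncol(sce)
        test_i <- withSeed(cfg$seed + 2, sample(n, round(n / 3)))
        model <- trainClassifier(sce[, -test_i], sce$group[-test_i],
                                 l1_strength = cfg$l1_strength,
                                 seed = cfg$seed)
        pred <- predictLabels(model, sce[, test_i])
        comp <- compositionMatrix(pred$labels, sce$group[test_i])
        writeTransferModel(model, file.path(outdir, "transfer_model.json"))
        .writeTSV(data.frame(cell_id = names(pred$labels),
                             predicted = pred$labels,
                             low_confidence = pred$low_confidence),
                  file.path(outdir, "transfer_predictions.tsv"))
        .writeTSV(data.frame(query = rownames(comp), comp,
                             check.names = FALSE),
                  file.path(outdir, "transfer_composition.tsv"))
        res$transfer <- list(model = model, predictions = pred,
                             composition = comp,
                             accuracy = mean(pred$labels ==
                                                 sce$group[test_i]))
    } else if (s == "trajectory") {
        sce <- .needQC(res)
        if (!is.null(cfg$tissue_include)) {
            sce <- sce[, sce$tissue %in% cfg$tissue_include]
        }
        hv <- selectVariableGenes(sce, n_top = min(cfg$n_variable_genes,
                                                   nrow(sce)))
        emb <- fitGPLVM(sce, genes = hv, q_latent = cfg$q_latent,
                        seed = cfg$seed, maxit = cfg$gplvm_maxit)
        emb <- selectAdaptationLV(emb, sce$tissue, nlt = cfg$nlt_tissues)
        X <- latentCoords(emb)
        .writeTSV(data.frame(cell_id = rownames(X), X,
                             adaptation_lv = adaptationLV(emb)),
                  file.path(outdir, "embedding.tsv"))
        .writeTSV(data.frame(dimension = seq_along(relevance(emb)),
                             relevance = relevance(emb),
                             selected = seq_along(relevance(emb)) ==
                                 emb@adaptationDim),
                  file.path(outdir, "relevance.tsv"))
        res$embedding <- emb; res$traj_sce <- sce
    } else if (s == "kinetics") {
        if (is.null(res$embedding)) stop("missing upstream embedding; ",
                                         "run the 'trajectory' stage first")
        sce <- res$traj_sce
        fits <- fitAllSwitchGenes(sce, adaptationLV(res$embedding),
                                  min_cells = cfg$min_cells,
                                  min_abs_corr = cfg$min_abs_corr,
                                  q_max = cfg$q_max)
        .writeTSV(fits, file.path(outdir, "switch_fits.tsv"))
        res$switch_fits <- fits
    } else if (s == "ordering") {
        if (is.null(res$switch_fits)) stop("missing upstream switch fits; ",
                                           "run the 'kinetics' stage first")
        tru <- geneTruth(res$traj_sce)
        sw <- tru[tru$class == "switch", ]
        cut3 <- quantile(sw$t0, c(1 / 3, 2 / 3))
        sets <- list(early_program = sw$gene[sw$t0 <= cut3[1]],
                     mid_program = sw$gene[sw$t0 > cut3[1] &
                                               sw$t0 <= cut3[2]],
                     late_program = sw$gene[sw$t0 > cut3[2]])
        timing <- termActivationTimes(res$switch_fits, sets)
        .writeTSV(timing, file.path(outdir, "program_timing.tsv"))
        res$timing <- timing
    } else if (s == "xspecies") {
        sp <- simulateSpeciesPair(n_orthologs = cfg$n_orthologs,
                                  n_paralog_swaps = cfg$n_paralog_swaps,
                                  seed = cfg$seed + 3)
        ov <- markerOverlap(sp$markers_a, sp$markers_b, sp$orthologs)
        subs <- detectParalogSubstitution(sp$stats_a, sp$stats_b,
                                          sp$markers_a, sp$markers_b,
                                          sp$families)
        .writeTSV(ov$shared, file.path(outdir, "xspecies_shared_markers.tsv"))
        .writeTSV(subs, file.path(outdir, "xspecies_substitutions.tsv"))
        res$xspecies <- list(overlap = ov, substitutions = subs)
    }
    res
}

.needQC <- function(res) {
    if (is.null(res$qc)) {
        stop("missing upstream QC'd matrix; run the 'qc' stage first")
    }
    res$qc
}

.writeManifest <- function(cfg, outdir) {
    arts <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
    sums <- tools::md5sum(file.path(outdir, arts))
    names(sums) <- arts
    jsonlite::write_json(list(
        package = "switchtraj",
        version = as.character(packageVersion("switchtraj")),
        r_version = as.character(getRversion()),
        seed = cfg$seed,
        config = cfg[order(names(cfg))],
        artifacts = as.list(sums),
        timestamp = format(Sys.time(), tz = "UTC")),
        file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}
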