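#' Full PRS association table for one case-control contrast
#'
#' Assembles the standard reporting layout for a PRS case-control analysis:
#' quintile rows with the middle quintile as reference, the top-percentile
#' contrast, continuous weighted and unweighted per-unit rows, group median
#' scores, and c-statistics of the adjusted weighted and unweighted models.
#'
#' @param scores score set from [scoreCohort()].
#' @param samples sample table with `phenotype`, `age`, `sex` aligned to
#'   `scores`.
#' @param caseLevels phenotype level(s) forming the case group.
#' @param reference reference quantile bin.
#' @param label outcome label stored in the model info.
#' @return \linkS4class{AssociationTable}; `modelInfo` carries
#'   `median_cases`, `median_controls`, `cstat_unweighted` and the
#'   continuous fits.
#' @export
prsAssociationTable <- function(scores, samples, caseLevels,
                                reference = "Q3", label = NULL) {
    sd_ <- as.data.frame(samples)
    sel <- sd_$phenotype %in% c("control", caseLevels)
    y <- as.integer(sd_$phenotype[sel] %in% caseLevels)
    cov <- sd_[sel, c("age", "sex")]
    cats <- scores$quantile_category[sel]
    pw <- scores$prs_weighted[sel]
    pu <- scores$prs_unweighted[sel]
    top <- scores$top_percentile[sel]

    qa <- quintileAssociation(cats, y, cov, reference)
    cw <- continuousAssociation(pw, y, cov)
    cu <- continuousAssociation(pu, y, cov)
    p99 <- topPercentileAssociation(top, cats, y, cov, reference)

    tb <- rbind(
        qa@table,
        data.frame(contrast = "P99", n_cases = p99$n_top_cases,
                   n_controls = sum(top & y == 0, na.rm = TRUE),
                   or_ = p99$or, ci_low = p99$ci_low, ci_high = p99$ci_high,
                   p = p99$p),
        data.frame(contrast = "Continuous", n_cases = sum(y == 1),
                   n_controls = sum(y == 0), or_ = cw$or,
                   ci_low = cw$ci_low, ci_high = cw$ci_high, p = cw$p),
        data.frame(contrast = "Continuous unweighted", n_cases = sum(y == 1),
                   n_controls = sum(y == 0), or_ = cu$or,
                   ci_low = cu$ci_low, ci_high = cu$ci_high, p = cu$p))
    new("AssociationTable", table = tb,
        modelInfo = list(outcome = label %||% paste(caseLevels, collapse = "+"),
                         adjustment = c("age", "sex"), reference = reference,
                         median_cases = median(pw[y == 1], na.rm = TRUE),
                         median_controls = median(pw[y == 0], na.rm = TRUE),
                         cstat_unweighted = c(cu$cstat$auc, cu$cstat$ci_low,
                                              cu$cstat$ci_high),
                         pct_top_cases = p99$pct_top_cases,
                         fit_continuous = cw$fit,
                         quintile_cstat = qa@cStatistic),
        cStatistic = c(cw$cstat$auc, cw$cstat$ci_low, cw$cstat$ci_high))
}

#' Serialize an AssociationTable to TSV
#'
#' Writes the contrast rows plus median-PRS and c-statistic footer rows.
#'
#' @param at \linkS4class{AssociationTable}.
#' @param path output file.
#' @export
writeAssociationTSV <- function(at, path) {
    tb <- at@table
    foot <- data.frame(
        contrast = c("PRS median cases", "PRS median controls",
                     "c-statistic", "c-statistic unweighted"),
        n_cases = NA, n_controls = NA,
        or_ = c(at@modelInfo$median_cases, at@modelInfo$median_controls,
                at@cStatistic[1], at@modelInfo$cstat_unweighted[1]),
        ci_low = c(NA, NA, at@cStatistic[2], at@modelInfo$cstat_unweighted[2]),
        ci_high = c(NA, NA, at@cStatistic[3], at@modelInfo$cstat_unweighted[3]),
        p = NA)
    out <- rbind(tb, foot)
    names(out)[names(out) == "or_"] <- "estimate"
    write.table(format(out, digits = 6), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Default demonstration pipeline configuration
#'
#' A simulated single-arm European-ancestry cohort over a 41-SNP panel at
#' reduced size (600 controls, 120 LC-MBL, 60 HC-MBL, 150 CLL) so the whole
#' pipeline runs in seconds.
#'
#' @param seed integer seed.
#' @return config list accepted by [runPipeline()].
#' @export
demoConfig <- function(seed = 1) {
    list(seed = seed,
         simulation = list(nPerGroup = c(control = 600, `LC-MBL` = 120,
                                         `HC-MBL` = 60, CLL = 150),
                           nSnps = 41),
         qc = list(snp_call_min = 0.95, sample_call_min = 0.90,
                   hwe_alpha = 1e-5),
         ancestry = list(run = TRUE),
         scoring = list(cutoffs = "external", missing_policy = "mean_impute"))
}

.validatePipelineConfig <- function(config) {
    hasSim <- !is.null(config$simulation)
    hasInp <- !is.null(config$inputs)
    if (hasSim == hasInp)
        stop("config must have exactly one of 'simulation' or 'inputs'")
    qc <- config$qc %||% list()
    for (k in c("snp_call_min", "sample_call_min"))
        if (!is.null(qc[[k]]) && (qc[[k]] <= 0 || qc[[k]] > 1))
            stop("qc threshold ", k, " outside (0, 1]")
    invisible(TRUE)
}

#' Run the full simulate/load -> QC -> ancestry -> score -> associate pipeline
#'
#' Deterministic for a fixed config and seed. Writes, under `outdir`:
#' the panel, sample table, genotypes (VCF + dosage TSV), QC report,
#' ancestry estimates, score set, one association table per contrast
#' (overall MBL, LC-MBL, HC-MBL, CLL — whichever phenotypes are present),
#' per-SNP association results, the heterogeneity trend test, a
#' Kruskal-Wallis comparison of score distributions across groups, and a
#' `manifest.json` with the config hash and per-stage row counts.
#'
#' @param config config list (see [demoConfig()]) or path to a YAML file.
#' @param outdir output directory, created if needed.
#' @return (invisibly) list with the in-memory stage objects and file paths.
#' @export
runPipeline <- function(config = demoConfig(), outdir = tempfile("cllprs_")) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    .validatePipelineConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed %||% 1L
    log_ <- function(...) message("[cllprs] ", ...)
    counts <- list()

    ## stage 1: genotypes
    if (!is.null(config$simulation)) {
        simArgs <- config$simulation
        if (!is.null(simArgs$nPerGroup))
            simArgs$nPerGroup <- unlist(simArgs$nPerGroup)
        simArgs$seed <- seed
        sc <- do.call(simulationConfig, simArgs)
        gex <- simulateCohort(sc)
        log_("simulated cohort: ", nrow(gex), " variants x ", ncol(gex),
             " samples")
    } else {
        inp <- config$inputs
        panel <- readPanelTSV(inp$panel)
        samples <- if (!is.null(inp$samples)) readSamplesTSV(inp$samples)
        gex <- if (!is.null(inp$vcf))
            readGenotypesVCF(inp$vcf, panel, samples)
        else readDosageTSV(inp$dosages, panel, samples)
        log_("loaded cohort: ", nrow(gex), " variants x ", ncol(gex),
             " samples")
    }
    writePanelTSV(snpPanel(gex), file.path(outdir, "panel.tsv"))
    writeSamplesTSV(sampleData(gex), file.path(outdir, "samples.tsv"))
    writeVCF(gex, file.path(outdir, "genotypes.vcf"))
    writeDosageTSV(gex, file.path(outdir, "dosages.tsv"))
    counts$input <- list(variants = nrow(gex), samples = ncol(gex))

    ## stage 2: QC
    qcArgs <- config$qc %||% list()
    qcRes <- qcFilter(gex,
                      snpCallMin = qcArgs$snp_call_min %||% 0.95,
                      sampleCallMin = qcArgs$sample_call_min %||% 0.90,
                      hweAlpha = qcArgs$hwe_alpha %||% 1e-5)
    gex <- qcRes$genotypes
    rep_ <- qcRes$report
    rv <- rep_@removedVariants; rs <- rep_@removedSamples
    write.table(rbind(
        data.frame(id = rv$variant_id, kind = rep("variant", nrow(rv)),
                   reason = rv$reason),
        data.frame(id = rs$sample_id, kind = rep("sample", nrow(rs)),
                   reason = rs$reason)),
        file.path(outdir, "qc_report.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    log_("QC: ", nrow(rep_@removedVariants), " variants and ",
         nrow(rep_@removedSamples), " samples removed; ", nrow(gex),
         " x ", ncol(gex), " retained")
    counts$qc <- list(variants = nrow(gex), samples = ncol(gex))

    ## stage 3: ancestry
    ancres <- NULL
    if (isTRUE((config$ancestry %||% list(run = TRUE))$run %||% TRUE)) {
        ancres <- estimateAdmixtureAll(gex)
        writeSamplesTSV(ancres, file.path(outdir, "ancestry.tsv"))
        log_("ancestry: ", sum(ancres$label == "EA"), " EA, ",
             sum(ancres$label == "AA"), " AA, ",
             sum(ancres$label == "OTHER"), " OTHER")
    }

    ## stage 4: scoring
    scArgs <- config$scoring %||% list()
    cutSpec <- scArgs$cutoffs %||% "external"
    cutoffs <- if (identical(cutSpec, "external")) eaReferenceCutoffs()
               else if (identical(cutSpec, "internal")) NULL
               else readCutoffsTSV(cutSpec)
    scores <- scoreCohort(gex, cutoffs = cutoffs,
                          missingPolicy = scArgs$missing_policy %||%
                              "mean_impute")
    writeSamplesTSV(scores, file.path(outdir, "scores.tsv"))
    counts$scored <- list(samples = sum(scores$scored))

    ## stage 5: association
    sd_ <- sampleData(gex)
    present <- levels(droplevels(factor(sd_$phenotype)))
    contrasts <- list(mbl_overall = c("LC-MBL", "HC-MBL"),
                      lc_mbl = "LC-MBL", hc_mbl = "HC-MBL", cll = "CLL")
    contrasts <- Filter(function(cl) all(cl %in% present), contrasts)
    tables <- list()
    for (nm in names(contrasts)) {
        at <- prsAssociationTable(scores, sd_, contrasts[[nm]], label = nm)
        writeAssociationTSV(at, file.path(outdir, paste0("assoc_", nm, ".tsv")))
        tables[[nm]] <- at
    }
    y <- as.integer(sd_$phenotype != "control")
    snpTab <- perSnpAssociation(gex, y)
    write.table(snpTab, file.path(outdir, "per_snp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    het <- NULL
    if (sum(present != "control") >= 2) {
        het <- heterogeneityTest(factor(sd_$phenotype,
                                        levels = c("control",
                                                   setdiff(present, "control"))),
                                 scores$prs_weighted, sd_)
        write.table(data.frame(lrt = het@lrt, df = het@df, p_het = het@pHet),
                    file.path(outdir, "heterogeneity.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    grp <- split(scores$prs_weighted, as.character(sd_$phenotype))
    kw <- if (length(grp) >= 2) kruskalWallis(grp) else NULL
    log_("association: ", length(tables), " contrast table(s) written")

    ## manifest
    cfgFile <- file.path(outdir, "config.yaml")
    yaml::write_yaml(config, cfgFile)
    manifest <- list(package = "cllprs",
                     version = as.character(packageVersion("cllprs")),
                     seed = seed,
                     config_hash = unname(tools::md5sum(cfgFile)),
                     counts = counts,
                     kruskal_wallis = kw,
                     heterogeneity_p = if (!is.null(het)) het@pHet)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(genotypes = gex, qc = rep_, ancestry = ancres,
                   scores = scores, tables = tables, heterogeneity = het,
                   kruskal = kw, outdir = outdir))
}

#' Read quantile cutoffs from TSV (kind/boundary columns)
#'
#' @param path TSV with columns `kind` (min/interior/max) and `boundary`.
#' @param nReference reference-set size recorded in the object.
#' @return \linkS4class{PrsCutoffs}.
#' @export
readCutoffsTSV <- function(path, nReference = NA_integer_) {
    df <- read.delim(path)
    new("PrsCutoffs", boundaries = df$boundary[df$kind == "interior"],
        range = range(df$boundary), source = "external_reference",
        nReference = as.integer(nReference))
}

#' Write a small self-contained demonstration fixture set
#'
#' A 41-variant, 200-sample simulated cohort (120 controls, 30 LC-MBL,
#' 20 HC-MBL, 30 CLL) written as VCF, dosage TSV, panel TSV and sample TSV;
#' regeneration is reproducible for a fixed seed.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return named file paths, invisibly.
#' @export
makeDemoFixtures <- function(seed = 1, dir = tempfile("cllprs_fixtures_")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sc <- simulationConfig(nPerGroup = c(control = 120, `LC-MBL` = 30,
                                         `HC-MBL` = 20, CLL = 30),
                           seed = seed)
    gex <- simulateCohort(sc)
    paths <- c(vcf = file.path(dir, "genotypes.vcf"),
               dosages = file.path(dir, "dosages.tsv"),
               panel = file.path(dir, "panel.tsv"),
               samples = file.path(dir, "samples.tsv"))
    writeVCF(gex, paths[["vcf"]])
    writeDosageTSV(gex, paths[["dosages"]])
    writePanelTSV(snpPanel(gex), paths[["panel"]])
    writeSamplesTSV(sampleData(gex), paths[["samples"]])
    invisible(paths)
}
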