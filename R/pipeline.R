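# End-to-end orchestration: simulate -> network -> classify -> quantify ->
# profile -> pan-BGC -> mutation scan, with a machine-readable JSON report.

#' Pipeline configuration
#'
#' @param seed mandatory global seed propagated to every stochastic stage.
#' @param sim a [simulationConfig()]; its seed is overridden by `seed`.
#' @param scoring a [scoringParams()].
#' @param tagTolDa tag screening tolerance (Da).
#' @param bgc list of arguments for [makeBGCMatrix()] (nStrains, nCore,
#'   nAccessory, nUnique).
#' @param cds list of arguments for the mutation-scan stage (nGenes,
#'   nSubstitutions, pSilent, nDeletions, shareProb).
#' @return classed list (`PipelineConfig`).
#' @export
pipelineConfig <- function(seed,
                           sim = simulationConfig(seed = seed),
                           scoring = scoringParams(),
                           tagTolDa = 0.01,
                           bgc = list(nStrains = 18L, nCore = 18L,
                                      nAccessory = 19L, nUnique = 5L),
                           cds = list(nGenes = 16L, nSubstitutions = 20L,
                                      pSilent = 0.1, nDeletions = 1L,
                                      shareProb = 0.3)) {
    stopifnot(length(seed) == 1L, is.finite(seed))
    sim$seed <- as.integer(seed)
    cfg <- list(seed = as.integer(seed), sim = sim, scoring = scoring,
                tagTolDa = tagTolDa, bgc = bgc, cds = cds)
    class(cfg) <- "PipelineConfig"
    cfg
}

.stage <- function(name, outDir, expr) {
    tryCatch(expr, error = function(e) {
        writeLines(paste0("FAILED at stage ", name, ": ",
                          conditionMessage(e)),
                   file.path(outDir, "FAILED"))
        stop("pipeline stage ", sQuote(name), " failed: ",
             conditionMessage(e), call. = FALSE)
    })
}

#' Run the full analysis pipeline on simulated data
#'
#' Generates a compound library, per-strain production, MS/MS spectra and
#' EIC traces; clusters spectra, builds and exports the molecular network,
#' assigns tag groups; quantifies relative abundances against the
#' reference strain; computes presence/exclusivity profiles and profile
#' clustering; generates and summarizes a pan-BGC matrix; plants and
#' recovers CDS mutations. All stage outputs are written under `outDir`
#' and summarized in a JSON report; re-running with the same configuration
#' reproduces the outputs exactly.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return the report, a named list (also written as `report.json`).
#' @export
runPipeline <- function(cfg, outDir = tempfile("strainmet_run_")) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    report <- list(params = list(seed = cfg$seed,
                                 sim = unclass(cfg$sim),
                                 scoring = unclass(cfg$scoring),
                                 tagTolDa = cfg$tagTolDa,
                                 bgc = cfg$bgc, cds = cfg$cds))

    lib <- .stage("simulate", outDir, makeLibrary(cfg$sim))
    prod <- .stage("simulate", outDir, makeProduction(lib$library, cfg$sim))
    spectra <- .stage("simulate", outDir,
                      simulateSpectra(lib$library, prod$production, cfg$sim))
    eic <- .stage("simulate", outDir,
                  simulateEIC(lib$library, prod$production, cfg$sim))
    writeMGF(spectra, file.path(outDir, "spectra.mgf"))
    writeMatrix(abundances(prod$production),
                file.path(outDir, "production.tsv"), "strain")
    report$simulate <- list(nCompounds = nrow(lib$library),
                            nSpectra = length(spectra),
                            strains = cfg$sim$strains)

    nodes <- .stage("network", outDir, clusterSpectra(spectra, cfg$scoring))
    net <- .stage("network", outDir, buildNetwork(nodes, cfg$scoring))
    net <- .stage("classify", outDir,
                  assignNodeGroups(net, spectra, tolDa = cfg$tagTolDa))
    exportNetwork(net, file.path(outDir, "network"))
    comps <- constellations(net)
    report$network <- list(nNodes = length(nodes),
                           nEdges = nrow(networkEdges(net)),
                           nConstellations = length(comps))
    report$classify <- as.list(table(net@nodeGroups))

    targets <- stats::setNames(lib$library$ionMz, lib$library$name)
    scm <- .stage("quantify", outDir,
                  eicAbundanceMatrix(eic$traces, targets,
                                     referenceStrain = cfg$sim$strains[1L],
                                     tolDa = 0.01))
    ra <- relativeAbundance(scm)
    bp <- bestProducer(scm)
    writeMatrix(abundances(ra), file.path(outDir, "relative_abundance.tsv"),
                "strain")
    write.table(bp, file.path(outDir, "best_producers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$quantify <- list(
        referenceStrain = referenceStrain(ra),
        referenceNonproducerCompounds =
            sum(raFlags(ra)[1L, ] == "reference-nonproducer"))

    pres <- presenceMatrix(scm)
    ps <- producingStrains(pres)
    tr <- .stage("profile", outDir, glogPareto(scm))
    pc <- clusterProfiles(tr)
    exportClustering(pc, file.path(outDir, "profiles"))
    report$profile <- list(exclusiveCount = ps$exclusiveCount,
                           perStrainCounts = as.list(ps$perStrainCounts))

    bgcSim <- .stage("panbgc", outDir, do.call(makeBGCMatrix,
                     c(cfg$bgc, list(seed = cfg$seed))))
    stats <- panBGCStats(bgcSim$matrix, strains(bgcSim$matrix)[1L])
    writeMatrix(bgcPresence(bgcSim$matrix), file.path(outDir, "bgc.tsv"),
                "strain")
    report$panbgc <- list(unionSize = stats$unionSize,
                          coreCount = stats$coreCount,
                          nonCoreFraction = stats$nonCoreFraction,
                          absentFromTypeStrain = stats$absentFromTypeStrain,
                          uniqueToOneStrain = nrow(stats$uniqueToOneStrain))

    genes <- .stage("mutscan", outDir,
                    makeReferenceGenes(cfg$cds$nGenes, seed = cfg$seed))
    cdsSim <- .stage("mutscan", outDir, makeCDSSet(
        genes, cfg$sim$strains,
        nSubstitutions = cfg$cds$nSubstitutions,
        pSilent = cfg$cds$pSilent, nDeletions = cfg$cds$nDeletions,
        shareProb = cfg$cds$shareProb, seed = cfg$seed))
    events <- .stage("mutscan", outDir,
                     classifyMutationSet(genes, cdsSim$sequences))
    mm <- mutationMatrix(events, strains = cfg$sim$strains,
                         genes = names(genes))
    write.table(events, file.path(outDir, "mutations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$mutscan <- list(distinctTotal = mm$distinctTotal,
                           perStrainTotals = as.list(mm$perStrainTotals),
                           kindTotals = as.list(mm$kindTotals))

    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
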