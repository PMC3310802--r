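#' @include simulate.R expansion.R novelty.R profile.R
NULL

#' Run the full architecture-content analysis pipeline
#'
#' Executes the stages build -> profile -> patterns -> expansion -> novelty
#' in order and writes every stage artifact plus a run manifest to the
#' output directory. Reruns with an identical config are bit-identical for
#' the deterministic stages (the manifest carries no timestamp, and all
#' randomness is driven by the config seed).
#'
#' @param config named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{mode}{`"simulate"`, `"tables"` (per-species hit tables) or
#'       `"matrix"` (pre-built dosage TSV).}
#'     \item{sim}{a [SimulationConfig-class] (simulate mode; defaults to
#'       [simulationConfig()] with the pipeline seed).}
#'     \item{tablesDir}{directory of hit tables (tables mode).}
#'     \item{matrixFile, totalsFile}{dosage TSV and totals JSON (matrix mode).}
#'     \item{scheme}{a [LineageScheme-class]; default
#'       [defaultLineageScheme()].}
#'     \item{eCutoff}{E-value cutoff, default `1e-2`.}
#'     \item{normalization}{a [NormalizationSpec-class]; default none.}
#'     \item{alphas}{significance levels, default `c(0.01, 0.05)`.}
#'     \item{bootstrapB}{resamples for [bootstrapAdjust()], default 1000.}
#'     \item{pseudoCount}{default 0.}
#'     \item{seed}{default 1.}
#'   }
#' @param outDir output directory (created if needed).
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    defaults <- list(mode = "simulate", sim = NULL, tablesDir = NULL,
                     matrixFile = NULL, totalsFile = NULL,
                     scheme = defaultLineageScheme(), eCutoff = 1e-2,
                     normalization = normalizationSpec(),
                     alphas = c(0.01, 0.05), bootstrapB = 1000L,
                     pseudoCount = 0, seed = 1L)
    config <- utils::modifyList(defaults, config)

    ## validate everything before any stage runs
    if (!config$mode %in% c("simulate", "tables", "matrix"))
        stop("unknown mode: ", config$mode)
    if (!is(config$scheme, "LineageScheme")) stop("scheme must be a LineageScheme")
    methods::validObject(config$scheme)
    if (any(config$alphas <= 0) || any(config$alphas >= 1))
        stop("alpha levels must lie in (0, 1)")
    if (config$mode == "tables" &&
        (is.null(config$tablesDir) || !dir.exists(config$tablesDir)))
        stop("tables mode requires an existing tablesDir")
    if (config$mode == "matrix" &&
        (is.null(config$matrixFile) || !file.exists(config$matrixFile)))
        stop("matrix mode requires an existing matrixFile")
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    art <- function(f) file.path(outDir, f)
    paths <- list()
    msg <- function(stage, ...) message("[", stage, "] ", ...)

    ## ---- build ----
    msg("build", "assembling architecture content (mode: ", config$mode, ")")
    truth <- NULL
    content <- switch(config$mode,
        simulate = {
            sim <- if (is.null(config$sim))
                simulationConfig(scheme = config$scheme, seed = config$seed)
            else config$sim
            out <- simulateContent(sim)
            truth <- out$truth
            utils::write.table(out$truth, art("ground_truth.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            paths$ground_truth <- art("ground_truth.tsv")
            out$content
        },
        tables = readDomainTables(config$tablesDir, config$eCutoff),
        matrix = readContent(config$matrixFile,
            if (is.null(config$totalsFile))
                paste0(config$matrixFile, ".totals.json")
            else config$totalsFile))
    sp <- speciesIds(content)
    known <- sp %in% unlist(lineageMembers(config$scheme), use.names = FALSE)
    if (!all(known))
        stop("species not covered by the lineage scheme: ",
             paste(sp[!known], collapse = ", "))
    writeContent(content, art("dosage.tsv"))
    paths$dosage <- art("dosage.tsv")

    ## ---- profile ----
    msg("profile", "per-genome profiles and cross-genome statistics")
    prof <- profileGenomes(content)
    utils::write.table(prof, art("genome_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$profiles <- art("genome_profiles.tsv")
    if (nrow(prof) >= 5L && stats::sd(prof$frac_predicted) > 0) {
        ad <- andersonDarling(prof$frac_predicted)
        jsonlite::write_json(unclass(ad), art("normality_overall.json"),
                             auto_unbox = TRUE, digits = NA)
        paths$normality <- art("normality_overall.json")
    }

    ## ---- patterns ----
    msg("patterns", "lineage presence/absence classification")
    asg <- assignPatterns(content, config$scheme)
    utils::write.table(as.data.frame(asg), art("pattern_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarizePatterns(asg)
    lab <- lineageLabels(config$scheme)
    pats <- allPatterns(lab)
    overall <- table(factor(asg$pattern_overall, levels = pats))
    fig2 <- data.frame(pattern = pats,
                       overall_count = as.integer(overall),
                       prevalent_count = patternCounts(summ)[pats],
                       prevalent_percentage = patternPercentages(summ)[pats])
    utils::write.table(fig2, art("pattern_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$patterns <- art("pattern_summary.tsv")
    paths$assignments <- art("pattern_assignments.tsv")

    ## ---- expansion ----
    msg("expansion", "lineage-pair dosage tests (B = ", config$bootstrapB, ")")
    res <- testExpansion(content, config$scheme,
                         normalization = config$normalization,
                         pseudoCount = config$pseudoCount)
    res <- bootstrapAdjust(res, content, config$scheme, B = config$bootstrapB,
                           seed = config$seed,
                           normalization = config$normalization,
                           pseudoCount = config$pseudoCount)
    utils::write.table(res, art("expansion_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$expansion <- art("expansion_results.tsv")
    for (a in config$alphas) {
        cls <- classifyExpansion(res, a)
        f <- art(sprintf("expansion_classification_a%s.tsv", format(a)))
        utils::write.table(cls, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths[[sprintf("classification_a%s", format(a))]] <- f
    }
    cons <- constrainedArchitectures(content, config$scheme)
    jsonlite::write_json(cons, art("constrained_architectures.json"))
    paths$constrained <- art("constrained_architectures.json")

    ## ---- novelty ----
    msg("novelty", "newly-emerged vs pre-existing domain analysis")
    ref <- referenceInventory(asg)
    scopes <- intersect(allPatterns(lab[-(1:2)]),
                        unique(asg$pattern[!is.na(asg$pattern)]))
    novrows <- lapply(scopes, function(sc) {
        ct <- buildContingency(asg, sc, ref)
        chi_s <- if (sum(ct$counts[c("single_new", "single_old")]) > 0)
            gofTest(ct$counts[c("single_new", "single_old")]) else NULL
        chi_m <- if (sum(ct$counts[c("multi_new", "multi_old")]) > 0)
            gofTest(ct$counts[c("multi_new", "multi_old")]) else NULL
        data.frame(scope = sc,
                   n_arch_single = ct$n_architectures[["single"]],
                   n_arch_multi = ct$n_architectures[["multi"]],
                   single_new = ct$counts[["single_new"]],
                   single_old = ct$counts[["single_old"]],
                   multi_new = ct$counts[["multi_new"]],
                   multi_old = ct$counts[["multi_old"]],
                   chi2_single = if (is.null(chi_s)) NA else chi_s$statistic,
                   p_single = if (is.null(chi_s)) NA else chi_s$p_value,
                   chi2_multi = if (is.null(chi_m)) NA else chi_m$statistic,
                   p_multi = if (is.null(chi_m)) NA else chi_m$p_value)
    })
    nov <- if (length(novrows)) do.call(rbind, novrows) else
        data.frame(scope = character(0))
    utils::write.table(nov, art("novelty_contingency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$novelty <- art("novelty_contingency.tsv")

    ## ---- manifest ----
    cfgTxt <- paste(deparse(config[c("mode", "eCutoff", "alphas",
                                     "bootstrapB", "pseudoCount", "seed")]),
                    collapse = "")
    tmp <- tempfile(); writeLines(cfgTxt, tmp)
    manifest <- list(
        package = "archevo",
        version = as.character(utils::packageVersion("archevo")),
        mode = config$mode, seed = config$seed,
        e_cutoff = config$eCutoff, alphas = config$alphas,
        bootstrap_B = config$bootstrapB,
        config_hash = unname(tools::md5sum(tmp)),
        n_architectures = nrow(dosage(content)),
        n_species = length(sp))
    unlink(tmp)
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    paths$manifest <- art("manifest.json")
    invisible(paths)
}
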