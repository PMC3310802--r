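#' @include AllGenerics.R
NULL

#' LineageScheme: species grouped into ordered lineages with majority rules
#'
#' A `LineageScheme` partitions the species of a multi-genome analysis into
#' ordered lineages and attaches to each lineage a majority threshold: the
#' minimum number of member species that must carry a domain architecture for
#' the architecture to count as present in that lineage. Lineage labels must
#' be distinct single characters so that presence/absence patterns can be
#' written unambiguously as concatenated labels (e.g. `"BCD"`).
#'
#' @slot labels character; ordered single-character lineage labels.
#' @slot members named list; lineage label -> character vector of species ids.
#'   Every species belongs to exactly one lineage.
#' @slot thresholds named integer; per-lineage majority threshold, between 1
#'   and the lineage size.
#'
#' @seealso [defaultLineageScheme()], [assignPatterns()]
#' @export
setClass("LineageScheme",
    slots = c(labels = "character", members = "list", thresholds = "integer"))

setValidity("LineageScheme", function(object) {
    msg <- character()
    lab <- object@labels
    if (length(lab) < 2L) msg <- c(msg, "need at least two lineages")
    if (any(nchar(lab) != 1L)) msg <- c(msg, "lineage labels must be single characters")
    if (anyDuplicated(lab)) msg <- c(msg, "lineage labels must be distinct")
    if (!identical(sort(names(object@members)), sort(lab)))
        msg <- c(msg, "members must be named by the lineage labels")
    if (!identical(sort(names(object@thresholds)), sort(lab)))
        msg <- c(msg, "thresholds must be named by the lineage labels")
    sp <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(sp))
        msg <- c(msg, "every species must belong to exactly one lineage")
    sizes <- lengths(object@members)[lab]
    thr <- object@thresholds[lab]
    if (any(is.na(thr)) || any(thr < 1L) || any(thr > sizes))
        msg <- c(msg, "thresholds must satisfy 1 <= threshold <= lineage size")
    if (length(msg)) msg else TRUE
})

#' Construct a LineageScheme
#'
#' @param labels ordered single-character lineage labels.
#' @param members named list mapping each label to its species ids.
#' @param thresholds named integer (or numeric) vector of per-lineage majority
#'   thresholds.
#' @return A validated [LineageScheme-class].
#' @examples
#' LineageScheme(c("A", "B"),
#'               list(A = c("s1", "s2", "s3"), B = c("s4", "s5")),
#'               c(A = 2, B = 2))
#' @export
LineageScheme <- function(labels, members, thresholds) {
    new("LineageScheme", labels = as.character(labels),
        members = members[labels],
        thresholds = stats::setNames(as.integer(thresholds[labels]), labels))
}

#' Default four-lineage scheme for the 14 green plant genomes
#'
#' Lineage A holds the five algal species (Cr, Ol, Ot, Cv, Vc; threshold 3 of
#' 5), lineage B the two early-diverging land plants (Pp moss, Sm spikemoss;
#' 2 of 2), lineage C the three monocots (Os, Zm, Sb; 2 of 3) and lineage D
#' the four dicots (Vv, At, Pt, Gm; 3 of 4).
#'
#' @return A [LineageScheme-class].
#' @examples
#' lineageThresholds(defaultLineageScheme())
#' @export
defaultLineageScheme <- function() {
    LineageScheme(
        labels = c("A", "B", "C", "D"),
        members = list(
            A = c("Cr", "Ol", "Ot", "Cv", "Vc"),
            B = c("Pp", "Sm"),
            C = c("Os", "Zm", "Sb"),
            D = c("Vv", "At", "Pt", "Gm")),
        thresholds = c(A = 3L, B = 2L, C = 2L, D = 3L))
}

#' @describeIn LineageScheme-class ordered lineage labels
#' @param x a `LineageScheme`.
#' @export
setMethod("lineageLabels", "LineageScheme", function(x) x@labels)

#' @describeIn LineageScheme-class species members per lineage
#' @export
setMethod("lineageMembers", "LineageScheme", function(x) x@members)

#' @describeIn LineageScheme-class majority thresholds per lineage
#' @export
setMethod("lineageThresholds", "LineageScheme", function(x) x@thresholds)

#' @describeIn LineageScheme-class named vector species -> lineage
#' @export
setMethod("speciesLineage", "LineageScheme", function(x) {
    sp <- unlist(x@members, use.names = FALSE)
    stats::setNames(rep(x@labels, lengths(x@members[x@labels])), sp)
})

setMethod("show", "LineageScheme", function(object) {
    cat("LineageScheme with", length(object@labels), "lineages\n")
    for (l in object@labels)
        cat(sprintf("  %s: %s (majority >= %d of %d)\n", l,
            paste(object@members[[l]], collapse = ", "),
            object@thresholds[[l]], length(object@members[[l]])))
})

#' ProteomeContent: architecture content of one proteome
#'
#' Holds, for one species, the mapping from predicted proteins to their
#' canonical domain-architecture strings together with the derived genomic
#' dosage (copy number per distinct architecture) and the total proteome
#' size. The conservation invariant `sum(dosage) == number of Pfam-predicted
#' proteins <= nProteinsTotal` is enforced by the validity method.
#'
#' Objects produced by arithmetic on dosages (see [annotationDelta()]) carry
#' an empty `proteinArchitectures` map: the per-protein assignment is no
#' longer known, only the copy numbers.
#'
#' @slot speciesId single species identifier.
#' @slot nProteinsTotal total number of proteins in the proteome (predicted
#'   plus non-predictable).
#' @slot dosage named integer vector: canonical architecture string -> copy
#'   number (all positive).
#' @slot proteinArchitectures named character: protein id -> canonical
#'   architecture string (may be empty).
#' @export
setClass("ProteomeContent",
    slots = c(speciesId = "character", nProteinsTotal = "integer",
              dosage = "integer", proteinArchitectures = "character"))

setValidity("ProteomeContent", function(object) {
    msg <- character()
    if (length(object@speciesId) != 1L || is.na(object@speciesId))
        msg <- c(msg, "speciesId must be a single string")
    d <- object@dosage
    if (length(d) && (is.null(names(d)) || any(!nzchar(names(d)))))
        msg <- c(msg, "dosage must be named by canonical architecture strings")
    if (anyDuplicated(names(d))) msg <- c(msg, "duplicated architecture in dosage")
    if (any(d < 1L)) msg <- c(msg, "dosage entries must be positive")
    if (sum(d) > object@nProteinsTotal)
        msg <- c(msg, "sum(dosage) exceeds nProteinsTotal")
    pa <- object@proteinArchitectures
    if (length(pa)) {
        if (anyDuplicated(names(pa))) msg <- c(msg, "duplicated protein id")
        tab <- table(pa)
        if (!identical(sort(names(tab)), sort(names(d))) ||
            !all(as.integer(tab[names(d)]) == d))
            msg <- c(msg, "dosage inconsistent with proteinArchitectures")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ProteomeContent-class dosage vector
#' @param x a `ProteomeContent`.
#' @export
setMethod("dosage", "ProteomeContent", function(x) x@dosage)

#' @describeIn ProteomeContent-class proteome size
#' @export
setMethod("nProteinsTotal", "ProteomeContent", function(x) x@nProteinsTotal)

#' @describeIn ProteomeContent-class species id
#' @export
setMethod("speciesIds", "ProteomeContent", function(x) x@speciesId)

#' @describeIn ProteomeContent-class distinct canonical strings
#' @export
setMethod("architectures", "ProteomeContent", function(x) names(x@dosage))

setMethod("show", "ProteomeContent", function(object) {
    cat(sprintf("ProteomeContent for %s: %d predicted proteins, %d distinct architectures (proteome size %d)\n",
        object@speciesId, sum(object@dosage), length(object@dosage),
        object@nProteinsTotal))
})

#' ArchitectureContent: architecture-by-species dosage matrix
#'
#' The central multi-genome container: a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single `"dosage"` assay is the architecture-by-species copy-number
#' matrix, with per-species proteome totals in `colData`. Rows are canonical
#' architecture strings; an architecture is kept only while its dosage is
#' positive in at least one species, and each column sum equals that species'
#' number of predicted proteins (at most its proteome total).
#'
#' @seealso [ArchitectureContent()], [mergeContent()], [assignPatterns()]
#' @export
setClass("ArchitectureContent", contains = "SummarizedExperiment")

setValidity("ArchitectureContent", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- SummarizedExperiment::assay(object, "dosage")
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
        msg <- c(msg, "rows must be uniquely named by canonical architecture strings")
    if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
        msg <- c(msg, "columns must be uniquely named by species ids")
    if (any(d < 0) || any(d != round(d)))
        msg <- c(msg, "dosage must be non-negative integers")
    if (nrow(d) && any(rowSums(d > 0) == 0))
        msg <- c(msg, "architectures absent from every species are not allowed")
    if (!"nProteinsTotal" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must carry nProteinsTotal")
    else if (any(colSums(d) > object$nProteinsTotal))
        msg <- c(msg, "column sums exceed per-species proteome totals")
    if (length(msg)) msg else TRUE
})

#' Construct an ArchitectureContent from a dosage matrix
#'
#' @param dosage integer matrix, rows named by canonical architecture strings,
#'   columns by species ids. Rows that are zero everywhere are dropped.
#' @param nProteinsTotal named integer vector of per-species proteome totals
#'   (one per column of `dosage`).
#' @return An [ArchitectureContent-class].
#' @examples
#' m <- matrix(c(2L, 0L, 1L, 3L), 2, 2,
#'             dimnames = list(c("WD40(1)", "PKinase(1)"), c("At", "Os")))
#' ArchitectureContent(m, c(At = 10L, Os = 10L))
#' @export
ArchitectureContent <- function(dosage, nProteinsTotal) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    keep <- rowSums(dosage > 0) > 0
    dosage <- dosage[keep, , drop = FALSE]
    nProteinsTotal <- as.integer(nProteinsTotal[colnames(dosage)])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        colData = S4Vectors::DataFrame(
            nProteinsTotal = nProteinsTotal, row.names = colnames(dosage)))
    new("ArchitectureContent", se)
}

#' @describeIn ArchitectureContent-class the dosage matrix
#' @param x an `ArchitectureContent`.
#' @export
setMethod("dosage", "ArchitectureContent",
    function(x) SummarizedExperiment::assay(x, "dosage"))

#' @describeIn ArchitectureContent-class named per-species proteome totals
#' @export
setMethod("nProteinsTotal", "ArchitectureContent",
    function(x) stats::setNames(x$nProteinsTotal, colnames(x)))

#' @describeIn ArchitectureContent-class species ids (column names)
#' @export
setMethod("speciesIds", "ArchitectureContent", function(x) colnames(x))

#' @describeIn ArchitectureContent-class canonical strings (row names)
#' @export
setMethod("architectures", "ArchitectureContent", function(x) rownames(x))

setMethod("show", "ArchitectureContent", function(object) {
    d <- dosage(object)
    cat(sprintf("ArchitectureContent: %d distinct architectures x %d species\n",
        nrow(d), ncol(d)))
    cat("  species:", paste(colnames(d), collapse = " "), "\n")
    cat(sprintf("  predicted proteins: %s\n",
        paste(colSums(d), collapse = " ")))
})

#' PatternSummary: counts of architectures per lineage pattern
#'
#' Summary of a pattern assignment: how many architectures fall into each of
#' the non-empty lineage presence/absence patterns (15 for four lineages),
#' the corresponding shares of prevalent architectures, and the bookkeeping
#' totals of the species-specific / removed / prevalent partition.
#'
#' @slot counts named integer over all non-empty patterns, in canonical order.
#' @slot percentages named numeric; `counts / n_prevalent` (zero when no
#'   architecture is prevalent).
#' @slot totals named integer: `n_total`, `n_species_specific`, `n_shared`,
#'   `n_removed`, `n_prevalent`, `n_lineage_specific`.
#' @seealso [summarizePatterns()]
#' @export
setClass("PatternSummary",
    slots = c(counts = "integer", percentages = "numeric", totals = "integer"))

setValidity("PatternSummary", function(object) {
    msg <- character()
    tt <- object@totals
    need <- c("n_total", "n_species_specific", "n_shared", "n_removed",
              "n_prevalent", "n_lineage_specific")
    if (!all(need %in% names(tt))) return("incomplete totals")
    if (sum(object@counts) != tt[["n_prevalent"]])
        msg <- c(msg, "pattern counts must sum to n_prevalent")
    if (tt[["n_species_specific"]] + tt[["n_shared"]] != tt[["n_total"]])
        msg <- c(msg, "n_species_specific + n_shared must equal n_total")
    if (tt[["n_removed"]] + tt[["n_prevalent"]] != tt[["n_shared"]])
        msg <- c(msg, "n_removed + n_prevalent must equal n_shared")
    if (length(msg)) msg else TRUE
})

#' @describeIn PatternSummary-class per-pattern counts
#' @param x a `PatternSummary`.
#' @export
setMethod("patternCounts", "PatternSummary", function(x) x@counts)

#' @describeIn PatternSummary-class per-pattern shares of prevalent set
#' @export
setMethod("patternPercentages", "PatternSummary", function(x) x@percentages)

#' @describeIn PatternSummary-class partition totals
#' @export
setMethod("patternTotals", "PatternSummary", function(x) x@totals)

setMethod("show", "PatternSummary", function(object) {
    tt <- object@totals
    cat(sprintf("PatternSummary: %d architectures (%d species-specific, %d removed as less common, %d prevalent)\n",
        tt[["n_total"]], tt[["n_species_specific"]], tt[["n_removed"]],
        tt[["n_prevalent"]]))
    nz <- object@counts[object@counts > 0]
    if (length(nz)) {
        cat("  prevalent architectures by pattern:\n")
        for (p in names(nz))
            cat(sprintf("    %-5s %6d (%5.1f%%)\n", p, nz[[p]],
                100 * object@percentages[[p]]))
    }
    cat(sprintf("  lineage-specific total: %d\n", tt[["n_lineage_specific"]]))
})

#' NormalizationSpec: dosage divisors for expansion testing
#'
#' Per-species divisors correct known annotation or recent-duplication biases
#' before any expansion test (canonically maize / 3 for its unmasked
#' annotation and soybean / 2 for its recent whole-genome duplication). The
#' optional WGD divisor models a return to a presumed pre-duplication
#' ancestral genome: it divides the dosage of a stated species set by
#' 2^rounds (canonically 8 for three rounds or 16 for four).
#'
#' @slot perSpeciesDivisor named numeric; species not listed divide by 1.
#' @slot wgdDivisor single positive numeric or `NA` (off).
#' @slot wgdSpecies species to which `wgdDivisor` applies.
#' @seealso [normalizationSpec()], [normalizeDosage()]
#' @export
setClass("NormalizationSpec",
    slots = c(perSpeciesDivisor = "numeric", wgdDivisor = "numeric",
              wgdSpecies = "character"))

setValidity("NormalizationSpec", function(object) {
    msg <- character()
    if (any(object@perSpeciesDivisor <= 0))
        msg <- c(msg, "per-species divisors must be positive")
    if (length(object@wgdDivisor) != 1L)
        msg <- c(msg, "wgdDivisor must be a single value (NA to disable)")
    else if (!is.na(object@wgdDivisor) && object@wgdDivisor <= 0)
        msg <- c(msg, "wgdDivisor must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a NormalizationSpec
#'
#' @param perSpeciesDivisor named numeric vector of per-species divisors
#'   (default none: every species divides by 1).
#' @param wgdDivisor single positive value, or `NA` to disable the
#'   whole-genome-duplication re-normalization.
#' @param wgdSpecies species ids the WGD divisor applies to.
#' @return A [NormalizationSpec-class].
#' @examples
#' normalizationSpec(c(Zm = 3, Gm = 2))
#' @export
normalizationSpec <- function(perSpeciesDivisor = numeric(0),
                              wgdDivisor = NA_real_,
                              wgdSpecies = character(0)) {
    new("NormalizationSpec", perSpeciesDivisor = perSpeciesDivisor,
        wgdDivisor = as.numeric(wgdDivisor), wgdSpecies = wgdSpecies)
}

setMethod("show", "NormalizationSpec", function(object) {
    cat("NormalizationSpec\n")
    if (length(object@perSpeciesDivisor))
        cat("  per-species divisors:",
            paste(names(object@perSpeciesDivisor), object@perSpeciesDivisor,
                  sep = "/", collapse = " "), "\n")
    else cat("  per-species divisors: none\n")
    if (!is.na(object@wgdDivisor))
        cat(sprintf("  WGD divisor %g on: %s\n", object@wgdDivisor,
            paste(object@wgdSpecies, collapse = " ")))
})

#' SimulationConfig: study conditions for the multi-genome simulator
#'
#' Full specification of a synthetic multi-genome content generation run.
#' See [simulationConfig()] for field semantics and defaults and
#' [simulateContent()] for the generative model.
#'
#' @slot scheme a [LineageScheme-class].
#' @slot patternMix named integer; planted architecture count per pattern.
#' @slot dosageModel list describing the per-cell copy-number distribution.
#' @slot expansionRules list of planted expansion rules.
#' @slot wgd list describing whole-genome duplication dosage inflation.
#' @slot dropoutProb per-cell probability of erasing presence.
#' @slot speciesSpecificRate number of unique architectures per species.
#' @slot domainPoolSize size of the shared domain-name pool.
#' @slot novelDomainFraction probability that an architecture confined to
#'   late lineages uses a reserved, newly-emerged domain namespace.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
    slots = c(scheme = "LineageScheme", patternMix = "integer",
              dosageModel = "list", expansionRules = "list", wgd = "list",
              dropoutProb = "numeric", speciesSpecificRate = "integer",
              domainPoolSize = "integer", novelDomainFraction = "numeric",
              seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    pats <- allPatterns(lineageLabels(object@scheme))
    if (length(object@patternMix)) {
        if (is.null(names(object@patternMix)) ||
            !all(names(object@patternMix) %in% pats))
            msg <- c(msg, "patternMix names must be valid lineage patterns")
        if (any(object@patternMix < 0)) msg <- c(msg, "patternMix counts must be >= 0")
    }
    if (object@dropoutProb < 0 || object@dropoutProb > 1)
        msg <- c(msg, "dropoutProb must be in [0, 1]")
    if (object@novelDomainFraction < 0 || object@novelDomainFraction > 1)
        msg <- c(msg, "novelDomainFraction must be in [0, 1]")
    if (object@speciesSpecificRate < 0) msg <- c(msg, "speciesSpecificRate must be >= 0")
    if (object@domainPoolSize < 3L) msg <- c(msg, "domainPoolSize too small")
    for (r in object@expansionRules) {
        if (!all(c("fraction", "targets", "fold") %in% names(r)))
            msg <- c(msg, "each expansion rule needs fraction, targets, fold")
        else {
            if (r$fraction < 0 || r$fraction > 1)
                msg <- c(msg, "expansion rule fraction must be in [0, 1]")
            if (r$fold <= 0) msg <- c(msg, "expansion rule fold must be > 0")
            if (!all(r$targets %in% lineageLabels(object@scheme)))
                msg <- c(msg, "expansion rule targets unknown lineage")
        }
    }
    if (length(object@wgd) &&
        !all(c("species", "rounds", "retention") %in% names(object@wgd)))
        msg <- c(msg, "wgd needs species, rounds, retention")
    if (length(object@wgd) &&
        (object@wgd$retention < 0 || object@wgd$retention > 1))
        msg <- c(msg, "wgd retention must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  %d planted architectures over %d patterns; %d species-specific per species\n",
        sum(object@patternMix), length(object@patternMix),
        object@speciesSpecificRate))
    cat(sprintf("  dosage model: %s; dropout %.3g; seed %d\n",
        object@dosageModel$type, object@dropoutProb, object@seed))
    if (length(object@expansionRules))
        cat(sprintf("  %d expansion rule(s)\n", length(object@expansionRules)))
    if (length(object@wgd))
        cat(sprintf("  WGD: %d round(s), retention %.2f on %s\n",
            object@wgd$rounds, object@wgd$retention,
            paste(object@wgd$species, collapse = " ")))
})
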