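#' Extract the genomic-dosage table of a content object
#'
#' The genomic dosage of a domain architecture is the number of proteins in a
#' genome bearing that architecture (its copy number). For a
#' [ProteomeContent-class] the dosage is a named integer vector over canonical
#' architecture strings; for an [ArchitectureContent-class] it is an
#' architecture-by-species integer matrix.
#'
#' @param x a `ProteomeContent` or `ArchitectureContent` object.
#' @return A named integer vector, or an integer matrix with architectures as
#'   rows and species as columns.
#' @examples
#' pc <- proteomeContent(c(p1 = "WD40(1)", p2 = "WD40(1)"), "At", 10L)
#' dosage(pc)
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Total proteome size(s) backing a content object
#'
#' @param x a `ProteomeContent` or `ArchitectureContent` object.
#' @return Integer count (per species for multi-genome content).
#' @export
setGeneric("nProteinsTotal", function(x) standardGeneric("nProteinsTotal"))

#' Species identifiers of a content object
#' @param x a content object.
#' @return Character vector of species ids.
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' Distinct canonical architecture strings of a content object
#' @param x a content object.
#' @return Character vector of canonical architecture strings.
#' @export
setGeneric("architectures", function(x) standardGeneric("architectures"))

#' Ordered lineage labels of a scheme
#' @param x a [LineageScheme-class].
#' @return Character vector of single-letter lineage labels, in scheme order.
#' @export
setGeneric("lineageLabels", function(x) standardGeneric("lineageLabels"))

#' Species membership of each lineage
#' @param x a [LineageScheme-class].
#' @return Named list mapping lineage label to its member species ids.
#' @export
setGeneric("lineageMembers", function(x) standardGeneric("lineageMembers"))

#' Majority-rule thresholds of each lineage
#' @param x a [LineageScheme-class].
#' @return Named integer vector: minimum number of member species that must
#'   carry an architecture for it to be majority-present in that lineage.
#' @export
setGeneric("lineageThresholds", function(x) standardGeneric("lineageThresholds"))

#' Map each species to its lineage
#' @param x a [LineageScheme-class].
#' @return Named character vector species id -> lineage label.
#' @export
setGeneric("speciesLineage", function(x) standardGeneric("speciesLineage"))

#' Per-pattern architecture counts of a pattern summary
#' @param x a [PatternSummary-class].
#' @return Named integer vector over the 15 non-empty lineage patterns.
#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))

#' Per-pattern shares of prevalent architectures
#' @param x a [PatternSummary-class].
#' @return Named numeric vector; shares of `nPrevalent`.
#' @export
setGeneric("patternPercentages", function(x) standardGeneric("patternPercentages"))

#' Bookkeeping totals of a pattern summary
#' @param x a [PatternSummary-class].
#' @return Named integer vector with elements `n_total`, `n_species_specific`,
#'   `n_shared`, `n_removed`, `n_prevalent`, `n_lineage_specific`.
#' @export
setGeneric("patternTotals", function(x) standardGeneric("patternTotals"))
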