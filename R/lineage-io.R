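#' @include AllClasses.R
NULL

#' Read / write a LineageScheme config file
#'
#' The config is YAML mapping each lineage label to a block with `species`
#' (list of species ids) and `majority` (the majority threshold):
#' \preformatted{
#' A:
#'   species: [Cr, Ol, Ot, Cv, Vc]
#'   majority: 3
#' B:
#'   species: [Pp, Sm]
#'   majority: 2
#' }
#' Lineage order in the file defines the scheme order.
#'
#' @param path path of the YAML file.
#' @return `readLineageScheme` returns a [LineageScheme-class];
#'   `writeLineageScheme` returns `path` invisibly.
#' @export
readLineageScheme <- function(path) {
    if (!file.exists(path)) stop("lineage scheme file not found: ", path)
    cfg <- yaml::read_yaml(path)
    labels <- names(cfg)
    members <- lapply(cfg, function(b) as.character(b$species))
    thresholds <- vapply(cfg, function(b) as.integer(b$majority), 0L)
    LineageScheme(labels, members, thresholds)
}

#' @rdname readLineageScheme
#' @param scheme a [LineageScheme-class].
#' @export
writeLineageScheme <- function(scheme, path) {
    cfg <- lapply(lineageLabels(scheme), function(l)
        list(species = lineageMembers(scheme)[[l]],
             majority = unname(lineageThresholds(scheme)[[l]])))
    names(cfg) <- lineageLabels(scheme)
    yaml::write_yaml(cfg, path)
    invisible(path)
}
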