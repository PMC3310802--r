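#' @include AllClasses.R
NULL

## Canonical architecture strings are maximal run-length encodings of the
## N->C domain order: "LysM(3) PKinase(1)" means three consecutive LysM
## instances followed by one PKinase. Adjacent runs always name distinct
## domains; "A B A" therefore stays three runs, never "A(2) B(1)".

.RUN_RE <- "^(.+)\\((\\d+)\\)$"

#' Parse a canonical architecture string into its runs
#'
#' @param x a single canonical architecture string, e.g. `"LysM(3) PKinase(1)"`.
#' @return A data.frame with columns `domain` (character) and `count`
#'   (integer), one row per run in N-to-C order.
#' @details The parser enforces the canonical-form invariants: every run
#'   count is at least 1 and adjacent runs name distinct domains (the
#'   run-length encoding is maximal). Strings violating either raise an
#'   error, so `parseArchitecture(architectureString(r))` round-trips.
#' @examples
#' parseArchitecture("LysM(3) PKinase(1)")
#' @seealso [architectureString()], [buildArchitecture()]
#' @export
parseArchitecture <- function(x) {
    stopifnot(is.character(x), length(x) == 1L, !is.na(x))
    toks <- strsplit(trimws(x), " +")[[1]]
    if (!length(toks)) stop("empty architecture string")
    m <- regmatches(toks, regexec(.RUN_RE, toks))
    bad <- lengths(m) != 3L
    if (any(bad))
        stop("malformed architecture token(s): ", paste(toks[bad], collapse = ", "))
    domain <- vapply(m, `[`, "", 2L)
    count <- as.integer(vapply(m, `[`, "", 3L))
    if (any(count < 1L)) stop("run counts must be >= 1")
    if (length(domain) > 1L && any(domain[-1L] == domain[-length(domain)]))
        stop("adjacent runs must name distinct domains (encoding not maximal): ", x)
    data.frame(domain = domain, count = count)
}

#' Assemble a canonical architecture string from runs
#'
#' @param runs data.frame with columns `domain` and `count` as returned by
#'   [parseArchitecture()].
#' @return Canonical architecture string.
#' @examples
#' architectureString(data.frame(domain = c("LysM", "PKinase"), count = c(3, 1)))
#' @export
architectureString <- function(runs) {
    stopifnot(is.data.frame(runs), all(c("domain", "count") %in% names(runs)),
              nrow(runs) >= 1L)
    if (any(runs$count < 1L)) stop("run counts must be >= 1")
    paste0(runs$domain, "(", as.integer(runs$count), ")", collapse = " ")
}

#' Total number of domain instances in an architecture
#'
#' Sums the run counts of each canonical string: `"LysM(3) PKinase(1)"` has
#' four domain instances. This instance count (not the number of runs)
#' defines the single- / double- / triple- / >=4-domain categories used in
#' genome profiling and the single- vs multi-domain split used in domain
#' novelty analysis.
#'
#' @param x character vector of canonical architecture strings.
#' @return Integer vector of domain-instance counts.
#' @examples
#' domainInstanceCount(c("WD40(1)", "LysM(3) PKinase(1)"))
#' @export
domainInstanceCount <- function(x) {
    stopifnot(is.character(x))
    counts <- regmatches(x, gregexpr("\\((\\d+)\\)", x))
    vapply(counts, function(cc) {
        if (!length(cc) || is.na(cc[1L])) stop("not a canonical architecture string")
        sum(as.integer(gsub("[()]", "", cc)))
    }, 0L)
}

#' Distinct domain names of architectures
#'
#' @param x character vector of canonical architecture strings.
#' @return A list (one element per string) of distinct domain names.
#' @examples
#' domainNames("LysM(3) PKinase(1) LysM(1)")
#' @export
domainNames <- function(x) {
    stopifnot(is.character(x))
    lapply(strsplit(trimws(x), " +"), function(toks)
        unique(sub(.RUN_RE, "\\1", toks)))
}

#' Does an architecture contain a given domain?
#'
#' @param x character vector of canonical architecture strings.
#' @param domain a single domain name (matched exactly, not as a substring
#'   of another name).
#' @return Logical vector.
#' @examples
#' containsDomain(c("WD40(2) SET(1)", "WD(1)"), "WD40")
#' @export
containsDomain <- function(x, domain) {
    stopifnot(is.character(domain), length(domain) == 1L, nzchar(domain))
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", domain)
    grepl(paste0("(^| )", esc, "\\("), x)
}

#' Build the canonical architecture of a single protein
#'
#' Orders the (non-overlapping, already filtered) domain hits of one protein
#' by alignment start and collapses consecutive identical domain names into
#' maximal runs, yielding the canonical N-to-C architecture string.
#'
#' @param hits data.frame of domain hits for one protein, with columns
#'   `protein_id`, `domain_name`, `ali_start` (any input order; sorting is
#'   internal).
#' @return Canonical architecture string.
#' @examples
#' h <- data.frame(protein_id = "p", domain_name = c("PKinase", "LysM", "LysM", "LysM"),
#'                 ali_start = c(200, 10, 60, 110))
#' buildArchitecture(h)  # "LysM(3) PKinase(1)"
#' @export
buildArchitecture <- function(hits) {
    if (!nrow(hits)) stop("a protein with no retained hits has no architecture")
    if (length(unique(hits$protein_id)) != 1L)
        stop("hits must all belong to one protein")
    dom <- hits$domain_name[order(hits$ali_start)]
    r <- rle(dom)
    architectureString(data.frame(domain = r$values, count = r$lengths))
}

#' Build canonical architectures for every protein in a hit table
#'
#' Vectorized counterpart of [buildArchitecture()] for a multi-protein hit
#' table (typically the output of [filterHits()]).
#'
#' @param hits data.frame of domain hits with columns `protein_id`,
#'   `domain_name`, `ali_start`.
#' @return Named character vector: protein id -> canonical architecture
#'   string, proteins in order of first appearance.
#' @export
buildArchitectures <- function(hits) {
    if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
    o <- order(match(hits$protein_id, unique(hits$protein_id)), hits$ali_start)
    pid <- hits$protein_id[o]
    dom <- hits$domain_name[o]
    n <- length(pid)
    newp <- c(TRUE, pid[-1L] != pid[-n])
    newrun <- newp | c(TRUE, dom[-1L] != dom[-n])
    runid <- cumsum(newrun)
    runstr <- paste0(dom[newrun], "(", tabulate(runid), ")")
    prot <- pid[newrun]
    out <- vapply(split(runstr, factor(prot, levels = unique(prot))),
                  paste, "", collapse = " ")
    out
}
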