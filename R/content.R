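#' @include architecture.R
NULL

#' Read a PfamScan-style domain hit table
#'
#' Parses the whitespace/tab-delimited per-domain output of a PfamScan-style
#' scan into a hit table. `#` comment lines and blank lines are ignored. The
#' column mapping is configurable; the default matches the classic
#' `pfam_scan.pl` layout (sequence id, alignment start/end, envelope
#' start/end, hmm accession, hmm name, ..., E-value in column 13).
#'
#' @param path path to the hit table.
#' @param speciesId species identifier attached to every hit.
#' @param columns named integer vector with elements `id`, `start`, `end`,
#'   `name`, `evalue` and optionally `accession` (use `NA` to skip the
#'   accession).
#' @return data.frame with columns `protein_id`, `species_id`, `domain_name`,
#'   `domain_accession`, `ali_start`, `ali_end`, `e_value`, one row per
#'   retained input row, in file order.
#' @details Rows whose mandatory columns are missing or unparsable (a
#'   non-numeric coordinate or E-value, `ali_start > ali_end`, a negative
#'   E-value) abort the read with an error naming the offending line
#'   number(s).
#' @seealso [filterHits()], [buildArchitectures()]
#' @export
readDomainHits <- function(path, speciesId,
                           columns = c(id = 1L, start = 2L, end = 3L,
                                       accession = 6L, name = 7L,
                                       evalue = 13L)) {
    if (!file.exists(path)) stop("input file not found: ", path)
    need <- c("id", "start", "end", "name", "evalue")
    if (!all(need %in% names(columns)))
        stop("columns must name id, start, end, name, evalue")
    lines <- readLines(path, warn = FALSE)
    lineno <- seq_along(lines)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]; lineno <- lineno[keep]
    if (!length(lines))
        return(data.frame(protein_id = character(0), species_id = character(0),
                          domain_name = character(0),
                          domain_accession = character(0),
                          ali_start = integer(0), ali_end = integer(0),
                          e_value = numeric(0)))
    fields <- strsplit(trimws(lines), "[ \t]+")
    maxcol <- max(columns[need], na.rm = TRUE)
    short <- lengths(fields) < maxcol
    if (any(short))
        stop("missing mandatory column(s) at line(s): ",
             paste(lineno[short], collapse = ", "))
    pick <- function(j) vapply(fields, `[`, "", j)
    suppressWarnings({
        ali_start <- as.numeric(pick(columns[["start"]]))
        ali_end <- as.numeric(pick(columns[["end"]]))
        e_value <- as.numeric(pick(columns[["evalue"]]))
    })
    bad <- is.na(ali_start) | is.na(ali_end) | is.na(e_value) |
        ali_start > ali_end | ali_start < 1 | e_value < 0
    if (any(bad))
        stop("unparsable or invalid row(s) at line(s): ",
             paste(lineno[bad], collapse = ", "))
    acc <- if (!is.na(columns["accession"]) && "accession" %in% names(columns))
        pick(columns[["accession"]]) else NA_character_
    data.frame(protein_id = pick(columns[["id"]]),
               species_id = speciesId,
               domain_name = pick(columns[["name"]]),
               domain_accession = acc,
               ali_start = as.integer(ali_start),
               ali_end = as.integer(ali_end),
               e_value = e_value)
}

#' Filter domain hits by E-value and resolve overlaps
#'
#' Applies the per-domain E-value cutoff (default 1e-2) and then, among
#' retained hits of the same protein whose alignment intervals overlap by at
#' least one residue, keeps only the hit with the smallest E-value (ties
#' broken by smaller `ali_start`, then lexicographically smaller
#' `domain_name`). The result is sorted by `(protein_id, ali_start)` and is
#' guaranteed non-overlapping within each protein, which makes
#' [buildArchitecture()] deterministic. The operation is idempotent.
#'
#' @param hits hit table as returned by [readDomainHits()].
#' @param eCutoff non-negative E-value threshold; hits with
#'   `e_value <= eCutoff` are retained.
#' @return Filtered hit table.
#' @export
filterHits <- function(hits, eCutoff = 1e-2) {
    if (!is.numeric(eCutoff) || length(eCutoff) != 1L || is.na(eCutoff) ||
        eCutoff < 0)
        stop("eCutoff must be a single non-negative number")
    h <- hits[hits$e_value <= eCutoff, , drop = FALSE]
    if (!nrow(h)) {
        rownames(h) <- NULL
        return(h)
    }
    h <- h[order(h$protein_id, h$ali_start, h$ali_end, h$domain_name), ,
           drop = FALSE]
    ## fast path: detect proteins containing any overlapping pair, using a
    ## segmented (per-protein) running max of alignment ends
    n <- nrow(h)
    newp <- !duplicated(h$protein_id)
    g <- cumsum(newp)
    big <- max(h$ali_end) + 1
    runmax <- cummax(g * big + h$ali_end) - g * big
    prevmax <- c(-Inf, runmax[-n])
    prevmax[newp] <- -Inf
    overlapping <- h$ali_start <= prevmax
    if (any(overlapping)) {
        bad <- unique(h$protein_id[overlapping])
        fix <- h$protein_id %in% bad
        resolved <- do.call(rbind, lapply(split(h[fix, , drop = FALSE],
                                                h$protein_id[fix]),
                                          .resolveOverlaps))
        h <- rbind(h[!fix, , drop = FALSE], resolved)
        h <- h[order(h$protein_id, h$ali_start), , drop = FALSE]
    }
    rownames(h) <- NULL
    h
}

## greedy best-E-value-first acceptance within one protein
.resolveOverlaps <- function(hp) {
    o <- order(hp$e_value, hp$ali_start, hp$domain_name)
    hp <- hp[o, , drop = FALSE]
    starts <- ends <- numeric(0)
    take <- logical(nrow(hp))
    for (i in seq_len(nrow(hp))) {
        s <- hp$ali_start[i]; e <- hp$ali_end[i]
        if (!any(s <= ends & e >= starts)) {
            take[i] <- TRUE
            starts <- c(starts, s); ends <- c(ends, e)
        }
    }
    hp[take, , drop = FALSE]
}

#' Aggregate per-protein architectures into one proteome's content
#'
#' @param architectures named character vector mapping protein id to
#'   canonical architecture string (typically from [buildArchitectures()]).
#' @param speciesId species identifier.
#' @param nProteinsTotal total proteome size; must be at least the number of
#'   predicted proteins.
#' @return A [ProteomeContent-class] whose dosage counts proteins per
#'   canonical string.
#' @examples
#' proteomeContent(c(p1 = "WD40(1)", p2 = "WD40(1)", p3 = "SET(1)"), "At", 5L)
#' @export
proteomeContent <- function(architectures, speciesId, nProteinsTotal) {
    if (anyDuplicated(names(architectures)))
        stop("duplicate protein_id in architectures")
    if (length(architectures) && is.null(names(architectures)))
        stop("architectures must be named by protein id")
    d <- if (length(architectures)) {
        tab <- table(architectures)
        stats::setNames(as.integer(tab), names(tab))[order(names(tab))]
    } else stats::setNames(integer(0), character(0))
    new("ProteomeContent", speciesId = speciesId,
        nProteinsTotal = as.integer(nProteinsTotal), dosage = d,
        proteinArchitectures = architectures)
}

#' Merge per-species proteome contents into a multi-genome matrix
#'
#' Takes the union of all architectures across species and fills the
#' architecture-by-species dosage matrix, zero where a species lacks an
#' architecture. Per-species column sums are preserved exactly.
#'
#' @param contents list of [ProteomeContent-class] objects with distinct
#'   species ids.
#' @return An [ArchitectureContent-class].
#' @export
mergeContent <- function(contents) {
    stopifnot(length(contents) >= 1L)
    sp <- vapply(contents, speciesIds, "")
    if (anyDuplicated(sp)) stop("duplicate species_id in contents")
    archs <- sort(unique(unlist(lapply(contents, architectures))))
    m <- matrix(0L, nrow = length(archs), ncol = length(sp),
                dimnames = list(archs, sp))
    for (i in seq_along(contents)) {
        d <- dosage(contents[[i]])
        m[names(d), i] <- d
    }
    ArchitectureContent(m, stats::setNames(
        vapply(contents, nProteinsTotal, 0L), sp))
}

#' Reconstruct a proteome version from annotation deltas
#'
#' Given the architecture content of one annotation version together with the
#' content of architectures newly added in that version and of architectures
#' deleted from the previous version, reconstructs the previous version by
#' elementwise dosage arithmetic: `previous = current - added + deleted`.
#' Architectures whose dosage reaches zero are dropped; a subtraction below
#' zero signals inconsistent inputs and aborts with the offending
#' architecture named. When no dosage hits zero the operation is reversible:
#' `annotationDelta(annotationDelta(x, a, d), d, a)` restores `x`.
#'
#' @param content [ProteomeContent-class] of the current annotation version.
#' @param added content of architectures added in the current version.
#' @param deleted content of architectures deleted since the previous version.
#' @return A [ProteomeContent-class] for the reconstructed previous version
#'   (protein-level assignments are not carried over).
#' @export
annotationDelta <- function(content, added, deleted) {
    ids <- c(speciesIds(content), speciesIds(added), speciesIds(deleted))
    if (length(unique(ids)) != 1L)
        stop("content, added and deleted must refer to the same species")
    d <- dosage(content)
    a <- dosage(added)
    dl <- dosage(deleted)
    archs <- sort(unique(c(names(d), names(a), names(dl))))
    get0i <- function(v) {
        out <- stats::setNames(integer(length(archs)), archs)
        out[names(v)] <- v
        out
    }
    mid <- get0i(d) - get0i(a)
    if (any(mid < 0L))
        stop("dosage below zero for architecture(s): ",
             paste(archs[mid < 0L], collapse = ", "))
    res <- mid + get0i(dl)
    res <- res[res > 0L]
    nt <- nProteinsTotal(content) - sum(a) + sum(dl)
    new("ProteomeContent", speciesId = speciesIds(content),
        nProteinsTotal = as.integer(nt), dosage = res,
        proteinArchitectures = stats::setNames(character(0), character(0)))
}

#' Write / read a multi-genome dosage matrix as TSV
#'
#' The matrix is written as a TSV with architectures as the first column and
#' one integer column per species; per-species proteome totals go to a
#' sidecar JSON file.
#'
#' @param x an [ArchitectureContent-class].
#' @param file TSV path.
#' @param totalsFile path of the sidecar JSON of proteome totals; defaults to
#'   `<file>.totals.json`.
#' @return `writeContent` returns `file` invisibly; `readContent` returns an
#'   [ArchitectureContent-class].
#' @export
writeContent <- function(x, file, totalsFile = paste0(file, ".totals.json")) {
    d <- dosage(x)
    df <- data.frame(architecture = rownames(d), d, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(nProteinsTotal(x)), totalsFile,
                         auto_unbox = TRUE)
    invisible(file)
}

#' @rdname writeContent
#' @export
readContent <- function(file, totalsFile = paste0(file, ".totals.json")) {
    df <- utils::read.delim(file, check.names = FALSE,
                            colClasses = "character")
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1L]]
    totals <- unlist(jsonlite::read_json(totalsFile))
    ArchitectureContent(m, stats::setNames(as.integer(totals), names(totals)))
}
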