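## shared in-code fixtures; everything is generated, nothing is stored

scheme14 <- defaultLineageScheme()
species14 <- unlist(lineageMembers(scheme14), use.names = FALSE)

## content object from a bare dosage matrix; totals default to 2x predicted
contentFromMatrix <- function(m, totals = NULL) {
    storage.mode(m) <- "integer"
    if (is.null(totals))
        totals <- stats::setNames(pmax(2L * colSums(m), 1L), colnames(m))
    ArchitectureContent(m, totals)
}

## random multi-genome fixture over the 14-species scheme
randomContent <- function(seed, nArch = 25L, zeroProb = 0.5, maxDosage = 6L) {
    set.seed(seed)
    m <- matrix(
        ifelse(stats::runif(nArch * 14) < zeroProb, 0L,
               sample.int(maxDosage, nArch * 14, replace = TRUE)),
        nrow = nArch, ncol = 14,
        dimnames = list(sprintf("DOM%03d(1)", seq_len(nArch)), species14))
    m[rowSums(m) == 0, 1L] <- 1L     # keep every architecture somewhere
    contentFromMatrix(m)
}

## a small hit table as a data.frame (already parsed)
hitRow <- function(protein, domain, start, end, e, species = "sp1") {
    data.frame(protein_id = protein, species_id = species,
               domain_name = domain, domain_accession = NA_character_,
               ali_start = as.integer(start), ali_end = as.integer(end),
               e_value = e)
}

## write a 13-column PfamScan-style file from (id, start, end, name, evalue)
writePfamFixture <- function(rows, path) {
    lines <- vapply(rows, function(r)
        paste(r$id, r$start, r$end, r$start, r$end, paste0("SYN_", r$name),
              r$name, "Domain", 1, 50, 50, 100.0, r$e, sep = "\t"), "")
    writeLines(c("# synthetic fixture", lines), path)
    path
}
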