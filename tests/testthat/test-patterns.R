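## convenience: content with one architecture present in the given species
presenceContent <- function(..., extra = NULL) {
    archs <- list(...)
    m <- matrix(0L, length(archs) + length(extra), 14,
                dimnames = list(c(sprintf("ARC%02d(1)", seq_along(archs)),
                                  names(extra)), species14))
    for (i in seq_along(archs)) m[i, archs[[i]]] <- 1L
    for (nm in names(extra)) m[nm, extra[[nm]]] <- 1L
    contentFromMatrix(m)
}

test_that("species-specific architectures are split out by definition", {
    ct <- presenceContent(c("Gm"), c("Pp", "Sm"), c("Cr", "Os"))
    sp <- splitSpeciesSpecific(ct)
    expect_equal(sp$species_specific, "ARC01(1)")
    expect_setequal(sp$shared, c("ARC02(1)", "ARC03(1)"))
})

test_that("planted species-specific rate is recovered exactly", {
    set.seed(23)
    n <- 50
    planted <- sort(sample(n, 20))
    m <- matrix(0L, n, 14, dimnames = list(sprintf("A%03d(1)", 1:n), species14))
    for (i in 1:n) {
        k <- if (i %in% planted) 1L else sample(2:14, 1)
        m[i, sample(14, k)] <- 1L
    }
    sp <- splitSpeciesSpecific(contentFromMatrix(m))
    expect_setequal(sp$species_specific, sprintf("A%03d(1)", planted))
})

test_that("lineage presence counts and majority flags follow thresholds", {
    ct <- presenceContent(
        c("Cr", "Ol", "Ot"),          # 3/5 algae -> majority
        c("Pp"),                      # 1/2 early-diverging -> no majority
        c("Vv", "At"))                # 2/4 dicots -> no majority (needs 3)
    asg <- assignPatterns(ct, scheme14)
    expect_equal(asg$presence_A, c(3L, 0L, 0L))
    expect_equal(asg$majority_A, c(TRUE, FALSE, FALSE))
    expect_equal(asg$majority_B, c(FALSE, FALSE, FALSE))
    expect_equal(asg$presence_D, c(0L, 0L, 2L))
    expect_equal(asg$majority_D, c(FALSE, FALSE, FALSE))
})

test_that("species not covered by the scheme raise a config error", {
    m <- matrix(1L, 1, 2, dimnames = list("A(1)", c("Cr", "XX")))
    expect_error(assignPatterns(contentFromMatrix(m), scheme14),
                 "missing.*XX")
})

test_that("strict prevalence removes architectures failing any occupied lineage", {
    ct <- presenceContent(
        ## majorities in A, B, C but a single dicot carrier: removed entirely
        c("Cr", "Ol", "Ot", "Pp", "Sm", "Os", "Zm", "Gm"),
        ## 3/5 algae and nowhere else: prevalent, pattern A
        c("Cr", "Ol", "Ot"),
        ## 1 alga + 1 monocot: fails the majority everywhere it occurs
        c("Cr", "Os"))
    asg <- assignPatterns(ct, scheme14)
    expect_equal(as.character(asg$status),
                 c("removed_less_common", "prevalent", "removed_less_common"))
    expect_equal(asg$pattern, c(NA, "A", NA))
    ## the alternative majority-only rule re-patterns instead of removing
    asg2 <- assignPatterns(ct, scheme14, prevalence = "majority")
    expect_equal(as.character(asg2$status[1]), "prevalent")
    expect_equal(asg2$pattern[1], "ABC")
})

test_that("pattern labels concatenate majority lineages in scheme order", {
    lab <- c("A", "B", "C", "D")
    expect_equal(classifyPattern(c(TRUE, TRUE, TRUE, TRUE), lab), "ABCD")
    expect_equal(classifyPattern(c(FALSE, TRUE, TRUE, TRUE), lab), "BCD")
    expect_equal(classifyPattern(c(FALSE, TRUE, FALSE, TRUE), lab), "BD")
    expect_error(classifyPattern(c(FALSE, FALSE, FALSE, FALSE), lab),
                 "undefined")
    expect_equal(length(allPatterns(lab)), 15L)
})

test_that("pattern summaries conserve the partition totals", {
    sim <- simulateContent(simulationConfig(
        patternMix = c(ABCD = 12L, BCD = 5L, A = 3L, CD = 2L),
        speciesSpecificRate = 2L, seed = 19L))
    asg <- assignPatterns(sim$content, scheme14)
    s <- summarizePatterns(asg)
    tt <- patternTotals(s)
    expect_equal(tt[["n_prevalent"]], sum(patternCounts(s)))
    expect_equal(tt[["n_species_specific"]] + tt[["n_shared"]], tt[["n_total"]])
    expect_equal(tt[["n_removed"]] + tt[["n_prevalent"]], tt[["n_shared"]])
    ## dropout 0: planted counts recovered exactly
    expect_equal(patternCounts(s)[["ABCD"]], 12L)
    expect_equal(patternCounts(s)[["BCD"]], 5L)
    expect_equal(patternCounts(s)[["A"]], 3L)
    expect_equal(patternCounts(s)[["CD"]], 2L)
    expect_equal(tt[["n_lineage_specific"]], 3L)
    expect_equal(sum(patternPercentages(s)), 1)
})

test_that("the three statuses partition every random fixture", {
    for (seed in 1:40) {
        ct <- randomContent(seed, nArch = 30L)
        asg <- assignPatterns(ct, scheme14)
        expect_equal(sum(table(asg$status)), nrow(dosage(ct)))
        s <- summarizePatterns(asg)
        tt <- patternTotals(s)
        expect_equal(tt[["n_species_specific"]] + tt[["n_removed"]] +
                     tt[["n_prevalent"]], tt[["n_total"]])
        ## prevalent architectures meet the majority rule wherever they occur
        prev <- asg[asg$status == "prevalent", ]
        for (l in c("A", "B", "C", "D")) {
            occ <- prev[[paste0("presence_", l)]] > 0
            expect_true(all(prev[[paste0("majority_", l)]][occ]))
        }
    }
})

test_that("adding a species occurrence never removes a pattern lineage", {
    set.seed(77)
    for (i in 1:15) {
        ct <- randomContent(i + 100, nArch = 20L)
        asg <- assignPatterns(ct, scheme14)
        prev <- which(asg$status == "prevalent")
        if (!length(prev)) next
        k <- prev[1]
        m <- dosage(ct)
        absent <- which(m[k, ] == 0)
        if (!length(absent)) next
        m[k, sample(absent, 1)] <- 1L
        asg2 <- assignPatterns(contentFromMatrix(m), scheme14)
        if (asg2$status[k] == "prevalent") {
            old <- strsplit(asg$pattern[k], "")[[1]]
            new <- strsplit(asg2$pattern[k], "")[[1]]
            expect_true(all(old %in% new))
        }
    }
})

test_that("domain subsets restrict the summary to matching architectures", {
    m <- matrix(0L, 4, 14, dimnames = list(
        c("WD40(1)", "WD40(1) SET(1)", "PK(1)", "WD40(2)"), species14))
    m[1, ] <- 1L                                   # universal
    m[2, ] <- 1L                                   # universal
    m[3, c("Os", "Zm", "Sb")] <- 1L                # monocot
    m[4, c("Cr", "Os")] <- 1L                      # fails majorities: removed
    asg <- assignPatterns(contentFromMatrix(m), scheme14)
    sub <- subsetByDomain(asg, "WD40")
    expect_equal(patternCounts(sub$prevalent)[["ABCD"]], 2L)
    expect_equal(sum(patternCounts(sub$prevalent)), 2L)
    expect_equal(sum(sub$overall_counts), 3L)      # removed arch still counted
    none <- subsetByDomain(asg, "ZNF")
    expect_equal(sum(patternCounts(none$prevalent)), 0L)
    expect_equal(sum(none$overall_counts), 0L)
})
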