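test_that("readDomainHits parses PfamScan-style tables", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(character(0), tmp)
    expect_equal(nrow(readDomainHits(tmp, "sp")), 0L)

    writePfamFixture(list(
        list(id = "p1", start = 10, end = 44, name = "LysM", e = "1e-9"),
        list(id = "p1", start = 60, end = 100, name = "LysM", e = "2e-5"),
        list(id = "p2", start = 5, end = 40, name = "WD40", e = "1e-3")), tmp)
    h <- readDomainHits(tmp, "At")
    expect_equal(nrow(h), 3L)
    expect_equal(h$ali_start, c(10L, 60L, 5L))
    expect_equal(h$ali_end, c(44L, 100L, 40L))
    expect_equal(h$domain_name, c("LysM", "LysM", "WD40"))
    expect_equal(h$species_id, rep("At", 3))
    expect_equal(h$e_value, c(1e-9, 2e-5, 1e-3))
})

test_that("readDomainHits reports malformed rows by line number", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writePfamFixture(list(
        list(id = "p1", start = 10, end = 44, name = "LysM", e = "1e-9"),
        list(id = "p2", start = 5, end = 40, name = "WD40", e = "NA")), tmp)
    expect_error(readDomainHits(tmp, "At"), "line.*3")
    expect_error(readDomainHits(file.path(tempdir(), "nope.tsv"), "At"),
                 "not found")
    ## start > end is invalid too
    writePfamFixture(list(
        list(id = "p1", start = 44, end = 10, name = "LysM", e = "1e-9")), tmp)
    expect_error(readDomainHits(tmp, "At"), "line.*2")
})

test_that("readDomainHits honors custom column mappings", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("# five-column layout", "p1\t10\t44\tLysM\t1e-9"), tmp)
    h <- readDomainHits(tmp, "At",
                        columns = c(id = 1, start = 2, end = 3, name = 4,
                                    evalue = 5, accession = NA))
    expect_equal(h$domain_name, "LysM")
    expect_equal(h$e_value, 1e-9)
})

test_that("filterHits applies the E-value cutoff", {
    h <- rbind(hitRow("p", "A", 1, 50, 0.5),
               hitRow("p", "B", 60, 100, 1e-3),
               hitRow("p", "C", 120, 150, 1e-2))
    f <- filterHits(h)
    expect_equal(f$domain_name, c("B", "C"))   # 0.5 removed, 1e-2 kept
    expect_error(filterHits(h, -1), "non-negative")
})

test_that("filterHits keeps the best hit among overlapping ones", {
    h <- rbind(hitRow("p", "A", 10, 100, 1e-5),
               hitRow("p", "B", 50, 120, 1e-3))
    f <- filterHits(h)
    expect_equal(f$domain_name, "A")
    ## nested hit fully inside another
    h2 <- rbind(hitRow("p", "A", 10, 200, 1e-3),
                hitRow("p", "B", 50, 80, 1e-8))
    expect_equal(filterHits(h2)$domain_name, "B")
    ## different proteins never interact
    h3 <- rbind(hitRow("p1", "A", 10, 100, 1e-5),
                hitRow("p2", "B", 50, 120, 1e-3))
    expect_equal(nrow(filterHits(h3)), 2L)
})

test_that("filterHits is idempotent and returns sorted output", {
    set.seed(13)
    for (i in 1:20) {
        n <- sample(3:12, 1)
        h <- do.call(rbind, lapply(seq_len(n), function(j) {
            s <- sample(1:500, 1)
            hitRow(paste0("p", sample(1:3, 1)), sample(LETTERS[1:5], 1),
                   s, s + sample(20:120, 1), 10^stats::runif(1, -10, 0))
        }))
        f1 <- filterHits(h)
        f2 <- filterHits(f1)
        expect_equal(f1, f2)
        expect_equal(order(f1$protein_id, f1$ali_start), seq_len(nrow(f1)))
        ## non-overlap within protein after filtering
        for (p in unique(f1$protein_id)) {
            fp <- f1[f1$protein_id == p, ]
            if (nrow(fp) > 1L)
                expect_true(all(fp$ali_start[-1] > cummax(fp$ali_end)[-nrow(fp)]))
        }
    }
})

test_that("proteomeContent counts proteins per canonical string", {
    pc <- proteomeContent(c(p1 = "WD40(1)", p2 = "WD40(1)"), "At", 10L)
    expect_equal(dosage(pc), c("WD40(1)" = 2L))
    empty <- proteomeContent(stats::setNames(character(0), character(0)),
                             "At", 10L)
    expect_equal(length(dosage(empty)), 0L)
    expect_error(proteomeContent(c(p1 = "A(1)", p1 = "B(1)"), "At", 10L),
                 "duplicate")
})

test_that("proteome dosage conserves the predicted-protein count", {
    set.seed(29)
    archs <- sprintf("DOM%02d(1)", 1:7)
    assign <- stats::setNames(sample(archs, 100, replace = TRUE),
                              sprintf("p%03d", 1:100))
    pc <- proteomeContent(assign, "Os", 150L)
    ## independent tally over the fixture
    expect_equal(sum(dosage(pc)), 100L)
    for (a in archs)
        expect_equal(unname(dosage(pc)[a]), sum(assign == a))
})

test_that("mergeContent unions architectures and preserves column sums", {
    p1 <- proteomeContent(c(x1 = "A(1)", x2 = "B(1)"), "s1", 4L)
    p2 <- proteomeContent(c(y1 = "C(1)", y2 = "C(1)"), "s2", 5L)
    mc <- mergeContent(list(p1, p2))
    d <- dosage(mc)
    expect_setequal(rownames(d), c("A(1)", "B(1)", "C(1)"))
    expect_equal(d["C(1)", "s1"], 0L)       # disjoint sets give zero blocks
    expect_equal(unname(colSums(d)), c(2L, 2L))
    single <- mergeContent(list(p1))
    expect_equal(dosage(single)[, "s1"], dosage(p1)[rownames(dosage(single))])
    expect_error(mergeContent(list(p1, p1)), "duplicate")
})

test_that("merged distinct-architecture count equals the set union", {
    set.seed(31)
    contents <- lapply(species14, function(sp) {
        archs <- sprintf("DOM%02d(1)", sample(1:40, sample(5:15, 1)))
        n <- length(archs)
        proteomeContent(stats::setNames(archs, sprintf("%s_p%d", sp, 1:n)),
                        sp, 50L)
    })
    mc <- mergeContent(contents)
    un <- unique(unlist(lapply(contents, architectures)))
    expect_equal(nrow(dosage(mc)), length(un))
    expect_equal(unname(colSums(dosage(mc))),
                 vapply(contents, function(p) sum(dosage(p)), 0L))
})

test_that("annotationDelta reconstructs previous annotation versions", {
    cur <- proteomeContent(stats::setNames(rep("X(1)", 3), paste0("p", 1:3)),
                           "At", 10L)
    addOne <- proteomeContent(c(q1 = "X(1)"), "At", 1L)
    delTwo <- proteomeContent(c(r1 = "Y(1)", r2 = "Y(1)"), "At", 2L)
    prev <- annotationDelta(cur, addOne, delTwo)
    expect_equal(dosage(prev), c("X(1)" = 2L, "Y(1)" = 2L))

    none <- proteomeContent(stats::setNames(character(0), character(0)), "At", 0L)
    same <- annotationDelta(cur, none, none)
    expect_equal(dosage(same), dosage(cur))

    tooMany <- proteomeContent(stats::setNames(rep("X(1)", 5), paste0("q", 1:5)),
                               "At", 5L)
    expect_error(annotationDelta(cur, tooMany, none), "X\\(1\\)")
})

test_that("annotationDelta is an involution on reversible deltas", {
    cur <- proteomeContent(
        stats::setNames(c(rep("X(1)", 4), rep("Z(2)", 2)), paste0("p", 1:6)),
        "At", 20L)
    a <- proteomeContent(c(a1 = "X(1)"), "At", 1L)
    d <- proteomeContent(c(d1 = "W(1)"), "At", 1L)
    back <- annotationDelta(annotationDelta(cur, a, d), d, a)
    expect_equal(dosage(back), dosage(cur))
    expect_equal(nProteinsTotal(back), nProteinsTotal(cur))
})

test_that("dosage matrices survive a TSV round trip", {
    ct <- randomContent(3)
    dirL <- withr::local_tempdir()
    f <- file.path(dirL, "dosage.tsv")
    writeContent(ct, f)
    back <- readContent(f)
    expect_equal(dosage(back), dosage(ct))
    expect_equal(nProteinsTotal(back), nProteinsTotal(ct))
})
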