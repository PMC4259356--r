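# Ortholog harmonization, the combined transcriptome, concordance, the
# subtraction ledger and Venn partitions.

test_that("symbols are harmonized by the case convention with logging", {
    map <- orthologMap(c("Postn", "Epha3", "Fscn1"))
    sig <- geneSignature("s", species = "mouse", symbols = c("Postn", "Epha3"))
    hs <- harmonizeSymbols(sig, map, "human")
    expect_identical(signatureSymbols(hs), c("POSTN", "EPHA3"))
    back <- harmonizeSymbols(hs, map, "mouse")
    expect_identical(signatureSymbols(back), c("Postn", "Epha3"))

    sigU <- geneSignature("u", species = "human",
                          symbols = c("POSTN", "NOTINMAP"))
    expect_message(hm <- harmonizeSymbols(sigU, map, "mouse"), "1/2")
    expect_identical(signatureSymbols(hm), "Postn")
    expect_identical(attr(hm, "unmapped"), "NOTINMAP")
})

test_that("ortholog collisions resolve to a single canonical pair", {
    map <- orthologMap(c("Abc1", "ABC1", "Xyz2"))
    expect_identical(sum(map$human == "ABC1"), 1L)
    expect_identical(attr(map, "collisions"), "ABC1")
    expect_identical(map$mouse[map$human == "ABC1"], "Abc1")
})

test_that("the common/unique partition reproduces the two-model counts", {
    # list sizes 654 and 583 with a 321-gene intersection must leave 333 and
    # 262 unique genes
    all <- sprintf("g%04d", 1:916)
    aGenes <- all[1:654]
    bGenes <- all[c(1:321, 655:916)]
    mk <- function(genes) S4Vectors::DataFrame(
        gene = genes, log2fc = 1, direction = 1L)
    obb <- buildObbmst(mk(aGenes), mk(bGenes), "C4-2B", "VCaP")
    expect_identical(nrow(obb@listA), 654L)
    expect_identical(nrow(obb@listB), 583L)
    expect_identical(nrow(obb@common), 321L)
    expect_identical(length(obb@uniqueA), 333L)
    expect_identical(length(obb@uniqueB), 262L)
    expect_identical(length(obbmstGenes(obb)), 916L)
})

test_that("identical lists give all-common, R^2 = 1 and no discordance", {
    d <- S4Vectors::DataFrame(gene = sprintf("g%02d", 1:30),
                              log2fc = rnorm(30), direction = 1L)
    obb <- buildObbmst(d, d)
    expect_identical(nrow(obb@common), 30L)
    expect_identical(length(obb@uniqueA), 0L)
    expect_equal(obb@r2, 1)
    expect_false(any(obb@common$discordant))
})

test_that("direction disagreements are flagged, not removed", {
    a <- S4Vectors::DataFrame(gene = c("g1", "g2"), log2fc = c(2, 1),
                              direction = c(1L, 1L))
    b <- S4Vectors::DataFrame(gene = c("g1", "g2", "g3"),
                              log2fc = c(-2, 1, 1),
                              direction = c(-1L, 1L, 1L))
    obb <- buildObbmst(a, b)
    expect_identical(nrow(obb@common), 2L)
    expect_identical(obb@common$discordant, c(TRUE, FALSE))
})

test_that("random lists partition exactly as brute-force set enumeration", {
    set.seed(12)
    pool <- sprintf("g%03d", 1:120)
    for (rep in 1:5) {
        a <- sample(pool, 50); b <- sample(pool, 50)
        mk <- function(g) S4Vectors::DataFrame(gene = g, log2fc = 1,
                                               direction = 1L)
        obb <- buildObbmst(mk(a), mk(b))
        common <- pool[vapply(pool, function(g)
            (g %in% a) && (g %in% b), logical(1))]
        expect_setequal(obb@common$gene, common)
        expect_setequal(obb@uniqueA, setdiff(a, common))
        expect_setequal(obb@uniqueB, setdiff(b, common))
    }
})

test_that("concordance R^2 and slope sign behave on exact lines", {
    x <- c(-2, -1, 0.5, 1, 3)
    expect_equal(concordanceR2(x, x), list(r2 = 1, slopeSign = 1))
    expect_equal(concordanceR2(x, -x), list(r2 = 1, slopeSign = -1))
    expect_error(concordanceR2(1:2, 1:2), "length")
})

test_that("curation conserves the start set and respects the order", {
    start <- sprintf("g%03d", 1:100)
    sigs <- list(
        geneSignature("infl", category = "inflammatory",
                      symbols = c(start[1:10], "x1")),
        geneSignature("wound", category = "wound",
                      symbols = c(start[8:14], "x2")),
        geneSignature("gastric", category = "non-osteotropic",
                      symbols = c(start[12:20], "x3")),
        geneSignature("mca", category = "osteotropic",
                      symbols = c(start[18:25], "x4")))
    led <- curate(start, sigs)
    comp <- ledgerComponents(led)
    # stage 1 swallows inflammatory + wound, later stages only what remains
    expect_identical(comp[["inflammatory-shared"]], start[1:14])
    expect_identical(comp[["universal"]], start[15:20])
    expect_identical(comp[["osteotropic"]], start[21:25])
    expect_identical(comp$core, start[26:100])
    expect_equal(sum(ledgerFractions(led)), 1)
    expect_identical(sort(unlist(comp, use.names = FALSE)), sort(start))

    # reversing the order changes components but not their union or the core
    led2 <- curate(start, sigs,
                   order = c("osteotropic", "non-osteotropic",
                             "inflammatory"))
    expect_identical(ledgerComponents(led2)$core, comp$core)
    expect_identical(ledgerComponents(led2)$osteotropic, start[18:25])
    expect_setequal(unlist(ledgerComponents(led2), use.names = FALSE),
                    unlist(comp, use.names = FALSE))

    # registry disjoint from the start set: everything is core
    ledNone <- curate(start, list(geneSignature("d", category = "osteotropic",
                                                symbols = "zzz")))
    expect_identical(ledgerComponents(ledNone)$core, sort(start))
    expect_error(curate(start, sigs, order = c("inflammatory", "bogus")),
                 "unknown")
})

test_that("curation ledgers survive a JSON round trip", {
    start <- sprintf("g%03d", 1:40)
    led <- curate(start, list(
        geneSignature("infl", category = "inflammatory",
                      symbols = start[1:5])))
    path <- tempfile(fileext = ".json")
    writeCurationLedger(led, path, tsvPath = tempfile(fileext = ".tsv"))
    back <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_identical(sort(back$components$core),
                     ledgerComponents(led)$core)
    expect_identical(back$stages$inflammatory$n_removed, 5L)
})

test_that("Venn regions equal the exhaustive membership tally", {
    expect_identical(vennPartition(list(A = c("a", "b"), B = c("a", "b"))),
                     c("A&B" = 2L))
    disj <- vennPartition(list(A = "a", B = "b", C = "c", D = "d"))
    expect_identical(sort(names(disj)), c("A", "B", "C", "D"))
    expect_true(all(disj == 1L))

    set.seed(13)
    pool <- sprintf("s%03d", 1:80)
    sets <- lapply(1:4, function(i) sample(pool, 30))
    names(sets) <- LETTERS[1:4]
    venn <- vennPartition(sets)
    expect_identical(sum(venn), length(unique(unlist(sets))))
    # brute force: classify every symbol by its membership vector
    for (sym in unique(unlist(sets))) {
        label <- paste(names(sets)[vapply(sets, function(s) sym %in% s,
                                          logical(1))], collapse = "&")
        expect_true(venn[[label]] >= 1L)
    }
    tally <- table(vapply(unique(unlist(sets)), function(sym)
        paste(names(sets)[vapply(sets, function(s) sym %in% s, logical(1))],
              collapse = "&"), character(1)))
    expect_identical(venn[sort(names(venn))],
                     stats::setNames(as.integer(tally), names(tally))[
                         sort(names(venn))])
})

test_that("GMT files round-trip signatures with species and category", {
    sigs <- list(
        a = geneSignature("a", species = "human", category = "inflammatory",
                          symbols = c("POSTN", "ASPN")),
        b = geneSignature("b", species = "mouse", category = "niche-HSC",
                          symbols = c("Ptn", "Epha3", "Tek")))
    path <- tempfile(fileext = ".gmt")
    writeGMT(sigs, path)
    back <- readGMT(path)
    expect_identical(names(back), c("a", "b"))
    expect_identical(signatureSymbols(back$a), c("POSTN", "ASPN"))
    expect_identical(back$b@species, "mouse")
    expect_identical(back$b@category, "niche-HSC")
})
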