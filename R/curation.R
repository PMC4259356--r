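## Ortholog harmonization, the combined two-model stroma transcriptome,
## cross-model concordance, sequential signature-subtraction curation, and
## Venn partitioning. Subtraction matches gene identity only (direction
## disagreements are logged, not filtered). The curation order is
## deliberately order-sensitive: the union of all removed components is
## order-invariant, per-component membership is not.

#' Create a gene signature
#'
#' @param name signature name.
#' @param species "mouse" or "human".
#' @param category curation/overlap category.
#' @param symbols gene symbols (duplicates collapsed).
#' @param direction optional +1/-1 per symbol.
#' @param provenance citation string.
#' @return a \linkS4class{GeneSignature}.
#' @export
geneSignature <- function(name, species = "mouse", category = "uncategorized",
                          symbols, direction = integer(),
                          provenance = "") {
    keep <- !duplicated(symbols)
    new("GeneSignature", name = name, species = species, category = category,
        symbols = symbols[keep],
        direction = if (length(direction)) as.integer(direction[keep])
                    else integer(),
        provenance = provenance)
}

#' @describeIn geneSignature symbol accessor.
#' @param x a \code{GeneSignature}.
#' @export
signatureSymbols <- function(x) x@symbols

setMethod("show", "GeneSignature", function(object) {
    cat(sprintf("GeneSignature '%s' (%s, %s): %d symbols\n",
                object@name, object@species, object@category,
                length(object@symbols)))
})

#' Build an ortholog map from a mouse symbol universe
#'
#' Case-convention mapping: the human ortholog of a mouse symbol is its
#' upper-case form. An override table can replace or extend pairs for
#' symbols where the convention fails.
#'
#' @param mouseSymbols mouse symbol universe.
#' @param overrides optional data.frame with columns \code{mouse},
#'   \code{human}.
#' @return data.frame with columns \code{mouse} and \code{human}; one-to-one
#'   after collision resolution (first mouse symbol wins, collisions
#'   attached as the \code{"collisions"} attribute).
#' @export
orthologMap <- function(mouseSymbols, overrides = NULL) {
    map <- data.frame(mouse = unique(mouseSymbols),
                      human = toupper(unique(mouseSymbols)),
                      stringsAsFactors = FALSE)
    if (!is.null(overrides)) {
        stopifnot(all(c("mouse", "human") %in% colnames(overrides)))
        map <- map[!map$mouse %in% overrides$mouse, , drop = FALSE]
        map <- rbind(map, overrides[, c("mouse", "human")])
    }
    dup <- duplicated(map$human)
    collisions <- map$human[dup]
    map <- map[!dup, , drop = FALSE]
    rownames(map) <- NULL
    attr(map, "collisions") <- unique(collisions)
    map
}

#' Translate a signature's symbols to the other species
#'
#' Unmapped symbols are dropped and logged; duplicates after translation are
#' collapsed.
#'
#' @param sig a \linkS4class{GeneSignature}.
#' @param map ortholog map data.frame (columns \code{mouse}, \code{human}).
#' @param targetSpecies "mouse" or "human".
#' @return the harmonized \linkS4class{GeneSignature}; dropped symbols in
#'   \code{attr(, "unmapped")}.
#' @export
harmonizeSymbols <- function(sig, map, targetSpecies = c("mouse", "human")) {
    stopifnot(is(sig, "GeneSignature"))
    targetSpecies <- match.arg(targetSpecies)
    if (!all(c("mouse", "human") %in% colnames(map)))
        stop("ortholog map must have 'mouse' and 'human' columns")
    if (sig@species == targetSpecies) return(sig)
    from <- if (targetSpecies == "mouse") "human" else "mouse"
    idx <- match(sig@symbols, map[[from]])
    unmapped <- sig@symbols[is.na(idx)]
    if (length(unmapped))
        message(sprintf("harmonizeSymbols: %d/%d symbols of '%s' unmapped and dropped",
                        length(unmapped), length(sig@symbols), sig@name))
    translated <- map[[targetSpecies]][idx[!is.na(idx)]]
    out <- geneSignature(name = sig@name, species = targetSpecies,
                         category = sig@category,
                         symbols = translated,
                         provenance = sig@provenance)
    attr(out, "unmapped") <- unmapped
    out
}

#' Squared Pearson concordance of paired log2 fold changes
#'
#' @param fcA,fcB paired per-gene log2 fold changes (length >= 3).
#' @return list with \code{r2} and \code{slopeSign} (+1/-1; a negative sign
#'   marks systematic discordance despite high R^2).
#' @export
concordanceR2 <- function(fcA, fcB) {
    stopifnot(length(fcA) == length(fcB), length(fcA) >= 3L)
    if (stats::sd(fcA) == 0 || stats::sd(fcB) == 0)
        return(list(r2 = NA_real_, slopeSign = NA_real_))
    r <- stats::cor(fcA, fcB)
    list(r2 = r^2, slopeSign = sign(r))
}

#' Combine two per-model DE lists into the joint stroma transcriptome
#'
#' A gene is "common" iff present in both lists regardless of direction;
#' direction disagreements on the common set are flagged discordant, not
#' removed. Cross-model concordance is the squared Pearson correlation of
#' the common genes' log2 fold changes.
#'
#' @param deA,deB \code{DataFrame}s from \code{\link{selectDE}} (columns
#'   \code{gene}, \code{log2fc}, \code{direction}).
#' @param modelA,modelB model names.
#' @return an \linkS4class{OBBMST}.
#' @export
buildObbmst <- function(deA, deB, modelA = "modelA", modelB = "modelB") {
    stopifnot(all(c("gene", "log2fc", "direction") %in% colnames(deA)),
              all(c("gene", "log2fc", "direction") %in% colnames(deB)))
    commonGenes <- intersect(deA$gene, deB$gene)
    ia <- match(commonGenes, deA$gene)
    ib <- match(commonGenes, deB$gene)
    common <- DataFrame(
        gene = commonGenes,
        log2fc_A = deA$log2fc[ia],
        log2fc_B = deB$log2fc[ib],
        discordant = deA$direction[ia] != deB$direction[ib])
    conc <- if (length(commonGenes) >= 3L)
        concordanceR2(common$log2fc_A, common$log2fc_B)
    else list(r2 = NA_real_, slopeSign = NA_real_)
    new("OBBMST",
        modelA = modelA, modelB = modelB,
        listA = DataFrame(deA[, c("gene", "log2fc", "direction")]),
        listB = DataFrame(deB[, c("gene", "log2fc", "direction")]),
        common = common,
        uniqueA = setdiff(deA$gene, deB$gene),
        uniqueB = setdiff(deB$gene, deA$gene),
        r2 = conc$r2, slopeSign = conc$slopeSign)
}

#' @describeIn buildObbmst all genes of the combined transcriptome (union of
#'   both models).
#' @param x an \code{OBBMST}.
#' @export
obbmstGenes <- function(x) {
    unique(c(x@listA$gene, x@listB$gene))
}

## internal: assemble a validated CurationLedger from removal sets
buildLedger <- function(start, stageList, componentNames) {
    remaining <- start
    stages <- list()
    components <- list()
    for (st in stageList) {
        removed <- sort(intersect(remaining, st$removed))
        remaining <- setdiff(remaining, removed)
        stages[[st$category]] <- list(category = st$category,
                                      signatures = st$signatures,
                                      removed = removed,
                                      remaining = remaining)
        components[[componentNames[[st$category]]]] <- removed
    }
    components$core <- sort(remaining)
    fractions <- vapply(components, length, integer(1)) /
        max(1L, length(start))
    new("CurationLedger", start = start, stages = stages,
        components = components, fractions = fractions)
}

#' Sequential signature-subtraction curation
#'
#' Stage k removes from the running remainder every gene present in the
#' union of the stage's signatures; the remainder after the last stage is
#' the core signature. The default order subtracts
#' inflammatory/wound/desmoplastic response signatures first, then stroma
#' signatures of non-osteotropic cancers, then stroma signatures of
#' osteotropic primary cancers, yielding the four-component decomposition
#' {inflammatory-shared, universal, osteotropic, core}.
#'
#' @param x an \linkS4class{OBBMST}, or a character vector of genes to
#'   curate.
#' @param signatures list of \linkS4class{GeneSignature}s (already
#'   harmonized to the gene universe's species).
#' @param order category subtraction order; every signature whose
#'   \code{category} matches a stage is subtracted at that stage.
#' @param componentNames stage category -> component name.
#' @return a \linkS4class{CurationLedger}.
#' @export
curate <- function(x, signatures,
                   order = c("inflammatory", "non-osteotropic",
                             "osteotropic"),
                   componentNames = c("inflammatory" = "inflammatory-shared",
                                      "non-osteotropic" = "universal",
                                      "osteotropic" = "osteotropic")) {
    start <- if (is(x, "OBBMST")) obbmstGenes(x) else as.character(x)
    stopifnot(all(vapply(signatures, is, logical(1), "GeneSignature")))
    cats <- vapply(signatures, function(s) s@category, character(1))
    ## inflammatory stage also swallows wound/desmoplastic-labelled sets
    stageCats <- list(
        "inflammatory" = c("inflammatory", "wound", "desmoplastic"),
        "non-osteotropic" = "non-osteotropic",
        "osteotropic" = "osteotropic")
    unknown <- setdiff(order, names(stageCats))
    if (length(unknown))
        stop("unknown curation category in order: ",
             paste(unknown, collapse = ", "))
    if (!all(names(componentNames) %in% order) ||
        length(order) != length(unique(order)))
        stop("order must be a permutation of the subtraction categories")
    stageList <- lapply(order, function(cat) {
        sel <- signatures[cats %in% stageCats[[cat]]]
        list(category = cat,
             signatures = vapply(sel, function(s) s@name, character(1)),
             removed = unique(unlist(lapply(sel, signatureSymbols))))
    })
    buildLedger(start, stageList, componentNames)
}

#' Region counts of a 2-4 set Venn partition
#'
#' Counts every non-empty region of the inclusion-exclusion lattice; region
#' labels join member set names with \code{"&"}. Counts sum to the size of
#' the union.
#'
#' @param sets named list of 2-4 character vectors.
#' @return named integer vector of region counts.
#' @export
vennPartition <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 2L, length(sets) <= 4L,
              !is.null(names(sets)))
    universe <- unique(unlist(sets, use.names = FALSE))
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
    label <- apply(membership, 1, function(row)
        paste(names(sets)[row], collapse = "&"))
    counts <- table(label)
    out <- stats::setNames(as.integer(counts), names(counts))
    stopifnot(sum(out) == length(universe))
    out
}
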