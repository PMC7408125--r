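# Pan-BGC presence/absence statistics, "grape" network export, pairwise CDS
# alignment and silent/non-silent mutation profiling.

#' Pan-BGC presence/absence statistics
#'
#' Set algebra over the family columns of a BGC presence/absence matrix:
#' the pan-cluster union size, the core (families conserved in every
#' strain), the non-core complement and its percent fraction (the
#' "strain-specific" fraction: absent from at least one strain), the type
#' strain's own family count and the families absent from it, and the
#' families unique to a single strain. Fractions are reported exactly,
#' never rounded internally.
#'
#' @param m a [BGCMatrix-class] or binary matrix (strains x families).
#' @param typeStrain label of the type/reference strain.
#' @return list of class `PanBGCStats`: `unionSize`, `coreCount`,
#'   `nonCoreCount`, `nonCoreFraction` (percent), `typeStrainCount`,
#'   `absentFromTypeStrain`, `uniqueToOneStrain` (data.frame family,
#'   strain).
#' @examples
#' sim <- makeBGCMatrix(18, nCore = 18, nAccessory = 19, nUnique = 5,
#'                      seed = 7)
#' panBGCStats(sim$matrix, "S1")
#' @export
panBGCStats <- function(m, typeStrain) {
    p <- if (is(m, "BGCMatrix")) bgcPresence(m) else as.matrix(m)
    if (!(typeStrain %in% rownames(p)))
        stop("type strain ", sQuote(typeStrain), " not in matrix")
    cs <- colSums(p)
    unionSize <- ncol(p)
    coreCount <- sum(cs == nrow(p))
    nonCore <- unionSize - coreCount
    uniqIdx <- which(cs == 1L)
    uniq <- data.frame(
        family = colnames(p)[uniqIdx],
        strain = vapply(uniqIdx, function(j) rownames(p)[p[, j] == 1][1L],
                        character(1L)),
        stringsAsFactors = FALSE)
    out <- list(unionSize = unionSize, coreCount = coreCount,
                nonCoreCount = nonCore,
                nonCoreFraction = 100 * nonCore / unionSize,
                typeStrainCount = sum(p[typeStrain, ] == 1),
                absentFromTypeStrain = unionSize - sum(p[typeStrain, ] == 1),
                uniqueToOneStrain = uniq)
    class(out) <- "PanBGCStats"
    out
}

#' @export
print.PanBGCStats <- function(x, ...) {
    cat("PanBGCStats: union", x$unionSize, "| core", x$coreCount,
        "| non-core", x$nonCoreCount,
        sprintf("(%.1f%% strain-specific)", x$nonCoreFraction),
        "| type strain", x$typeStrainCount,
        "| absent from type strain", x$absentFromTypeStrain,
        "| unique", nrow(x$uniqueToOneStrain), "\n")
    invisible(x)
}

#' BGC "grape" network
#'
#' One node per (family, strain) presence; complete intra-family subgraphs
#' ("grapes") with edge weights given by the family's orthology score
#' (default 1). Families never connect to each other.
#'
#' @param m a [BGCMatrix-class] or binary matrix.
#' @param orthology optional named numeric vector of per-family scores in
#'   `[0, 1]`.
#' @param prefix optional output path prefix; when given, writes
#'   `<prefix>.graphml`, `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return an [igraph::graph] object, invisibly when `prefix` is given.
#' @export
bgcNetwork <- function(m, orthology = NULL, prefix = NULL) {
    p <- if (is(m, "BGCMatrix")) bgcPresence(m) else as.matrix(m)
    if (!is.null(orthology) &&
        (any(orthology < 0) || any(orthology > 1)))
        stop("orthology scores must lie in [0, 1]")
    nodes <- data.frame(name = character(0), family = character(0),
                        strain = character(0), stringsAsFactors = FALSE)
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
    for (fam in colnames(p)) {
        present <- rownames(p)[p[, fam] == 1]
        ids <- paste(fam, present, sep = "|")
        nodes <- rbind(nodes, data.frame(name = ids, family = fam,
                                         strain = present,
                                         stringsAsFactors = FALSE))
        w <- if (!is.null(orthology) && fam %in% names(orthology))
            orthology[[fam]] else 1
        k <- length(ids)
        if (k >= 2L) for (i in 1:(k - 1L)) for (j in (i + 1L):k)
            edges <- rbind(edges, data.frame(from = ids[i], to = ids[j],
                                             weight = w,
                                             stringsAsFactors = FALSE))
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    if (!is.null(prefix)) {
        igraph::write_graph(g, paste0(prefix, ".graphml"),
                            format = "graphml")
        write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        return(invisible(g))
    }
    g
}

#' Global pairwise alignment of two coding sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties (defaults:
#' open 10, extend 0.5, match +2, mismatch -3), via Biostrings. The
#' reference defines the reading frame and must have length divisible by 3.
#'
#' @param ref reference CDS (character or `DNAString`), length divisible
#'   by 3.
#' @param query query CDS.
#' @param gapOpening,gapExtension affine gap penalties.
#' @param match,mismatch substitution scores.
#' @return list of class `CDSAlignment`: `refAligned`, `queryAligned`
#'   (equal-length gapped strings), `score`.
#' @export
alignCDS <- function(ref, query, gapOpening = 10, gapExtension = 0.5,
                     match = 2, mismatch = -3) {
    ref <- as.character(ref); query <- as.character(query)
    if (!nzchar(ref) || !nzchar(query)) stop("empty sequence")
    if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", query))
        stop("sequences must be over {A,C,G,T}")
    if (nchar(ref) %% 3L != 0L)
        stop("reference length must be divisible by 3")
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                   mismatch = mismatch,
                                                   baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(
        pattern = query, subject = ref, type = "global",
        substitutionMatrix = sm, gapOpening = gapOpening,
        gapExtension = gapExtension)
    out <- list(refAligned = as.character(Biostrings::alignedSubject(aln)),
                queryAligned = as.character(Biostrings::alignedPattern(aln)),
                score = Biostrings::score(aln))
    class(out) <- "CDSAlignment"
    out
}

#' @export
print.CDSAlignment <- function(x, ...) {
    cat("CDSAlignment: ", nchar(x$refAligned), " columns, score ",
        x$score, "\n", sep = "")
    invisible(x)
}

# slide an in-frame-length deletion to a codon boundary where the sequence
# context makes placements equivalent (indel normalization)
.alignGapToCodon <- function(refChars, start, len) {
    i <- start
    canLeft <- function(i) i > 1L && refChars[i - 1L] == refChars[i + len - 1L]
    canRight <- function(i) (i + len - 1L) < length(refChars) &&
        refChars[i] == refChars[i + len]
    j <- i
    while ((j - 1L) %% 3L != 0L && canLeft(j)) j <- j - 1L
    if ((j - 1L) %% 3L == 0L) return(j)
    j <- i
    while ((j - 1L) %% 3L != 0L && canRight(j)) j <- j + 1L
    if ((j - 1L) %% 3L == 0L) return(j)
    NA_integer_
}

#' Classify mutations from a CDS alignment
#'
#' Walks the alignment codon by codon in the reference frame (bacterial
#' codon table 11). Each differing codon yields one event: silent when the
#' translated residues are equal, non-silent otherwise. Gap runs whose
#' length is divisible by 3 are reported as one in-frame deletion (or
#' insertion) event, normalized to a codon boundary when the sequence
#' context allows; frame-breaking gaps are flagged `"frameshift"` with a
#' warning and excluded from the silent/non-silent tally.
#'
#' @param aln a `CDSAlignment` from [alignCDS()].
#' @param gene,strain labels recorded on the events.
#' @return data.frame with columns `strain`, `gene`, `codon`, `kind`,
#'   `refCodon`, `altCodon`, `refAA`, `altAA`; zero rows for identical
#'   sequences.
#' @export
classifyMutations <- function(aln, gene = NA_character_,
                              strain = NA_character_) {
    stopifnot(inherits(aln, "CDSAlignment"))
    cR <- strsplit(aln$refAligned, "")[[1L]]
    cQ <- strsplit(aln$queryAligned, "")[[1L]]
    n <- length(cR)
    refPos <- cumsum(cR != "-")          # alignment column -> ref coordinate
    events <- list()
    emit <- function(codon, kind, refCodon, altCodon, refAA, altAA)
        events[[length(events) + 1L]] <<- data.frame(
            strain = strain, gene = gene, codon = codon, kind = kind,
            refCodon = refCodon, altCodon = altCodon, refAA = refAA,
            altAA = altAA, stringsAsFactors = FALSE)
    refSeq <- paste0(cR[cR != "-"], collapse = "")
    refChars <- cR[cR != "-"]
    maskedCodons <- integer(0)   # ref codons covered by indels
    # deletion runs (gap in query)
    runs <- rle(cQ == "-")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
        len <- runs$lengths[k]
        colStart <- starts[k]
        rStart <- refPos[colStart]
        if (len %% 3L != 0L) {
            warning("frame-breaking deletion of length ", len,
                    " at reference position ", rStart)
            emit(codon = (rStart - 1L) %/% 3L + 1L, kind = "frameshift",
                 refCodon = substr(refSeq, rStart, rStart + len - 1L),
                 altCodon = strrep("-", len), refAA = NA_character_,
                 altAA = NA_character_)
            maskedCodons <- c(maskedCodons,
                              ((rStart - 1L) %/% 3L + 1L):
                              ((rStart + len - 2L) %/% 3L + 1L))
            next
        }
        pos <- .alignGapToCodon(refChars, rStart, len)
        if (is.na(pos)) {
            warning("in-frame gap not alignable to a codon boundary at ",
                    "reference position ", rStart)
            pos <- rStart
            kind <- "frameshift"
        } else {
            kind <- "in-frame deletion"
        }
        codon1 <- (pos - 1L) %/% 3L + 1L
        refCodon <- substr(refSeq, pos, pos + len - 1L)
        refAA <- if (kind == "in-frame deletion")
            paste0(vapply(seq_len(len %/% 3L), function(i)
                .translateCodon(substr(refCodon, 3L * i - 2L, 3L * i)),
                character(1L)), collapse = "")
        else NA_character_
        emit(codon = codon1, kind = kind, refCodon = refCodon,
             altCodon = strrep("-", len), refAA = refAA,
             altAA = if (kind == "in-frame deletion") "-" else NA_character_)
        maskedCodons <- c(maskedCodons,
                          codon1:((pos + len - 2L) %/% 3L + 1L))
    }
    # insertion runs (gap in reference)
    runsR <- rle(cR == "-")
    endsR <- cumsum(runsR$lengths)
    startsR <- endsR - runsR$lengths + 1L
    for (k in which(runsR$values)) {
        len <- runsR$lengths[k]
        colStart <- startsR[k]
        rAt <- refPos[colStart]          # ref base before/at the insertion
        kind <- if (len %% 3L == 0L) "in-frame insertion" else "frameshift"
        if (kind == "frameshift")
            warning("frame-breaking insertion of length ", len,
                    " after reference position ", rAt)
        emit(codon = max(1L, (rAt - 1L) %/% 3L + 1L), kind = kind,
             refCodon = "", altCodon = paste0(
                 cQ[colStart:(colStart + len - 1L)], collapse = ""),
             refAA = NA_character_, altAA = NA_character_)
        maskedCodons <- c(maskedCodons, max(1L, (rAt - 1L) %/% 3L + 1L))
    }
    # substitutions, codon by codon in the reference frame
    qAtRef <- rep(NA_character_, nchar(refSeq))
    ok <- cR != "-" & cQ != "-"
    qAtRef[refPos[ok]] <- cQ[ok]
    nCodons <- nchar(refSeq) %/% 3L
    for (cd in seq_len(nCodons)) {
        if (cd %in% maskedCodons) next
        idx <- (3L * cd - 2L):(3L * cd)
        q <- qAtRef[idx]
        if (anyNA(q)) next
        refCodon <- substr(refSeq, idx[1L], idx[3L])
        altCodon <- paste0(q, collapse = "")
        if (refCodon == altCodon) next
        refAA <- .translateCodon(refCodon)
        altAA <- .translateCodon(altCodon)
        emit(codon = cd,
             kind = if (identical(refAA, altAA)) "silent" else "non-silent",
             refCodon = refCodon, altCodon = altCodon, refAA = refAA,
             altAA = altAA)
    }
    if (length(events) == 0L)
        return(data.frame(strain = character(), gene = character(),
                          codon = integer(), kind = character(),
                          refCodon = character(), altCodon = character(),
                          refAA = character(), altAA = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, events)
    out <- out[order(out$codon), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify mutations across a multi-gene, multi-strain CDS set
#'
#' Aligns every strain's version of every gene against the reference and
#' pools the classified events.
#'
#' @param refGenes reference ORFs (`DNAStringSet`).
#' @param strainSets named list (per strain) of `DNAStringSet` with the
#'   same gene names.
#' @param ... passed to [alignCDS()].
#' @return pooled events data.frame (see [classifyMutations()]).
#' @export
classifyMutationSet <- function(refGenes, strainSets, ...) {
    out <- list()
    for (s in names(strainSets)) {
        seqs <- strainSets[[s]]
        for (g in names(refGenes)) {
            ev <- classifyMutations(
                alignCDS(refGenes[[g]], seqs[[g]], ...),
                gene = g, strain = s)
            if (nrow(ev)) out[[length(out) + 1L]] <- ev
        }
    }
    if (length(out) == 0L)
        return(classifyMutations(alignCDS("ATGTAA", "ATGTAA")))
    res <- do.call(rbind, out)
    res <- res[order(res$strain, res$gene, res$codon), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Per-gene, per-strain mutation counts
#'
#' An identical event (same gene, codon, change and kind) shared by several
#' strains counts once per strain in the per-strain totals but once overall
#' in the distinct-mutation total, matching the shared-symbol bookkeeping
#' of conserved-cluster mutation tables.
#'
#' @param events events data.frame from [classifyMutations()] /
#'   [classifyMutationSet()].
#' @param strains,genes optional label universes (to include zero rows and
#'   columns); default: the labels seen in `events`.
#' @return list: `counts` (genes x strains matrix), `perStrainTotals`,
#'   `perGeneDistinct`, `distinctTotal`, `kindTotals` (distinct events by
#'   kind).
#' @export
mutationMatrix <- function(events, strains = NULL, genes = NULL) {
    if (is.null(strains)) strains <- sort(unique(events$strain))
    if (is.null(genes)) genes <- sort(unique(events$gene))
    counts <- matrix(0L, length(genes), length(strains),
                     dimnames = list(genes, strains))
    key <- if (nrow(events))
        paste(events$gene, events$codon, events$refCodon, events$altCodon,
              events$kind, sep = "|")
    else character(0)
    for (i in seq_len(nrow(events))) {
        g <- events$gene[i]; s <- events$strain[i]
        if (g %in% genes && s %in% strains)
            counts[g, s] <- counts[g, s] + 1L
    }
    distinct <- !duplicated(key)
    perGeneDistinct <- vapply(genes, function(g)
        length(unique(key[events$gene == g])), integer(1L))
    list(counts = counts,
         perStrainTotals = colSums(counts),
         perGeneDistinct = perGeneDistinct,
         distinctTotal = length(unique(key)),
         kindTotals = table(events$kind[distinct]))
}
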