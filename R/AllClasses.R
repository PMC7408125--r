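#' @include AllGenerics.R
NULL

#' strainmet: strain-level chemical and genomic heterogeneity analysis
#'
#' Core S4 data model: MS/MS spectra, consensus spectra, extracted-ion
#' chromatogram traces, strain x compound abundance matrices, relative
#' abundance matrices, BGC presence/absence matrices and molecular networks.
#'
#' @import methods
#' @importFrom stats median rnorm runif rlnorm rbinom dist hclust cutree sd
#' @importFrom utils read.delim write.table head
#' @name strainmet-package
#' @keywords internal
"_PACKAGE"

#' A single MS/MS scan
#'
#' Holds one centroided tandem mass spectrum: precursor m/z, charge,
#' retention time, the originating strain/sample label and the fragment peak
#' list. Peaks are always stored sorted ascending by m/z; the constructor
#' enforces this, so downstream code may rely on it.
#'
#' @slot id character scan identifier.
#' @slot strain character strain/sample label (may be `NA`).
#' @slot precursorMz numeric precursor m/z in Da, > 0.
#' @slot charge integer precursor charge, >= 1.
#' @slot rt numeric retention time in seconds, >= 0.
#' @slot peaks two-column numeric matrix (`mz`, `intensity`), sorted by `mz`.
#'
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        id = "character",
        strain = "character",
        precursorMz = "numeric",
        charge = "integer",
        rt = "numeric",
        peaks = "matrix"
    )
)

setValidity("Spectrum", function(object) {
    msg <- character()
    p <- object@peaks
    if (!is.numeric(p) || ncol(p) != 2L)
        msg <- c(msg, "peaks must be a numeric matrix with columns mz, intensity")
    else {
        if (!identical(colnames(p), c("mz", "intensity")))
            msg <- c(msg, "peak columns must be named mz, intensity")
        if (nrow(p) > 0L) {
            if (any(p[, 1L] <= 0)) msg <- c(msg, "all peak m/z must be > 0")
            if (any(p[, 2L] < 0)) msg <- c(msg, "all intensities must be >= 0")
            if (is.unsorted(p[, 1L])) msg <- c(msg, "peaks must be sorted ascending by m/z")
        }
    }
    if (length(object@precursorMz) != 1L || is.na(object@precursorMz) ||
        object@precursorMz <= 0)
        msg <- c(msg, "precursorMz must be a single positive number")
    if (length(object@charge) != 1L || is.na(object@charge) || object@charge < 1L)
        msg <- c(msg, "charge must be a positive integer")
    if (length(object@rt) != 1L || is.na(object@rt) || object@rt < 0)
        msg <- c(msg, "rt must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param id scan identifier.
#' @param precursorMz precursor m/z (Da).
#' @param peaks two-column numeric matrix or data.frame (m/z, intensity);
#'   re-sorted ascending by m/z.
#' @param charge precursor charge (default 1).
#' @param rt retention time in seconds (default 0).
#' @param strain strain/sample label (default `NA`).
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum("scan1", 256.0967, cbind(c(121.06, 91.05), c(100, 20)))
#' peaks(s)   # re-sorted ascending
#' @export
Spectrum <- function(id, precursorMz, peaks, charge = 1L, rt = 0,
                     strain = NA_character_) {
    peaks <- as.matrix(peaks)
    if (ncol(peaks) != 2L)
        stop("peaks must have two columns (mz, intensity)")
    storage.mode(peaks) <- "double"
    colnames(peaks) <- c("mz", "intensity")
    peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
    rownames(peaks) <- NULL
    new("Spectrum", id = as.character(id), strain = as.character(strain),
        precursorMz = as.numeric(precursorMz), charge = as.integer(charge),
        rt = as.numeric(rt), peaks = peaks)
}

#' @describeIn Spectrum scan identifier.
#' @param x a `Spectrum`.
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@id)

#' @describeIn Spectrum precursor m/z.
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' @describeIn Spectrum peak matrix (mz, intensity).
#' @export
setMethod("peaks", "Spectrum", function(x) x@peaks)

#' @describeIn Spectrum retention time (s).
#' @export
setMethod("rtime", "Spectrum", function(x) x@rt)

#' @describeIn Spectrum strain/sample label.
#' @export
setMethod("spectrumStrain", "Spectrum", function(x) x@strain)

setMethod("show", "Spectrum", function(object) {
    cat("Spectrum", object@id, "\n",
        " precursor m/z ", format(object@precursorMz, digits = 9),
        " (", object@charge, "+), rt ", object@rt, " s, strain ",
        object@strain, "\n  ", nrow(object@peaks), " peaks\n", sep = "")
})

#' A consensus MS/MS spectrum
#'
#' Merged representative of a cluster of replicate spectra, as produced by
#' [clusterSpectra()]. Extends [Spectrum-class] with the member scan ids and
#' the set of strains the members were observed in. The precursor m/z is the
#' median of the members' precursors and the peak list is the
#' tolerance-merged, intensity-summed union of the members' peaks.
#'
#' @slot memberIds character ids of the clustered member scans.
#' @slot strainsObserved character strains contributing members.
#' @exportClass ConsensusSpectrum
setClass("ConsensusSpectrum",
    contains = "Spectrum",
    representation(memberIds = "character", strainsObserved = "character")
)

setValidity("ConsensusSpectrum", function(object) {
    if (length(object@memberIds) < 1L)
        "a consensus spectrum needs at least one member" else TRUE
})

#' @describeIn ConsensusSpectrum member scan ids.
#' @param x a `ConsensusSpectrum`.
#' @export
setMethod("memberIds", "ConsensusSpectrum", function(x) x@memberIds)

#' @describeIn ConsensusSpectrum strains contributing members.
#' @export
setMethod("strainsObserved", "ConsensusSpectrum", function(x) x@strainsObserved)

setMethod("show", "ConsensusSpectrum", function(object) {
    cat("ConsensusSpectrum", object@id, "\n",
        " precursor m/z ", format(object@precursorMz, digits = 9),
        ", ", length(object@memberIds), " members, strains: ",
        paste(object@strainsObserved, collapse = ","), "\n  ",
        nrow(object@peaks), " peaks\n", sep = "")
})

#' An extracted-ion-chromatogram trace
#'
#' Intensity versus retention time for a narrow m/z window around
#' `targetMz`. The retention-time grid is strictly increasing and shared with
#' the intensity vector.
#'
#' @slot rt numeric retention-time grid in seconds, strictly increasing.
#' @slot intensity numeric intensities, >= 0, same length as `rt`.
#' @slot targetMz numeric centre of the extracted m/z window (Da).
#' @slot tolDa numeric half-width of the m/z window (Da).
#' @exportClass EICTrace
setClass("EICTrace",
    representation(rt = "numeric", intensity = "numeric",
                   targetMz = "numeric", tolDa = "numeric")
)

setValidity("EICTrace", function(object) {
    msg <- character()
    if (length(object@rt) != length(object@intensity))
        msg <- c(msg, "rt and intensity must have equal length")
    if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
        msg <- c(msg, "rt grid must be strictly increasing")
    if (any(object@intensity < 0))
        msg <- c(msg, "intensities must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct an EICTrace
#' @param rt retention-time grid (s), strictly increasing.
#' @param intensity intensity per grid point.
#' @param targetMz extracted m/z (Da).
#' @param tolDa extraction half-window (Da).
#' @return an [EICTrace-class].
#' @export
EICTrace <- function(rt, intensity, targetMz = NA_real_, tolDa = 0.01) {
    new("EICTrace", rt = as.numeric(rt), intensity = as.numeric(intensity),
        targetMz = as.numeric(targetMz), tolDa = as.numeric(tolDa))
}

setMethod("show", "EICTrace", function(object) {
    cat("EICTrace: m/z ", format(object@targetMz, digits = 8), " +/- ",
        object@tolDa, " Da, ", length(object@rt), " points, rt [",
        min(object@rt), ", ", max(object@rt), "] s\n", sep = "")
})

#' Strain x compound abundance matrix
#'
#' Peak-area abundances for a set of strains (rows) against a set of
#' compounds (columns), with one strain designated as the reference for
#' relative-abundance computation.
#'
#' @slot values non-negative numeric matrix, dimnames = (strains, compounds).
#' @slot referenceStrain character, one of the row names.
#' @exportClass StrainCompoundMatrix
setClass("StrainCompoundMatrix",
    representation(values = "matrix", referenceStrain = "character")
)

setValidity("StrainCompoundMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must carry strain row names and compound column names")
    else {
        if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate strain labels")
        if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate compound labels")
        if (!(object@referenceStrain %in% rownames(v)))
            msg <- c(msg, "referenceStrain must be one of the strains")
    }
    if (is.numeric(v) && any(v < 0)) msg <- c(msg, "abundances must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a StrainCompoundMatrix
#' @param values non-negative matrix with strain rownames and compound
#'   colnames.
#' @param referenceStrain reference strain label (default: first row).
#' @return a [StrainCompoundMatrix-class].
#' @export
StrainCompoundMatrix <- function(values, referenceStrain = rownames(values)[1L]) {
    new("StrainCompoundMatrix", values = as.matrix(values),
        referenceStrain = referenceStrain)
}

#' @describeIn StrainCompoundMatrix the abundance matrix.
#' @param x a `StrainCompoundMatrix`.
#' @export
setMethod("abundances", "StrainCompoundMatrix", function(x) x@values)

#' @describeIn StrainCompoundMatrix strain labels.
#' @export
setMethod("strains", "StrainCompoundMatrix", function(x) rownames(x@values))

#' @describeIn StrainCompoundMatrix compound labels.
#' @export
setMethod("compounds", "StrainCompoundMatrix", function(x) colnames(x@values))

#' @describeIn StrainCompoundMatrix reference strain label.
#' @export
setMethod("referenceStrain", "StrainCompoundMatrix", function(x) x@referenceStrain)

setMethod("show", "StrainCompoundMatrix", function(object) {
    cat("StrainCompoundMatrix: ", nrow(object@values), " strains x ",
        ncol(object@values), " compounds (reference ",
        object@referenceStrain, ")\n", sep = "")
})

#' Relative-abundance matrix
#'
#' Abundances expressed in percent of the reference strain, compound by
#' compound (reference fixed to 100 wherever it produces the compound).
#' Compounds the reference does not produce cannot be put on that scale; for
#' those columns the absolute areas are retained and flagged
#' `"reference-nonproducer"` rather than divided by zero.
#'
#' @slot values numeric matrix: percent of reference, or absolute area in
#'   flagged columns.
#' @slot flags character matrix, same shape: `""` or
#'   `"reference-nonproducer"`.
#' @slot referenceStrain character.
#' @exportClass RAMatrix
setClass("RAMatrix",
    representation(values = "matrix", flags = "matrix",
                   referenceStrain = "character")
)

setValidity("RAMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@flags)))
        msg <- c(msg, "values and flags must have the same shape")
    if (any(object@values < 0)) msg <- c(msg, "relative abundances must be >= 0")
    ref <- object@referenceStrain
    if (!(ref %in% rownames(object@values)))
        msg <- c(msg, "referenceStrain must be one of the strains")
    else {
        ok <- object@flags[ref, ] == "" & object@values[ref, ] > 0
        if (any(abs(object@values[ref, ok] - 100) > 1e-9))
            msg <- c(msg, "reference row must be 100 wherever it produces")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn RAMatrix the percent (or flagged absolute) values.
#' @param x an `RAMatrix`.
#' @export
setMethod("abundances", "RAMatrix", function(x) x@values)

#' @describeIn RAMatrix per-cell flags.
#' @export
setMethod("raFlags", "RAMatrix", function(x) x@flags)

#' @describeIn RAMatrix strain labels.
#' @export
setMethod("strains", "RAMatrix", function(x) rownames(x@values))

#' @describeIn RAMatrix compound labels.
#' @export
setMethod("compounds", "RAMatrix", function(x) colnames(x@values))

#' @describeIn RAMatrix reference strain label.
#' @export
setMethod("referenceStrain", "RAMatrix", function(x) x@referenceStrain)

setMethod("show", "RAMatrix", function(object) {
    nf <- sum(object@flags[1L, ] != "")
    cat("RAMatrix: ", nrow(object@values), " strains x ", ncol(object@values),
        " compounds, reference ", object@referenceStrain, " = 100%",
        if (nf) paste0(" (", nf, " reference-nonproducer columns)"), "\n",
        sep = "")
})

#' BGC family presence/absence matrix
#'
#' Binary strains x BGC-families matrix. Every family column must be present
#' in at least one strain (a family observed nowhere is not a family).
#'
#' @slot presence binary matrix, strains in rows, BGC families in columns.
#' @exportClass BGCMatrix
setClass("BGCMatrix", representation(presence = "matrix"))

setValidity("BGCMatrix", function(object) {
    msg <- character()
    p <- object@presence
    if (!all(p %in% c(0, 1))) msg <- c(msg, "presence must be binary 0/1")
    if (is.null(rownames(p)) || is.null(colnames(p)))
        msg <- c(msg, "presence needs strain rownames and family colnames")
    else {
        if (anyDuplicated(rownames(p))) msg <- c(msg, "duplicate strain labels")
        if (anyDuplicated(colnames(p))) msg <- c(msg, "duplicate family labels")
    }
    if (ncol(p) > 0L && any(colSums(p) == 0))
        msg <- c(msg, "every BGC family must be present in at least one strain")
    if (length(msg)) msg else TRUE
})

#' Construct a BGCMatrix
#' @param presence binary matrix (strains x families) with dimnames.
#' @return a [BGCMatrix-class].
#' @export
BGCMatrix <- function(presence) {
    m <- as.matrix(presence)
    storage.mode(m) <- "double"
    new("BGCMatrix", presence = m)
}

#' @describeIn BGCMatrix the binary presence matrix.
#' @param x a `BGCMatrix`.
#' @export
setMethod("bgcPresence", "BGCMatrix", function(x) x@presence)

#' @describeIn BGCMatrix strain labels.
#' @export
setMethod("strains", "BGCMatrix", function(x) rownames(x@presence))

setMethod("show", "BGCMatrix", function(object) {
    cat("BGCMatrix: ", nrow(object@presence), " strains x ",
        ncol(object@presence), " BGC families; core ",
        sum(colSums(object@presence) == nrow(object@presence)), "\n", sep = "")
})

#' A molecular network
#'
#' Nodes are consensus spectra; undirected edges connect nodes whose modified
#' cosine similarity is at least the networking threshold. Edge attributes
#' carry the cosine score and the matched peak count.
#'
#' @slot nodes list of [ConsensusSpectrum-class] (or [Spectrum-class]).
#' @slot edges data.frame with columns `from`, `to`, `cosine`,
#'   `matchedPeaks`.
#' @slot params the [scoringParams()] list the network was built with.
#' @slot nodeGroups named character vector of tag-group calls (optional,
#'   filled by [assignNodeGroups()]).
#' @exportClass MolecularNetwork
setClass("MolecularNetwork",
    representation(nodes = "list", edges = "data.frame", params = "list",
                   nodeGroups = "character")
)

setValidity("MolecularNetwork", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("from", "to", "cosine", "matchedPeaks")
    if (!all(need %in% names(e)))
        msg <- c(msg, "edges must have columns from, to, cosine, matchedPeaks")
    else if (nrow(e)) {
        if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
        if (any(e$cosine < 0 | e$cosine > 1 + 1e-9))
            msg <- c(msg, "cosine scores must lie in [0, 1]")
        ids <- vapply(object@nodes, spectrumId, character(1L))
        if (!all(c(e$from, e$to) %in% ids))
            msg <- c(msg, "edge endpoints must be node ids")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MolecularNetwork node list.
#' @param x a `MolecularNetwork`.
#' @export
setMethod("networkNodes", "MolecularNetwork", function(x) x@nodes)

#' @describeIn MolecularNetwork edge table.
#' @export
setMethod("networkEdges", "MolecularNetwork", function(x) x@edges)

setMethod("show", "MolecularNetwork", function(object) {
    cat("MolecularNetwork: ", length(object@nodes), " nodes, ",
        nrow(object@edges), " edges (min cosine ",
        object@params$minCosine, ")\n", sep = "")
})
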