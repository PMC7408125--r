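# Diagnostic tag-fragment screening: assign spectra/consensus nodes to
# compound groups by the presence of characteristic fragment ions.

#' Default diagnostic tag set
#'
#' The three tag fragments that partition bagremycin-related compounds into
#' groups: m/z 121.06 for the classical (p-vinylphenol-containing) group 1,
#' 255.04 (C10H11N2O4S+) for the sulfur-containing group 2, and 178.05
#' (C9H8NO3+) for the lactone group 3, which also admits an unsaturated
#' alternative fragment at 176.0706. Groups 1 and 3 may present the tag as
#' a neutral loss instead of the charged fragment.
#'
#' The group 1 printed m/z (121.06) is taken as authoritative for matching;
#' `exactMz` stores the electron-corrected cation mass closest to it
#' (C8H9O+, 121.0648 -- the commonly printed composition C8H8O+ computes to
#' 120.06, a known inconsistency of such tables).
#'
#' @return data.frame with columns `group`, `tagMz`, `exactMz`, `altMz`,
#'   `formulaNote`, `allowNeutralLoss`.
#' @export
defaultTagSet <- function() {
    data.frame(
        group = 1:3,
        tagMz = c(121.06, 255.04, 178.05),
        exactMz = c(ionMz("C8H9O+", "cation"),
                    ionMz("C10H11N2O4S+", "cation"),
                    ionMz("C9H8NO3+", "cation")),
        altMz = c(NA_real_, NA_real_, 176.0706),
        formulaNote = c("C8H9O+ (printed composition C8H8O+ computes to 120.06)",
                        "C10H11N2O4S+", "C9H8NO3+"),
        allowNeutralLoss = c(TRUE, FALSE, TRUE),
        stringsAsFactors = FALSE)
}

#' Read a tag set from TSV
#'
#' Columns: `group`, `tagMz`, optional `altMz`, `allowNeutralLoss`; a
#' missing required column is an error.
#'
#' @param path TSV path.
#' @return data.frame as [defaultTagSet()].
#' @export
readTagSet <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("group", "tagMz", "allowNeutralLoss")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("tag set file is missing column(s): ", paste(miss, collapse = ", "))
    if (!("altMz" %in% names(df))) df$altMz <- NA_real_
    if (!("exactMz" %in% names(df))) df$exactMz <- df$tagMz
    if (anyDuplicated(df$group)) stop("duplicate groups in tag set")
    if (any(df$tagMz <= 0)) stop("tag m/z must be > 0")
    df
}

#' Screen a spectrum for diagnostic tag fragments
#'
#' A direct hit is any fragment within `tolDa` of a tag's m/z (or its
#' alternative m/z); a neutral-loss hit, allowed only for tags flagged so,
#' is a fragment whose distance below the precursor matches the tag's
#' neutral-mass equivalent (tag m/z minus the proton mass) within `tolDa`.
#' The tolerance is absolute in Da because tags are conventionally printed
#' at two decimals.
#'
#' @param s a [Spectrum-class] with at least one peak.
#' @param tags tag set, see [defaultTagSet()].
#' @param tolDa matching tolerance (Da), default 0.01.
#' @return data.frame with columns `group`, `mode`
#'   (`"direct"`/`"alt"`/`"neutral-loss"`), `matchedMz`; zero rows when
#'   nothing matches.
#' @export
screenTags <- function(s, tags = defaultTagSet(), tolDa = 0.01) {
    pk <- peaks(s)
    if (nrow(pk) == 0L) stop("cannot screen a spectrum with no peaks")
    proton <- particleMasses()[["proton"]]
    ev <- list()
    add <- function(group, mode, mz)
        ev[[length(ev) + 1L]] <<- data.frame(group = group, mode = mode,
                                             matchedMz = mz,
                                             stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tags))) {
        hit <- which(abs(pk[, 1L] - tags$tagMz[i]) <= tolDa)
        for (h in hit) add(tags$group[i], "direct", pk[h, 1L])
        if (!is.na(tags$altMz[i])) {
            hit <- which(abs(pk[, 1L] - tags$altMz[i]) <= tolDa)
            for (h in hit) add(tags$group[i], "alt", pk[h, 1L])
        }
        if (isTRUE(tags$allowNeutralLoss[i])) {
            neutral <- tags$tagMz[i] - proton
            loss <- precursorMz(s) - pk[, 1L]
            hit <- which(abs(loss - neutral) <= tolDa)
            for (h in hit) add(tags$group[i], "neutral-loss", pk[h, 1L])
        }
    }
    if (length(ev) == 0L)
        return(data.frame(group = integer(), mode = character(),
                          matchedMz = numeric(), stringsAsFactors = FALSE))
    do.call(rbind, ev)
}

#' Classify a node from member tag evidence
#'
#' Each member spectrum votes for the single group its evidence supports;
#' members whose evidence names more than one group are ambiguous. Within a
#' member, direct (and alternative-m/z) hits outrank neutral-loss hits: a
#' neutral loss is only trusted when no charged tag was seen, since any
#' fragment sitting a tag's neutral mass below the precursor would
#' otherwise masquerade as a second group. The call is the majority group
#' over unambiguous voters; a tie, no evidence at all, or an ambiguous
#' majority yields `"ND"` (not defined) with the multiplicity flag set when
#' multi-tag evidence was seen.
#'
#' @param evidenceList list of evidence data.frames (one per member
#'   spectrum, as returned by [screenTags()]); a single data.frame is
#'   treated as one member.
#' @return list with `group` (`"1"`, `"2"`, `"3"` or `"ND"`), `ambiguous`
#'   (logical multiplicity flag) and `votes` (named integer vector).
#' @export
classifyNode <- function(evidenceList) {
    if (is.data.frame(evidenceList)) evidenceList <- list(evidenceList)
    if (length(evidenceList) == 0L) stop("need at least one member spectrum")
    votes <- integer(0)
    sawMulti <- FALSE
    for (ev in evidenceList) {
        direct <- ev[ev$mode %in% c("direct", "alt"), , drop = FALSE]
        gs <- unique(if (nrow(direct)) direct$group else ev$group)
        if (length(gs) == 1L) {
            key <- as.character(gs)
            votes[key] <- (if (key %in% names(votes)) votes[[key]] else 0L) + 1L
        } else if (length(gs) > 1L) {
            sawMulti <- TRUE
        }
    }
    if (length(votes) == 0L)
        return(list(group = "ND", ambiguous = sawMulti, votes = votes))
    top <- votes[votes == max(votes)]
    if (length(top) > 1L || sawMulti)
        return(list(group = "ND", ambiguous = TRUE, votes = votes))
    list(group = names(top), ambiguous = FALSE, votes = votes)
}

#' Assign tag groups to the nodes of a molecular network
#'
#' Screens the member spectra of every consensus node and stores the
#' resulting group calls on the network, from where [exportNetwork()]
#' writes them into the node table.
#'
#' @param g a [MolecularNetwork-class] whose nodes are
#'   [ConsensusSpectrum-class] objects.
#' @param spectra the list of member [Spectrum-class] objects the network
#'   was clustered from.
#' @param tags tag set, see [defaultTagSet()].
#' @param tolDa screening tolerance (Da).
#' @return the network with `nodeGroups` filled.
#' @export
assignNodeGroups <- function(g, spectra, tags = defaultTagSet(),
                             tolDa = 0.01) {
    byId <- stats::setNames(spectra,
                            vapply(spectra, spectrumId, character(1L)))
    calls <- character(0)
    for (node in networkNodes(g)) {
        members <- byId[intersect(memberIds(node), names(byId))]
        ev <- lapply(members, screenTags, tags = tags, tolDa = tolDa)
        calls[spectrumId(node)] <- if (length(ev)) classifyNode(ev)$group
                                   else "ND"
    }
    g@nodeGroups <- calls
    validObject(g)
    g
}
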