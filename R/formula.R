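# Exact-mass arithmetic: monoisotopic masses, ion m/z conventions, ppm
# errors, RDBE, coarse isotope patterns and CHNOS formula decomposition.

# Monoisotopic atomic masses (Da), most abundant isotope (CODATA/AME2020).
.ELEMENT_MASS <- c(
    C  = 12.0,
    H  = 1.00782503207,
    N  = 14.0030740048,
    O  = 15.9949146196,
    S  = 31.97207100,
    P  = 30.97376163,
    Na = 22.9897692809,
    K  = 38.96370668,
    Cl = 34.96885268,
    Fe = 55.9349375
)

.PROTON_MASS <- 1.007276466621
.ELECTRON_MASS <- 0.000548579909

# natural abundances of the +1/+2 heavy isotopes, for coarse M+1/M+2
.ISO_R1 <- c(C = 0.0107, H = 0.000115, N = 0.00364, O = 0.00038,
             S = 0.0075)
.ISO_R2 <- c(O = 0.00205, S = 0.0425)

#' Molecular formula
#'
#' An element-count map with a charge annotation; the unit of all exact-mass
#' arithmetic in the package. Construct with [parseFormula()].
#'
#' @slot counts named integer vector of element counts (non-negative, at
#'   least one positive). Supported elements: C, H, N, O, S, P, Na, K, Cl,
#'   Fe.
#' @slot charge integer charge annotation (e.g. `1L` for a cation, `0L` for
#'   a neutral molecule).
#' @exportClass Formula
setClass("Formula", representation(counts = "integer", charge = "integer"))

setValidity("Formula", function(object) {
    msg <- character()
    cts <- object@counts
    if (is.null(names(cts)) || !all(names(cts) %in% names(.ELEMENT_MASS)))
        msg <- c(msg, paste0("unknown element symbol(s): ",
                 paste(setdiff(names(cts), names(.ELEMENT_MASS)), collapse = ", ")))
    if (any(cts < 0L)) msg <- c(msg, "element counts must be non-negative")
    if (!any(cts > 0L)) msg <- c(msg, "formula must contain at least one atom")
    if (length(msg)) msg else TRUE
})

#' Parse a molecular formula string
#'
#' Accepts Hill-like strings with an optional trailing charge sign, e.g.
#' `"C20H20N2O6S"`, `"C10H11N2O4S+"`, `"H2O"`. The charge suffix may be
#' `"+"`, `"-"`, `"2+"` etc.
#'
#' @param x formula string (or a `Formula`, returned as is).
#' @return a [Formula-class] object. `parseFormula(formulaString(f))` is the
#'   identity.
#' @examples
#' f <- parseFormula("C10H11N2O4S+")
#' monoisotopicMass(f)
#' @export
parseFormula <- function(x) {
    if (is(x, "Formula")) return(x)
    stopifnot(is.character(x), length(x) == 1L)
    s <- gsub("[[:space:]_]", "", x)
    # a trailing digit belongs to the last element ("O3+" is O3, charge +1);
    # multiply charged ions are expressed via the z argument of ionMz()
    charge <- 0L
    signs <- regmatches(s, regexpr("[+]+$|[-]+$", s))
    if (length(signs) == 1L && nzchar(signs)) {
        charge <- nchar(signs) * (if (startsWith(signs, "+")) 1L else -1L)
        s <- sub("[+]+$|[-]+$", "", s)
    }
    if (!nzchar(s)) stop("empty formula: ", sQuote(x))
    m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1L]]
    toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1L]]
    if (sum(attr(m, "match.length")) != nchar(s))
        stop("cannot parse formula: ", sQuote(x))
    counts <- integer(0)
    for (tok in toks) {
        el <- regmatches(tok, regexpr("^[A-Z][a-z]?", tok))
        n <- sub("^[A-Z][a-z]?", "", tok)
        n <- if (nzchar(n)) as.integer(n) else 1L
        counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    }
    new("Formula", counts = counts, charge = charge)
}

#' Render a Formula as a string
#'
#' Hill order (C, H, then remaining elements alphabetically), with a
#' trailing charge sign when charged.
#'
#' @param f a [Formula-class] or formula string.
#' @return character formula.
#' @export
formulaString <- function(f) {
    f <- parseFormula(f)
    cts <- f@counts[f@counts > 0L]
    els <- names(cts)
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
    body <- paste0(vapply(ord, function(e)
        paste0(e, if (cts[[e]] > 1L) cts[[e]] else ""), character(1L)),
        collapse = "")
    z <- f@charge
    suffix <- if (z == 0L) "" else strrep(if (z > 0L) "+" else "-", abs(z))
    paste0(body, suffix)
}

setMethod("show", "Formula", function(object) {
    cat("Formula:", formulaString(object), "\n")
})

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times monoisotopic atomic masses, in the neutral
#' frame (no electron correction; the charge annotation is ignored here and
#' applied by [ionMz()]).
#'
#' @param f a [Formula-class] or formula string.
#' @return mass in Da.
#' @examples
#' monoisotopicMass("H2O")  # 18.0106
#' @export
monoisotopicMass <- function(f) {
    f <- parseFormula(f)
    sum(f@counts * .ELEMENT_MASS[names(f@counts)])
}

#' Ion m/z of a formula
#'
#' Two conventions are supported, matching the two ways compound tables in
#' the field print formulas:
#' \describe{
#'   \item{`"protonated"`}{the formula is the neutral molecule M; the ion is
#'     \eqn{[M+zH]^{z+}} and m/z = (M + z m_p)/z with m_p the proton mass.}
#'   \item{`"cation"`}{the formula already describes the cation; m/z =
#'     (M - z m_e)/z with the electron mass removed.}
#' }
#' The electron-mass correction is what makes 4-decimal agreement with
#' high-resolution instruments possible.
#'
#' @param f a [Formula-class] or formula string.
#' @param mode `"protonated"` or `"cation"`.
#' @param z charge, a positive integer (default: the formula's charge
#'   annotation if positive, else 1).
#' @return m/z in Da.
#' @examples
#' ionMz("C20H20N2O6S", "protonated")   # 417.1115
#' ionMz("C10H11N2O4S+", "cation")      # 255.0434
#' @export
ionMz <- function(f, mode = c("protonated", "cation"), z = NULL) {
    f <- parseFormula(f)
    mode <- match.arg(mode)
    if (is.null(z)) z <- if (f@charge > 0L) f@charge else 1L
    z <- as.integer(z)
    if (is.na(z) || z < 1L) stop("charge z must be a positive integer")
    m <- monoisotopicMass(f)
    mz <- switch(mode,
        protonated = (m + z * .PROTON_MASS) / z,
        cation = (m - z * .ELECTRON_MASS) / z)
    if (mz <= 0) stop("non-positive ion m/z")
    mz
}

#' Signed mass error in parts per million
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da), > 0.
#' @return `1e6 * (observed - theoretical) / theoretical`, vectorized.
#' @export
ppmError <- function(observed, theoretical) {
    if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
    1e6 * (observed - theoretical) / theoretical
}

#' Ring and double-bond equivalents
#'
#' `C - H/2 + N/2 + 1`, with halogens counted like hydrogen. A standard
#' valence plausibility filter for formula candidates; half-integer values
#' indicate even-electron ions.
#'
#' @param f a [Formula-class] or formula string.
#' @return RDBE (possibly half-integer).
#' @examples
#' rdbe("C6H6")  # benzene: 4
#' @export
rdbe <- function(f) {
    f <- parseFormula(f)
    ct <- function(e) if (e %in% names(f@counts)) f@counts[[e]] else 0L
    ct("C") - (ct("H") + ct("Cl")) / 2 + (ct("N") + ct("P")) / 2 + 1
}

#' Coarse isotope pattern (M, M+1, M+2)
#'
#' First-order approximation from heavy-isotope abundance ratios (13C, 2H,
#' 15N, 17O/18O, 33S/34S), with the single second-order 2-heavy-atom term
#' for M+2. Intended as the qualitative check used when confirming a
#' formula assignment, not as fine isotope structure.
#'
#' @param f a [Formula-class] or formula string (CHNOS).
#' @param nPeaks number of peaks to return (default 3).
#' @return numeric vector `c(M = 1, M1, M2, ...)` relative to M.
#' @export
isotopePattern <- function(f, nPeaks = 3L) {
    f <- parseFormula(f)
    ct <- function(e) if (e %in% names(f@counts)) f@counts[[e]] else 0L
    m1 <- sum(vapply(names(.ISO_R1), function(e) ct(e) * .ISO_R1[[e]],
                     numeric(1L)))
    m2 <- sum(vapply(names(.ISO_R2), function(e) ct(e) * .ISO_R2[[e]],
                     numeric(1L))) + m1^2 / 2
    out <- c(M = 1, `M+1` = m1, `M+2` = m2)
    out[seq_len(min(nPeaks, 3L))]
}

#' Decompose an ion m/z into candidate CHNOS formulas
#'
#' Exhaustive enumeration of elemental compositions within per-element
#' bounds whose theoretical ion m/z (under the given convention) lies within
#' `tolPpm` of the target. Candidates are filtered by a minimum RDBE and an
#' optional nitrogen-rule check, and ranked by |ppm| ascending with ties
#' broken by smaller total atom count.
#'
#' @param targetMz target ion m/z (Da), > 0.
#' @param mode ion convention, see [ionMz()].
#' @param z charge (default 1).
#' @param tolPpm matching tolerance in ppm (default 3).
#' @param bounds named vector of per-element maxima. Default
#'   `c(C = 60, H = 80, N = 6, O = 15, S = 3)`.
#' @param minRdbe minimum RDBE (default -0.5).
#' @param nitrogenRule if `TRUE`, keep only compositions whose neutral-frame
#'   nominal mass parity is consistent with the nitrogen count.
#' @return data.frame with columns `formula`, `C`, `H`, `N`, `O`, `S`,
#'   `theoreticalMz`, `ppm`, `rdbe`; zero rows when nothing matches.
#' @examples
#' hits <- decomposeMass(417.1115, "protonated", tolPpm = 3)
#' head(hits$formula)
#' @export
decomposeMass <- function(targetMz, mode = c("protonated", "cation"), z = 1L,
                          tolPpm = 3,
                          bounds = c(C = 60, H = 80, N = 6, O = 15, S = 3),
                          minRdbe = -0.5, nitrogenRule = FALSE) {
    mode <- match.arg(mode)
    stopifnot(targetMz > 0, tolPpm >= 0, all(is.finite(bounds)))
    z <- as.integer(z)
    b <- function(e) if (e %in% names(bounds)) as.integer(bounds[[e]]) else 0L
    # neutral-frame mass the composition must hit
    neutral <- switch(mode,
        protonated = targetMz * z - z * .PROTON_MASS,
        cation = targetMz * z + z * .ELECTRON_MASS)
    tolDa <- targetMz * z * tolPpm * 1e-6
    mH <- .ELEMENT_MASS[["H"]]
    res <- vector("list", 64L); nres <- 0L
    for (nN in 0:b("N")) for (nO in 0:b("O")) for (nS in 0:b("S")) {
        base <- nN * .ELEMENT_MASS[["N"]] + nO * .ELEMENT_MASS[["O"]] +
            nS * .ELEMENT_MASS[["S"]]
        if (base > neutral + tolDa) next
        cMax <- min(b("C"), floor((neutral + tolDa - base) / 12))
        for (nC in 0:cMax) {
            rem <- neutral - base - 12 * nC
            hLo <- max(0L, ceiling((rem - tolDa) / mH))
            hHi <- min(b("H"), floor((rem + tolDa) / mH))
            if (hHi < hLo) next
            for (nH in hLo:hHi) {
                mass <- base + 12 * nC + nH * mH
                mz <- switch(mode,
                    protonated = (mass + z * .PROTON_MASS) / z,
                    cation = (mass - z * .ELECTRON_MASS) / z)
                ppm <- ppmError(targetMz, mz)
                if (abs(ppm) > tolPpm) next
                rd <- nC - nH / 2 + nN / 2 + 1
                if (rd < minRdbe) next
                if (nitrogenRule) {
                    nominal <- 12L * nC + nH + 14L * nN + 16L * nO + 32L * nS
                    if ((nominal %% 2L == 0L) != (nN %% 2L == 0L)) next
                }
                nres <- nres + 1L
                res[[nres]] <- c(nC, nH, nN, nO, nS, mz, ppm, rd)
            }
        }
    }
    if (nres == 0L)
        return(data.frame(formula = character(), C = integer(), H = integer(),
                          N = integer(), O = integer(), S = integer(),
                          theoreticalMz = numeric(), ppm = numeric(),
                          rdbe = numeric()))
    m <- do.call(rbind, res[seq_len(nres)])
    out <- data.frame(
        formula = apply(m, 1L, function(r) {
            cts <- c(C = r[1L], H = r[2L], N = r[3L], O = r[4L], S = r[5L])
            cts <- cts[cts > 0]
            paste0(names(cts), ifelse(cts > 1, cts, ""), collapse = "")
        }),
        C = as.integer(m[, 1L]), H = as.integer(m[, 2L]),
        N = as.integer(m[, 3L]), O = as.integer(m[, 4L]),
        S = as.integer(m[, 5L]),
        theoreticalMz = m[, 6L], ppm = m[, 7L], rdbe = m[, 8L])
    total <- out$C + out$H + out$N + out$O + out$S
    out <- out[order(abs(out$ppm), total), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Proton and electron masses used by the package
#'
#' @return named numeric vector with elements `proton` and `electron` (Da).
#' @export
particleMasses <- function() {
    c(proton = .PROTON_MASS, electron = .ELECTRON_MASS)
}
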