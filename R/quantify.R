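# Semi-quantification: EIC extraction, baseline-subtracted trapezoidal peak
# integration, relative abundance against a reference strain, best-producer
# calls.

#' Extract an ion chromatogram from a set of channel traces
#'
#' Sums the intensity of every trace whose channel m/z lies within `tolDa`
#' of `targetMz`, on the shared retention-time grid. When no channel
#' matches, a flat zero trace (on the grid of the first channel) is
#' returned with a warning.
#'
#' @param traces list of [EICTrace-class] for one sample.
#' @param targetMz target m/z (Da).
#' @param tolDa channel matching tolerance (Da).
#' @return an [EICTrace-class].
#' @export
extractEIC <- function(traces, targetMz, tolDa = 0.01) {
    stopifnot(length(traces) >= 1L)
    sel <- Filter(function(t) !is.na(t@targetMz) &&
                      abs(t@targetMz - targetMz) <= tolDa, traces)
    grid <- traces[[1L]]@rt
    if (length(sel) == 0L) {
        warning("no channel within ", tolDa, " Da of m/z ", targetMz,
                "; returning zero trace")
        return(EICTrace(grid, rep(0, length(grid)), targetMz, tolDa))
    }
    for (t in sel)
        if (!isTRUE(all.equal(t@rt, sel[[1L]]@rt)))
            stop("channel traces must share one retention-time grid")
    y <- Reduce(`+`, lapply(sel, function(t) t@intensity))
    EICTrace(sel[[1L]]@rt, y, targetMz, tolDa)
}

# half-width-at-half-max based sigma estimate around the apex
.apexSigma <- function(rt, y, apex) {
    half <- y[apex] / 2
    l <- apex; while (l > 1L && y[l] > half) l <- l - 1L
    r <- apex; while (r < length(y) && y[r] > half) r <- r + 1L
    fwhm <- rt[r] - rt[l]
    max(fwhm / 2.3548, diff(range(rt)) / length(rt))
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the baseline-subtracted trace over a retention
#' time window. The baseline is the median intensity outside the window
#' (robust to the peak itself); a negative integral is clipped to 0 with a
#' warning. When no window is given, one is chosen as apex +/- 3 sigma with
#' sigma estimated from the full width at half maximum.
#'
#' @param trace an [EICTrace-class].
#' @param rtWindow numeric `c(start, end)` in seconds, or `NULL` for the
#'   automatic apex window.
#' @param baseline `"median"` (out-of-window median, the default) or
#'   `"none"`.
#' @return peak area (intensity x seconds), >= 0.
#' @export
integratePeak <- function(trace, rtWindow = NULL, baseline = "median") {
    rt <- trace@rt; y <- trace@intensity
    if (is.null(rtWindow)) {
        if (all(y == 0)) return(0)
        apex <- which.max(y)
        s <- .apexSigma(rt, y, apex)
        rtWindow <- c(rt[apex] - 3 * s, rt[apex] + 3 * s)
    }
    if (rtWindow[2L] <= rtWindow[1L]) stop("empty integration window")
    inWin <- rt >= rtWindow[1L] & rt <= rtWindow[2L]
    if (sum(inWin) < 2L)
        stop("integration window [", rtWindow[1L], ", ", rtWindow[2L],
             "] covers fewer than 2 grid points")
    b <- if (identical(baseline, "median") && any(!inWin))
        median(y[!inWin]) else 0
    area <- pracma::trapz(rt[inWin], y[inWin] - b)
    if (area < 0) {
        warning("negative integrated area clipped to 0")
        area <- 0
    }
    area
}

#' Relative abundance against the reference strain
#'
#' For every compound the reference strain produces, abundances are
#' expressed as percent of the reference (the reference row is 100 there by
#' construction). For compounds the reference does not produce there is no
#' denominator to fix to 100%; those columns keep their absolute areas and
#' are flagged `"reference-nonproducer"` rather than divided by zero.
#'
#' @param m a [StrainCompoundMatrix-class].
#' @return an [RAMatrix-class].
#' @examples
#' m <- StrainCompoundMatrix(matrix(c(10, 35), 2, 1,
#'     dimnames = list(c("MM109", "MM37"), "ferroverdinA")))
#' abundances(relativeAbundance(m))  # MM37 at 350%
#' @export
relativeAbundance <- function(m) {
    v <- abundances(m)
    ref <- referenceStrain(m)
    out <- v
    flags <- matrix("", nrow(v), ncol(v), dimnames = dimnames(v))
    for (j in seq_len(ncol(v))) {
        r <- v[ref, j]
        if (r > 0) {
            out[, j] <- 100 * v[, j] / r
        } else {
            flags[, j] <- "reference-nonproducer"
        }
    }
    new("RAMatrix", values = out, flags = flags, referenceStrain = ref)
}

#' Best producing strain per compound
#'
#' Argmax of abundance per compound; ties are broken by lexicographic
#' strain label and flagged; an all-zero compound gets `"none"`.
#'
#' @param m a [StrainCompoundMatrix-class] or [RAMatrix-class].
#' @return data.frame with columns `compound`, `strain`, `tied`.
#' @export
bestProducer <- function(m) {
    v <- abundances(m)
    res <- lapply(seq_len(ncol(v)), function(j) {
        col <- v[, j]
        if (all(col == 0))
            return(data.frame(compound = colnames(v)[j], strain = "none",
                              tied = FALSE, stringsAsFactors = FALSE))
        top <- which(col == max(col))
        winners <- sort(rownames(v)[top])
        data.frame(compound = colnames(v)[j], strain = winners[1L],
                   tied = length(winners) > 1L, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Quantify production from EIC traces
#'
#' Convenience wrapper: for every strain and every target ion, extract the
#' EIC and integrate its peak, assembling a [StrainCompoundMatrix-class].
#'
#' @param tracesByStrain named list (per strain) of lists of
#'   [EICTrace-class], as produced by [simulateEIC()].
#' @param targets named numeric vector of target ion m/z values (names =
#'   compound labels).
#' @param referenceStrain reference strain label (default: first strain).
#' @param tolDa channel tolerance (Da).
#' @param rtWindows optional named list of fixed integration windows.
#' @return a [StrainCompoundMatrix-class] of peak areas.
#' @export
eicAbundanceMatrix <- function(tracesByStrain, targets,
                               referenceStrain = names(tracesByStrain)[1L],
                               tolDa = 0.01, rtWindows = NULL) {
    stopifnot(length(tracesByStrain) >= 1L, length(targets) >= 1L,
              !is.null(names(targets)))
    strains <- names(tracesByStrain)
    m <- matrix(0, length(strains), length(targets),
                dimnames = list(strains, names(targets)))
    for (s in strains) for (cp in names(targets)) {
        tr <- extractEIC(tracesByStrain[[s]], targets[[cp]], tolDa)
        win <- if (!is.null(rtWindows)) rtWindows[[cp]] else NULL
        m[s, cp] <- integratePeak(tr, win)
    }
    StrainCompoundMatrix(m, referenceStrain = referenceStrain)
}
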