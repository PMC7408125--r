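# MGF (Mascot Generic Format) reading/writing and labelled-matrix I/O.
# MGF is the GNPS-compatible on-disk spectrum format; mzML/mzXML conversion
# is upstream of this package.

#' Read an MGF file
#'
#' Parses a Mascot Generic Format file (`BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS`, optional `CHARGE`, `RTINSECONDS` and `TITLE`) into a list of
#' [Spectrum-class] objects. Peak rows are whitespace-separated
#' m/z--intensity pairs; peaks are re-sorted ascending by m/z on read.
#'
#' The strain label is taken from a `STRAIN=<label>` token inside `TITLE`
#' when present, otherwise from `defaultStrain`; spectra from multi-strain
#' studies should carry the mapping explicitly so runs are reproducible.
#'
#' @param path MGF file path.
#' @param defaultStrain strain label used when `TITLE` carries no
#'   `STRAIN=` token.
#' @return list of [Spectrum-class]; empty list (with a warning) for an
#'   empty file.
#' @seealso [writeMGF()]
#' @export
readMGF <- function(path, defaultStrain = NA_character_) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    nonblank <- which(nzchar(trimws(lines)))
    if (length(nonblank) == 0L) {
        warning("empty MGF file: ", path)
        return(list())
    }
    spectra <- list()
    i <- 1L
    n <- length(lines)
    while (i <= n) {
        if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
        blockStart <- i
        i <- i + 1L
        hdr <- list()
        mzs <- numeric(0); ints <- numeric(0)
        repeat {
            if (i > n)
                stop("MGF parse error: block starting at line ", blockStart,
                     " has no END IONS")
            ln <- trimws(lines[i])
            if (ln == "END IONS") break
            if (grepl("=", ln, fixed = TRUE)) {
                key <- toupper(sub("=.*$", "", ln))
                hdr[[key]] <- sub("^[^=]*=", "", ln)
            } else if (nzchar(ln)) {
                xs <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1L]]))
                if (length(xs) < 2L || anyNA(xs[1:2]))
                    stop("MGF parse error: non-numeric peak line at line ", i,
                         ": ", sQuote(ln))
                mzs <- c(mzs, xs[1L]); ints <- c(ints, xs[2L])
            }
            i <- i + 1L
        }
        i <- i + 1L
        if (is.null(hdr$PEPMASS))
            stop("MGF parse error: block starting at line ", blockStart,
                 " is missing PEPMASS")
        pep <- suppressWarnings(
            as.numeric(strsplit(trimws(hdr$PEPMASS), "[[:space:]]+")[[1L]][1L]))
        if (is.na(pep))
            stop("MGF parse error: non-numeric PEPMASS in block at line ",
                 blockStart)
        charge <- 1L
        if (!is.null(hdr$CHARGE)) {
            z <- suppressWarnings(as.integer(gsub("[+-]", "", hdr$CHARGE)))
            if (!is.na(z) && z >= 1L) charge <- z
        }
        rt <- if (!is.null(hdr$RTINSECONDS))
            suppressWarnings(as.numeric(hdr$RTINSECONDS)) else 0
        if (is.na(rt)) rt <- 0
        title <- if (!is.null(hdr$TITLE)) hdr$TITLE else
            paste0("scan", length(spectra) + 1L)
        strain <- defaultStrain
        toks <- strsplit(trimws(title), "[[:space:]]+")[[1L]]
        st <- grep("^STRAIN=", toks, value = TRUE)
        if (length(st)) {
            strain <- sub("^STRAIN=", "", st[1L])
            toks <- setdiff(toks, st)
        }
        id <- if (length(toks)) paste(toks, collapse = " ") else title
        spectra[[length(spectra) + 1L]] <-
            Spectrum(id = id, precursorMz = pep, charge = charge, rt = rt,
                     strain = strain, peaks = cbind(mzs, ints))
    }
    spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [readMGF()]: m/z values are written with 6 decimal places and
#' intensities with 6 significant digits, so a read/write round trip is
#' lossless at that precision. The strain label is embedded as a `STRAIN=`
#' token in `TITLE`.
#'
#' @param spectra non-empty list of [Spectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMGF <- function(spectra, path) {
    if (length(spectra) == 0L)
        stop("refusing to write an empty spectrum list")
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (s in spectra) {
        title <- spectrumId(s)
        if (!is.na(spectrumStrain(s)))
            title <- paste0(title, " STRAIN=", spectrumStrain(s))
        writeLines(c(
            "BEGIN IONS",
            paste0("TITLE=", title),
            paste0("PEPMASS=", sprintf("%.6f", precursorMz(s))),
            paste0("CHARGE=", s@charge, "+"),
            paste0("RTINSECONDS=", sprintf("%.3f", rtime(s)))
        ), con)
        p <- peaks(s)
        if (nrow(p))
            writeLines(sprintf("%.6f %.6g", p[, 1L], p[, 2L]), con)
        writeLines(c("END IONS", ""), con)
    }
    invisible(path)
}

#' Read a labelled numeric matrix from TSV/CSV
#'
#' First column holds row labels, header row holds column labels. Rows are
#' strains and columns compounds (or BGC families) by convention;
#' `transpose = TRUE` flips an input stored the other way around. Blank or
#' missing cells are imputed as 0 with a warning; duplicate labels or
#' non-numeric cells are errors.
#'
#' @param path file path; tab delimiter unless the file name ends in `.csv`.
#' @param transpose flip rows/columns after reading.
#' @return numeric matrix with unique row and column names.
#' @export
readMatrix <- function(path, transpose = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.delim(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE, colClasses = "character")
    if (ncol(df) < 2L) stop("matrix file needs row labels plus data columns")
    rl <- df[[1L]]
    if (anyDuplicated(rl)) stop("duplicate row labels in ", path)
    if (anyDuplicated(colnames(df)[-1L])) stop("duplicate column labels in ", path)
    vals <- as.matrix(df[, -1L, drop = FALSE])
    blank <- is.na(vals) | !nzchar(trimws(vals))
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) & !blank, arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric cell at row ", sQuote(rl[bad[1L, 1L]]), ", column ",
             sQuote(colnames(vals)[bad[1L, 2L]]), " in ", path)
    if (any(blank)) {
        warning(sum(blank), " missing cell(s) imputed as 0 in ", path)
        num[blank] <- 0
    }
    dimnames(num) <- list(rl, colnames(vals))
    if (transpose) num <- t(num)
    num
}

#' Write a labelled matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param labelHeader header for the row-label column.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(m, path, labelHeader = "label") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- labelHeader
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
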