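# Minimal Mascot Generic Format (MGF) reader/writer for MS/MS peak lists.
# Covers the dialect the identification engine consumes: TITLE, PEPMASS,
# CHARGE, RTINSECONDS and (m/z, intensity) pairs between BEGIN/END IONS.

#' Construct an MS/MS spectrum record
#'
#' @param precursor_mz precursor m/z.
#' @param polarity `"+"` or `"-"`.
#' @param peaks two-column numeric matrix (m/z, intensity); rows are sorted
#'   by m/z on construction.
#' @param rt retention time in minutes (optional).
#' @param title optional identifier.
#' @return object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(precursor_mz, polarity, peaks,
                            rt = NA_real_, title = "") {
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0)
  polarity <- match.arg(polarity, c("+", "-"))
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(peaks) > 0) {
    if (any(!is.finite(peaks)) || any(peaks[, "intensity"] < 0)) {
      lip_stop("peak intensities must be finite and non-negative", "ParseError")
    }
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  }
  structure(list(precursor_mz = precursor_mz, polarity = polarity,
                 rt = rt, peaks = peaks, title = title),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %s prec %.4f m/z, %d peaks%s\n",
              x$polarity, x$precursor_mz, nrow(x$peaks),
              if (nzchar(x$title)) paste0(" [", x$title, "]") else ""))
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' @param path path to an MGF file.
#' @return list of `"spectrum_record"` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(begins) != length(ends)) {
    lip_stop(sprintf("unbalanced BEGIN/END IONS in '%s'", path), "ParseError")
  }
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1):(ends[k] - 1)]
    hdr <- grepl("=", block, fixed = TRUE)
    keyvals <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(keyvals, `[`, character(1), 1))
    vals <- vapply(keyvals, function(x) paste(x[-1], collapse = "="), character(1))
    pep <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1])
    charge <- vals[match("CHARGE", keys)]
    polarity <- if (!is.na(charge) && grepl("-", charge)) "-" else "+"
    rt <- suppressWarnings(as.numeric(vals[match("RTINSECONDS", keys)])) / 60
    title <- vals[match("TITLE", keys)]
    peak_lines <- block[!hdr & nzchar(trimws(block))]
    peaks <- if (length(peak_lines)) {
      do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                            function(x) as.numeric(x[1:2])))
    } else matrix(numeric(0), ncol = 2)
    out[[k]] <- spectrum_record(pep, polarity, peaks, rt = rt,
                                title = if (is.na(title)) "" else title)
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra list of `"spectrum_record"` objects.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(s$title)) writeLines(paste0("TITLE=", s$title), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(paste0("CHARGE=1", s$polarity), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.2f", s$rt * 60), con)
    if (nrow(s$peaks) > 0) {
      writeLines(sprintf("%.6f %.2f", s$peaks[, 1], s$peaks[, 2]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
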