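#' Construct a single scan
#'
#' A scan is one centroided mass spectrum acquired at one time point within a
#' continuous measurement. Peaks are stored sorted by m/z and the total ion
#' current (TIC) is the sum of all peak intensities.
#'
#' @param mz numeric vector of peak m/z values (Da).
#' @param intensity numeric vector of peak intensities (counts, all >= 0).
#' @param scan_index integer scan index within the measurement (0-based,
#'   following the acquisition order).
#' @param time acquisition time in seconds, or `NA` if unknown.
#' @return An object of class `ms_scan` with fields `mz`, `intensity`,
#'   `scan_index`, `time` and `tic`.
#' @export
ms_scan <- function(mz, intensity, scan_index, time = NA_real_) {
  mz <- as.double(mz)
  intensity <- as.double(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length")
  }
  if (anyNA(mz) || anyNA(intensity)) stop("peaks must not contain NA")
  if (any(intensity < 0)) stop("negative intensity in scan ", scan_index)
  o <- order(mz)
  structure(
    list(
      mz = mz[o],
      intensity = intensity[o],
      scan_index = as.integer(scan_index),
      time = as.double(time),
      tic = sum(intensity)
    ),
    class = "ms_scan"
  )
}

#' @export
print.ms_scan <- function(x, ...) {
  cat(sprintf(
    "<ms_scan> index %d, %d peaks, TIC %.4g%s\n",
    x$scan_index, length(x$mz), x$tic,
    if (is.na(x$time)) "" else sprintf(", t = %.2f s", x$time)
  ))
  invisible(x)
}

#' Construct a measurement (an ordered series of scans)
#'
#' A measurement is one continuous acquisition from one sample (here,
#' typically ~5 minutes / ~300 scans). Scans are ordered by `scan_index`.
#'
#' @param label character label identifying the measurement.
#' @param scans list of [ms_scan()] objects.
#' @return An object of class `ms_measurement`.
#' @export
ms_measurement <- function(label, scans) {
  if (length(scans) < 1L) stop("a measurement needs at least one scan")
  idx <- vapply(scans, function(s) s$scan_index, integer(1))
  if (anyDuplicated(idx)) stop("duplicate scan_index in measurement")
  scans <- scans[order(idx)]
  structure(list(label = as.character(label), scans = scans),
            class = "ms_measurement")
}

#' @export
print.ms_measurement <- function(x, ...) {
  tics <- vapply(x$scans, function(s) s$tic, double(1))
  cat(sprintf("<ms_measurement> '%s': %d scans, median TIC %.4g\n",
              x$label, length(x$scans), stats::median(tics)))
  invisible(x)
}

#' @export
length.ms_measurement <- function(x) length(x$scans)

#' Read a centroided scan series from an mzML file
#'
#' Reads every MS spectrum of an mzML file into a measurement. Only
#' centroided (peak-picked) data are accepted: spectra flagged as
#' profile mode raise an error, since downstream binning operates on
#' discrete peak lists and silent centroiding would change the data.
#'
#' @param path path to an mzML file.
#' @param label measurement label; defaults to the file name without
#'   extension.
#' @return An [ms_measurement()].
#' @export
read_mzml <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) stop("no spectra in ", path)
  if (!is.null(hdr$centroided)) {
    profile <- which(!is.na(hdr$centroided) & !hdr$centroided)
    if (length(profile) > 0L) {
      stop(sprintf(
        "profile-mode spectrum in %s (spectrum %s); centroided data required",
        path, paste(hdr$seqNum[profile[1]], collapse = ", ")
      ))
    }
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  rt <- if (!is.null(hdr$retentionTime)) hdr$retentionTime else rep(NA_real_, nrow(hdr))
  scans <- vector("list", length(pk))
  for (i in seq_along(pk)) {
    scans[[i]] <- ms_scan(pk[[i]][, 1], pk[[i]][, 2],
                          scan_index = i - 1L, time = rt[i])
  }
  ms_measurement(label, scans)
}

#' Read a scan series from a delimited peak table
#'
#' The table dialect is fixed: comma- or tab-delimited UTF-8 text with a
#' header line naming the columns `scan_index`, `mz`, `intensity`. Rows are
#' grouped by `scan_index` into scans; duplicate (scan, m/z) rows have their
#' intensities summed, consistent with binning semantics.
#'
#' @param path path to the peak table.
#' @param label measurement label; defaults to the file name without
#'   extension.
#' @return An [ms_measurement()].
#' @export
read_peaktable <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  need <- c("scan_index", "mz", "intensity")
  if (!all(need %in% names(tab))) {
    stop("peak table must have header columns scan_index, mz, intensity")
  }
  if (nrow(tab) == 0L) stop("no scans in ", path)
  conv <- function(col) {
    x <- suppressWarnings(as.double(tab[[col]]))
    bad <- which(is.na(x) & !is.na(tab[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s at line %d of %s", col, bad[1] + 1L, path))
    }
    x
  }
  si <- conv("scan_index")
  mz <- conv("mz")
  inten <- conv("intensity")
  if (any(inten < 0)) {
    stop("negative intensity at line ",
         which(inten < 0)[1] + 1L, " of ", path)
  }
  scans <- lapply(split(seq_len(nrow(tab)), si), function(rows) {
    m <- mz[rows]
    v <- inten[rows]
    # sum duplicate m/z within the scan
    agg <- rowsum(v, group = m)
    ms_scan(as.double(rownames(agg)), as.double(agg[, 1]),
            scan_index = si[rows[1]])
  })
  ms_measurement(label, unname(scans))
}

#' Write a measurement as a delimited peak table
#'
#' Inverse of [read_peaktable()]: writes `scan_index,mz,intensity` rows in
#' scan order.
#'
#' @param m an [ms_measurement()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_peaktable <- function(m, path, sep = ",") {
  stopifnot(inherits(m, "ms_measurement"))
  rows <- do.call(rbind, lapply(m$scans, function(s) {
    if (length(s$mz) == 0L) return(NULL)
    data.frame(scan_index = s$scan_index, mz = s$mz, intensity = s$intensity)
  }))
  if (is.null(rows)) rows <- data.frame(scan_index = integer(),
                                        mz = double(), intensity = double())
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Total ion current trace of a measurement
#'
#' @param m an [ms_measurement()].
#' @return A data frame with columns `scan_index` and `tic`, one row per
#'   scan in scan order.
#' @export
tic_trace <- function(m) {
  stopifnot(inherits(m, "ms_measurement"))
  data.frame(
    scan_index = vapply(m$scans, function(s) s$scan_index, integer(1)),
    tic = vapply(m$scans, function(s) s$tic, double(1))
  )
}

#' Write a TIC trace as CSV
#'
#' @param m an [ms_measurement()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tic_trace <- function(m, path) {
  utils::write.csv(tic_trace(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
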