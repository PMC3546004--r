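#' Construct a peak
#'
#' A peak is the apex of an analyte's intensity trace, represented as a triple
#' of a nominal-mass vector, an intensity vector of the same length, and a
#' retention time in seconds, plus bookkeeping about where it came from.
#'
#' @param chromatogram_id Identifier of the parent chromatogram.
#' @param index 1-based position of the peak within its parent chromatogram.
#' @param apex_scan 1-based scan index of the peak apex.
#' @param mass_bins Ordered integer nominal masses (Da).
#' @param intensities Non-negative intensities, one per mass bin.
#' @param rt Retention time in seconds (>= 0).
#' @return An object of class `"peak"`.
#' @export
peak <- function(chromatogram_id, index, apex_scan, mass_bins, intensities, rt) {
  if (length(mass_bins) != length(intensities))
    stop("mass_bins and intensities must have equal length")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (rt < 0) stop("rt must be >= 0")
  structure(
    list(chromatogram_id = chromatogram_id, index = as.integer(index),
         apex_scan = as.integer(apex_scan),
         mass_bins = as.integer(mass_bins),
         intensities = as.numeric(intensities), rt = as.numeric(rt)),
    class = "peak")
}

#' Construct a chromatogram
#'
#' A chromatogram is an ordered set of peaks, optionally backed by the full
#' series of binned mass spectra (scans).
#'
#' @param id Identifier.
#' @param mass_range Inclusive integer pair `c(min_mass, max_mass)` in Da.
#' @param scans Optional dense numeric matrix, rows = scans, columns = mass
#'   bins spanning `mass_range`.
#' @param scan_rts Optional strictly increasing numeric vector of per-scan
#'   retention times in seconds; required when `scans` is given.
#' @param peaks Optional list of [peak()] objects, ordered by retention time.
#' @return An object of class `"chromatogram"`.
#' @export
chromatogram <- function(id, mass_range, scans = NULL, scan_rts = NULL,
                         peaks = list()) {
  mass_range <- as.integer(mass_range)
  if (length(mass_range) != 2L || mass_range[1] >= mass_range[2])
    stop("mass_range must be an increasing integer pair")
  n_bins <- mass_range[2] - mass_range[1] + 1L
  if (!is.null(scans)) {
    scans <- as.matrix(scans)
    if (ncol(scans) != n_bins)
      stop("scans must have one column per mass bin in mass_range")
    if (is.null(scan_rts)) stop("scan_rts required when scans are given")
    if (length(scan_rts) != nrow(scans))
      stop("scan_rts must have one entry per scan")
    if (any(diff(scan_rts) <= 0)) stop("scan_rts must be strictly increasing")
  }
  obj <- structure(
    list(id = id, mass_range = mass_range, scans = scans,
         scan_rts = scan_rts, peaks = peaks),
    class = "chromatogram")
  validate_chromatogram(obj)
  obj
}

validate_chromatogram <- function(chrom) {
  rts <- vapply(chrom$peaks, `[[`, numeric(1), "rt")
  if (length(rts) > 1L && any(diff(rts) < 0))
    stop("peaks must be ordered by nondecreasing rt")
  if (!is.null(chrom$scans) && length(chrom$peaks)) {
    apex <- vapply(chrom$peaks, `[[`, integer(1), "apex_scan")
    if (any(apex < 1L) || any(apex > nrow(chrom$scans)))
      stop("every peak apex_scan must lie within the scan series")
  }
  invisible(chrom)
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram '%s': %d peaks, %s scans, m/z %d-%d>\n",
              x$id, length(x$peaks),
              if (is.null(x$scans)) "no" else nrow(x$scans),
              x$mass_range[1], x$mass_range[2]))
  invisible(x)
}

#' Bin raw m/z readings onto integer nominal masses
#'
#' Each raw m/z value is rounded half-up to the nearest integer Da; the
#' intensities of readings that map to the same bin are summed. Readings whose
#' rounded mass falls outside `mass_range` are discarded.
#'
#' @param raw_mz Numeric m/z values.
#' @param raw_intensity Numeric intensities, same length as `raw_mz`.
#' @param mass_range Inclusive integer pair `c(min_mass, max_mass)`.
#' @return Numeric vector of length `max_mass - min_mass + 1`, named by bin.
#' @export
bin_masses <- function(raw_mz, raw_intensity, mass_range) {
  if (length(raw_mz) != length(raw_intensity))
    stop("raw_mz and raw_intensity must have equal length")
  mass_range <- as.integer(mass_range)
  if (mass_range[1] >= mass_range[2]) stop("mass_range min must be < max")
  if (length(raw_mz) && (!all(is.finite(raw_mz)) || !all(is.finite(raw_intensity))))
    stop("non-finite values in input")
  bins <- seq.int(mass_range[1], mass_range[2])
  out <- numeric(length(bins))
  names(out) <- bins
  if (length(raw_mz)) {
    # round half-up, not banker's rounding
    m <- as.integer(floor(raw_mz + 0.5))
    keep <- m >= mass_range[1] & m <= mass_range[2]
    if (any(keep)) {
      agg <- tapply(raw_intensity[keep], m[keep], sum)
      out[as.character(names(agg))] <- as.numeric(agg)
    }
  }
  out
}

#' Normalize a binned mass spectrum to unit Euclidean length
#'
#' All-zero input is returned unchanged.
#'
#' @param v Non-negative finite numeric vector.
#' @return Vector with Euclidean norm 1 (or all zeros).
#' @export
normalize_scan <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

#' Zero out intensities at a set of nominal masses
#'
#' Used to remove signals of derivatization reagents (e.g. masses 73 and 147
#' for TMS-derivatized samples) from all spectra of a chromatogram. Masses
#' outside the chromatogram's mass range are ignored; the operation is
#' idempotent.
#'
#' @param chrom A [chromatogram()].
#' @param masses Integer masses (Da) to zero.
#' @return The chromatogram with the listed bins zeroed in every peak
#'   spectrum and every scan.
#' @export
mask_masses <- function(chrom, masses) {
  masses <- as.integer(masses)
  cols <- masses - chrom$mass_range[1] + 1L
  cols <- cols[cols >= 1L & cols <= (chrom$mass_range[2] - chrom$mass_range[1] + 1L)]
  if (!length(cols)) return(chrom)
  if (!is.null(chrom$scans)) chrom$scans[, cols] <- 0
  chrom$peaks <- lapply(chrom$peaks, function(p) {
    p$intensities[cols] <- 0
    p
  })
  chrom
}

#' Read a tab-delimited peak list and attach peaks to a chromatogram
#'
#' Each line of the file describes one peak; the first column is the integer
#' apex scan index (further columns are ignored). The peak's spectrum is
#' looked up from the chromatogram's scan series at the apex scan and its
#' retention time from `scan_rts`.
#'
#' @param path Path to a tab-delimited peak-list file.
#' @param chrom A [chromatogram()] with scans and scan_rts.
#' @param base Index base of the file (0 or 1); files exported from peak
#'   finders commonly use 0-based apex indices, the default.
#' @return The chromatogram with `peaks` attached, sorted by retention time.
#' @export
read_peak_list <- function(path, chrom, base = 0L) {
  if (is.null(chrom$scans)) stop("chromatogram must carry a scan series")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  chrom$peaks <- list()
  if (!length(lines)) return(chrom)
  first <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  apex <- suppressWarnings(as.integer(first))
  bad <- which(is.na(apex) | suppressWarnings(as.numeric(first)) != apex)
  if (length(bad))
    stop(sprintf("line %d: first field '%s' is not an integer scan index",
                 bad[1], first[bad[1]]))
  apex <- apex - as.integer(base) + 1L  # to 1-based internal
  oob <- which(apex < 1L | apex > nrow(chrom$scans))
  if (length(oob))
    stop(sprintf("line %d: apex scan index %d outside scan range 1..%d",
                 oob[1], apex[oob[1]] + as.integer(base) - 1L, nrow(chrom$scans)))
  ord <- order(chrom$scan_rts[apex])
  apex <- apex[ord]
  bins <- seq.int(chrom$mass_range[1], chrom$mass_range[2])
  chrom$peaks <- lapply(seq_along(apex), function(i) {
    peak(chrom$id, i, apex[i], bins, chrom$scans[apex[i], ], chrom$scan_rts[apex[i]])
  })
  validate_chromatogram(chrom)
  chrom
}

#' Write a chromatogram's peak apex indices as a tab-delimited peak list
#'
#' @param chrom A [chromatogram()] with peaks.
#' @param path Output path.
#' @param base Index base to write (0 or 1).
#' @export
write_peak_list <- function(chrom, path, base = 0L) {
  apex <- vapply(chrom$peaks, `[[`, integer(1), "apex_scan")
  writeLines(as.character(apex - 1L + as.integer(base)), path)
  invisible(path)
}

#' Write a chromatogram's scan series as a dense TSV matrix
#'
#' Format: a one-line header `rt<TAB>m<min><TAB>...<TAB>m<max>` naming the
#' mass bins, then one row per scan with the retention time followed by the
#' binned intensities.
#'
#' @param chrom A [chromatogram()] with scans.
#' @param path Output path.
#' @export
write_scan_matrix <- function(chrom, path) {
  if (is.null(chrom$scans)) stop("chromatogram has no scan series")
  bins <- seq.int(chrom$mass_range[1], chrom$mass_range[2])
  df <- data.frame(rt = chrom$scan_rts, chrom$scans, check.names = FALSE)
  colnames(df) <- c("rt", paste0("m", bins))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense TSV scan matrix into a chromatogram
#'
#' @param path Path written by [write_scan_matrix()].
#' @param id Identifier for the new chromatogram (default: file base name).
#' @return A [chromatogram()] with scans and scan_rts.
#' @export
read_scan_matrix <- function(path, id = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (colnames(df)[1] != "rt") stop("scan matrix must start with an 'rt' column")
  bins <- as.integer(sub("^m", "", colnames(df)[-1]))
  if (any(is.na(bins)) || any(diff(bins) != 1L))
    stop("scan matrix header must name consecutive integer mass bins")
  chromatogram(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
               mass_range = range(bins),
               scans = as.matrix(df[, -1, drop = FALSE]),
               scan_rts = df$rt)
}

#' Read an ANDI-MS/netCDF chromatogram
#'
#' Adapter around the Bioconductor `mzR` reader: scans are binned onto integer
#' nominal masses with [bin_masses()] so the result is the same in-memory type
#' as [read_scan_matrix()] produces.
#'
#' @param path Path to an ANDI-MS (netCDF) file.
#' @param mass_range Inclusive integer mass range for binning.
#' @param id Identifier (default: file base name).
#' @return A [chromatogram()].
#' @export
read_andi <- function(path, mass_range, id = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("the ANDI/netCDF adapter requires the 'mzR' package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- t(vapply(pk, function(sp) bin_masses(sp[, 1], sp[, 2], mass_range),
                    numeric(mass_range[2] - mass_range[1] + 1L)))
  chromatogram(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
               mass_range = mass_range, scans = scans,
               scan_rts = hdr$retentionTime)
}

# ---- multiple alignment tables -------------------------------------------

#' Construct a multiple alignment table
#'
#' One row per aligned peak group (or per reference scan, for profile
#' alignments); one column per chromatogram holding the 1-based scan index of
#' that chromatogram's member, or `NA` for an absent entry.
#'
#' @param cells Integer matrix, rows = groups, columns = chromatograms.
#' @param chromatogram_ids Column identifiers.
#' @param median_rt Numeric vector of per-row median retention times (s).
#' @return A data frame of class `"alignment_table"` with the id columns and
#'   a `median_rt` column.
#' @export
alignment_table <- function(cells, chromatogram_ids, median_rt) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (ncol(cells) != length(chromatogram_ids))
    stop("one column per chromatogram id required")
  if (nrow(cells) != length(median_rt))
    stop("median_rt must have one entry per row")
  if (nrow(cells) && any(rowSums(!is.na(cells)) == 0L))
    stop("each row must have at least one present entry")
  df <- as.data.frame(cells)
  colnames(df) <- chromatogram_ids
  df$median_rt <- as.numeric(median_rt)
  class(df) <- c("alignment_table", "data.frame")
  df
}

#' Extract the scan-index cell matrix of an alignment table
#'
#' @param tab An [alignment_table()].
#' @return Integer matrix (NA = absent), one column per chromatogram.
#' @export
at_cells <- function(tab) {
  as.matrix(tab[, setdiff(colnames(tab), "median_rt"), drop = FALSE])
}

#' Chromatogram ids of an alignment table
#' @param tab An [alignment_table()].
#' @export
at_ids <- function(tab) setdiff(colnames(tab), "median_rt")

#' Write an alignment table as TSV
#'
#' Cells are scan indices in the requested base, or `-` for absent entries;
#' the last column is the row median retention time.
#'
#' @param tab An [alignment_table()].
#' @param path Output path.
#' @param base Index base to write (0 or 1).
#' @export
write_alignment_table <- function(tab, path, base = 0L) {
  cells <- at_cells(tab)
  out <- matrix(as.character(cells - 1L + as.integer(base)),
                nrow = nrow(cells))
  out[is.na(cells)] <- "-"
  df <- as.data.frame(out)
  colnames(df) <- at_ids(tab)
  df$median_rt <- tab$median_rt
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment table written by [write_alignment_table()]
#'
#' @param path Input path.
#' @param base Index base of the file (0 or 1).
#' @return An [alignment_table()].
#' @export
read_alignment_table <- function(path, base = 0L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (!"median_rt" %in% colnames(df))
    stop("alignment table must carry a median_rt column")
  ids <- setdiff(colnames(df), "median_rt")
  cells <- sapply(df[ids], function(x) {
    x[x == "-"] <- NA
    as.integer(x)
  })
  cells <- matrix(cells, nrow = nrow(df),
                  dimnames = list(NULL, ids)) + 1L - as.integer(base)
  alignment_table(cells, ids, as.numeric(df$median_rt))
}
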