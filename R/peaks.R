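#' Construct a CE fingerprint profile
#'
#' A profile is the peak list of one clone in one marker panel: fragment
#' sizes in base pairs (fractional values allowed, as reported by
#' fragment-analysis software) and peak heights in relative fluorescence
#' units (RFU).  Peaks are stored sorted by size; duplicate sizes are
#' collapsed to the tallest peak so that sizes are strictly increasing.
#'
#' @param clone_id Clone (sample) label.
#' @param panel Panel label, e.g. `"TBP-1"`, `"TBP-2"` or an AFLP primer
#'   combination id such as `"PC48"`.
#' @param size Numeric vector of fragment sizes (bp), all `> 0`.
#' @param height Numeric vector of peak heights (RFU), all `>= 0`.
#' @return An object of class `tbp_profile`: a list with elements
#'   `clone_id`, `panel` and `peaks` (a data frame with columns `size`,
#'   `height`, and logical flag columns `stutter` and `below_threshold`).
#' @export
tbp_profile <- function(clone_id, panel, size = numeric(), height = numeric()) {
  stopifnot(length(size) == length(height))
  size <- as.numeric(size)
  height <- as.numeric(height)
  if (any(!is.finite(size)) || any(size <= 0))
    stop("peak sizes must be finite and > 0")
  if (any(!is.finite(height)) || any(height < 0))
    stop("peak heights must be finite and >= 0")
  ord <- order(size, -height)
  size <- size[ord]
  height <- height[ord]
  keep <- !duplicated(size)
  peaks <- data.frame(
    size = size[keep],
    height = height[keep],
    stutter = logical(sum(keep)),
    below_threshold = logical(sum(keep))
  )
  structure(
    list(clone_id = as.character(clone_id), panel = as.character(panel),
         peaks = peaks),
    class = "tbp_profile"
  )
}

#' @export
print.tbp_profile <- function(x, ...) {
  cat(sprintf("<tbp_profile> clone %s, panel %s: %d peak(s)\n",
              x$clone_id, x$panel, nrow(x$peaks)))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10))
  invisible(x)
}

#' Read a fragment-analysis peak table
#'
#' Parses a delimited export (one row per detected peak) into a list of
#' [tbp_profile()] objects, one per (sample, panel) combination.  Column
#' names are mapped through `dialect`, so exports with arbitrary headers
#' can be read without editing the file.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param dialect Named list mapping the roles `sample`, `size`, `height`
#'   and (optionally) `panel` to column names in the file.  When no panel
#'   column is given, `default_panel` is used for every row.
#' @param sep Field separator; `"\t"` for TSV (default), `","` for CSV.
#' @param default_panel Panel label used when the file has no panel
#'   column.  Defaults to the file name without extension.
#' @return List of `tbp_profile` objects, ordered by first appearance of
#'   each (sample, panel) pair.
#' @export
read_peak_table <- function(path,
                            dialect = list(sample = "sample", size = "size",
                                           height = "height", panel = "panel"),
                            sep = "\t",
                            default_panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  for (role in c("sample", "size", "height")) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(tab))
      stop(sprintf("peak table '%s' is missing mandatory column '%s' (role: %s)",
                   path, if (is.null(col)) role else col, role))
  }
  size <- suppressWarnings(as.numeric(tab[[dialect$size]]))
  height <- suppressWarnings(as.numeric(tab[[dialect$height]]))
  bad <- which(is.na(size) | is.na(height))
  if (length(bad))
    stop(sprintf("non-numeric size/height in '%s' at data line %d",
                 path, bad[1]))
  sample <- as.character(tab[[dialect$sample]])
  panel_col <- dialect$panel
  if (!is.null(panel_col) && panel_col %in% names(tab)) {
    panel <- as.character(tab[[panel_col]])
  } else {
    if (is.null(default_panel))
      default_panel <- tools::file_path_sans_ext(basename(path))
    panel <- rep(default_panel, nrow(tab))
  }
  key <- paste(sample, panel, sep = "\r")
  out <- lapply(unique(key), function(k) {
    i <- which(key == k)
    tbp_profile(sample[i[1]], panel[i[1]], size[i], height[i])
  })
  out
}

#' Write profiles to a normalized peak table
#'
#' @param profiles A `tbp_profile` or list of them.
#' @param path Output file path (TSV with columns sample, panel, size,
#'   height).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(profiles, path) {
  if (inherits(profiles, "tbp_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    if (!nrow(p$peaks)) return(NULL)
    data.frame(sample = p$clone_id, panel = p$panel,
               size = sprintf("%.2f", p$peaks$size),
               height = p$peaks$height)
  }))
  if (is.null(rows))
    rows <- data.frame(sample = character(), panel = character(),
                       size = character(), height = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter peaks by height and size window
#'
#' Applies the detection threshold and scoring window used for dominant
#' fingerprint panels (for the AFLP panels of this pipeline: 150 RFU and
#' 50--450 bp).  The window is closed on both ends.  The input profile is
#' not modified; filtering is idempotent.
#'
#' @param profile A [tbp_profile()].
#' @param min_height Minimum peak height in RFU (`>= 0`).
#' @param size_window Length-2 numeric, closed size interval in bp.
#' @return A new `tbp_profile` containing only the passing peaks.
#' @export
filter_peaks <- function(profile, min_height = 150,
                         size_window = c(0, Inf)) {
  stopifnot(inherits(profile, "tbp_profile"),
            min_height >= 0, length(size_window) == 2,
            size_window[1] < size_window[2])
  keep <- profile$peaks$height >= min_height &
    profile$peaks$size >= size_window[1] &
    profile$peaks$size <= size_window[2]
  out <- profile
  out$peaks <- profile$peaks[keep, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}

#' Flag SSR stutter peaks
#'
#' PCR slippage across an SSR produces minor products one to a few repeat
#' units shorter than the true allele peak.  A peak is flagged as stutter
#' iff a taller peak exists at `size + k * unit` (within 0.5 bp) for some
#' `k` in `1..max_units`, and its height is strictly below
#' `max_rel_height` times that peak's height.  Flags are annotations
#' only; by default flagged peaks are kept for scoring.
#'
#' @param profile A [tbp_profile()].
#' @param unit SSR repeat unit length in nt (e.g. 3 for a CTT repeat).
#' @param max_units Largest repeat-unit offset considered (default 4).
#' @param max_rel_height Stutter peaks must be below this fraction of the
#'   main peak's height (default 1, i.e. merely shorter *and* lower).
#' @param size_tol Size-match tolerance in bp (default 0.5, sub-nucleotide
#'   CE sizing jitter).
#' @return The profile with its `stutter` flag column updated.
#' @export
flag_stutter <- function(profile, unit = 3, max_units = 4,
                         max_rel_height = 1, size_tol = 0.5) {
  stopifnot(inherits(profile, "tbp_profile"),
            unit >= 1, max_units >= 1,
            max_rel_height > 0, max_rel_height <= 1)
  pk <- profile$peaks
  n <- nrow(pk)
  flag <- logical(n)
  if (n > 1) {
    for (i in seq_len(n)) {
      for (k in seq_len(max_units)) {
        target <- pk$size[i] + k * unit
        j <- which(abs(pk$size - target) <= size_tol)
        if (length(j) &&
            any(pk$height[j] > pk$height[i] &
                pk$height[i] < max_rel_height * pk$height[j])) {
          flag[i] <- TRUE
          break
        }
      }
    }
  }
  out <- profile
  out$peaks$stutter <- flag
  out
}
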