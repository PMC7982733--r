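#' Construct a binary marker matrix
#'
#' @param cells Binary (0/1) matrix, clones in rows (rownames = clone
#'   ids), markers in columns.
#' @param panel Character vector, one panel label per column.
#' @param size Numeric vector, one representative fragment size (bp) per
#'   column (may be `NA` for anonymous markers).
#' @return Object of class `marker_matrix`: the cells matrix with
#'   attributes `panel` and `size`; column names are `"panel:size"` (or
#'   the supplied colnames when sizes are missing).
#' @export
marker_matrix <- function(cells, panel, size = rep(NA_real_, ncol(cells))) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (!all(cells %in% c(0L, 1L))) stop("cells must be binary 0/1")
  if (is.null(rownames(cells))) stop("cells must have clone ids as rownames")
  stopifnot(length(panel) == ncol(cells), length(size) == ncol(cells))
  cn <- ifelse(is.na(size), paste0(panel, ":", seq_len(ncol(cells))),
               paste0(panel, ":", format(size, trim = TRUE)))
  if (anyDuplicated(cn)) cn <- make.unique(cn)
  colnames(cells) <- cn
  structure(cells, panel = as.character(panel), size = as.numeric(size),
            class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d clone(s) x %d marker(s), %d panel(s)\n",
              nrow(x), ncol(x), length(unique(attr(x, "panel")))))
  invisible(x)
}

# subsetting keeps the panel/size attributes in step with the columns
#' @export
`[.marker_matrix` <- function(x, i, j, drop = FALSE) {
  cells <- unclass(x)
  attr(cells, "panel") <- NULL
  attr(cells, "size") <- NULL
  out <- cells[i, j, drop = FALSE]
  panel <- attr(x, "panel")
  size <- attr(x, "size")
  if (!missing(j)) {
    jj <- seq_len(ncol(cells))
    names(jj) <- colnames(cells)
    jj <- jj[j]
    panel <- panel[jj]
    size <- size[jj]
  }
  structure(out, panel = panel, size = size,
            class = c("marker_matrix", "matrix", "array"))
}

#' Bin peak sizes into markers
#'
#' Within each panel, peak sizes from all profiles are clustered by
#' single linkage: two sizes belong to the same marker iff they are
#' connected by a chain of gaps each `<= tolerance`.  Each cluster
#' becomes one marker labelled by its median size; a clone scores 1 for
#' a marker iff it contributed at least one peak to the cluster.  With
#' `tolerance = 0` every distinct size is its own marker.
#'
#' @param profiles List of [tbp_profile()] objects.
#' @param tolerance Maximum within-marker gap in bp (`>= 0`).  Defaults
#'   to 0.5, single-nucleotide CE resolution; 1.0 is typical for AFLP.
#' @param use_stutter Include peaks flagged as stutter (default `TRUE`;
#'   reproducible stutters are scored like any marker).
#' @return A [marker_matrix()] with one row per clone (ordered by first
#'   appearance) and one column per (panel, size cluster).
#' @export
bin_peaks <- function(profiles, tolerance = 0.5, use_stutter = TRUE) {
  stopifnot(tolerance >= 0)
  if (inherits(profiles, "tbp_profile")) profiles <- list(profiles)
  clones <- unique(vapply(profiles, `[[`, "", "clone_id"))
  long <- do.call(rbind, lapply(profiles, function(p) {
    pk <- p$peaks
    if (!use_stutter) pk <- pk[!pk$stutter, , drop = FALSE]
    if (!nrow(pk)) return(NULL)
    data.frame(clone = p$clone_id, panel = p$panel, size = pk$size)
  }))
  if (is.null(long) || !nrow(long)) stop("no peaks to bin")
  cols <- list()
  panels <- unique(long$panel)
  for (pn in panels) {
    sub <- long[long$panel == pn, , drop = FALSE]
    ord <- order(sub$size)
    sz <- sub$size[ord]
    cl <- sub$clone[ord]
    # single-linkage clusters on the line = runs split where gap > tolerance
    brk <- if (length(sz) > 1) which(diff(sz) > tolerance) else integer()
    grp <- rep(seq_len(length(brk) + 1L),
               diff(c(0L, brk, length(sz))))
    for (g in unique(grp)) {
      i <- which(grp == g)
      span <- max(sz[i]) - min(sz[i])
      if (tolerance > 0 && span > 5 * tolerance)
        warning(sprintf(
          "panel %s: marker cluster spanning %.2f bp (> 5 x tolerance); possible over-merge",
          pn, span))
      cols[[length(cols) + 1L]] <- list(
        panel = pn, size = stats::median(sz[i]), clones = unique(cl[i]))
    }
  }
  cells <- matrix(0L, length(clones), length(cols),
                  dimnames = list(clones, NULL))
  for (j in seq_along(cols)) cells[cols[[j]]$clones, j] <- 1L
  marker_matrix(cells,
                panel = vapply(cols, `[[`, "", "panel"),
                size = vapply(cols, `[[`, 0, "size"))
}

#' Concatenate marker matrices over panels
#'
#' Used for the combined-intron analysis: marker columns of several
#' panels (e.g. TBP first and second intron) are concatenated for the
#' same clone set, panel tags retained.
#'
#' @param ... [marker_matrix()] objects sharing the same clone rows.
#' @return A single [marker_matrix()].
#' @export
combine_marker_matrices <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1)
  rows <- rownames(mats[[1]])
  for (m in mats)
    if (!identical(sort(rownames(m)), sort(rows)))
      stop("marker matrices must contain the same clones")
  cells <- do.call(cbind, lapply(mats, function(m) unclass(m)[rows, , drop = FALSE]))
  marker_matrix(cells,
                panel = unlist(lapply(mats, attr, "panel")),
                size = unlist(lapply(mats, attr, "size")))
}

#' Write / read a marker matrix as wide TSV
#'
#' Columns are headed `panel:size`; rows are clones.
#'
#' @param matrix A [marker_matrix()].
#' @param path File path.
#' @return `path` invisibly / a [marker_matrix()].
#' @export
write_marker_matrix <- function(matrix, path) {
  df <- data.frame(clone = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_matrix
#' @export
read_marker_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- df[[1]]
  hdr <- colnames(cells)
  panel <- sub(":[^:]*$", "", hdr)
  size <- suppressWarnings(as.numeric(sub("^.*:", "", hdr)))
  marker_matrix(cells, panel = panel, size = size)
}

#' Panel amplification and polymorphism statistics
#'
#' For each panel: TNM, the total number of markers; NMM, the number of
#' monomorphic markers (present in every clone); and overall PP, the
#' percentage polymorphism `100 * (TNM - NMM) / TNM` computed over the
#' panel totals.
#'
#' @param matrix A [marker_matrix()].
#' @return List with `per_panel` (data frame: panel, TNM, NMM),
#'   `TNM_total`, `NMM_total` and `PP`.
#' @export
matrix_stats <- function(matrix) {
  stopifnot(inherits(matrix, "marker_matrix"), ncol(matrix) >= 1)
  panel <- attr(matrix, "panel")
  mono <- colSums(matrix) == nrow(matrix)
  per_panel <- data.frame(
    panel = unique(panel),
    TNM = as.integer(table(factor(panel, unique(panel)))),
    NMM = as.integer(tapply(mono, factor(panel, unique(panel)), sum))
  )
  tnm <- sum(per_panel$TNM)
  nmm <- sum(per_panel$NMM)
  list(per_panel = per_panel, TNM_total = tnm, NMM_total = nmm,
       PP = 100 * (tnm - nmm) / tnm)
}

#' Fixed private markers per group
#'
#' A marker is *fixed private* for group G iff it is present in every
#' clone of G and absent from every clone outside G.
#'
#' @param matrix A [marker_matrix()].
#' @param groups Named character vector or list mapping every clone id
#'   (names) to one group label.
#' @return Named integer vector of counts, one per group (group label
#'   order of first appearance).
#' @export
fixed_private_markers <- function(matrix, groups) {
  groups <- unlist(groups)
  miss <- setdiff(rownames(matrix), names(groups))
  if (length(miss))
    stop("clone(s) not mapped to a group: ", paste(miss, collapse = ", "))
  g <- groups[rownames(matrix)]
  labs <- unique(g)
  out <- stats::setNames(integer(length(labs)), labs)
  for (lab in labs) {
    inside <- unclass(matrix)[g == lab, , drop = FALSE]
    outside <- unclass(matrix)[g != lab, , drop = FALSE]
    fixed <- colSums(inside) == nrow(inside)
    private <- if (nrow(outside)) colSums(outside) == 0 else TRUE
    out[lab] <- sum(fixed & private)
  }
  out
}

#' Detected loci per clone and group means
#'
#' The number of detected loci (NDL) of a clone in a panel is its row sum
#' over that panel's markers.  Group NDL per panel is the mean over
#' member clones; a per-group grand mean over panels is reported both
#' exactly and rounded half-up to the nearest integer, as such tables
#' are customarily printed.
#'
#' @param matrix A [marker_matrix()].
#' @param groups Clone-to-group mapping as in [fixed_private_markers()].
#' @return List with `ndl` (matrix: groups x panels of mean NDL),
#'   `grand_mean` and `grand_mean_printed` (named per-group vectors).
#' @export
group_mean_loci <- function(matrix, groups) {
  groups <- unlist(groups)
  miss <- setdiff(rownames(matrix), names(groups))
  if (length(miss))
    stop("clone(s) not mapped to a group: ", paste(miss, collapse = ", "))
  g <- groups[rownames(matrix)]
  panel <- attr(matrix, "panel")
  labs <- unique(g)
  pans <- unique(panel)
  ndl <- matrix(NA_real_, length(labs), length(pans),
                dimnames = list(labs, pans))
  for (pn in pans) {
    sub <- unclass(matrix)[, panel == pn, drop = FALSE]
    rs <- rowSums(sub)
    for (lab in labs) ndl[lab, pn] <- mean(rs[g == lab])
  }
  gm <- rowMeans(ndl)
  list(ndl = ndl, grand_mean = gm, grand_mean_printed = round_half_up(gm))
}

#' Pairwise marker-count inflation
#'
#' Percent excess of one group's mean detected-locus count over
#' another's: `100 * (mean_A - mean_B) / mean_B`, reported rounded
#' half-up to the nearest integer.  An inflated marker complement is the
#' expected signature of a hybrid group carrying the union of two
#' parental marker sets.
#'
#' @param mean_a,mean_b Grand mean detected loci of the focal and the
#'   reference group (`mean_b > 0`).
#' @return List with `percent` (exact) and `printed` (integer).
#' @export
marker_inflation <- function(mean_a, mean_b) {
  stopifnot(mean_b > 0)
  pct <- 100 * (mean_a - mean_b) / mean_b
  list(percent = pct, printed = round_half_up(pct))
}

# round half away from zero, the convention of the printed tables
# (base round() rounds half to even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)
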