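#' Binary dissimilarity between clone fingerprints
#'
#' For each clone pair the matching counts are `a` (both present), `b`
#' (first only) and `c` (second only); joint absences `d` are ignored,
#' as is standard for dominant fingerprint markers.  Jaccard distance is
#' `1 - a / (a + b + c)`; Dice distance is `1 - 2a / (2a + b + c)`.  A
#' pair with `a + b + c = 0` gets distance 0 with a warning.
#'
#' @param matrix A [marker_matrix()] (or plain binary matrix with clone
#'   rownames).
#' @param metric `"jaccard"` or `"dice"`.
#' @return A [stats::dist] object with attribute `metric`.
#' @export
binary_distance <- function(matrix, metric = c("jaccard", "dice")) {
  metric <- match.arg(metric)
  x <- as.matrix(matrix)
  if (nrow(x) < 2) stop("need at least two clones")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sum(x[i, ] == 1 & x[j, ] == 1)
      b <- sum(x[i, ] == 1 & x[j, ] == 0)
      cc <- sum(x[i, ] == 0 & x[j, ] == 1)
      if (a + b + cc == 0) {
        warned <- TRUE
        dij <- 0
      } else {
        dij <- switch(metric,
                      jaccard = 1 - a / (a + b + cc),
                      dice = 1 - 2 * a / (2 * a + b + cc))
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (warned)
    warning("clone pair(s) with no scored markers; distance set to 0")
  out <- stats::as.dist(d)
  attr(out, "metric") <- metric
  out
}

#' p-distance between aligned sequences
#'
#' Proportion of differing sites between two aligned nucleotide
#' sequences.  With *complete* deletion, every alignment column that
#' contains a gap or ambiguity (anything outside A, C, G, T) in any
#' sequence is removed before comparison; with *pairwise* deletion such
#' columns are removed per pair.
#'
#' @param alignment Character vector of equal-length aligned sequences
#'   (named), or anything coercible via `as.character()` per element
#'   (e.g. a `Biostrings::DNAStringSet`).
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return A [stats::dist] object with attribute `metric = "p-distance"`.
#' @export
p_distance <- function(alignment, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  seqs <- toupper(vapply(alignment, function(s) as.character(s)[1], ""))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- mat %in% c("A", "C", "G", "T")
  dim(ok) <- dim(mat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (deletion == "complete") {
    keep <- colSums(ok) == n
    if (!any(keep)) stop("no alignment columns survive complete deletion")
    mat <- mat[, keep, drop = FALSE]
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- mean(mat[i, ] != mat[j, ])
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        keep <- ok[i, ] & ok[j, ]
        if (!any(keep)) stop("no shared unambiguous sites for a pair")
        d[i, j] <- d[j, i] <- mean(mat[i, keep] != mat[j, keep])
      }
    }
  }
  out <- stats::as.dist(d)
  attr(out, "metric") <- "p-distance"
  out
}
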