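#' Mantel matrix correlation with permutation test
#'
#' Pearson correlation between the `n(n-1)/2` off-diagonal entries of
#' two distance matrices over the same objects, with a one-tailed
#' permutation test: rows and columns of the second matrix are permuted
#' jointly and the p-value is `(1 + #\{r_perm >= r_obs\}) / (permutations
#' + 1)`.
#'
#' @param d1,d2 [stats::dist] objects or symmetric matrices with the
#'   same labels.  When the label sets match but the order differs, `d2`
#'   is reordered to `d1`; a genuine label mismatch is an error.
#' @param permutations Number of random permutations (default 999).
#' @param seed Optional integer seed.
#' @return Object of class `mantel_result`: list with `r`, `p`,
#'   `permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = NULL) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (is.null(l1) || is.null(l2))
    stop("both matrices must carry labels")
  if (!setequal(l1, l2))
    stop("label mismatch between the two distance matrices")
  m2 <- m2[l1, l1]
  n <- nrow(m1)
  low <- lower.tri(m1)
  v1 <- m1[low]
  r_obs <- stats::cor(v1, m2[low])
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(permutations)) {
    idx <- sample.int(n)
    if (stats::cor(v1, m2[idx, idx][low]) >= r_obs - 1e-12)
      count <- count + 1L
  }
  structure(list(r = r_obs, p = (1 + count) / (permutations + 1),
                 permutations = permutations, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$permutations))
  invisible(x)
}
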