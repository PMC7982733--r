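# shared fixture builders for the test suite

profile_from <- function(clone, panel, size, height = rep(1000, length(size))) {
  tbp_profile(clone, panel, size, height)
}

random_binary_matrix <- function(n_clones, n_markers, p = 0.5,
                                 panel = "PC1") {
  cells <- matrix(rbinom(n_clones * n_markers, 1, p), n_clones,
                  dimnames = list(paste0("c", seq_len(n_clones)), NULL))
  marker_matrix(cells, panel = rep(panel, n_markers))
}

# brute-force fixed-private oracle: per-marker scan, independent of the
# implementation under test
fpm_oracle <- function(cells, groups) {
  g <- groups[rownames(cells)]
  out <- setNames(integer(length(unique(g))), unique(g))
  for (j in seq_len(ncol(cells))) {
    for (lab in unique(g)) {
      inside <- cells[g == lab, j]
      outside <- cells[g != lab, j]
      if (all(inside == 1) && (length(outside) == 0 || all(outside == 0)))
        out[lab] <- out[lab] + 1L
    }
  }
  out
}

# connected components of the within-tolerance graph (binning oracle)
components_oracle <- function(sizes, tol) {
  n <- length(sizes)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(sizes[i] - sizes[j]) <= tol && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# one simulated hybrid-inference trio; returns verdict and expectation
run_trio <- function(type = c("hybrid", "parent", "unrelated"), seed,
                     dropout = 0.1, n_private = 100) {
  type <- match.arg(type)
  base <- list(n_shared = 60, n_polymorphic = 30, dropout_rate = dropout,
               seed = seed)
  if (type == "hybrid") {
    mm <- do.call(simulate_aflp_panel, c(list(
      groups = c(A = 3, B = 3),
      n_private_fixed = c(A = n_private, B = n_private),
      hybrid = list(name = "H", parents = c("A", "B"), size = 1,
                    n_private = 8)), base))
    cand <- "H1"; expected <- "hybrid"
  } else if (type == "parent") {
    mm <- do.call(simulate_aflp_panel, c(list(
      groups = c(A = 4, B = 3),
      n_private_fixed = c(A = n_private, B = n_private)), base))
    cand <- "A4"; expected <- "parent_A_like"
  } else {
    mm <- do.call(simulate_aflp_panel, c(list(
      groups = c(A = 3, B = 3, C = 1),
      n_private_fixed = c(A = n_private, B = n_private, C = n_private)),
      base))
    cand <- "C1"; expected <- "inconclusive"
  }
  rep <- call_hybrid(mm, cand, parents = c("A", "B"))
  list(verdict = rep$verdict, expected = expected, report = rep)
}
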