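#' Simulate a multi-species TBP study
#'
#' Builds several species models, derives clones with allelic SSR
#' variants from each, optionally adds interspecific hybrids between
#' the first two species, and simulates first- and second-intron CE
#' electropherograms for every clone.  This emulates the structure of a
#' clone-collection fingerprinting study: species-distinct amplicon
#' ladders, clone-level allelic variation, stutter peaks, and hybrid
#' profiles that merge two parental marker sets.
#'
#' @param n_species Number of species models.
#' @param clones_per_species Clones derived per species.
#' @param n_hybrids Hybrid clones between species 1 and 2 (0 when
#'   `n_species < 2`).
#' @param n_loci Loci per species model.
#' @param noise_sd Per-amplicon CE sizing error SD in bp.
#' @param seed Integer seed.
#' @return List with `clones` (named list of `tbp_clone`), `groups`
#'   (named clone -> species vector), `profiles_intron1`,
#'   `profiles_intron2` (lists of [tbp_profile()]).
#' @export
simulate_tbp_study <- function(n_species = 3, clones_per_species = 4,
                               n_hybrids = 2, n_loci = 6, noise_sd = 0.8,
                               seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  model_seeds <- sample.int(1e6, n_species)
  clone_seeds <- sample.int(1e6, n_species * clones_per_species + n_hybrids)
  sim_seeds <- sample.int(1e6, 2 * (n_species * clones_per_species + n_hybrids))
  models <- lapply(seq_len(n_species), function(i)
    make_species_model(sprintf("sp%d", i), n_loci = n_loci,
                       seed = model_seeds[i]))
  clones <- list()
  groups <- character()
  k <- 0L
  for (i in seq_len(n_species)) {
    for (j in seq_len(clones_per_species)) {
      k <- k + 1L
      id <- sprintf("sp%d_c%d", i, j)
      clones[[id]] <- derive_clone(models[[i]], id,
                                   n_variant_loci = min(1, n_loci - 1),
                                   seed = clone_seeds[k])
      groups[id] <- sprintf("sp%d", i)
    }
  }
  if (n_species >= 2 && n_hybrids > 0) {
    pa <- clones[[sprintf("sp1_c%d", 1)]]
    for (j in seq_len(n_hybrids)) {
      k <- k + 1L
      id <- sprintf("hyb_c%d", j)
      pb <- clones[[sprintf("sp2_c%d", min(j, clones_per_species))]]
      clones[[id]] <- make_hybrid_clone(pa, pb, id,
                                        mode = "allotetraploid_hybrid",
                                        seed = clone_seeds[k])
      groups[id] <- "hybrid"
    }
  }
  prof1 <- list(); prof2 <- list()
  for (i in seq_along(clones)) {
    prof1[[i]] <- simulate_electropherogram(clones[[i]], "intron1",
                                            noise_sd = noise_sd,
                                            seed = sim_seeds[2 * i - 1])
    prof2[[i]] <- simulate_electropherogram(clones[[i]], "intron2",
                                            noise_sd = noise_sd,
                                            seed = sim_seeds[2 * i])
  }
  list(clones = clones, groups = groups,
       profiles_intron1 = prof1, profiles_intron2 = prof2)
}

#' Score a CE-TBP study end to end
#'
#' The standard scoring chain for a two-region TBP fingerprinting
#' study: filter peaks, bin sizes into binary markers per region,
#' count polymorphic markers, compute Jaccard distances per region,
#' measure inter-region agreement by the Mantel test, concatenate the
#' two marker matrices and build the combined neighbor-joining tree.
#'
#' @param profiles_intron1,profiles_intron2 Lists of [tbp_profile()]
#'   for the two TBP regions (same clones).
#' @param min_height Peak detection threshold in RFU (default 150).
#' @param tolerance Binning tolerance in bp (default 0.5 for CE-TBP).
#' @param mantel_permutations,mantel_seed Mantel test parameters.
#' @return List with `matrix_intron1`, `matrix_intron2`, `combined`,
#'   `n_markers` (per region and total), `n_polymorphic`, `dist_intron1`,
#'   `dist_intron2`, `mantel` and `tree`.
#' @export
score_tbp_study <- function(profiles_intron1, profiles_intron2,
                            min_height = 150, tolerance = 0.5,
                            mantel_permutations = 999, mantel_seed = 1) {
  flt <- function(ps) lapply(ps, filter_peaks, min_height = min_height)
  m1 <- bin_peaks(flt(profiles_intron1), tolerance = tolerance)
  m2 <- bin_peaks(flt(profiles_intron2), tolerance = tolerance)
  s1 <- matrix_stats(m1); s2 <- matrix_stats(m2)
  d1 <- binary_distance(m1, "jaccard")
  d2 <- binary_distance(m2, "jaccard")
  mt <- mantel_test(d1, d2, permutations = mantel_permutations,
                    seed = mantel_seed)
  comb <- combine_marker_matrices(m1, m2)
  tree <- if (nrow(comb) >= 3) neighbor_joining(binary_distance(comb,
                                                                "jaccard"))
  else NULL
  list(matrix_intron1 = m1, matrix_intron2 = m2, combined = comb,
       n_markers = c(intron1 = s1$TNM_total, intron2 = s2$TNM_total,
                     total = s1$TNM_total + s2$TNM_total),
       n_polymorphic = c(intron1 = s1$TNM_total - s1$NMM_total,
                         intron2 = s2$TNM_total - s2$NMM_total,
                         total = (s1$TNM_total - s1$NMM_total) +
                           (s2$TNM_total - s2$NMM_total)),
       dist_intron1 = d1, dist_intron2 = d2, mantel = mt, tree = tree)
}

#' Score a deposited two-region peak table
#'
#' Convenience wrapper for re-analysing an exported CE-TBP peak table
#' (TSV with columns sample, panel, size, height, panels labelled
#' `TBP-1`/`TBP-2`): reads the table and runs [score_tbp_study()].
#'
#' @param path Peak table path.
#' @param panel_intron1,panel_intron2 Panel labels of the two regions.
#' @param ... Passed to [score_tbp_study()].
#' @return See [score_tbp_study()].
#' @export
score_tbp_peak_table <- function(path, panel_intron1 = "TBP-1",
                                 panel_intron2 = "TBP-2", ...) {
  profiles <- read_peak_table(path)
  pan <- vapply(profiles, `[[`, "", "panel")
  score_tbp_study(profiles[pan == panel_intron1],
                  profiles[pan == panel_intron2], ...)
}
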