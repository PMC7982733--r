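# Synthetic beta-tubulin locus architecture
# ----------------------------------------
# Every simulated locus follows the conserved land-plant beta-tubulin
# layout: three exons, two introns at fixed positions.  The generator's
# universal primer pairs sit at the exon-intron borders so that every
# region-1 amplicon equals intron1 + 305 nt of exonic flank and every
# region-2 amplicon equals intron2 + 232 nt, the constants observed at
# all annotated loci of the sequenced reference clones.  An SSR (CTT by
# default) inside intron 1 of some loci drives allelic length ladders
# and stutter artifacts.

# fixed synthetic universal primers (verbatim on the plus strand;
# reverse primers are embedded as their reverse complement)
SYN_PRIMER_SEQ <- c(
  F1 = "GCTACGTACGATCGATTGCAA",
  R1 = "CATGGATCCGTTAGCTAGGTT",
  F2 = "TTGACCGGTAGCATCAGGTCA",
  R2 = "GGTTACGCGATAGCTTCCAGT"
)

#' Universal primer pairs of the synthetic locus model
#'
#' The concrete primer sequences embedded by the generator at the
#' exon--intron borders of every synthetic beta-tubulin locus.  These
#' are synthetic stand-ins: the real universal TBP primer sequences are
#' not part of this package's data.
#'
#' @return Named list with `intron1` and `intron2`, each a list of
#'   `forward` and `reverse` [degenerate_primer()] objects.
#' @export
synthetic_tbp_primers <- function() {
  list(
    intron1 = list(forward = degenerate_primer("SYN-F1", SYN_PRIMER_SEQ["F1"]),
                   reverse = degenerate_primer("SYN-R1", SYN_PRIMER_SEQ["R1"])),
    intron2 = list(forward = degenerate_primer("SYN-F2", SYN_PRIMER_SEQ["F2"]),
                   reverse = degenerate_primer("SYN-R2", SYN_PRIMER_SEQ["R2"]))
  )
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic small integer from a string, for per-amplicon RNG streams
str_seed <- function(...) {
  s <- paste(..., collapse = "|")
  v <- utf8ToInt(s)
  as.integer(sum(v * (seq_along(v) %% 31 + 1)) %% 2147483L) + 1L
}

#' Build a synthetic species model
#'
#' Draws a set of beta-tubulin locus templates for one species: distinct
#' intron lengths per locus (so the species' predicted amplicon sizes do
#' not collide), an SSR inside intron 1 of a configurable fraction of
#' loci, and the universal primer sites embedded at the exon--intron
#' borders.  Deterministic for a fixed seed.
#'
#' @param species_id Species label.
#' @param n_loci Number of beta-tubulin loci (`>= 1`).  Duckweed genomes
#'   in this size range carry roughly 4--12.
#' @param intron1_range,intron2_range Integer intervals (nt) from which
#'   reference intron lengths are drawn without collision.
#' @param ssr List: `motif` (repeat unit, default `"CTT"`), `n_range`
#'   (admissible reference repeat counts), `pool_halfwidth` (allele pool
#'   spans `n0 +- halfwidth` units) and `prob` (fraction of loci whose
#'   intron 1 hosts the SSR).  Set `prob = 0` for SSR-free models.
#' @param flanks Exonic flank constants per region (nt), default
#'   [tbp_flank_constants()].
#' @param intron1_lengths,intron2_lengths Optional explicit reference
#'   intron lengths (one per locus), overriding the random draw.
#' @param seed Integer seed (required).
#' @return Object of class `tbp_species_model`.
#' @export
make_species_model <- function(species_id = "sp1", n_loci = 6,
                               intron1_range = c(80, 520),
                               intron2_range = c(60, 450),
                               ssr = list(motif = "CTT", n_range = c(5, 15),
                                          pool_halfwidth = 2, prob = 0.5),
                               flanks = tbp_flank_constants(),
                               intron1_lengths = NULL,
                               intron2_lengths = NULL,
                               seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_loci < 1) stop("n_loci must be >= 1")
  ssr_def <- list(motif = "CTT", n_range = c(5, 15), pool_halfwidth = 2,
                  prob = 0.5)
  ssr <- utils::modifyList(ssr_def, ssr)
  unit <- nchar(ssr$motif)
  min_flanks_in_intron <- 20L
  if (ssr$prob > 0 &&
      intron1_range[1] < unit * ssr$n_range[2] + min_flanks_in_intron)
    stop("intron1 range too small to host the SSR")
  if (diff(intron1_range) + 1 < n_loci || diff(intron2_range) + 1 < n_loci)
    stop("intron ranges too narrow to draw distinct lengths for all loci")
  set.seed(seed)
  # primer-site geometry (lengths of the exon segments flanking introns)
  b1 <- 155L                         # exon2 prefix through R1 3' end
  a1 <- as.integer(flanks[["intron1"]]) - b1   # F1 start to exon1 end
  b2 <- 122L                         # exon3 prefix through R2 3' end
  a2 <- as.integer(flanks[["intron2"]]) - b2   # F2 start to exon2 end
  if (a1 < 21 || a2 < 21) stop("flank constants too small for 21-nt primers")
  e1 <- a1 + 30L
  e2 <- b1 + a2 + 16L
  e3 <- b2 + 28L
  il1 <- if (!is.null(intron1_lengths)) {
    stopifnot(length(intron1_lengths) == n_loci)
    as.integer(intron1_lengths)
  } else sample(seq(intron1_range[1], intron1_range[2]), n_loci)
  il2 <- if (!is.null(intron2_lengths)) {
    stopifnot(length(intron2_lengths) == n_loci)
    as.integer(intron2_lengths)
  } else sample(seq(intron2_range[1], intron2_range[2]), n_loci)
  has_ssr <- stats::runif(n_loci) < ssr$prob
  loci <- vector("list", n_loci)
  allele_pool <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    exon1 <- strsplit(rand_dna(e1), "")[[1]]
    exon1[(e1 - a1 + 1):(e1 - a1 + 21)] <- strsplit(SYN_PRIMER_SEQ[["F1"]], "")[[1]]
    exon2 <- strsplit(rand_dna(e2), "")[[1]]
    exon2[(b1 - 20):b1] <- strsplit(rc(SYN_PRIMER_SEQ[["R1"]]), "")[[1]]
    exon2[(e2 - a2 + 1):(e2 - a2 + 21)] <- strsplit(SYN_PRIMER_SEQ[["F2"]], "")[[1]]
    exon3 <- strsplit(rand_dna(e3), "")[[1]]
    exon3[(b2 - 20):b2] <- strsplit(rc(SYN_PRIMER_SEQ[["R2"]]), "")[[1]]
    if (has_ssr[i]) {
      n0 <- sample(seq(ssr$n_range[1], ssr$n_range[2]), 1)
      base <- il1[i] - unit * n0
      if (base < min_flanks_in_intron) {
        n0 <- max(1L, (il1[i] - min_flanks_in_intron) %/% unit)
        base <- il1[i] - unit * n0
      }
      pool <- seq(max(1L, n0 - ssr$pool_halfwidth), n0 + ssr$pool_halfwidth)
    } else {
      n0 <- 0L
      base <- il1[i]
      pool <- 0L
    }
    left <- base %/% 2L
    loci[[i]] <- list(
      locus_id = sprintf("%s_L%02d", species_id, i),
      exon1 = paste(exon1, collapse = ""),
      exon2 = paste(exon2, collapse = ""),
      exon3 = paste(exon3, collapse = ""),
      intron1_left = rand_dna(left),
      intron1_right = rand_dna(base - left),
      intron2 = rand_dna(il2[i]),
      motif = ssr$motif,
      ref_repeat_n = n0,
      ssr_in_intron1 = has_ssr[i],
      intron1_ref_len = il1[i],
      intron2_len = il2[i]
    )
    allele_pool[[i]] <- pool
  }
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  names(allele_pool) <- names(loci)
  structure(list(species_id = species_id, loci = loci,
                 allele_pool = allele_pool, ssr_unit = unit,
                 flanks = flanks, seed = seed),
            class = "tbp_species_model")
}

# realize one locus at a given repeat count
realize_locus <- function(tmpl, n, flanks) {
  intron1 <- paste0(tmpl$intron1_left,
                    strrep(tmpl$motif, max(0L, n)),
                    tmpl$intron1_right)
  seq <- paste0(tmpl$exon1, intron1, tmpl$exon2, tmpl$intron2, tmpl$exon3)
  il1 <- nchar(intron1)
  il2 <- nchar(tmpl$intron2)
  e1 <- nchar(tmpl$exon1); e2 <- nchar(tmpl$exon2)
  list(locus_id = tmpl$locus_id,
       repeat_n = n,
       ssr_in_intron1 = tmpl$ssr_in_intron1,
       seq = seq,
       intron1_len = il1, intron2_len = il2,
       intron1_start = e1 + 1L, intron1_end = e1 + il1,
       intron2_start = e1 + il1 + e2 + 1L,
       intron2_end = e1 + il1 + e2 + il2,
       amp_intron1 = il1 + as.integer(flanks[["intron1"]]),
       amp_intron2 = il2 + as.integer(flanks[["intron2"]]))
}

#' Derive a clone genome from a species model
#'
#' Realizes every locus of the model at its reference allele and then
#' shifts `n_variant_loci` SSR-bearing loci by a random non-zero number
#' of repeat units from the locus allele pool (allelic InDel intron
#' variants).  The clone is diploid; both haplotypes are identical
#' unless `heterozygous = TRUE`, in which case the second haplotype
#' draws its own variant alleles.
#'
#' @param model A [make_species_model()] result.
#' @param clone_id Clone label.
#' @param n_variant_loci How many loci differ from the species reference
#'   (`<=` number of SSR-bearing loci).
#' @param heterozygous Draw independent alleles for the two haplotypes.
#' @param seed Integer seed.
#' @return Object of class `tbp_clone`.
#' @export
derive_clone <- function(model, clone_id, n_variant_loci = 0,
                         heterozygous = FALSE, seed) {
  stopifnot(inherits(model, "tbp_species_model"))
  if (missing(seed)) stop("a seed is required")
  if (n_variant_loci > length(model$loci))
    stop("n_variant_loci exceeds the number of loci")
  ssr_ids <- names(model$loci)[vapply(model$loci, `[[`, TRUE,
                                      "ssr_in_intron1")]
  if (n_variant_loci > length(ssr_ids))
    stop("variant requested on more loci than carry an SSR")
  set.seed(seed)
  pick <- if (n_variant_loci > 0) sample(ssr_ids, n_variant_loci) else character()
  draw_hap <- function() {
    lapply(model$loci, function(tmpl) {
      n <- tmpl$ref_repeat_n
      if (tmpl$locus_id %in% pick) {
        pool <- setdiff(model$allele_pool[[tmpl$locus_id]], n)
        if (!length(pool))
          stop("locus ", tmpl$locus_id, " has a single admissible allele")
        n <- if (length(pool) == 1) pool else sample(pool, 1)
      }
      realize_locus(tmpl, n, model$flanks)
    })
  }
  hap1 <- draw_hap()
  hap2 <- if (heterozygous) draw_hap() else hap1
  structure(list(clone_id = clone_id, species = model$species_id,
                 haplotypes = list(hap1, hap2),
                 ploidy_mode = "diploid",
                 ssr_unit = model$ssr_unit, flanks = model$flanks,
                 seed = seed),
            class = "tbp_clone")
}

#' Cross two clones into an interspecific hybrid
#'
#' A homoploid hybrid (AB) carries one haplotype sampled from each
#' parent; an allotetraploid (AABB) carries both full haplotype sets of
#' both parents.  In either mode the hybrid's predicted marker set is
#' the union of the contributed haplotypes' marker sets.
#'
#' @param a,b Parent [derive_clone()] genomes (expected to derive from
#'   different species models; same-species parents are flagged with a
#'   warning, not an error).
#' @param clone_id Label of the hybrid clone.
#' @param mode `"homoploid_hybrid"` or `"allotetraploid_hybrid"`.
#' @param seed Integer seed (haplotype sampling in homoploid mode).
#' @return A `tbp_clone` with `ploidy_mode` set to `mode`.
#' @export
make_hybrid_clone <- function(a, b, clone_id,
                              mode = c("homoploid_hybrid",
                                       "allotetraploid_hybrid"),
                              seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "tbp_clone"), inherits(b, "tbp_clone"))
  if (missing(seed)) stop("a seed is required")
  if (identical(a$species, b$species))
    warning("parents derive from the same species model")
  if (!identical(a$flanks, b$flanks))
    stop("parents were built with different flank constants")
  set.seed(seed)
  haps <- if (mode == "homoploid_hybrid") {
    list(a$haplotypes[[sample(length(a$haplotypes), 1)]],
         b$haplotypes[[sample(length(b$haplotypes), 1)]])
  } else {
    c(a$haplotypes, b$haplotypes)
  }
  structure(list(clone_id = clone_id,
                 species = c(a$species, b$species),
                 haplotypes = haps, ploidy_mode = mode,
                 ssr_unit = a$ssr_unit, flanks = a$flanks,
                 seed = seed),
            class = "tbp_clone")
}

#' Predicted amplicon sizes of a clone
#'
#' @param clone A `tbp_clone`.
#' @param region `"intron1"` or `"intron2"`.
#' @return Sorted unique predicted amplicon lengths (nt) over all
#'   haplotypes.
#' @export
clone_amplicon_sizes <- function(clone, region = c("intron1", "intron2")) {
  region <- match.arg(region)
  field <- if (region == "intron1") "amp_intron1" else "amp_intron2"
  sort(unique(unlist(lapply(clone$haplotypes, function(h)
    vapply(h, `[[`, 0L, field)))))
}

# amplicon predictions for a clone genome via its annotation
predict_clone_amplicons <- function(clone, region = c("intron1", "intron2"),
                                    forward = NULL, reverse = NULL,
                                    max_length = 2000) {
  region <- match.arg(region)
  if (is.null(forward) || is.null(reverse)) {
    pr <- synthetic_tbp_primers()[[region]]
    forward <- pr$forward; reverse <- pr$reverse
  }
  rows <- list()
  seen <- character()
  for (h in clone$haplotypes) {
    for (loc in h) {
      key <- paste(loc$locus_id, loc$repeat_n)
      if (key %in% seen) next
      seen <- c(seen, key)
      hit <- predict_amplicons(stats::setNames(loc$seq, loc$locus_id),
                               forward = forward, reverse = reverse,
                               region = region, max_length = max_length)
      if (nrow(hit)) {
        hit$intron_length <- if (region == "intron1") loc$intron1_len
        else loc$intron2_len
        rows[[length(rows) + 1L]] <- hit
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a CE-TBP electropherogram peak list
#'
#' One main peak per distinct predicted amplicon length of the clone in
#' the chosen region.  Detected size = predicted + a per-amplicon
#' rounded Gaussian error bounded to +-3 nt; this error is a property
#' of the clone/amplicon (derived from the clone's own seed), so
#' replicate amplifications of the same clone agree.  Heights are drawn
#' log-uniform in `rfu_range`.  SSR-bearing amplicons optionally gain
#' stutter peaks 1..`k_max` repeat units below the main peak, each with
#' height a Beta-distributed fraction (capped at `max_rel`) of the main
#' peak.
#'
#' @param clone A `tbp_clone`.
#' @param region `"intron1"` or `"intron2"`.
#' @param noise_sd SD (bp) of the per-amplicon sizing error; 0 for exact
#'   sizes.
#' @param stutter List: `enabled`, `k_max` (default 4), `max_rel` (cap
#'   on the stutter/main height ratio, default 0.6).
#' @param rfu_range Height range (RFU), log-uniform.
#' @param replicate_noise_sd Extra per-call sizing jitter (bp) for
#'   repeatability experiments; 0 keeps replicates identical in size.
#' @param seed Integer seed for the height/stutter draws of this
#'   amplification.
#' @return A [tbp_profile()] (panel `"TBP-1"` or `"TBP-2"`) with a
#'   `truth` attribute: data frame of main peaks (detected size,
#'   predicted size, locus ids) and the vector of stutter sizes.
#' @export
simulate_electropherogram <- function(clone,
                                      region = c("intron1", "intron2"),
                                      noise_sd = 0.8,
                                      stutter = list(enabled = TRUE,
                                                     k_max = 4,
                                                     max_rel = 0.6),
                                      rfu_range = c(500, 30000),
                                      replicate_noise_sd = 0,
                                      seed) {
  region <- match.arg(region)
  if (missing(seed)) stop("a seed is required")
  st_def <- list(enabled = TRUE, k_max = 4, max_rel = 0.6)
  stutter <- utils::modifyList(st_def, stutter)
  field <- if (region == "intron1") "amp_intron1" else "amp_intron2"
  panel <- if (region == "intron1") "TBP-1" else "TBP-2"
  loci <- unlist(clone$haplotypes, recursive = FALSE)
  if (!length(loci)) {
    prof <- tbp_profile(clone$clone_id, panel)
    attr(prof, "truth") <- list(main = data.frame(), stutter_sizes = numeric())
    return(prof)
  }
  pred <- vapply(loci, `[[`, 0L, field)
  has_ssr <- vapply(loci, `[[`, TRUE, "ssr_in_intron1") & region == "intron1"
  ids <- vapply(loci, `[[`, "", "locus_id")
  sizes <- sort(unique(pred))
  main <- data.frame(predicted = sizes)
  main$loci <- vapply(sizes, function(s)
    paste(sort(unique(ids[pred == s])), collapse = ","), "")
  main$ssr <- vapply(sizes, function(s) any(has_ssr[pred == s]), TRUE)
  # per-amplicon sizing error: a property of the clone, not of this call
  main$detected <- vapply(seq_len(nrow(main)), function(i) {
    if (noise_sd == 0) return(as.numeric(main$predicted[i]))
    err <- with_seed(str_seed(clone$clone_id, region, main$predicted[i],
                              clone$seed),
                     stats::rnorm(1, 0, noise_sd))
    main$predicted[i] + round(max(-3, min(3, err)))
  }, 0)
  set.seed(seed)
  if (replicate_noise_sd > 0)
    main$detected <- main$detected +
      round(pmax(-3, pmin(3, stats::rnorm(nrow(main), 0, replicate_noise_sd))))
  main$height <- exp(stats::runif(nrow(main), log(rfu_range[1]),
                                  log(rfu_range[2])))
  size <- main$detected
  height <- main$height
  stutter_sizes <- numeric()
  if (isTRUE(stutter$enabled)) {
    unit <- clone$ssr_unit
    for (i in which(main$ssr)) {
      for (k in seq_len(stutter$k_max)) {
        s <- main$detected[i] - k * unit
        if (s <= 0) next
        f <- stutter$max_rel * stats::rbeta(1, 2, 5) / k
        size <- c(size, s)
        height <- c(height, main$height[i] * f)
        stutter_sizes <- c(stutter_sizes, s)
      }
    }
  }
  # main peaks win collisions with stutter at the same size
  ord <- order(size, -height)
  keep <- !duplicated(size[ord])
  prof <- tbp_profile(clone$clone_id, panel, size[ord][keep],
                      height[ord][keep])
  attr(prof, "truth") <- list(main = main,
                              stutter_sizes = sort(unique(stutter_sizes)))
  prof
}

#' Write clone genomes to FASTA
#'
#' One record per haplotype locus, named
#' `<clone>|hap<i>|<locus_id>|n=<repeat count>`.
#'
#' @param clones A `tbp_clone` or list of them.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(clones, path) {
  if (inherits(clones, "tbp_clone")) clones <- list(clones)
  seqs <- character()
  for (cl in clones) {
    for (i in seq_along(cl$haplotypes)) {
      for (loc in cl$haplotypes[[i]]) {
        nm <- sprintf("%s|hap%d|%s|n=%d", cl$clone_id, i, loc$locus_id,
                      loc$repeat_n)
        seqs[nm] <- loc$seq
      }
    }
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export the planted truth of clones as JSON
#'
#' @param clones A `tbp_clone` or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(clones, path) {
  if (inherits(clones, "tbp_clone")) clones <- list(clones)
  truth <- lapply(clones, function(cl) {
    list(clone_id = cl$clone_id, species = cl$species,
         ploidy_mode = cl$ploidy_mode,
         amplicons_intron1 = clone_amplicon_sizes(cl, "intron1"),
         amplicons_intron2 = clone_amplicon_sizes(cl, "intron2"),
         loci = lapply(cl$haplotypes, function(h)
           lapply(unname(h), function(loc)
             list(locus_id = loc$locus_id, repeat_n = loc$repeat_n,
                  intron1_len = loc$intron1_len,
                  intron2_len = loc$intron2_len,
                  amp_intron1 = loc$amp_intron1,
                  amp_intron2 = loc$amp_intron2))))
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate an AFLP marker panel
#'
#' Plants a binary marker matrix with known structure: `n_shared`
#' markers present in every clone, `n_private_fixed[g]` fixed private
#' markers per group (present in all of group g, absent elsewhere),
#' `n_polymorphic[g]` markers segregating inside group g (random
#' non-empty proper member subsets), and optionally a hybrid group
#' whose rows are the union of one random member profile per parent
#' group plus `hybrid$n_private` planted hybrid-private markers.
#' Observational dropout then flips each 1 to 0 independently with
#' probability `dropout_rate`.
#'
#' @param groups Named integer vector: clones per (non-hybrid) group.
#' @param n_shared Count of markers shared by every clone.
#' @param n_private_fixed Per-group fixed private marker counts (single
#'   number recycled, or named per group).
#' @param n_polymorphic Per-group within-group polymorphic marker counts
#'   (groups of size 1 get none).
#' @param hybrid Optional list: `name`, `parents` (two group names),
#'   `size` (default 1), `n_private` (default 0).
#' @param dropout_rate Per-cell probability of losing a present marker.
#' @param panel Panel label.
#' @param seed Integer seed.
#' @return A [marker_matrix()] with attributes `groups` (named clone ->
#'   group vector) and `truth` (planted marker classes and, for each
#'   hybrid clone, the parent profiles it merged and its pre-dropout
#'   row).
#' @export
simulate_aflp_panel <- function(groups, n_shared = 40,
                                n_private_fixed = 20, n_polymorphic = 10,
                                hybrid = NULL, dropout_rate = 0,
                                panel = "PC1", seed) {
  if (missing(seed)) stop("a seed is required")
  if (is.null(names(groups)) || any(groups < 1))
    stop("groups must be a named vector of sizes >= 1")
  gnames <- names(groups)
  expand_per_group <- function(x) {
    if (is.null(names(x))) return(stats::setNames(rep(x, length.out =
                                                        length(gnames)), gnames))
    if (!all(gnames %in% names(x))) stop("per-group counts must cover all groups")
    x[gnames]
  }
  npf <- expand_per_group(n_private_fixed)
  npoly <- expand_per_group(n_polymorphic)
  npoly[groups < 2] <- 0
  set.seed(seed)
  clones <- unlist(lapply(gnames, function(g)
    sprintf("%s%d", g, seq_len(groups[[g]]))))
  gmap <- stats::setNames(rep(gnames, groups), clones)
  hclones <- character()
  if (!is.null(hybrid)) {
    stopifnot(all(hybrid$parents %in% gnames), length(hybrid$parents) == 2)
    hsize <- if (is.null(hybrid$size)) 1L else hybrid$size
    hpriv <- if (is.null(hybrid$n_private)) 0L else hybrid$n_private
    hclones <- sprintf("%s%d", hybrid$name, seq_len(hsize))
    gmap <- c(gmap, stats::setNames(rep(hybrid$name, hsize), hclones))
  }
  all_clones <- c(clones, hclones)
  cols <- list()
  add_col <- function(members, class) {
    cols[[length(cols) + 1L]] <<- list(members = members, class = class)
  }
  for (i in seq_len(n_shared)) add_col(all_clones, "shared")
  for (g in gnames) {
    memb <- clones[gmap[clones] == g]
    for (i in seq_len(npf[[g]])) add_col(memb, paste0("private:", g))
    if (npoly[[g]] > 0) {
      for (i in seq_len(npoly[[g]])) {
        k <- sample(length(memb) - 1L, 1)
        add_col(sample(memb, k), paste0("polymorphic:", g))
      }
    }
  }
  if (!is.null(hybrid) && hpriv > 0)
    for (i in seq_len(hpriv)) add_col(hclones, paste0("private:", hybrid$name))
  cells <- matrix(0L, length(all_clones), length(cols),
                  dimnames = list(all_clones, NULL))
  for (j in seq_along(cols)) cells[cols[[j]]$members, j] <- 1L
  hybrid_truth <- list()
  if (!is.null(hybrid)) {
    pa <- clones[gmap[clones] == hybrid$parents[1]]
    pb <- clones[gmap[clones] == hybrid$parents[2]]
    for (h in hclones) {
      da <- sample(pa, 1); db <- sample(pb, 1)
      merged <- pmax(cells[da, ], cells[db, ])
      own <- cells[h, ]        # planted hybrid-private (and shared) markers
      cells[h, ] <- pmax(merged, own)
      hybrid_truth[[h]] <- list(parent_a = da, parent_b = db,
                                row = cells[h, ])
    }
  }
  truth <- list(classes = vapply(cols, `[[`, "", "class"),
                planted_fpm = npf, hybrids = hybrid_truth)
  if (dropout_rate > 0) {
    drop <- matrix(stats::runif(length(cells)) < dropout_rate, nrow(cells))
    cells[drop & cells == 1L] <- 0L
  }
  sizes <- round(seq(50, 450, length.out = length(cols)), 1)
  out <- marker_matrix(cells, panel = rep(panel, length(cols)), size = sizes)
  attr(out, "groups") <- gmap
  attr(out, "truth") <- truth
  out
}
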