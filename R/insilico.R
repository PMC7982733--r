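IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define a (possibly degenerate) PCR primer
#'
#' @param name Primer label.
#' @param sequence 5'->3' sequence over the IUPAC nucleotide alphabet.
#' @param max_mismatches Mismatches tolerated when locating annealing
#'   sites (default 0).
#' @return Object of class `tbp_primer`.
#' @export
degenerate_primer <- function(name, sequence, max_mismatches = 0) {
  sequence <- toupper(gsub("[ ′-]", "", sequence))
  bad <- which(!strsplit(sequence, "")[[1]] %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("primer '%s': illegal character at position %d", name, bad[1]))
  structure(list(name = name, sequence = sequence,
                 max_mismatches = as.integer(max_mismatches)),
            class = "tbp_primer")
}

#' Expand a degenerate primer into concrete sequences
#'
#' Cartesian expansion over all degenerate positions; the number of
#' concrete sequences equals the product of the per-position code
#' cardinalities.
#'
#' @param primer A [degenerate_primer()] or plain IUPAC string.
#' @return Character vector of concrete A/C/G/T sequences.
#' @export
expand_iupac <- function(primer) {
  seq <- if (inherits(primer, "tbp_primer")) primer$sequence else
    toupper(primer)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("illegal IUPAC character at position %d", bad[1]))
  sets <- IUPAC_CODES[chars]
  out <- do.call(expand.grid,
                 c(rev(sets), list(stringsAsFactors = FALSE)))
  sort(apply(out[, rev(seq_along(sets)), drop = FALSE], 1, paste,
             collapse = ""))
}

#' Built-in single-locus diagnostic primer pair
#'
#' The gene-specific pair annealing to the first intron--exon borders of
#' the homoeologous loci TUBB 11-1 / TUBB 23-1 of the *L. minor* group,
#' which amplifies the 463-nt (allele A, *L. turionifera* type) and
#' 436-nt (allele B, *L. minor* type) diagnostic fragments.
#'
#' @return Named list of two [degenerate_primer()] objects.
#' @export
tbp_primers <- function() {
  list(
    forward = degenerate_primer("I-Fw_11-23_1", "TTCAGGGTATGCGATCTATTC"),
    reverse = degenerate_primer("I-Rv_11-23_1", "GGAATCCTGCAMKTAAATGAYG")
  )
}

# count mismatches of a concrete/IUPAC pattern against a subject window;
# an N in the subject never counts as a match
iupac_mismatches <- function(pattern_chars, window_chars) {
  mm <- 0L
  for (k in seq_along(pattern_chars)) {
    allowed <- IUPAC_CODES[[pattern_chars[k]]]
    if (!window_chars[k] %in% allowed) mm <- mm + 1L
  }
  mm
}

#' Locate primer annealing sites
#'
#' Forward hits are matches of the primer (any IUPAC expansion) on the
#' plus strand; reverse hits are matches of its reverse complement.  An
#' `N` in the subject sequence never counts as a match.  Matching is
#' delegated to `Biostrings::matchPattern` with the subject treated
#' literally.
#'
#' @param seq Subject sequence (character or `Biostrings::DNAString`).
#' @param primer A [degenerate_primer()].
#' @return Data frame with columns `start`, `end` (1-based inclusive),
#'   `strand` (`"+"`/`"-"`) and `mismatches`.
#' @export
find_primer_sites <- function(seq, primer) {
  stopifnot(inherits(primer, "tbp_primer"))
  subj <- Biostrings::DNAString(as.character(seq))
  subj_chars <- strsplit(as.character(subj), "")[[1]]
  scan <- function(pat_string, strand) {
    pat <- Biostrings::DNAString(pat_string)
    hits <- Biostrings::matchPattern(pat, subj,
                                     max.mismatch = primer$max_mismatches,
                                     fixed = "subject")
    st <- Biostrings::start(hits)
    en <- Biostrings::end(hits)
    keep <- st >= 1 & en <= length(subj)
    st <- st[keep]; en <- en[keep]
    if (!length(st))
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), mismatches = integer()))
    pat_chars <- strsplit(pat_string, "")[[1]]
    mm <- vapply(seq_along(st), function(i)
      iupac_mismatches(pat_chars, subj_chars[st[i]:en[i]]), 0L)
    ok <- mm <= primer$max_mismatches
    data.frame(start = st[ok], end = en[ok],
               strand = rep(strand, sum(ok)), mismatches = mm[ok])
  }
  fwd <- scan(primer$sequence, "+")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(primer$sequence)))
  rev <- scan(rc, "-")
  out <- rbind(fwd, rev)
  out[order(out$start), , drop = FALSE]
}

#' Region flank constants of the universal TBP primer pairs
#'
#' Exonic flank carried by each amplicon in addition to the intron: the
#' distance from the forward primer's 5' start to the end of the
#' upstream exon plus the downstream exon prefix through the reverse
#' primer's 3' end.  For the universal pairs used here the constants are
#' 305 nt (first-intron region) and 232 nt (second-intron region), so
#' `amplicon = intron + flank` at every locus of a region.
#'
#' @return Named numeric vector `c(intron1 = 305, intron2 = 232)`.
#' @export
tbp_flank_constants <- function() c(intron1 = 305, intron2 = 232)

#' Recover an intron length from an amplicon size
#'
#' @param amplicon Amplicon length(s) in nt.
#' @param region `"intron1"` or `"intron2"`.
#' @param flank Flank constants, as from [tbp_flank_constants()].
#' @return Intron length(s) in nt.
#' @export
intron_from_amplicon <- function(amplicon, region = c("intron1", "intron2"),
                                 flank = tbp_flank_constants()) {
  region <- match.arg(region)
  amplicon - flank[[region]]
}

#' Predict amplicons from a sequence set or clone genome
#'
#' Every (forward `+`, reverse `-`) site pair on the same sequence with
#' a positive span not exceeding `max_length` yields one predicted
#' amplicon; the amplicon length is the inclusive span from the forward
#' hit's 5' start to the reverse hit's 3' end.  When an intron
#' annotation is available (synthetic clone genomes carry one;
#' otherwise supply `annotation`), the intron length is reported
#' alongside.
#'
#' @param x Named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a synthetic clone genome
#'   (`tbp_clone`).
#' @param forward,reverse [degenerate_primer()] objects.  For a
#'   `tbp_clone`, defaults to the generator's universal pair for
#'   `region`.
#' @param region Region label recorded in the output (`"intron1"` or
#'   `"intron2"`).
#' @param max_length Length cap in nt suppressing spurious cross-locus
#'   pairings (default 2000).
#' @param annotation Optional named numeric vector of intron lengths per
#'   locus id.
#' @return Data frame with columns `locus_id`, `region`,
#'   `amplicon_length`, `intron_length`, `start`, `end`, `nested`.
#' @export
predict_amplicons <- function(x, forward = NULL, reverse = NULL,
                              region = c("intron1", "intron2"),
                              max_length = 2000, annotation = NULL) {
  region <- match.arg(region)
  if (inherits(x, "tbp_clone"))
    return(predict_clone_amplicons(x, region = region,
                                   forward = forward, reverse = reverse,
                                   max_length = max_length))
  if (is.null(forward) || is.null(reverse))
    stop("forward and reverse primers are required for raw sequences")
  seqs <- vapply(x, function(s) as.character(s)[1], "")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- list()
  for (id in names(seqs)) {
    sites_f <- find_primer_sites(seqs[[id]], forward)
    sites_r <- find_primer_sites(seqs[[id]], reverse)
    fw <- sites_f[sites_f$strand == "+", , drop = FALSE]
    rv <- sites_r[sites_r$strand == "-", , drop = FALSE]
    if (!nrow(fw) || !nrow(rv)) {
      message("no amplicon predicted for ", id, " (missing primer site)")
      next
    }
    for (i in seq_len(nrow(fw))) {
      for (j in seq_len(nrow(rv))) {
        len <- rv$end[j] - fw$start[i] + 1L
        if (len > 0 && len <= max_length)
          rows[[length(rows) + 1L]] <- data.frame(
            locus_id = id, region = region, amplicon_length = len,
            intron_length = if (!is.null(annotation) && id %in% names(annotation))
              annotation[[id]] else NA_real_,
            start = fw$start[i], end = rv$end[j])
      }
    }
  }
  if (!length(rows))
    return(data.frame(locus_id = character(), region = character(),
                      amplicon_length = integer(),
                      intron_length = numeric(),
                      start = integer(), end = integer(),
                      nested = logical()))
  out <- do.call(rbind, rows)
  # flag amplicons fully contained in a longer one on the same sequence
  out$nested <- vapply(seq_len(nrow(out)), function(i) {
    same <- out$locus_id == out$locus_id[i]
    any(same & out$start <= out$start[i] & out$end >= out$end[i] &
          (out$start < out$start[i] | out$end > out$end[i]))
  }, TRUE)
  rownames(out) <- NULL
  out
}

#' Assign CE peaks to predicted amplicons
#'
#' Each observed peak is matched to the nearest prediction with
#' `|detected - predicted| <= tolerance` (ties broken towards smaller
#' absolute delta, then smaller locus id).  Unmatched peaks are
#' re-tested against predictions shifted by whole SSR units
#' (`+- k * ssr_unit`, `k <= max_variant_units`) and, if matched,
#' flagged as allelic length variants.  One peak maps to at most one
#' locus; a prediction may collect several variant peaks.
#'
#' @param profile A [tbp_profile()].
#' @param predictions Data frame from [predict_amplicons()] (columns
#'   `locus_id`, `amplicon_length`).
#' @param tolerance Maximum |delta| in bp for a direct match (default 3,
#'   the largest sizing discrepancy observed between CE-detected and
#'   predicted amplicons).
#' @param ssr_unit SSR repeat unit in nt (default 3).
#' @param max_variant_units Largest repeat-unit shift tried (default 10).
#' @return Data frame with columns `size`, `locus_id` (`NA` when
#'   unassigned), `delta` (detected - predicted), `variant_flag`.
#' @export
assign_peaks <- function(profile, predictions, tolerance = 3,
                         ssr_unit = 3, max_variant_units = 10) {
  stopifnot(tolerance >= 0)
  sizes <- profile$peaks$size
  preds <- predictions[order(predictions$locus_id), , drop = FALSE]
  out <- data.frame(size = sizes, locus_id = NA_character_,
                    delta = NA_real_, variant_flag = FALSE)
  if (!nrow(preds)) return(out)
  for (i in seq_along(sizes)) {
    delta <- sizes[i] - preds$amplicon_length
    cand <- which(abs(delta) <= tolerance)
    if (length(cand)) {
      best <- cand[order(abs(delta[cand]), preds$locus_id[cand])][1]
      out$locus_id[i] <- preds$locus_id[best]
      out$delta[i] <- delta[best]
      next
    }
    # SSR ladder: integer repeat-unit shifts off a prediction
    best <- NULL
    for (k in seq_len(max_variant_units)) {
      for (s in c(-1, 1)) {
        resid <- sizes[i] - (preds$amplicon_length + s * k * ssr_unit)
        hit <- which(abs(resid) <= tolerance)
        if (length(hit)) {
          h <- hit[order(abs(resid[hit]), preds$locus_id[hit])][1]
          if (is.null(best) || abs(resid[h]) < best$resid) {
            best <- list(resid = abs(resid[h]), locus = preds$locus_id[h],
                         delta = sizes[i] - preds$amplicon_length[h])
          }
        }
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) {
      out$locus_id[i] <- best$locus
      out$delta[i] <- best$delta
      out$variant_flag[i] <- TRUE
    }
  }
  out
}

#' Reference beta-tubulin amplicon table for the sequenced clones
#'
#' Predicted and CE-detected amplicon sizes and intron lengths at every
#' beta-tubulin locus of the two fully sequenced *L. minor*-group clones
#' (8627 and 5500), for both TBP target regions.  Rows whose detected
#' peaks are SSR allelic variants are flagged.
#'
#' @return Data frame with columns `clone`, `locus`, `region`,
#'   `predicted`, `detected`, `detected_all`, `intron`,
#'   `allelic_variant`.
#' @export
tubb_reference <- function() {
  path <- system.file("extdata", "tubb_amplicons_lminor.tsv",
                      package = "tbpfinger")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Reference AFLP panel statistics for the *L. minor* species group
#'
#' Per-primer-combination marker totals (TNM), monomorphic counts (NMM)
#' and per-group mean detected-locus counts (NDL) for the four clone
#' groups of the *L. minor* complex, together with each group's fixed
#' private marker count and NDL total over the ten panels.  The
#' per-panel NDL entries are printed rounded to integers, so the group
#' totals (carried unrounded through the original analysis) are the
#' authoritative source for group grand means; summing the rounded
#' per-panel entries drifts by a few loci for some groups.
#'
#' @return List with elements `per_panel` (data frame), `fpm` (named
#'   numeric vector) and `group_means` (named numeric vector of grand
#'   mean NDL per group, totals / number of panels).
#' @export
aflp_reference <- function() {
  p1 <- system.file("extdata", "aflp_panel_stats.tsv", package = "tbpfinger")
  p2 <- system.file("extdata", "aflp_fixed_private.tsv",
                    package = "tbpfinger")
  per_panel <- utils::read.table(p1, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  grp <- utils::read.table(p2, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(per_panel = per_panel,
       fpm = stats::setNames(grp$fpm, grp$group),
       group_means = stats::setNames(grp$ndl_total / nrow(per_panel),
                                     grp$group))
}
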