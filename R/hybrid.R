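row_markers <- function(matrix, clone) {
  x <- unclass(matrix)
  if (!clone %in% rownames(x)) stop("clone not in matrix: ", clone)
  colnames(x)[x[clone, ] == 1]
}

#' Partition a candidate's markers by parental origin
#'
#' The reference set of a parent group is the union of its member
#' marker sets; the diagnostic set is the markers *fixed* in that group
#' (present in every member) and absent from every member of the other
#' group.  Each candidate marker is classified as `A_only`, `B_only`,
#' `shared_AB` or `candidate_private` by membership in the two
#' reference sets.
#'
#' @param candidate Character vector of the candidate's marker ids.
#' @param group_a,group_b Lists of member marker-id vectors (one per
#'   clone), non-empty.
#' @return Object of class `origin_partition`: list with `classes`
#'   (named per candidate marker), `counts`, the reference and
#'   diagnostic sets, and the candidate set.
#' @export
partition_origin <- function(candidate, group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  if (!length(candidate))
    warning("candidate has no markers; all class counts are zero")
  ref_a <- Reduce(union, group_a)
  ref_b <- Reduce(union, group_b)
  fixed_a <- Reduce(intersect, group_a)
  fixed_b <- Reduce(intersect, group_b)
  diag_a <- setdiff(fixed_a, ref_b)
  diag_b <- setdiff(fixed_b, ref_a)
  cls <- vapply(candidate, function(m) {
    ina <- m %in% ref_a; inb <- m %in% ref_b
    if (ina && inb) "shared_AB"
    else if (ina) "A_only"
    else if (inb) "B_only"
    else "candidate_private"
  }, "")
  lev <- c("A_only", "B_only", "shared_AB", "candidate_private",
           "unresolved")
  counts <- table(factor(cls, levels = lev))
  structure(list(classes = cls,
                 counts = stats::setNames(as.integer(counts), lev),
                 ref_a = ref_a, ref_b = ref_b,
                 diag_a = diag_a, diag_b = diag_b,
                 candidate = candidate),
            class = "origin_partition")
}

#' Union coverage and parental recovery of a partition
#'
#' `union_coverage` is the fraction of the candidate's markers found in
#' the union of the two parental reference sets (1 minus the
#' candidate-private fraction).  `parental_recovery` of a group is the
#' fraction of that group's diagnostic markers present in the
#' candidate (`NA` when the diagnostic set is empty).
#'
#' @param partition An [partition_origin()] result.
#' @return List with `union_coverage`, `parental_recovery_a`,
#'   `parental_recovery_b`.
#' @export
union_coverage <- function(partition) {
  stopifnot(inherits(partition, "origin_partition"))
  nc <- length(partition$candidate)
  cov <- if (nc == 0) 0 else
    1 - partition$counts[["candidate_private"]] / nc
  rec <- function(diag) {
    if (!length(diag)) return(NA_real_)
    mean(diag %in% partition$candidate)
  }
  list(union_coverage = cov,
       parental_recovery_a = rec(partition$diag_a),
       parental_recovery_b = rec(partition$diag_b))
}

#' Genotype a diagnostic codominant locus from peak sizes
#'
#' For a locus whose two alleles amplify at known distinct sizes (the
#' diagnostic single-locus assay of this pipeline uses 463 nt for the
#' *L. turionifera*-type allele A and 436 nt for the *L. minor*-type
#' allele B), the call is `AB` iff peaks match both sizes within
#' tolerance (the doublet of a hybrid), `AA`/`BB` for a single match,
#' `null` when neither allele is seen.
#'
#' @param peaks A [tbp_profile()] or numeric vector of peak sizes (bp).
#' @param alleleA_size,alleleB_size Expected amplicon sizes of the two
#'   alleles (must differ).
#' @param tolerance Size-match tolerance in bp (default 3).
#' @return Object of class `genotype_call`: list with `call` and
#'   `supporting` peak sizes.
#' @export
diagnostic_genotype <- function(peaks, alleleA_size = 463,
                                alleleB_size = 436, tolerance = 3) {
  if (inherits(peaks, "tbp_profile")) peaks <- peaks$peaks$size
  stopifnot(alleleA_size != alleleB_size, tolerance >= 0)
  hit_a <- peaks[abs(peaks - alleleA_size) <= tolerance]
  hit_b <- peaks[abs(peaks - alleleB_size) <= tolerance]
  call <- if (length(hit_a) && length(hit_b)) "AB"
  else if (length(hit_a)) "AA"
  else if (length(hit_b)) "BB"
  else "null"
  structure(list(call = call, supporting = c(hit_a, hit_b)),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype %s (supporting peaks: %s)\n", x$call,
              if (length(x$supporting))
                paste(x$supporting, collapse = ", ") else "none"))
  invisible(x)
}

#' Decide whether a candidate fingerprint is an interspecific hybrid
#'
#' Operationalizes the hybrid argument for codominant multilocus
#' fingerprints: a hybrid carries (nearly) the union of the two
#' parental marker sets, so both parental recoveries and the union
#' coverage should be high, and its marker count is inflated relative
#' to either parent group.  The verdict is `"hybrid"` iff both parental
#' recoveries reach `min_parental_recovery` and union coverage reaches
#' `min_union_coverage`; `"parent_A_like"`/`"parent_B_like"` when one
#' recovery is high and the other low (`<= 1 - min_parental_recovery`);
#' otherwise `"inconclusive"`.  Marker-count inflation is reported but,
#' being sensitive to per-clone marker-yield differences, is
#' informative only and never gates the verdict.  Note that a
#' codominant length fingerprint cannot distinguish a homoploid hybrid
#' from an allotetraploid; no ploidy claim is made.
#'
#' @param matrix A [marker_matrix()] containing candidate and parents.
#' @param candidate Candidate clone id.
#' @param parents Character vector of the two parent group labels.
#' @param groups Clone-to-group mapping (defaults to the matrix's
#'   `groups` attribute).
#' @param thresholds List: `min_parental_recovery` (default 0.8),
#'   `min_union_coverage` (default 0.9).
#' @param genotype Optional [diagnostic_genotype()] call to echo in the
#'   report.
#' @return Object of class `hybrid_report`.
#' @export
call_hybrid <- function(matrix, candidate, parents,
                        groups = attr(matrix, "groups"),
                        thresholds = list(min_parental_recovery = 0.8,
                                          min_union_coverage = 0.9),
                        genotype = NULL) {
  stopifnot(length(parents) == 2)
  th <- utils::modifyList(list(min_parental_recovery = 0.8,
                               min_union_coverage = 0.9), thresholds)
  if (is.null(groups)) stop("a clone-to-group mapping is required")
  groups <- unlist(groups)
  memb_a <- setdiff(names(groups)[groups == parents[1]], candidate)
  memb_b <- setdiff(names(groups)[groups == parents[2]], candidate)
  if (!length(memb_a) || !length(memb_b))
    stop("both parent groups need at least one member besides the candidate")
  cand_set <- row_markers(matrix, candidate)
  sets_a <- lapply(memb_a, row_markers, matrix = matrix)
  sets_b <- lapply(memb_b, row_markers, matrix = matrix)
  part <- partition_origin(cand_set, sets_a, sets_b)
  cov <- union_coverage(part)
  mean_a <- mean(vapply(sets_a, length, 0L))
  mean_b <- mean(vapply(sets_b, length, 0L))
  infl <- c(
    vs_a = if (mean_a > 0) marker_inflation(length(cand_set), mean_a)$percent
    else NA_real_,
    vs_b = if (mean_b > 0) marker_inflation(length(cand_set), mean_b)$percent
    else NA_real_)
  t <- th$min_parental_recovery
  ra <- cov$parental_recovery_a
  rb <- cov$parental_recovery_b
  verdict <- if (!is.na(ra) && !is.na(rb) && ra >= t && rb >= t &&
                 cov$union_coverage >= th$min_union_coverage) "hybrid"
  else if (!is.na(ra) && ra >= t && (!is.na(rb) && rb <= 1 - t)) "parent_A_like"
  else if (!is.na(rb) && rb >= t && (!is.na(ra) && ra <= 1 - t)) "parent_B_like"
  else "inconclusive"
  structure(list(candidate = candidate, parents = parents,
                 partition = part,
                 union_coverage = cov$union_coverage,
                 parental_recovery = c(A = ra, B = rb),
                 inflation = infl,
                 thresholds = th,
                 genotype = genotype,
                 verdict = verdict),
            class = "hybrid_report")
}

#' @export
print.hybrid_report <- function(x, ...) {
  cat(sprintf("Hybrid report for %s (parents %s / %s)\n", x$candidate,
              x$parents[1], x$parents[2]))
  cat("  marker classes:",
      paste(names(x$partition$counts), x$partition$counts, sep = "=",
            collapse = " "), "\n")
  cat(sprintf("  union coverage      %.3f (threshold %.2f)\n",
              x$union_coverage, x$thresholds$min_union_coverage))
  cat(sprintf("  parental recovery   A %.3f / B %.3f (threshold %.2f)\n",
              x$parental_recovery[["A"]], x$parental_recovery[["B"]],
              x$thresholds$min_parental_recovery))
  cat(sprintf("  marker inflation    %+.1f%% vs A, %+.1f%% vs B (informative only)\n",
              x$inflation[["vs_a"]], x$inflation[["vs_b"]]))
  if (!is.null(x$genotype))
    cat("  diagnostic genotype:", x$genotype$call, "\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Serialize a hybrid report to JSON
#'
#' @param report A [call_hybrid()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hybrid_report <- function(report, path) {
  out <- list(candidate = report$candidate, parents = report$parents,
              counts = as.list(report$partition$counts),
              union_coverage = report$union_coverage,
              parental_recovery = as.list(report$parental_recovery),
              inflation_percent = as.list(report$inflation),
              thresholds = report$thresholds,
              genotype = if (!is.null(report$genotype))
                report$genotype$call else NULL,
              verdict = report$verdict)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
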