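test_that("partition_origin classifies candidate markers by set membership", {
  part <- partition_origin(candidate = c("1", "2", "3", "4", "5"),
                           group_a = list(c("1", "2", "3")),
                           group_b = list(c("3", "4", "5")))
  expect_equal(part$counts[["A_only"]], 2)
  expect_equal(part$counts[["B_only"]], 2)
  expect_equal(part$counts[["shared_AB"]], 1)
  expect_equal(part$counts[["candidate_private"]], 0)
  expect_equal(sum(part$counts), 5)
  # pure parent-A pattern
  pa <- partition_origin(c("1", "2", "3"), list(c("1", "2", "3")),
                         list(c("4", "5")))
  expect_equal(pa$counts[["B_only"]], 0)
  # empty candidate warns, all-zero counts
  expect_warning(p0 <- partition_origin(character(),
                                        list("1"), list("2")), "no markers")
  expect_equal(sum(p0$counts), 0)
})

test_that("union_coverage and parental recovery behave at the boundaries", {
  part <- partition_origin(c("a", "f", "x"), list(c("a", "f"), c("a", "f")),
                           list(c("b")))
  cov <- union_coverage(part)
  expect_equal(cov$union_coverage, 2 / 3)
  expect_equal(cov$parental_recovery_a, 1)   # diag(A) = {a, f}
  expect_equal(cov$parental_recovery_b, 0)   # diag(B) = {b}, absent
  # coverage non-increasing in added candidate-private markers
  covs <- vapply(0:4, function(k) {
    cand <- c("a", "f", paste0("priv", seq_len(k)))
    union_coverage(partition_origin(cand, list(c("a", "f")),
                                    list("b")))$union_coverage
  }, 0)
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("diagnostic_genotype calls AA/BB/AB/null from peak sizes", {
  expect_equal(diagnostic_genotype(c(463, 436))$call, "AB")
  expect_equal(diagnostic_genotype(c(463))$call, "AA")
  expect_equal(diagnostic_genotype(c(436))$call, "BB")
  expect_equal(diagnostic_genotype(c(500))$call, "null")
  # tolerance respected
  expect_equal(diagnostic_genotype(c(465, 434), tolerance = 3)$call, "AB")
  expect_equal(diagnostic_genotype(c(465, 434), tolerance = 1)$call, "null")
  expect_error(diagnostic_genotype(c(400), alleleA_size = 400,
                                   alleleB_size = 400))
})

test_that("call_hybrid reaches the right verdict on clean cases", {
  mm <- simulate_aflp_panel(groups = c(A = 3, B = 3), n_shared = 20,
                            n_private_fixed = 25, n_polymorphic = 10,
                            hybrid = list(name = "H", parents = c("A", "B"),
                                          size = 1, n_private = 4),
                            dropout_rate = 0, seed = 55)
  rep <- call_hybrid(mm, "H1", parents = c("A", "B"))
  expect_equal(rep$verdict, "hybrid")
  # the 4 planted hybrid-private markers are candidate-private relative
  # to A u B, so coverage sits just below 1 but above the threshold
  expect_lt(rep$union_coverage, 1)
  expect_gte(rep$union_coverage, 0.9)
  expect_equal(rep$parental_recovery[["A"]], 1)
  expect_equal(rep$parental_recovery[["B"]], 1)
  expect_gt(rep$inflation[["vs_a"]], 0)
  # a perfect hybrid with no private markers covers the union exactly
  mm0 <- simulate_aflp_panel(groups = c(A = 3, B = 3), n_shared = 20,
                             n_private_fixed = 25, n_polymorphic = 10,
                             hybrid = list(name = "H", parents = c("A", "B"),
                                           size = 1, n_private = 0),
                             dropout_rate = 0, seed = 57)
  rep0 <- call_hybrid(mm0, "H1", parents = c("A", "B"))
  expect_equal(rep0$union_coverage, 1)
  # a parent member is parent-like
  mmp <- simulate_aflp_panel(groups = c(A = 4, B = 3), n_shared = 20,
                             n_private_fixed = 25, n_polymorphic = 10,
                             dropout_rate = 0, seed = 56)
  repp <- call_hybrid(mmp, "A4", parents = c("A", "B"))
  expect_equal(repp$verdict, "parent_A_like")
  expect_equal(repp$parental_recovery[["B"]], 0)
})

test_that("verdicts are symmetric under parent-group swap", {
  mm <- simulate_aflp_panel(groups = c(A = 3, B = 3), n_shared = 10,
                            n_private_fixed = 15, n_polymorphic = 5,
                            hybrid = list(name = "H", parents = c("A", "B"),
                                          size = 1, n_private = 2),
                            dropout_rate = 0, seed = 58)
  r1 <- call_hybrid(mm, "H1", parents = c("A", "B"))
  r2 <- call_hybrid(mm, "H1", parents = c("B", "A"))
  expect_equal(r1$verdict, r2$verdict)
  expect_equal(r1$parental_recovery[["A"]], r2$parental_recovery[["B"]])
  mmp <- simulate_aflp_panel(groups = c(A = 4, B = 3), n_shared = 10,
                             n_private_fixed = 15, n_polymorphic = 5,
                             dropout_rate = 0, seed = 59)
  p1 <- call_hybrid(mmp, "A4", parents = c("A", "B"))
  p2 <- call_hybrid(mmp, "A4", parents = c("B", "A"))
  expect_equal(p1$verdict, "parent_A_like")
  expect_equal(p2$verdict, "parent_B_like")
})

test_that("hybrid reports serialize to JSON", {
  mm <- simulate_aflp_panel(groups = c(A = 3, B = 3), n_shared = 10,
                            n_private_fixed = 15, n_polymorphic = 5,
                            hybrid = list(name = "H", parents = c("A", "B"),
                                          size = 1, n_private = 0),
                            dropout_rate = 0, seed = 60)
  rep <- call_hybrid(mm, "H1", parents = c("A", "B"),
                     genotype = diagnostic_genotype(c(463, 436)))
  tmp <- tempfile(fileext = ".json")
  write_hybrid_report(rep, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$verdict, "hybrid")
  expect_equal(back$genotype, "AB")
  expect_equal(back$counts$candidate_private, 0)
})
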