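test_that("species models are seed-deterministic and structurally sound", {
  m1 <- make_species_model("sp", n_loci = 6, seed = 1)
  m2 <- make_species_model("sp", n_loci = 6, seed = 1)
  expect_identical(m1, m2)
  m3 <- make_species_model("sp", n_loci = 6, seed = 2)
  l1 <- vapply(m1$loci, `[[`, 0L, "intron1_ref_len")
  l3 <- vapply(m3$loci, `[[`, 0L, "intron1_ref_len")
  expect_false(identical(l1, l3))
  # 9 loci -> 9 distinct first-intron amplicon lengths (drawn without collision)
  m9 <- make_species_model("sp", n_loci = 9, seed = 7)
  c9 <- derive_clone(m9, "c", seed = 1)
  expect_length(clone_amplicon_sizes(c9, "intron1"), 9)
  # single locus, SSR disabled -> allele pool of size 1
  m1l <- make_species_model("sp", n_loci = 1, ssr = list(prob = 0), seed = 3)
  expect_length(m1l$allele_pool[[1]], 1)
  expect_error(make_species_model("sp", n_loci = 0, seed = 1), "n_loci")
  expect_error(make_species_model("sp", n_loci = 2,
                                  intron1_range = c(30, 40), seed = 1),
               "too small")
})

test_that("every locus embeds the primer sites once and obeys the flank sums", {
  m <- make_species_model("sp", n_loci = 5, seed = 42)
  cl <- derive_clone(m, "c", seed = 1)
  pr <- synthetic_tbp_primers()
  for (loc in cl$haplotypes[[1]]) {
    for (region in c("intron1", "intron2")) {
      f <- find_primer_sites(loc$seq, pr[[region]]$forward)
      r <- find_primer_sites(loc$seq, pr[[region]]$reverse)
      expect_equal(sum(f$strand == "+"), 1)
      expect_equal(sum(r$strand == "-"), 1)
    }
    expect_equal(loc$amp_intron1 - loc$intron1_len, 305)
    expect_equal(loc$amp_intron2 - loc$intron2_len, 232)
  }
})

test_that("derive_clone shifts SSR alleles by whole units", {
  m <- make_species_model("sp", n_loci = 6, ssr = list(prob = 1), seed = 8)
  c0 <- derive_clone(m, "ref", n_variant_loci = 0, seed = 1)
  ref_sizes <- clone_amplicon_sizes(c0, "intron1")
  ref_by_locus <- vapply(c0$haplotypes[[1]], `[[`, 0L, "amp_intron1")
  # no variants: clone equals the model reference
  expect_equal(ref_by_locus,
               vapply(m$loci, function(l) l$intron1_ref_len + 305L,
                      0L, USE.NAMES = TRUE))
  c1 <- derive_clone(m, "var", n_variant_loci = 2, seed = 9)
  var_by_locus <- vapply(c1$haplotypes[[1]], `[[`, 0L, "amp_intron1")
  delta <- var_by_locus - ref_by_locus
  expect_equal(sum(delta != 0), 2)
  expect_true(all(delta %% 3 == 0))
  # reproducible
  expect_identical(derive_clone(m, "var", n_variant_loci = 2, seed = 9), c1)
  # cannot request variants on SSR-free loci
  m0 <- make_species_model("sp", n_loci = 3, ssr = list(prob = 0), seed = 2)
  expect_error(derive_clone(m0, "x", n_variant_loci = 1, seed = 1), "SSR")
})

test_that("hybrid marker sets are unions of the contributed haplotypes", {
  ma <- make_species_model("spA", n_loci = 6, seed = 11)
  mb <- make_species_model("spB", n_loci = 5, seed = 12)
  ca <- derive_clone(ma, "a", n_variant_loci = 1, heterozygous = TRUE,
                     seed = 13)
  cb <- derive_clone(mb, "b", seed = 14)
  hy <- make_hybrid_clone(ca, cb, "h", mode = "allotetraploid_hybrid",
                          seed = 15)
  expect_length(hy$haplotypes, 4)
  u <- sort(unique(c(clone_amplicon_sizes(ca, "intron1"),
                     clone_amplicon_sizes(cb, "intron1"))))
  expect_equal(clone_amplicon_sizes(hy, "intron1"), u)
  # homoploid: one haplotype per parent, reproducible choice
  h1 <- make_hybrid_clone(ca, cb, "h", mode = "homoploid_hybrid", seed = 16)
  h2 <- make_hybrid_clone(ca, cb, "h", mode = "homoploid_hybrid", seed = 16)
  expect_identical(h1, h2)
  expect_length(h1$haplotypes, 2)
  for (h in h1$haplotypes)
    expect_true(all(vapply(h, `[[`, 0L, "amp_intron1") %in% u))
  expect_warning(make_hybrid_clone(ca, ca, "x", seed = 1), "same species")
})

test_that("electropherogram simulation honours noise and stutter contracts", {
  m <- make_species_model("sp", n_loci = 6, ssr = list(prob = 1), seed = 20)
  cl <- derive_clone(m, "c", seed = 21)
  exact <- simulate_electropherogram(cl, "intron1", noise_sd = 0,
                                     stutter = list(enabled = FALSE),
                                     seed = 5)
  expect_equal(exact$peaks$size, clone_amplicon_sizes(cl, "intron1"))
  # same sizes for two seeds when noise_sd = 0, different RFU draws
  again <- simulate_electropherogram(cl, "intron1", noise_sd = 0,
                                     stutter = list(enabled = FALSE),
                                     seed = 6)
  expect_equal(again$peaks$size, exact$peaks$size)
  expect_false(identical(again$peaks$height, exact$peaks$height))
  # sizing error bounded by 3 nt and identical across replicate calls
  n1 <- simulate_electropherogram(cl, "intron1", noise_sd = 2,
                                  stutter = list(enabled = FALSE), seed = 7)
  n2 <- simulate_electropherogram(cl, "intron1", noise_sd = 2,
                                  stutter = list(enabled = FALSE), seed = 99)
  expect_equal(n1$peaks$size, n2$peaks$size)
  expect_true(all(abs(n1$peaks$size - exact$peaks$size) <= 3))
  # stutter peaks only at main - k*unit, strictly lower than their main
  st <- simulate_electropherogram(cl, "intron1", noise_sd = 0,
                                  stutter = list(enabled = TRUE, k_max = 4),
                                  seed = 8)
  truth <- attr(st, "truth")
  mains <- truth$main$detected
  for (s in truth$stutter_sizes) {
    src <- mains[(mains - s) %% 3 == 0 & mains > s & mains - s <= 12]
    expect_true(length(src) >= 1)
    main_h <- st$peaks$height[st$peaks$size %in% src]
    stut_h <- st$peaks$height[st$peaks$size == s]
    if (length(stut_h) && !(s %in% mains))
      expect_true(all(stut_h < max(main_h)))
  }
  # clone without loci -> empty profile
  empty <- cl; empty$haplotypes <- list()
  e <- simulate_electropherogram(empty, "intron1", seed = 1)
  expect_equal(nrow(e$peaks), 0)
})

test_that("simulated AFLP panels plant recoverable structure", {
  mm <- simulate_aflp_panel(groups = c(G1 = 3, G2 = 3, G3 = 2),
                            n_shared = 20,
                            n_private_fixed = c(G1 = 44, G2 = 26, G3 = 8),
                            n_polymorphic = 10, dropout_rate = 0, seed = 33)
  fpm <- fixed_private_markers(mm, attr(mm, "groups"))
  expect_equal(fpm, c(G1 = 44, G2 = 26, G3 = 8))
  # deterministic
  mm2 <- simulate_aflp_panel(groups = c(G1 = 3, G2 = 3, G3 = 2),
                             n_shared = 20,
                             n_private_fixed = c(G1 = 44, G2 = 26, G3 = 8),
                             n_polymorphic = 10, dropout_rate = 0, seed = 33)
  expect_identical(unclass(mm), unclass(mm2))
  # hybrid rows are unions: mean loci of the hybrid group >= parent means
  mh <- simulate_aflp_panel(groups = c(A = 3, B = 3), n_shared = 20,
                            n_private_fixed = 30, n_polymorphic = 10,
                            hybrid = list(name = "H", parents = c("A", "B"),
                                          size = 2, n_private = 5),
                            dropout_rate = 0, seed = 44)
  g <- attr(mh, "groups")
  rs <- rowSums(unclass(mh))
  expect_gte(mean(rs[g[rownames(mh)] == "H"]), mean(rs[g[rownames(mh)] == "A"]))
  expect_gte(mean(rs[g[rownames(mh)] == "H"]), mean(rs[g[rownames(mh)] == "B"]))
  # each hybrid row contains its recorded parents' rows
  tr <- attr(mh, "truth")
  for (h in names(tr$hybrids)) {
    pa <- tr$hybrids[[h]]$parent_a
    pb <- tr$hybrids[[h]]$parent_b
    expect_true(all(unclass(mh)[h, ] >= pmax(unclass(mh)[pa, ],
                                             unclass(mh)[pb, ])))
  }
})

test_that("clone FASTA and truth JSON exports are readable and faithful", {
  m <- make_species_model("sp", n_loci = 3, seed = 2)
  cl <- derive_clone(m, "c1", seed = 3)
  fa <- tempfile(fileext = ".fasta")
  write_clone_fasta(cl, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_length(seqs, 6)  # 3 loci x 2 haplotypes
  expect_true(all(grepl("^c1\\|hap[12]\\|sp_L0[123]\\|n=", names(seqs))))
  js <- tempfile(fileext = ".json")
  write_truth_json(cl, js)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$amplicons_intron1[[1]],
               clone_amplicon_sizes(cl, "intron1"))
})
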