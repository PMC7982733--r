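test_that("binary distances match hand counts and vegan, and Jaccard >= Dice", {
  cells <- rbind(c(1, 1, 0), c(1, 0, 1))
  rownames(cells) <- c("x", "y")
  m <- marker_matrix(cells, panel = rep("P", 3))
  expect_equal(as.numeric(binary_distance(m, "jaccard")), 1 - 1 / 3)
  expect_equal(as.numeric(binary_distance(m, "dice")), 1 - 2 / 4)
  # identical and disjoint rows
  cells2 <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  m2 <- marker_matrix(cells2, panel = rep("P", 4))
  dj <- as.matrix(binary_distance(m2, "jaccard"))
  expect_equal(dj["a", "b"], 0)
  expect_equal(dj["a", "c"], 1)
  skip_if_not_installed("vegan")
  set.seed(2)
  for (i in 1:10) {
    m3 <- random_binary_matrix(5, 20, p = 0.6)
    dj <- binary_distance(m3, "jaccard")
    dd <- binary_distance(m3, "dice")
    expect_equal(as.numeric(dj),
                 as.numeric(vegan::vegdist(unclass(m3), "jaccard",
                                           binary = TRUE)))
    expect_true(all(as.numeric(dj) >= as.numeric(dd) - 1e-12))
  }
})

test_that("p-distance handles complete and pairwise deletion", {
  expect_equal(as.numeric(p_distance(c(a = "ACGT", b = "ACGA"))), 0.25)
  # gap column dropped for everyone under complete deletion
  d <- p_distance(c(a = "A-GT", b = "AAGA"), deletion = "complete")
  expect_equal(as.numeric(d), 1 / 3)
  expect_equal(as.numeric(p_distance(c(a = "ACGT", b = "ACGT"))), 0)
  # complete removes a column for all, pairwise only for affected pairs
  al <- c(a = "ACGT", b = "AC-T", c = "ACGA")
  dc <- as.matrix(p_distance(al, "complete"))
  dp <- as.matrix(p_distance(al, "pairwise"))
  expect_equal(dc["a", "c"], 1 / 3)
  expect_equal(dp["a", "c"], 1 / 4)
  expect_error(p_distance(c(a = "----", b = "AAAA")), "survive")
  expect_error(p_distance(c(a = "ACG", b = "ACGT")), "equal length")
})

test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ reproduces additive matrices exactly (cophenetic equality)", {
  skip_if_not_installed("ape")
  set.seed(31)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.3, 2)
    D <- ape::cophenetic.phylo(tr)
    mine <- neighbor_joining(D)
    expect_equal(cophenetic_distances(mine)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ recovers the split and branch lengths of a 4-taxon tree", {
  # path distances of ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- neighbor_joining(D)
  expect_equal(cophenetic_distances(tr)[rownames(D), colnames(D)], D)
  # AB|CD split present
  n <- length(tr$tip.label)
  kids <- lapply((n + 1):(n + tr$Nnode), function(nd)
    sort(tbpfinger:::tips_below(tr, nd)))
  expect_true(any(vapply(kids, identical, TRUE, c("A", "B"))) ||
                any(vapply(kids, identical, TRUE, c("C", "D"))))
})

test_that("duplicate taxa form a deterministic zero-length cherry", {
  D <- matrix(c(0, 0, 5, 5, 0, 0, 5, 5, 5, 5, 0, 2, 5, 5, 2, 0), 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(write_newick(t1), write_newick(t2))
  cm <- cophenetic_distances(t1)
  expect_equal(cm["a", "b"], 0)
})

test_that("UPGMA builds ultrametric trees and recovers ultrametric input", {
  D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  cm <- cophenetic_distances(tr)
  expect_equal(cm["A", "B"], 2)       # cherry at height 1
  expect_equal(cm["A", "C"], 8)       # root at height 4
  expect_equal(setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label), c(C = 4, A = 1, B = 1)[tr$tip.label])
  # random ultrametric matrices: exact recovery by cophenetic equality
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:9, 1)
    base <- dist(matrix(rnorm(n * 4), n))
    attr(base, "Labels") <- paste0("t", 1:n)
    U <- as.matrix(cophenetic(hclust(base, "average")))  # ultrametric oracle
    mine <- upgma(U)
    expect_equal(cophenetic_distances(mine)[rownames(U), colnames(U)], U,
                 tolerance = 1e-8)
    # leaf-to-root depths all equal
    cm <- cophenetic_distances(mine)
    expect_lt(max(cm) / 2 - min(apply(cm, 1, max)) / 2, 1e-8)
  }
})

test_that("newick serialization round-trips and reports malformed input", {
  s <- "((A:1,B:1)75:3,C:4);"
  tr <- read_newick(s)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_true("75" %in% tr$node.label)
  expect_equal(write_newick(tr), s)
  expect_error(read_newick("((A:1,B:1):3,C:4"), "position")
  expect_error(read_newick("(A:1,:2);"), "position")
  skip_if_not_installed("ape")
  # agree with ape on a nontrivial tree
  set.seed(3)
  t0 <- ape::rtree(6)
  s0 <- ape::write.tree(t0)
  mine <- read_newick(s0)
  back <- ape::read.tree(text = write_newick(mine))
  expect_equal(ape::cophenetic.phylo(back)[t0$tip.label, t0$tip.label],
               ape::cophenetic.phylo(t0)[t0$tip.label, t0$tip.label],
               tolerance = 1e-6)
})

test_that("bootstrap gives 100% support to a clean split and is reproducible", {
  cells <- rbind(a = c(1, 1, 1, 0, 0, 0), b = c(1, 1, 1, 0, 0, 0),
                 c = c(1, 1, 0, 0, 0, 1),
                 d = c(0, 0, 0, 1, 1, 0), e = c(0, 0, 0, 1, 1, 0),
                 f = c(0, 0, 1, 1, 1, 0))
  m <- marker_matrix(cells, panel = rep("P", 6))
  tr <- bootstrap_support(m, "nj", "jaccard", replicates = 100, seed = 1)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(any(sup == 100))
  tr2 <- bootstrap_support(m, "nj", "jaccard", replicates = 100, seed = 1)
  expect_identical(write_newick(tr), write_newick(tr2))
  # single replicate runs
  tr3 <- bootstrap_support(m, "upgma", "dice", replicates = 1, seed = 9)
  expect_s3_class(tr3, "phylo")
})

test_that("mantel matches trivial identities and the exhaustive oracle", {
  set.seed(23)
  m1 <- as.matrix(dist(matrix(rnorm(24), 6)))
  rownames(m1) <- colnames(m1) <- letters[1:6]
  r <- mantel_test(m1, m1, permutations = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_gte(r$p, 1 / 100)
  r2 <- mantel_test(m1, 0.5 + 0.2 * m1, permutations = 99, seed = 1)
  expect_equal(r2$r, 1)
  expect_error(mantel_test(m1, m1[-1, -1]), "mismatch")
  # n = 4: Monte-Carlo p within binomial error of the exact 4! enumeration
  m4 <- as.matrix(dist(matrix(rnorm(12), 4)))
  rownames(m4) <- colnames(m4) <- letters[1:4]
  m4b <- as.matrix(dist(matrix(rnorm(12), 4)))
  rownames(m4b) <- colnames(m4b) <- letters[1:4]
  low <- lower.tri(m4)
  r_obs <- cor(m4[low], m4b[low])
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  exact <- mean(apply(perms, 1, function(p)
    cor(m4[low], m4b[p, p][low]) >= r_obs - 1e-12))
  B <- 1999
  mc <- mantel_test(m4, m4b, permutations = B, seed = 7)
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(mc$p - exact), 4 * se + 2 / B)
})
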