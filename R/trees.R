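# Internal tree nodes during agglomeration are nested lists:
#   leaf:     list(leaf = "label")
#   internal: list(children = list(list(node = <node>, length = <num>), ...),
#                  support = <num or NA>)
# build_phylo() converts the final nested node into an ape-compatible
# "phylo" structure (edge matrix, edge.length, tip.label, Nnode,
# node.label) without calling ape.

new_leaf <- function(label) list(leaf = label)

new_inner <- function(children, lengths, support = NA_real_) {
  list(children = Map(function(n, l) list(node = n, length = l),
                      children, lengths),
       support = support)
}

node_tips <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  unlist(lapply(node$children, function(ch) node_tips(ch$node)))
}

build_phylo <- function(root) {
  tips <- node_tips(root)
  n <- length(tips)
  env <- new.env(parent = emptyenv())
  env$edge <- matrix(0L, 0, 2)
  env$len <- numeric()
  env$tip <- character()
  env$nodelab <- character()
  env$next_tip <- 0L
  env$next_node <- n
  number <- function(node) {
    if (!is.null(node$leaf)) {
      env$next_tip <- env$next_tip + 1L
      env$tip[env$next_tip] <- node$leaf
      return(env$next_tip)
    }
    env$next_node <- env$next_node + 1L
    me <- env$next_node
    sup <- node$support
    env$nodelab[me - n] <- if (is.null(sup) || is.na(sup)) "" else
      format(sup, trim = TRUE)
    for (ch in node$children) {
      pos <- nrow(env$edge) + 1L
      env$edge <- rbind(env$edge, c(me, NA))
      env$len[pos] <- ch$length
      child_id <- number(ch$node)
      env$edge[pos, 2] <- child_id
    }
    me
  }
  number(root)
  structure(list(edge = env$edge, edge.length = env$len,
                 tip.label = env$tip, Nnode = env$next_node - n,
                 node.label = env$nodelab),
            class = "phylo", order = "cladewise")
}

# smallest leaf label under each active node; used for deterministic
# tie-breaking when two joins score equally
rep_label <- function(node) min(node_tips(node))

dist_to_matrix <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  m
}

#' Neighbor-joining tree
#'
#' Classic Saitou--Nei agglomeration from a dissimilarity matrix.  At
#' each step the pair minimising
#' `Q(i,j) = (m - 2) d(i,j) - r_i - r_j` is joined; ties are broken
#' deterministically towards the lexicographically lowest pair of leaf
#' labels.  Negative branch lengths are clamped to zero with the deficit
#' transferred to the sister edge.  The returned tree is unrooted (the
#' root node is a trifurcation).
#'
#' @param d A [stats::dist] or symmetric matrix with labels; at least 3
#'   taxa.
#' @return A `phylo` tree (ape-compatible).
#' @export
neighbor_joining <- function(d) {
  D <- dist_to_matrix(d)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  nodes <- lapply(rownames(D), new_leaf)
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (is.null(best) || q < best$q - 1e-12) {
          best <- list(q = q, i = i, j = j)
        } else if (abs(q - best$q) <= 1e-12) {
          key_new <- sort(c(rep_label(nodes[[i]]), rep_label(nodes[[j]])))
          key_old <- sort(c(rep_label(nodes[[best$i]]),
                            rep_label(nodes[[best$j]])))
          if (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2]))
            best <- list(q = q, i = i, j = j)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    u <- new_inner(list(nodes[[i]], nodes[[j]]), c(li, lj))
    keep <- setdiff(seq_len(m), c(i, j))
    du <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du), c(du, 0))
    nodes <- c(nodes[keep], list(u))
    rownames(D) <- colnames(D) <- NULL
  }
  # final trifurcation: closed-form three-taxon lengths
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  root <- new_inner(nodes, pmax(c(la, lb, lc), 0))
  build_phylo(root)
}

#' UPGMA tree
#'
#' Average-linkage agglomeration: the closest pair of clusters is merged
#' at height half their (size-weighted) mean distance, yielding a rooted
#' ultrametric tree.  Ties break towards the lexicographically lowest
#' pair of leaf labels.
#'
#' @param d A [stats::dist] or symmetric matrix with labels; at least 2
#'   taxa.
#' @return A rooted `phylo` tree.
#' @export
upgma <- function(d) {
  D <- dist_to_matrix(d)
  n <- nrow(D)
  if (n < 2) stop("UPGMA needs at least 2 taxa")
  nodes <- lapply(rownames(D), new_leaf)
  sizes <- rep(1, n)
  heights <- rep(0, n)
  while (length(nodes) > 1) {
    m <- length(nodes)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (is.null(best) || D[i, j] < best$d - 1e-12) {
          best <- list(d = D[i, j], i = i, j = j)
        } else if (abs(D[i, j] - best$d) <= 1e-12) {
          key_new <- sort(c(rep_label(nodes[[i]]), rep_label(nodes[[j]])))
          key_old <- sort(c(rep_label(nodes[[best$i]]),
                            rep_label(nodes[[best$j]])))
          if (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2]))
            best <- list(d = D[i, j], i = i, j = j)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- D[i, j] / 2
    u <- new_inner(list(nodes[[i]], nodes[[j]]),
                   c(h - heights[i], h - heights[j]))
    keep <- setdiff(seq_len(m), c(i, j))
    du <- (sizes[i] * D[i, keep] + sizes[j] * D[j, keep]) /
      (sizes[i] + sizes[j])
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du), c(du, 0))
    rownames(D) <- colnames(D) <- NULL
    nodes <- c(nodes[keep], list(u))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    heights <- c(heights[keep], h)
  }
  build_phylo(nodes[[1]])
}

# --- tree utilities -------------------------------------------------------

phylo_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  unlist(lapply(phylo_children(tree, node), function(ch) tips_below(tree, ch)))
}

# internal bipartitions as canonical keys.  For unrooted comparison the
# side of each split not containing the reference tip is used.
tree_splits <- function(tree, rooted = FALSE) {
  n <- length(tree$tip.label)
  root <- n + 1L
  inner <- setdiff(unique(tree$edge[, 1]), integer(0))
  nodes <- setdiff(sort(unique(tree$edge[, 2][tree$edge[, 2] > n])), root)
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1]
  keys <- vapply(nodes, function(nd) {
    s <- sort(tips_below(tree, nd))
    if (!rooted && ref %in% s) s <- setdiff(all_tips, s)
    paste(s, collapse = "\r")
  }, "")
  stats::setNames(keys, nodes)
}

#' Bootstrap support for a distance tree
#'
#' Columns (markers or alignment sites) are resampled with replacement;
#' the tree is rebuilt for each replicate, and each internal edge of the
#' point-estimate tree is annotated with the percentage of replicates
#' containing the same bipartition (clade, for rooted UPGMA trees).
#' Support values are stored in `node.label`.
#'
#' @param x A [marker_matrix()] (binary metrics) or aligned sequences
#'   (for `metric = "p-distance"`).
#' @param method `"nj"` or `"upgma"`.
#' @param metric `"jaccard"`, `"dice"` or `"p-distance"`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @return The point-estimate `phylo` tree with support percentages in
#'   `node.label` (root label empty).
#' @export
bootstrap_support <- function(x, method = c("nj", "upgma"),
                              metric = c("jaccard", "dice", "p-distance"),
                              replicates = 1000, seed = NULL) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  stopifnot(replicates >= 1)
  if (metric == "p-distance") {
    seqs <- toupper(vapply(x, function(s) as.character(s)[1], ""))
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    chars <- do.call(rbind, strsplit(seqs, ""))
    rownames(chars) <- names(seqs)
    ncols <- ncol(chars)
    dist_of <- function(cols) {
      sub <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      p_distance(stats::setNames(sub, rownames(chars)))
    }
  } else {
    cells <- unclass(as.matrix(x))
    ncols <- ncol(cells)
    dist_of <- function(cols)
      suppressWarnings(binary_distance(
        marker_matrix(cells[, cols, drop = FALSE],
                      panel = rep("boot", length(cols))),
        metric = metric))
  }
  builder <- if (method == "nj") neighbor_joining else upgma
  point <- builder(dist_of(seq_len(ncols)))
  rooted <- method == "upgma"
  keys <- tree_splits(point, rooted = rooted)
  hits <- stats::setNames(numeric(length(keys)), names(keys))
  done <- 0L
  if (!is.null(seed)) set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    rep_tree <- tryCatch(builder(dist_of(cols)), error = function(e) NULL)
    if (is.null(rep_tree)) next
    done <- done + 1L
    rk <- tree_splits(rep_tree, rooted = rooted)
    hits <- hits + as.numeric(keys %in% rk)
  }
  if (done == 0L) stop("all bootstrap replicates failed")
  support <- 100 * hits / done
  n <- length(point$tip.label)
  lab <- point$node.label
  for (k in seq_along(keys)) {
    nd <- as.integer(names(keys)[k])
    lab[nd - n] <- format(round(support[k], 1), trim = TRUE)
  }
  point$node.label <- lab
  attr(point, "replicates") <- done
  point
}

# --- Newick serialization -------------------------------------------------

fmt_len <- function(x) {
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Write a tree in Newick format
#'
#' Branch lengths are written to 6 decimal places; internal-node labels
#' (bootstrap support) are rendered after the closing parenthesis.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  n <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  recurse <- function(node, len) {
    if (node <= n) {
      s <- tree$tip.label[node]
    } else {
      idx <- which(tree$edge[, 1] == node)
      inner <- paste(vapply(idx, function(e)
        recurse(tree$edge[e, 2],
                if (has_len) tree$edge.length[e] else NA), ""),
        collapse = ",")
      lab <- if (!is.null(tree$node.label)) tree$node.label[node - n] else ""
      if (is.na(lab)) lab <- ""
      s <- paste0("(", inner, ")", lab)
    }
    if (has_len && !is.na(len)) s <- paste0(s, ":", fmt_len(len))
    s
  }
  out <- paste0(recurse(n + 1L, NA), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a Newick tree
#'
#' Recursive-descent parser; malformed input raises an error naming the
#' character position.  Internal node labels are kept in `node.label`.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Treat `text` as a path.
#' @return A `phylo` tree.
#' @export
read_newick <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  text <- gsub("[ \n\t]", "", text)
  pos <- 1L
  nc <- nchar(text)
  peek <- function() if (pos <= nc) substr(text, pos, pos) else ""
  fail <- function(msg) stop(sprintf("newick parse error at position %d: %s",
                                     pos, msg))
  read_label <- function() {
    start <- pos
    while (pos <= nc && !substr(text, pos, pos) %in%
           c("(", ")", ",", ":", ";")) pos <<- pos + 1L
    substr(text, start, pos - 1L)
  }
  read_length <- function() {
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    s <- read_label()
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) fail("invalid branch length")
    v
  }
  read_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      children <- list()
      lens <- numeric()
      repeat {
        ch <- read_node()
        children <- c(children, list(ch$node))
        lens <- c(lens, ch$length)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      lab <- read_label()
      sup <- suppressWarnings(as.numeric(lab))
      node <- new_inner(children, lens,
                        support = if (nzchar(lab) && !is.na(sup)) sup
                        else NA_real_)
      list(node = node, length = read_length())
    } else {
      lab <- read_label()
      if (!nzchar(lab)) fail("expected a taxon label")
      list(node = new_leaf(lab), length = read_length())
    }
  }
  root <- read_node()
  if (peek() != ";") fail("expected ';'")
  tree <- build_phylo(root$node)
  if (all(is.na(tree$edge.length))) tree$edge.length <- NULL
  else tree$edge.length[is.na(tree$edge.length)] <- 0
  tree
}

# cophenetic (leaf-to-leaf path length) matrix of a phylo tree; used by
# tests and by additive/ultrametric recovery checks
#' Pairwise leaf-to-leaf path distances of a tree
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric matrix of path-length distances between leaves.
#' @export
cophenetic_distances <- function(tree) {
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  depth <- numeric(total)
  parent <- integer(total)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    parent[ch] <- p
    depth[ch] <- depth[p] + tree$edge.length[e]
  }
  anc <- function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    ai <- anc(i)
    for (j in (i + 1):n) {
      aj <- anc(j)
      mrca <- intersect(ai, aj)[1]
      d[i, j] <- d[j, i] <- depth[i] + depth[j] - 2 * depth[mrca]
    }
  }
  d
}
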