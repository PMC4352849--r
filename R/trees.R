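#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration: the closest pair of clusters is merged at
#' the height of its distance, cluster distances are size-weighted averages,
#' and branch lengths halve merge heights so the tree is ultrametric (every
#' root-to-leaf path has the same length). Ties in the minimum distance are
#' broken by the lexicographically smallest pair of cluster labels (a
#' cluster is labelled by its smallest member), so output is deterministic.
#'
#' @param d a symmetric distance matrix with dimnames (or a `dist`).
#' @return a rooted, ultrametric `phylo` tree (package \pkg{ape}).
#' @export
upgma <- function(d) {
  d <- as_dist_matrix(d, min_taxa = 2)
  labels <- rownames(d)
  # build with placeholder labels: the final phylo carries the originals, so
  # arbitrary population names survive (ape's parser rewrites odd characters)
  ph <- sprintf("@%d@", seq_along(labels))
  nodes <- setNames(as.list(ph), labels) # Newick fragment per cluster
  height <- setNames(rep(0, length(labels)), labels)
  size <- setNames(rep(1L, length(labels)), labels)
  act <- d
  while (nrow(act) > 1) {
    pair <- min_pair(act)
    i <- pair[1]
    j <- pair[2]
    h <- act[i, j] / 2
    li <- rownames(act)[i]
    lj <- rownames(act)[j]
    new_lab <- min(li, lj)
    frag <- sprintf(
      "(%s:%.15g,%s:%.15g)",
      nodes[[li]], h - height[li], nodes[[lj]], h - height[lj]
    )
    others <- setdiff(rownames(act), c(li, lj))
    merged <- (size[li] * act[li, others] + size[lj] * act[lj, others]) /
      (size[li] + size[lj])
    act <- act[others, others, drop = FALSE]
    if (length(others) > 0) {
      act <- rbind(cbind(act, merged), c(merged, 0))
      rownames(act)[nrow(act)] <- new_lab
      colnames(act)[ncol(act)] <- new_lab
    } else {
      act <- matrix(0, 1, 1, dimnames = list(new_lab, new_lab))
    }
    nodes[[new_lab]] <- frag
    height[new_lab] <- h
    size[new_lab] <- size[li] + size[lj]
  }
  relabel_placeholders(
    ape::read.tree(text = paste0(nodes[[rownames(act)[1]]], ";")), labels
  )
}

relabel_placeholders <- function(phy, labels) {
  idx <- as.integer(sub("^@(\\d+)@$", "\\1", phy$tip.label))
  phy$tip.label <- labels[idx]
  phy
}

#' Neighbor-joining tree
#'
#' Saitou & Nei's agglomeration by the Q criterion, producing an unrooted
#' tree that exactly recovers any additive (four-point-condition) distance
#' matrix. Ties in Q are broken by the lexicographically smallest label
#' pair. A negative branch-length estimate is clipped to zero and its
#' deficit moved to the sister branch, preserving the path length through
#' the new node.
#'
#' @param d a symmetric distance matrix with dimnames (or a `dist`), at
#'   least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as_dist_matrix(d, min_taxa = 3)
  labels <- rownames(d)
  nodes <- setNames(as.list(sprintf("@%d@", seq_along(labels))), labels)
  act <- d
  while (nrow(act) > 3) {
    r <- nrow(act)
    rs <- rowSums(act)
    q <- (r - 2) * act - outer(rs, rs, `+`)
    diag(q) <- Inf
    pair <- min_pair(q)
    i <- pair[1]
    j <- pair[2]
    li <- rownames(act)[i]
    lj <- rownames(act)[j]
    bi <- act[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- act[i, j] - bi
    if (bi < 0) {
      bj <- bj + bi
      bi <- 0
    } else if (bj < 0) {
      bi <- bi + bj
      bj <- 0
    }
    new_lab <- min(li, lj)
    frag <- sprintf("(%s:%.15g,%s:%.15g)", nodes[[li]], bi, nodes[[lj]], bj)
    others <- setdiff(rownames(act), c(li, lj))
    dnew <- (act[li, others] + act[lj, others] - act[li, lj]) / 2
    act <- act[others, others, drop = FALSE]
    act <- rbind(cbind(act, dnew), c(dnew, 0))
    rownames(act)[nrow(act)] <- new_lab
    colnames(act)[ncol(act)] <- new_lab
    nodes[[new_lab]] <- frag
  }
  labs <- rownames(act)
  b1 <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  b2 <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  b3 <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  txt <- sprintf(
    "(%s:%.15g,%s:%.15g,%s:%.15g);",
    nodes[[labs[1]]], b[1], nodes[[labs[2]]], b[2], nodes[[labs[3]]], b[3]
  )
  relabel_placeholders(ape::read.tree(text = txt), labels)
}

# smallest off-diagonal entry; ties broken by the lexicographically
# smallest (sorted) pair of row/column labels
min_pair <- function(m) {
  mm <- m
  diag(mm) <- Inf
  idx <- which(mm == min(mm), arr.ind = TRUE)
  labs <- rownames(m)
  key <- apply(idx, 1, function(rc) {
    paste(sort(c(labs[rc[1]], labs[rc[2]])), collapse = "\r")
  })
  best <- idx[order(key)[1], ]
  sort(unname(best))
}

# quote a leaf label if it contains Newick metacharacters
nwk_label <- function(x) {
  ifelse(grepl("[][ \t(),:;']", x),
    paste0("'", gsub("'", "''", x), "'"), x
  )
}

as_dist_matrix <- function(d, min_taxa) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`d` must be a square matrix or dist")
  if (max(abs(d - t(d))) > 1e-8) abort("`d` must be symmetric")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) < min_taxa) {
    abort(paste0("need at least ", min_taxa, " taxa"))
  }
  d
}

#' Bootstrap-over-loci tree with support values
#'
#' Builds the reference tree from the full locus set, then resamples loci
#' with replacement `n_reps` times, rebuilding the DA distance matrix and
#' tree per replicate. The support of each internal edge of the reference
#' tree is the fraction of replicate trees containing the same bipartition
#' of the populations, stored as internal node labels (as tree-drawing
#' software expects).
#'
#' @param freqs multi-population frequency tibble.
#' @param loci locus set to resample from (default: loci shared by all
#'   populations).
#' @param n_reps bootstrap replicates.
#' @param method tree method, `"upgma"` or `"nj"`.
#' @param seed integer seed (`NULL`: session RNG).
#' @return the reference `phylo` tree with `node.label` support fractions.
#' @export
bootstrap_over_loci <- function(freqs, loci = NULL, n_reps = 1000,
                                method = c("upgma", "nj"), seed = NULL) {
  method <- match.arg(method)
  build <- if (method == "upgma") upgma else neighbor_joining
  d0 <- da_matrix(freqs, loci = loci)
  loci <- attr(d0, "loci_used")
  if (length(loci) < 2) {
    warn("bootstrap over a single locus is degenerate: all resamples identical")
  }
  ref <- build(d0)
  boots <- with_seed_or_rng(seed, {
    purrr::map(seq_len(n_reps), function(i) {
      bl <- sample(loci, length(loci), replace = TRUE)
      build(da_matrix(freqs, loci = bl))
    })
  })
  boot_splits <- purrr::map(boots, tree_bipartitions)
  ref_splits <- tree_bipartitions(ref)
  n_tip <- length(ref$tip.label)
  support <- vapply(seq_len(ref$Nnode), function(nd) {
    node_id <- n_tip + nd
    key <- split_key_for_node(ref, node_id)
    if (is.na(key)) return(NA_real_)
    mean(vapply(boot_splits, function(s) key %in% s, logical(1)))
  }, numeric(1))
  ref$node.label <- ifelse(is.na(support), "", sprintf("%.3f", support))
  attr(ref, "support") <- support
  attr(ref, "n_reps") <- n_reps
  ref
}

# Canonical bipartition keys of a tree: for each internal edge, the tip set
# on the side not containing the first (alphabetical) tip, sorted and
# collapsed to a string. Trivial splits (single tip / all-but-one) excluded.
tree_bipartitions <- function(phy) {
  n_tip <- length(phy$tip.label)
  keys <- vapply(seq_len(phy$Nnode), function(nd) {
    split_key_for_node(phy, n_tip + nd)
  }, character(1))
  keys[!is.na(keys)]
}

split_key_for_node <- function(phy, node_id) {
  tips <- sort(phy$tip.label)
  clade <- tips_under(phy, node_id)
  other <- setdiff(tips, clade)
  side <- if (tips[1] %in% clade) other else clade
  if (length(side) < 2 || length(side) > length(tips) - 2) {
    return(NA_character_)
  }
  paste(sort(side), collapse = "|")
}

tips_under <- function(phy, node_id) {
  n_tip <- length(phy$tip.label)
  if (node_id <= n_tip) return(phy$tip.label[node_id])
  kids <- phy$edge[phy$edge[, 1] == node_id, 2]
  unlist(lapply(kids, tips_under, phy = phy))
}

#' Newick serialization
#'
#' `to_newick()` writes a `phylo` tree (with branch lengths and any support
#' values as internal node labels) as a Newick string or file;
#' `from_newick()` parses one back. `from_newick(to_newick(t))` preserves
#' topology, branch lengths and node labels.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is also written there.
#' @return `to_newick()`: the Newick string (invisibly if `file` is given);
#'   `from_newick()`: a `phylo`.
#' @export
to_newick <- function(tree, file = NULL) {
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) {
      return(nwk_label(tree$tip.label[node]))
    }
    parts <- vapply(kids[[as.character(node)]], function(e) {
      s <- rec(tree$edge[e, 2])
      if (!is.null(tree$edge.length)) {
        s <- paste0(s, ":", sprintf("%.15g", tree$edge.length[e]))
      }
      s
    }, character(1))
    lab <- if (is.null(tree$node.label)) "" else {
      nl <- tree$node.label[node - n_tip]
      if (is.na(nl)) "" else nwk_label(nl)
    }
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  txt <- paste0(rec(n_tip + 1L), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname to_newick
#' @param text a Newick string (or path, for `file`-based reading use
#'   `ape::read.tree` directly).
#' @export
from_newick <- function(text) {
  ape::read.tree(text = text)
}
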