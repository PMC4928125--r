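# Distance-based gene trees: p-distances with pairwise deletion, a
# deterministic neighbor-joining implementation, column-resampling bootstrap
# support, and partition of rooted trees into clade-pure subfamilies with
# orthology pairing.

#' Protein p-distance matrix with pairwise deletion
#'
#' d(a, b) is the proportion of differing residues over the columns where
#' neither sequence has a gap; pairs with no comparable column are `NA`
#' (flagged undefined).
#'
#' @param aln Protein alignment tibble (`gene_id`, `seq`).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = gene ids.
#' @export
p_distance_matrix <- function(aln) {
  if (nrow(aln) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (length(unique(nchar(aln$seq))) != 1) {
    stop("sequences must have equal aligned length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$gene_id
  gap <- m == "-" | m == "." | m == "X"
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$gene_id, aln$gene_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      denom <- sum(ok)
      d[i, j] <- d[j, i] <- if (denom == 0) {
        NA_real_
      } else {
        sum(m[i, ok] != m[j, ok]) / denom
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (Studier-Keppler Q matrix). Ties in the Q matrix
#' break on the lowest index pair, so the result is deterministic given the
#' input taxon order. Negative estimated branch lengths are clamped to zero
#' with the deficit moved to the sibling branch, preserving path lengths.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (any(is.na(d))) {
    bad <- sort(which(is.na(d), arr.ind = TRUE)[1, ])
    stop(
      "undefined distance between ", rownames(d)[bad[1]], " and ",
      colnames(d)[bad[2]], call. = FALSE
    )
  }
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d)

  n_tip <- n
  next_node <- 2L * n_tip - 2L # internal node counter (ape numbering fixed later)
  # active entries: node id (tip 1..n_tip, internals n_tip+1..)
  active <- seq_len(n_tip)
  edges <- NULL # rows: parent, child, length
  next_internal <- n_tip + 1L

  D <- d
  ids <- active
  while (length(ids) > 3) {
    m <- length(ids)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest-index tie-break: scan column-major for the minimum
    min_q <- min(Q)
    hit <- which(Q - min_q <= abs(min_q) * 1e-12, arr.ind = TRUE)
    hit <- hit[order(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])), ,
      drop = FALSE
    ]
    i <- min(hit[1, ])
    j <- max(hit[1, ])
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) {
      vj <- vj + vi
      vi <- 0
    }
    if (vj < 0) {
      vi <- vi + vj
      vj <- 0
    }
    new <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(new, ids[i], vi), c(new, ids[j], vj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    ids <- c(ids[keep], new)
  }
  # final three-way join (closed form)
  i <- 1
  j <- 2
  k <- 3
  vi <- (D[i, j] + D[i, k] - D[j, k]) / 2
  vj <- (D[i, j] + D[j, k] - D[i, k]) / 2
  vk <- (D[i, k] + D[j, k] - D[i, j]) / 2
  root <- next_internal
  for (x in list(c(1, vi), c(2, vj), c(3, vk))) {
    v <- max(x[2], 0)
    edges <- rbind(edges, c(root, ids[x[1]], v))
  }

  # renumber internals into ape convention: tips 1..n, root n+1, then others
  internal <- sort(unique(edges[, 1]))
  new_id <- seq_len(n_tip + length(internal))
  map <- integer(max(internal))
  map[root] <- n_tip + 1L
  rest <- setdiff(internal, root)
  if (length(rest) > 0) map[rest] <- n_tip + 1L + seq_along(rest)
  renum <- function(x) ifelse(x <= n_tip, x, map[x])
  phy <- list(
    edge = cbind(renum(edges[, 1]), renum(edges[, 2])),
    edge.length = edges[, 3],
    tip.label = labels,
    Nnode = length(internal)
  )
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  stats::reorder(phy, "cladewise")
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances per replicate, and scores each internal bipartition of the
#' full-data tree by the percentage of replicates containing it. Replicates
#' with undefined distances are skipped (they stay in the denominator).
#'
#' @param aln Protein alignment tibble.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The full-data NJ `phylo` with `node.label` supports (0-100), an
#'   attribute `split_support` (named vector keyed by bipartition), and, for
#'   alignments of identical sequences, attribute `unresolved = TRUE` with
#'   all supports zero.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  d <- p_distance_matrix(aln)
  tree <- nj_tree(d)
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$gene_id
  n_col <- ncol(m)

  if (all(d == 0, na.rm = TRUE)) {
    supp <- rep(0, tree$Nnode)
    tree$node.label <- as.character(supp)
    attr(tree, "split_support") <- setNames(
      numeric(0), character(0)
    )
    attr(tree, "unresolved") <- TRUE
    return(tree)
  }

  keys_full <- split_keys(tree)
  counts <- setNames(rep(0, length(keys_full)), keys_full)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(n_col, n_col, replace = TRUE)
    rep_aln <- tibble::tibble(
      gene_id = aln$gene_id,
      seq = apply(m[, cols, drop = FALSE], 1, paste0, collapse = "")
    )
    dr <- p_distance_matrix(rep_aln)
    if (any(is.na(dr))) next
    kr <- split_keys(nj_tree(dr))
    hit <- intersect(keys_full, kr)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  tree$node.label <- vapply(
    seq_len(tree$Nnode) + length(tree$tip.label),
    function(node) {
      key <- node_split_key(tree, node)
      if (key %in% names(support)) {
        format(round(support[[key]], 1))
      } else {
        "" # root / trivial split
      }
    }, character(1)
  )
  attr(tree, "split_support") <- support
  tree
}

# canonical key of the bipartition induced by an internal node (or edge)
node_split_key <- function(tree, node) {
  leaves <- leaf_sets(tree)[[node]]
  all_l <- sort(tree$tip.label)
  side <- sort(leaves)
  other <- setdiff(all_l, side)
  if (length(side) < 2 || length(other) < 2) {
    return(NA_character_)
  }
  a <- paste(side, collapse = ",")
  b <- paste(other, collapse = ",")
  if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

# keys of all nontrivial bipartitions of a tree
split_keys <- function(tree) {
  n_tip <- length(tree$tip.label)
  keys <- vapply(
    seq_len(tree$Nnode) + n_tip,
    function(node) node_split_key(tree, node), character(1)
  )
  unique(keys[!is.na(keys)])
}

# Root an unrooted gene tree on the branch whose bipartition best separates
# the clades: maximise the number of leaves on their majority side; ties
# prefer the longer branch, then the lower edge index.
root_by_clade_purity <- function(tree, clade_map) {
  clade_of <- setNames(clade_map$clade, clade_map$gene_id)
  missing <- setdiff(tree$tip.label, names(clade_of))
  if (length(missing) > 0) {
    stop(
      "leaves missing from clade map: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  sets <- leaf_sets(tree)
  n_tip <- length(tree$tip.label)
  score <- vapply(seq_len(nrow(tree$edge)), function(e) {
    side <- sets[[tree$edge[e, 2]]]
    other <- setdiff(tree$tip.label, side)
    g1 <- sum(clade_of[side] == "grass")
    e1 <- length(side) - g1
    g2 <- sum(clade_of[other] == "grass")
    e2 <- length(other) - g2
    max(g1 + e2, e1 + g2)
  }, numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1) {
    best <- best[order(-tree$edge.length[best], best)][1]
  }
  node <- tree$edge[best, 2]
  len <- tree$edge.length[best]
  rooted <- phytools::reroot(tree, node, position = len / 2)
  stats::reorder(rooted, "cladewise")
}

#' Partition a gene tree into clade-pure subfamilies
#'
#' The tree is rooted on the branch best separating grasses from eudicots,
#' then cut into subfamilies: descending from the root, a clade-pure node
#' with bootstrap support at or above `min_support` becomes a subfamily
#' unless it is an within-clade duplication node (both children span two or
#' more species and their species sets overlap), in which case each side is
#' partitioned separately. Leaves covered by no qualifying clade become
#' singleton subfamilies flagged `unplaced`. Each subfamily is paired with
#' the subfamily(ies) of the opposite clade sharing its most recent common
#' ancestor.
#'
#' @param tree Gene tree (`phylo`), rooted or unrooted; node labels or a
#'   `split_support` attribute (from [bootstrap_support()]) supply supports,
#'   otherwise every split counts as fully supported.
#' @param clade_map Tibble mapping `gene_id` to `species` and `clade`.
#' @param min_support Minimum bootstrap percentage for a subfamily-defining
#'   node (default 50).
#' @return Tibble `subfamily_id`, `clade`, `gene_id`, `species`, `support`,
#'   `unplaced`, `partners` (comma-separated partner subfamily ids).
#' @export
partition_subfamilies <- function(tree, clade_map, min_support = 50) {
  clade_of <- setNames(clade_map$clade, clade_map$gene_id)
  species_of <- setNames(clade_map$species, clade_map$gene_id)
  support_tab <- attr(tree, "split_support")
  rooted <- root_by_clade_purity(tree, clade_map)
  n_tip <- length(rooted$tip.label)
  sets <- leaf_sets(rooted)
  children_of <- split(rooted$edge[, 2], rooted$edge[, 1])

  support_of <- function(node) {
    if (node <= n_tip) {
      return(NA_real_)
    }
    if (is.null(support_tab)) {
      return(100)
    }
    key <- node_split_key(rooted, node)
    if (is.na(key) || !(key %in% names(support_tab))) {
      return(100)
    }
    unname(support_tab[[key]])
  }
  is_dup_node <- function(node) {
    kids <- children_of[[as.character(node)]]
    if (is.null(kids) || length(kids) < 2) {
      return(FALSE)
    }
    sp <- lapply(kids, function(k) unique(species_of[sets[[k]]]))
    if (any(lengths(sp) < 2)) {
      return(FALSE)
    }
    for (a in seq_along(sp)) {
      for (b in seq_along(sp)) {
        if (a < b && length(intersect(sp[[a]], sp[[b]])) > 0) {
          return(TRUE)
        }
      }
    }
    FALSE
  }

  groups <- list()
  recurse <- function(node) {
    leaves <- sets[[node]]
    pure <- length(unique(clade_of[leaves])) == 1
    supp <- support_of(node)
    qualifies <- pure && (node <= n_tip || is.na(supp) || supp >= min_support)
    if (qualifies && !is_dup_node(node)) {
      groups[[length(groups) + 1]] <<- list(
        node = node, leaves = leaves,
        clade = unname(clade_of[leaves[1]]),
        support = if (node <= n_tip) NA_real_ else supp,
        unplaced = FALSE
      )
      return(invisible())
    }
    if (node <= n_tip) {
      groups[[length(groups) + 1]] <<- list(
        node = node, leaves = leaves, clade = unname(clade_of[leaves[1]]),
        support = NA_real_, unplaced = !qualifies
      )
      return(invisible())
    }
    for (k in children_of[[as.character(node)]]) recurse(k)
    invisible()
  }
  recurse(n_tip + 1L)

  # label subfamilies per clade in tree traversal order
  counters <- c(grass = 0L, eudicot = 0L)
  for (i in seq_along(groups)) {
    cl <- groups[[i]]$clade
    counters[cl] <- counters[cl] + 1L
    groups[[i]]$id <- paste0(
      ifelse(cl == "grass", "GSF", "ESF"), counters[cl]
    )
  }

  # orthology pairing: most recent common ancestor across clades
  depth <- node_depths(rooted)
  mrca_all <- ape::mrca(rooted, full = TRUE)
  node_of <- vapply(groups, function(g) g$node, numeric(1))
  clade_g <- vapply(groups, function(g) g$clade, character(1))
  partners <- rep("", length(groups))
  for (i in seq_along(groups)) {
    others <- which(clade_g != clade_g[i])
    if (length(others) == 0) next
    dep <- vapply(others, function(j) {
      depth[mrca_all[node_of[i], node_of[j]]]
    }, numeric(1))
    best <- others[dep == max(dep)]
    partners[i] <- paste(
      vapply(groups[best], function(g) g$id, character(1)),
      collapse = ","
    )
  }

  dplyr::bind_rows(lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    tibble::tibble(
      subfamily_id = g$id, clade = g$clade, gene_id = g$leaves,
      species = unname(species_of[g$leaves]),
      support = g$support, unplaced = g$unplaced, partners = partners[i]
    )
  }))
}

# edge-count depth of every node from the root
node_depths <- function(tree) {
  n_total <- length(tree$tip.label) + tree$Nnode
  depth <- rep(0, n_total)
  tree <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + 1
  }
  depth
}
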