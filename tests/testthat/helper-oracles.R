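# Independent oracles and small fixture builders used across the suite.

# Exhaustive-summation log-likelihood over all internal-state assignments,
# using Matrix::expm for transition probabilities (independent of the
# package's eigendecomposition/pruning route). Only feasible for tiny trees.
brute_force_loglik <- function(aln, tree, kappa, omega, pi) {
  tree <- stats::reorder(tree, "postorder")
  Q <- gy94_rate_matrix(kappa, omega, pi)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  internal_ids <- n_tip + seq_len(n_int)
  codons <- sense_codons()
  seqs <- lapply(aln$seq, function(s) {
    match(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)), codons)
  })
  names(seqs) <- aln$gene_id
  n_sites <- length(seqs[[1]])

  grid <- as.matrix(expand.grid(rep(list(1:61), n_int)))
  colnames(grid) <- internal_ids
  total <- 0
  for (site in seq_len(n_sites)) {
    state_of <- function(node, combo_col) {
      if (node <= n_tip) {
        rep(seqs[[tree$tip.label[node]]][site], nrow(grid))
      } else {
        grid[, as.character(node)]
      }
    }
    lik <- pi[grid[, as.character(n_tip + 1)]]
    for (e in seq_len(nrow(tree$edge))) {
      pa <- state_of(tree$edge[e, 1])
      ch <- state_of(tree$edge[e, 2])
      lik <- lik * P[[e]][cbind(pa, ch)]
    }
    total <- total + log(sum(lik))
  }
  total
}

# Brute-force COG construction: enumerate all three-species triangles, then
# merge triangles transitively whenever they share an edge.
brute_force_cogs <- function(edges, species_of) {
  if (nrow(edges) == 0) {
    return(list())
  }
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  has_edge <- function(a, b) {
    any((edges$gene_a == a & edges$gene_b == b) |
      (edges$gene_a == b & edges$gene_b == a))
  }
  tris <- list()
  if (length(genes) >= 3) {
    combos <- combn(genes, 3)
    for (k in seq_len(ncol(combos))) {
      v <- combos[, k]
      if (length(unique(species_of[v])) == 3 &&
        has_edge(v[1], v[2]) && has_edge(v[1], v[3]) &&
        has_edge(v[2], v[3])) {
        tris[[length(tris) + 1]] <- sort(v)
      }
    }
  }
  if (length(tris) == 0) {
    return(list())
  }
  # merge triangles sharing an edge, to a fixed point
  groups <- lapply(tris, function(t) list(genes = t, edges = combn(t, 2)))
  edge_keys <- function(g) apply(g$edges, 2, paste, collapse = "~")
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (i >= j || is.null(groups[[j]])) next
        if (length(intersect(edge_keys(groups[[i]]), edge_keys(groups[[j]]))) > 0) {
          groups[[i]]$genes <- sort(unique(c(
            groups[[i]]$genes,
            groups[[j]]$genes
          )))
          groups[[i]]$edges <- cbind(groups[[i]]$edges, groups[[j]]$edges)
          groups[j] <- list(NULL) # keep list length stable while iterating
          changed <- TRUE
        }
      }
    }
    groups <- groups[!vapply(groups, is.null, logical(1))]
  }
  sorted <- lapply(groups, function(g) g$genes)
  sorted[order(vapply(sorted, paste, character(1), collapse = ","))]
}

# Hit table (outfmt-6 shape) derived from a simulated family's protein
# identities: bitscore proportional to fractional identity, with self hits
# carrying the sequence length.
make_hits_from_family <- function(fam) {
  prot <- translate_alignment(fam$aln)
  n <- nrow(prot)
  len <- nchar(prot$seq[1])
  rows <- list()
  m <- do.call(rbind, strsplit(prot$seq, ""))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ident <- mean(m[i, ] == m[j, ])
      score <- round(ident * 2 * len, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        query_gene = prot$gene_id[i], subject_gene = prot$gene_id[j],
        pident = 100 * ident, length = len, mismatch = sum(m[i, ] != m[j, ]),
        gapopen = 0, qstart = 1, qend = len, sstart = 1, send = len,
        evalue = 10^(-score / 10), bitscore = score
      )
    }
  }
  dplyr::bind_rows(rows)
}

# full expected roster (losses are judged against the configured species,
# not the surviving ones)
roster_of <- function(fam) {
  list(
    grass = paste0("g", seq_len(fam$truth$config$n_grass_species)),
    eudicot = paste0("e", seq_len(fam$truth$config$n_eudicot_species))
  )
}

# classify events end-to-end from a simulated family via the NJ/partition
# route (no bootstrap filtering)
recover_events <- function(fam, min_support = 0) {
  prot <- translate_alignment(fam$aln)
  tree <- nj_tree(p_distance_matrix(prot))
  sf <- partition_subfamilies(tree, fam$clade_map, min_support = min_support)
  roster <- roster_of(fam)
  dplyr::bind_rows(
    classify_duplications(sf, fam$clade_map, roster),
    classify_losses(sf, fam$clade_map, roster)
  )
}
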