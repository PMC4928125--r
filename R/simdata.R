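# Synthetic two-clade gene families: a seeded generator for species trees,
# GY94 sequence evolution, and gene families carrying injected old/recent
# duplications and losses together with a machine-readable truth log.

#' Configuration for the synthetic gene-family generator
#'
#' Defaults describe a small two-clade study family: five species per clade,
#' 300 codons, moderate purifying selection differing between clades, and no
#' injected duplication/loss events.
#'
#' @param n_grass_species,n_eudicot_species Species per clade (each >= 2).
#' @param root_codons Number of codon sites in the family.
#' @param kappa Transition/transversion rate ratio.
#' @param omega_grass,omega_eudicot dN/dS applied to every branch inside the
#'   respective clade (including its stem).
#' @param branch_length_range Length-2 vector; every branch length is drawn
#'   uniformly from this range (expected substitutions per codon site).
#' @param n_old_dups_grass,n_old_dups_eudicot Stem duplications per clade
#'   (each adds one clade-wide subfamily).
#' @param n_recent_dups Species-specific duplications (terminal-branch).
#' @param n_recent_losses Species-specific losses (single-copy slots only).
#' @param site_classes Optional list with elements `omegas` and `props`: when
#'   given, each site is assigned a fixed omega class drawn from `props`
#'   (shared by all branches) and the clade omegas are ignored. Used for
#'   site-model recovery experiments.
#' @param base_freqs Optional 3 x 4 matrix of position-specific nucleotide
#'   frequencies (columns T,C,A,G) defining the root/stationary codon
#'   distribution through F3x4; default uniform.
#' @param seed Integer seed governing all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_grass_species = 5, n_eudicot_species = 5,
                       root_codons = 300, kappa = 2,
                       omega_grass = 0.2, omega_eudicot = 0.2,
                       branch_length_range = c(0.05, 0.3),
                       n_old_dups_grass = 0, n_old_dups_eudicot = 0,
                       n_recent_dups = 0, n_recent_losses = 0,
                       site_classes = NULL, base_freqs = NULL, seed = 1) {
  cfg <- list(
    n_grass_species = n_grass_species, n_eudicot_species = n_eudicot_species,
    root_codons = root_codons, kappa = kappa,
    omega_grass = omega_grass, omega_eudicot = omega_eudicot,
    branch_length_range = branch_length_range,
    n_old_dups_grass = n_old_dups_grass,
    n_old_dups_eudicot = n_old_dups_eudicot,
    n_recent_dups = n_recent_dups, n_recent_losses = n_recent_losses,
    site_classes = site_classes, base_freqs = base_freqs, seed = as.integer(seed)
  )
  counts <- c(
    cfg$n_old_dups_grass, cfg$n_old_dups_eudicot,
    cfg$n_recent_dups, cfg$n_recent_losses, cfg$root_codons
  )
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$n_grass_species < 2 || cfg$n_eudicot_species < 2) {
    stop("each clade needs at least 2 species", call. = FALSE)
  }
  if (!all(is.finite(c(cfg$omega_grass, cfg$omega_eudicot))) ||
    cfg$omega_grass <= 0 || cfg$omega_eudicot <= 0) {
    stop("omega values must be finite and positive", call. = FALSE)
  }
  if (length(cfg$branch_length_range) != 2 ||
    any(cfg$branch_length_range < 0) ||
    cfg$branch_length_range[1] > cfg$branch_length_range[2]) {
    stop("invalid branch_length_range", call. = FALSE)
  }
  if (!is.null(site_classes)) {
    stopifnot(
      length(site_classes$omegas) == length(site_classes$props),
      abs(sum(site_classes$props) - 1) < 1e-8
    )
  }
  tips_single <- cfg$n_grass_species * (1 + cfg$n_old_dups_grass) +
    cfg$n_eudicot_species * (1 + cfg$n_old_dups_eudicot)
  if (cfg$n_recent_dups > tips_single) {
    stop("more recent duplications requested than gene slots", call. = FALSE)
  }
  if (cfg$n_recent_losses > tips_single - cfg$n_recent_dups) {
    stop("more losses requested than single-copy genes available",
      call. = FALSE
    )
  }
  structure(cfg, class = "sim_config")
}

# deterministic string hash for per-branch substreams (< 2^31)
cs_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2100000000
  as.integer(h)
}

branch_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + cs_hash(key)) %% 2147483647)
}

draw_len <- function(range) runif(1, range[1], range[2])

# random binary subtree over labels; returns newick fragment including the
# subtree's own stem branch length
random_subtree_newick <- function(labels, range) {
  if (length(labels) == 1) {
    return(sprintf("%s:%.10f", labels, draw_len(range)))
  }
  labels <- sample(labels)
  s <- if (length(labels) == 2) 1 else sample(length(labels) - 1, 1)
  left <- random_subtree_newick(labels[seq_len(s)], range)
  right <- random_subtree_newick(labels[-seq_len(s)], range)
  sprintf("(%s,%s):%.10f", left, right, draw_len(range))
}

#' Simulate a rooted two-clade species tree
#'
#' The root bipartition separates the grass leaves (`g1..gN`) from the
#' eudicot leaves (`e1..eM`); topologies within each clade are random and all
#' branch lengths are drawn uniformly from `branch_length_range`.
#'
#' @param n_grass,n_eudicot Species per clade (each >= 2).
#' @param branch_length_range Length-2 range for branch lengths.
#' @param seed Integer seed.
#' @return A rooted binary `phylo` object.
#' @export
simulate_species_tree <- function(n_grass, n_eudicot,
                                  branch_length_range = c(0.05, 0.3),
                                  seed = 1) {
  if (n_grass < 2 || n_eudicot < 2) {
    stop("each clade needs at least 2 species", call. = FALSE)
  }
  set.seed(seed)
  g <- random_subtree_newick(paste0("g", seq_len(n_grass)), branch_length_range)
  e <- random_subtree_newick(paste0("e", seq_len(n_eudicot)), branch_length_range)
  ape::read.tree(text = sprintf("(%s,%s);", g, e))
}

#' Evolve a codon sequence along one branch under GY94
#'
#' Simulates the child of `parent` after branch length `t` under the GY94
#' continuous-time Markov chain (rates into stop codons are zero because the
#' state space is the 61 sense codons); one unit of `t` is one expected
#' substitution per codon site at stationarity.
#'
#' @param parent Nucleotide string of sense codons.
#' @param t Branch length (>= 0).
#' @param kappa,omega GY94 parameters.
#' @param pi Codon frequencies (default uniform).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Child sequence (nucleotide string, same codon length).
#' @export
evolve_codon_sequence <- function(parent, t, kappa, omega,
                                  pi = uniform_codon_freqs(), seed = NULL) {
  stopifnot(t >= 0)
  idx <- codon_indices(split_codons(parent))
  if (any(is.na(idx))) {
    stop("parent must contain only unambiguous sense codons", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (t == 0) {
    return(parent)
  }
  child <- evolve_indices(idx, t, gy94_eigen(kappa, omega, pi))
  paste0(codon_tables()$codons[child], collapse = "")
}

# vectorized one-branch simulation on codon indices
evolve_indices <- function(idx, t, eig) {
  if (t == 0) {
    return(idx)
  }
  P <- gy94_prob(eig, t)
  child <- integer(length(idx))
  for (s in unique(idx)) {
    sites <- which(idx == s)
    child[sites] <- sample.int(61, length(sites), replace = TRUE, prob = P[s, ])
  }
  child
}

#' Simulate a complete two-clade gene family with truth log
#'
#' Builds a gene tree from the species tree by injecting the configured
#' events, then evolves codon sequences along it:
#' * old duplications sit on a clade's stem, so every species of that clade
#'   inherits the extra subfamily;
#' * recent duplications split one species' terminal branch in half, yielding
#'   a second copy (`<gene>x2`) in the same subfamily;
#' * recent losses prune one single-copy gene.
#' The emitted "alignment" is the true site homology and is gap-free by
#' construction (no indel process is simulated).
#'
#' @param config A [sim_config()].
#' @return A `sim_family` list: `aln` (codon alignment tibble), `clade_map`,
#'   `gene_tree`, `species_tree`, `subfamilies` (gene -> true subfamily), and
#'   `truth` (events tibble, per-species copy numbers, site classes, config).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  range <- cfg$branch_length_range
  set.seed(cfg$seed)

  clade_spec <- list(
    grass = list(
      prefix = "g", n = cfg$n_grass_species,
      dups = cfg$n_old_dups_grass, sf_prefix = "G"
    ),
    eudicot = list(
      prefix = "e", n = cfg$n_eudicot_species,
      dups = cfg$n_old_dups_eudicot, sf_prefix = "E"
    )
  )

  events <- list()
  clade_newick <- lapply(names(clade_spec), function(cl) {
    sp <- clade_spec[[cl]]
    species <- paste0(sp$prefix, seq_len(sp$n))
    n_sf <- sp$dups + 1
    sfs <- paste0(sp$sf_prefix, seq_len(n_sf))
    subs <- vapply(sfs, function(sf) {
      random_subtree_newick(paste0(species, "_", sf), range)
    }, character(1))
    chain <- subs[1]
    if (n_sf > 1) {
      for (i in 2:n_sf) {
        chain <- sprintf("(%s,%s):%.10f", chain, subs[i], draw_len(range))
        events[[length(events) + 1]] <<- tibble::tibble(
          kind = "old_dup", clade = cl, species = NA_character_,
          subfamily = sfs[i]
        )
      }
    }
    chain
  })
  tree <- ape::read.tree(
    text = sprintf("(%s,%s);", clade_newick[[1]], clade_newick[[2]])
  )

  # recent duplications: split a terminal branch at its midpoint
  dup_targets <- character(0)
  if (cfg$n_recent_dups > 0) {
    dup_targets <- sample(tree$tip.label, cfg$n_recent_dups)
    for (tg in dup_targets) {
      i <- match(tg, tree$tip.label)
      len <- tree$edge.length[tree$edge[, 2] == i]
      tree <- phytools::bind.tip(tree, paste0(tg, "x2"),
        edge.length = len / 2, where = i, position = len / 2
      )
      events[[length(events) + 1]] <- tibble::tibble(
        kind = "recent_dup",
        clade = ifelse(startsWith(tg, "g"), "grass", "eudicot"),
        species = sub("_.*$", "", tg),
        subfamily = sub("^[^_]*_", "", tg)
      )
    }
  }

  # recent losses: prune single-copy genes untouched by duplication
  if (cfg$n_recent_losses > 0) {
    eligible <- setdiff(tree$tip.label, c(dup_targets, paste0(dup_targets, "x2")))
    lost <- sample(eligible, cfg$n_recent_losses)
    for (tg in lost) {
      tree <- ape::drop.tip(tree, tg)
      events[[length(events) + 1]] <- tibble::tibble(
        kind = "recent_loss",
        clade = ifelse(startsWith(tg, "g"), "grass", "eudicot"),
        species = sub("_.*$", "", tg),
        subfamily = sub("^[^_]*_", "", tg)
      )
    }
  }

  clade_map <- tibble::tibble(
    gene_id = tree$tip.label,
    species = sub("_.*$", "", tree$tip.label),
    clade = ifelse(startsWith(tree$tip.label, "g"), "grass", "eudicot")
  )
  subfamilies <- tibble::tibble(
    gene_id = tree$tip.label,
    subfamily = sub("x2$", "", sub("^[^_]*_", "", tree$tip.label))
  )

  # stationary distribution
  pi <- if (is.null(cfg$base_freqs)) {
    uniform_codon_freqs()
  } else {
    pi_f3x4(cfg$base_freqs)
  }

  # per-site omega labels (fixed across the tree) or clade omegas per branch
  n_sites <- cfg$root_codons
  if (!is.null(cfg$site_classes)) {
    set.seed(branch_seed(cfg$seed, "SITE_CLASSES"))
    site_label <- sample(seq_along(cfg$site_classes$omegas), n_sites,
      replace = TRUE, prob = cfg$site_classes$props
    )
    omegas_used <- cfg$site_classes$omegas
  } else {
    site_label <- NULL
    omegas_used <- c(grass = cfg$omega_grass, eudicot = cfg$omega_eudicot)
  }

  regimes <- edge_clade_regimes(tree, clade_map) # 1 = grass, 2 = eudicot
  if (is.null(site_label)) {
    eigs <- list(
      gy94_eigen(cfg$kappa, cfg$omega_grass, pi),
      gy94_eigen(cfg$kappa, cfg$omega_eudicot, pi)
    )
  } else {
    # classes share one branch-length scale so fast classes stay fast
    eigs_class <- gy94_eigen_mixture(
      cfg$kappa, omegas_used, cfg$site_classes$props, pi
    )
  }

  # root sequence from pi, then preorder traversal with per-branch substreams
  # keyed by the child subtree's sorted leaf set
  set.seed(branch_seed(cfg$seed, "ROOT"))
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1]] <- sample.int(61, n_sites, replace = TRUE, prob = pi)
  sets <- leaf_sets(tree)
  tree_pre <- stats::reorder(tree, "cladewise")
  pre_order <- match(
    paste(tree_pre$edge[, 1], tree_pre$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  for (e in pre_order) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    key <- paste(sort(sets[[child]]), collapse = "|")
    set.seed(branch_seed(cfg$seed, key))
    par_seq <- seqs[[parent]]
    if (is.null(site_label)) {
      seqs[[child]] <- evolve_indices(par_seq, t_e, eigs[[regimes[e]]])
    } else {
      out <- integer(n_sites)
      for (k in seq_along(omegas_used)) {
        sel <- site_label == k
        if (any(sel)) out[sel] <- evolve_indices(par_seq[sel], t_e, eigs_class[[k]])
      }
      seqs[[child]] <- out
    }
  }

  codons <- codon_tables()$codons
  aln <- tibble::tibble(
    gene_id = tree$tip.label,
    seq = vapply(seq_len(n_tip), function(i) {
      paste0(codons[seqs[[i]]], collapse = "")
    }, character(1))
  )

  events <- if (length(events) > 0) {
    dplyr::bind_rows(events)
  } else {
    tibble::tibble(
      kind = character(0), clade = character(0),
      species = character(0), subfamily = character(0)
    )
  }
  copy_numbers <- clade_map |>
    dplyr::count(.data$species, name = "copies")

  structure(list(
    aln = aln, clade_map = clade_map, gene_tree = tree,
    species_tree = simulate_species_tree(
      cfg$n_grass_species, cfg$n_eudicot_species, range, cfg$seed
    ),
    subfamilies = subfamilies,
    truth = list(
      events = events, copy_numbers = copy_numbers,
      site_label = site_label, omegas = omegas_used, config = cfg
    )
  ), class = "sim_family")
}

#' Write a simulated family to disk
#'
#' Emits `cds.fasta`, `aln.fasta` (identical, gap-free true alignment),
#' `clade_map.tsv`, `gene_tree.nwk`, `species_tree.nwk` and `truth.json`.
#'
#' @param fam A `sim_family` from [simulate_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_family <- function(fam, dir) {
  stopifnot(inherits(fam, "sim_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fam$aln, file.path(dir, "cds.fasta"))
  write_fasta(fam$aln, file.path(dir, "aln.fasta"))
  readr::write_tsv(fam$clade_map, file.path(dir, "clade_map.tsv"))
  ape::write.tree(fam$gene_tree, file.path(dir, "gene_tree.nwk"))
  ape::write.tree(fam$species_tree, file.path(dir, "species_tree.nwk"))
  truth <- fam$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
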