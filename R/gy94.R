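# GY94 codon substitution machinery: F3x4 equilibrium frequencies, the rate
# matrix over the 61 sense codons, its reversible eigendecomposition, and the
# Felsenstein-pruning log-likelihood over a tree.

#' F3x4 codon equilibrium frequencies
#'
#' Estimates position-specific nucleotide frequencies from a codon alignment
#' and forms codon frequencies as the product over the three positions, with
#' stop codons removed and the vector renormalized to sum to one.
#'
#' @param aln Codon alignment tibble (`gene_id`, `seq`).
#' @return Named numeric vector of length 61 over [sense_codons()].
#' @export
f3x4_frequencies <- function(aln) {
  cod <- codon_matrix(aln)
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, cs_nucs))
  for (p in 1:3) {
    nucs <- substr(cod, p, p)
    nucs <- nucs[nucs %in% cs_nucs]
    if (length(nucs) == 0) {
      stop("no observed nucleotides at codon position ", p, call. = FALSE)
    }
    tab <- table(factor(nucs, levels = cs_nucs))
    pos_freq[p, ] <- as.numeric(tab) / sum(tab)
  }
  pi_f3x4(pos_freq)
}

# Codon frequencies from a 3 x 4 matrix of position-specific nucleotide
# frequencies (columns in T,C,A,G order).
pi_f3x4 <- function(pos_freq) {
  tabs <- codon_tables()
  pi <- apply(tabs$nuc, 1, function(cod) {
    pos_freq[1, cod[1]] * pos_freq[2, cod[2]] * pos_freq[3, cod[3]]
  })
  pi <- pi / sum(pi)
  setNames(pi, tabs$codons)
}

#' Uniform codon frequencies
#'
#' @return Named numeric vector, each sense codon at 1/61.
#' @export
uniform_codon_freqs <- function() {
  tabs <- codon_tables()
  setNames(rep(1 / 61, 61), tabs$codons)
}

#' GY94 instantaneous rate matrix
#'
#' Off-diagonal rate from codon i to j is zero unless the codons differ at a
#' single nucleotide, and otherwise `pi[j] * kappa^[transition] *
#' omega^[nonsynonymous]`. The matrix is rescaled so that one unit of branch
#' length equals one expected substitution per codon site at stationarity
#' (`-sum(pi * diag(Q)) == 1`).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (> 0).
#' @param pi Codon frequency vector of length 61 (defaults to uniform).
#' @return A 61 x 61 generator matrix.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = uniform_codon_freqs()) {
  stopifnot(kappa > 0, omega > 0)
  pi <- validate_pi(pi)
  tabs <- codon_tables()
  Q <- matrix(0, 61, 61, dimnames = list(tabs$codons, tabs$codons))
  Q[tabs$single] <- rep(pi, each = 61)[tabs$single]
  Q[tabs$single & tabs$transition] <- Q[tabs$single & tabs$transition] * kappa
  Q[tabs$single & !tabs$synonymous] <-
    Q[tabs$single & !tabs$synonymous] * omega
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix", call. = FALSE)
  Q / scale
}

validate_pi <- function(pi) {
  if (length(pi) != 61 || any(!is.finite(pi)) || any(pi < 0) ||
    abs(sum(pi) - 1) > 1e-6) {
    stop("pi must be 61 nonnegative frequencies summing to 1", call. = FALSE)
  }
  pi / sum(pi)
}

# Unnormalized GY94 generator plus its stationary substitution rate.
gy94_q_raw <- function(kappa, omega, pi) {
  tabs <- codon_tables()
  Q <- matrix(0, 61, 61)
  Q[tabs$single] <- rep(pi, each = 61)[tabs$single]
  Q[tabs$single & tabs$transition] <- Q[tabs$single & tabs$transition] * kappa
  Q[tabs$single & !tabs$synonymous] <-
    Q[tabs$single & !tabs$synonymous] * omega
  diag(Q) <- -rowSums(Q)
  list(Q = Q, rate = -sum(pi * diag(Q)))
}

# Reversible eigendecomposition of a GY94 generator: Q = A diag(d) Ainv with
# A = diag(1/sqrt(pi)) V from the symmetric eigenproblem of
# diag(sqrt(pi)) Q diag(1/sqrt(pi)). Frequencies are floored at 1e-10 (and
# renormalized) so alignments with unobserved states remain usable. `scale`
# divides the generator; the default (its own stationary rate) gives one
# expected substitution per codon site per unit branch length. Site-class
# mixtures pass the mixture-average rate instead, so that fast classes stay
# fast relative to slow ones under one shared set of branch lengths.
gy94_eigen <- function(kappa, omega, pi = uniform_codon_freqs(),
                       scale = NULL) {
  pi <- validate_pi(pi)
  pi <- pmax(pi, 1e-10)
  pi <- pi / sum(pi)
  raw <- gy94_q_raw(kappa, omega, pi)
  if (is.null(scale)) scale <- raw$rate
  if (scale <= 0) stop("degenerate rate matrix", call. = FALSE)
  Q <- raw$Q / scale
  sq <- sqrt(pi)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(
    A = diag(1 / sq) %*% e$vectors,
    Ainv = t(e$vectors) %*% diag(sq),
    d = e$values,
    pi = pi
  )
}

# Eigendecompositions for a site-class mixture sharing one branch-length
# scale (the mixture-average substitution rate).
gy94_eigen_mixture <- function(kappa, omegas, props, pi) {
  pi2 <- validate_pi(pi)
  pi2 <- pmax(pi2, 1e-10)
  pi2 <- pi2 / sum(pi2)
  rates <- vapply(
    omegas, function(w) gy94_q_raw(kappa, w, pi2)$rate,
    numeric(1)
  )
  scale <- sum(props * rates)
  lapply(omegas, function(w) gy94_eigen(kappa, w, pi, scale = scale))
}

# Transition probability matrix for one eigendecomposed regime.
gy94_prob <- function(eig, t) {
  P <- eig$A %*% (exp(eig$d * t) * eig$Ainv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# ---- pruning-likelihood plumbing -------------------------------------------

# Compress an alignment into codon site patterns for the tip order `tips`.
# Returns list(states = ntip x npat integer matrix (0 = missing),
#              weights, pattern_of_site).
codon_patterns <- function(aln, tips) {
  cod <- codon_matrix(aln)
  rownames(cod) <- aln$gene_id
  cod <- cod[tips, , drop = FALSE]
  tabs <- codon_tables()
  idx <- matrix(tabs$index[cod], nrow = nrow(cod))
  stop_hit <- is.na(idx) & cod %in% c("TAA", "TAG", "TGA")
  if (any(stop_hit)) {
    stop("stop codon in alignment at likelihood stage", call. = FALSE)
  }
  idx[is.na(idx)] <- 0L
  key <- apply(idx, 2, paste0, collapse = ",")
  upat <- !duplicated(key)
  pattern_of_site <- match(key, key[upat])
  list(
    states = idx[, upat, drop = FALSE],
    weights = as.numeric(table(factor(pattern_of_site, levels = seq_len(sum(upat))))),
    pattern_of_site = pattern_of_site
  )
}

# Postorder tree prep shared by likelihood calls.
prep_tree <- function(tree, gene_ids) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object", call. = FALSE)
  if (!setequal(tree$tip.label, gene_ids)) {
    stop("tree tip labels must match alignment gene ids", call. = FALSE)
  }
  stats::reorder(tree, "postorder")
}

# Edge regime labels for the two-ratio branch model: each edge takes the clade
# of its child subtree's leaves (majority vote if mixed, which only occurs on
# trees not rooted at the clade split).
edge_clade_regimes <- function(tree, clade_map) {
  clade_of <- setNames(clade_map$clade, clade_map$gene_id)
  missing <- setdiff(tree$tip.label, names(clade_of))
  if (length(missing) > 0) {
    stop(
      "leaves missing from clade map: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  n_tip <- length(tree$tip.label)
  desc <- leaf_sets(tree)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    leaves <- if (child <= n_tip) tree$tip.label[child] else desc[[child]]
    cl <- clade_of[leaves]
    if (all(cl == "grass")) {
      1L
    } else if (all(cl == "eudicot")) {
      2L
    } else if (sum(cl == "grass") >= sum(cl == "eudicot")) 1L else 2L
  }, integer(1))
}

# Leaf label sets per internal node (indexed by ape node number).
leaf_sets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_total <- n_tip + tree$Nnode
  sets <- vector("list", n_total)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' GY94 log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61 sense codons with per-pattern numerical
#' rescaling. Gap codons are treated as missing data. Three model flavours
#' share this entry point:
#' one-ratio (scalar `omega`), two-ratio branch model (`omega` of length 2
#' named `grass`/`eudicot` plus `clade_map`), and a discrete site-class
#' mixture (`omega` of length K plus `site_props` of matching length), whose
#' per-site likelihood is the proportion-weighted mixture over classes.
#'
#' @param aln Codon alignment tibble.
#' @param tree `phylo` tree whose tip labels match `aln$gene_id`; branch
#'   lengths in expected substitutions per codon site.
#' @param kappa Transition/transversion ratio.
#' @param omega dN/dS ratio(s); see Details.
#' @param pi Codon frequencies (default F3x4 from the alignment).
#' @param clade_map Clade map tibble, required for the branch model.
#' @param site_props Mixture proportions for the site-class model.
#' @return Log-likelihood (scalar) with attributes `site_loglik` (per codon
#'   site) and, for mixtures, `class_posterior` (sites x classes).
#' @export
codon_loglik <- function(aln, tree, kappa, omega, pi = NULL,
                         clade_map = NULL, site_props = NULL) {
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- validate_pi(pi)
  tree <- prep_tree(tree, aln$gene_id)
  pat <- codon_patterns(aln, tree$tip.label)

  branch_model <- !is.null(clade_map) && length(omega) == 2 &&
    is.null(site_props)
  if (branch_model) {
    regimes <- edge_clade_regimes(tree, clade_map)
    om <- omega[c("grass", "eudicot")]
    if (any(is.na(om))) stop("branch model omega must be named grass/eudicot",
      call. = FALSE
    )
    eigen_sets <- list(lapply(om, function(w) gy94_eigen(kappa, w, pi)))
    weights <- 1
  } else if (!is.null(site_props)) {
    stopifnot(length(site_props) == length(omega))
    if (abs(sum(site_props) - 1) > 1e-8) {
      stop("site_props must sum to 1", call. = FALSE)
    }
    regimes <- rep(1L, nrow(tree$edge))
    eigen_sets <- lapply(
      gy94_eigen_mixture(kappa, omega, site_props, pi), list
    )
    weights <- site_props
  } else {
    stopifnot(length(omega) == 1)
    regimes <- rep(1L, nrow(tree$edge))
    eigen_sets <- list(list(gy94_eigen(kappa, omega, pi)))
    weights <- 1
  }

  pi_used <- eigen_sets[[1]][[1]]$pi
  ll_pat <- cs_pruning_loglik(
    edge = tree$edge, edge_len = tree$edge.length,
    edge_regime = as.integer(regimes), tip_states = pat$states,
    n_tip = length(tree$tip.label),
    n_node_total = length(tree$tip.label) + tree$Nnode,
    root = length(tree$tip.label) + 1L,
    eigen_sets = eigen_sets, pi = pi_used
  )
  if (length(weights) > 1) {
    m <- apply(ll_pat, 1, max)
    site_ll_pat <- m + log(as.vector(exp(ll_pat - m) %*% weights))
    post_pat <- exp(ll_pat - m) * rep(weights, each = nrow(ll_pat))
    post_pat <- post_pat / rowSums(post_pat)
  } else {
    site_ll_pat <- ll_pat[, 1]
    post_pat <- NULL
  }
  total <- sum(site_ll_pat * pat$weights)
  site_ll <- site_ll_pat[pat$pattern_of_site]
  out <- total
  attr(out, "site_loglik") <- site_ll
  if (!is.null(post_pat)) {
    attr(out, "class_posterior") <- post_pat[pat$pattern_of_site, , drop = FALSE]
  }
  out
}
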