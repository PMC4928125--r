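# Maximum-likelihood codon models on trees: one-ratio (M0), two-ratio branch
# model (clade-specific omega), and the discrete three-class site model
# (M3K3), with likelihood ratio tests and naive empirical Bayes site
# detection.
#
# Optimization alternates a substitution-parameter block (kappa, omegas,
# class proportions) with a branch-length block, both on log/softmax scales
# under L-BFGS-B, until the relative log-likelihood gain drops below 1e-8.
# Eigendecompositions are cached across the branch-length block, which is
# what makes repeated fits cheap.

#' Fit a GY94 codon model by maximum likelihood
#'
#' @param aln Codon alignment tibble (`gene_id`, `seq`).
#' @param tree `phylo` tree over `aln$gene_id`; `NULL` builds a
#'   neighbor-joining starting tree from protein p-distances.
#' @param model `"M0"` (one omega), `"BRANCH2"` (omega per clade; needs
#'   `clade_map`), or `"M3K3"` (three site classes with free proportions).
#' @param clade_map Clade map tibble (required for `BRANCH2`).
#' @param pi Codon frequencies; default F3x4 from the alignment.
#' @param n_starts Number of optimization starts; the first is deterministic
#'   (M0-guided), additional starts perturb it randomly (seeded).
#' @param seed Seed for random restarts.
#' @param omega_bounds,kappa_bounds,bl_bounds Box constraints.
#' @param max_cycles Maximum block-alternation cycles.
#' @param init Optional `codon_fit` used to initialize (e.g. an M0 fit).
#' @return A `codon_fit` object: `model`, `lnL`, `kappa`, `omega` (named for
#'   BRANCH2, ordered ascending for M3K3), `props` (M3K3), `tree` with
#'   fitted branch lengths, `pi`, `converged`, `bound_hit`, `n_params`.
#' @export
fit_codon_model <- function(aln, tree = NULL,
                            model = c("M0", "BRANCH2", "M3K3"),
                            clade_map = NULL, pi = NULL,
                            n_starts = 1, seed = 1,
                            omega_bounds = c(1e-4, 20),
                            kappa_bounds = c(0.1, 100),
                            bl_bounds = c(1e-6, 10),
                            max_cycles = 8, init = NULL) {
  model <- match.arg(model)
  if (model == "BRANCH2" && is.null(clade_map)) {
    stop("BRANCH2 requires a clade_map", call. = FALSE)
  }
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- validate_pi(pi)
  pi_floor <- pmax(pi, 1e-10)
  pi_floor <- pi_floor / sum(pi_floor)

  if (is.null(tree)) {
    prot <- translate_alignment(aln)
    d <- p_distance_matrix(prot)
    if (any(is.na(d))) d[is.na(d)] <- max(d, na.rm = TRUE)
    tree <- if (nrow(aln) >= 3) {
      nj_tree(d)
    } else {
      ape::read.tree(text = sprintf(
        "(%s:%.6f,%s:%.6f);", aln$gene_id[1], max(d[1, 2] / 2, 0.01),
        aln$gene_id[2], max(d[1, 2] / 2, 0.01)
      ))
    }
  }
  tree <- prep_tree(tree, aln$gene_id)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  tree$edge.length <- pmin(pmax(tree$edge.length, bl_bounds[1]), bl_bounds[2])
  pat <- codon_patterns(aln, tree$tip.label)
  n_edge <- nrow(tree$edge)
  regimes <- if (model == "BRANCH2") {
    edge_clade_regimes(tree, clade_map)
  } else {
    rep(1L, n_edge)
  }

  # ---- likelihood evaluator with eigen cache -------------------------------
  cache <- new.env(parent = emptyenv())
  eigen_sets_for <- function(kappa, omegas, props) {
    key <- paste(signif(c(kappa, omegas, props), 15), collapse = "_")
    hit <- cache$key
    if (identical(hit, key)) {
      return(cache$val)
    }
    val <- if (model == "BRANCH2") {
      list(lapply(omegas, function(w) gy94_eigen(kappa, w, pi_floor)))
    } else if (model == "M3K3") {
      lapply(gy94_eigen_mixture(kappa, omegas, props, pi_floor), list)
    } else {
      lapply(omegas, function(w) list(gy94_eigen(kappa, w, pi_floor)))
    }
    cache$key <- key
    cache$val <- val
    val
  }
  pattern_loglik <- function(kappa, omegas, props, bl) {
    es <- eigen_sets_for(kappa, omegas, props)
    ll <- cs_pruning_loglik(
      edge = tree$edge, edge_len = bl, edge_regime = as.integer(regimes),
      tip_states = pat$states, n_tip = length(tree$tip.label),
      n_node_total = length(tree$tip.label) + tree$Nnode,
      root = length(tree$tip.label) + 1L,
      eigen_sets = es, pi = es[[1]][[1]]$pi
    )
    if (length(props) > 1) {
      m <- apply(ll, 1, max)
      m + log(as.vector(exp(ll - m) %*% props))
    } else {
      ll[, 1]
    }
  }
  total_loglik <- function(kappa, omegas, props, bl) {
    v <- sum(pattern_loglik(kappa, omegas, props, bl) * pat$weights)
    if (!is.finite(v)) -1e12 else v
  }

  n_omega <- switch(model, M0 = 1L, BRANCH2 = 2L, M3K3 = 3L)
  softmax <- function(raw) {
    z <- exp(c(raw, 0) - max(c(raw, 0)))
    z / sum(z)
  }

  run_one <- function(kappa0, omegas0, raw0, bl0) {
    kappa <- kappa0
    omegas <- omegas0
    raw <- raw0
    bl <- bl0
    conv_ok <- TRUE
    last <- -Inf
    for (cycle in seq_len(max_cycles)) {
      # substitution-parameter block
      sp0 <- c(log(kappa), log(omegas), raw)
      lo <- c(log(kappa_bounds[1]), rep(log(omega_bounds[1]), n_omega),
        rep(-20, length(raw))
      )
      hi <- c(log(kappa_bounds[2]), rep(log(omega_bounds[2]), n_omega),
        rep(20, length(raw))
      )
      obj_sp <- function(p) {
        k <- exp(p[1])
        om <- exp(p[2:(1 + n_omega)])
        pr <- if (length(raw) > 0) softmax(p[-(1:(1 + n_omega))]) else 1
        -total_loglik(k, om, pr, bl)
      }
      o1 <- optim(sp0, obj_sp,
        method = "L-BFGS-B", lower = lo, upper = hi,
        control = list(maxit = 200, factr = 1e7)
      )
      kappa <- exp(o1$par[1])
      omegas <- exp(o1$par[2:(1 + n_omega)])
      if (length(raw) > 0) raw <- o1$par[-(1:(1 + n_omega))]

      # branch-length block (eigens cached: kappa/omegas fixed)
      props <- if (length(raw) > 0) softmax(raw) else 1
      obj_bl <- function(p) -total_loglik(kappa, omegas, props, exp(p))
      o2 <- optim(log(bl), obj_bl,
        method = "L-BFGS-B",
        lower = rep(log(bl_bounds[1]), n_edge),
        upper = rep(log(bl_bounds[2]), n_edge),
        control = list(maxit = 200, factr = 1e7)
      )
      bl <- exp(o2$par)
      lnL <- -o2$value
      conv_ok <- o1$convergence == 0 && o2$convergence == 0
      if (is.finite(last) && (lnL - last) < 1e-8 * abs(lnL)) {
        last <- lnL
        break
      }
      last <- lnL
    }
    list(
      lnL = last, kappa = kappa, omegas = omegas,
      props = if (length(raw) > 0) softmax(raw) else NULL,
      bl = bl, converged = conv_ok
    )
  }

  # deterministic first start, guided by a cheap M0 fit for the richer models
  if (!is.null(init) && inherits(init, "codon_fit")) {
    kappa0 <- init$kappa
    bl0 <- init$tree$edge.length
    base_omega <- if (length(init$omega) == 1) init$omega else mean(init$omega)
  } else if (model != "M0") {
    m0 <- fit_codon_model(aln, tree,
      model = "M0", pi = pi, n_starts = 1,
      omega_bounds = omega_bounds, kappa_bounds = kappa_bounds,
      bl_bounds = bl_bounds, max_cycles = max_cycles
    )
    kappa0 <- m0$kappa
    bl0 <- m0$tree$edge.length
    base_omega <- unname(m0$omega)
  } else {
    kappa0 <- 2
    bl0 <- tree$edge.length
    base_omega <- 0.4
  }
  clamp <- function(x, b) pmin(pmax(x, b[1] * 1.0001), b[2] * 0.9999)
  omegas0 <- switch(model,
    M0 = clamp(base_omega, omega_bounds),
    BRANCH2 = clamp(rep(base_omega, 2), omega_bounds),
    M3K3 = clamp(base_omega * c(0.2, 1, 3), omega_bounds)
  )
  raw0 <- if (model == "M3K3") c(0, 0) else numeric(0)
  starts <- list(list(
    kappa = clamp(kappa0, kappa_bounds), omegas = omegas0, raw = raw0,
    bl = clamp(bl0, bl_bounds)
  ))
  if (n_starts > 1) {
    set.seed(seed)
    for (s in 2:n_starts) {
      starts[[s]] <- list(
        kappa = clamp(kappa0 * exp(runif(1, -1, 1)), kappa_bounds),
        omegas = clamp(omegas0 * exp(runif(n_omega, -1.5, 1.5)), omega_bounds),
        raw = if (length(raw0) > 0) runif(length(raw0), -1, 1) else raw0,
        bl = clamp(bl0 * exp(runif(n_edge, -0.7, 0.7)), bl_bounds)
      )
    }
  }
  fits <- lapply(starts, function(s) {
    run_one(s$kappa, s$omegas, s$raw, s$bl)
  })
  best <- fits[[which.max(vapply(fits, function(f) f$lnL, numeric(1)))]]

  omegas <- best$omegas
  props <- best$props
  if (model == "M3K3") {
    ord <- order(omegas)
    omegas <- omegas[ord]
    props <- props[ord]
    names(omegas) <- paste0("omega", seq_along(omegas))
    names(props) <- paste0("p", seq_along(props))
  } else if (model == "BRANCH2") {
    names(omegas) <- c("grass", "eudicot")
  } else {
    names(omegas) <- "omega"
  }
  tol <- 1e-4
  bound_hit <- c(
    kappa = best$kappa / kappa_bounds[1] < 1 + tol ||
      best$kappa / kappa_bounds[2] > 1 - tol,
    omega = any(omegas / omega_bounds[1] < 1 + tol) ||
      any(omegas / omega_bounds[2] > 1 - tol)
  )
  fitted_tree <- tree
  fitted_tree$edge.length <- best$bl
  n_params <- 1L + n_omega + n_edge +
    if (model == "M3K3") length(props) - 1L else 0L
  structure(list(
    model = model, lnL = best$lnL, kappa = best$kappa, omega = omegas,
    props = props, tree = fitted_tree, pi = pi, regimes = regimes,
    converged = best$converged, bound_hit = bound_hit,
    n_params = n_params, n_sites = sum(pat$weights),
    aln_ids = aln$gene_id
  ), class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("GY94 codon model fit (", x$model, ")\n", sep = "")
  cat("  lnL:", format(x$lnL, digits = 10), "\n")
  cat("  kappa:", signif(x$kappa, 4), "\n")
  cat("  omega:", paste(
    names(x$omega), signif(x$omega, 4),
    sep = "=", collapse = ", "
  ), "\n")
  if (!is.null(x$props)) {
    cat("  proportions:", paste(signif(x$props, 4), collapse = ", "), "\n")
  }
  cat(
    "  sites:", x$n_sites, " converged:", x$converged,
    " bound hit:", any(x$bound_hit), "\n"
  )
  invisible(x)
}

#' Likelihood ratio test between nested codon model fits
#'
#' The statistic is `2 * |lnL_alt - lnL_null|` (the absolute-value convention
#' used when reading pairs of printed -lnL values) with an upper-tail
#' chi-square p-value.
#'
#' @param null_fit,alt_fit `codon_fit` objects or bare log-likelihood values
#'   (either sign convention; only the absolute difference matters).
#' @param df Chi-square degrees of freedom (>= 1). Defaults to the
#'   difference in free parameter counts when both arguments are fits.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `models`.
#' @export
lrt <- function(null_fit, alt_fit, df = NULL) {
  lnl_of <- function(x) if (inherits(x, "codon_fit")) x$lnL else as.numeric(x)
  l0 <- lnl_of(null_fit)
  l1 <- lnl_of(alt_fit)
  if (is.null(df)) {
    if (inherits(null_fit, "codon_fit") && inherits(alt_fit, "codon_fit")) {
      df <- alt_fit$n_params - null_fit$n_params
    } else {
      stop("df must be supplied for bare log-likelihoods", call. = FALSE)
    }
  }
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stat <- 2 * abs(l1 - l0)
  models <- if (inherits(null_fit, "codon_fit") &&
    inherits(alt_fit, "codon_fit")) {
    paste(null_fit$model, "vs", alt_fit$model)
  } else {
    "lnL pair"
  }
  tibble::tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    models = models
  )
}

# p-value display with the below-floor convention used in report tables
format_p <- function(p, floor = 1e-12) {
  ifelse(p < floor, sprintf("<%.2e", floor), sprintf("%.3g", p))
}

#' Naive empirical Bayes detection of positively selected sites
#'
#' Computes per-site posterior probabilities over the fitted M3 omega
#' classes (posterior proportional to class proportion times class site
#' likelihood) and lists the sites whose total posterior mass on classes
#' with omega > 1 reaches `threshold`. The list is empty when no fitted
#' class has omega > 1.
#'
#' @param m3_fit Converged `codon_fit` with `model == "M3K3"`.
#' @param aln The codon alignment the model was fitted to.
#' @param threshold Posterior threshold (default 0.95).
#' @return A `site_selection` list: `sites` tibble (1-based codon site,
#'   posterior per class, posterior of positive selection, selected flag),
#'   `selected` (site numbers), `omega`, `threshold`.
#' @export
neb_sites <- function(m3_fit, aln, threshold = 0.95) {
  stopifnot(inherits(m3_fit, "codon_fit"), m3_fit$model == "M3K3")
  if (!m3_fit$converged) {
    warning("site detection on a non-converged fit")
  }
  ll <- codon_loglik(aln, m3_fit$tree,
    kappa = m3_fit$kappa,
    omega = unname(m3_fit$omega), pi = m3_fit$pi,
    site_props = unname(m3_fit$props)
  )
  post <- attr(ll, "class_posterior")
  pos_classes <- which(m3_fit$omega > 1)
  p_pos <- if (length(pos_classes) > 0) {
    rowSums(post[, pos_classes, drop = FALSE])
  } else {
    rep(0, nrow(post))
  }
  sites <- tibble::as_tibble(post, .name_repair = ~ paste0(
    "posterior_class", seq_len(ncol(post))
  )) |>
    dplyr::mutate(
      site = dplyr::row_number(), .before = 1
    ) |>
    dplyr::mutate(
      posterior_positive = p_pos,
      selected = length(pos_classes) > 0 & p_pos >= threshold
    )
  structure(list(
    sites = sites,
    selected = sites$site[sites$selected],
    omega = m3_fit$omega, props = m3_fit$props, threshold = threshold
  ), class = "site_selection")
}

#' @export
print.site_selection <- function(x, ...) {
  cat("Positively selected sites (naive empirical Bayes, threshold ",
    x$threshold, ")\n",
    sep = ""
  )
  cat(
    "  omega classes:", paste(signif(x$omega, 3), collapse = ", "),
    "; proportions:", paste(signif(x$props, 3), collapse = ", "), "\n"
  )
  if (length(x$selected) == 0) {
    cat("  no sites selected\n")
  } else {
    cat("  sites:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}
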