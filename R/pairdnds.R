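# Pairwise dN/dS: the Nei-Gojobori (1986) counting estimator with
# Jukes-Cantor correction, randomized within-subfamily pair sampling, and the
# paired t-test comparison of grass versus eudicot omega samples.

#' Nei-Gojobori (NG86) pairwise dN/dS
#'
#' Counts synonymous and nonsynonymous sites (fractional, averaged over the
#' two sequences) and differences (equal-weight averaging over all minimal
#' mutational pathways, stop-passing pathways excluded), then applies the
#' Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` to both proportions.
#' Codon columns gapped in either sequence are dropped pairwise.
#'
#' @param a,b Equal-length in-frame nucleotide strings.
#' @return One-row tibble: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `omega`, `valid` (FALSE when a correction is undefined or `dS` is 0),
#'   `method`.
#' @export
ng86 <- function(a, b) {
  ca <- split_codons(a)
  cb <- split_codons(b)
  if (length(ca) != length(cb)) {
    stop("sequences must have equal codon length", call. = FALSE)
  }
  tabs <- codon_tables()
  ia <- unname(tabs$index[ca])
  ib <- unname(tabs$index[cb])
  gap <- grepl("-", ca) | grepl("-", cb)
  stop_a <- is.na(ia) & !gap & !grepl("[^ACGT]", ca)
  stop_b <- is.na(ib) & !gap & !grepl("[^ACGT]", cb)
  if (any(stop_a | stop_b)) {
    stop("stop codon in sequence", call. = FALSE)
  }
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no comparable codons", call. = FALSE)
  ia <- ia[ok]
  ib <- ib[ok]

  ng <- tabs$ng86
  S <- (sum(ng$syn_sites[ia]) + sum(ng$syn_sites[ib])) / 2
  N <- 3 * length(ia) - S
  pairs <- cbind(ia, ib)
  Sd <- sum(ng$sd[pairs])
  Nd <- sum(ng$nd[pairs])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) {
      return(NA_real_)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  tibble::tibble(
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
    omega = omega,
    valid = !is.na(dS) && !is.na(dN) && dS > 0,
    method = "NG86"
  )
}

#' Pairwise maximum-likelihood dN/dS
#'
#' Fits the one-ratio GY94/F3x4 model to a two-sequence alignment (a single
#' branch), giving a maximum-likelihood counterpart to [ng86()] behind the
#' same contract. Used for cross-method concordance, not mixed with NG86
#' results.
#'
#' @inheritParams ng86
#' @return One-row tibble with `omega`, `kappa`, `t`, `lnL`, `valid`,
#'   `method`.
#' @export
ml_pair_omega <- function(a, b) {
  aln <- tibble::tibble(gene_id = c("seq_a", "seq_b"), seq = c(a, b))
  tree <- ape::read.tree(text = "(seq_a:0.05,seq_b:0.05);")
  fit <- fit_codon_model(aln, tree, model = "M0")
  tibble::tibble(
    omega = unname(fit$omega), kappa = fit$kappa,
    t = sum(fit$tree$edge.length), lnL = fit$lnL,
    valid = fit$converged, method = "ML"
  )
}

#' Random within-subfamily omega sample
#'
#' Draws `n_pairs` distinct unordered member pairs uniformly without
#' replacement (all pairs when fewer exist) and estimates omega for each with
#' [ng86()]. Invalid estimates are kept in the table but flagged.
#'
#' @param aln Codon alignment tibble covering the subfamily members.
#' @param members Character vector of gene ids (>= 2).
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed.
#' @return Tibble `gene_a`, `gene_b`, `dN`, `dS`, `omega`, `valid`.
#' @export
sample_pair_omegas <- function(aln, members, n_pairs = 20, seed = 1) {
  members <- unique(members)
  if (length(members) < 2) {
    stop("need at least 2 subfamily members", call. = FALSE)
  }
  missing <- setdiff(members, aln$gene_id)
  if (length(missing) > 0) {
    stop(
      "members absent from alignment: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  all_pairs <- t(combn(sort(members), 2))
  set.seed(seed)
  take <- if (nrow(all_pairs) <= n_pairs) {
    seq_len(nrow(all_pairs))
  } else {
    sort(sample.int(nrow(all_pairs), n_pairs))
  }
  seq_of <- setNames(aln$seq, aln$gene_id)
  purrr::map_dfr(take, function(i) {
    est <- ng86(seq_of[[all_pairs[i, 1]]], seq_of[[all_pairs[i, 2]]])
    tibble::tibble(
      gene_a = all_pairs[i, 1], gene_b = all_pairs[i, 2],
      dN = est$dN, dS = est$dS, omega = est$omega, valid = est$valid
    )
  })
}

#' Paired t-test comparison of clade omega samples
#'
#' Samples are index-paired (the i-th grass value against the i-th eudicot
#' value); pairs with an invalid member are dropped together. The statistic
#' is `mean(d) / (sd(d)/sqrt(n))` with `df = n - 1` and a two-sided p-value.
#' Zero-variance nonzero-mean differences are a degenerate path: the verdict
#' is significant, p is reported below machine floor and flagged.
#'
#' @param grass_sample,eudicot_sample Equal-length numeric omega samples.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `n`, `mean_grass`, `mean_eudicot`,
#'   `mean_difference`, `t`, `df`, `p_value`, `significant`, `degenerate`,
#'   `pairing`.
#' @export
compare_clades <- function(grass_sample, eudicot_sample, alpha = 0.05) {
  if (length(grass_sample) != length(eudicot_sample)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  ok <- is.finite(grass_sample) & is.finite(eudicot_sample)
  g <- grass_sample[ok]
  e <- eudicot_sample[ok]
  n <- length(g)
  if (n < 2) stop("need at least 2 valid pairs", call. = FALSE)
  d <- g - e
  md <- mean(d)
  sdd <- sd(d)
  # zero variance up to floating-point representation of the differences
  degenerate <- sdd <= 1e-12 * max(abs(md), .Machine$double.xmin)
  if (degenerate) {
    if (md == 0) {
      tstat <- 0
      p <- 1
    } else {
      tstat <- sign(md) * Inf
      p <- .Machine$double.xmin
    }
  } else {
    tstat <- md / (sdd / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  tibble::tibble(
    n = n, mean_grass = mean(g), mean_eudicot = mean(e),
    mean_difference = md, t = tstat, df = n - 1, p_value = p,
    significant = p < alpha & !(degenerate && md == 0),
    degenerate = degenerate, pairing = "index"
  )
}

#' Clade omega comparison for every orthologous subfamily pair
#'
#' For each mutually-paired grass/eudicot subfamily pair, draws omega samples
#' in both subfamilies and runs [compare_clades()].
#'
#' @param aln Codon alignment tibble.
#' @param subfamilies Tibble from [partition_subfamilies()].
#' @param n_pairs Pairs per subfamily.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return Tibble with one row per orthologous subfamily pair.
#' @export
compare_subfamily_omegas <- function(aln, subfamilies, n_pairs = 20,
                                     alpha = 0.05, seed = 1) {
  placed <- subfamilies |> dplyr::filter(!.data$unplaced)
  sf <- placed |>
    dplyr::distinct(.data$subfamily_id, .data$clade, .data$partners)
  members_of <- split(placed$gene_id, placed$subfamily_id)
  out <- NULL
  grass_sf <- sf |> dplyr::filter(.data$clade == "grass")
  for (i in seq_len(nrow(grass_sf))) {
    gid <- grass_sf$subfamily_id[i]
    partners <- strsplit(grass_sf$partners[i], ",")[[1]]
    partners <- partners[nzchar(partners)]
    for (pid in partners) {
      gm <- members_of[[gid]]
      em <- members_of[[pid]]
      if (length(gm) < 2 || length(em) < 2) next
      gs <- sample_pair_omegas(aln, gm, n_pairs,
        seed = branch_seed(seed, paste0(gid, "|", pid, "|g"))
      )
      es <- sample_pair_omegas(aln, em, n_pairs,
        seed = branch_seed(seed, paste0(gid, "|", pid, "|e"))
      )
      m <- min(nrow(gs), nrow(es))
      cmp <- tryCatch(
        compare_clades(gs$omega[seq_len(m)], es$omega[seq_len(m)], alpha),
        error = function(err) NULL
      )
      if (is.null(cmp)) next
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble::tibble(grass_subfamily = gid, eudicot_subfamily = pid), cmp
      ))
    }
  }
  out %||% tibble::tibble(
    grass_subfamily = character(0), eudicot_subfamily = character(0)
  )
}
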