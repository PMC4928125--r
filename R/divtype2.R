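# Type-II functional divergence between two subfamily clusters: a moment
# estimator of the divergence coefficient theta-II from dually-conserved
# alignment columns, with a one-sided z-test against 0.

#' Classify alignment columns between two clusters
#'
#' Columns with more than 50% gaps in either cluster are excluded. Among the
#' rest, a column is `conserved_same` when each cluster shows a single
#' residue (gaps ignored) and the residues agree across clusters,
#' `conserved_different` when both are internally fixed but differ across
#' clusters (the type-II pattern), and `other` otherwise.
#'
#' @param cluster_a,cluster_b Protein alignment tibbles sharing one master
#'   column coordinate system (equal aligned lengths).
#' @return List: `counts` (named: conserved_same, conserved_different,
#'   other, excluded), `category` per column, `analyzed` logical per column.
#' @export
classify_sites <- function(cluster_a, cluster_b) {
  if (nrow(cluster_a) < 2 || nrow(cluster_b) < 2) {
    stop("each cluster needs at least 2 sequences", call. = FALSE)
  }
  la <- unique(nchar(cluster_a$seq))
  lb <- unique(nchar(cluster_b$seq))
  if (length(la) != 1 || length(lb) != 1 || la != lb) {
    stop("clusters must share one master alignment coordinate system",
      call. = FALSE
    )
  }
  ma <- do.call(rbind, strsplit(cluster_a$seq, ""))
  mb <- do.call(rbind, strsplit(cluster_b$seq, ""))
  is_gap <- function(x) x == "-" | x == "." | x == "X"
  n_col <- ncol(ma)
  category <- character(n_col)
  for (j in seq_len(n_col)) {
    a <- ma[, j]
    b <- mb[, j]
    if (mean(is_gap(a)) > 0.5 || mean(is_gap(b)) > 0.5) {
      category[j] <- "excluded"
      next
    }
    ra <- unique(a[!is_gap(a)])
    rb <- unique(b[!is_gap(b)])
    category[j] <- if (length(ra) == 1 && length(rb) == 1) {
      if (ra == rb) "conserved_same" else "conserved_different"
    } else {
      "other"
    }
  }
  counts <- c(
    conserved_same = sum(category == "conserved_same"),
    conserved_different = sum(category == "conserved_different"),
    other = sum(category == "other"),
    excluded = sum(category == "excluded")
  )
  list(counts = counts, category = category, analyzed = category != "excluded")
}

#' Estimate the type-II functional divergence coefficient
#'
#' `theta_II = (F_obs - F_exp) / (1 - F_exp)`, where `F_obs` is the fraction
#' of between-cluster fixed differences among dually-conserved columns and
#' `F_exp` its no-divergence expectation: the p-distance between the two
#' cluster consensus sequences (majority residue per column, a proxy for the
#' cluster ancestors) over the analyzed columns, passed through the Poisson
#' correction `D = -log(1 - p)` and `F_exp = 1 - exp(-D)`. Conditioning on
#' the consensus rather than mean pairwise distance nets out within-cluster
#' tip variation, so theta-II centres on zero for neutrally diverged
#' clusters and rises when conserved sites carry an excess of fixed
#' between-cluster differences. The standard error propagates the binomial
#' variance of `F_obs`; the z-test against 0 is one-sided (divergence means
#' theta-II > 0).
#'
#' @inheritParams classify_sites
#' @return One-row tibble: `theta`, `se`, `z`, `p_value`, `f_obs`, `f_exp`,
#'   `n_conserved`, `n_analyzed`, plus the site-category counts and a
#'   `valid` flag (FALSE when no dually-conserved sites exist).
#' @export
estimate_theta2 <- function(cluster_a, cluster_b) {
  cls <- classify_sites(cluster_a, cluster_b)
  n_analyzed <- sum(cls$analyzed)
  if (n_analyzed < 20) {
    stop("need at least 20 analyzed columns", call. = FALSE)
  }
  n_same <- cls$counts[["conserved_same"]]
  n_diff <- cls$counts[["conserved_different"]]
  n_cons <- n_same + n_diff

  base <- tibble::tibble(
    conserved_same = n_same, conserved_different = n_diff,
    other = cls$counts[["other"]], excluded = cls$counts[["excluded"]],
    n_conserved = n_cons, n_analyzed = n_analyzed
  )
  if (n_cons == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(
        theta = NA_real_, se = NA_real_, z = NA_real_, p_value = NA_real_,
        f_obs = NA_real_, f_exp = NA_real_, valid = FALSE
      ), base
    ))
  }

  # consensus (ancestral-proxy) p-distance over the analyzed columns
  keep <- which(cls$analyzed)
  consensus <- function(aln) {
    m <- do.call(rbind, strsplit(aln$seq, ""))[, keep, drop = FALSE]
    apply(m, 2, function(col) {
      col <- col[!(col %in% c("-", ".", "X"))]
      if (length(col) == 0) {
        return(NA_character_)
      }
      tab <- sort(table(col), decreasing = TRUE)
      # majority residue; ties break lexicographically for determinism
      cand <- names(tab)[tab == max(tab)]
      sort(cand)[1]
    })
  }
  ca <- consensus(cluster_a)
  cb <- consensus(cluster_b)
  ok <- !is.na(ca) & !is.na(cb)
  p_bar <- sum(ca[ok] != cb[ok]) / sum(ok)
  p_bar <- min(p_bar, 0.999)
  d_poisson <- -log(1 - p_bar)
  f_exp <- 1 - exp(-d_poisson)
  f_obs <- n_diff / n_cons

  theta <- (f_obs - f_exp) / (1 - f_exp)
  se <- sqrt(f_obs * (1 - f_obs) / n_cons) / (1 - f_exp)
  degenerate <- se == 0
  z <- if (degenerate) {
    if (theta > 0) Inf else if (theta < 0) -Inf else 0
  } else {
    theta / se
  }
  p <- pnorm(z, lower.tail = FALSE)
  dplyr::bind_cols(
    tibble::tibble(
      theta = theta, se = se, z = z, p_value = p,
      f_obs = f_obs, f_exp = f_exp, valid = TRUE
    ), base
  )
}

#' Simulate a pair of protein clusters with optional type-II shifts
#'
#' Generates two clusters descended from one ancestral protein. A
#' `shift_fraction` of columns switches to a different fixed residue in
#' cluster B only (those columns stay internally constrained in both
#' clusters — the type-II pattern); the remaining columns diverge neutrally:
#' the cluster-B consensus changes with probability `stem_p`, and every
#' sequence carries independent per-column noise with probability `noise`.
#'
#' @param n_per_cluster Sequences per cluster.
#' @param n_columns Alignment columns.
#' @param shift_fraction Fraction of columns with a cluster-B fixed shift.
#' @param stem_p Neutral consensus-divergence probability per column.
#' @param noise Per-sequence, per-column substitution probability at
#'   unshifted columns.
#' @param seed Integer seed.
#' @return List: `cluster_a`, `cluster_b` (alignment tibbles),
#'   `shifted_sites` (column indices).
#' @export
simulate_divergent_clusters <- function(n_per_cluster = 5, n_columns = 300,
                                        shift_fraction = 0, stem_p = 0.05,
                                        noise = 0.05, seed = 1) {
  set.seed(seed)
  aa <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  anc <- sample(aa, n_columns, replace = TRUE)
  cons_a <- anc
  cons_b <- anc
  n_shift <- round(shift_fraction * n_columns)
  shifted <- if (n_shift > 0) sort(sample(n_columns, n_shift)) else integer(0)
  for (s in shifted) cons_b[s] <- sample(setdiff(aa, anc[s]), 1)
  neutral <- setdiff(seq_len(n_columns), shifted)
  stem_hit <- neutral[runif(length(neutral)) < stem_p]
  for (s in stem_hit) cons_b[s] <- sample(setdiff(aa, cons_b[s]), 1)

  draw_cluster <- function(cons, prefix) {
    tibble::tibble(
      gene_id = paste0(prefix, seq_len(n_per_cluster)),
      seq = vapply(seq_len(n_per_cluster), function(i) {
        s <- cons
        hit <- intersect(which(runif(n_columns) < noise), neutral)
        for (h in hit) s[h] <- sample(setdiff(aa, s[h]), 1)
        paste0(s, collapse = "")
      }, character(1))
    )
  }
  list(
    cluster_a = draw_cluster(cons_a, "a"),
    cluster_b = draw_cluster(cons_b, "b"),
    shifted_sites = shifted
  )
}

#' Theta-II for every pair of subfamily clusters
#'
#' Applies [estimate_theta2()] to each unordered pair of placed subfamilies
#' with at least two members, using the shared master protein alignment.
#'
#' @param aln Master protein alignment tibble.
#' @param subfamilies Tibble from [partition_subfamilies()].
#' @return Tibble with `cluster_a`, `cluster_b` and the [estimate_theta2()]
#'   columns; pairs failing preconditions are skipped.
#' @export
theta2_table <- function(aln, subfamilies) {
  placed <- subfamilies |> dplyr::filter(!.data$unplaced)
  members_of <- split(placed$gene_id, placed$subfamily_id)
  members_of <- members_of[lengths(members_of) >= 2]
  ids <- names(members_of)
  out <- NULL
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        ca <- aln |> dplyr::filter(.data$gene_id %in% members_of[[ids[i]]])
        cb <- aln |> dplyr::filter(.data$gene_id %in% members_of[[ids[j]]])
        est <- tryCatch(estimate_theta2(ca, cb), error = function(e) NULL)
        if (is.null(est)) next
        out <- dplyr::bind_rows(out, dplyr::bind_cols(
          tibble::tibble(cluster_a = ids[i], cluster_b = ids[j]), est
        ))
      }
    }
  }
  out %||% tibble::tibble(cluster_a = character(0), cluster_b = character(0))
}
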