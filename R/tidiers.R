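# broom-style tidiers for fitted objects.

#' Tidy a codon model fit
#'
#' One row per estimated substitution parameter (kappa, omegas, class
#' proportions).
#'
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @method tidy codon_fit
#' @export
tidy.codon_fit <- function(x, ...) {
  terms <- c("kappa", paste0("omega_", names(x$omega)))
  est <- c(x$kappa, unname(x$omega))
  if (!is.null(x$props)) {
    terms <- c(terms, names(x$props))
    est <- c(est, unname(x$props))
  }
  tibble::tibble(term = terms, estimate = est)
}

#' One-line summary of a codon model fit
#'
#' @inheritParams tidy.codon_fit
#' @return One-row tibble: `model`, `lnL`, `n_params`, `n_sites`,
#'   `converged`, `bound_hit`.
#' @method glance codon_fit
#' @export
glance.codon_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, lnL = x$lnL, n_params = x$n_params,
    n_sites = x$n_sites, converged = x$converged,
    bound_hit = any(x$bound_hit)
  )
}

#' Tidy a site-selection result
#'
#' @param x A `site_selection` from [neb_sites()].
#' @param ... Unused.
#' @return The per-site posterior tibble.
#' @method tidy site_selection
#' @export
tidy.site_selection <- function(x, ...) {
  x$sites
}

#' One-line summary of a site-selection result
#'
#' @inheritParams tidy.site_selection
#' @return One-row tibble: `n_sites`, `n_selected`, `threshold`,
#'   `max_omega`.
#' @method glance site_selection
#' @export
glance.site_selection <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites), n_selected = length(x$selected),
    threshold = x$threshold, max_omega = max(x$omega)
  )
}
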