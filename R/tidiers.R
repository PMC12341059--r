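#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dwell-time fit
#'
#' One row per fitted component: `term`, `tau` (s), `weight`.
#'
#' @param x A `dwell_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dwell_fit <- function(x, ...) {
  if (nrow(x$components) == 0)
    return(tibble::tibble(term = character(0), tau = numeric(0),
                          weight = numeric(0)))
  terms <- if (x$kind == "open") "tau_open"
           else paste0("tau_closed", seq_len(nrow(x$components)))
  tibble::tibble(term = terms, tau = x$components$tau,
                 weight = x$components$weight)
}

#' Glance at a dwell-time fit
#'
#' @inheritParams tidy.dwell_fit
#' @return A one-row tibble: `kind`, `n_components`, `n_dwells`, `sse`,
#'   `converged`.
#' @export
glance.dwell_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_components = nrow(x$components),
                 n_dwells = x$n_dwells, sse = x$sse, converged = x$converged)
}

#' Tidy a slope-conductance fit
#'
#' @param x A `conductance_fit`.
#' @param ... Unused.
#' @return A tibble with `term` (slope_conductance_pS, intercept_pA) and
#'   `estimate`.
#' @export
tidy.conductance_fit <- function(x, ...) {
  tibble::tibble(term = c("slope_conductance_pS", "intercept_pA"),
                 estimate = c(x$slope_conductance, x$intercept))
}

#' Glance at a slope-conductance fit
#'
#' @inheritParams tidy.conductance_fit
#' @return A one-row tibble: `slope_conductance`, `r_squared`, `n_points`.
#' @export
glance.conductance_fit <- function(x, ...) {
  tibble::tibble(slope_conductance = x$slope_conductance,
                 r_squared = x$r_squared, n_points = x$n_points)
}

#' Tidy a group comparison
#'
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @return The pairwise tibble with the omnibus row prepended.
#' @export
tidy.comparison_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(group_a = "(omnibus)", group_b = "(omnibus)",
                   adjusted_p = x$omnibus_p),
    dplyr::select(x$pairwise, group_a, group_b, adjusted_p))
}
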