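#' Tidy a mixture fit into its component table
#'
#' @param x A `mixture_fit` from [fit_distance_distribution()].
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `weight`, `mean`,
#'   `sd`.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 weight = x$weights, mean = x$means, sd = x$sds)
}

#' @rdname tidy.mixture_fit
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(n = x$n, selected_model = x$selected_model,
                 n_components = x$n_components,
                 bic_gaussian = unname(x$bic["gaussian"]),
                 bic_bimodal = unname(x$bic["bimodal_gaussian"]),
                 loglik = x$loglik)
}

#' Tidy paired-cohort results
#'
#' @param x A `paired_cohort` from [paired_group_test()].
#' @param ... Unused.
#' @return `tidy()`: the per-fly pairs; `glance()`: one row with `n`,
#'   `test_used`, `statistic`, `p_value`.
#' @method tidy paired_cohort
#' @export
tidy.paired_cohort <- function(x, ...) x$pairs

#' @rdname tidy.paired_cohort
#' @method glance paired_cohort
#' @export
glance.paired_cohort <- function(x, ...) {
  tibble::tibble(n = x$n, test_used = x$test_used,
                 statistic = x$statistic, p_value = x$p_value)
}

#' Tidy group comparisons
#'
#' @param x A `group_comparison` from [group_compare()].
#' @param ... Unused.
#' @return `tidy()`: the Tukey pairwise table (ANOVA) or the group summary
#'   (t test); `glance()`: one row with the omnibus test.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$pairwise)) x$pairwise else x$group_summary
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test_used = x$test_used, statistic = x$statistic,
                 p_value = x$p_value)
}

#' @rdname tidy.paired_cohort
#' @method tidy optogenetic_result
#' @export
tidy.optogenetic_result <- function(x, ...) x$per_preparation

#' @rdname tidy.paired_cohort
#' @method glance optogenetic_result
#' @export
glance.optogenetic_result <- function(x, ...) {
  tibble::tibble(n = x$n, test_used = x$test_used,
                 statistic = x$statistic, p_value = x$p_value)
}

#' Tidy a circuit trajectory
#'
#' @param x A `circuit_trajectory` from [run_protocol()].
#' @param ... Unused.
#' @return `tidy()`: the per-phase response table; `glance()`: the per-phase
#'   model PI in wide form.
#' @method tidy circuit_trajectory
#' @export
tidy.circuit_trajectory <- function(x, ...) x$responses

#' @rdname tidy.circuit_trajectory
#' @method glance circuit_trajectory
#' @export
glance.circuit_trajectory <- function(x, ...) {
  last <- x$pi[!duplicated(x$pi$phase, fromLast = TRUE), ]
  tidyr::pivot_wider(last[, c("phase", "pi_model")],
                     names_from = "phase", values_from = "pi_model",
                     names_prefix = "pi_")
}
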