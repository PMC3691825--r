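#' Tidy a fitted binary states model
#'
#' @param x A `bsm_fit` from [bsm()].
#' @param ... Unused.
#' @return The per-gene results tibble (`gene_id`, `profile`,
#'   `defined_stages`, `n_transitions`, `class`, `p`, `q`, `selected`).
#' @export
tidy.bsm_fit <- function(x, ...) {
  x$results
}

#' One-row summary of a fitted binary states model
#'
#' @inheritParams tidy.bsm_fit
#' @return One-row tibble: dataset dimensions, fitted parameters, number of
#'   permutations, number of distinct observed profiles and number of
#'   selected genes.
#' @export
glance.bsm_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = x$G, n_samples = x$N, n_stages = x$Z,
    t = x$params$t, u = x$params$u, mp = x$params$mp,
    sd_mode = x$params$sd_mode, B = x$B,
    n_profiles_observed = dplyr::n_distinct(x$results$profile),
    n_selected = sum(x$results$selected), q_cutoff = x$q_cutoff
  )
}

#' Tidy a grid-search result
#'
#' @param x A `bsm_grid` from [estimate_params()].
#' @param ... Unused.
#' @return The full score table: one row per `(t, u, mp)` combination with
#'   the observed and random defined-gene totals and the NF score.
#' @export
tidy.bsm_grid <- function(x, ...) {
  x$table
}

#' One-row summary of a grid search
#'
#' @inheritParams tidy.bsm_grid
#' @return One-row tibble with the winning parameters and the score
#'   landscape extremes.
#' @export
glance.bsm_grid <- function(x, ...) {
  tibble::tibble(
    t = x$params$t, u = x$params$u, mp = x$params$mp,
    sd_mode = x$sd_mode, nf_mode = x$nf_mode, P = x$P,
    n_combinations = nrow(x$table),
    NF_best = max(x$table$NF), NF_worst = min(x$table$NF),
    n_genes = x$G
  )
}

#' Tidy a profile null distribution
#'
#' @param x A `bsm_null` from [build_null()].
#' @param ... Unused.
#' @return Tibble with `profile`, `count` and `freq`, plus transition and
#'   defined-stage annotations.
#' @export
tidy.bsm_null <- function(x, ...) {
  tibble::tibble(
    profile = x$profile, count = x$count, freq = x$freq,
    n_transitions = count_transitions(x$profile),
    defined_stages = defined_stage_count(x$profile)
  )
}

#' Tidy a simulation study
#'
#' @param x A `bsm_simstudy` from [run_simulation_study()].
#' @param ... Unused.
#' @return The per-dataset recovery tibble.
#' @export
tidy.bsm_simstudy <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a simulation study
#'
#' @inheritParams tidy.bsm_simstudy
#' @return One-row tibble with run counts and, per method, the pooled
#'   overall recovery (`recovery_<method>` columns).
#' @export
glance.bsm_simstudy <- function(x, ...) {
  rs <- recovery_summary(x)
  ov <- rs[rs$stages == "overall", ]
  out <- tibble::tibble(
    n_runs = dplyr::n_distinct(tibble::as_tibble(x)$run),
    n_positive_total = sum(ov$n_positive[1])
  )
  for (i in seq_len(nrow(ov))) {
    out[[paste0("recovery_", ov$method[i])]] <- ov$recovery[i]
  }
  out
}
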