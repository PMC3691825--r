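#' Discretization parameters for the binary states model
#'
#' Bundles the three discretization parameters: the cutoff `t` separating
#' active from inactive expression, the uncertainty multiplier `u`, and the
#' minimum stage proportion `mp`.  The uncertainty band around the cutoff is
#' `[t - u*sd, t + u*sd]`; values inside it get the uncertain state 0.
#'
#' @param t Cutoff on the uniformized expression scale, `0 < t < 1`.
#'   Default 0.5 (the per-sample median after uniformization).
#' @param u Unitless multiplier of a standard deviation giving the
#'   half-width of the uncertainty band; `u >= 0`.  Default 0 (no band).
#' @param mp Minimum proportion of a stage's samples that must share a state
#'   for the stage to be called active or inactive, `0 < mp <= 1`.
#'   Default 0.7.
#' @param sd_mode `"per-gene"` scales `u` by each gene's own sample standard
#'   deviation (adapting the band to per-gene variation); `"global"` uses
#'   the standard deviation of the whole matrix for every gene.
#' @return An object of class `bsm_params`.
#' @seealso [estimate_params()] to choose these values by grid search.
#' @export
bsm_params <- function(t = 0.5, u = 0, mp = 0.7,
                       sd_mode = c("per-gene", "global")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(t > 0, t < 1, u >= 0, mp > 0, mp <= 1)
  structure(list(t = t, u = u, mp = mp, sd_mode = sd_mode),
            class = "bsm_params")
}

#' @export
print.bsm_params <- function(x, ...) {
  cat(sprintf("BSM parameters: t = %g, u = %g (%s sd), mp = %g\n",
              x$t, x$u, x$sd_mode, x$mp))
  invisible(x)
}

#' Effective uncertainty half-width per gene
#'
#' Converts the unitless multiplier `u` into expression-scale half-widths by
#' multiplying it with a standard deviation: each gene's own row standard
#' deviation (`sd_mode = "per-gene"`) or the standard deviation of all
#' matrix entries broadcast to every gene (`"global"`).  A zero-variance
#' gene gets half-width 0.
#'
#' @inheritParams uniformize
#' @param u Uncertainty multiplier, `u >= 0`.
#' @inheritParams bsm_params
#' @return Tibble with columns `gene_id` and `h` (half-width in expression
#'   units).
#' @export
effective_uncertainty <- function(data, u, sd_mode = c("per-gene", "global")) {
  sd_mode <- match.arg(sd_mode)
  m <- as_expr_matrix(data)
  h <- half_widths(m, u, sd_mode)
  tibble::tibble(gene_id = rownames(m),
                 h = unname(rep(h, length.out = nrow(m))))
}

#' Ternary state of a single expression value
#'
#' A value strictly above `t + h` is active (+1), strictly below `t - h`
#' inactive (-1), and anything inside the closed band -- including the exact
#' boundaries, and the cutoff itself when `h = 0` -- is uncertain (0).
#'
#' @param gev Expression value(s) on the uniformized scale.
#' @param t Cutoff.
#' @param h Uncertainty half-width (expression units), `h >= 0`.
#' @return Integer vector over \{-1, 0, +1\}, recycled over `gev`.
#' @examples
#' sample_state(c(0.9, 0.5, 0.45, 0.30), t = 0.5, h = c(0, 0, 0.1, 0.1))
#' @export
sample_state <- function(gev, t, h = 0) {
  as.integer((gev > t + h) - (gev < t - h))
}

#' Binarize an expression matrix into sample states
#'
#' Applies [sample_state()] elementwise with per-gene half-widths from
#' [effective_uncertainty()].  Binarization looks at one sample at a time
#' and therefore ignores the stage design entirely; permuting stage labels
#' later does not change this matrix.
#'
#' @inheritParams uniformize
#' @param params A [bsm_params()] object.
#' @param warn_scale Warn when values fall outside `[0, 1]` (an indication
#'   that the data were not uniformized).
#' @return Tibble `gene_id` plus one integer column per sample over
#'   \{-1, 0, +1\}, with attributes `params` and `u_eff` (per-gene
#'   half-widths).
#' @export
binarize <- function(data, params = bsm_params(), warn_scale = TRUE) {
  m <- as_expr_matrix(data)
  if (warn_scale && (min(m) < 0 || max(m) > 1)) {
    warning("expression values outside [0, 1]; did you forget uniformize()?",
            call. = FALSE)
  }
  h <- half_widths(m, params$u, params$sd_mode)
  S <- ternary_states(m, params$t, h)
  out <- expr_tbl(S)
  out <- dplyr::mutate(out, dplyr::across(-"gene_id", as.integer))
  attr(out, "params") <- params
  attr(out, "u_eff") <- rep(h, length.out = nrow(m))
  out
}
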