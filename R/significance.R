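#' Permute the stage labels of a design
#'
#' Shuffles the sample-to-stage assignment uniformly at random while keeping
#' the per-stage sample counts and the stage order fixed -- the permutation
#' scheme behind the profile null distribution.
#'
#' @inheritParams gene_profiles
#' @param seed Optional integer seed for a reproducible permutation.
#' @return A stage-design tibble with the same samples and stage sizes.
#' @export
permute_design <- function(design, seed = NULL) {
  design <- check_design(design)
  shuffle <- function() sample(design$stage)
  design$stage <- if (is.null(seed)) shuffle() else
    withr::with_seed(seed, shuffle())
  design
}

#' Build the permutation null over stage-state profiles
#'
#' Recomputes every gene's profile under `B` independent permutations of
#' the stage labels and tallies how often each of the `3^Z` profiles
#' occurs.  Binarization ignores stage labels, so the sample-state matrix
#' is computed once and only the per-stage aggregation is repeated.  The
#' counts always sum to `G * B`.  All genes share this single
#' profile-indexed null table.
#'
#' @inheritParams gene_profiles
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed for the permutation stream.
#' @return Object of class `bsm_null`: a tibble with columns `profile`,
#'   `count` and `freq` (count / (G*B)) covering the full profile space,
#'   with attributes `G`, `B`, `Z` and `mp`.
#' @export
build_null <- function(states, design, mp = NULL, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  mp <- mp %||% attr(states, "params")$mp
  if (is.null(mp)) stop("mp not given and not recorded on 'states'",
                        call. = FALSE)
  seed <- resolve_seed(seed)
  S <- as_expr_matrix(states)
  al <- align_design(colnames(S), design)
  counts <- null_profile_counts((S == 1) + 0, (S == -1) + 0, al$idx, al$n,
                                mp, B, seed)
  G <- nrow(S)
  out <- tibble::tibble(
    profile = code_to_profile(0:(3^al$Z - 1), al$Z),
    count = counts,
    freq = counts / (G * B)
  )
  structure(out, G = G, B = B, Z = al$Z, mp = mp, seed = seed,
            class = c("bsm_null", class(out)))
}

#' Empirical profile p-value against a permutation null
#'
#' `p = min(1, (1 + count(profile)) / (G * B))`: the pseudo-count keeps
#' never-observed profiles at the achievable floor `1 / (G * B)` and the
#' cap keeps ubiquitous profiles at 1.  Profiles absent from the null table
#' are treated as count 0.
#'
#' @inheritParams count_transitions
#' @param null A `bsm_null` from [build_null()].
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
profile_p_value <- function(profile, null) {
  stopifnot(inherits(null, "bsm_null"))
  G <- attr(null, "G")
  B <- attr(null, "B")
  cnt <- null$count[match(profile, null$profile)]
  cnt[is.na(cnt)] <- 0
  pmin(1, (1 + cnt) / (G * B))
}

#' FDR-adjusted q-values
#'
#' Benjamini-Hochberg step-up by default; `method = "storey"` additionally
#' scales by the estimated null proportion `pi0 = min(1, mean(p > 0.5) /
#' 0.5)`.  Both are monotone in the p-value ranks.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @param method `"BH"` or `"storey"`.
#' @return Numeric vector of q-values in `(0, 1]`.
#' @export
q_values <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  stopifnot(all(p > 0), all(p <= 1))
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Select significant genes by q-value
#'
#' @param results Tibble with at least `gene_id`, `p` and `q` columns (as
#'   produced by [bsm()] / [tidy.bsm_fit()]).
#' @param q_cutoff Keep genes with `q <= q_cutoff` (default 0.2).
#' @return The selected rows, ordered by `p` then `gene_id`.
#' @export
select_genes <- function(results, q_cutoff = 0.2) {
  out <- dplyr::filter(results, .data$q <= q_cutoff)
  dplyr::arrange(out, .data$p, .data$gene_id)
}
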