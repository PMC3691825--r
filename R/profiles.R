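#' Encode and decode stage-state profiles
#'
#' A stage-state profile is an ordered vector over \{-1, 0, +1\}, one entry
#' per progression stage, written as a dot-separated string such as
#' `"1.0.-1.1"` (active in stage 1, uncertain in stage 2, inactive in
#' stage 3, active in stage 4).
#'
#' @param states Integer vector over \{-1, 0, +1\} (`encode_profile`), or a
#'   list of such vectors.
#' @param profile Character vector of dot-separated profile strings
#'   (`decode_profile`).
#' @return `encode_profile()` a character scalar/vector; `decode_profile()`
#'   a list of integer vectors.
#' @export
encode_profile <- function(states) {
  if (is.list(states)) {
    vapply(states, function(v) paste(as.integer(v), collapse = "."),
           character(1))
  } else {
    paste(as.integer(states), collapse = ".")
  }
}

#' @rdname encode_profile
#' @export
decode_profile <- function(profile) {
  lapply(strsplit(as.character(profile), ".", fixed = TRUE), function(p) {
    v <- suppressWarnings(as.integer(p))
    if (anyNA(v) || any(!v %in% c(-1L, 0L, 1L))) {
      stop("invalid profile encoding: '", paste(p, collapse = "."), "'",
           call. = FALSE)
    }
    v
  })
}

#' Aggregate one stage's sample states into a stage state
#'
#' Let `pa` and `pi` be the fractions of the stage's samples (uncertain
#' samples included in the denominator) in the active and inactive state.
#' The stage is active (+1) when `pa >= mp` and `pa > pi`, inactive (-1)
#' when `pi >= mp` and `pi > pa`, and uncertain (0) otherwise -- including
#' the exact tie `pa == pi`, which can only occur at `mp <= 0.5`.
#'
#' @param states Integer vector of the stage's sample states over
#'   \{-1, 0, +1\}.
#' @param mp Minimum proportion, `0 < mp <= 1`.
#' @return Integer scalar in \{-1, 0, +1\}.
#' @export
stage_state <- function(states, mp) {
  stopifnot(length(states) > 0, mp > 0, mp <= 1)
  n <- length(states)
  pa <- sum(states == 1) / n
  pb <- sum(states == -1) / n
  as.integer((pa >= mp && pa > pb) - (pb >= mp && pb > pa))
}

#' Per-gene stage-state profiles
#'
#' Aggregates a sample-state matrix into one profile per gene by applying
#' the [stage_state()] rule within each stage, in the design's progression
#' order.  The result depends only on the multiset of states within each
#' stage, never on sample order.
#'
#' @param states Sample-state tibble from [binarize()] (`gene_id` plus one
#'   integer column per sample).
#' @param design Stage design from [stage_design()] / [read_design()].
#' @param mp Minimum proportion; defaults to the `mp` recorded by
#'   [binarize()] when available.
#' @return Tibble with columns `gene_id`, `profile` (dot string),
#'   `defined_stages`, `n_transitions` and `class`.
#' @export
gene_profiles <- function(states, design, mp = NULL) {
  mp <- mp %||% attr(states, "params")$mp
  if (is.null(mp)) stop("mp not given and not recorded on 'states'",
                        call. = FALSE)
  S <- as_expr_matrix(states)
  al <- align_design(colnames(S), design)
  ind <- stage_indicator(al$idx, al$Z)
  SP <- stage_state_counts((S == 1) %*% ind, (S == -1) %*% ind, al$n, mp)
  prof <- code_to_profile(profile_codes(SP), al$Z)
  tibble::tibble(
    gene_id = rownames(S),
    profile = prof,
    defined_stages = defined_stage_count(prof),
    n_transitions = count_transitions(prof),
    class = classify_profile(prof)
  )
}

#' Count activation transitions in a profile
#'
#' A transition is a sign change between consecutive *nonzero* entries of
#' the profile: uncertain stages are skipped, so `-1.0.1` contains one
#' transition.  Transitions are the marker of progression-relevant
#' behavior; oncogene- and TSG-like profiles have exactly one.
#'
#' @param profile Character vector of profile strings.
#' @return Integer vector of transition counts.
#' @examples
#' count_transitions(c("1.1.1.1", "1.0.-1.1", "1.-1.-1.-1"))
#' @export
count_transitions <- function(profile) {
  vapply(decode_profile(profile), function(v) {
    nz <- v[v != 0]
    if (length(nz) < 2) return(0L)
    sum(nz[-1] * nz[-length(nz)] < 0)
  }, integer(1))
}

#' Number of defined (non-uncertain) stages in a profile
#'
#' @inheritParams count_transitions
#' @return Integer vector counting the nonzero entries of each profile.
#' @export
defined_stage_count <- function(profile) {
  vapply(decode_profile(profile), function(v) sum(v != 0L), integer(1))
}

#' Enumerate the full profile space for Z stages
#'
#' All `3^Z` stage-state profiles in a deterministic order (stage 1 varies
#' fastest), annotated with transition counts, defined-stage counts and
#' class labels.  For Z = 4 this is the 81-profile space of which 50 carry
#' at least one transition and 14 exactly two.
#'
#' @param Z Number of progression stages, `Z >= 1`.
#' @return Tibble with columns `profile`, `n_transitions`, `defined_stages`,
#'   `class`.
#' @export
enumerate_profiles <- function(Z) {
  stopifnot(Z >= 1)
  prof <- code_to_profile(0:(3^Z - 1), Z)
  tibble::tibble(
    profile = prof,
    n_transitions = count_transitions(prof),
    defined_stages = defined_stage_count(prof),
    class = classify_profile(prof)
  )
}

#' Classify a profile into the oncogene/TSG taxonomy
#'
#' Profiles are labelled by their transition structure:
#' \describe{
#'   \item{`uncertain-only`}{every stage uncertain (all zeros).}
#'   \item{`flat`}{no transition but at least one defined stage.}
#'   \item{`oncogene` family}{exactly one transition, from inactive to
#'     active: the gene switches on during progression.}
#'   \item{`tsg` family}{exactly one transition, from active to inactive:
#'     tumor-suppressor-like loss of activity.}
#'   \item{`two-transition`}{exactly two transitions ("2 t" profiles, e.g.
#'     active in normal and metastasis but inactive in between).}
#'   \item{`multi-transition`}{three or more transitions.}
#' }
#' Within the one-transition families, `-early` marks profiles whose first
#' two stages are both defined with opposite signs (the switch happens
#' already at the second stage), and `-late` marks fully defined profiles
#' whose single transition sits between the last two stages.  The late TSG
#' label carries the metastasis-suppressor alias (`tsg-late-msg`): a gene
#' active through all pre-metastatic stages and lost only at metastasis.
#' When both apply (possible only at Z = 2) the early label wins.
#'
#' @inheritParams count_transitions
#' @return Character vector of class labels.
#' @export
classify_profile <- function(profile) {
  vapply(decode_profile(profile), function(v) {
    k <- {
      nz <- v[v != 0]
      if (length(nz) < 2) 0L else sum(nz[-1] * nz[-length(nz)] < 0)
    }
    if (k == 0L) {
      return(if (all(v == 0L)) "uncertain-only" else "flat")
    }
    if (k == 2L) return("two-transition")
    if (k > 2L) return("multi-transition")
    nz <- v[v != 0]
    fam <- if (nz[which(nz[-1] * nz[-length(nz)] < 0)[1] + 1L] == 1L) {
      "oncogene"
    } else {
      "tsg"
    }
    Z <- length(v)
    early <- Z >= 2 && v[1] != 0L && v[2] != 0L && v[1] != v[2]
    late <- all(v != 0L) && v[Z] != v[Z - 1]
    if (early) {
      paste0(fam, "-early")
    } else if (late) {
      if (fam == "tsg") "tsg-late-msg" else "oncogene-late"
    } else {
      fam
    }
  }, character(1))
}
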