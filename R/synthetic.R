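#' Valid (mean, sd) levels for active/inactive stage values
#'
#' Synthetic active values are Gaussian with mean drawn from
#' \{0.625, 0.750, 0.875\} and sd from \{0.125, 0.250, 0.375\}, keeping only
#' combinations with `mean - sd >= 0.5` so that draws sit clearly above the
#' midpoint.  Inactive values mirror this below 0.5 (`mean + sd <= 0.5`
#' with means \{0.125, 0.250, 0.375\}).  Six of the nine combinations
#' survive on each side.
#'
#' @param state `+1` (active) or `-1` (inactive).
#' @return Tibble with columns `mean` and `sd`.
#' @export
valid_level_params <- function(state) {
  stopifnot(state %in% c(-1, 1))
  sds <- c(0.125, 0.250, 0.375)
  means <- if (state == 1) c(0.625, 0.750, 0.875) else c(0.125, 0.250, 0.375)
  g <- expand.grid(mean = means, sd = sds, KEEP.OUT.ATTRS = FALSE)
  keep <- if (state == 1) g$mean - g$sd >= 0.5 else g$mean + g$sd <= 0.5
  tibble::as_tibble(g[keep, , drop = FALSE])
}

#' Draw synthetic expression values for one gene in one stage
#'
#' Active/inactive stages draw `n` Gaussians with a (mean, sd) pair chosen
#' uniformly from [valid_level_params()]; uncertain stages draw a balanced
#' two-component mixture (`ceiling(n/2)` samples from N(0.75, 0.15), the
#' rest from N(0.25, 0.15)).  All draws are clipped into `[0, 1]`.
#'
#' @param state Stage state in \{-1, 0, +1\}.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
gen_stage_values <- function(state, n, seed = NULL) {
  stopifnot(state %in% c(-1, 0, 1), n >= 1)
  draw <- function() {
    if (state == 0) {
      n1 <- ceiling(n / 2)
      x <- c(rnorm(n1, 0.75, 0.15), rnorm(n - n1, 0.25, 0.15))
    } else {
      lv <- valid_level_params(state)
      i <- sample.int(nrow(lv), 1)
      x <- rnorm(n, lv$mean[i], lv$sd[i])
    }
    pmin(pmax(x, 0), 1)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Specification of a synthetic benchmark dataset
#'
#' Describes a dataset of `n_total` genes over `Z` ordered stages with
#' `n_per_stage` samples each: a small set of positive genes following
#' ideal progression profiles (oncogene/TSG-like, with at least one
#' activation transition) and negatives following transition-free profiles
#' (flat or uncertainty-containing).  Default positive counts are 60, 180
#' and 200 for 2, 3 and 4 stages.
#'
#' @param Z Number of stages (2, 3 or 4).
#' @param n_per_stage Samples per stage; the benchmark uses 10--50.
#' @param n_positive Number of positive genes; default depends on `Z`.
#' @param n_total Total genes (default 5000).
#' @param restrict_roster For `Z = 4`, restrict the positive profiles to
#'   the six canonical examples instead of all 14 fully defined profiles
#'   with at least one transition.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(Z, n_per_stage, n_positive = NULL,
                           n_total = 5000, restrict_roster = FALSE) {
  stopifnot(Z %in% 2:4, n_total >= 1)
  if (!n_per_stage %in% c(10, 20, 30, 40, 50)) {
    warning("n_per_stage ", n_per_stage,
            " is outside the benchmark set {10,20,30,40,50}; proceeding",
            call. = FALSE)
  }
  if (is.null(n_positive)) n_positive <- c(`2` = 60, `3` = 180, `4` = 200)[[as.character(Z)]]
  stopifnot(n_positive >= 1, n_positive <= n_total)
  structure(list(Z = Z, n_per_stage = n_per_stage, n_positive = n_positive,
                 n_total = n_total, restrict_roster = restrict_roster),
            class = "synthetic_spec")
}

#' Positive and negative profile rosters
#'
#' Positives are the "ideal" progression profiles: every stage defined
#' (no zeros) and at least one transition -- 2 profiles at Z = 2, 6 at
#' Z = 3 and 14 at Z = 4 (for Z = 4 the six canonical examples are listed
#' first, so a restricted roster is a prefix).  Negatives are all
#' transition-free profiles, including ones with uncertain stages.
#'
#' @param Z Number of stages.
#' @param restricted Use only the six canonical Z = 4 profiles.
#' @return Character vector of profile strings.
#' @export
positive_profiles <- function(Z, restricted = FALSE) {
  all_p <- enumerate_profiles(Z)
  full <- all_p$profile[all_p$defined_stages == Z & all_p$n_transitions >= 1]
  if (Z == 4) {
    canonical <- c("1.1.1.-1", "-1.1.1.-1", "-1.-1.-1.1",
                   "1.-1.-1.1", "1.-1.-1.-1", "-1.1.1.1")
    if (restricted) return(canonical)
    return(c(canonical, setdiff(full, canonical)))
  }
  full
}

#' @rdname positive_profiles
#' @export
negative_profiles <- function(Z) {
  all_p <- enumerate_profiles(Z)
  all_p$profile[all_p$n_transitions == 0]
}

#' Generate a synthetic benchmark dataset
#'
#' Builds the expression matrix, stage design and ground-truth table for a
#' [synthetic_spec()].  Positives are allocated as evenly as possible
#' across the positive roster (remainders go to the leading profiles);
#' negatives cycle through the transition-free roster until `n_total`
#' genes.  Gene order is shuffled so that identifiers carry no information
#' about the truth.  Values are generated per gene and stage by the
#' [gen_stage_values()] scheme and are already on the unit scale, so no
#' uniformization is applied downstream.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed; the whole dataset is reproducible
#'   from it.
#' @return List with elements `expression` (tibble, marked uniformized),
#'   `design` (stage design tibble) and `truth` (tibble `gene_id`,
#'   `is_positive`, `true_profile`).
#' @export
gen_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  build <- function() {
    Z <- spec$Z
    n <- spec$n_per_stage
    N <- Z * n
    pos_roster <- positive_profiles(Z, restricted = spec$restrict_roster)
    neg_roster <- negative_profiles(Z)
    np <- spec$n_positive
    base <- np %/% length(pos_roster)
    extra <- np %% length(pos_roster)
    pos_profiles <- rep(pos_roster, times = base +
                          (seq_along(pos_roster) <= extra))
    neg_profiles_v <- rep_len(neg_roster, spec$n_total - np)
    profiles <- c(pos_profiles, neg_profiles_v)
    is_pos <- c(rep(TRUE, np), rep(FALSE, length(neg_profiles_v)))
    G <- length(profiles)

    m <- matrix(0, G, N)
    states_by_profile <- decode_profile(unique(profiles))
    names(states_by_profile) <- unique(profiles)
    lv_act <- valid_level_params(1)
    lv_ina <- valid_level_params(-1)
    for (pr in names(states_by_profile)) {
      rows <- which(profiles == pr)
      ng <- length(rows)
      st <- states_by_profile[[pr]]
      for (z in seq_len(Z)) {
        cols <- ((z - 1) * n + 1):(z * n)
        if (st[z] == 0) {
          n1 <- ceiling(n / 2)
          vals <- cbind(
            matrix(rnorm(ng * n1, 0.75, 0.15), ng, n1),
            if (n - n1 > 0) matrix(rnorm(ng * (n - n1), 0.25, 0.15),
                                   ng, n - n1)
          )
        } else {
          lv <- if (st[z] == 1) lv_act else lv_ina
          i <- sample.int(nrow(lv), ng, replace = TRUE)
          vals <- matrix(rnorm(ng * n, mean = lv$mean[i], sd = lv$sd[i]),
                         ng, n)
        }
        m[rows, cols] <- pmin(pmax(vals, 0), 1)
      }
    }

    ord <- sample.int(G)
    m <- m[ord, , drop = FALSE]
    profiles <- profiles[ord]
    is_pos <- is_pos[ord]
    ids <- sprintf("g%04d", seq_len(G))
    rownames(m) <- ids
    colnames(m) <- sprintf("s%03d", seq_len(N))

    expr <- expr_tbl(m)
    attr(expr, "uniformized") <- TRUE
    design <- stage_design(
      data.frame(sample_id = colnames(m),
                 stage = rep(paste0("stage", seq_len(Z)), each = n)),
      stage_order = paste0("stage", seq_len(Z))
    )
    truth <- tibble::tibble(gene_id = ids, is_positive = is_pos,
                            true_profile = profiles)
    list(expression = expr, design = design, truth = truth)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' The 40-run simulation study design
#'
#' 14 two-stage, 16 three-stage and 10 four-stage datasets with samples
#' per stage cycling through 10, 20, 30, 40, 50 -- totalling 5,720 positive
#' genes (14x60 + 16x180 + 10x200).
#'
#' @return Tibble with columns `run`, `Z`, `n_per_stage`.
#' @export
simulation_design <- function() {
  zs <- c(rep(2L, 14), rep(3L, 16), rep(4L, 10))
  ns <- c(rep_len(c(10L, 20L, 30L, 40L, 50L), 14),
          rep_len(c(10L, 20L, 30L, 40L, 50L), 16),
          rep_len(c(10L, 20L, 30L, 40L, 50L), 10))
  tibble::tibble(run = seq_along(zs), Z = zs, n_per_stage = ns)
}

#' Run the recovery benchmark on synthetic datasets
#'
#' For each dataset in `study`, generates the data, runs each method, takes
#' its top `N` genes with `N` equal to the number of positive genes, and
#' scores recovery = |top N intersect positives| / N.  The BSM route runs
#' the full pipeline per dataset: grid-search parameter estimation against
#' `P` random datasets (cached across datasets of equal shape), a
#' permutation null of size `B`, and ranking by empirical p-value.
#'
#' @param study Tibble with columns `Z` and `n_per_stage` (default
#'   [simulation_design()]).
#' @param methods Subset of `c("bsm", "ttest", "wilcoxon", "ftest",
#'   "copa")`.
#' @inheritParams bsm
#' @param restrict_roster Passed to [synthetic_spec()].
#' @param progress Emit a message per dataset.
#' @return Object of class `bsm_simstudy`: one row per dataset x method
#'   with columns `run`, `Z`, `n_per_stage`, `method`, `n_positive`,
#'   `n_recovered`, `recovery`, and the fitted `t`, `u`, `mp` for BSM.
#'   See [glance.bsm_simstudy()] and [recovery_summary()].
#' @export
run_simulation_study <- function(study = simulation_design(),
                                 methods = "bsm", P = 100, B = 1000,
                                 q_cutoff = 0.2, seed = NULL,
                                 restrict_roster = FALSE,
                                 progress = FALSE) {
  methods <- match.arg(methods, c("bsm", "ttest", "wilcoxon", "ftest",
                                  "copa"), several.ok = TRUE)
  seed <- resolve_seed(seed)
  run_id <- if ("run" %in% names(study)) study$run else seq_len(nrow(study))
  dr_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(study) * length(methods))
  k <- 0L
  for (i in seq_len(nrow(study))) {
    Z <- study$Z[i]
    n <- study$n_per_stage[i]
    spec <- synthetic_spec(Z, n, restrict_roster = restrict_roster)
    syn <- gen_dataset(spec, seed = derive_seed(seed, paste0("data", i)))
    positives <- syn$truth$gene_id[syn$truth$is_positive]
    N_top <- length(positives)
    for (meth in methods) {
      rk <- switch(meth,
        bsm = {
          fit <- bsm(syn$expression, syn$design, P = P, B = B,
                     q_cutoff = q_cutoff, apply_uniformize = "never",
                     seed = derive_seed(seed, paste0("fit", i)),
                     dr_cache = dr_cache,
                     dr_seed = derive_seed(seed, "dr-shared"))
          bsm_ranking(fit)
        },
        ttest = stage_vs_rest_scores(syn$expression, syn$design, test = "t"),
        wilcoxon = stage_vs_rest_scores(syn$expression, syn$design,
                                        test = "wilcoxon"),
        ftest = ftest_scores(syn$expression, syn$design),
        copa = copa_scores(syn$expression, syn$design)
      )
      top <- rk$gene_id[rk$rank <= N_top]
      rec <- length(intersect(top, positives))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        run = run_id[i], Z = Z, n_per_stage = n, method = meth,
        n_positive = N_top, n_recovered = rec, recovery = rec / N_top,
        t = if (meth == "bsm") fit$params$t else NA_real_,
        u = if (meth == "bsm") fit$params$u else NA_real_,
        mp = if (meth == "bsm") fit$params$mp else NA_real_
      )
      if (progress) {
        message(sprintf("run %d (Z=%d, n=%d): %s recovered %d/%d (%.1f%%)",
                        i, Z, n, meth, rec, N_top, 100 * rec / N_top))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, seed = seed, P = P, B = B,
            class = c("bsm_simstudy", class(out)))
}

#' Pooled recovery of a simulation study
#'
#' Pools recovered and positive gene counts per method, overall and per
#' stage count, mirroring how the benchmark reports "overall" and
#' per-stage recovery percentages.
#'
#' @param study A `bsm_simstudy` from [run_simulation_study()].
#' @return Tibble with columns `method`, `stages` (`"overall"` or the
#'   stage count), `n_positive`, `n_recovered`, `recovery`.
#' @export
recovery_summary <- function(study) {
  tbl <- tibble::as_tibble(study)
  per_z <- tbl |>
    dplyr::group_by(.data$method, stages = as.character(.data$Z)) |>
    dplyr::summarise(n_positive = sum(.data$n_positive),
                     n_recovered = sum(.data$n_recovered), .groups = "drop")
  overall <- tbl |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(stages = "overall", n_positive = sum(.data$n_positive),
                     n_recovered = sum(.data$n_recovered), .groups = "drop")
  dplyr::bind_rows(overall, per_z) |>
    dplyr::mutate(recovery = .data$n_recovered / .data$n_positive) |>
    dplyr::arrange(.data$method, .data$stages)
}
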