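# Shared fixtures: tiny in-code datasets and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_expression <- function(values, gene_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  G <- nrow(m)
  N <- ncol(m)
  tibble::tibble(
    gene_id = gene_ids %||% paste0("g", seq_len(G)),
    !!!stats::setNames(lapply(seq_len(N), function(j) m[, j]),
                       sample_ids %||% paste0("s", seq_len(N)))
  )
}

toy_design <- function(stages, sample_ids = NULL, stage_order = NULL) {
  stage_design(
    data.frame(sample_id = sample_ids %||% paste0("s", seq_along(stages)),
               stage = stages),
    stage_order = stage_order %||% unique(stages)
  )
}

# independent transition counter: run-length encoding of the nonzero
# subsequence (vs the sign-product rule used by the package)
oracle_transitions <- function(states) {
  nz <- states[states != 0]
  if (length(nz) == 0) return(0L)
  length(rle(nz)$values) - 1L
}

# enumerate all profiles for Z stages as integer rows, independent of
# enumerate_profiles(): recursive cartesian product
oracle_profile_space <- function(Z) {
  if (Z == 1) return(matrix(c(-1L, 0L, 1L), ncol = 1))
  rest <- oracle_profile_space(Z - 1)
  do.call(rbind, lapply(c(-1L, 0L, 1L), function(s) {
    cbind(rest, s)
  }))
}

# plain-loop BSM profile computation for oracle comparisons
oracle_profiles <- function(expr_tbl_data, design, t, u, mp,
                            sd_mode = "per-gene") {
  m <- as.matrix(expr_tbl_data[, -1])
  rownames(m) <- expr_tbl_data[[1]]
  global_sd <- stats::sd(as.vector(m))
  lv <- levels(design$stage)
  vapply(seq_len(nrow(m)), function(g) {
    h <- if (u == 0) 0 else if (sd_mode == "per-gene") {
      u * stats::sd(m[g, ])
    } else {
      u * global_sd
    }
    st <- integer(length(lv))
    for (z in seq_along(lv)) {
      smp <- design$sample_id[design$stage == lv[z]]
      vals <- m[g, smp]
      states <- ifelse(vals > t + h, 1L, ifelse(vals < t - h, -1L, 0L))
      pa <- mean(states == 1)
      pi_ <- mean(states == -1)
      st[z] <- if (pa >= mp && pa > pi_) 1L else
        if (pi_ >= mp && pi_ > pa) -1L else 0L
    }
    paste(st, collapse = ".")
  }, character(1))
}
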