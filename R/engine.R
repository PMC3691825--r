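# Internal numeric kernels.  All heavy computation happens here on plain
# matrices; the exported surface converts to/from tibbles at the boundary.

# tibble (gene_id + one column per sample) -> numeric matrix with dimnames
as_expr_matrix <- function(data) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  ids <- as.character(data[[1]])
  m <- as.matrix(data[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(data[-1], is.numeric, logical(1)))[1]
    stop("expression column '", names(data)[-1][bad], "' is not numeric",
         call. = FALSE)
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing value at gene '", ids[idx[1]], "', sample '",
         colnames(m)[idx[2]], "'; matrices with missing cells are rejected",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated gene id: '", ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated sample id: '", colnames(m)[duplicated(colnames(m))][1],
         "'", call. = FALSE)
  }
  rownames(m) <- ids
  m
}

expr_tbl <- function(m, id_col = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, ..gene.. = rownames(m), .before = 1)
  names(out)[1] <- id_col
  out
}

# Align a stage design to the sample columns of an expression/state tibble.
# Returns list(idx, n, levels, Z): idx[i] is the stage index of sample column i.
align_design <- function(sample_ids, design) {
  design <- check_design(design)
  lv <- levels(design$stage)
  pos <- match(sample_ids, design$sample_id)
  if (anyNA(pos)) {
    stop("sample '", sample_ids[is.na(pos)][1],
         "' is missing from the stage design", call. = FALSE)
  }
  extra <- setdiff(design$sample_id, sample_ids)
  if (length(extra)) {
    stop("design sample '", extra[1], "' is absent from the matrix",
         call. = FALSE)
  }
  idx <- as.integer(design$stage[pos])
  n <- tabulate(idx, length(lv))
  list(idx = idx, n = n, levels = lv, Z = length(lv))
}

row_sds <- function(X) {
  n <- ncol(X)
  if (n < 2) return(rep(0, nrow(X)))
  m <- rowMeans(X)
  v <- (rowSums(X * X) - n * m * m) / (n - 1)
  sqrt(pmax(v, 0))
}

# h may be a scalar or a per-gene vector; recycling down columns matches genes
ternary_states <- function(X, t, h) {
  (X > t + h) - (X < t - h)
}

stage_indicator <- function(stage_idx, Z) {
  N <- length(stage_idx)
  ind <- matrix(0, N, Z)
  ind[cbind(seq_len(N), stage_idx)] <- 1
  ind
}

# CP/CN: G x (Z*k) active/inactive counts (k stacked designs);
# n_rep: per-column stage sizes.  Proportions use ALL samples in the stage
# (uncertain samples count in the denominator); ties resolve to 0.
stage_state_counts <- function(CP, CN, n_rep, mp) {
  pa <- sweep(CP, 2, n_rep, "/")
  pb <- sweep(CN, 2, n_rep, "/")
  (pa >= mp & pa > pb) - (pb >= mp & pb > pa)
}

# base-3 profile code, stage 1 = least significant digit; 0 .. 3^Z - 1
profile_codes <- function(S) {
  Z <- ncol(S)
  as.integer(round(drop((S + 1) %*% 3^(0:(Z - 1)))))
}

code_to_profile <- function(code, Z) {
  digits <- matrix(0L, length(code), Z)
  c0 <- code
  for (z in seq_len(Z)) {
    digits[, z] <- c0 %% 3L
    c0 <- c0 %/% 3L
  }
  digits <- digits - 1L
  apply(digits, 1, paste, collapse = ".")
}

# count of genes defined in exactly s stages, s = 0..Z
defined_table <- function(S, Z) {
  d <- rowSums(S != 0)
  tabulate(d + 1L, Z + 1L)
}

# Defined-stage count tables for every (t, u, mp) grid cell on one matrix.
# Returns (Z+1) x ncombo matrix; combo order = u outer, then t, then mp,
# matching grid_combos().
grid_tables <- function(X, stage_idx, n_vec, t_grid, u_grid, mp_grid,
                        sd_mode = "per-gene") {
  Z <- length(n_vec)
  ind <- stage_indicator(stage_idx, Z)
  ncombo <- length(t_grid) * length(u_grid) * length(mp_grid)
  out <- matrix(0, Z + 1, ncombo)
  combo <- 0L
  for (u in u_grid) {
    h <- half_widths(X, u, sd_mode)
    V <- X - h
    W <- X + h
    for (t in t_grid) {
      CP <- (V > t) %*% ind
      CN <- (W < t) %*% ind
      for (mp in mp_grid) {
        combo <- combo + 1L
        S <- stage_state_counts(CP, CN, n_vec, mp)
        out[, combo] <- defined_table(S, Z)
      }
    }
  }
  out
}

grid_combos <- function(t_grid, u_grid, mp_grid) {
  g <- expand.grid(mp = mp_grid, t = t_grid, u = u_grid,
                   KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(t = g$t, u = g$u, mp = g$mp)
}

half_widths <- function(X, u, sd_mode) {
  if (u == 0) return(0)
  if (sd_mode == "per-gene") u * row_sds(X) else u * stats::sd(X)
}

# Mean defined-stage tables over P random Uniform(0,1) datasets of the same
# shape and stage layout (the false-assignment reference for the NF score).
dr_tables <- function(G, N, stage_idx, n_vec, t_grid, u_grid, mp_grid,
                      P, sd_mode, seed) {
  acc <- NULL
  withr::with_seed(seed, {
    for (p in seq_len(P)) {
      X <- matrix(stats::runif(G * N), G, N)
      tab <- grid_tables(X, stage_idx, n_vec, t_grid, u_grid, mp_grid, sd_mode)
      acc <- if (is.null(acc)) tab else acc + tab
    }
  })
  acc / P
}

# Profile-code null counts over B permutations of the stage labels.
# pos/neg: G x N numeric 0/1 sample-state indicators (binarization is
# permutation invariant, so they are computed once).
null_profile_counts <- function(pos, neg, stage_idx, n_vec, mp, B, seed,
                                chunk = 64L) {
  Z <- length(n_vec)
  G <- nrow(pos)
  N <- ncol(pos)
  w <- 3^(0:(Z - 1))
  counts <- numeric(3^Z)
  withr::with_seed(seed, {
    done <- 0L
    while (done < B) {
      nb <- min(chunk, B - done)
      IND <- matrix(0, N, Z * nb)
      for (b in seq_len(nb)) {
        perm <- sample(stage_idx)
        IND[cbind(seq_len(N), (b - 1L) * Z + perm)] <- 1
      }
      n_rep <- rep(n_vec, nb)
      S <- stage_state_counts(pos %*% IND, neg %*% IND, n_rep, mp)
      S1 <- sweep(S + 1, 2, rep(w, nb), "*")
      codes <- matrix(0, G, nb)
      for (z in seq_len(Z)) {
        codes <- codes + S1[, seq.int(z, Z * nb, by = Z), drop = FALSE]
      }
      counts <- counts + tabulate(as.integer(round(codes)) + 1L, 3^Z)
      done <- done + nb
    }
  })
  counts
}

# Deterministic sub-seed derivation so that independent stages of a pipeline
# (grid search, permutations, per-dataset generation) get reproducible,
# non-overlapping streams from one user seed.  Kept below 2^31.
derive_seed <- function(seed, key) {
  h <- 0
  for (k in utf8ToInt(key)) h <- (h * 131 + k) %% 2147483563
  as.integer((h + as.numeric(seed)) %% 2147483563 + 1)
}

resolve_seed <- function(seed) {
  if (is.null(seed)) seed <- sample.int(2147483562L, 1)
  as.integer(seed)
}
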