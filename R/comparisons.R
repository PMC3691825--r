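# Reference implementations of the comparison selectors.  Rankings are
# deterministic: ascending p (or descending outlier score) with ties broken
# by gene id.

rank_scores <- function(gene_id, score, decreasing = FALSE) {
  key <- if (decreasing) -score else score
  ord <- order(key, gene_id)
  rk <- integer(length(ord))
  rk[ord] <- seq_along(ord)
  rk
}

#' Stage-versus-rest differential expression scores
#'
#' For every gene and every stage, runs a two-sample test (Welch t or
#' Wilcoxon rank-sum with normal approximation) of that stage's samples
#' against all remaining samples pooled.  A gene's score is its minimum
#' p-value across stages -- the only monotone aggregation consistent with
#' ranking by "most significant" -- and genes are ranked by ascending
#' score.  A gene with zero variance in both groups gets p = 1.
#'
#' @inheritParams uniformize
#' @inheritParams gene_profiles
#' @param test `"t"` (Welch) or `"wilcoxon"`.
#' @return Tibble with `gene_id`, `score` (min p across stages),
#'   `best_stage` and `rank`.
#' @export
stage_vs_rest_scores <- function(data, design, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  m <- as_expr_matrix(data)
  al <- align_design(colnames(m), design)
  G <- nrow(m)
  pmat <- matrix(1, G, al$Z)
  for (z in seq_len(al$Z)) {
    in_z <- al$idx == z
    if (sum(in_z) < 2 || sum(!in_z) < 2) {
      stop("stage '", al$levels[z], "' or its complement has fewer than 2 ",
           "samples", call. = FALSE)
    }
    pmat[, z] <- if (test == "t") {
      welch_p(m[, in_z, drop = FALSE], m[, !in_z, drop = FALSE])
    } else {
      wilcoxon_p(m[, in_z, drop = FALSE], m[, !in_z, drop = FALSE])
    }
  }
  score <- apply(pmat, 1, min)
  best <- al$levels[apply(pmat, 1, which.min)]
  tibble::tibble(gene_id = rownames(m), score = score, best_stage = best,
                 rank = rank_scores(rownames(m), score))
}

# vectorized two-sided Welch t-test over rows; zero variance in both
# groups -> p = 1
welch_p <- function(A, B) {
  n1 <- ncol(A)
  n2 <- ncol(B)
  m1 <- rowMeans(A)
  m2 <- rowMeans(B)
  # variances below 1e-16 on the unit expression scale are numerical noise
  v1 <- row_sds(A)^2
  v2 <- row_sds(B)^2
  v1[v1 < 1e-16] <- 0
  v2[v2 < 1e-16] <- 0
  se2 <- v1 / n1 + v2 / n2
  # two constant groups: no test; equal means -> no signal, different
  # means -> complete separation, floored at a tiny p
  p <- ifelse(m1 == m2, 1, 1e-300)
  ok <- se2 > 0
  tt <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * pt(-abs(tt), df)
  p
}

# two-sided Wilcoxon rank-sum, normal approximation with tie correction and
# continuity correction (matching wilcox.test(exact = FALSE))
wilcoxon_p <- function(A, B) {
  n1 <- ncol(A)
  n2 <- ncol(B)
  n <- n1 + n2
  X <- cbind(A, B)
  vapply(seq_len(nrow(X)), function(g) {
    r <- rank(X[g, ])
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }, numeric(1))
}

#' Across-stage F-test scores
#'
#' Classic one-way analysis-of-variance F-test per gene across all stages
#' (equal-variance form).  Genes with no within-stage variance but a
#' between-stage difference would give p = 0; their score is floored at a
#' tiny epsilon so ranks stay finite and deterministic.  Genes with no
#' variance at all get p = 1.
#'
#' @inheritParams stage_vs_rest_scores
#' @return Tibble with `gene_id`, `score` (p-value) and `rank`.
#' @export
ftest_scores <- function(data, design) {
  m <- as_expr_matrix(data)
  al <- align_design(colnames(m), design)
  if (any(al$n < 2)) stop("every stage needs >= 2 samples", call. = FALSE)
  N <- ncol(m)
  Z <- al$Z
  ind <- stage_indicator(al$idx, Z)
  gm <- rowMeans(m)
  sm <- sweep(m %*% ind, 2, al$n, "/")      # stage means, G x Z
  ssb <- rowSums(sweep(sm - gm, 2, al$n, "*") * (sm - gm))
  sst <- rowSums((m - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  Fst <- (ssb / (Z - 1)) / (ssw / (N - Z))
  p <- pf(Fst, Z - 1, N - Z, lower.tail = FALSE)
  # degenerate variance decompositions (relative to total variance):
  # all-between -> epsilon floor, no variance at all -> no signal
  p[ssw <= 1e-12 * sst & sst > 0] <- 0
  p[sst <= 1e-16] <- 1
  score <- unname(pmax(p, 1e-300))
  tibble::tibble(gene_id = rownames(m), score = score,
                 rank = rank_scores(rownames(m), score))
}

#' Quantile-based outlier (COPA-style) scores
#'
#' Per gene and stage, takes the maximum of the 75th, 90th and 95th
#' percentiles of the stage's values (linear interpolation between order
#' statistics), then the maximum across stages.  Genes are ranked by
#' descending score; intended for data on the uniformized `[0, 1]` scale.
#'
#' @inheritParams stage_vs_rest_scores
#' @param probs Percentile levels (default `c(0.75, 0.90, 0.95)`).
#' @return Tibble with `gene_id`, `score` and `rank` (1 = highest score).
#' @export
copa_scores <- function(data, design, probs = c(0.75, 0.90, 0.95)) {
  m <- as_expr_matrix(data)
  al <- align_design(colnames(m), design)
  qmax <- matrix(-Inf, nrow(m), al$Z)
  for (z in seq_len(al$Z)) {
    sub <- m[, al$idx == z, drop = FALSE]
    qs <- t(apply(sub, 1, quantile, probs = probs, names = FALSE))
    qmax[, z] <- apply(qs, 1, max)
  }
  score <- apply(qmax, 1, max)
  tibble::tibble(gene_id = rownames(m), score = score,
                 rank = rank_scores(rownames(m), score, decreasing = TRUE))
}

#' Top-N genes of a ranking
#'
#' @param ranking Tibble with `gene_id` and `rank` columns.
#' @param n Number of genes to keep.
#' @return Character vector of the `n` top-ranked gene ids, in rank order.
#' @export
top_genes <- function(ranking, n) {
  ranking$gene_id[order(ranking$rank)][seq_len(min(n, nrow(ranking)))]
}

#' Overlap fraction between two equal-size gene selections
#'
#' `|a intersect b| / |a|`, with the top-N convention enforcing equal set
#' sizes.
#'
#' @param a,b Character vectors of gene ids with `length(a) == length(b)`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap <- function(a, b) {
  if (length(a) != length(b)) {
    stop("overlap requires equal-size selections (top-N convention); got ",
         length(a), " and ", length(b), call. = FALSE)
  }
  length(intersect(a, b)) / length(a)
}

#' Compare selectors on one dataset
#'
#' Runs each method, keeps its top `n` genes, and reports the pairwise
#' overlap matrix plus (when a truth table is supplied) each method's
#' recovery of the positive genes.  External rankings (e.g. from tools not
#' reimplemented here) can be supplied as two-column tibbles
#' (`gene_id`, `rank`) via `extra_rankings`.
#'
#' @inheritParams stage_vs_rest_scores
#' @param methods Subset of `c("ttest", "wilcoxon", "ftest", "copa")`.
#' @param n Selection size (top-N convention).
#' @param truth Optional truth tibble (`gene_id`, `is_positive`).
#' @param bsm_fit Optional fitted [bsm()] object to include as method
#'   `"bsm"`.
#' @param extra_rankings Optional named list of external ranking tibbles.
#' @return List with `top` (named list of gene-id vectors), `overlap`
#'   (tibble of pairwise fractions) and `recovery` (tibble or `NULL`).
#' @export
compare_methods <- function(data, design,
                            methods = c("ttest", "wilcoxon", "ftest", "copa"),
                            n, truth = NULL, bsm_fit = NULL,
                            extra_rankings = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  rankings <- list()
  for (meth in methods) {
    rankings[[meth]] <- switch(meth,
      ttest = stage_vs_rest_scores(data, design, "t"),
      wilcoxon = stage_vs_rest_scores(data, design, "wilcoxon"),
      ftest = ftest_scores(data, design),
      copa = copa_scores(data, design)
    )
  }
  if (!is.null(bsm_fit)) rankings$bsm <- bsm_ranking(bsm_fit)
  for (nm in names(extra_rankings)) rankings[[nm]] <- extra_rankings[[nm]]
  tops <- lapply(rankings, top_genes, n = n)
  pairs <- expand.grid(a = names(tops), b = names(tops),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
  ov <- tibble::tibble(
    method_a = pairs$a, method_b = pairs$b,
    overlap = mapply(function(a, b) overlap(tops[[a]], tops[[b]]),
                     pairs$a, pairs$b)
  )
  rec <- NULL
  if (!is.null(truth)) {
    positives <- truth$gene_id[truth$is_positive]
    rec <- tibble::tibble(
      method = names(tops),
      n_recovered = vapply(tops, function(tp)
        length(intersect(tp, positives)), integer(1)),
      recovery = vapply(tops, function(tp)
        length(intersect(tp, positives)) / length(positives), numeric(1))
    )
  }
  list(top = tops, overlap = ov, recovery = rec)
}
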