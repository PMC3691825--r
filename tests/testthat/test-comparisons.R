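make_cmp_fixture <- function() {
  set.seed(81)
  # gene 1: stage-1 high vs rest; gene 2: flat constant; gene 3: noise;
  # gene 4: graded stage means
  m <- rbind(
    c(rep(0.9, 10), rep(0.1, 30)),
    rep(0.5, 40),
    runif(40),
    rep(c(0.2, 0.4, 0.6, 0.8), each = 10) + rnorm(40, 0, 0.05)
  )
  list(x = toy_expression(m, sample_ids = paste0("s", 1:40)),
       d = toy_design(rep(paste0("st", 1:4), each = 10),
                      sample_ids = paste0("s", 1:40)))
}

test_that("stage-versus-rest t scores match a per-stage loop oracle", {
  fx <- make_cmp_fixture()
  sc <- stage_vs_rest_scores(fx$x, fx$d, test = "t")
  expect_equal(sc$score[2], 1)             # constant gene: no signal
  expect_equal(sc$rank[2], 4L)             # ranked last
  expect_equal(sc$best_stage[1], "st1")    # maximal separation at stage 1
  m <- as.matrix(fx$x[, -1])
  oracle <- vapply(1:4, function(g) {
    min(vapply(1:4, function(z) {
      in_z <- fx$d$stage == paste0("st", z)
      if (sd(m[g, in_z]) == 0 && sd(m[g, !in_z]) == 0) {
        # untestable split: equal constants carry no signal, different
        # constants are complete separation
        return(if (mean(m[g, in_z]) == mean(m[g, !in_z])) 1 else 1e-300)
      }
      stats::t.test(m[g, in_z], m[g, !in_z])$p.value
    }, numeric(1)))
  }, numeric(1))
  expect_equal(sc$score, oracle, tolerance = 1e-12)
})

test_that("stage-versus-rest wilcoxon scores match wilcox.test", {
  fx <- make_cmp_fixture()
  sc <- stage_vs_rest_scores(fx$x, fx$d, test = "wilcoxon")
  m <- as.matrix(fx$x[, -1])
  oracle <- vapply(1:4, function(g) {
    min(vapply(1:4, function(z) {
      in_z <- fx$d$stage == paste0("st", z)
      suppressWarnings(stats::wilcox.test(m[g, in_z], m[g, !in_z],
                                          exact = FALSE)$p.value)
    }, numeric(1)))
  }, numeric(1))
  # constant gene: degenerate ranks, defined as no signal
  expect_equal(sc$score[2], 1)
  expect_equal(sc$score[-2], oracle[-2], tolerance = 1e-9)
})

test_that("f-test scores match one-way ANOVA and are label-invariant", {
  fx <- make_cmp_fixture()
  sc <- ftest_scores(fx$x, fx$d)
  m <- as.matrix(fx$x[, -1])
  grp <- factor(fx$d$stage[match(colnames(m), fx$d$sample_id)])
  oracle <- vapply(c(3, 4), function(g) {
    stats::oneway.test(m[g, ] ~ grp, var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(sc$score[c(3, 4)], oracle, tolerance = 1e-9)
  expect_equal(sc$score[2], 1)   # no variance at all
  expect_lte(sc$score[1], 1e-100)  # between-stage variance only
  expect_equal(sc$rank[1], 1L)
  expect_equal(sc$rank[4], 2L)  # graded means, tiny variance

  # invariant to stage relabeling
  relab <- fx$d
  relab$stage <- factor(as.character(relab$stage),
                        levels = paste0("st", 4:1))
  expect_equal(ftest_scores(fx$x, relab)$score, sc$score)
})

test_that("f-test p-values are uniform under the null", {
  set.seed(82)
  x <- toy_expression(matrix(rnorm(1000 * 24, 0.5, 0.1), 1000, 24))
  d <- toy_design(rep(c("A", "B", "C"), each = 8),
                  sample_ids = paste0("s", 1:24))
  p <- ftest_scores(x, d)$score
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.03)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.05)
})

test_that("quantile outlier scores match a sort-based oracle", {
  fx <- make_cmp_fixture()
  sc <- copa_scores(fx$x, fx$d)
  expect_equal(sc$score[2], 0.5)  # constant gene: all quantiles 0.5
  one_hot <- toy_expression(rbind(c(rep(1, 10), rep(0.2, 30))),
                            sample_ids = paste0("s", 1:40))
  expect_equal(copa_scores(one_hot, fx$d)$score, 1)

  m <- as.matrix(fx$x[, -1])
  oracle <- vapply(1:4, function(g) {
    max(vapply(1:4, function(z) {
      vals <- sort(m[g, fx$d$stage == paste0("st", z)])
      max(vapply(c(0.75, 0.9, 0.95), function(pr) {
        idx <- 1 + pr * (length(vals) - 1)  # linear interpolation
        lo <- floor(idx); hi <- ceiling(idx)
        vals[lo] + (idx - lo) * (vals[hi] - vals[lo])
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(sc$score, oracle, tolerance = 1e-12)
})

test_that("overlap enforces the top-N convention", {
  expect_equal(overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap(c("a", "b", "c"), c("c", "d", "a")), 2 / 3)
  expect_error(overlap(c("a"), c("a", "b")), "equal-size")
})

test_that("compare_methods reports overlaps and recovery on known truth", {
  syn <- gen_dataset(synthetic_spec(2, 10, n_positive = 30, n_total = 300),
                     seed = 91)
  cmp <- compare_methods(syn$expression, syn$design, n = 30,
                         truth = syn$truth)
  expect_setequal(names(cmp$top), c("ttest", "wilcoxon", "ftest", "copa"))
  expect_true(all(lengths(cmp$top) == 30))
  expect_true(all(cmp$overlap$overlap >= 0 & cmp$overlap$overlap <= 1))
  # the two rank tests agree far beyond chance on clean signal
  tw <- cmp$overlap$overlap[cmp$overlap$method_a == "ttest" &
                              cmp$overlap$method_b == "wilcoxon"]
  expect_gt(tw, 0.5)
  expect_gt(cmp$recovery$recovery[cmp$recovery$method == "ttest"], 0.5)
})

test_that("null-data rankings recover labels at chance level", {
  set.seed(92)
  x <- toy_expression(matrix(runif(400 * 20), 400, 20))
  d <- toy_design(rep(c("A", "B"), each = 10),
                  sample_ids = paste0("s", 1:20))
  fake_pos <- sample(x$gene_id, 40)
  for (fn in list(function() stage_vs_rest_scores(x, d, "t"),
                  function() ftest_scores(x, d),
                  function() copa_scores(x, d))) {
    rec <- length(intersect(top_genes(fn(), 40), fake_pos)) / 40
    expect_lt(rec, 0.35)  # chance is 0.10; generous noise bound
  }
})
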