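test_that("level parameters keep activation clear of the midpoint", {
  act <- valid_level_params(1)
  expect_equal(nrow(act), 6)
  expect_true(all(act$mean - act$sd >= 0.5))
  expect_equal(
    dplyr::arrange(act, mean, sd),
    tibble::tibble(mean = c(0.625, 0.75, 0.75, 0.875, 0.875, 0.875),
                   sd = c(0.125, 0.125, 0.25, 0.125, 0.25, 0.375))
  )
  ina <- valid_level_params(-1)
  expect_equal(nrow(ina), 6)
  expect_true(all(ina$mean + ina$sd <= 0.5))
  # mirror image about 0.5
  expect_equal(sort(1 - ina$mean), sort(act$mean))
  expect_false(any(vapply(seq_len(nrow(act)), function(i)
    act$mean[i] == 0.625 && act$sd[i] == 0.375, logical(1))))
})

test_that("stage value generation matches its distributional contract", {
  a <- gen_stage_values(1, 10000, seed = 51)
  expect_true(all(a >= 0 & a <= 1))
  expect_gte(mean(a), 0.5)
  i <- gen_stage_values(-1, 10000, seed = 52)
  expect_lte(mean(i), 0.5)
  u <- gen_stage_values(0, 10000, seed = 53)
  expect_lt(abs(mean(u) - 0.5), 0.02)
  expect_identical(gen_stage_values(0, 50, seed = 54),
                   gen_stage_values(0, 50, seed = 54))
})

test_that("generated datasets have the specified composition", {
  syn3 <- gen_dataset(synthetic_spec(3, 10), seed = 61)
  expect_equal(sum(syn3$truth$is_positive), 180)
  expect_equal(nrow(syn3$truth), 5000)
  expect_equal(nrow(syn3$expression), 5000)
  expect_equal(ncol(syn3$expression) - 1, 30)
  expect_equal(as.integer(table(syn3$design$stage)), rep(10, 3))

  syn2 <- gen_dataset(synthetic_spec(2, 20), seed = 62)
  expect_equal(sum(syn2$truth$is_positive), 60)
  expect_equal(sum(!syn2$truth$is_positive), 4940)

  # truth invariant: positives transition, negatives do not
  for (syn in list(syn2, syn3)) {
    expect_true(all(count_transitions(
      syn$truth$true_profile[syn$truth$is_positive]) >= 1))
    expect_true(all(count_transitions(
      syn$truth$true_profile[!syn$truth$is_positive]) == 0))
  }
  m <- as.matrix(syn3$expression[, -1])
  expect_true(all(m >= 0 & m <= 1))
  expect_identical(gen_dataset(synthetic_spec(3, 10), seed = 61)$expression,
                   syn3$expression)
})

test_that("positive rosters are the fully defined transitioning profiles", {
  expect_setequal(positive_profiles(2), c("1.-1", "-1.1"))
  p3 <- positive_profiles(3)
  expect_equal(length(p3), 6)
  expect_true(all(defined_stage_count(p3) == 3 & count_transitions(p3) >= 1))
  p4 <- positive_profiles(4)
  expect_equal(length(p4), 14)
  expect_true(all(defined_stage_count(p4) == 4 & count_transitions(p4) >= 1))
  expect_equal(positive_profiles(4, restricted = TRUE), p4[1:6])
  # Z=4 allocation: 200 = 14 x 14 + 4 spread to the leading profiles
  syn4 <- gen_dataset(synthetic_spec(4, 10), seed = 63)
  alloc <- table(syn4$truth$true_profile[syn4$truth$is_positive])
  expect_equal(sort(as.integer(alloc)), c(rep(14, 10), rep(15, 4)))
  expect_true(all(negative_profiles(4) %in%
                    enumerate_profiles(4)$profile))
  expect_equal(length(negative_profiles(4)), 31)
})

test_that("a noise-free caricature reproduces the true profiles", {
  # values pinned at ideal component means: active 0.875, inactive 0.125
  profs <- positive_profiles(4)
  states <- do.call(rbind, decode_profile(profs))
  n <- 6
  m <- matrix(0, length(profs), 4 * n)
  for (z in 1:4) {
    m[, ((z - 1) * n + 1):(z * n)] <-
      ifelse(states[, z] == 1, 0.875, 0.125)
  }
  x <- toy_expression(m, gene_ids = profs,
                      sample_ids = paste0("s", 1:(4 * n)))
  d <- toy_design(rep(paste0("st", 1:4), each = n),
                  sample_ids = paste0("s", 1:(4 * n)))
  st <- binarize(x, bsm_params(0.5, 0, 0.7), warn_scale = FALSE)
  got <- gene_profiles(st, d)
  expect_equal(got$profile, profs)
})

test_that("the 40-run study design pools to 5720 positives", {
  des <- simulation_design()
  expect_equal(nrow(des), 40)
  expect_equal(as.integer(table(des$Z)), c(14, 16, 10))
  expect_true(all(des$n_per_stage %in% c(10, 20, 30, 40, 50)))
  npos <- c(`2` = 60, `3` = 180, `4` = 200)[as.character(des$Z)]
  expect_equal(sum(npos), 5720)
})

test_that("recovery scoring is exact for perfect and random rankings", {
  syn <- gen_dataset(synthetic_spec(2, 10, n_positive = 20, n_total = 200),
                     seed = 71)
  positives <- syn$truth$gene_id[syn$truth$is_positive]
  # a method returning the truth exactly
  perfect <- tibble::tibble(
    gene_id = c(positives, setdiff(syn$truth$gene_id, positives)),
    rank = seq_len(200)
  )
  expect_equal(length(intersect(top_genes(perfect, 20), positives)) / 20, 1)
  # random rankings recover ~ N/G in expectation (hypergeometric)
  set.seed(72)
  recs <- replicate(300, {
    rnd <- tibble::tibble(gene_id = sample(syn$truth$gene_id),
                          rank = seq_len(200))
    length(intersect(top_genes(rnd, 20), positives)) / 20
  })
  expect_lt(abs(mean(recs) - 20 / 200), 0.02)
})
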