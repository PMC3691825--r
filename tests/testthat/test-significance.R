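test_that("permuting a design preserves stage sizes and order", {
  d <- toy_design(rep(c("N", "PIN", "PCA", "Met"), c(39, 13, 32, 20)),
                  sample_ids = paste0("s", 1:104))
  p1 <- permute_design(d, seed = 4)
  expect_equal(as.integer(table(p1$stage)), c(39, 13, 32, 20))
  expect_equal(levels(p1$stage), levels(d$stage))
  expect_equal(p1$sample_id, d$sample_id)
  expect_identical(permute_design(d, seed = 4), p1)
  expect_false(identical(p1$stage, d$stage))
})

test_that("the permutation null conserves counts and matches a loop oracle", {
  set.seed(11)
  x <- toy_expression(matrix(runif(5 * 8), 5, 8))
  d <- toy_design(rep(c("A", "B"), each = 4), sample_ids = paste0("s", 1:8))
  st <- binarize(x, bsm_params(0.5, 0, 0.6), warn_scale = FALSE)
  B <- 20
  nl <- build_null(st, d, B = B, seed = 13)
  expect_equal(sum(nl$count), 5 * B)

  # independent recount: plain loop over permutations using the same stream
  seed_used <- attr(nl, "seed")
  counts <- integer(0)
  withr::with_seed(seed_used, {
    sm <- as.matrix(st[, -1])
    idx <- as.integer(d$stage)
    for (b in seq_len(B)) {
      perm <- sample(idx)
      profs <- vapply(seq_len(nrow(sm)), function(g) {
        paste(vapply(1:2, function(z) {
          stage_state(sm[g, perm == z], mp = 0.6)
        }, integer(1)), collapse = ".")
      }, character(1))
      counts <- c(counts, profs)
    }
  })
  oracle <- table(counts)
  for (pr in names(oracle)) {
    expect_identical(nl$count[nl$profile == pr],
                     as.numeric(oracle[[pr]]))
  }
  expect_equal(sum(nl$count[!nl$profile %in% names(oracle)]), 0)
})

test_that("a permutation-invariant gene always keeps its profile", {
  st <- toy_expression(matrix(1L, 1, 8), sample_ids = paste0("s", 1:8))
  d <- toy_design(rep(c("A", "B", "C", "D"), each = 2),
                  sample_ids = paste0("s", 1:8))
  nl <- build_null(st, d, mp = 0.7, B = 5, seed = 1)
  expect_equal(nl$count[nl$profile == "1.1.1.1"], 5)
  expect_equal(sum(nl$count), 5)
})

test_that("empirical p-values follow the pseudo-counted formula", {
  d <- toy_design(rep(c("A", "B"), each = 4), sample_ids = paste0("s", 1:8))
  st <- binarize(toy_expression(matrix(runif(100 * 8, 0.6, 1), 100, 8)),
                 bsm_params(0.5, 0, 0.7), warn_scale = FALSE)
  nl <- build_null(st, d, B = 10, seed = 2)
  # every gene is constitutively active: all mass on 1.1
  expect_equal(nl$count[nl$profile == "1.1"], 1000)
  expect_equal(profile_p_value("1.1", nl), 1)  # capped at 1
  expect_equal(profile_p_value("-1.1", nl), 1 / 1000)  # never observed

  # direct arithmetic on a hand-built null
  fake <- nl
  fake$count[] <- 0
  fake$count[fake$profile == "1.-1"] <- 4
  attr(fake, "G") <- 100; attr(fake, "B") <- 10
  expect_equal(profile_p_value("1.-1", fake), 5 / 1000)
  expect_equal(profile_p_value(c("1.-1", "0.0"), fake), c(0.005, 0.001))
})

test_that("rarer null profiles never get larger p-values", {
  d <- toy_design(rep(c("A", "B"), each = 10),
                  sample_ids = paste0("s", 1:20))
  set.seed(3)
  st <- binarize(toy_expression(matrix(runif(200 * 20), 200, 20)),
                 bsm_params(0.5, 0, 0.6), warn_scale = FALSE)
  nl <- build_null(st, d, B = 50, seed = 4)
  p <- profile_p_value(nl$profile, nl)
  ord <- order(nl$count)
  expect_true(all(diff(p[ord]) >= 0))
})

test_that("q-values implement Benjamini-Hochberg with optional pi0", {
  p <- c(0.01, 0.02, 0.03, 1.0)
  expect_equal(q_values(p), c(0.04, 0.04, 0.04, 1.0))
  expect_equal(q_values(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  ps <- runif(100)^2
  q <- q_values(ps)
  expect_true(all(diff(q[order(ps)]) >= 0))
  expect_true(all(q_values(ps, "storey") <= q + 1e-12))
})

test_that("gene selection respects the q cutoff and deterministic order", {
  res <- tibble::tibble(gene_id = c("b", "a", "c", "d"),
                        p = c(0.001, 0.001, 0.2, 0.9),
                        q = c(0.01, 0.01, 0.4, 0.9))
  sel <- select_genes(res, q_cutoff = 0.2)
  expect_equal(sel$gene_id, c("a", "b"))
  expect_equal(nrow(select_genes(res, q_cutoff = 0)), 0)
  expect_equal(nrow(select_genes(res, q_cutoff = 1)), 4)
})

test_that("p-values are calibrated on label-permuted data", {
  # permute the labels of a structured dataset first: a fresh permutation
  # null then describes the data themselves, so observed profile
  # frequencies must match null frequencies and (almost) nothing is
  # significant
  syn <- gen_dataset(synthetic_spec(2, 10, n_positive = 100,
                                    n_total = 1000), seed = 41)
  st <- binarize(syn$expression, bsm_params(0.5, 0, 0.7),
                 warn_scale = FALSE)
  nl <- build_null(st, syn$design, B = 200, seed = 43)
  # profile frequencies of permuted datasets, averaged over 10 designs,
  # match the null table (single permutations co-vary across genes)
  obs <- rowMeans(vapply(1:10, function(k) {
    dp <- permute_design(syn$design, seed = 430 + k)
    pr <- gene_profiles(st, dp, mp = 0.7)
    as.numeric(prop.table(table(factor(pr$profile, levels = nl$profile))))
  }, numeric(nrow(nl))))
  expect_lt(max(abs(obs - nl$freq)), 0.05)
  # and almost nothing in a permuted dataset is significant
  pr1 <- gene_profiles(st, permute_design(syn$design, seed = 44), mp = 0.7)
  q <- q_values(profile_p_value(pr1$profile, nl))
  expect_lt(mean(q <= 0.2), 0.01)
})
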