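two_group_norm <- function(seed = 71, n_per = 12, magnitude = 1.5) {
  co <- generate_cohort(cohort_spec(
    n_subtypes = 2, samples_per_subtype = n_per, signature_size = 15,
    signature_magnitude = magnitude, seed = seed
  ))
  list(
    norm = normalize_rp(co$expression, co$gene_lengths),
    clusters = tibble::tibble(
      sample = co$true_labels$sample, cluster = co$true_labels$subtype
    ),
    cohort = co
  )
}

test_that("fold-change profile is zero against itself and scales as medians", {
  m <- as_expr(tibble::tibble(
    gene = c("A", "B"),
    g1 = c(4, 3), g2 = c(4, 5), g3 = c(2, 1), g4 = c(2, 3)
  ), "fpkm")
  cl <- tibble::tibble(
    sample = paste0("g", 1:4),
    cluster = rep(c("big", "small"), each = 2)
  )
  # medians: big = (4, 4), small = (2, 2); gene A small/big = log2(1/2)
  fc <- log2_fc_profile(m, cl, reference = "big", pseudocount = 0)
  expect_equal(fc$log2_fc[fc$group == "big"], c(0, 0))
  expect_equal(fc$log2_fc[fc$group == "small" & fc$rp == "A"], -1)

  # group median 2x reference -> log2_fc = 1
  fc2 <- log2_fc_profile(m, cl, reference = "small", pseudocount = 0)
  expect_equal(fc2$log2_fc[fc2$group == "big" & fc2$rp == "A"], 1)
})

test_that("the reference defaults to the largest cluster", {
  m <- random_expr(5, 7, seed = 72)
  cl <- tibble::tibble(
    sample = paste0("S", 1:7),
    cluster = c(rep("maj", 4), rep("min", 3))
  )
  fc <- log2_fc_profile(m, cl, pseudocount = 1)
  expect_true(all(fc$reference == "maj"))
  de <- rp_differential(m, cl, pseudocount = 1)
  expect_true(all(de$reference == "maj"))
  expect_true(all(de$group == "min"))
})

test_that("swapping group and reference negates the profile", {
  tg <- two_group_norm()
  f1 <- log2_fc_profile(tg$norm, tg$clusters, reference = "subtype_1")
  f2 <- log2_fc_profile(tg$norm, tg$clusters, reference = "subtype_2")
  expect_equal(
    f1$log2_fc[f1$group == "subtype_2"],
    -f2$log2_fc[f2$group == "subtype_1"],
    tolerance = 1e-12
  )
})

test_that("wilcoxon matches full enumeration on small groups", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1) # 2 / C(6, 3)
  expect_equal(res$p_value, oracle_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))

  withr::with_seed(73, {
    for (rep in 1:10) {
      x <- sample(100, sample(3:8, 1))
      y <- sample(1000, sample(3:8, 1)) + 0.5
      expect_equal(
        wilcoxon_rank_sum(x, y)$p_value,
        oracle_wilcoxon_p(x, y),
        tolerance = 1e-12
      )
    }
  })
})

test_that("wilcoxon handles identical groups, ties, and empty input", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  tied <- wilcoxon_rank_sum(c(1, 1, 2, 2), c(1, 2, 2, 3))
  expect_false(tied$exact) # ties force the corrected normal approximation
  expect_true(tied$p_value > 0 && tied$p_value <= 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation tracks the exact p for all sizes <= 10", {
  # exhaustive over group sizes and data (the p-values depend on the data
  # only through the rank sum); the corrected normal approximation agrees
  # with the exact enumeration to ~1e-2 in typical cases, with a worst case
  # just under 0.04 at the smallest sizes
  errs <- c()
  withr::with_seed(74, {
    for (nx in 3:10) {
      for (ny in nx:10) {
        for (rep in 1:3) {
          x <- rnorm(nx)
          y <- rnorm(ny, mean = runif(1, -1, 1))
          p_exact <- oracle_wilcoxon_p(x, y)
          p_norm <- suppressWarnings(
            stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
          )
          errs <- c(errs, abs(p_norm - p_exact))
        }
      }
    }
  })
  expect_lt(max(errs), 0.04)
  expect_lt(median(errs), 1e-2)
})

test_that("wilcoxon p is invariant under strictly monotone transforms", {
  withr::with_seed(75, {
    x <- rlnorm(12)
    y <- rlnorm(15) * 1.5
  })
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(wilcoxon_rank_sum(log(x), log(y))$p_value, p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3)$p_value, p0)
})

test_that("differential table carries consistent fold changes and BH columns", {
  tg <- two_group_norm()
  de <- rp_differential(tg$norm, tg$clusters, reference = "subtype_1")
  expect_equal(nrow(de), 78)
  expect_true(all(de$p_bh >= de$p_raw - 1e-15))
  expect_true(all(de$p_bh <= 1))
  expect_true(all(de$n_group == 12 & de$n_ref == 12))
  # BH-significant set is a subset of the raw-significant set
  expect_true(all(de$rp[de$p_bh < 0.05] %in% de$rp[de$p_raw < 0.05]))
  fc <- log2_fc_profile(tg$norm, tg$clusters, reference = "subtype_1")
  expect_equal(
    de$log2_fc,
    fc$log2_fc[match(paste(de$rp, de$group), paste(fc$rp, fc$group))]
  )
})

test_that("a single deviant RP ranks first in noiseless data", {
  sig <- matrix(0, 2, 78)
  sig[2, 40] <- 1
  co <- generate_cohort(cohort_spec(
    n_subtypes = 2, samples_per_subtype = 8, signature_log2 = sig,
    noise_sd = 0, seed = 76
  ))
  norm <- normalize_rp(co$expression, co$gene_lengths)
  cl <- tibble::tibble(sample = co$true_labels$sample, cluster = co$true_labels$subtype)
  de <- rp_differential(norm, cl, reference = "subtype_1")
  top <- rank_top_rps(de, k = 1)
  expect_equal(top$rp, rp_gene_set()[40])
})

test_that("ranking is a total order, stable under row permutation", {
  tg <- two_group_norm()
  de <- rp_differential(tg$norm, tg$clusters, reference = "subtype_1")
  withr::with_seed(77, shuf <- de[sample(nrow(de)), ])
  expect_identical(rank_top_rps(de, 20)$rp, rank_top_rps(shuf, 20)$rp)
})

test_that("planted signature RPs dominate the top ranks (10 seeds)", {
  hits <- vapply(1:10, function(s) {
    tg <- two_group_norm(seed = 200 + s, n_per = 25, magnitude = 0.8)
    de <- rp_differential(tg$norm, tg$clusters, reference = "subtype_1")
    top15 <- rank_top_rps(de, 15)$rp
    # subtype_2's planted block is RPs 16..30 of the panel; subtype_1's block
    # (RPs 1..15) also separates the groups and is equally legitimate
    planted <- rp_gene_set()[1:30]
    sum(top15 %in% planted)
  }, numeric(1))
  expect_true(all(hits >= 12))
})
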