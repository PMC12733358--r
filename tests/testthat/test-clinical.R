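test_that("fisher test reproduces the recurrence enrichment contrast", {
  # 65/206 vs 4/65 recurrent samples between the two B-ALL-like clusters
  res <- fisher_exact_2x2(65, 141, 4, 61)
  expect_equal(signif(res$p_value, 2), 1.4e-5)
  expect_equal(res$odds_ratio, (65 * 61) / (141 * 4))
})

test_that("fisher test handles degenerate and fully separated tables", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1)
  res <- fisher_exact_2x2(5, 0, 0, 5)
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12) # 2 of the 6 tables
  expect_equal(res$odds_ratio, Inf)
  expect_warning(z <- fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_equal(z$p_value, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "integers")
})

test_that("fisher p equals hypergeometric enumeration (all tables, n <= 16)", {
  for (n in 2:16) {
    for (a in 0:n) {
      for (b in 0:(n - a)) {
        for (cc in 0:(n - a - b)) {
          d <- n - a - b - cc
          m <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
          if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
          expect_equal(
            fisher_exact_2x2(a, b, cc, d)$p_value,
            oracle_fisher_p(a, b, cc, d),
            tolerance = 1e-7,
            info = paste(a, b, cc, d)
          )
        }
      }
    }
  }
})

test_that("fisher p equals enumeration on random tables up to n = 30", {
  withr::with_seed(81, {
    for (rep in 1:300) {
      n <- sample(17:30, 1)
      cuts <- sort(sample(0:n, 3, replace = TRUE))
      cells <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
      m <- matrix(cells, 2, byrow = TRUE)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      expect_equal(
        fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value,
        oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
        tolerance = 1e-7
      )
    }
  })
})

test_that("fisher p is invariant under simultaneous row and column swaps", {
  withr::with_seed(82, {
    for (rep in 1:25) {
      cells <- sample(0:12, 4, replace = TRUE)
      m <- matrix(cells, 2, byrow = TRUE)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      p <- fisher_exact_2x2(m)$p_value
      expect_equal(fisher_exact_2x2(m[2:1, 2:1])$p_value, p, tolerance = 1e-12)
      expect_equal(fisher_exact_2x2(t(m))$p_value, p, tolerance = 1e-12)
    }
  })
})

test_that("KM median is the earliest time the estimate reaches 0.5", {
  sv <- tibble::tibble(time_years = 1:5, event = 1L)
  km <- km_estimate(sv)
  expect_equal(km$median, 3) # S(3) = 0.4 <= 0.5, S(2) = 0.6
  expect_true(km$median_reached)

  censored <- tibble::tibble(time_years = 1:5, event = 0L)
  km0 <- km_estimate(censored)
  expect_false(km0$median_reached)
  expect_true(is.na(km0$median))
  expect_error(km_estimate(tibble::tibble(time_years = c(1, -1), event = 1L)), "positive")
})

test_that("KM equals the empirical survival function without censoring", {
  withr::with_seed(83, sv <- tibble::tibble(time_years = rexp(40, 0.3), event = 1L))
  km <- km_estimate(sv)
  orc <- oracle_km(sv$time_years, sv$event)
  expect_equal(km$curve$time, orc$time)
  expect_equal(km$curve$estimate, orc$surv, tolerance = 1e-12)
  # and the product-limit estimate equals the empirical tail fraction
  emp <- vapply(orc$time, function(t) mean(sv$time_years > t), numeric(1))
  expect_equal(km$curve$estimate, emp, tolerance = 1e-12)
})

test_that("KM matches the product-limit oracle under censoring", {
  withr::with_seed(84, sv <- tibble::tibble(
    time_years = rexp(60, 0.4), event = rbinom(60, 1, 0.6)
  ))
  km <- km_estimate(sv)
  orc <- oracle_km(sv$time_years, sv$event)
  est_at <- km$curve$estimate[match(orc$time, km$curve$time)]
  expect_equal(est_at, orc$surv, tolerance = 1e-12)
})

test_that("log-rank is null on identical groups and errors with no events", {
  sv <- tibble::tibble(
    time_years = rep(c(1, 2, 3, 4), 2),
    event = rep(c(1L, 0L, 1L, 1L), 2),
    grp = rep(c("a", "b"), each = 4)
  )
  lr <- logrank_test(sv, "grp")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  sv0 <- tibble::tibble(time_years = 1:4, event = 0L, grp = c("a", "a", "b", "b"))
  expect_error(logrank_test(sv0, "grp"), "events")
})

test_that("cox score test on a binary covariate equals the log-rank chi-square", {
  withr::with_seed(85, {
    sv <- tibble::tibble(
      time_years = c(rexp(80, 0.5), rexp(80, 0.2)),
      event = 1L,
      grp = rep(c(1, 0), each = 80)
    )
  })
  lr <- logrank_test(sv, "grp")
  fit <- cox_ph(sv, "grp")
  sc <- summary(fit$fit)$sctest[["test"]]
  expect_equal(sc, lr$statistic, tolerance = 1e-6)
})

test_that("cox recovers a planted log hazard ratio without bias", {
  ests <- ses <- numeric(20)
  for (s in 1:20) {
    withr::with_seed(500 + s, {
      x <- rep(c(1, 0), each = 200)
      sv <- tibble::tibble(
        time_years = rexp(400, rate = 0.2 * exp(1.0 * x)),
        event = 1L, x = x
      )
    })
    fit <- cox_ph(sv, "x")
    ests[s] <- fit$coefficients$estimate
    ses[s] <- fit$coefficients$std_error
  }
  expect_true(all(abs(ests - 1.0) <= 3 * ses))
  expect_lt(abs(mean(ests) - 1.0), 0.1)
})

test_that("cox is well calibrated under the null", {
  cover <- vapply(1:20, function(s) {
    withr::with_seed(700 + s, {
      sv <- tibble::tibble(
        time_years = rexp(150, 0.3), event = 1L, x = rnorm(150)
      )
    })
    fit <- cox_ph(sv, "x")
    abs(fit$coefficients$estimate) < 3 * fit$coefficients$std_error
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("cox rejects constant covariates and flags separation", {
  sv <- tibble::tibble(time_years = rexp(20, 1), event = 1L, x = 1)
  expect_error(cox_ph(sv, "x"), "constant")
  # perfectly separating covariate: monotone likelihood, flagged not crashed
  sep <- tibble::tibble(
    time_years = c(1:10, 101:110), event = 1L, x = rep(c(1, 0), each = 10)
  )
  fit <- cox_ph(sep, "x")
  expect_false(fit$converged)
})

test_that("clinical report flags a subtype-linked marker (20 seeds)", {
  hits <- vapply(1:20, function(s) {
    labels <- tibble::tibble(
      sample = sprintf("s%03d", 1:210),
      cluster = rep(c("cluster_1", "cluster_2"), c(150, 60))
    )
    withr::with_seed(900 + s, {
      clinical <- tibble::tibble(
        sample_id = labels$sample,
        marker = rbinom(210, 1, ifelse(labels$cluster == "cluster_1", 0.6, 0.1))
      )
    })
    rep <- cluster_clinical_report(labels, clinical)
    rep$tests$p_value[rep$tests$variable == "marker"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("clinical report is calibrated when clusters are a label permutation", {
  # 40 independent null covariates across 5 seeds: about 5% flagged at 0.05
  rates <- vapply(1:5, function(s) {
    withr::with_seed(950 + s, {
      labels <- tibble::tibble(
        sample = sprintf("s%03d", 1:200),
        cluster = sample(rep(c("cluster_1", "cluster_2"), each = 100))
      )
      clinical <- tibble::tibble(sample_id = labels$sample)
      for (j in 1:40) clinical[[paste0("v", j)]] <- rnorm(200)
    })
    rep <- cluster_clinical_report(labels, clinical)
    mean(rep$tests$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(rates), 0.12)
})

test_that("clinical report keeps honest denominators and skips flat covariates", {
  labels <- tibble::tibble(
    sample = sprintf("s%02d", 1:40),
    cluster = rep(c("cluster_1", "cluster_2"), each = 20)
  )
  withr::with_seed(99, {
    clinical <- tibble::tibble(
      sample_id = labels$sample,
      marker = c(rbinom(20, 1, 0.7), rbinom(20, 1, 0.2)),
      age = rnorm(40, 8, 3),
      flat = 1,
      time_years = rexp(40, 0.3),
      event = rbinom(40, 1, 0.7)
    )
    clinical$marker[c(3, 25, 30)] <- NA # missing values, pairwise complete
  })
  rep <- cluster_clinical_report(labels, clinical)
  mk <- rep$tests[rep$tests$variable == "marker", ]
  expect_equal(mk$n_1, 19L)
  expect_equal(mk$n_2, 18L)
  expect_equal(rep$tests$type[rep$tests$variable == "flat"], "skipped")
  expect_equal(rep$tests$type[rep$tests$variable == "age"], "continuous")
  expect_s3_class(rep$cox, "rp_cox")
  expect_equal(nrow(rep$km), 2)

  # dropping the survival columns skips the survival battery
  rep2 <- cluster_clinical_report(labels, clinical[, 1:4])
  expect_null(rep2$km)
  expect_null(rep2$logrank)

  dir <- withr::local_tempdir()
  write_clinical_report(rep, dir)
  expect_true(file.exists(file.path(dir, "clinical_tests.tsv")))
  js <- jsonlite::read_json(file.path(dir, "clinical_report.json"))
  expect_equal(js$clusters_compared[[1]], "cluster_1")
})
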