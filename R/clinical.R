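# Cluster-versus-clinical statistics: two-sided Fisher's exact tests for
# categorical covariates, Wilcoxon rank-sum tests for continuous ones,
# Kaplan-Meier estimates with explicit "not reached" medians, log-rank tests
# and multivariate Cox proportional-hazards fits (Efron ties).

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value follows the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a small
#' relative tolerance for floating-point ties). The odds ratio is the sample
#' odds ratio `(a*d)/(b*c)`, with `Inf`/0 conventions for zero cells.
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows = groups, columns =
#'   outcome yes/no; alternatively `a` may be a 2x2 matrix.
#' @return A one-row tibble `p_value`, `odds_ratio`, `a`, `b`, `c`, `d`.
#' @examples
#' fisher_exact_2x2(65, 141, 4, 61) # recurrence enrichment contrast
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("all cell counts must be nonnegative")
  if (any(cells != round(cells))) abort("cell counts must be integers")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warn("a margin of the 2x2 table is zero; p-value defined as 1")
    p <- 1
  } else {
    p <- fisher.test(m)$p.value
  }
  tibble(p_value = p, odds_ratio = or, a = a, b = b, c = c, d = d)
}

#' Kaplan-Meier estimate with explicit not-reached median
#'
#' Product-limit estimator of the survival function. The median is the
#' earliest time at which the estimate drops to 0.5 or below; when the
#' estimate never reaches 0.5 the median is *not reached*, reported as an
#' explicit flag (never a numeric placeholder).
#'
#' @param data A data frame with time and event columns.
#' @param time,event Column names (default `"time_years"`, `"event"`).
#' @return An object of class `rp_km`: list with `curve` (tibble `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate`), `median` (`NA` when not
#'   reached), `median_reached`, `n`, `events`.
#' @export
km_estimate <- function(data, time = "time_years", event = "event") {
  tt <- data[[time]]
  ev <- data[[event]]
  if (!length(tt)) abort("no samples")
  if (any(tt <= 0)) abort("survival times must be positive")
  fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(
    curve = tibble(
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, estimate = fit$surv
    ),
    median = if (is.na(med)) NA_real_ else med,
    median_reached = !is.na(med),
    n = sum(fit$n), events = sum(ev)
  ), class = "rp_km")
}

#' @export
print.rp_km <- function(x, ...) {
  med <- if (x$median_reached) sprintf("%.3g", x$median) else "not reached"
  cat(sprintf("<rp_km> n = %d, events = %d, median = %s\n", x$n, x$events, med))
  invisible(x)
}

#' @method tidy rp_km
#' @export
tidy.rp_km <- function(x, ...) x$curve

#' @method glance rp_km
#' @export
glance.rp_km <- function(x, ...) {
  tibble(
    n = x$n, events = x$events, median = x$median,
    median_reached = x$median_reached
  )
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic summed over distinct event
#' times, referred to a chi-square with 1 degree of freedom.
#'
#' @param data A data frame with time, event and group columns.
#' @param group Column name holding the two group labels.
#' @inheritParams km_estimate
#' @return A one-row tibble `statistic`, `df`, `p_value`, `n_1`, `n_2`.
#' @export
logrank_test <- function(data, group, time = "time_years", event = "event") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("logrank_test compares exactly two groups")
  if (sum(data[[event]]) == 0) abort("no events in either group")
  if (any(data[[time]] <= 0)) abort("survival times must be positive")
  sd <- survival::survdiff(survival::Surv(data[[time]], data[[event]]) ~ g)
  tibble(
    statistic = sd$chisq, df = 1L,
    p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n_1 = sd$n[1], n_2 = sd$n[2]
  )
}

#' Multivariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron tie handling. Monotone
#' likelihood (e.g. a covariate perfectly separating events) is flagged in
#' the result rather than raised; constant covariates are an error naming
#' the offender.
#'
#' @param data A data frame with time, event and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @inheritParams km_estimate
#' @return An object of class `rp_cox`: list with `coefficients` (tibble
#'   `term`, `estimate` (log hazard ratio), `std_error`, `statistic`,
#'   `p_value`), `converged`, `n`, `events`, and the underlying `fit`.
#' @export
cox_ph <- function(data, covariates, time = "time_years", event = "event") {
  if (sum(data[[event]]) < 2) abort("need at least 2 events")
  if (any(data[[time]] <= 0)) abort("survival times must be positive")
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) abort(paste0("covariate '", cv, "' not found"))
    if (length(unique(v[!is.na(v)])) < 2) {
      abort(paste0("covariate '", cv, "' is constant"))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(", time, ",", event, ") ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = tibble(
      term = rownames(sm),
      estimate = sm[, "coef"], std_error = sm[, "se(coef)"],
      statistic = sm[, "z"], p_value = sm[, "Pr(>|z|)"]
    ),
    converged = !flagged && fit$iter < fit$control$iter.max,
    n = fit$n, events = fit$nevent, fit = fit
  ), class = "rp_cox")
}

#' @export
print.rp_cox <- function(x, ...) {
  cat(sprintf(
    "<rp_cox> n = %d, events = %d%s\n",
    x$n, x$events, if (x$converged) "" else " [convergence flagged]"
  ))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy rp_cox
#' @export
tidy.rp_cox <- function(x, ...) x$coefficients

#' @method glance rp_cox
#' @export
glance.rp_cox <- function(x, ...) {
  tibble(n = x$n, events = x$events, converged = x$converged)
}

#' Cluster-versus-clinical report
#'
#' Runs the full battery for two clusters: for every binary/categorical
#' covariate a two-sided Fisher's exact test (multi-level covariates are
#' collapsed level-vs-rest into 2x2 tables), for every continuous covariate a
#' two-sided Wilcoxon rank-sum test, and per survival endpoint Kaplan-Meier
#' medians per cluster, a log-rank test, and a Cox model of cluster
#' membership plus any requested adjustment covariates. Missing values are
#' handled pairwise-complete and the denominators actually used are always
#' reported. Single-level covariates are skipped with a note.
#'
#' @param clusters An `rp_clusters` tibble; the report compares
#'   `compare` (default: the two largest clusters).
#' @param clinical A data frame with a `sample_id` (or `sample`) column,
#'   optional survival columns, and covariates.
#' @param covariates Covariate column names; default every column other than
#'   identifiers and survival columns.
#' @param compare Length-2 character vector of cluster labels to contrast.
#' @param time,event Survival column names; endpoint skipped when absent.
#' @param cox_covariates Extra covariates to adjust the Cox model for
#'   (default none: cluster membership only).
#' @return A list of class `rp_clinical_report`: `tests` (tibble `variable`,
#'   `type`, `statistic`, `p_value`, `n_1`, `n_2`, `note`), `km` (per-cluster
#'   glance tibble), `logrank`, `cox` (or `NULL`), `clusters_compared`.
#' @export
cluster_clinical_report <- function(clusters, clinical, covariates = NULL,
                                    compare = NULL, time = "time_years",
                                    event = "event", cox_covariates = character()) {
  id_col <- if ("sample_id" %in% names(clinical)) "sample_id" else "sample"
  if (!id_col %in% names(clinical)) abort("clinical table needs a sample_id column")
  sizes <- sort(table(clusters$cluster[clusters$cluster != "unassigned"]), decreasing = TRUE)
  if (length(sizes) < 2) abort("need at least 2 clusters with samples")
  compare <- compare %||% names(sizes)[1:2]
  df <- clusters |>
    filter(.data$cluster %in% compare) |>
    left_join(clinical, by = setNames(id_col, "sample"))
  df$cluster <- factor(df$cluster, levels = compare)
  covariates <- covariates %||% setdiff(
    names(clinical), c(id_col, time, event, "true_subtype")
  )

  tests <- purrr::map_dfr(covariates, function(cv) {
    v <- df[[cv]]
    ok <- !is.na(v)
    lv <- unique(v[ok])
    n1 <- sum(ok & df$cluster == compare[1])
    n2 <- sum(ok & df$cluster == compare[2])
    if (length(lv) < 2) {
      return(tibble(
        variable = cv, type = "skipped", statistic = NA_real_,
        p_value = NA_real_, n_1 = n1, n_2 = n2, note = "single level"
      ))
    }
    if (is.numeric(v) && length(lv) > 2) {
      wt <- wilcoxon_rank_sum(
        v[ok & df$cluster == compare[1]],
        v[ok & df$cluster == compare[2]]
      )
      tibble(
        variable = cv, type = "continuous", statistic = wt$statistic,
        p_value = wt$p_value, n_1 = n1, n_2 = n2, note = "wilcoxon"
      )
    } else {
      lv <- sort(as.character(lv))
      purrr::map_dfr(if (length(lv) == 2) lv[2] else lv, function(level) {
        aa <- sum(ok & df$cluster == compare[1] & as.character(v) == level)
        bb <- n1 - aa
        cc <- sum(ok & df$cluster == compare[2] & as.character(v) == level)
        dd <- n2 - cc
        ft <- fisher_exact_2x2(aa, bb, cc, dd)
        tibble(
          variable = if (length(lv) == 2) cv else paste0(cv, "=", level),
          type = "categorical", statistic = ft$odds_ratio,
          p_value = ft$p_value, n_1 = n1, n_2 = n2, note = "fisher"
        )
      })
    }
  })

  km <- logrank <- cox <- NULL
  if (all(c(time, event) %in% names(df)) && any(!is.na(df[[time]]))) {
    sdf <- df[!is.na(df[[time]]) & !is.na(df[[event]]), ]
    km <- purrr::map_dfr(compare, function(cl) {
      g <- glance(km_estimate(sdf[sdf$cluster == cl, ], time, event))
      mutate(g, cluster = cl, .before = 1)
    })
    logrank <- logrank_test(sdf, "cluster", time, event)
    sdf$rp_cluster <- as.integer(sdf$cluster == compare[1])
    cox <- cox_ph(sdf, c("rp_cluster", cox_covariates), time, event)
  }

  structure(list(
    tests = tests, km = km, logrank = logrank, cox = cox,
    clusters_compared = compare
  ), class = "rp_clinical_report")
}

#' @export
print.rp_clinical_report <- function(x, ...) {
  cat(sprintf(
    "<rp_clinical_report> %s vs %s\n",
    x$clusters_compared[1], x$clusters_compared[2]
  ))
  print(x$tests)
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank p = %.3g\n", x$logrank$p_value))
  }
  invisible(x)
}

#' Serialize a clinical report
#'
#' Writes the flat test table as TSV and the full report (including KM
#' medians with a `"not reached"` sentinel) as JSON.
#'
#' @param report An `rp_clinical_report`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_clinical_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "clinical_tests.tsv")
  readr::write_tsv(report$tests, tsv, progress = FALSE)
  km <- report$km
  if (!is.null(km)) {
    km$median <- ifelse(km$median_reached, as.character(km$median), "not reached")
  }
  obj <- list(
    clusters_compared = report$clusters_compared,
    tests = report$tests,
    km = km,
    logrank = report$logrank,
    cox = if (!is.null(report$cox)) {
      list(coefficients = report$cox$coefficients, converged = report$cox$converged)
    }
  )
  js <- file.path(dir, "clinical_report.json")
  jsonlite::write_json(obj, js, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(c(tsv, js))
}
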