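# The six structural equations of the hierarchical path model:
# respiration -> physiology -> CSF flow, CSF flow variables inter-related.
path_model_equations <- function() {
  list(
    SSS = c("Dia", "Chest", "Lung", "Inhale"),
    HR = c("Dia", "Chest", "Lung", "SSS", "Inhale"),
    MaxFlow = c("HR", "SSS", "MeanPV"),
    MeanPV = c("MaxFlow", "HR", "SSS"),
    Dis = c("MaxFlow", "MeanPV"),
    NET = c("Dis", "MeanPV", "MaxFlow")
  )
}

path_model_variables <- function() {
  unique(c(names(path_model_equations()),
           unlist(path_model_equations(), use.names = FALSE)))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column `j` on the remaining
#' columns. Perfect collinearity is reported as `Inf` rather than an error,
#' matching its use as a screening statistic.
#'
#' @param data A data frame.
#' @param columns Character vector of column names to screen (default: all
#'   numeric columns).
#' @return Tibble with `term`, `r_squared`, `vif`, sorted as given.
#' @export
compute_vif <- function(data, columns = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(length(columns) >= 2, all(columns %in% names(data)))
  if (nrow(data) < length(columns) + 2) {
    abort("Need at least `length(columns) + 2` rows to compute VIFs.")
  }
  X <- as.matrix(data[, columns])
  if (any(apply(X, 2, stats::sd) == 0)) {
    abort(paste0("Constant column(s): ",
                 paste(columns[apply(X, 2, stats::sd) == 0], collapse = ", "),
                 "."))
  }
  out <- purrr::map(seq_along(columns), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared) # perfect fits allowed
    vif <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    tibble(term = columns[j], r_squared = r2, vif = vif)
  })
  dplyr::bind_rows(out)
}

#' Fit the hierarchical path model
#'
#' Fits the six structural equations by ordinary least squares on z-scored
#' variables, so coefficients are standardized betas; paths with two-sided
#' `p < alpha` are retained in the causal diagram. When a `region` column is
#' present the model is fitted separately per region.
#'
#' @param data Feature table with columns `Dia`, `Chest`, `Lung`, `Inhale`,
#'   `SSS`, `HR`, `MeanPV`, `MaxFlow`, `Dis`, `NET` (one row per observation,
#'   participant x breathing condition), optionally `region`.
#' @param alpha Path retention threshold (default 0.05, two-sided).
#' @param standardize Z-score all variables before fitting (default TRUE),
#'   making the coefficients standardized betas; set FALSE to fit on the
#'   variables' own scales.
#' @return A `path_model_fit`: list with `paths` (tibble `region`,
#'   `response`, `term`, `beta`, `se`, `p_value`, `retained`), `fits`
#'   (per-region list of `lm` objects), `alpha`, `n`.
#' @export
fit_path_model <- function(data, alpha = 0.05, standardize = TRUE) {
  stopifnot(is.data.frame(data))
  vars <- path_model_variables()
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("Feature table is missing: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (anyNA(data[, vars])) abort("Modeled columns contain missing values.")
  regions <- if ("region" %in% names(data)) unique(data$region) else "all"
  all_paths <- list()
  all_fits <- list()
  for (rg in regions) {
    df <- if ("region" %in% names(data)) data[data$region == rg, ] else data
    z <- if (standardize) {
      as.data.frame(lapply(df[, vars], function(x) as.numeric(scale(x))))
    } else {
      as.data.frame(df[, vars])
    }
    fits <- purrr::imap(path_model_equations(), function(rhs, lhs) {
      f <- stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
      fit <- lm(f, data = z)
      if (fit$rank < length(rhs) + 1L) {
        dropped <- names(coef(fit))[is.na(coef(fit))]
        abort(paste0("Rank-deficient design in equation for ", lhs,
                     "; collinear term(s): ",
                     paste(dropped, collapse = ", "), "."))
      }
      fit
    })
    paths <- purrr::imap(fits, function(fit, lhs) {
      sm <- summary(fit)$coefficients
      terms <- rownames(sm)[rownames(sm) != "(Intercept)"]
      tibble(region = rg, response = lhs, term = terms,
             beta = sm[terms, "Estimate"], se = sm[terms, "Std. Error"],
             p_value = sm[terms, "Pr(>|t|)"])
    })
    paths <- dplyr::bind_rows(paths) %>%
      dplyr::mutate(retained = .data$p_value < alpha)
    all_paths[[rg]] <- paths
    all_fits[[rg]] <- fits
  }
  structure(list(paths = dplyr::bind_rows(all_paths), fits = all_fits,
                 alpha = alpha, n = nrow(data)),
            class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("<path_model_fit> %d observations, alpha = %g\n", x$n, x$alpha))
  ret <- x$paths[x$paths$retained, ]
  if (nrow(ret) == 0) {
    cat("  no retained paths\n")
  } else {
    for (i in seq_len(nrow(ret))) {
      cat(sprintf("  [%s] %s -> %s  beta = %+.3f (p = %.4g)\n",
                  ret$region[i], ret$term[i], ret$response[i],
                  ret$beta[i], ret$p_value[i]))
    }
  }
  invisible(x)
}

#' @describeIn fit_path_model Tidy the fitted paths (one row per path).
#' @param x,object A `path_model_fit`.
#' @param ... Unused.
#' @export
tidy.path_model_fit <- function(x, ...) x$paths

#' @describeIn fit_path_model Per-equation model summary (R-squared, n).
#' @export
glance.path_model_fit <- function(x, ...) {
  purrr::imap(x$fits, function(fits, rg) {
    purrr::imap(fits, function(fit, lhs) {
      sm <- summary(fit)
      tibble(region = rg, response = lhs, r_squared = sm$r.squared,
             adj_r_squared = sm$adj.r.squared,
             n = length(stats::fitted(fit)))
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
}

#' Regress respiratory rate out of a set of metrics
#'
#' Each named metric is replaced by the residuals of an OLS fit on the
#' respiratory-rate column, leaving the RR-independent variance; residuals
#' are exactly uncorrelated with RR.
#'
#' @param data A data frame.
#' @param metrics Character vector of columns to residualize.
#' @param rr_col Name of the respiratory-rate column (default `"RR"`).
#' @return The data frame with the metric columns replaced by residuals.
#' @export
residualize_rr <- function(data, metrics, rr_col = "RR") {
  stopifnot(is.data.frame(data), rr_col %in% names(data),
            all(metrics %in% names(data)))
  if (stats::sd(data[[rr_col]]) == 0) {
    abort("Respiratory rate is constant; residualization is undefined.")
  }
  for (m in metrics) {
    data[[m]] <- unname(resid(lm(data[[m]] ~ data[[rr_col]])))
  }
  data
}

#' Two-group comparison with t-based confidence intervals
#'
#' Two-sided Student's t-test (pooled variance by default, Welch optional,
#' paired for within-subject contrasts) plus per-group mean and t-based 95%
#' confidence interval.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping vector aligned with `values`.
#' @param paired Paired test (requires matched ordering within groups).
#' @param welch Use the Welch (unequal-variance) statistic.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `ci_lo_a`, `ci_hi_a`, `ci_lo_b`, `ci_hi_b`.
#' @export
group_compare <- function(values, labels, paired = FALSE, welch = FALSE,
                          conf_level = 0.95) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  a <- values[labels == levels(labels)[1]]
  b <- values[labels == levels(labels)[2]]
  if (length(a) < 2 || length(b) < 2) abort("Need >= 2 values per group.")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && !paired) {
    if (mean(a) == mean(b)) {
      # identical degenerate groups: no evidence of difference
      tt <- list(statistic = c(t = 0), parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      abort("Zero variance in both groups.")
    }
  } else {
    tt <- t.test(a, b, paired = paired, var.equal = !welch)
  }
  ci <- function(x) {
    m <- mean(x)
    half <- qt(1 - (1 - conf_level) / 2, length(x) - 1) *
      stats::sd(x) / sqrt(length(x))
    c(m - half, m + half)
  }
  ca <- ci(a); cb <- ci(b)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
         ci_lo_a = ca[1], ci_hi_a = ca[2], ci_lo_b = cb[1], ci_hi_b = cb[2])
}

#' Median split into High and Low groups
#'
#' Values strictly above the median are labelled `High`; values at or below
#' the median are labelled `Low` (ties at the median go to `Low`). A warning
#' is raised when all values are equal.
#'
#' @param values Numeric vector (length >= 2).
#' @return Factor with levels `High`, `Low`.
#' @export
median_split <- function(values) {
  stopifnot(length(values) >= 2)
  if (length(unique(values)) == 1) {
    warn("All values equal: everything assigned to Low.")
  }
  med <- median(values)
  factor(ifelse(values > med, "High", "Low"), levels = c("High", "Low"))
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return One-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance: correlation undefined.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = length(x))
}
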