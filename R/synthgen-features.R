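#' Default standardized path coefficients for feature-table simulation
#'
#' A recursive (acyclic) truth for the six structural equations: moderate
#' respiratory-to-physiological and physiological-to-CSF effects, with the
#' reciprocal direct paths between `MeanPV` and `MaxFlow` set to zero.
#' Per-equation ordinary least squares is consistent for recursive systems
#' with independent disturbances; a genuinely simultaneous reciprocal pair is
#' not identifiable that way, which is why the default truth routes their
#' association through shared upstream predictors.
#'
#' @return Named list of named coefficient vectors, one per equation.
#' @export
default_path_coefficients <- function() {
  list(
    SSS = c(Dia = 0.45, Chest = 0.15, Lung = 0, Inhale = 0.25),
    HR = c(Dia = 0, Chest = 0, Lung = 0, SSS = 0.30, Inhale = 0.35),
    MaxFlow = c(HR = 0.25, SSS = 0.35, MeanPV = 0),
    MeanPV = c(MaxFlow = 0, HR = 0.30, SSS = 0.30),
    Dis = c(MaxFlow = 0.50, MeanPV = 0.20),
    NET = c(Dis = 0.55, MeanPV = 0, MaxFlow = 0.20)
  )
}

# Natural scales (mean, sd) used to dress the standardized variables.
feature_scales <- function() {
  list(
    Inhale = c(5, 2.5), Lung = c(0.30, 0.15), Chest = c(0.030, 0.015),
    Dia = c(0.30, 0.15), SSS = c(0.15, 0.08), HR = c(3, 1.5),
    MeanPV = c(0.9, 0.3), MaxFlow = c(0.5, 0.2), Dis = c(0.30, 0.15),
    NET = c(8, 5)
  )
}

#' Simulate a feature table from the structural path equations
#'
#' Generates one observation per (participant x breathing condition) row.
#' Exogenous respiratory features (`Dia`, `Chest`, `Lung`, `Inhale`) are
#' drawn from a correlated standard normal (pairwise correlation
#' `exo_cor`); each endogenous variable is its equation's linear combination
#' of standardized predictors plus an independent Gaussian disturbance whose
#' variance tops the variable up to unit population variance (scaled by
#' `noise_scale`). Generation is recursive in the order `MeanPV` before
#' `MaxFlow` unless the supplied coefficients make the pair simultaneous, in
#' which case the implied 2x2 linear system is solved.
#'
#' @param n Number of observations.
#' @param coefs Standardized coefficients, as [default_path_coefficients()].
#' @param exo_cor Pairwise correlation among exogenous features.
#' @param noise_scale Multiplier on the disturbance SDs: 1 gives unit
#'   population variances. Either a single number or a named vector/list with
#'   one entry per endogenous variable (`SSS`, `HR`, `MaxFlow`, `MeanPV`,
#'   `Dis`, `NET`). Setting a single equation's scale to 0 makes that
#'   response an exact linear combination of its predictors (so its
#'   coefficients are recovered to machine precision); setting all of them
#'   to 0 makes the system deterministic and the downstream designs exactly
#'   collinear, which [fit_path_model()] reports as rank deficiency.
#' @param seed Integer seed.
#' @param natural_scale Dress variables in plausible units (default FALSE:
#'   return standardized variables).
#' @return Tibble with the ten model variables, `RR` (breaths/min,
#'   anticorrelated with `Inhale`), `group`, `condition`, `region` columns,
#'   and attribute `truth` (the coefficient list actually used).
#' @export
sim_feature_table <- function(n = 45, coefs = default_path_coefficients(),
                              exo_cor = 0.4, noise_scale = 1, seed = 1L,
                              natural_scale = FALSE) {
  stopifnot(n >= 10, all(unlist(noise_scale) >= 0))
  ns_for <- function(lhs) {
    if (length(noise_scale) == 1 && is.null(names(noise_scale))) {
      as.numeric(noise_scale)
    } else {
      as.numeric(noise_scale[[lhs]])
    }
  }
  set.seed(as.integer(seed))
  exo <- c("Dia", "Chest", "Lung", "Inhale")
  S <- matrix(exo_cor, 4, 4); diag(S) <- 1
  Z <- matrix(rnorm(n * 4), n, 4) %*% chol(S)
  colnames(Z) <- exo
  df <- as.data.frame(Z)
  # population covariance ledger for disturbance-variance bookkeeping
  cov_pop <- S
  rownames(cov_pop) <- colnames(cov_pop) <- exo

  add_var <- function(df, cov_pop, lhs, beta) {
    preds <- names(beta)
    Sxx <- cov_pop[preds, preds, drop = FALSE]
    explained <- as.numeric(t(beta) %*% Sxx %*% beta)
    if (explained >= 1) {
      abort(sprintf("Coefficients for %s imply R^2 >= 1 (%.2f).",
                    lhs, explained))
    }
    sd_e <- sqrt(1 - explained) * ns_for(lhs)
    y <- as.matrix(df[, preds]) %*% beta + rnorm(nrow(df), sd = sd_e)
    df[[lhs]] <- as.numeric(y)
    cov_y <- cov_pop[, preds, drop = FALSE] %*% beta
    cov_pop <- cbind(cov_pop, cov_y)
    cov_pop <- rbind(cov_pop, c(as.numeric(cov_y),
                                explained + (1 - explained) * ns_for(lhs)^2))
    rownames(cov_pop)[nrow(cov_pop)] <- lhs
    colnames(cov_pop)[ncol(cov_pop)] <- lhs
    list(df = df, cov = cov_pop)
  }

  simultaneous <- coefs$MaxFlow[["MeanPV"]] != 0 && coefs$MeanPV[["MaxFlow"]] != 0
  step <- add_var(df, cov_pop, "SSS", coefs$SSS)
  step <- add_var(step$df, step$cov, "HR", coefs$HR)
  if (!simultaneous) {
    # recursive order: MeanPV first (its MaxFlow coefficient must be zero
    # unless MaxFlow's MeanPV coefficient is zero, handled below)
    if (coefs$MeanPV[["MaxFlow"]] == 0) {
      step <- add_var(step$df, step$cov, "MeanPV",
                      coefs$MeanPV[c("HR", "SSS")])
      step <- add_var(step$df, step$cov, "MaxFlow", coefs$MaxFlow)
    } else {
      step <- add_var(step$df, step$cov, "MaxFlow",
                      coefs$MaxFlow[c("HR", "SSS")])
      step <- add_var(step$df, step$cov, "MeanPV", coefs$MeanPV)
    }
  } else {
    # solve the simultaneous 2x2 block: x = B z + e, x = (MaxFlow, MeanPV)
    b3 <- coefs$MaxFlow[["MeanPV"]]; c1 <- coefs$MeanPV[["MaxFlow"]]
    if (abs(1 - b3 * c1) < 1e-8) abort("Reciprocal pair is singular.")
    dfx <- step$df
    zH <- dfx$HR; zS <- dfx$SSS
    e1 <- rnorm(n, sd = 0.5 * ns_for("MaxFlow"))
    e2 <- rnorm(n, sd = 0.5 * ns_for("MeanPV"))
    r1 <- coefs$MaxFlow[["HR"]] * zH + coefs$MaxFlow[["SSS"]] * zS + e1
    r2 <- coefs$MeanPV[["HR"]] * zH + coefs$MeanPV[["SSS"]] * zS + e2
    det <- 1 - b3 * c1
    dfx$MaxFlow <- (r1 + b3 * r2) / det
    dfx$MeanPV <- (r2 + c1 * r1) / det
    step$df <- dfx
    step$cov <- stats::cov(as.matrix(dfx)) # empirical fallback for downstream
  }
  step <- add_var(step$df, step$cov, "Dis", coefs$Dis)
  step <- add_var(step$df, step$cov, "NET", coefs$NET)
  df <- step$df

  # respiratory rate: anticorrelated with inhale length
  df$RR <- 10 - 2 * df$Inhale +
    rnorm(n, sd = 1.5 * max(mean(unlist(noise_scale)), 0.1))
  df$group <- rep(c("T", "NT"), length.out = n)
  df$condition <- rep(c("RB", "DB"), each = ceiling(n / 2))[seq_len(n)]
  df$region <- "FM"
  if (natural_scale) {
    sc <- feature_scales()
    for (v in names(sc)) df[[v]] <- sc[[v]][1] + sc[[v]][2] * df[[v]]
  }
  out <- as_tibble(df)
  attr(out, "truth") <- coefs
  # population-standardized truth: beta * sd(x) / sd(y) from the covariance
  # ledger (equal to `coefs` when every disturbance scale is 1)
  v <- diag(step$cov)
  attr(out, "truth_std") <- purrr::imap(coefs, function(beta, lhs) {
    beta * sqrt(v[names(beta)] / v[[lhs]])
  })
  out
}
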