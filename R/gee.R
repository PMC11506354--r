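#' Per-event reaction-time table
#'
#' Sums observed minutes over vessel-present blocks by (event, behavioral
#' state, reaction) for the three reaction categories POS/NEU/NEG, the
#' input of the clustered reaction-time models. Combinations with zero
#' observed time are absent (the gamma family has no mass at 0), and the
#' factors carry the modeling reference levels: reaction `NEU`, behavior
#' `TRA`.
#'
#' @param ev An `event_set` (typically after [exclude_rare_states()]).
#' @return Data frame `event_id`, `behavior`, `reaction`, `time_min`, one
#'   row per observed combination; empty (with a warning) when no
#'   vessel-present blocks exist.
#' @export
reaction_time_table <- function(ev) {
  stopifnot(inherits(ev, "event_set"))
  blocks <- ev$blocks[ev$blocks$vessel_present, , drop = FALSE]
  beh_levels <- c("TRA", setdiff(behavior_states(), "TRA"))
  reac_levels <- c("NEU", "POS", "NEG")
  if (nrow(blocks) == 0L) {
    warning("no vessel-present blocks: reaction-time table is empty")
    return(data.frame(event_id = character(0),
                      behavior = factor(character(0), levels = beh_levels),
                      reaction = factor(character(0), levels = reac_levels),
                      time_min = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(duration_min ~ event_id + state + reaction,
                          data = blocks, FUN = sum)
  agg <- agg[agg$duration_min > 0, , drop = FALSE]
  out <- data.frame(
    event_id = agg$event_id,
    behavior = factor(agg$state,
                      levels = intersect(beh_levels, unique(agg$state))),
    reaction = factor(as.character(agg$reaction),
                      levels = intersect(reac_levels,
                                         unique(as.character(agg$reaction)))),
    time_min = agg$duration_min, stringsAsFactors = FALSE)
  out <- out[order(out$event_id, out$behavior, out$reaction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reaction budget: share of vessel-present time per reaction
#'
#' @param rows Reaction-time table from [reaction_time_table()].
#' @return Named numeric vector of percentages (POS, NEU, NEG) summing
#'   to 100.
#' @export
reaction_budget <- function(rows) {
  if (nrow(rows) == 0L) stop("reaction-time table is empty")
  total <- sum(rows$time_min)
  vapply(c("POS", "NEU", "NEG"), function(r)
    100 * sum(rows$time_min[as.character(rows$reaction) == r]) / total,
    numeric(1))
}

gee_formula <- function(model_id) {
  switch(model_id,
         M0 = time_min ~ 1,
         M1 = time_min ~ reaction,
         M2 = time_min ~ reaction + behavior,
         M3 = time_min ~ reaction * behavior,
         stop("unknown model id: ", model_id))
}

#' Fit a gamma GEE to clustered reaction times
#'
#' Fits a marginal gamma-family regression of time spent per reaction (and
#' optionally behavior) with generalized estimating equations, clustering
#' on the sighting event. The model suite follows the conventional nested
#' triple: `M1` time ~ reaction, `M2` adds the behavioral state, `M3` adds
#' their interaction; reference levels are reaction `NEU` and behavior
#' `TRA`.
#'
#' Estimation is Fisher scoring on the estimating equations
#' \eqn{\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0} with gamma variance
#' \eqn{V(\mu) = \mu^2}, moment estimators of the dispersion and of the
#' exchangeable working-correlation parameter \eqn{\alpha} updated at each
#' step (the Liang-Zeger scheme; \eqn{\alpha} may be negative and is kept
#' above the positive-definiteness bound \eqn{-1/(n_{max}-1)}), and the
#' robust (sandwich) covariance for inference. With the independence
#' working structure and a single observation per cluster the fit
#' coincides with the ordinary gamma GLM.
#'
#' @param rows Reaction-time table ([reaction_time_table()] or
#'   [generate_gee_dataset()] output).
#' @param model_id `"M1"`, `"M2"` or `"M3"` (`"M0"` fits the
#'   intercept-only null model).
#' @param link `"inverse"` (gamma canonical, default) or `"log"`.
#' @param corstr `"exchangeable"` (default) or `"independence"` (fixes
#'   `alpha = 0`).
#' @param tol,max_iter Convergence tolerance on the relative coefficient
#'   change and the iteration cap.
#' @return A `gee_fit`: coefficients, robust SEs and covariance,
#'   `alpha`, `dispersion`, per-coefficient Wald chi-square tests,
#'   cluster/observation counts and convergence information.
#' @seealso [compare_models()]
#' @export
fit_gee <- function(rows, model_id = "M1",
                    link = c("inverse", "log"),
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-10, max_iter = 100L) {
  model_id <- match.arg(model_id, c("M0", "M1", "M2", "M3"))
  link <- match.arg(link)
  corstr <- match.arg(corstr)
  stopifnot(is.data.frame(rows), all(c("event_id", "time_min") %in% names(rows)))
  if (any(rows$time_min <= 0)) stop("times must be positive (gamma support)")

  formula <- gee_formula(model_id)
  needed <- all.vars(formula)[-1L]
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0L) {
    stop("rows lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  mf <- stats::model.frame(formula, data = rows)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  cluster <- as.character(rows$event_id)
  cl_idx <- split(seq_len(n), cluster)
  m <- length(cl_idx)
  if (m < 2L) stop("need at least 2 clusters (events)")
  n_max <- max(lengths(cl_idx))

  linkinv <- switch(link, inverse = function(eta) 1 / eta,
                    log = function(eta) exp(eta))
  mu_eta <- switch(link, inverse = function(eta) -1 / eta^2,
                   log = function(eta) exp(eta))

  # start at the independence GLM solution
  glm_fam <- stats::Gamma(link = link)
  start_fit <- stats::glm.fit(X, y, family = glm_fam)
  beta <- start_fit$coefficients

  alpha <- 0; phi <- 1
  converged <- FALSE
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- linkinv(eta)
    if (any(!is.finite(mu)) || any(mu <= 0)) {
      stop("fitted means left the gamma support at iteration ", iter,
           "; trace of max |delta|: ", paste(signif(trace, 3), collapse = ", "))
    }
    r <- (y - mu) / mu  # Pearson residuals, sqrt(V(mu)) = mu
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; n_pairs <- 0
      for (idx in cl_idx) {
        ni <- length(idx)
        if (ni > 1L) {
          ri <- r[idx]
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          n_pairs <- n_pairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (n_pairs > p) num / ((n_pairs - p) * phi) else 0
      lower <- -1 / (n_max - 1) + 1e-6
      if (alpha < lower) alpha <- lower
      if (alpha > 1 - 1e-6) alpha <- 1 - 1e-6
    }

    M <- matrix(0, p, p)
    U <- numeric(p)
    d <- mu_eta(eta)
    for (idx in cl_idx) {
      ni <- length(idx)
      Di <- X[idx, , drop = FALSE] * d[idx]
      Ai <- mu[idx]  # sqrt of gamma variance
      # R^{-1} for exchangeable: (I - a/(1+(ni-1)a) J) / (1-a)
      if (ni == 1L) {
        VinvD <- Di / Ai^2
        U <- U + as.numeric(crossprod(VinvD, y[idx] - mu[idx]))
        M <- M + crossprod(Di, VinvD)
      } else {
        Ds <- Di / Ai          # A^{-1/2} D
        rs <- (y[idx] - mu[idx]) / Ai
        a <- alpha
        f <- a / (1 + (ni - 1) * a)
        RinvDs <- (Ds - f * matrix(colSums(Ds), ni, p, byrow = TRUE)) / (1 - a)
        Rinvrs <- (rs - f * sum(rs)) / (1 - a)
        U <- U + as.numeric(crossprod(Ds, Rinvrs))
        M <- M + crossprod(Ds, RinvDs)
      }
    }
    delta <- solve(M, U)
    beta <- beta + delta
    step <- max(abs(delta) / pmax(abs(beta), 1e-8))
    trace <- c(trace, step)
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("GEE did not converge in ", max_iter,
         " iterations; trace of max |delta|: ",
         paste(signif(utils::tail(trace, 8), 3), collapse = ", "))
  }

  # final quantities and sandwich covariance at the solution
  eta <- as.numeric(X %*% beta)
  mu <- linkinv(eta)
  d <- mu_eta(eta)
  M <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (idx in cl_idx) {
    ni <- length(idx)
    Di <- X[idx, , drop = FALSE] * d[idx]
    Ai <- mu[idx]
    Ds <- Di / Ai
    rs <- (y[idx] - mu[idx]) / Ai
    if (ni == 1L) {
      RinvDs <- Ds; Rinvrs <- rs
    } else {
      a <- alpha
      f <- a / (1 + (ni - 1) * a)
      RinvDs <- (Ds - f * matrix(colSums(Ds), ni, p, byrow = TRUE)) / (1 - a)
      Rinvrs <- (rs - f * sum(rs)) / (1 - a)
    }
    gi <- as.numeric(crossprod(Ds, Rinvrs))
    M <- M + crossprod(Ds, RinvDs)
    B <- B + tcrossprod(gi)
  }
  Minv <- solve(M)
  vcov_robust <- Minv %*% B %*% Minv
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  robust_se <- sqrt(diag(vcov_robust))
  wald <- (beta / robust_se)^2
  wald_p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)

  structure(list(
    model_id = model_id, formula = formula, link = link, corstr = corstr,
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    robust_se = stats::setNames(robust_se, colnames(X)),
    vcov_robust = vcov_robust,
    naive_vcov = phi * Minv,
    alpha = if (corstr == "exchangeable") alpha else 0,
    dispersion = phi,
    wald = data.frame(term = colnames(X), estimate = as.numeric(beta),
                      robust_se = robust_se, wald_chisq = as.numeric(wald),
                      p_value = as.numeric(wald_p), row.names = NULL,
                      stringsAsFactors = FALSE),
    n_clusters = m, n_obs = n, iterations = iter, converged = converged,
    data_signature = c(n = n, sum_y = sum(y), n_clusters = m)
  ), class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Gamma GEE fit ", x$model_id, " (", deparse(x$formula), ")\n",
      "  link = ", x$link, ", working correlation = ", x$corstr,
      " (alpha = ", signif(x$alpha, 4), "), dispersion = ",
      signif(x$dispersion, 4), "\n",
      "  ", x$n_obs, " rows in ", x$n_clusters, " event clusters\n",
      sep = "")
  tb <- x$wald
  tb$estimate <- signif(tb$estimate, 4)
  tb$robust_se <- signif(tb$robust_se, 4)
  tb$wald_chisq <- signif(tb$wald_chisq, 4)
  tb$p_value <- signif(tb$p_value, 3)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Wald comparison of nested GEE models
#'
#' Tests whether the coefficients present in the larger of two nested GEE
#' fits but absent from the smaller are jointly zero, using the larger
#' model's robust covariance: \eqn{W = b' V_b^{-1} b \sim \chi^2_{df}}
#' with `df` the number of extra coefficients. Both fits must come from
#' the same rows.
#'
#' @param fit_a,fit_b Two `gee_fit` objects with nested designs (in either
#'   order).
#' @return List of class `model_comparison`: `pair`, `df`,
#'   `wald_statistic`, `p_value`, `extra_terms`.
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "gee_fit"), inherits(fit_b, "gee_fit"))
  if (!isTRUE(all.equal(fit_a$data_signature, fit_b$data_signature))) {
    stop("models were fitted on different rows; refit on identical data")
  }
  terms_a <- names(fit_a$coefficients)
  terms_b <- names(fit_b$coefficients)
  if (all(terms_a %in% terms_b) && length(terms_b) > length(terms_a)) {
    small <- fit_a; large <- fit_b
  } else if (all(terms_b %in% terms_a) && length(terms_a) > length(terms_b)) {
    small <- fit_b; large <- fit_a
  } else if (setequal(terms_a, terms_b)) {
    stop("models have identical terms (df = 0); nothing to compare")
  } else {
    stop("models are not nested: neither design contains the other")
  }
  extra <- setdiff(names(large$coefficients), names(small$coefficients))
  b <- large$coefficients[extra]
  V <- large$vcov_robust[extra, extra, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(V, b))
  df <- length(extra)
  structure(list(pair = c(small$model_id, large$model_id), df = df,
                 wald_statistic = W,
                 p_value = stats::pchisq(W, df, lower.tail = FALSE),
                 extra_terms = extra),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(x$pair[1], "vs.", x$pair[2], ": Wald chi-square =",
      signif(x$wald_statistic, 4), "on", x$df, "df, p =",
      signif(x$p_value, 3), "\n")
  invisible(x)
}
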