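#' Binomial-logit generalized estimating equations
#'
#' Marginal mean model on the logit scale for bounded outcomes rescaled to
#' binomial successes/trials, fit by Fisher-scoring estimating equations with
#' a working correlation (independence or exchangeable) over
#' within-participant clusters, and the classical (Liang-Zeger) sandwich
#' covariance.  Percent-scored measures give non-integer successes; the
#' estimating equations operate on proportions with trials as prior weights,
#' so they are quasi-binomial by construction and integrality is never
#' required.
#'
#' @name gee
NULL

# Core solver.  y: observed proportions; w: binomial trials (prior weights);
# X: design matrix; cluster: cluster id per row.
gee_binomial <- function(y, w, X, cluster,
                         corstr = c("independence", "exchangeable"),
                         maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  p <- ncol(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(w) == n, length(cluster) == n)
  idx <- split(seq_len(n), cluster)
  # start from per-column empirical logits (valid for cell-indicator designs;
  # generic fallback zero otherwise)
  colsum_sw <- drop(crossprod(X, y * w))
  colsum_w <- drop(crossprod(X, w))
  beta <- if (all(X %in% c(0, 1)) && all(rowSums(X) == 1)) {
    stats::qlogis(pmin(pmax(colsum_sw / colsum_w, 1e-6), 1 - 1e-6))
  } else {
    rep(0, p)
  }
  alpha <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu) / w
    e <- (y - mu) / sqrt(v)
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0
      npair <- 0
      for (ii in idx) {
        ei <- e[ii]
        ni <- length(ei)
        if (ni > 1L) {
          num <- num + (sum(ei)^2 - sum(ei^2)) / 2
          npair <- npair + ni * (ni - 1) / 2
        }
      }
      alpha <- if (npair > p) num / ((npair - p) * phi) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    B <- matrix(0, p, p)
    U <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      mui <- mu[ii]
      wi <- w[ii]
      Di <- Xi * (mui * (1 - mui))
      sdi <- sqrt(mui * (1 - mui) / wi)
      ni <- length(ii)
      Ri <- if (corstr == "exchangeable" && ni > 1L) {
        (1 - alpha) * diag(ni) + alpha
      } else diag(ni)
      Vinv <- solve(outer(sdi, sdi) * Ri)
      DtV <- crossprod(Di, Vinv)
      B <- B + DtV %*% Di
      U <- U + DtV %*% (y[ii] - mui)
    }
    delta <- solve(B, U)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  # sandwich at the solution
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    mui <- mu[ii]
    wi <- w[ii]
    Di <- Xi * (mui * (1 - mui))
    sdi <- sqrt(mui * (1 - mui) / wi)
    ni <- length(ii)
    Ri <- if (corstr == "exchangeable" && ni > 1L) {
      (1 - alpha) * diag(ni) + alpha
    } else diag(ni)
    Vinv <- solve(outer(sdi, sdi) * Ri)
    DtV <- crossprod(Di, Vinv)
    B <- B + DtV %*% Di
    ui <- DtV %*% (y[ii] - mui)
    M <- M + tcrossprod(ui)
  }
  Binv <- solve(B)
  vcov <- Binv %*% M %*% Binv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(coefficients = beta, vcov = vcov, alpha = alpha, phi = phi,
       converged = converged, iterations = it, corstr = corstr,
       n_clusters = length(idx), n_obs = n)
}

#' Rescale a bounded score to binomial successes/trials
#'
#' The score is shifted to a minimum of zero by subtracting the measure's
#' minimum possible score (the binomial "successes") and the score range is
#' the number of "trials".
#'
#' @param score numeric score(s) within `[total_min, total_max]`.
#' @param spec a [measure_spec()].
#' @return data.frame with columns `successes` and `trials`.
#' @export
rescale_to_binomial <- function(score, spec) {
  stopifnot(inherits(spec, "measure_spec"))
  if (any(score < spec$total_min | score > spec$total_max)) {
    stop("score outside [", spec$total_min, ", ", spec$total_max, "] for ",
         spec$name)
  }
  data.frame(successes = score - spec$total_min,
             trials = rep(spec$total_max - spec$total_min, length(score)))
}

cell_name <- function(arm, timepoint) paste(arm, timepoint, sep = ".")

#' Fit the saturated marginal binomial model for one longitudinal measure
#'
#' Rescales the measure to successes/trials, fits a saturated arm-by-timepoint
#' cell-means model on the logit scale with participants as correlation
#' clusters, and attaches the robust sandwich covariance.  Cells observed
#' entirely at a boundary (all zero successes or all trials) receive a 0.5
#' continuity adjustment to successes and failures so their logits stay
#' finite; affected cells are reported in `adjusted_cells`.
#'
#' @param dataset a long-format `trial_dataset` (complete data).
#' @param measure measure name present in `dataset$measure`.
#' @param registry measure registry supplying the bounds.
#' @param working_correlation `"independence"` (default; the sandwich keeps
#'   inference valid regardless) or `"exchangeable"`.
#' @return An object of class `gee_fit`: coefficients (cell logits, ordered
#'   arm-major), robust `vcov`, a `cells` data.frame with empirical and
#'   model-based summaries, convergence information, and the design layout.
#' @export
fit_marginal_binomial <- function(dataset, measure,
                                  registry = measure_registry(),
                                  working_correlation = "independence") {
  stopifnot(is.data.frame(dataset))
  spec <- registry[[measure]]
  if (is.null(spec)) stop("measure not in registry: ", measure)
  d <- dataset[dataset$measure == measure, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for measure ", measure)
  arms <- unique(d$arm)
  tps <- sort(unique(d$timepoint))
  counts <- table(d$participant_id)
  if (any(counts != length(tps))) {
    stop("incomplete data: every participant needs one row per timepoint")
  }
  bin <- rescale_to_binomial(d$score, spec)
  y <- bin$successes / bin$trials
  w <- bin$trials
  cell <- factor(cell_name(d$arm, d$timepoint),
                 levels = as.vector(t(outer(arms, tps, cell_name))))
  # continuity adjustment for degenerate boundary cells
  cell_succ <- tapply(bin$successes, cell, sum)
  cell_trials <- tapply(bin$trials, cell, sum)
  degenerate <- names(cell_succ)[cell_succ == 0 | cell_succ == cell_trials]
  if (length(degenerate)) {
    in_deg <- as.character(cell) %in% degenerate
    y[in_deg] <- (bin$successes[in_deg] + 0.5) / (bin$trials[in_deg] + 1)
  }
  X <- stats::model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  fit <- gee_binomial(y, w, X, cluster = d$participant_id,
                      corstr = working_correlation)
  if (!fit$converged) stop("estimating equations failed to converge for ",
                           measure)
  cells <- data.frame(
    cell = levels(cell),
    arm = rep(arms, each = length(tps)),
    timepoint = rep(tps, times = length(arms)),
    n = as.vector(tapply(y, cell, length)),
    empirical_mean = as.vector(tapply(d$score, cell, mean)),
    empirical_sd = as.vector(tapply(d$score, cell, stats::sd)),
    logit = unname(fit$coefficients),
    se_logit = sqrt(diag(fit$vcov)))
  range_ <- spec$total_max - spec$total_min
  cells$model_mean <- spec$total_min + range_ * stats::plogis(cells$logit)
  z <- stats::qnorm(0.975)
  cells$ci_low <- spec$total_min +
    range_ * stats::plogis(cells$logit - z * cells$se_logit)
  cells$ci_high <- spec$total_min +
    range_ * stats::plogis(cells$logit + z * cells$se_logit)
  structure(c(fit,
              list(measure = measure, spec = spec, cells = cells,
                   arms = arms, timepoints = tps,
                   adjusted_cells = degenerate)),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "Marginal binomial fit for '%s' (%s working correlation, %d clusters)\n",
    x$measure, x$corstr, x$n_clusters))
  print(x$cells[, c("arm", "timepoint", "empirical_mean", "model_mean",
                    "ci_low", "ci_high")], row.names = FALSE, digits = 4)
  invisible(x)
}
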