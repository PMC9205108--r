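#' Build the regressor matrix of the duration-interacted conditional logit
#'
#' One row per alternative. The duration column holds the alternative's
#' survival duration `t`; the column of each estimated (dimension,
#' level-group) holds `t` when the alternative's level for that dimension
#' falls in the group, else 0. Reference levels (level 1 and groups merged to
#' the reference) contribute nothing: a state at level 1 of every dimension
#' has only its duration column populated, so its systematic utility is
#' `alpha * t` and all states carry zero utility at zero duration — the QALY
#' anchoring built into the design matrix.
#'
#' @param dataset Long-format choice data (see [simulate_choices()]).
#' @param spec A [model_spec()].
#' @return Numeric matrix, rows aligned with `dataset`, columns named as the
#'   model coefficients (duration first).
#' @export
build_regressors <- function(dataset, spec = default_model_spec()) {
  dims <- fact8d_dimensions()
  lev <- as.matrix(dataset[, dims])
  if (anyNA(lev) || any(lev < 1) || any(lev > 5) || any(lev != round(lev))) {
    stop("dimension levels must be integers 1..5", call. = FALSE)
  }
  t <- dataset$duration
  if (any(!is.finite(t))) stop("non-finite duration", call. = FALSE)
  nm <- coef_names(spec)
  cmap <- level_column_map(spec)
  x <- matrix(0, nrow(dataset), length(nm), dimnames = list(NULL, nm))
  x[, 1] <- t
  for (d in dims) {
    col <- cmap[d, lev[, d]]
    hit <- !is.na(col)
    x[cbind(which(hit), col[hit])] <- t[hit]
  }
  x
}

# Collapse a long choice dataset into per-set differences: for each
# (respondent, set), D = x_A - x_B and y = 1 if A was chosen. Only
# differences enter the paired logit likelihood.
prepare_clogit <- function(dataset, spec, weights = NULL) {
  validate_choices(dataset)
  x <- build_regressors(dataset, spec)
  key <- paste(dataset$resp_id, dataset$set_id, sep = "\r")
  ukey <- unique(key)
  is_a <- dataset$alt == "A"
  ia <- match(ukey, ifelse(is_a, key, NA))
  ib <- match(ukey, ifelse(!is_a, key, NA))
  d <- x[ia, , drop = FALSE] - x[ib, , drop = FALSE]
  y <- dataset$chosen[ia]
  cluster <- dataset$resp_id[ia]
  w <- rep(1, length(ukey))
  weighted <- !is.null(weights)
  if (weighted) {
    wv <- stats::setNames(as.numeric(weights), names(weights))
    if (is.null(names(weights))) {
      stop("weights must be named by respondent id", call. = FALSE)
    }
    w <- wv[as.character(cluster)]
    if (anyNA(w)) stop("weights missing for some respondents", call. = FALSE)
  }
  # spec-independent data fingerprint so nested fits on the same data match
  list(d = d, y = y, w = w, cluster = cluster, weighted = weighted,
       fingerprint = c(n_obs = length(y), n_resp = length(unique(cluster)),
                       chosen_dur = sum(dataset$duration * dataset$chosen),
                       lev_sum = sum(as.matrix(dataset[, fact8d_dimensions()]) *
                                       dataset$duration),
                       w_sum = sum(w), w_sq = sum(w^2)))
}

#' Conditional logit log-likelihood and analytic gradient
#'
#' The weighted paired-logit (pseudo-)log-likelihood
#' `sum_i w_i sum_s log P(chosen alternative)` with
#' `P(A) = plogis((x_A - x_B)' theta)`, and its analytic gradient
#' `sum w (y - p) (x_A - x_B)`. Mostly useful for verifying the optimiser
#' against numerical differentiation.
#'
#' @param params Numeric coefficient vector ordered as [build_regressors()]
#'   columns (duration first).
#' @param dataset Long-format choice data.
#' @param spec A [model_spec()].
#' @param weights Optional respondent weights (named by `resp_id`).
#' @return List with `value` and `gradient`.
#' @export
loglik_clogit <- function(params, dataset, spec = default_model_spec(),
                          weights = NULL) {
  prep <- prepare_clogit(dataset, spec, weights)
  if (length(params) != ncol(prep$d)) {
    stop("params has length ", length(params), ", model needs ",
         ncol(prep$d), call. = FALSE)
  }
  clogit_ll(params, prep)
}

clogit_ll <- function(theta, prep) {
  eta <- drop(prep$d %*% theta)
  # log P(observed) = y*eta - log(1+exp(eta)), numerically stable form
  ll <- sum(prep$w * (prep$y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)))
  p <- stats::plogis(eta)
  list(value = ll,
       gradient = drop(crossprod(prep$d, prep$w * (prep$y - p))),
       p = p)
}

#' Fit the duration-interacted conditional logit
#'
#' Maximum (pseudo-)likelihood by Newton-Raphson with the analytic gradient
#' and Hessian, started at zero and iterated until the gradient max-norm
#' falls below `gtol`. Respondent weights (e.g. from [rake()]) multiply each
#' respondent's log-likelihood contribution (survey-weighted
#' pseudo-likelihood). The reported covariance is the clustered sandwich with
#' respondents as clusters — scores are summed within respondent before the
#' meat is formed — accounting for the correlation among one respondent's
#' repeated choices; with one observation per cluster it reduces to the
#' ordinary heteroskedasticity-robust estimator. The model-based inverse
#' information is kept alongside.
#'
#' `AIC = 2k - 2LL`; `BIC = k log(N) - 2LL` with `N` the number of choice-set
#' observations by default (`bic_n` overrides the convention).
#'
#' @param dataset Long-format choice data.
#' @param spec A [model_spec()].
#' @param weights Optional [rake()] weights, named by respondent id.
#' @param gtol Gradient max-norm convergence criterion.
#' @param max_iter Newton iteration cap.
#' @param bic_n Sample-size convention for BIC (default: choice sets).
#' @return Object of class `fact8d_fit`; see Details for fields.
#' @details Fields: `coefficients`, `se` (cluster-robust), `vcov`
#'   (sandwich), `vcov_model`, `loglik`, `k`, `n_obs` (choice sets),
#'   `n_clusters`, `aic`, `bic`, `converged`, `iterations`, `grad_norm`,
#'   `spec`, `weighted`.
#' @export
fit_clogit <- function(dataset, spec = default_model_spec(), weights = NULL,
                       gtol = 1e-6, max_iter = 100, bic_n = NULL) {
  prep <- prepare_clogit(dataset, spec, weights)
  k <- ncol(prep$d)
  if (all(prep$y == 1) || all(prep$y == 0)) {
    stop("degenerate dataset: the same alternative is chosen everywhere",
         call. = FALSE)
  }
  theta <- numeric(k)
  cur <- clogit_ll(theta, prep)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- cur$gradient
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    wpq <- prep$w * cur$p * (1 - cur$p)
    info <- crossprod(prep$d * wpq, prep$d)
    step <- tryCatch(solve(info, g), error = function(e) {
      stop("singular Hessian: model not identified on these data ",
           "(complete separation or an unobserved level group)",
           call. = FALSE)
    })
    # damped Newton: halve until the likelihood does not decrease
    lambda <- 1
    repeat {
      cand <- clogit_ll(theta + lambda * step, prep)
      if (cand$value >= cur$value - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    theta <- theta + lambda * step
    cur <- cand
  }
  if (!converged && max(abs(cur$gradient)) < gtol) converged <- TRUE
  if (!converged) {
    warning("conditional logit did not converge in ", max_iter,
            " iterations (gradient max-norm ",
            format(max(abs(cur$gradient))), ")", call. = FALSE)
  }
  wpq <- prep$w * cur$p * (1 - cur$p)
  info <- crossprod(prep$d * wpq, prep$d)
  bread <- tryCatch(solve(info), error = function(e) {
    stop("singular Hessian at the optimum", call. = FALSE)
  })
  scores <- prep$d * (prep$w * (prep$y - cur$p))
  cluster_scores <- rowsum(scores, group = as.character(prep$cluster))
  meat <- crossprod(cluster_scores)
  vcov <- bread %*% meat %*% bread
  vcov <- (vcov + t(vcov)) / 2
  nm <- coef_names(spec)
  dimnames(vcov) <- dimnames(bread) <- list(nm, nm)
  n_obs <- length(prep$y)
  n_bic <- if (is.null(bic_n)) n_obs else bic_n
  structure(list(
    coefficients = stats::setNames(theta, nm),
    se = stats::setNames(sqrt(diag(vcov)), nm),
    vcov = vcov,
    vcov_model = bread,
    loglik = cur$value,
    k = k,
    n_obs = n_obs,
    n_clusters = length(unique(prep$cluster)),
    aic = 2 * k - 2 * cur$value,
    bic = k * log(n_bic) - 2 * cur$value,
    converged = converged,
    iterations = iter,
    grad_norm = max(abs(cur$gradient)),
    spec = spec,
    weighted = prep$weighted,
    fingerprint = prep$fingerprint
  ), class = "fact8d_fit")
}

#' @export
print.fact8d_fit <- function(x, ...) {
  cat("Duration-interacted conditional logit",
      if (x$weighted) "(survey-weighted pseudo-likelihood)" else "(unweighted)",
      "\n")
  cat(sprintf("  %d choice sets, %d respondents (clusters), %d parameters\n",
              x$n_obs, x$n_clusters, x$k))
  cat(sprintf("  logLik %.2f  AIC %.2f  BIC %.2f  %s\n", x$loglik, x$aic,
              x$bic, if (x$converged) "converged" else "NOT CONVERGED"))
  print(coefficient_table(x), digits = 3)
  invisible(x)
}

#' @export
coef.fact8d_fit <- function(object, ...) object$coefficients

#' @export
vcov.fact8d_fit <- function(object, ...) object$vcov

#' @export
logLik.fact8d_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Coefficient table of a fitted model
#'
#' @param fit A `fact8d_fit`.
#' @return Data.frame: term, estimate, cluster-robust SE, z, p.
#' @export
coefficient_table <- function(fit) {
  z <- fit$coefficients / fit$se
  data.frame(term = names(fit$coefficients),
             estimate = as.numeric(fit$coefficients),
             robust_se = as.numeric(fit$se),
             z = as.numeric(z),
             p_value = 2 * stats::pnorm(-abs(z)),
             row.names = NULL)
}

#' Likelihood-ratio test between nested conditional logits
#'
#' `statistic = 2 (LL_full - LL_nested)` (floored at zero), with degrees of
#' freedom the difference in free parameters and the p-value from the
#' chi-squared upper tail. Both fits must come from the same data and
#' weights; a fingerprint check refuses mismatched inputs.
#'
#' @param nested,full `fact8d_fit` objects, `nested$k < full$k`.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "fact8d_fit"), inherits(full, "fact8d_fit"))
  if (nested$k >= full$k) {
    stop("nested model must have fewer parameters than the full model",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(nested$fingerprint, full$fingerprint)) ||
      nested$weighted != full$weighted) {
    stop("fits come from different datasets or weights", call. = FALSE)
  }
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  df <- full$k - nested$k
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
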