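#' Assess sample representativeness against population margins
#'
#' For each margin variable, compares the sample level proportions with the
#' population targets: the maximum absolute deviation, a goodness-of-fit
#' chi-squared statistic (`sum (O - E)^2 / E` with expected counts from the
#' targets) with its p-value, and a flag raised when any level deviates by at
#' least `threshold` (default 2 percentage points — the conventional rule for
#' deciding which variables to rake).
#'
#' @param profiles Cohort data.frame (e.g. from [simulate_respondents()]).
#' @param targets A [margin_targets()].
#' @param threshold Flagging threshold on the absolute proportion deviation.
#' @return Data.frame of class `fact8d_rep_report`: one row per variable with
#'   `variable`, `max_abs_dev`, `chisq`, `df`, `p_value`, `flagged`.
#' @export
assess_representativeness <- function(profiles, targets, threshold = 0.02) {
  stopifnot(inherits(targets, "fact8d_margins"))
  vars <- intersect(names(targets), names(profiles))
  if (!length(vars)) stop("no margin variable found in profiles", call. = FALSE)
  n <- nrow(profiles)
  rows <- lapply(vars, function(v) {
    tg <- targets[[v]]
    lev <- as.character(profiles[[v]])
    unknown <- setdiff(unique(lev), names(tg))
    if (length(unknown)) {
      stop("level(s) of ", v, " not in targets: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    obs <- table(factor(lev, levels = names(tg)))
    p_obs <- as.numeric(obs) / n
    expected <- n * tg
    keep <- expected > 0
    chisq <- sum((as.numeric(obs)[keep] - expected[keep])^2 / expected[keep])
    df <- sum(keep) - 1
    data.frame(variable = v,
               max_abs_dev = max(abs(p_obs - as.numeric(tg))),
               chisq = chisq, df = df,
               p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
               flagged = max(abs(p_obs - as.numeric(tg))) >= threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fact8d_rep_report", "data.frame")
  out
}

#' Raked (iterative proportional fitting) survey weights
#'
#' Computes one positive weight per respondent so that the weighted sample
#' margins of the chosen variables match the population targets. Classical
#' raking: cycle through the variables, multiplying each respondent's weight
#' by `target proportion / current weighted sample proportion` of their
#' level, until every raked margin is within `tol` of target. Weights always
#' sum to `n` (each pass preserves the total when targets sum to 1).
#'
#' Raking on a single variable reduces to post-stratification: the weight of
#' a respondent at level `g` is exactly `target_g / sample_g`. With no
#' trimming a weight can grow large when a positive-target level is rare in
#' the sample; the optional `cap` bounds weights (applied each cycle, margins
#' then only approximate).
#'
#' @param profiles Cohort data.frame.
#' @param targets A [margin_targets()].
#' @param variables Variables to rake on. Default: the variables flagged by
#'   [assess_representativeness()] at the 2-point rule.
#' @param tol Convergence tolerance on the weighted margin deviations.
#' @param max_iter Maximum IPF cycles.
#' @param cap Optional upper bound on weights (no trimming by default).
#' @param initial Optional starting weights (e.g. an earlier raking);
#'   defaults to 1. Raking already-raked weights is a fixed point: no weight
#'   moves by more than the tolerance.
#' @return Numeric vector of class `fact8d_weights`, named by `resp_id`, with
#'   attributes `iterations`, `max_dev` and `variables`.
#' @export
#' @examples
#' prof <- simulate_respondents(n = 400, seed = 3)
#' w <- rake(prof, canadian_margins())
#' sum(w) == nrow(prof)
rake <- function(profiles, targets, variables = NULL, tol = 1e-6,
                 max_iter = 100, cap = NULL, initial = NULL) {
  stopifnot(inherits(targets, "fact8d_margins"))
  if (is.null(variables)) {
    rep <- assess_representativeness(profiles, targets)
    variables <- rep$variable[rep$flagged]
  }
  if (!length(variables)) {
    stop("no variable to rake on (none flagged); pass `variables` explicitly",
         call. = FALSE)
  }
  absent <- setdiff(variables, intersect(names(targets), names(profiles)))
  if (length(absent)) {
    stop("cannot rake on ", paste(absent, collapse = ", "),
         ": not in both profiles and targets", call. = FALSE)
  }
  n <- nrow(profiles)
  lev <- lapply(variables, function(v) as.character(profiles[[v]]))
  names(lev) <- variables
  for (v in variables) {
    tg <- targets[[v]]
    present <- names(tg)[tg > 0]
    empty <- setdiff(present, unique(lev[[v]]))
    if (length(empty)) {
      stop("cannot rake ", v, ": no respondent at level(s) ",
           paste(empty, collapse = ", "), " with positive target",
           call. = FALSE)
    }
  }
  w <- if (is.null(initial)) rep(1, n) else as.numeric(initial)
  stopifnot(length(w) == n, all(w > 0))
  max_dev <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (v in variables) {
      tg <- targets[[v]]
      cur <- tapply(w, factor(lev[[v]], levels = names(tg)), sum)
      cur[is.na(cur)] <- 0
      ratio <- ifelse(cur > 0, n * tg / cur, 1)
      w <- w * ratio[lev[[v]]]
      if (!is.null(cap)) w <- pmin(w, cap)
    }
    max_dev <- max(vapply(variables, function(v) {
      tg <- targets[[v]]
      cur <- tapply(w, factor(lev[[v]], levels = names(tg)), sum)
      cur[is.na(cur)] <- 0
      max(abs(cur / sum(w) - tg))
    }, numeric(1)))
    if (max_dev < tol) break
  }
  if (max_dev >= tol && is.null(cap)) {
    stop("raking did not converge in ", max_iter,
         " iterations (last max margin deviation ", format(max_dev), ")",
         call. = FALSE)
  }
  w <- as.numeric(w) * n / sum(w)
  structure(stats::setNames(w, profiles$resp_id),
            iterations = iter, max_dev = max_dev, variables = variables,
            class = "fact8d_weights")
}

#' @export
print.fact8d_weights <- function(x, ...) {
  cat("Raked weights for", length(x), "respondents on: ",
      paste(attr(x, "variables"), collapse = ", "), "\n")
  cat("converged in", attr(x, "iterations"), "cycle(s); max margin deviation",
      format(attr(x, "max_dev")), "\n")
  cat("range:", format(range(x)), " sum:", format(sum(x)), "\n")
  invisible(x)
}

#' Weighted sample margins under a weight vector
#'
#' Reports the weighted level proportions of every margin variable (raked or
#' not) next to the targets; margins of non-raked variables may move under
#' raking, which is reported rather than silently altered.
#'
#' @param profiles Cohort data.frame.
#' @param targets A [margin_targets()].
#' @param weights Numeric weights aligned with `profiles` (default all 1).
#' @return Data.frame: variable, level, target, unweighted, weighted.
#' @export
weighted_margins <- function(profiles, targets, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(profiles))
  rows <- lapply(names(targets), function(v) {
    if (!v %in% names(profiles)) return(NULL)
    tg <- targets[[v]]
    f <- factor(as.character(profiles[[v]]), levels = names(tg))
    wsum <- tapply(weights, f, sum)
    wsum[is.na(wsum)] <- 0
    data.frame(variable = v, level = names(tg), target = as.numeric(tg),
               unweighted = as.numeric(table(f)) / nrow(profiles),
               weighted = as.numeric(wsum) / sum(weights))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write weight vectors as CSV
#' @param path CSV path (`resp_id`, `weight`).
#' @param weights A `fact8d_weights` vector.
#' @return The weights / the path, invisibly.
#' @export
read_weights_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(stats::setNames(df$weight, df$resp_id), class = "fact8d_weights")
}

#' @rdname read_weights_csv
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(data.frame(resp_id = names(weights),
                              weight = as.numeric(weights)),
                   path, row.names = FALSE)
  invisible(path)
}
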