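#' Detect monotonicity violations in a fitted conditional logit
#'
#' Two kinds of violation are flagged, per dimension, on the estimated level
#' groups ordered from mildest to worst:
#' * **positive coefficient** — an estimated group with coefficient `>= 0`,
#'   implying that a *worse* level than the reference raises utility;
#' * **reversed ordering** — an adjacent pair of estimated groups where the
#'   worse group's coefficient is strictly greater (less negative) than the
#'   milder group's.
#'
#' Records are ordered mildest level first within dimension, dimensions in
#' canonical order.
#'
#' @param fit A `fact8d_fit`, or a [true_preferences()] object (e.g. a
#'   published coefficient table) to screen directly.
#' @param spec The [model_spec()] the coefficients belong to; defaults to the
#'   fit's own spec (the unconstrained spec for preference objects).
#' @return Data.frame with columns `dimension`, `group` (levels of the
#'   offending group), `kind` (`"positive"`/`"reversal"`), `coef`,
#'   `milder_group`, `milder_coef` (NA for positive-coefficient records).
#' @export
#' @examples
#' detect_violations(published_model_coefficients(2))
detect_violations <- function(fit, spec = NULL) {
  gc <- group_coefficients(fit, spec)
  out <- list()
  for (d in fact8d_dimensions()) {
    gs <- gc[[d]]
    est <- gs[!vapply(gs, `[[`, logical(1), "reference")]
    prev <- NULL
    for (g in est) {
      if (g$coef >= 0) {
        out[[length(out) + 1L]] <- data.frame(
          dimension = d, group = level_label(g$levels), kind = "positive",
          coef = g$coef, milder_group = NA_character_, milder_coef = NA_real_)
      }
      if (!is.null(prev) && g$coef > prev$coef) {
        out[[length(out) + 1L]] <- data.frame(
          dimension = d, group = level_label(g$levels), kind = "reversal",
          coef = g$coef, milder_group = level_label(prev$levels),
          milder_coef = prev$coef)
      }
      prev <- g
    }
  }
  if (!length(out)) {
    return(data.frame(dimension = character(), group = character(),
                      kind = character(), coef = numeric(),
                      milder_group = character(), milder_coef = numeric()))
  }
  res <- do.call(rbind, out)
  dim_rank <- match(res$dimension, fact8d_dimensions())
  lvl_rank <- vapply(strsplit(ifelse(is.na(res$milder_group), res$group,
                                     res$milder_group), "-"),
                     function(x) as.numeric(x[1]), numeric(1))
  # at equal mildest level a positive (reference-merge) record goes first
  res <- res[order(dim_rank, lvl_rank, res$kind != "positive"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

level_label <- function(levels) {
  lv <- sort(levels)
  if (length(lv) == 1) as.character(lv) else paste0(min(lv), "-", max(lv))
}

# Per-dimension ordered list of groups with their coefficient values.
group_coefficients <- function(fit, spec = NULL) {
  if (inherits(fit, "fact8d_preferences")) {
    if (is.null(spec)) spec <- default_model_spec()
    beta <- fit$beta
    get_coef <- function(d, levels) beta[d, min(levels)]
  } else if (inherits(fit, "fact8d_fit")) {
    if (is.null(spec)) spec <- fit$spec
    if (!identical(coef_names(spec), names(fit$coefficients))) {
      stop("fit does not match spec", call. = FALSE)
    }
    get_coef <- function(d, levels) {
      fit$coefficients[[group_name(d, levels)]]
    }
  } else {
    stop("fit must be a fact8d_fit or fact8d_preferences object",
         call. = FALSE)
  }
  res <- lapply(fact8d_dimensions(), function(d) {
    lapply(spec$groups[[d]], function(g) {
      list(levels = g$levels, reference = g$reference,
           coef = if (g$reference) 0 else get_coef(d, g$levels))
    })
  })
  names(res) <- fact8d_dimensions()
  res
}

#' Impose monotonicity by iterative level collapsing
#'
#' Fits the conditional logit, detects violations, applies one round of
#' merges, refits, and repeats until the fit is monotone or `max_rounds` is
#' exhausted. Merge rules within a round (all of a round's violations are
#' applied together, mildest first within each dimension):
#' * a positive-coefficient group whose milder neighbours are all (by then)
#'   reference merges **into the reference** (coefficient fixed at 0);
#' * a reversed adjacent pair merges into one shared group;
#' * a group already consumed by a merge this round is skipped and, if its
#'   violation persists, handled after the refit.
#'
#' The constrained model is nested in the unconstrained one, so its
#' log-likelihood can never exceed the unconstrained fit's.
#'
#' @param dataset Long-format choice data.
#' @param spec Starting [model_spec()].
#' @param weights Optional respondent weights.
#' @param max_rounds Maximum fit-detect-merge rounds.
#' @param forced_merges Optional list of merges applied to `spec` before any
#'   fitting, each `list(dimension =, levels =, to_reference =)` — e.g. to
#'   reproduce a published collapsing pattern exactly.
#' @param ... Passed to [fit_clogit()].
#' @return List: `spec` (final), `fit` (final), `history` (per round: the
#'   violation table and the merges applied).
#' @export
constrain <- function(dataset, spec = default_model_spec(), weights = NULL,
                      max_rounds = 10, forced_merges = NULL, ...) {
  if (!is.null(forced_merges)) {
    for (m in forced_merges) {
      spec <- if (isTRUE(m$to_reference)) {
        merge_to_reference(spec, m$dimension, m$levels)
      } else {
        merge_levels(spec, m$dimension, m$levels)
      }
    }
  }
  history <- list()
  fit <- fit_clogit(dataset, spec, weights, ...)
  for (round in seq_len(max_rounds)) {
    viol <- detect_violations(fit, spec)
    if (!nrow(viol)) {
      return(list(spec = spec, fit = fit, history = history))
    }
    merges <- plan_merges(spec, viol)
    spec <- merges$spec
    history[[round]] <- list(violations = viol, merges = merges$applied)
    fit <- fit_clogit(dataset, spec, weights, ...)
  }
  viol <- detect_violations(fit, spec)
  if (nrow(viol)) {
    stop("monotonicity not achieved after ", max_rounds,
         " rounds; residual violations:\n",
         paste(utils::capture.output(print(viol)), collapse = "\n"),
         call. = FALSE)
  }
  list(spec = spec, fit = fit, history = history)
}

# Apply one round of merges to the spec. Violations arrive mildest-first per
# dimension; a group takes part in at most one merge per round, and
# reference-adjacency is evaluated against the within-round state so that
# e.g. two successive positive groups both collapse to the reference in one
# round.
plan_merges <- function(spec, violations) {
  applied <- list()
  consumed <- character()
  for (i in seq_len(nrow(violations))) {
    v <- violations[i, ]
    d <- v$dimension
    gs <- spec$groups[[d]]
    # locate the offending group in the current spec by its mildest level
    g_lv <- as.integer(strsplit(v$group, "-")[[1]])[1]
    gi <- which(vapply(gs, function(g) g_lv %in% g$levels, logical(1)))
    if (!length(gi)) next                     # already merged away this round
    g <- gs[[gi]]
    gkey <- paste(d, min(g$levels))
    if (gkey %in% consumed || g$reference) next
    if (v$kind == "positive") {
      milder <- gs[seq_len(gi - 1)]
      if (all(vapply(milder, `[[`, logical(1), "reference")) ||
          gi == 1) {
        spec <- merge_to_reference(spec, d, g$levels)
        applied[[length(applied) + 1L]] <- list(
          dimension = d, levels = g$levels, to_reference = TRUE)
        consumed <- c(consumed, gkey)
      }
      # positive but not reference-adjacent: the paired reversal record
      # (always present, since the milder estimated group is below zero)
      # handles it
    } else {
      if (gi == 1) next
      prev <- gs[[gi - 1]]
      if (prev$reference) next                # becomes a positive case later
      pkey <- paste(d, min(prev$levels))
      if (pkey %in% consumed) next
      lv <- sort(c(prev$levels, g$levels))
      spec <- merge_levels(spec, d, lv)
      applied[[length(applied) + 1L]] <- list(
        dimension = d, levels = lv, to_reference = FALSE)
      consumed <- c(consumed, gkey, pkey, paste(d, min(lv)))
    }
  }
  list(spec = spec, applied = applied)
}

#' Convert fitted coefficients to a value set (MRS anchoring)
#'
#' The utility decrement of level `l` of dimension `d` is the marginal rate
#' of substitution between that level and survival duration:
#' `w[d, l] = -beta[d, l] / alpha`, the share of remaining life years a
#' respondent would give up to avoid the level. Group coefficients are
#' expanded to all five levels (merged-to-reference levels get 0, merged
#' levels share their group's value). Decrements are computed from the
#' unrounded coefficients; rounding happens only on export.
#'
#' @param fit A `fact8d_fit` (typically the constrained fit), or a
#'   [true_preferences()] object.
#' @param label,country,source Metadata for the resulting set.
#' @return A [value_set()]; non-monotone inputs yield a flagged set.
#' @export
#' @examples
#' derive_value_set(published_model_coefficients(3))
derive_value_set <- function(fit, label = "derived value set", country = "",
                             source = NULL) {
  if (inherits(fit, "fact8d_preferences")) {
    alpha <- fit$alpha
    beta <- fit$beta
    if (is.null(source)) source <- fit$label
  } else if (inherits(fit, "fact8d_fit")) {
    alpha <- fit$coefficients[["duration"]]
    beta <- expand_coefficients(fit$spec, fit$coefficients)
    if (is.null(source)) {
      source <- paste0("conditional logit fit (", fit$k, " parameters, ",
                       if (fit$weighted) "weighted" else "unweighted", ")")
    }
  } else {
    stop("fit must be a fact8d_fit or fact8d_preferences object",
         call. = FALSE)
  }
  if (alpha <= 0) {
    stop("duration coefficient alpha = ", format(alpha),
         " is not positive: MRS anchoring undefined", call. = FALSE)
  }
  value_set(-beta / alpha, label = label, country = country, source = source)
}

#' Compare two coefficient fits term by term
#'
#' Numeric stand-in for the usual unweighted-versus-weighted scatterplot:
#' paired estimates, their differences, and a concordance summary.
#'
#' @param a,b `fact8d_fit` objects on the same [model_spec()].
#' @return Data.frame (term, estimate_a, estimate_b, difference) with
#'   attributes `max_abs_difference` and `sign_agreement` (share of terms
#'   whose estimates agree in sign).
#' @export
compare_fits <- function(a, b) {
  stopifnot(inherits(a, "fact8d_fit"), inherits(b, "fact8d_fit"))
  if (!identical(names(a$coefficients), names(b$coefficients))) {
    stop("fits use different model specs", call. = FALSE)
  }
  out <- data.frame(term = names(a$coefficients),
                    estimate_a = as.numeric(a$coefficients),
                    estimate_b = as.numeric(b$coefficients),
                    difference = as.numeric(b$coefficients - a$coefficients),
                    row.names = NULL)
  attr(out, "max_abs_difference") <- max(abs(out$difference))
  attr(out, "sign_agreement") <- mean(sign(out$estimate_a) ==
                                        sign(out$estimate_b))
  out
}
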