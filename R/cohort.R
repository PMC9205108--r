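#' Population margin targets
#'
#' Marginal population proportions per demographic variable, the calibration
#' targets for representativeness checks and raking.
#'
#' @param margins Named list; each element a named numeric vector of level
#'   proportions summing to 1 (to within 1e-9, unless `normalise = TRUE`).
#' @param normalise Divide each margin by its sum first (for targets printed
#'   at limited precision).
#' @return Object of class `fact8d_margins`.
#' @export
margin_targets <- function(margins, normalise = FALSE) {
  stopifnot(is.list(margins), length(names(margins)) == length(margins))
  margins <- lapply(margins, function(m) {
    if (is.null(names(m)) || any(!nzchar(names(m)))) {
      stop("every margin level must be named", call. = FALSE)
    }
    if (any(m < 0)) stop("margin proportions must be >= 0", call. = FALSE)
    if (normalise) m <- m / sum(m)
    if (abs(sum(m) - 1) > 1e-9) {
      stop("margin proportions must sum to 1 (off by ",
           format(sum(m) - 1), ")", call. = FALSE)
    }
    m
  })
  structure(margins, class = "fact8d_margins")
}

#' @export
print.fact8d_margins <- function(x, ...) {
  cat("Margin targets for", length(x), "variable(s):\n")
  for (v in names(x)) {
    cat("  ", v, ": ", paste0(names(x[[v]]), "=", round(x[[v]], 3),
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read and write margin targets as JSON
#' @param path JSON path.
#' @param margins A [margin_targets()] object.
#' @return The margins object / the path, invisibly.
#' @export
read_margins <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  margin_targets(lapply(x, unlist))
}

#' @rdname read_margins
#' @export
write_margins <- function(margins, path) {
  jsonlite::write_json(lapply(unclass(margins), as.list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a respondent cohort
#'
#' Draws `n` respondent profiles. Quota variables (by default sex, age group
#' and region, mirroring census-aligned quota sampling) are filled exactly:
#' level counts are the largest-remainder rounding of `n * target`, assigned
#' in random order. Non-quota variables are sampled independently, either at
#' their targets or at the distorted proportions in `skew`, which emulates a
#' self-selected online panel (e.g. over-representation of one language or of
#' higher education) so that downstream raking has real work to do.
#'
#' @param margins A [margin_targets()]; defaults to [canadian_margins()].
#' @param n Number of respondents (default 1582, the analysis-set size of the
#'   Canadian valuation).
#' @param skew Named list of per-variable sampling proportions overriding the
#'   targets for non-quota variables; `NULL` samples all at target. Default
#'   [canadian_sample_skew()].
#' @param seed Integer seed.
#' @param quota_vars Variables filled by exact quota.
#' @return Data.frame of class `fact8d_profiles`: `resp_id` plus one factor
#'   column per margin variable.
#' @export
simulate_respondents <- function(margins = canadian_margins(), n = 1582,
                                 skew = canadian_sample_skew(), seed = 1,
                                 quota_vars = c("sex", "age_group", "region")) {
  stopifnot(inherits(margins, "fact8d_margins"), n >= 1)
  quota_vars <- intersect(quota_vars, names(margins))
  for (v in quota_vars) {
    if (n < length(margins[[v]])) {
      stop("n = ", n, " is smaller than the number of quota cells for ", v,
           call. = FALSE)
    }
  }
  with_seed(seed, {
    out <- data.frame(resp_id = seq_len(n))
    for (v in names(margins)) {
      target <- margins[[v]]
      if (v %in% quota_vars) {
        counts <- largest_remainder(n * target)
        lev <- sample(rep(names(target), counts))
      } else {
        p <- target
        if (!is.null(skew[[v]])) {
          p <- skew[[v]]
          if (!setequal(names(p), names(target))) {
            stop("skew levels for ", v, " do not match the margin levels",
                 call. = FALSE)
          }
          p <- p[names(target)] / sum(p)
        }
        lev <- sample(names(target), n, replace = TRUE, prob = p)
      }
      out[[v]] <- factor(lev, levels = names(target))
    }
    class(out) <- c("fact8d_profiles", "data.frame")
    out
  })
}

# Integer counts summing to round(sum(x)) via the largest-remainder method.
largest_remainder <- function(x) {
  total <- round(sum(x))
  base <- floor(x)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(x))
}

#' Probability that alternative A is chosen
#'
#' The closed-form choice probability of the duration-interacted conditional
#' logit: with systematic utilities
#' `V_j = t_j * (alpha + sum_d beta[d, l_j(d)])`, alternative A is chosen with
#' probability `plogis(V_A - V_B)` (i.i.d. type-I extreme value errors). This
#' is the oracle both for the choice simulator and for checking the fitted
#' model.
#'
#' @param prefs A [true_preferences()] object.
#' @param choice_set Two rows of a `fact8d_design` (one choice set), or a full
#'   design, in which case one probability per set is returned.
#' @return Numeric vector of P(A chosen), one element per set.
#' @export
#' @examples
#' choice_probability(published_model_coefficients(3),
#'                    generate_design(seed = 1))
choice_probability <- function(prefs, choice_set) {
  stopifnot(inherits(prefs, "fact8d_preferences"))
  v <- systematic_utility(prefs, choice_set)
  key <- paste(choice_set$block, choice_set$set, sep = ".")
  ukey <- unique(key)
  is_a <- choice_set$alt == "A"
  va <- v[is_a][match(ukey, key[is_a])]
  vb <- v[!is_a][match(ukey, key[!is_a])]
  if (anyNA(va) || anyNA(vb)) {
    stop("each choice set needs one A and one B alternative", call. = FALSE)
  }
  stats::setNames(stats::plogis(va - vb), ukey)
}

systematic_utility <- function(prefs, rows) {
  m <- as_state_matrix(rows)
  dec <- numeric(nrow(m))
  for (d in fact8d_dimensions()) dec <- dec + prefs$beta[d, m[, d]]
  rows$duration * (prefs$alpha + dec)
}

#' Simulate DCE choices under a random-utility model
#'
#' Every respondent faces each choice set of their block and picks
#' alternative A with probability [choice_probability()]; draws are
#' independent Bernoulli (conditional logit has no within-respondent error
#' correlation beyond the shared preferences). An optional completion model
#' truncates the task list of a random fraction of respondents, emulating the
#' inclusion rule that respondents completing at least one choice set stay in
#' the analysis set.
#'
#' @param design A `fact8d_design` (respondents cycle through its blocks).
#' @param prefs A [true_preferences()] object.
#' @param profiles Cohort from [simulate_respondents()] (or an integer number
#'   of respondents).
#' @param seed Integer seed.
#' @param completion `NULL` for full completion, or
#'   `list(frac_partial =, min_sets =)`: the given respondent fraction
#'   completes a uniform number of sets between `min_sets` and one fewer than
#'   the block size, the tail being dropped. Default matches the Canadian
#'   study: 81 of 1582 respondents partial.
#' @return Data.frame of class `fact8d_choices`, long format: `resp_id`,
#'   `set_id`, `alt`, `chosen`, `duration` and the eight dimension levels.
#' @export
simulate_choices <- function(design, prefs, profiles, seed = 1,
                             completion = list(frac_partial = 81 / 1582,
                                               min_sets = 1)) {
  n <- if (is.numeric(profiles)) as.integer(profiles) else nrow(profiles)
  resp_ids <- if (is.numeric(profiles)) seq_len(n) else profiles$resp_id
  blocks <- sort(unique(design$block))
  p_a <- lapply(blocks, function(b) {
    choice_probability(prefs, design[design$block == b, , drop = FALSE])
  })
  names(p_a) <- blocks
  dims <- fact8d_dimensions()
  with_seed(seed, {
    resp_block <- blocks[((seq_len(n) - 1L) %% length(blocks)) + 1L]
    per_block <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      b <- blocks[bi]
      in_b <- which(resp_block == b)
      if (!length(in_b)) next
      rows <- design[design$block == b, c("set", "alt", "duration", dims),
                     drop = FALSE]
      rows <- rows[order(rows$set, rows$alt), , drop = FALSE]
      sets <- sort(unique(rows$set))
      n_sets <- length(sets)
      pa <- p_a[[as.character(b)]][paste(b, sets, sep = ".")]
      n_b <- length(in_b)
      # how many sets each respondent completes (tail dropped)
      n_done <- rep(n_sets, n_b)
      if (!is.null(completion) && completion$frac_partial > 0) {
        partial <- runif(n_b) < completion$frac_partial
        n_done[partial] <- sample(seq(completion$min_sets, n_sets - 1L),
                                  sum(partial), replace = TRUE)
      }
      # Bernoulli(p_A) draws, one per respondent x set
      a_chosen <- matrix(runif(n_b * n_sets), n_b, n_sets) <
        matrix(pa, n_b, n_sets, byrow = TRUE)
      long <- rows[rep(seq_len(nrow(rows)), times = n_b), , drop = FALSE]
      resp_idx <- rep(seq_len(n_b), each = nrow(rows))
      set_idx <- match(long$set, sets)
      is_a <- long$alt == "A"
      drawn_a <- a_chosen[cbind(resp_idx, set_idx)]
      keep <- set_idx <= n_done[resp_idx]
      per_block[[bi]] <- data.frame(
        resp_id = resp_ids[in_b][resp_idx[keep]],
        set_id = long$set[keep],
        alt = long$alt[keep],
        chosen = as.integer(ifelse(is_a[keep], drawn_a[keep], !drawn_a[keep])),
        duration = long$duration[keep],
        long[keep, dims, drop = FALSE]
      )
    }
    out <- do.call(rbind, per_block)
    out <- out[order(out$resp_id, out$set_id, out$alt), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("fact8d_choices", "data.frame")
    out
  })
}

#' Validate a long-format choice dataset
#'
#' @param dataset Data.frame with columns `resp_id`, `set_id`, `alt`,
#'   `chosen`, `duration` and the eight dimension levels.
#' @return The dataset, invisibly; errors name the missing column or the
#'   violated invariant (exactly one chosen alternative per respondent-set,
#'   both alternatives present).
#' @export
validate_choices <- function(dataset) {
  need <- c("resp_id", "set_id", "alt", "chosen", "duration",
            fact8d_dimensions())
  absent <- setdiff(need, names(dataset))
  if (length(absent)) {
    stop("choice data lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(dataset$resp_id, dataset$set_id)
  n_alt <- table(key)
  if (any(n_alt != 2)) {
    stop("every (respondent, set) must have exactly 2 alternatives",
         call. = FALSE)
  }
  n_chosen <- tapply(dataset$chosen, key, sum)
  if (any(n_chosen != 1)) {
    stop("every (respondent, set) must have exactly one chosen alternative",
         call. = FALSE)
  }
  invisible(dataset)
}

#' Read and write choice datasets as CSV
#' @param path CSV path.
#' @param dataset A `fact8d_choices` data.frame.
#' @return The validated dataset / the path, invisibly.
#' @export
read_choices_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_choices(df)
  class(df) <- c("fact8d_choices", "data.frame")
  df
}

#' @rdname read_choices_csv
#' @export
write_choices_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}
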