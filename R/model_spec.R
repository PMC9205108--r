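#' Model specification for the duration-interacted conditional logit
#'
#' A model spec records, for each dimension, how severity levels 2-5 are
#' partitioned into estimated coefficient groups. Level 1 is always the
#' reference. A group may instead be merged *to* the reference (its
#' coefficient fixed at 0), and adjacent levels may share one coefficient —
#' the mechanism by which monotonicity violations are collapsed away. The
#' free-parameter count is `1` (duration) `+` the number of non-reference
#' groups.
#'
#' @param groups Named list (one element per dimension) of lists of groups;
#'   each group is `list(levels =, reference =)` with `levels` a contiguous
#'   run within 2..5. See [default_model_spec()].
#' @return Object of class `fact8d_model_spec`.
#' @seealso [merge_levels()], [merge_to_reference()], [n_parameters()],
#'   [published_constrained_spec()]
#' @export
model_spec <- function(groups) {
  dims <- fact8d_dimensions()
  stopifnot(setequal(names(groups), dims))
  for (d in dims) {
    covered <- sort(unlist(lapply(groups[[d]], `[[`, "levels")))
    if (!identical(as.integer(covered), 2:5)) {
      stop("groups for ", d, " must partition levels 2..5", call. = FALSE)
    }
    for (g in groups[[d]]) {
      lv <- sort(g$levels)
      if (!all(diff(lv) == 1)) {
        stop("group levels must be contiguous (", d, ")", call. = FALSE)
      }
    }
  }
  groups <- lapply(groups[dims], function(gs) {
    gs[order(vapply(gs, function(g) min(g$levels), numeric(1)))]
  })
  structure(list(groups = groups), class = "fact8d_model_spec")
}

#' @describeIn model_spec The unconstrained spec: one coefficient per level
#'   2-5 of every dimension (33 free parameters).
#' @export
default_model_spec <- function() {
  dims <- fact8d_dimensions()
  g <- lapply(dims, function(d) {
    lapply(2:5, function(l) list(levels = l, reference = FALSE))
  })
  names(g) <- dims
  model_spec(g)
}

#' Collapse levels in a model spec
#'
#' `merge_levels()` fuses the groups covering the given (adjacent) levels of
#' one dimension into a single shared coefficient; `merge_to_reference()`
#' fixes them at the reference (coefficient 0).
#'
#' @param spec A [model_spec()].
#' @param dimension Dimension name.
#' @param levels Levels (within 2..5) to collapse; the union of the groups
#'   they touch must be contiguous.
#' @return The modified spec.
#' @export
merge_levels <- function(spec, dimension, levels) {
  alter_groups(spec, dimension, levels, reference = FALSE)
}

#' @rdname merge_levels
#' @export
merge_to_reference <- function(spec, dimension, levels) {
  alter_groups(spec, dimension, levels, reference = TRUE)
}

alter_groups <- function(spec, dimension, levels, reference) {
  stopifnot(inherits(spec, "fact8d_model_spec"),
            dimension %in% fact8d_dimensions())
  gs <- spec$groups[[dimension]]
  touched <- vapply(gs, function(g) any(g$levels %in% levels), logical(1))
  if (!any(touched)) stop("levels not found in spec", call. = FALSE)
  merged_levels <- sort(unique(unlist(lapply(gs[touched], `[[`, "levels"))))
  ref <- reference || all(vapply(gs[touched], `[[`, logical(1), "reference"))
  new <- c(gs[!touched], list(list(levels = merged_levels, reference = ref)))
  spec$groups[[dimension]] <- new
  model_spec(spec$groups)
}

#' Number of free parameters of a model spec
#' @param spec A [model_spec()].
#' @return Integer: 1 (duration) + number of estimated level groups.
#' @export
n_parameters <- function(spec) {
  1L + sum(vapply(spec$groups, function(gs) {
    sum(!vapply(gs, `[[`, logical(1), "reference"))
  }, integer(1)))
}

# Names of the estimated coefficients, in canonical order: duration first,
# then per dimension the non-reference groups by ascending mildest level.
coef_names <- function(spec) {
  nm <- "duration"
  for (d in fact8d_dimensions()) {
    for (g in spec$groups[[d]]) {
      if (!g$reference) nm <- c(nm, group_name(d, g$levels))
    }
  }
  nm
}

group_name <- function(dimension, levels) {
  lv <- sort(levels)
  lab <- if (length(lv) == 1) lv else paste0(min(lv), "-", max(lv))
  paste0(dimension, ":L", lab)
}

#' @export
print.fact8d_model_spec <- function(x, ...) {
  cat("Conditional logit spec,", n_parameters(x), "free parameters\n")
  for (d in fact8d_dimensions()) {
    lab <- vapply(x$groups[[d]], function(g) {
      paste0("{", paste(g$levels, collapse = ","), "}",
             if (g$reference) "=ref" else "")
    }, character(1))
    cat("  ", format(d, width = 8), paste(lab, collapse = " "), "\n")
  }
  invisible(x)
}

# Map each (dimension, level) to its coefficient column (NA = reference).
level_column_map <- function(spec) {
  nm <- coef_names(spec)
  m <- matrix(NA_integer_, 8, 5, dimnames = list(fact8d_dimensions(), NULL))
  for (d in fact8d_dimensions()) {
    for (g in spec$groups[[d]]) {
      if (!g$reference) m[d, g$levels] <- match(group_name(d, g$levels), nm)
    }
  }
  m
}

#' Expand group coefficients to a full 8 x 5 beta matrix
#'
#' Levels merged to the reference (and level 1) get 0; merged levels share
#' their group's value.
#'
#' @param spec A [model_spec()].
#' @param coefficients Named vector as returned by [fit_clogit()].
#' @return 8 x 5 matrix of per-level coefficients.
#' @export
expand_coefficients <- function(spec, coefficients) {
  cmap <- level_column_map(spec)
  beta <- matrix(0, 8, 5, dimnames = list(fact8d_dimensions(),
                                          paste0("L", 1:5)))
  nm <- coef_names(spec)
  for (d in fact8d_dimensions()) {
    for (l in 2:5) {
      if (!is.na(cmap[d, l])) beta[d, l] <- coefficients[[nm[cmap[d, l]]]]
    }
  }
  beta
}
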