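#' The eight FACT-8D dimensions, in canonical display order
#'
#' The FACT-8D describes health states on eight dimensions drawn from the
#' FACT-G: pain, fatigue (lack of energy), nausea, problems sleeping, problems
#' doing work (including work at home), problems with support from family
#' and/or friends, sadness, and worry that health will get worse. Each
#' dimension is rated on five severity levels, 1 ("Not at all", best) to 5
#' ("Very much", worst). The display order is fixed; it is the order used
#' throughout this package for states, designs, coefficients and value sets.
#'
#' @return Character vector of the eight dimension identifiers.
#' @export
#' @examples
#' fact8d_dimensions()
fact8d_dimensions <- function() {
  c("pain", "fatigue", "nausea", "sleep", "work", "support", "sadness", "worry")
}

#' @rdname fact8d_dimensions
#' @export
fact8d_levels <- function() 1:5

#' The nine FACT-G items feeding the FACT-8D
#'
#' @return Character vector of item identifiers in instrument order.
#' @export
factg_items <- function() {
  c("GP1", "GP2", "GP4", "GF1", "GF5", "GS2", "GS3", "GE1", "GE6")
}

#' Construct and validate a FACT-8D health state
#'
#' A health state is a named integer vector giving the severity level
#' (1 = best, 5 = worst) on each of the eight dimensions.
#'
#' @param pain,fatigue,nausea,sleep,work,support,sadness,worry Integer severity
#'   levels in 1..5.
#' @return Named integer vector of class `fact8d_state`.
#' @export
#' @examples
#' health_state()                    # full health
#' health_state(pain = 5, work = 3)
health_state <- function(pain = 1L, fatigue = 1L, nausea = 1L, sleep = 1L,
                         work = 1L, support = 1L, sadness = 1L, worry = 1L) {
  s <- c(pain = pain, fatigue = fatigue, nausea = nausea, sleep = sleep,
         work = work, support = support, sadness = sadness, worry = worry)
  validate_state(s)
  structure(as.integer(s), names = fact8d_dimensions(), class = "fact8d_state")
}

validate_state <- function(s) {
  if (!all(fact8d_dimensions() %in% names(s))) {
    stop("a health state needs all eight dimensions: missing ",
         paste(setdiff(fact8d_dimensions(), names(s)), collapse = ", "),
         call. = FALSE)
  }
  lv <- unlist(s[fact8d_dimensions()], use.names = FALSE)
  if (anyNA(lv) || !all(lv == as.integer(lv)) || any(lv < 1L) || any(lv > 5L)) {
    stop("dimension levels must be integers in 1..5", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.fact8d_state <- function(x, ...) {
  cat("FACT-8D health state (1 = best, 5 = worst)\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

# Coerce a state-like object (fact8d_state, named vector, one-row data.frame,
# or matrix of states) to an n x 8 integer matrix in canonical column order.
as_state_matrix <- function(state) {
  if (is.data.frame(state)) state <- as.matrix(state[, fact8d_dimensions(), drop = FALSE])
  if (is.matrix(state)) {
    if (!all(fact8d_dimensions() %in% colnames(state))) {
      stop("state matrix must have the eight dimension columns", call. = FALSE)
    }
    m <- state[, fact8d_dimensions(), drop = FALSE]
  } else {
    validate_state(state)
    m <- matrix(as.integer(state[fact8d_dimensions()]), nrow = 1,
                dimnames = list(NULL, fact8d_dimensions()))
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 1L) || any(m > 5L)) {
    stop("dimension levels must be integers in 1..5", call. = FALSE)
  }
  m
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls do not perturb
# user-level reproducibility.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
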