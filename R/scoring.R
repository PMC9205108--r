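#' Map FACT-G item responses to a FACT-8D health state
#'
#' Translates the nine FACT-G items (each scored 0-4) into the eight FACT-8D
#' dimension levels (1 = best .. 5 = worst). Negatively phrased items map
#' directly (`level = score + 1`): GP4 (pain), GP1 (fatigue), GP2 (nausea),
#' GE1 (sadness), GE6 (worry). Positively phrased items are reverse scored
#' (`level = 5 - score`): GF5 (sleeping well) and GF1 (able to work). The
#' support dimension combines GS2 (family support) and GS3 (friend support)
#' by taking the better of the two: `level = 5 - max(GS2, GS3)`.
#'
#' @param responses Named numeric vector or one-row data.frame with elements
#'   GP1, GP2, GP4, GF1, GF5, GS2, GS3, GE1, GE6 (integers 0-4). A multi-row
#'   data.frame maps row-wise and returns a state matrix.
#' @param missing Policy for missing items: `"strict"` (default) refuses to
#'   score and names the offending item(s).
#' @return A [health_state()] (or, for a multi-row input, an n x 8 integer
#'   matrix of levels).
#' @export
#' @examples
#' map_factg_to_state(c(GP1 = 0, GP2 = 0, GP4 = 0, GF1 = 4, GF5 = 4,
#'                      GS2 = 4, GS3 = 4, GE1 = 0, GE6 = 0))  # full health
map_factg_to_state <- function(responses, missing = c("strict")) {
  missing <- match.arg(missing)
  if (is.data.frame(responses) && nrow(responses) > 1) {
    m <- factg_to_level_matrix(responses, missing)
    return(m)
  }
  if (is.data.frame(responses)) responses <- unlist(responses[1, ])
  m <- factg_to_level_matrix(as.data.frame(as.list(responses)), missing)
  structure(as.integer(m[1, ]), names = fact8d_dimensions(),
            class = "fact8d_state")
}

factg_to_level_matrix <- function(df, missing = "strict") {
  need <- factg_items()
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("missing FACT-G item column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sc <- as.matrix(df[, need])
  storage.mode(sc) <- "double"
  if (missing == "strict" && anyNA(sc)) {
    bad <- need[colSums(is.na(sc)) > 0]
    stop("missing FACT-G item score(s) for: ", paste(bad, collapse = ", "),
         " (strict policy refuses to score)", call. = FALSE)
  }
  ok <- is.na(sc) | (sc %in% 0:4)
  if (!all(ok)) {
    bad <- need[colSums(!ok) > 0]
    stop("FACT-G item scores must be integers 0-4; out of range: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lev <- cbind(
    pain    = sc[, "GP4"] + 1,
    fatigue = sc[, "GP1"] + 1,
    nausea  = sc[, "GP2"] + 1,
    sleep   = 5 - sc[, "GF5"],
    work    = 5 - sc[, "GF1"],
    support = 5 - pmax(sc[, "GS2"], sc[, "GS3"]),
    sadness = sc[, "GE1"] + 1,
    worry   = sc[, "GE6"] + 1
  )
  storage.mode(lev) <- "integer"
  lev
}

#' Score a FACT-8D health state to a utility
#'
#' Utility is additive over dimensions:
#' `U = 1 - sum_d w[d, l(d)]`, where `w[d, l]` is the value set's decrement
#' for level `l` of dimension `d`. Full precision is kept; round only for
#' reporting.
#'
#' @param state A [health_state()], named level vector, or an n x 8
#'   matrix/data.frame of levels for vectorised scoring.
#' @param valueset A [value_set()].
#' @return Numeric utility (vector for matrix input); 1 is full health, 0 as
#'   bad as dead, negative worse than dead.
#' @export
#' @examples
#' score_state(health_state(), canadian_value_set())           # 1
#' score_state(health_state(pain = 3), canadian_value_set())   # 0.923
score_state <- function(state, valueset) {
  stopifnot(inherits(valueset, "fact8d_value_set"))
  m <- as_state_matrix(state)
  w <- valueset$decrements
  tot <- numeric(nrow(m))
  for (d in fact8d_dimensions()) tot <- tot + w[d, m[, d]]
  1 - tot
}

#' Score FACT-G item responses directly to a utility
#'
#' Convenience composition of [map_factg_to_state()] and [score_state()].
#'
#' @inheritParams map_factg_to_state
#' @inheritParams score_state
#' @return Numeric utility (vector for a multi-row data.frame).
#' @export
score_factg <- function(responses, valueset, missing = "strict") {
  if (is.data.frame(responses) && nrow(responses) != 1) {
    lev <- factg_to_level_matrix(responses, missing)
    return(score_state(lev, valueset))
  }
  score_state(map_factg_to_state(responses, missing), valueset)
}

#' Utilities of every describable FACT-8D state
#'
#' Enumerates all `5^8 = 390,625` states of the classification and scores
#' each; mainly used to verify the scoring range (`[pits, 1]`) and, for
#' monotone sets, that worsening any single dimension never raises utility.
#'
#' @inheritParams score_state
#' @return Data frame with the eight level columns and a `utility` column.
#' @export
enumerate_state_utilities <- function(valueset) {
  grid <- expand.grid(rep(list(1:5), 8), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- fact8d_dimensions()
  grid$utility <- score_state(grid, valueset)
  grid
}

#' Score a CSV of FACT-G responses to utilities
#'
#' Reads a CSV with one row per individual and columns
#' `GP1,GP2,GP4,GF1,GF5,GS2,GS3,GE1,GE6` (integers 0-4, blank = missing),
#' appends a `utility` column and writes the result. Rows that cannot be
#' scored (missing or out-of-range items) get `NA` utility and are reported,
#' not fatal.
#'
#' @param responses_file Input CSV path.
#' @param valueset A [value_set()], the name `"canada"`, or a path to a value
#'   set JSON/CSV.
#' @param out_file Output CSV path; default appends `_scored` to the input
#'   name.
#' @return Invisibly, a list with the scored data frame (`data`), a data.frame
#'   of row-level `errors`, and summary statistics of the utilities.
#' @export
score_factg_file <- function(responses_file, valueset = "canada",
                             out_file = NULL) {
  vs <- resolve_value_set(valueset)
  if (is.null(out_file)) {
    out_file <- sub("(\\.[^.]*)?$", "_scored.csv",
                    sub("\\.csv$", "", responses_file, ignore.case = TRUE))
  }
  df <- utils::read.csv(responses_file, stringsAsFactors = FALSE)
  errors <- data.frame(row = integer(), message = character())
  if (nrow(df) == 0) {
    warning("no response rows in ", responses_file, call. = FALSE)
    df$utility <- numeric(0)
  } else {
    df$utility <- vapply(seq_len(nrow(df)), function(i) {
      u <- tryCatch(score_factg(df[i, , drop = FALSE], vs),
                    error = function(e) {
                      errors[nrow(errors) + 1L, ] <<-
                        list(row = i, message = conditionMessage(e))
                      NA_real_
                    })
      as.numeric(u)
    }, numeric(1))
  }
  utils::write.csv(df, out_file, row.names = FALSE)
  u <- df$utility[!is.na(df$utility)]
  summary <- if (length(u)) {
    c(n = length(u), mean = mean(u), min = min(u), max = max(u))
  } else {
    c(n = 0, mean = NA, min = NA, max = NA)
  }
  invisible(list(data = df, errors = errors, summary = summary,
                 out_file = out_file))
}

resolve_value_set <- function(valueset) {
  if (inherits(valueset, "fact8d_value_set")) return(valueset)
  if (is.character(valueset) && length(valueset) == 1) {
    if (tolower(valueset) %in% c("canada", "canadian")) {
      return(canadian_value_set())
    }
    if (file.exists(valueset)) return(read_value_set(valueset))
  }
  stop("valueset must be a fact8d_value_set, \"canada\", or a file path",
       call. = FALSE)
}
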