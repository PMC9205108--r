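#' Permitted survival durations in the choice task
#'
#' Each alternative in a choice set pairs a FACT-8D health state with a
#' survival duration drawn from four levels: 1, 2, 5 or 10 years.
#'
#' @return Integer vector of permitted durations (years).
#' @export
duration_levels <- function() c(1L, 2L, 5L, 10L)

#' Generate a partial-profile DCE design
#'
#' Builds blocks of binary choice sets over the nine attributes (eight
#' FACT-8D dimensions plus survival duration). To limit task complexity only
#' `n_differ` attributes differ between the two alternatives of a set (the
#' differing attributes would be highlighted to the respondent); the remaining
#' dimensions are held equal at a common level drawn once per set. Levels for
#' the differing attributes are chosen by randomised level-balanced search:
#' `n_candidates` candidate blocks are drawn and the one whose attribute-level
#' frequencies deviate least from uniform (sum of squared deviations) is kept.
#' The published design matrix of the Canadian study is not public; this
#' generator reproduces its structural constraints, and [read_design_csv()]
#' ingests an externally supplied design for users who have one.
#'
#' @param n_blocks Number of 16-set blocks (>= 1).
#' @param seed Integer seed; the same seed yields the identical design.
#' @param n_sets Choice sets per block (default 16).
#' @param n_differ Number of attributes differing within a set (default 5).
#' @param require_duration_differs If `TRUE` (default) duration is always one
#'   of the differing attributes, so `n_differ - 1` dimensions differ.
#' @param n_candidates Candidate blocks scored per retained block.
#' @return Object of class `fact8d_design`: a data.frame with columns
#'   `block`, `set`, `alt` ("A"/"B"), `duration`, the eight dimension levels,
#'   and per-attribute `differs.*` highlight flags; attributes `seed` and
#'   `balance` (the balance score of each retained block).
#' @export
#' @examples
#' d <- generate_design(n_blocks = 1, seed = 7)
#' validate_design(d)$n_violations
generate_design <- function(n_blocks = 1, seed = 1, n_sets = 16, n_differ = 5,
                            require_duration_differs = TRUE,
                            n_candidates = 20) {
  stopifnot(n_blocks >= 1, n_sets >= 1)
  dims <- fact8d_dimensions()
  if (n_differ > length(dims) + 1) {
    stop("at most ", length(dims) + 1, " attributes can differ (8 dimensions",
         " + duration)", call. = FALSE)
  }
  if (n_differ < 2) stop("n_differ must be at least 2", call. = FALSE)
  n_dim_differ <- if (require_duration_differs) n_differ - 1 else NULL
  if (!is.null(n_dim_differ) && n_dim_differ > length(dims)) {
    stop("n_differ too large when duration must differ", call. = FALSE)
  }

  with_seed(seed, {
    blocks <- vector("list", n_blocks)
    balance <- numeric(n_blocks)
    for (b in seq_len(n_blocks)) {
      cands <- replicate(n_candidates,
                         random_block(b, n_sets, n_differ,
                                      require_duration_differs),
                         simplify = FALSE)
      scores <- vapply(cands, block_balance_score, numeric(1))
      best <- which.min(scores)
      blocks[[b]] <- cands[[best]]
      balance[b] <- scores[best]
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    structure(out, seed = seed, balance = balance,
              class = c("fact8d_design", "data.frame"))
  })
}

# One random block satisfying the structural constraints.
random_block <- function(block, n_sets, n_differ, require_duration_differs) {
  dims <- fact8d_dimensions()
  lev_a <- lev_b <- matrix(0L, n_sets, 8, dimnames = list(NULL, dims))
  dur <- matrix(0L, n_sets, 2)
  flags <- matrix(FALSE, n_sets, 9,
                  dimnames = list(NULL, c("duration", dims)))
  for (s in seq_len(n_sets)) {
    if (require_duration_differs) {
      dur_differs <- TRUE
    } else {
      dur_differs <- runif(1) < n_differ / 9
    }
    nd <- n_differ - dur_differs
    diff_dims <- sample(dims, nd)
    shared <- setdiff(dims, diff_dims)
    common <- sample(1:5, length(shared), replace = TRUE)
    lev_a[s, shared] <- lev_b[s, shared] <- common
    for (d in diff_dims) {
      pair <- sample(1:5, 2)            # without replacement: levels differ
      lev_a[s, d] <- pair[1]; lev_b[s, d] <- pair[2]
    }
    dur[s, ] <- if (dur_differs) sample(duration_levels(), 2) else
      rep(sample(duration_levels(), 1), 2)
    flags[s, ] <- c(dur_differs, dims %in% diff_dims)
  }
  # interleave A/B rows per set
  lev <- matrix(0L, 2 * n_sets, 8, dimnames = list(NULL, dims))
  lev[seq(1, 2 * n_sets, 2), ] <- lev_a
  lev[seq(2, 2 * n_sets, 2), ] <- lev_b
  out <- data.frame(block = block, set = rep(seq_len(n_sets), each = 2),
                    alt = rep(c("A", "B"), n_sets),
                    duration = as.integer(t(dur)), lev)
  fl <- flags[rep(seq_len(n_sets), each = 2), , drop = FALSE]
  colnames(fl) <- paste0("differs.", colnames(fl))
  cbind(out, as.data.frame(fl))
}

# Sum over attributes of squared deviation of level frequencies from uniform.
block_balance_score <- function(block) {
  score <- 0
  for (d in fact8d_dimensions()) {
    f <- tabulate(block[[d]], 5) / nrow(block)
    score <- score + sum((f - 1 / 5)^2)
  }
  fd <- vapply(duration_levels(), function(t) mean(block$duration == t),
               numeric(1))
  score + sum((fd - 1 / 4)^2)
}

#' Validate a DCE design against the structural constraints
#'
#' Checks every choice set: exactly two alternatives; the stated number of
#' differing attributes; duration drawn from [duration_levels()]; dimension
#' levels in 1..5; highlight flags consistent with the attributes that
#' actually differ. Violations are reported, not thrown.
#'
#' @param design A `fact8d_design` (or equivalent data.frame).
#' @param n_differ Expected number of differing attributes per set.
#' @return List with `violations` (data.frame: block, set, problem),
#'   `n_violations`, `differ_counts` per set, `duration_usage`, and
#'   `level_frequencies` per dimension.
#' @export
validate_design <- function(design, n_differ = 5) {
  dims <- fact8d_dimensions()
  viol <- list()
  note <- function(b, s, msg) {
    viol[[length(viol) + 1L]] <<- data.frame(block = b, set = s, problem = msg)
  }
  key <- interaction(design$block, design$set, drop = TRUE)
  differ_counts <- data.frame(block = integer(), set = integer(),
                              n_differ = integer())
  for (k in levels(key)) {
    rows <- design[key == k, , drop = FALSE]
    b <- rows$block[1]; s <- rows$set[1]
    if (nrow(rows) != 2) {
      note(b, s, paste0(nrow(rows), " alternatives (need 2)"))
      next
    }
    if (!all(rows$duration %in% duration_levels())) {
      note(b, s, paste0("duration not in {",
                        paste(duration_levels(), collapse = ", "), "}: ",
                        paste(setdiff(rows$duration, duration_levels()),
                              collapse = ", ")))
    }
    lev <- as.matrix(rows[, dims])
    if (any(lev < 1 | lev > 5)) note(b, s, "dimension level outside 1..5")
    nd <- sum(lev[1, ] != lev[2, ]) + (rows$duration[1] != rows$duration[2])
    differ_counts[nrow(differ_counts) + 1L, ] <- list(b, s, nd)
    if (nd != n_differ) {
      note(b, s, paste0(nd, " attributes differ (need ", n_differ, ")"))
    }
    fl <- grep("^differs\\.", names(rows), value = TRUE)
    if (length(fl)) {
      actual <- c(duration = rows$duration[1] != rows$duration[2],
                  stats::setNames(lev[1, ] != lev[2, ], dims))
      claimed <- unlist(rows[1, fl])
      names(claimed) <- sub("^differs\\.", "", fl)
      off <- names(actual)[actual[names(claimed)] != claimed]
      if (length(off)) {
        note(b, s, paste0("highlight flag mismatch: ",
                          paste(off, collapse = ", ")))
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(block = integer(), set = integer(), problem = character())
  freq <- sapply(dims, function(d) tabulate(design[[d]], 5) / nrow(design))
  rownames(freq) <- paste0("L", 1:5)
  list(violations = violations, n_violations = nrow(violations),
       differ_counts = differ_counts,
       duration_usage = table(factor(design$duration,
                                     levels = duration_levels())),
       level_frequencies = freq)
}

#' Randomise which alternative is shown as Situation A
#'
#' Swaps the A/B labels of each choice set independently with probability 1/2,
#' leaving attribute order untouched; which alternative a respondent sees
#' first carries no information, and estimation is invariant to the swap.
#'
#' @param design A `fact8d_design`.
#' @param seed Integer seed.
#' @return The design with labels swapped per the seeded pattern; the logical
#'   swap pattern is attached as attribute `swapped`.
#' @export
randomize_presentation <- function(design, seed = 1) {
  key <- interaction(design$block, design$set, drop = TRUE)
  sets <- levels(key)
  swap <- with_seed(seed, runif(length(sets)) < 0.5)
  names(swap) <- sets
  alt <- as.character(design$alt)
  flip <- swap[as.character(key)]
  alt[flip] <- c(A = "B", B = "A")[alt[flip]]
  design$alt <- alt
  ord <- order(design$block, design$set, design$alt)
  out <- design[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- attr(design, "seed")
  attr(out, "balance") <- attr(design, "balance")
  attr(out, "swapped") <- swap
  class(out) <- class(design)
  out
}

#' Read and write design CSV files
#'
#' The exchange format is one row per set x alternative with columns `block`,
#' `set`, `alt`, `duration` and the eight dimension levels; `differs.*`
#' highlight columns are optional and preserved when present.
#'
#' @param path CSV path.
#' @param design A `fact8d_design`.
#' @return `read_design_csv()` a `fact8d_design`; `write_design_csv()` the
#'   path, invisibly.
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "set", "alt", "duration", fact8d_dimensions())
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("design file lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  structure(df, class = c("fact8d_design", "data.frame"))
}

#' @rdname read_design_csv
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}
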