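test_that("FACT-G items map to dimension levels with correct phrasing direction", {
  # all-best responses: direct items at 0, reverse-scored items at 4
  s <- map_factg_to_state(best_responses())
  expect_s3_class(s, "fact8d_state")
  expect_true(all(s == 1L))

  # all-worst responses
  expect_true(all(map_factg_to_state(worst_responses()) == 5L))

  # direct (negatively phrased) items: level = score + 1
  r <- best_responses(); r["GP4"] <- 2
  expect_equal(map_factg_to_state(r)[["pain"]], 3L)
  r <- best_responses(); r["GE6"] <- 3
  expect_equal(map_factg_to_state(r)[["worry"]], 4L)

  # reverse-scored items: level = 5 - score
  r <- best_responses(); r["GF5"] <- 1
  expect_equal(map_factg_to_state(r)[["sleep"]], 4L)
  r <- best_responses(); r["GF1"] <- 2
  expect_equal(map_factg_to_state(r)[["work"]], 3L)
})

test_that("support takes the better of GS2 and GS3", {
  r <- best_responses(); r["GS2"] <- 1; r["GS3"] <- 3
  s <- map_factg_to_state(r)
  expect_equal(s[["support"]], 2L)          # 5 - max(1, 3)
  expect_true(all(s[setdiff(fact8d_dimensions(), "support")] == 1L))

  # symmetric in the two items
  r2 <- best_responses(); r2["GS2"] <- 3; r2["GS3"] <- 1
  expect_equal(map_factg_to_state(r2)[["support"]], 2L)

  # all 25 (GS2, GS3) pairs land on the 5 levels via the max rule
  for (g2 in 0:4) for (g3 in 0:4) {
    r <- best_responses(); r["GS2"] <- g2; r["GS3"] <- g3
    expect_equal(map_factg_to_state(r)[["support"]], 5L - max(g2, g3))
  }
})

test_that("mapping is a bijection on the grid for single-item dimensions", {
  items <- c(pain = "GP4", fatigue = "GP1", nausea = "GP2", sadness = "GE1",
             worry = "GE6", sleep = "GF5", work = "GF1")
  reversed <- c("sleep", "work")
  for (d in names(items)) {
    seen <- integer()
    for (score in 0:4) {
      r <- best_responses(); r[items[[d]]] <- score
      seen <- c(seen, map_factg_to_state(r)[[d]])
    }
    expect_setequal(seen, 1:5)
    expect_equal(seen, if (d %in% reversed) 5:1 else 1:5)
  }
})

test_that("strict missing policy refuses and names the item; range checks", {
  r <- best_responses(); r["GS3"] <- NA
  expect_error(map_factg_to_state(r), "GS3")
  r <- as.list(best_responses()); r$GE1 <- NULL
  expect_error(map_factg_to_state(as.data.frame(r)), "GE1")
  r <- best_responses(); r["GP1"] <- 7
  expect_error(map_factg_to_state(r), "GP1")
  expect_error(health_state(pain = 6), "1..5")
  expect_error(health_state(pain = 0), "1..5")
})

test_that("scoring reproduces the anchor utilities of the Canadian set", {
  cvs <- canadian_value_set()
  expect_identical(score_state(health_state(), cvs), 1)
  expect_equal(score_state(worst_state(), cvs), -0.652, tolerance = 1e-12)
  expect_equal(round(score_state(worst_state(), cvs), 2), -0.65)
  expect_equal(score_state(health_state(pain = 3), cvs), 1 - 0.077)
  expect_equal(score_factg(best_responses(), cvs), 1)
  expect_equal(score_factg(worst_responses(), cvs), -0.652)
  r <- best_responses(); r["GP4"] <- 4
  expect_equal(score_factg(r, cvs), 1 - 0.384)
})

test_that("scoring is additive over dimensions", {
  cvs <- canadian_value_set()
  set.seed(42)
  for (i in 1:25) {
    lv <- sample(1:5, 8, replace = TRUE)
    s1 <- do.call(health_state,
                  as.list(stats::setNames(lv, fact8d_dimensions())))
    d <- sample(fact8d_dimensions(), 1)
    new_l <- sample(setdiff(1:5, s1[[d]]), 1)
    s2 <- s1; s2[[d]] <- new_l
    expect_equal(score_state(s1, cvs) - score_state(s2, cvs),
                 cvs$decrements[d, new_l] - cvs$decrements[d, s1[[d]]])
  }
})

test_that("pits equals one minus the sum of worst decrements", {
  expect_equal(pits(canadian_value_set()), 1 - 1.652, tolerance = 1e-12)
  zero <- value_set(matrix(0, 8, 5,
                           dimnames = list(fact8d_dimensions(), NULL)))
  expect_identical(pits(zero), 1)
  one <- zero$decrements; one["pain", 5] <- 0.5
  expect_equal(pits(value_set(one)), 0.5)
  # pits is the minimum over the full state space, 1 the maximum
  cvs <- canadian_value_set()
  expect_equal(score_state(worst_state(), cvs), pits(cvs))
})

test_that("value sets round-trip through JSON and CSV", {
  cvs <- canadian_value_set()
  j <- tempfile(fileext = ".json"); csv <- tempfile(fileext = ".csv")
  write_value_set(cvs, j, digits = NA)
  write_value_set(cvs, csv, digits = NA)
  expect_equal(read_value_set(j)$decrements, cvs$decrements)
  expect_equal(read_value_set(csv)$decrements, cvs$decrements)
  expect_equal(read_value_set(j)$label, cvs$label)
  # 3-dp export rounding is applied at the boundary only
  vs <- value_set(cvs$decrements + 1e-5 * (cvs$decrements > 0))
  write_value_set(vs, j, digits = 3)
  expect_equal(read_value_set(j)$decrements, round(vs$decrements, 3))
  unlink(c(j, csv))
})

test_that("non-monotone and negative decrements are flagged, not rejected", {
  dec <- canadian_value_set()$decrements
  dec["worry", 3] <- 0.05                # below level 2: reversal
  vs <- value_set(dec)
  expect_false(vs$monotone)
  expect_true(any(vs$violations$dimension == "worry"))
  dec["fatigue", 2] <- -0.01             # negative decrement
  vs2 <- value_set(dec)
  expect_true(any(vs2$violations$kind == "negative decrement"))
  # level 1 must still be zero
  dec2 <- canadian_value_set()$decrements; dec2[1, 1] <- 0.1
  expect_error(value_set(dec2), "level 1")
})

test_that("shipped value-set files mirror the packaged fixture", {
  j <- system.file("extdata", "canadian_value_set.json", package = "fact8d")
  expect_true(nzchar(j))
  expect_equal(read_value_set(j)$decrements, canadian_value_set()$decrements)
  csv <- system.file("extdata", "canadian_value_set.csv", package = "fact8d")
  expect_equal(read_value_set(csv)$decrements,
               round(canadian_value_set()$decrements, 3))
})
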