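test_that("regressors interact every active level dummy with duration", {
  ch <- tiny_choices()
  x <- build_regressors(ch)
  expect_equal(colnames(x)[1], "duration")
  expect_equal(ncol(x), 33)
  # all-level-1 state at t = 1: only the duration column is nonzero
  i_ref <- which(ch$resp_id == 1 & ch$set_id == 1 & ch$alt == "B")
  expect_equal(unname(x[i_ref, "duration"]), 1)
  expect_true(all(x[i_ref, -1] == 0))
  # pain level 5 at t = 10: the pain worst column carries t
  i_pain <- which(ch$resp_id == 1 & ch$set_id == 1 & ch$alt == "A")
  expect_equal(unname(x[i_pain, "pain:L5"]), 10)
  expect_equal(unname(x[i_pain, "duration"]), 10)
  expect_equal(sum(x[i_pain, ] != 0), 2)

  # a spec merging work levels 3 and 4: one shared column receives t
  spec <- merge_levels(default_model_spec(), "work", 3:4)
  xm <- build_regressors(ch, spec)
  i_work <- which(ch$resp_id == 1 & ch$set_id == 2 & ch$alt == "A")
  expect_equal(unname(xm[i_work, "work:L3-4"]), 2)
  ch4 <- ch; ch4$work[i_work] <- 4L; ch4$duration[i_work] <- 7
  expect_equal(unname(build_regressors(ch4, spec)[i_work, "work:L3-4"]), 7)
  # merged-to-reference levels contribute nothing
  spec_ref <- merge_to_reference(default_model_spec(), "pain", 2:5)
  xr <- build_regressors(ch, spec_ref)
  expect_false(any(grepl("^pain", colnames(xr))))
})

test_that("model specs count parameters and enforce contiguity", {
  expect_equal(n_parameters(default_model_spec()), 33)  # 1 + 8 x 4
  expect_equal(n_parameters(published_constrained_spec()), 23)
  expect_error(merge_levels(default_model_spec(), "pain", c(2, 5)),
               "contiguous")
  s <- merge_levels(default_model_spec(), "sleep", 4:5)
  expect_equal(n_parameters(s), 32)
  expect_equal(n_parameters(merge_to_reference(s, "sleep", 2:3)), 30)
})

test_that("log-likelihood closed forms and analytic gradient", {
  ch <- small_sim()$choices
  k <- 33
  m <- length(unique(paste(ch$resp_id, ch$set_id)))
  # zero parameters: every set contributes log(1/2)
  ll0 <- loglik_clogit(numeric(k), ch)
  expect_equal(ll0$value, m * log(0.5), tolerance = 1e-12)
  # the 16-set case printed in closed form
  one <- ch[ch$resp_id == ch$resp_id[1], ]
  expect_equal(loglik_clogit(numeric(k), one)$value, 16 * log(0.5),
               tolerance = 1e-12)
  expect_equal(round(16 * log(0.5), 4), -11.0904)

  # analytic gradient vs central finite differences at random parameters
  set.seed(14)
  theta <- rnorm(k, sd = 0.05)
  sub <- ch[ch$resp_id %in% unique(ch$resp_id)[1:40], ]
  g <- loglik_clogit(theta, sub)$gradient
  h <- 1e-6
  g_num <- vapply(seq_len(k), function(j) {
    e <- numeric(k); e[j] <- h
    (loglik_clogit(theta + e, sub)$value -
       loglik_clogit(theta - e, sub)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - g_num)), 1e-4)   # FD noise at sums of ~600 terms
  expect_lt(max(abs(g - g_num)) / max(abs(g)), 1e-6)

  # doubling all weights doubles value and gradient exactly
  ids <- unique(sub$resp_id)
  w1 <- stats::setNames(rep(1, length(ids)), ids)
  w2 <- stats::setNames(rep(2, length(ids)), ids)
  l1 <- loglik_clogit(theta, sub, weights = w1)
  l2 <- loglik_clogit(theta, sub, weights = w2)
  expect_identical(l2$value, 2 * l1$value)
  expect_identical(l2$gradient, 2 * l1$gradient)
  # and the unweighted objective is the all-ones weighted one, bit for bit
  expect_identical(loglik_clogit(theta, sub)$value, l1$value)
})

test_that("fitting converges to the clogit MLE with correct information criteria", {
  sim <- small_sim()
  fit <- fit_clogit(sim$choices)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-6)
  expect_equal(fit$k, 33)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(fit$bic, fit$k * log(fit$n_obs) - 2 * fit$loglik)
  expect_equal(fit$n_obs, nrow(sim$choices) / 2)
  # covariance is symmetric positive semidefinite
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  # unweighted fit equals all-ones weighted fit in the objective
  ids <- unique(sim$choices$resp_id)
  fit_w1 <- fit_clogit(sim$choices,
                       weights = stats::setNames(rep(1, length(ids)), ids))
  expect_identical(fit_w1$loglik, fit$loglik)
  expect_equal(fit_w1$coefficients, fit$coefficients)
})

test_that("estimates agree with survival::clogit (independent implementation)", {
  skip_if_not_installed("survival")
  library(survival)        # clogit dispatches to coxph in the search path
  sim <- small_sim()
  ch <- sim$choices[sim$choices$resp_id %in%
                      unique(sim$choices$resp_id)[1:150], ]
  fit <- fit_clogit(ch)
  x <- build_regressors(ch)
  df <- data.frame(chosen = ch$chosen,
                   strat = paste(ch$resp_id, ch$set_id),
                   id = ch$resp_id, x, check.names = TRUE)
  terms <- paste(colnames(df)[-(1:3)], collapse = " + ")
  ref <- survival::clogit(
    stats::as.formula(paste("chosen ~", terms,
                            "+ strata(strat) + cluster(id)")),
    data = df, method = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("estimates are invariant to A/B relabeling", {
  sim <- small_sim()
  ch <- sim$choices[sim$choices$resp_id %in%
                      unique(sim$choices$resp_id)[1:100], ]
  flipped <- ch
  flipped$alt <- c(A = "B", B = "A")[ch$alt]
  fit <- fit_clogit(ch)
  fitf <- fit_clogit(flipped)
  expect_equal(fitf$coefficients, fit$coefficients, tolerance = 1e-8)
  expect_equal(fitf$loglik, fit$loglik, tolerance = 1e-10)
})

test_that("likelihood only sees within-set differences", {
  sim <- small_sim()
  ch <- sim$choices[sim$choices$resp_id %in%
                      unique(sim$choices$resp_id)[1:50], ]
  set.seed(77)
  theta <- rnorm(33, sd = 0.05)
  # with equal durations, perturbing a dimension the two alternatives share
  # changes both sides identically: the difference -- and hence the
  # likelihood -- is untouched (shared levels only cancel when durations
  # match, because duration multiplies the dummies)
  key <- paste(ch$resp_id, ch$set_id)
  ch$duration <- ave(ch$duration, key, FUN = function(x) x[1])
  ch2 <- ch
  for (k in unique(key)) {
    i <- which(key == k)
    shared <- fact8d_dimensions()[sapply(fact8d_dimensions(), function(d)
      ch[i[1], d] == ch[i[2], d])]
    d <- shared[1]
    ch2[i, d] <- (ch[i[1], d] %% 5L) + 1L
  }
  expect_false(identical(ch2, ch))
  ll1 <- loglik_clogit(theta, ch)
  ll2 <- loglik_clogit(theta, ch2)
  expect_equal(ll2$value, ll1$value, tolerance = 1e-10)
})

test_that("one observation per cluster reduces the sandwich to HC robust", {
  sim <- small_sim()
  # each respondent contributes a single set, varied across respondents; a
  # compact spec (levels 2-5 pooled per dimension) keeps the model
  # identified on so few sets
  keep_set <- (sim$choices$resp_id %% 16L) + 1L
  ch <- sim$choices[sim$choices$set_id == keep_set, ]
  spec <- default_model_spec()
  for (d in fact8d_dimensions()) spec <- merge_levels(spec, d, 2:5)
  fit <- fit_clogit(ch, spec)
  # HC sandwich computed directly from per-set scores
  x <- build_regressors(ch, spec)
  is_a <- ch$alt == "A"
  d <- x[is_a, ] - x[!is_a, ]
  y <- ch$chosen[is_a]
  p <- stats::plogis(drop(d %*% fit$coefficients))
  info <- crossprod(d * (p * (1 - p)), d)
  meat <- crossprod(d * (y - p))
  hc <- solve(info) %*% meat %*% solve(info)
  expect_equal(unname(fit$vcov), unname(hc), tolerance = 1e-8)
})

test_that("degenerate and mismatched inputs are refused", {
  ch <- tiny_choices()
  one_sided <- ch
  one_sided$chosen <- ifelse(one_sided$alt == "A", 1, 0)
  expect_error(fit_clogit(one_sided), "degenerate")
  expect_error(loglik_clogit(numeric(5), ch), "length")
})

test_that("likelihood-ratio test: statistic, df, p-value, guards", {
  sim <- small_sim()
  ch <- sim$choices[sim$choices$resp_id %in%
                      unique(sim$choices$resp_id)[1:120], ]
  full <- fit_clogit(ch)
  nested <- fit_clogit(ch, published_constrained_spec())
  lr <- lr_test(nested, full)
  expect_equal(lr$statistic, 2 * (full$loglik - nested$loglik))
  expect_equal(lr$df, 10)
  expect_equal(lr$df, full$k - nested$k)
  expect_equal(lr$p_value,
               pchisq(lr$statistic, 10, lower.tail = FALSE))
  # the closed-form textbook case: LL -100 vs -98 with 2 df
  f1 <- full; f1$loglik <- -100; f1$k <- 31
  f2 <- full; f2$loglik <- -98
  lr2 <- lr_test(f1, f2)
  expect_equal(lr2$statistic, 4)
  expect_equal(lr2$p_value, exp(-2), tolerance = 1e-12)
  # identical fits: statistic 0, p = 1
  f3 <- full; f3$k <- 32
  lr3 <- lr_test(f3, full)
  expect_equal(lr3$statistic, 0)
  expect_equal(lr3$p_value, 1)
  # different data are refused
  other <- fit_clogit(sim$choices[sim$choices$resp_id %in%
                                    unique(sim$choices$resp_id)[1:119], ],
                      published_constrained_spec())
  expect_error(lr_test(other, full), "different")
})

test_that("estimation error shrinks with sample size (consistency)", {
  design <- generate_design(n_blocks = 8, seed = 51)
  prefs <- published_model_coefficients(3)
  truth <- c(prefs$alpha, unlist(lapply(fact8d_dimensions(),
                                        function(d) prefs$beta[d, 2:5])))
  rmse <- vapply(c(100, 400, 1600), function(n) {
    ch <- simulate_choices(design, prefs, n, seed = 52, completion = NULL)
    fit <- fit_clogit(ch)
    sqrt(mean((fit$coefficients - truth)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
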