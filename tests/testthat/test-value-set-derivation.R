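test_that("violation detection on the published weighted (Model 2) coefficients", {
  viol <- detect_violations(published_model_coefficients(2))
  # positive coefficients: sleep levels 2 (+0.024) and 3 (+0.036)
  pos <- viol[viol$kind == "positive", ]
  expect_true(all(c("2", "3") %in% pos$group[pos$dimension == "sleep"]))
  # reversed adjacent pairs: support 3 vs 2 and worry 3 vs 2
  rev <- viol[viol$kind == "reversal", ]
  expect_true(any(rev$dimension == "support" & rev$group == "3" &
                    rev$milder_group == "2"))
  expect_true(any(rev$dimension == "worry" & rev$group == "3" &
                    rev$milder_group == "2"))
  # pain level 2 (+0.014) is positive too
  expect_true(any(pos$dimension == "pain" & pos$group == "2"))
  # ordering: mildest first within dimension, canonical dimension order
  expect_false(is.unsorted(match(viol$dimension, fact8d_dimensions())))
})

test_that("strictly decreasing coefficients yield no violations; constructed reversals are caught", {
  clean <- true_preferences(0.3, cbind(0, -sweep(matrix(1:4, 8, 4,
                                                        byrow = TRUE),
                                                 1, 1:8 / 100, "*")))
  expect_equal(nrow(detect_violations(clean)), 0)

  beta <- matrix(0, 8, 5, dimnames = list(fact8d_dimensions(), NULL))
  beta[, 2:5] <- -0.1
  beta["worry", 4] <- -0.05
  beta["worry", 5] <- -0.03            # L5 above L4: one reversal
  one <- detect_violations(true_preferences(0.3, beta))
  expect_equal(nrow(one[one$kind == "reversal", ]), 2)  # L4>L3 and L5>L4
  expect_true(any(one$dimension == "worry" & one$group == "5" &
                    one$milder_group == "4"))
})

test_that("constraining simulated data reaches a monotone fit with lower LL", {
  sim <- small_sim()
  ch <- sim$choices
  full <- fit_clogit(ch)
  cons <- constrain(ch)
  expect_equal(nrow(detect_violations(cons$fit)), 0)
  expect_lte(cons$fit$loglik, full$loglik + 1e-8)
  expect_lt(cons$fit$k, full$k + 1)
  # LR statistic vs the unconstrained model is >= 0 by nestedness
  if (cons$fit$k < full$k) {
    expect_gte(lr_test(cons$fit, full)$statistic, 0)
  }
  # merge history records every applied merge
  n_merges <- sum(lengths(lapply(cons$history, `[[`, "merges")))
  expect_equal(cons$fit$k, 33 - (33 - n_parameters(cons$spec)))
  expect_gte(n_merges, 33 - cons$fit$k)
})

test_that("constraining a monotone fit is idempotent", {
  sim <- small_sim()
  sub <- sim$choices[sim$choices$resp_id %in%
                       unique(sim$choices$resp_id)[1:200], ]
  cons1 <- constrain(sub)
  cons2 <- constrain(sub, cons1$spec)
  expect_equal(cons2$fit$k, cons1$fit$k)
  expect_length(cons2$history, 0)
  expect_equal(cons2$fit$coefficients, cons1$fit$coefficients,
               tolerance = 1e-8)
})

test_that("forced merges reproduce the published collapsing pattern", {
  merges <- list(
    list(dimension = "pain", levels = 2, to_reference = TRUE),
    list(dimension = "sleep", levels = 2:3, to_reference = TRUE),
    list(dimension = "sleep", levels = 4:5),
    list(dimension = "work", levels = 3:4),
    list(dimension = "support", levels = 2:3),
    list(dimension = "sadness", levels = 2, to_reference = TRUE),
    list(dimension = "sadness", levels = 3:4),
    list(dimension = "worry", levels = 2:3),
    list(dimension = "worry", levels = 4:5)
  )
  sim <- small_sim()
  sub <- sim$choices[sim$choices$resp_id %in%
                       unique(sim$choices$resp_id)[1:100], ]
  cons <- constrain(sub, forced_merges = merges, max_rounds = 10)
  expect_lte(cons$fit$k, 23)       # noise on 100 respondents merges further
  spec0 <- default_model_spec()
  for (m in merges) {
    spec0 <- if (isTRUE(m$to_reference)) {
      merge_to_reference(spec0, m$dimension, m$levels)
    } else {
      merge_levels(spec0, m$dimension, m$levels)
    }
  }
  expect_equal(n_parameters(spec0), 23)
  expect_equal(spec0$groups, published_constrained_spec()$groups)
})

test_that("MRS anchoring: decrements are -beta/alpha expanded over groups", {
  m3 <- published_model_coefficients(3)
  vs <- derive_value_set(m3)
  expect_equal(round(vs$decrements["nausea", "L5"], 3), 0.298)
  expect_equal(round(vs$decrements["fatigue", "L5"], 3), 0.164)
  expect_equal(round(vs$decrements["sleep", "L4"], 3), 0.077)
  expect_equal(vs$decrements["nausea", "L5"], 0.109 / 0.366,
               tolerance = 1e-12)
  # merged levels share a value; reference levels are zero
  expect_equal(vs$decrements["sleep", "L4"], vs$decrements["sleep", "L5"])
  expect_equal(unname(vs$decrements["pain", "L2"]), 0)
  # zero coefficients: all decrements zero, PITS = 1
  zero <- true_preferences(0.3, matrix(0, 8, 5))
  expect_identical(pits(derive_value_set(zero)), 1)
  # non-positive alpha refuses anchoring
  bad <- published_model_coefficients(3); bad$alpha <- -0.1
  expect_error(derive_value_set(bad), "alpha")
})

test_that("anchoring identity holds end to end on a constrained fit", {
  sim <- small_sim()
  cons <- constrain(sim$choices)
  vs <- derive_value_set(cons$fit)
  expect_true(vs$monotone)
  worst <- do.call(health_state,
                   as.list(stats::setNames(rep(5L, 8), fact8d_dimensions())))
  expect_equal(score_state(worst, vs), pits(vs), tolerance = 1e-12)
  expect_equal(pits(vs), 1 - sum(apply(vs$decrements, 1, max)))
  # utilities of sampled states lie in [pits, 1]
  set.seed(61)
  states <- matrix(sample(1:5, 800, replace = TRUE), 100, 8,
                   dimnames = list(NULL, fact8d_dimensions()))
  u <- score_state(states, vs)
  expect_true(all(u >= pits(vs) - 1e-12 & u <= 1 + 1e-12))
})

test_that("fit comparison pairs estimates and summarises concordance", {
  sim <- small_sim()
  sub <- sim$choices[sim$choices$resp_id %in%
                       unique(sim$choices$resp_id)[1:150], ]
  fit <- fit_clogit(sub)
  cmp_same <- compare_fits(fit, fit)
  expect_true(all(cmp_same$difference == 0))
  expect_equal(attr(cmp_same, "sign_agreement"), 1)
  # two seeds of the same generator agree in sign on well-identified terms
  ch_b <- simulate_choices(sim$design, sim$prefs, 300, seed = 62,
                           completion = NULL)
  fit_b <- fit_clogit(ch_b)
  cmp <- compare_fits(fit_clogit(sim$choices), fit_b)
  strong <- abs(sim$prefs$beta[, 2:5]) >= 0.04
  strong_terms <- paste0(rep(rownames(strong), 4), ":L",
                         rep(2:5, each = 8))[as.vector(strong)]
  agree <- sign(cmp$estimate_a) == sign(cmp$estimate_b)
  expect_true(all(agree[cmp$term %in% c("duration", strong_terms)]))
  expect_gt(attr(cmp, "max_abs_difference"), 0)
  # mismatched specs are refused
  fit_c <- fit_clogit(sub, published_constrained_spec())
  expect_error(compare_fits(fit, fit_c), "spec")
})

test_that("weighted and unweighted fits differ under outcome-correlated skew", {
  # two latent preference classes tied to a demographic level; the panel
  # over-samples one level, so the unweighted fit is tilted and raking
  # moves the estimates
  design <- generate_design(n_blocks = 6, seed = 63)
  strong <- published_model_coefficients(3)
  weak <- true_preferences(strong$alpha, strong$beta / 4)
  n_a <- 360; n_b <- 40                  # panel: 90% group a
  ch_a <- simulate_choices(design, strong, n_a, seed = 64, completion = NULL)
  ch_b <- simulate_choices(design, weak, n_b, seed = 65, completion = NULL)
  ch_b$resp_id <- ch_b$resp_id + n_a
  ch <- rbind(ch_a, ch_b)
  class(ch) <- c("fact8d_choices", "data.frame")
  prof <- data.frame(resp_id = 1:(n_a + n_b),
                     group = rep(c("a", "b"), c(n_a, n_b)))
  tg <- margin_targets(list(group = c(a = 0.5, b = 0.5)))
  w <- rake(prof, tg, variables = "group")
  fit_u <- fit_clogit(ch)
  fit_w <- fit_clogit(ch, weights = w)
  cmp <- compare_fits(fit_u, fit_w)
  expect_gt(attr(cmp, "max_abs_difference"), 0.01)
  expect_true(fit_w$weighted)
  expect_false(fit_u$weighted)
})
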