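# Shared small fixtures, built once per test run.

best_responses <- function() {
  c(GP1 = 0, GP2 = 0, GP4 = 0, GF1 = 4, GF5 = 4, GS2 = 4, GS3 = 4,
    GE1 = 0, GE6 = 0)
}

worst_responses <- function() {
  c(GP1 = 4, GP2 = 4, GP4 = 4, GF1 = 0, GF5 = 0, GS2 = 0, GS3 = 0,
    GE1 = 4, GE6 = 4)
}

worst_state <- function() {
  do.call(health_state,
          as.list(stats::setNames(rep(5L, 8), fact8d_dimensions())))
}

# A moderate simulated dataset reused by the model tests: 8 design blocks,
# 300 respondents, truth = the published constrained coefficients.
sim_cache <- new.env()
small_sim <- function() {
  if (is.null(sim_cache$data)) {
    design <- generate_design(n_blocks = 8, seed = 5)
    prefs <- published_model_coefficients(3)
    choices <- simulate_choices(design, prefs, 300, seed = 6,
                                completion = NULL)
    sim_cache$data <- list(design = design, prefs = prefs, choices = choices)
  }
  sim_cache$data
}

# Hand-built two-respondent, two-set choice dataset with known structure.
tiny_choices <- function() {
  lev <- function(...) {
    s <- stats::setNames(rep(1L, 8), fact8d_dimensions())
    mod <- list(...)
    s[names(mod)] <- as.integer(unlist(mod))
    as.list(s)
  }
  rows <- rbind(
    data.frame(resp_id = 1, set_id = 1, alt = "A", chosen = 1, duration = 10,
               lev(pain = 5)),
    data.frame(resp_id = 1, set_id = 1, alt = "B", chosen = 0, duration = 1,
               lev()),
    data.frame(resp_id = 1, set_id = 2, alt = "A", chosen = 0, duration = 2,
               lev(work = 3)),
    data.frame(resp_id = 1, set_id = 2, alt = "B", chosen = 1, duration = 5,
               lev(nausea = 2)),
    data.frame(resp_id = 2, set_id = 1, alt = "A", chosen = 0, duration = 10,
               lev(pain = 5)),
    data.frame(resp_id = 2, set_id = 1, alt = "B", chosen = 1, duration = 1,
               lev()),
    data.frame(resp_id = 2, set_id = 2, alt = "A", chosen = 1, duration = 2,
               lev(work = 3)),
    data.frame(resp_id = 2, set_id = 2, alt = "B", chosen = 0, duration = 5,
               lev(nausea = 2))
  )
  class(rows) <- c("fact8d_choices", "data.frame")
  rows
}
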