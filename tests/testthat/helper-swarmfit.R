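# Shared builders for the test suite. All fixtures are generated in code.

# Synthetic event sequence with directly specified contexts.
makeEvents <- function(y, f_opp = 0, s_fwd = Inf, s_near = NA_real_,
                       agent = "a1") {
  n <- length(y)
  switchEvents(data.frame(
    agent = rep_len(agent, n), step = stats::ave(seq_len(n),
                                                 rep_len(agent, n),
                                                 FUN = seq_along),
    y = y, f_opp = rep_len(f_opp, n), s_fwd = rep_len(s_fwd, n),
    s_near = rep_len(s_near, n)
  ))
}

# Random single-timestep contexts for probability-rule property tests.
randomContexts <- function(n, seed) {
  withr::with_seed(seed, {
    hasOpp <- stats::runif(n) < 0.8
    s_near <- ifelse(hasOpp, stats::runif(n, -pi, pi), NA_real_)
    s_fwd <- ifelse(hasOpp & s_near >= 0, s_near,
                    ifelse(hasOpp, stats::runif(n, 0, pi), Inf))
    s_fwd[hasOpp & stats::runif(n) < 0.3] <- Inf
    data.frame(agent = "a1", step = seq_len(n), y = 0L,
               f_opp = ifelse(hasOpp, stats::runif(n), 0),
               s_fwd = s_fwd, s_near = s_near)
  })
}

# Quick ring simulation shortcut.
quickRing <- function(N = 4, T = 50, model = "bernoulli",
                      params = c(p0 = 0.1), seed = 1, init = "random") {
  simulateRing(ringSimConfig(N = N, T = T, model = model, params = params,
                             seed = seed, init = init))
}
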