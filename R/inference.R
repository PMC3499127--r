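# The model-selection engine: sequence likelihoods for switching models,
# maximum-likelihood fitting, information criteria, Laplace-approximate
# marginal likelihoods and Bayes factors, model ranking, the data-driven
# switch-probability profile, and a simulate-fit-aggregate recovery harness.

# Bernoulli sequence log-likelihood for already-clipped probabilities.
.bernLL <- function(y, p) sum(y * log(p) + (1 - y) * log(1 - p))

# Aggregated binomial term with closed-form (clipped) rate.
.binTerm <- function(s, n) {
  if (n == 0) return(0)
  p <- .clipProb(s / n)
  s * log(p) + (n - s) * log(1 - p)
}

.orderedParams <- function(model, params) {
  missing <- setdiff(model@params, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  params[model@params]
}

#' Sequence log-likelihood of a switching model
#'
#' The probability of the complete observed sequence of direction changes
#' conditioned on the model: the sum over records of
#' `y * log(p) + (1 - y) * log(1 - p)`, where `p` is the model's switch
#' probability for that record's context, with memory states threaded per
#' agent in time order for non-Markovian models. Log-likelihoods of
#' independent event sets add.
#'
#' @param model Model name or [SwitchingModel-class].
#' @param params Named numeric parameters, inside the model's declared
#'   bounds.
#' @param events A [SwitchEvents-class].
#' @return The log-likelihood (a nonpositive number).
#' @export
sequenceLogLik <- function(model, params, events) {
  model <- getSwitchingModel(model)
  params <- .orderedParams(model, params)
  if (any(params < model@lower - 1e-12) || any(params > model@upper + 1e-12)) {
    stop("domain error: parameters outside the declared bounds of ",
         sQuote(model@name))
  }
  rec <- eventRecords(events)
  .bernLL(rec$y, model@probFn(params, rec))
}

# --- optimisation backends --------------------------------------------------

# Multi-start bound-constrained simplex search on logit-transformed
# coordinates. fn takes a named parameter vector and returns a log-likelihood.
.maximizeSmooth <- function(fn, lower, upper, nStarts = 10, seed = NULL) {
  d <- length(lower)
  span <- upper - lower
  toBox <- function(z) lower + span * stats::plogis(z)
  fromBox <- function(x) {
    stats::qlogis(pmin(pmax((x - lower) / span, 1e-6), 1 - 1e-6))
  }
  if (d == 1) {
    opt <- stats::optimize(function(x) {
      p <- stats::setNames(x, names(lower))
      fn(p)
    }, lower = lower, upper = upper, maximum = TRUE, tol = 1e-9)
    return(list(par = stats::setNames(opt$maximum, names(lower)),
                value = opt$objective, converged = TRUE))
  }
  starts <- .withSeed(seed, {
    s <- lapply(seq_len(max(nStarts - 1, 0)), function(i) {
      lower + span * stats::runif(d, 0.05, 0.95)
    })
    c(list(lower + span / 2), s)
  })
  best <- NULL
  anyConv <- FALSE
  for (st in starts) {
    res <- tryCatch(
      stats::optim(fromBox(st), function(z) -fn(stats::setNames(toBox(z), names(lower))),
                   method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) anyConv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimisation starts failed")
  list(par = stats::setNames(toBox(best$par), names(lower)),
       value = -best$value, converged = anyConv)
}

# --- model-specific profile fitters ----------------------------------------

# Zone model: for a fixed threshold w the trigger partition is fixed and the
# in/out rates have closed-form MLEs; the likelihood depends on w only
# through the partition, so scanning the observed separations gives the
# exact maximum. The smallest threshold attaining the maximum is reported.
.fitZoneProfile <- function(model, events) {
  rec <- eventRecords(events)
  y <- rec$y
  mf <- rec$s_fwd
  n <- length(y)
  S <- sum(y)
  fin <- which(is.finite(mf))
  if (!length(fin)) {
    p <- .clipProb(S / n)
    return(list(params = c(p0 = S / n, p1 = S / n, w = model@lower[["w"]]),
                logLik = .binTerm(S, n), converged = TRUE,
                details = list(method = "profile", note = "no finite separations")))
  }
  o <- fin[order(mf[fin])]
  mv <- mf[o]
  yv <- y[o]
  cs <- cumsum(yv)
  uIdx <- which(!duplicated(mv, fromLast = TRUE))
  wCand <- mv[uIdx]
  ok <- wCand >= model@lower[["w"]] & wCand <= model@upper[["w"]]
  uIdx <- uIdx[ok]
  wCand <- wCand[ok]
  n1 <- uIdx
  s1 <- cs[uIdx]
  ll <- mapply(.binTerm, s1, n1) + mapply(.binTerm, S - s1, n - n1)
  b <- which.max(ll)
  p1 <- s1[b] / n1[b]
  p0 <- if (n - n1[b] > 0) (S - s1[b]) / (n - n1[b]) else p1
  list(params = c(p0 = p0, p1 = p1, w = wCand[b]), logLik = ll[b],
       converged = TRUE, details = list(method = "profile", nCandidates = length(wCand)))
}

# Refractory memory model: profile over (w, tau); for each pair the active
# partition is fixed and the two rates have closed-form MLEs.
.fitD1Profile <- function(model, events, nW = 60) {
  rec <- eventRecords(events)
  y <- rec$y
  mf <- rec$s_fwd
  n <- length(y)
  S <- sum(y)
  blocks <- .agentBlocks(rec$agent)
  finVals <- mf[is.finite(mf)]
  if (!length(finVals)) {
    return(list(params = c(p0 = S / n, p1 = S / n, w = model@lower[["w"]],
                           tau = model@lower[["tau"]]),
                logLik = .binTerm(S, n), converged = TRUE,
                details = list(method = "profile", note = "no finite separations")))
  }
  wCand <- sort(unique(stats::quantile(finVals, probs = seq(0, 1, length.out = nW),
                                       type = 1, names = FALSE)))
  wCand <- wCand[wCand >= model@lower[["w"]] & wCand <= model@upper[["w"]]]
  taus <- seq(ceiling(model@lower[["tau"]]), floor(model@upper[["tau"]]))
  best <- list(ll = -Inf)
  for (w in wCand) {
    enc <- is.finite(mf) & mf <= w
    tse <- .timeSinceEncounter(enc, blocks)
    for (tau in taus) {
      act <- tse$ever & tse$u < tau
      n1 <- sum(act)
      s1 <- sum(y[act])
      ll <- .binTerm(s1, n1) + .binTerm(S - s1, n - n1)
      if (ll > best$ll) best <- list(ll = ll, w = w, tau = tau, n1 = n1, s1 = s1)
    }
  }
  p1 <- if (best$n1 > 0) best$s1 / best$n1 else S / n
  p0 <- if (n - best$n1 > 0) (S - best$s1) / (n - best$n1) else p1
  list(params = c(p0 = p0, p1 = p1, w = best$w, tau = best$tau),
       logLik = best$ll, converged = TRUE,
       details = list(method = "profile", nW = length(wCand), nTau = length(taus)))
}

# Decaying-trace model: profile over w; smooth simplex search over
# (p0, k, lam) inside each zone candidate.
.fitD2Profile <- function(model, events, nStarts = 10, seed = NULL, nW = 15) {
  rec <- eventRecords(events)
  y <- rec$y
  mf <- rec$s_fwd
  blocks <- .agentBlocks(rec$agent)
  finVals <- mf[is.finite(mf)]
  smoothIdx <- c("p0", "k", "lam")
  lo <- model@lower[smoothIdx]
  hi <- model@upper[smoothIdx]
  if (!length(finVals)) {
    S <- sum(y)
    n <- length(y)
    return(list(params = c(p0 = S / n, k = 0, w = model@lower[["w"]], lam = 1),
                logLik = .binTerm(S, n), converged = TRUE,
                details = list(method = "profile", note = "no finite separations")))
  }
  wCand <- sort(unique(stats::quantile(finVals, probs = seq(0, 1, length.out = nW),
                                       type = 1, names = FALSE)))
  wCand <- wCand[wCand >= model@lower[["w"]] & wCand <= model@upper[["w"]]]
  innerStarts <- max(2L, ceiling(nStarts / 5))
  best <- list(value = -Inf)
  for (g in seq_along(wCand)) {
    enc <- is.finite(mf) & mf <= wCand[g]
    fn <- function(p) {
      m <- .encounterTrace(enc, p[["lam"]], blocks)
      .bernLL(y, .clipProb(p[["p0"]] + p[["k"]] * m))
    }
    res <- .maximizeSmooth(fn, lo, hi, nStarts = innerStarts,
                           seed = if (is.null(seed)) NULL else deriveSeed(seed, "d2w", g))
    if (res$value > best$value) {
      best <- res
      best$w <- wCand[g]
    }
  }
  list(params = c(best$par["p0"], best$par["k"], w = best$w, best$par["lam"]),
       logLik = best$value, converged = best$converged,
       details = list(method = "profile+simplex", nW = length(wCand)))
}

# --- public fitting surface -------------------------------------------------

.buildFitResult <- function(model, events, raw) {
  n <- nEvents(events)
  k <- length(model@params)
  params <- raw$params[model@params]
  new("ModelFitResult",
      model = model@name, params = params, logLik = raw$logLik,
      nEvents = as.integer(n), nParams = as.integer(k),
      aic = 2 * k - 2 * raw$logLik, bic = k * log(n) - 2 * raw$logLik,
      logMarginal = NA_real_, converged = isTRUE(raw$converged),
      flags = character(), details = raw$details %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-likelihood fit of a switching model
#'
#' Maximises [sequenceLogLik()] over the model's declared parameter box.
#' Smooth models use a multi-start bound-constrained simplex search on
#' logit-transformed coordinates; models with threshold-type parameters
#' (the zone width, the memory duration) use an exact profile scan over the
#' observed separations with closed-form rate estimates, combined with a
#' simplex search over their smooth parameters.
#'
#' @param model Model name or [SwitchingModel-class].
#' @param events A nonempty [SwitchEvents-class].
#' @param nStarts Number of random starts for simplex searches.
#' @param seed Integer seed for the random starts.
#' @return A [ModelFitResult-class].
#' @export
fitMLE <- function(model, events, nStarts = 10, seed = NULL) {
  model <- getSwitchingModel(model)
  rec <- eventRecords(events)
  if (!nrow(rec)) stop("events must be nonempty")
  raw <- if (!is.null(model@fitFn)) {
    model@fitFn(model, events, nStarts, seed)
  } else {
    out <- .maximizeSmooth(function(p) .bernLL(rec$y, model@probFn(p, rec)),
                           model@lower, model@upper, nStarts = nStarts,
                           seed = seed)
    list(params = out$par, logLik = out$value, converged = out$converged,
         details = list(method = "simplex"))
  }
  .buildFitResult(model, events, raw)
}

#' Laplace-approximate log marginal likelihood
#'
#' Approximates `log p(data | model)` under independent uniform priors over
#' the model's declared parameter bounds:
#' `logLik(MLE) + (d/2) log(2*pi) - (1/2) log det(I) + log prior(MLE)`,
#' with the observed information `I` obtained by central finite differences.
#' Integer-valued parameters are excluded from the curvature term and
#' contribute their uniform prior mass. When the fit sits on a bound or the
#' information matrix is not positive definite (as happens for
#' threshold-type parameters, whose likelihood is piecewise constant), the
#' approximation falls back to the BIC form `logLik - (d/2) log(n)`, and the
#' result carries `attr(, "method") = "bic"`.
#'
#' @param fit A converged [ModelFitResult-class].
#' @param events The [SwitchEvents-class] the fit was computed on.
#' @return The approximate log marginal likelihood, with attribute
#'   `"method"` set to `"laplace"` or `"bic"`.
#' @export
logMarginalLaplace <- function(fit, events) {
  model <- getSwitchingModel(fit@model)
  rec <- eventRecords(events)
  params <- fit@params
  contNames <- setdiff(model@params, model@integerParams)
  intNames <- model@integerParams
  priorLog <- 0
  if (length(contNames)) {
    priorLog <- priorLog - sum(log(model@upper[contNames] - model@lower[contNames]))
  }
  if (length(intNames)) {
    priorLog <- priorLog -
      sum(log(floor(model@upper[intNames]) - ceiling(model@lower[intNames]) + 1))
  }
  bicValue <- fit@logLik - (fit@nParams / 2) * log(max(fit@nEvents, 1))
  fallback <- function() structure(bicValue, method = "bic")
  if (!fit@converged || !length(contNames)) return(fallback())
  x0 <- params[contNames]
  nearBound <- any(x0 - model@lower[contNames] < 1e-6) ||
    any(model@upper[contNames] - x0 < 1e-6)
  if (nearBound) return(fallback())
  f <- function(x) {
    pp <- params
    pp[contNames] <- x
    .bernLL(rec$y, model@probFn(pp, rec))
  }
  H <- tryCatch(-pracma::hessian(f, x0), error = function(e) NULL)
  if (is.null(H)) return(fallback())
  ev <- tryCatch(eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(ev)) || any(ev <= 1e-8)) return(fallback())
  d <- length(contNames)
  structure(
    fit@logLik + (d / 2) * log(2 * pi) - 0.5 * sum(log(ev)) + priorLog,
    method = "laplace"
  )
}

#' Fit and rank a set of switching models
#'
#' Fits every candidate model to the same event sequence, computes the
#' selection criterion, and orders the models by it (descending; ties broken
#' by fewer parameters). The default criterion is the Laplace-approximate
#' log marginal likelihood, so the ordering realises Bayes-factor selection;
#' log Bayes factors are reported against the mean-field baseline when it is
#' among the candidates. A model whose fit fails is dropped with its error
#' recorded and ranking proceeds with the survivors. The result is invariant
#' to the order of the candidate list.
#'
#' @param models Character vector of model names (default: the full
#'   registry).
#' @param events A [SwitchEvents-class].
#' @param criterion `"marginal"`, `"loglik"`, `"AIC"` or `"BIC"`.
#' @param nStarts,seed Passed to [fitMLE()]; per-model seeds are derived
#'   from `seed` so candidate order does not perturb fits.
#' @return A [ModelRanking-class].
#' @export
rankModels <- function(models = switchingModels(), events,
                       criterion = c("marginal", "loglik", "AIC", "BIC"),
                       nStarts = 10, seed = NULL) {
  criterion <- match.arg(criterion)
  if (length(models) < 2) stop("need at least two candidate models")
  fits <- list()
  errors <- list()
  for (name in models) {
    s <- if (is.null(seed)) NULL else deriveSeed(seed, paste0("fit-", name))
    out <- tryCatch(fitMLE(name, events, nStarts = nStarts, seed = s),
                    error = function(e) e)
    if (inherits(out, "error")) {
      errors[[name]] <- conditionMessage(out)
    } else {
      lm <- logMarginalLaplace(out, events)
      out@logMarginal <- as.numeric(lm)
      if (identical(attr(lm, "method"), "bic")) {
        out@flags <- c(out@flags, "marginal:bic-fallback")
      }
      fits[[name]] <- out
    }
  }
  if (!length(fits)) stop("all model fits failed")
  score <- vapply(fits, function(f) {
    switch(criterion,
           marginal = f@logMarginal, loglik = f@logLik,
           AIC = -f@aic, BIC = -f@bic)
  }, numeric(1))
  nPar <- vapply(fits, function(f) f@nParams, integer(1))
  ord <- order(-score, nPar, names(fits))
  fits <- fits[ord]
  mfMarg <- if ("meanfield" %in% names(fits)) fits[["meanfield"]]@logMarginal else NA_real_
  logBF <- vapply(fits, function(f) f@logMarginal - mfMarg, numeric(1))
  tab <- data.frame(
    model = names(fits),
    nParams = vapply(fits, function(f) f@nParams, integer(1)),
    logLik = vapply(fits, function(f) f@logLik, numeric(1)),
    AIC = vapply(fits, function(f) f@aic, numeric(1)),
    BIC = vapply(fits, function(f) f@bic, numeric(1)),
    logMarginal = vapply(fits, function(f) f@logMarginal, numeric(1)),
    logBF = logBF,
    converged = vapply(fits, function(f) f@converged, logical(1)),
    row.names = NULL
  )
  new("ModelRanking", results = c(fits, list(.errors = errors)[length(errors) > 0]),
      criterion = criterion, table = tab, logBF = logBF)
}

#' Empirical switch-probability profile
#'
#' The data-driven "plot first" summary: the observed switch rate as a
#' function of the signed position of the nearest opposite-direction
#' neighbour, with Wilson confidence intervals per bin. Records with no
#' opposite-direction neighbour are excluded; empty bins are marked with
#' `NA` intervals.
#'
#' @param events A [SwitchEvents-class].
#' @param breaks Bin edges partitioning `(-pi, pi]`.
#' @param conf Confidence level.
#' @return Data frame with one row per bin: `mid`, `n`, `k`, `p`, `lower`,
#'   `upper`.
#' @export
switchProfile <- function(events, breaks = seq(-pi, pi, length.out = 13),
                          conf = 0.95) {
  rec <- eventRecords(events)
  ok <- !is.na(rec$s_near)
  bin <- cut(rec$s_near[ok], breaks)
  y <- rec$y[ok]
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(mid = mids, n = 0L, k = 0L, p = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  for (b in seq_along(mids)) {
    sel <- as.integer(bin) == b
    n <- sum(sel, na.rm = TRUE)
    out$n[b] <- n
    if (n > 0) {
      k <- sum(y[sel], na.rm = TRUE)
      ci <- .wilsonCI(k, n, conf)
      out$k[b] <- as.integer(k)
      out$p[b] <- k / n
      out$lower[b] <- ci[[1]]
      out$upper[b] <- ci[[2]]
    }
  }
  out
}

#' Simulate-fit-aggregate parameter recovery
#'
#' Simulates ring trajectories from a model at known parameters, refits the
#' model to each replicate, and reports per-parameter bias and root mean
#' squared error. Deterministic given the seed.
#'
#' @param model Model name or [SwitchingModel-class].
#' @param trueParams Named generating parameters.
#' @param simConfig A [ringSimConfig()] whose `model`/`params` are
#'   overridden by `model`/`trueParams`.
#' @param nReps Number of replicates (at least 2).
#' @param seed Integer master seed.
#' @param nStarts Starts per fit.
#' @return List with `estimates` (replicates by parameters matrix) and
#'   `table` (data frame: `param`, `true`, `mean`, `bias`, `rmse`).
#' @export
recoveryHarness <- function(model, trueParams, simConfig = ringSimConfig(),
                            nReps = 10, seed = 1, nStarts = 5) {
  stopifnot(nReps >= 2)
  model <- getSwitchingModel(model)
  est <- matrix(NA_real_, nReps, length(model@params),
                dimnames = list(NULL, model@params))
  for (rep in seq_len(nReps)) {
    cfg <- simConfig
    cfg$model <- model@name
    cfg$params <- trueParams
    cfg$seed <- deriveSeed(seed, "recover-sim", rep)
    ev <- extractEvents(simulateRing(cfg))
    fit <- fitMLE(model, ev, nStarts = nStarts,
                  seed = deriveSeed(seed, "recover-fit", rep))
    est[rep, ] <- fit@params[model@params]
  }
  true <- trueParams[colnames(est)]
  tab <- data.frame(
    param = colnames(est),
    true = as.numeric(true),
    mean = colMeans(est),
    bias = colMeans(est) - as.numeric(true),
    rmse = sqrt(colMeans(sweep(est, 2, as.numeric(true))^2)),
    row.names = NULL
  )
  list(estimates = est, table = tab)
}
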