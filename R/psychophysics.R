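#' Synthetic 4AFC observer
#'
#' A simulated observer whose probability of a correct orientation report is
#' `gamma + (1 - gamma - lapse) * pnorm((log10(x) - log10(alpha)) / slope)`
#' with guess rate `gamma = 0.25`. With zero lapse the probability at
#' `x = alpha` is 0.625, i.e. `alpha` is the threshold at the 62.5% criterion.
#'
#' @param alpha_arcsec True threshold in arcsec.
#' @param slope SD of the cumulative Gaussian on log10 size (default 0.08).
#' @param lapse Lapse rate in `[0, 0.06]` (default 0.01).
#' @param gamma Guess rate (default 0.25).
#' @return Object of class `synthetic_observer`.
#' @export
synthetic_observer <- function(alpha_arcsec, slope = 0.08, lapse = 0.01,
                               gamma = 0.25) {
  stopifnot(alpha_arcsec > 0, slope > 0, lapse >= 0, lapse <= 0.25,
            gamma > 0, gamma < 1)
  structure(list(alpha_arcsec = alpha_arcsec, slope = slope, lapse = lapse,
                 gamma = gamma),
            class = "synthetic_observer")
}

#' @export
print.synthetic_observer <- function(x, ...) {
  cat(sprintf("<synthetic_observer> alpha %.1f arcsec, slope %.3f, lapse %.3f\n",
              x$alpha_arcsec, x$slope, x$lapse))
  invisible(x)
}

## probability of a correct response at gap size x (arcsec)
.observer_p <- function(obs, x_arcsec) {
  obs$gamma + (1 - obs$gamma - obs$lapse) *
    stats::pnorm((log10(x_arcsec) - log10(obs$alpha_arcsec)) / obs$slope)
}

#' QUEST staircase options
#'
#' Watson-Pelli QUEST internals. The threshold grid and prior live on log10
#' gap size (arcsec). The internal psychometric used for the posterior update
#' is the QUEST Weibull
#' `p(correct) = delta * gamma + (1 - delta) * (1 - (1 - gamma) *
#' exp(-10^(beta * (x - T))))`.
#'
#' @param prior_mean_arcsec Center of the Gaussian prior (default 40 arcsec).
#' @param prior_sd Prior SD in log10 units (default 0.5).
#' @param beta Weibull slope (default 3.5).
#' @param delta Lapse allowance (default 0.01).
#' @param gamma Guess rate (default 0.25, 4AFC).
#' @param grain Grid step in log10 units (default 0.005).
#' @param range Grid span, log10 arcsec (default `c(log10(2), log10(400))`).
#' @return Object of class `quest_options`.
#' @export
quest_options <- function(prior_mean_arcsec = 40, prior_sd = 0.5,
                          beta = 3.5, delta = 0.01, gamma = 0.25,
                          grain = 0.005, range = c(log10(2), log10(400))) {
  stopifnot(prior_mean_arcsec > 0, prior_sd > 0, beta > 0,
            delta >= 0, delta < 1, gamma > 0, gamma < 1, grain > 0)
  structure(list(prior_mean = log10(prior_mean_arcsec), prior_sd = prior_sd,
                 beta = beta, delta = delta, gamma = gamma,
                 grain = grain, range = range),
            class = "quest_options")
}

#' Create a QUEST staircase
#'
#' @param options A [quest_options()].
#' @return Object of class `quest_state` with a normalized posterior over
#'   log10 threshold and empty histories.
#' @export
quest_create <- function(options = quest_options()) {
  stopifnot(inherits(options, "quest_options"))
  grid <- seq(options$range[1], options$range[2], by = options$grain)
  post <- stats::dnorm(grid, options$prior_mean, options$prior_sd)
  structure(list(grid = grid, posterior = post / sum(post),
                 options = options,
                 stim_log10 = numeric(0), correct = logical(0)),
            class = "quest_state")
}

## QUEST internal psychometric at stimulus x (log10) for threshold grid T
.quest_p <- function(opt, x, T) {
  opt$delta * opt$gamma + (1 - opt$delta) *
    (1 - (1 - opt$gamma) * exp(-10^(opt$beta * (x - T))))
}

#' Next stimulus and Bayesian update of a QUEST staircase
#'
#' `quest_next()` returns the posterior-mode threshold estimate (log10
#' arcsec) as the recommended next stimulus; `quest_update()` folds in one
#' trial outcome, keeping the posterior normalized.
#'
#' @param state A `quest_state`.
#' @param x_log10 Presented stimulus, log10 arcsec.
#' @param correct Logical trial outcome.
#' @return `quest_next()`: numeric log10 arcsec. `quest_update()`: the
#'   updated `quest_state`.
#' @export
quest_next <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  state$grid[which.max(state$posterior)]
}

#' @rdname quest_next
#' @export
quest_update <- function(state, x_log10, correct) {
  stopifnot(inherits(state, "quest_state"), is.logical(correct))
  p <- .quest_p(state$options, x_log10, state$grid)
  lik <- if (correct) p else 1 - p
  post <- state$posterior * lik
  s <- sum(post)
  if (s <= 0) stop("degenerate QUEST posterior")
  state$posterior <- post / s
  state$stim_log10 <- c(state$stim_log10, x_log10)
  state$correct <- c(state$correct, correct)
  state
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf("<quest_state> %d trials, mode %.1f arcsec\n",
              length(x$stim_log10), 10^quest_next(x)))
  invisible(x)
}

## gap sizes are quantized to whole raster pixels before presentation
.quantize_gap <- function(gap_arcsec, pixel_scale = 0.1) {
  px_arcsec <- pixel_scale * 60
  max(px_arcsec, round(gap_arcsec / px_arcsec) * px_arcsec)
}

#' Run one QUEST staircase against a synthetic observer
#'
#' Each trial presents the posterior-mode size (quantized to whole raster
#' pixels), draws a uniformly random orientation, and samples the observer's
#' response; reproducible for a fixed seed.
#'
#' @param observer A [synthetic_observer()].
#' @param n_trials Trials per run (default 20).
#' @param run Run index recorded in the output (default 1).
#' @param options A [quest_options()].
#' @param pixel_scale Raster pixel scale for size quantization (default 0.1).
#' @param seed Optional RNG seed.
#' @return data.frame of `trial_record`s: `run`, `trial`, `gap_arcsec`,
#'   `orientation`, `response`, `correct`; the final `quest_state` is
#'   attached as attribute `state`.
#' @export
quest_run <- function(observer, n_trials = 20, run = 1L,
                      options = quest_options(), pixel_scale = 0.1,
                      seed = NULL) {
  stopifnot(inherits(observer, "synthetic_observer"))
  if (!is.null(seed)) set.seed(seed)
  state <- quest_create(options)
  dirs <- c("up", "down", "left", "right")
  rec <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    gap <- .quantize_gap(10^quest_next(state), pixel_scale)
    orient <- sample(dirs, 1)
    p <- .observer_p(observer, gap)
    correct <- stats::runif(1) < p
    response <- if (correct) orient else sample(setdiff(dirs, orient), 1)
    state <- quest_update(state, log10(gap), correct)
    rec[[i]] <- data.frame(run = run, trial = i, gap_arcsec = gap,
                           orientation = orient, response = response,
                           correct = correct)
  }
  out <- do.call(rbind, rec)
  attr(out, "state") <- state
  out
}

#' Pool trials from consecutive staircase runs
#'
#' Concatenates the trial records of several runs of one observer/eye
#' (the protocol pools 5 runs of 20 trials into ~100 trials for fitting).
#'
#' @param runs List of [quest_run()] data.frames.
#' @return Single pooled data.frame.
#' @export
pool_runs <- function(runs) {
  stopifnot(is.list(runs))
  if (!length(runs)) stop("no runs to pool; fit refused")
  ids <- vapply(runs, function(r) r$run[1], numeric(1))
  if (anyDuplicated(ids)) stop("duplicate run indices detected while pooling")
  do.call(rbind, runs)
}

#' Maximum-likelihood psychometric fit with threshold at 62.5% correct
#'
#' Fits `p(correct) = gamma + (1 - gamma - lapse) * pnorm((log10(x) - mu) /
#' sigma)` by maximum likelihood (guess rate fixed, lapse bounded in
#' `[0, lapse_max]`), and reports the gap size where the fitted probability
#' equals the 4AFC criterion `p = 0.625`, the midpoint between guessing and
#' perfect performance. The optional confidence interval is a nonparametric
#' bootstrap over trials.
#'
#' @param trials data.frame with `gap_arcsec` and `correct` columns (e.g.
#'   from [pool_runs()]).
#' @param gamma Guess rate (default 0.25).
#' @param lapse_max Upper bound on the lapse rate (default 0.06).
#' @param criterion Threshold criterion probability (default 0.625).
#' @param n_boot Bootstrap resamples for the 95% CI (default 500; 0 skips).
#' @param seed Optional RNG seed for the bootstrap.
#' @return Object of class `psychometric_fit`: `threshold_arcsec`, `ci95`,
#'   `mu`, `sigma`, `lapse`, `criterion`, `n_trials`, `loglik`.
#' @export
fit_psychometric <- function(trials, gamma = 0.25, lapse_max = 0.06,
                             criterion = 0.625, n_boot = 500, seed = NULL) {
  stopifnot(is.data.frame(trials),
            all(c("gap_arcsec", "correct") %in% names(trials)))
  if (nrow(trials) < 20) stop("need at least 20 trials to fit")
  x <- log10(trials$gap_arcsec)
  k <- as.logical(trials$correct)
  if (length(unique(x)) < 2) stop("need at least 2 distinct stimulus levels")
  if (all(k) || all(!k)) stop("all-correct or all-wrong data; fit undefined")
  est <- .fit_ml(x, k, gamma, lapse_max)
  thr <- .fit_threshold(est, gamma, criterion)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(x)
    bt <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (all(k[i]) || all(!k[i]) || length(unique(x[i])) < 2) return(NA_real_)
      tryCatch(
        .fit_threshold(.fit_ml(x[i], k[i], gamma, lapse_max), gamma, criterion),
        error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(threshold_arcsec = thr, ci95 = ci,
                 mu = est$mu, sigma = est$sigma, lapse = est$lapse,
                 criterion = criterion, n_trials = nrow(trials),
                 loglik = -est$nll),
            class = "psychometric_fit")
}

## aggregated binomial ML fit of (mu, sigma, lapse)
.fit_ml <- function(x, k, gamma, lapse_max) {
  lev <- sort(unique(x))
  n_i <- vapply(lev, function(l) sum(x == l), numeric(1))
  k_i <- vapply(lev, function(l) sum(k[x == l]), numeric(1))
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    lapse <- lapse_max * stats::plogis(par[3])
    p <- gamma + (1 - gamma - lapse) * stats::pnorm((lev - mu) / sigma)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(k_i * log(p) + (n_i - k_i) * log(1 - p))
  }
  start <- c(stats::weighted.mean(lev, n_i), log(max(stats::sd(x), 0.02)), 0)
  fit <- NULL
  for (st in list(start, start + c(0.1, 0.5, 0), start - c(0.1, 0.5, 0))) {
    f1 <- stats::optim(st, nll, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-9))
    ## polish: restart the simplex from the first optimum
    f1 <- tryCatch(stats::optim(f1$par, nll, method = "Nelder-Mead",
                                control = list(maxit = 5000, reltol = 1e-9)),
                   error = function(e) f1)
    if (is.null(fit) || f1$value < fit$value - 1e-9 ||
        (fit$convergence != 0 && f1$convergence == 0))
      fit <- f1
    if (fit$convergence == 0) break
  }
  if (fit$convergence != 0)
    stop("psychometric fit did not converge (optim code ", fit$convergence,
         ", value ", signif(fit$value, 6), ")")
  list(mu = fit$par[1], sigma = exp(fit$par[2]),
       lapse = lapse_max * stats::plogis(fit$par[3]), nll = fit$value)
}

.fit_threshold <- function(est, gamma, criterion) {
  z <- stats::qnorm((criterion - gamma) / (1 - gamma - est$lapse))
  10^(est$mu + est$sigma * z)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> threshold %.1f arcsec at p = %.3f (n = %d)\n",
              x$threshold_arcsec, x$criterion, x$n_trials))
  if (all(is.finite(x$ci95)))
    cat(sprintf("  95%% CI [%.1f, %.1f] arcsec; sigma %.3f, lapse %.3f\n",
                x$ci95[1], x$ci95[2], x$sigma, x$lapse))
  invisible(x)
}

#' Threshold relative to the Nyquist limit
#'
#' @param fit A [fit_psychometric()] result (or threshold in arcsec).
#' @param landmarks A [foveolar_landmarks()] (or Nyquist limit in arcsec).
#' @return List with `ratio` (threshold / Nyquist) and `difference_arcsec`
#'   (threshold - Nyquist).
#' @export
threshold_vs_nyquist <- function(fit, landmarks) {
  thr <- if (inherits(fit, "psychometric_fit")) fit$threshold_arcsec else fit
  ny <- if (inherits(landmarks, "foveolar_landmarks"))
    landmarks$nyquist_arcsec else landmarks
  stopifnot(thr > 0, ny > 0)
  list(ratio = thr / ny, difference_arcsec = thr - ny)
}
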