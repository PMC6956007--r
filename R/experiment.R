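# Simulation-study driver: generate datasets at known truth, estimate
# repeatedly, and tabulate the mean and dispersion of the estimates
# across stimulus designs.

#' Simulation scenario
#'
#' One cell of the simulation-study grid: how many trials per dataset,
#' the stimulus design, the trial window, and how many independent
#' repetitions of the generate-then-estimate experiment to run.
#'
#' @param Nit Trials per dataset (default 100).
#' @param NU Stimulus components (default 5).
#' @param Amax Stimulus amplitude (default 100).
#' @param f0 Base frequency in kHz (default 1/3).
#' @param Tf Window length, ms (default 30).
#' @param dt Step, ms (default 0.01).
#' @param R Repetitions per scenario cell (default 50).
#' @return An object of class `"fn_scenario"`.
#' @export
fn_scenario <- function(Nit = 100, NU = 5, Amax = 100, f0 = 1/3,
                        Tf = 30, dt = 0.01, R = 50) {
  stopifnot(Nit >= 1, NU >= 1, Amax >= 0, f0 > 0, Tf > 0, dt > 0, R >= 1)
  structure(list(Nit = as.integer(Nit), NU = as.integer(NU),
                 Amax = Amax, f0 = f0, Tf = Tf, dt = dt,
                 R = as.integer(R)),
            class = "fn_scenario")
}

#' @export
print.fn_scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: Nit = %d, NU = %d, Amax = %g, f0 = %g kHz, Tf = %g ms, dt = %g ms, R = %d\n",
    x$Nit, x$NU, x$Amax, x$f0, x$Tf, x$dt, x$R))
  invisible(x)
}

#' Generate a synthetic dataset at known truth
#'
#' Runs the generative pipeline once per trial: draw fresh phases,
#' evaluate the phased-cosine stimulus, integrate the model at `truth`
#' from state (0, 0), and Bernoulli-sample a spike train from the rate
#' trajectory.  Each trial consumes its own recorded sub-seed derived
#' from `seed`, so any single trial can be replayed independently.
#'
#' @param truth True [fn_params].
#' @param scenario An [fn_scenario()].
#' @param seed Master seed (integer).
#' @return An [fn_dataset()] carrying `truth`, `scenario`, `seed` and
#'   per-trial seeds.
#' @export
generate_dataset <- function(truth, scenario, seed) {
  truth <- as_fn_params(truth)
  stopifnot(inherits(scenario, "fn_scenario"))
  grid <- time_grid(scenario$Tf, scenario$dt)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, scenario$Nit)
  trials <- lapply(seq_len(scenario$Nit), function(m) {
    set.seed(trial_seeds[m])
    spec <- stimulus_spec(scenario$NU, scenario$Amax, scenario$f0,
                          sample_phases(scenario$NU))
    rate <- integrate_rate(truth, evaluate_stimulus(spec, grid), grid)
    spikes <- suppressWarnings(sample_spikes_bernoulli(rate))
    fn_trial(spec, spikes, grid)
  })
  ds <- fn_dataset(trials, truth = truth, scenario = scenario, seed = seed)
  ds$trial_seeds <- trial_seeds
  ds
}

#' Repeated generate-and-estimate experiment
#'
#' Runs `scenario$R` independent repetitions of
#' [generate_dataset()] followed by [fn_estimate()], and summarises the
#' per-parameter mean and sample standard deviation (denominator R - 1)
#' of the estimates.  Repetitions whose estimation fails are recorded
#' and excluded; the summary reports the effective R.
#'
#' @param truth True [fn_params].
#' @param scenario An [fn_scenario()].
#' @param seed Master seed; repetition r uses a sub-seed derived from it.
#' @param bounds,init,control Passed to [fn_estimate()].  The default
#'   `init = NULL` draws a fresh random in-bounds start per repetition.
#' @param rep_seeds Optional explicit vector of `R` per-repetition
#'   seeds, overriding the derivation from `seed` (repeating a seed
#'   replays the identical repetition).
#' @return An object of class `"fn_experiment"`: `scenario`, `truth`,
#'   `estimates` (R x 5 matrix of raw estimates), `mean`, `sd`,
#'   `effective_R`, `failures`.
#' @export
run_experiment <- function(truth, scenario, seed,
                           bounds = default_bounds(), init = NULL,
                           control = list(), rep_seeds = NULL) {
  truth <- as_fn_params(truth)
  stopifnot(inherits(scenario, "fn_scenario"))
  if (scenario$R < 2) stop("need R >= 2 repetitions for a standard deviation")
  if (is.null(rep_seeds)) {
    set.seed(seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, scenario$R)
  } else if (length(rep_seeds) != scenario$R) {
    stop("rep_seeds must have length R")
  }
  est <- matrix(NA_real_, scenario$R, 5,
                dimnames = list(NULL, c("a", "b", "c", "d", "F")))
  failures <- character(0)
  for (r in seq_len(scenario$R)) {
    fit <- tryCatch({
      ds <- generate_dataset(truth, scenario, rep_seeds[r])
      set.seed(rep_seeds[r] %% 1000000L + 7L)  # init stream, distinct from data
      fn_estimate(ds, bounds = bounds, init = init, control = control)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("repetition %d: %s", r,
                                      conditionMessage(fit)))
    } else {
      est[r, ] <- unclass(fit$theta_hat)
    }
  }
  ok <- stats::complete.cases(est)
  if (sum(ok) < 2)
    stop("experiment failed: fewer than 2 successful repetitions")
  if (length(failures))
    warning(length(failures), " repetition(s) failed and were excluded")
  structure(list(scenario = scenario, truth = truth,
                 estimates = est[ok, , drop = FALSE],
                 mean = colMeans(est[ok, , drop = FALSE]),
                 sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
                 effective_R = sum(ok), failures = failures,
                 seed = seed),
            class = "fn_experiment")
}

#' @export
print.fn_experiment <- function(x, ...) {
  cat("simulation experiment ("); print(x$scenario)
  cat(sprintf("effective R = %d\nmean estimates:\n", x$effective_R))
  print(round(x$mean, 5))
  cat("standard deviations:\n")
  print(signif(x$sd, 4))
  invisible(x)
}

#' Scenario sweep
#'
#' Runs [run_experiment()] over a list of scenarios and binds the
#' per-scenario means and standard deviations into two tables (rows:
#' scenarios; columns: the five parameters), the layout used for the
#' bias/dispersion summaries of the simulation study.
#'
#' @param truth True [fn_params].
#' @param scenarios List of [fn_scenario()]s.
#' @param seed Master seed; each scenario uses a derived sub-seed.
#' @param label Function mapping a scenario to its row label (default:
#'   its `Nit`).
#' @param ... Passed to [run_experiment()].
#' @return List with `mean` and `sd` data frames, and `experiments`
#'   (the per-scenario `fn_experiment`s; failed scenarios are `NULL`
#'   with the error message in `errors`).
#' @export
sweep_experiments <- function(truth, scenarios, seed,
                              label = function(s) s$Nit, ...) {
  if (length(scenarios) == 0L) stop("empty scenario grid")
  set.seed(seed)
  sc_seeds <- sample.int(.Machine$integer.max - 1L, length(scenarios))
  experiments <- vector("list", length(scenarios))
  errors <- character(length(scenarios))
  for (i in seq_along(scenarios)) {
    experiments[[i]] <- tryCatch(
      run_experiment(truth, scenarios[[i]], sc_seeds[i], ...),
      error = function(e) { errors[i] <<- conditionMessage(e); NULL })
  }
  ok <- !vapply(experiments, is.null, logical(1))
  labels <- vapply(scenarios, label, numeric(1))
  mk <- function(field) {
    df <- as.data.frame(do.call(rbind, lapply(experiments[ok], `[[`, field)))
    names(df) <- c("a", "b", "c", "d", "F")
    cbind(case = labels[ok], df)
  }
  list(mean = mk("mean"), sd = mk("sd"),
       experiments = experiments, errors = errors[!ok])
}

#' Relative-error series between consecutive estimates
#'
#' Convergence diagnostic for a sequence of estimates indexed by growing
#' sample size: `ER(k) = |theta(k) - theta(k-1)| / |theta(k-1)|`,
#' computed per parameter from the second case on.  Division by a zero
#' previous estimate yields `Inf`.
#'
#' @param estimates Data frame or matrix of per-case parameter
#'   estimates, cases in rows (ascending sample size); an optional
#'   first column named `Nit` or `case` supplies row labels.
#' @return Data frame of class `"relative_error_series"`: one row per
#'   case from the second on, columns `case` and one `ER` per
#'   parameter.
#' @examples
#' est <- data.frame(Nit = c(25, 50), a = c(255.7506, 209.6757))
#' relative_error_series(est)   # ER = 0.18016
#' @export
relative_error_series <- function(estimates) {
  estimates <- as.data.frame(estimates)
  lab_col <- intersect(c("Nit", "case"), names(estimates))[1]
  if (!is.na(lab_col)) {
    labels <- estimates[[lab_col]]
    estimates <- estimates[setdiff(names(estimates), lab_col)]
  } else {
    labels <- seq_len(nrow(estimates))
  }
  if (nrow(estimates) < 2L) stop("need at least 2 cases")
  m <- as.matrix(estimates)
  cur <- m[-1, , drop = FALSE]
  prev <- m[-nrow(m), , drop = FALSE]
  er <- abs(cur - prev) / abs(prev)
  er[prev == 0 & cur != 0] <- Inf
  er[prev == 0 & cur == 0] <- 0
  out <- cbind(data.frame(case = labels[-1]), as.data.frame(er))
  class(out) <- c("relative_error_series", class(out))
  out
}
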