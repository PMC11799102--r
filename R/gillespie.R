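## Exact stochastic simulation of the full rescue process.
##
## Direct-method Gillespie on the continuous-time model: every type-i cell
## divides at rate lambda_i = 1 + s(n, i) and dies at rate 1; division
## outcomes come from the mode's pair kernel. A division of a fully
## wild-type cell carries a mutation with probability u * n (at most one
## per division); each mutation founds a labelled lineage so that the
## first mutation whose descendants survive to the horizon can be
## identified. No tau-leaping: the simulation is exact.

#' Configuration of a rescue simulation
#'
#' @param model A [fitness_model()].
#' @param mode `"regular"` or `"random"`.
#' @param u Per-locus per-replication mutation probability; `u * n <= 1`.
#' @param N0 Initial wild-type population size (integer >= 1).
#' @param uN0 Alternative to `(u, N0)`: the product only, split by default
#'   as `u = uN0 / 1000`, `N0 = 1000`.
#' @param t_max Time horizon in mean-lifespan units.
#' @param grid_dt Spacing of the recording grid for trajectories.
#' @param event_cap Maximum number of events per replicate; trajectories
#'   hitting it are flagged as truncated.
#' @param mutate_any_wildtype_replication If `TRUE`, mutations may also
#'   arise in heterozygote cells' wild-type plasmid replications
#'   (sensitivity analysis; off by default to match the analytic model,
#'   which ignores recurrent mutation). Currently only the default
#'   `FALSE` is implemented by the simulator.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(model, mode = c("regular", "random"),
                              u = NULL, N0 = NULL, uN0 = NULL,
                              t_max = 25, grid_dt = 0.5, event_cap = 2e7,
                              mutate_any_wildtype_replication = FALSE) {
  stopifnot(inherits(model, "fitness_model"))
  mode <- match.arg(mode)
  if (is.null(u) || is.null(N0)) {
    if (is.null(uN0)) stop("supply either (u, N0) or uN0")
    N0 <- if (is.null(N0)) 1000L else N0
    u <- uN0 / N0
  }
  stopifnot(u >= 0, u * model$n <= 1, N0 >= 1, N0 == floor(N0),
            t_max > 0, grid_dt > 0)
  if (mutate_any_wildtype_replication) {
    stop("mutation from heterozygote wild-type replications is not ",
         "implemented")
  }
  structure(list(model = model, mode = mode, u = u, N0 = as.integer(N0),
                 t_max = t_max, grid_dt = grid_dt, event_cap = event_cap),
            class = "simulation_config")
}

#' Simulate one population trajectory of the rescue process
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @return An object of class `rescue_trajectory`: list with `time`
#'   (recording grid), `counts` ((n+1) x length(time) matrix of per-type
#'   cell counts; row `i + 1` is type `i`, mutant-lineage cells that
#'   segregate back to type 0 rejoin the wild-type pool), `outcome`
#'   (`"extinct"`, `"surviving"` or `"truncated"`), `t_extinct`,
#'   `first_success_time` (arrival time of the first mutation whose
#'   descendants are alive at the horizon, `NA` if none),
#'   `mutation_times`, `events`.
#' @export
simulate_trajectory <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  model <- config$model
  n <- model$n
  ker <- pair_kernel(n, config$mode)
  flat <- flatten_kernel(ker)
  if (config$mode == "random") {
    hs <- single_mutation_pair_pmf(n)
    hs_cum <- cumsum(hs$prob)
    hs_cum <- hs_cum / hs_cum[length(hs_cum)]
    hs_j <- as.integer(hs$j); hs_k <- as.integer(hs$k)
  } else {
    hs_j <- 1L; hs_k <- 0L; hs_cum <- 1
  }
  grid <- seq(0, config$t_max, by = config$grid_dt)
  res <- cpp_gillespie(n, model$lambda, config$u * n,
                       if (config$mode == "regular") 0L else 1L,
                       flat$offsets, flat$j, flat$k, flat$cum,
                       hs_j, hs_k, hs_cum,
                       as.numeric(config$N0), config$t_max, grid,
                       config$event_cap)
  counts <- res$trajectory
  dimnames(counts) <- list(type = 0:n, NULL)
  structure(
    list(time = grid, counts = counts,
         outcome = c("extinct", "surviving", "truncated")[res$outcome + 1L],
         t_extinct = res$t_extinct,
         first_success_time = res$first_success_time,
         mutation_times = res$mutation_times, events = res$events,
         config = config),
    class = "rescue_trajectory"
  )
}

#' @export
print.rescue_trajectory <- function(x, ...) {
  cat("Rescue trajectory: n =", x$config$model$n, ",", x$config$mode,
      "replication;", x$outcome, "\n")
  cat("  mutations:", length(x$mutation_times),
      "; first successful at:",
      if (is.na(x$first_success_time)) "none"
      else signif(x$first_success_time, 4), "\n")
  invisible(x)
}

#' Replicate rescue simulations and summarize
#'
#' Runs `n_reps` independent trajectories (independent seeded streams
#' derived from `seed`) and reports the rescued fraction --- replicates
#' with mutant-carrying cells alive at the horizon --- together with the
#' survivor-conditioned mean population-size curve and the mean arrival
#' time of the first successful rescue mutation.
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Optional integer master seed.
#' @return A list with `n_reps`, `rescued` (count), `survival_fraction`,
#'   `se` (binomial standard error), `time` (grid),
#'   `survivor_mean` (mean total population among rescued replicates on
#'   the grid; `NULL` if none were rescued), `survivor_trajectories`
#'   (matrix of rescued replicates' total population on the grid),
#'   `mean_first_success` (`NA` if none), `outcomes` (per-replicate data
#'   frame), `truncated` (count).
#' @export
replicate_experiment <- function(config, n_reps, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(n_reps) != 1L || n_reps < 1) stop("n_reps must be >= 1")
  n_reps <- as.integer(n_reps)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, config$t_max, by = config$grid_dt)
  totals <- matrix(0, n_reps, length(grid))
  rescued <- logical(n_reps)
  outc <- character(n_reps)
  tfirst <- rep(NA_real_, n_reps)
  nmut <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    tr <- simulate_trajectory(config)
    totals[r, ] <- colSums(tr$counts)
    rescued[r] <- !is.na(tr$first_success_time)
    outc[r] <- tr$outcome
    tfirst[r] <- tr$first_success_time
    nmut[r] <- length(tr$mutation_times)
  }
  frac <- mean(rescued)
  list(
    n_reps = n_reps, rescued = sum(rescued), survival_fraction = frac,
    se = sqrt(frac * (1 - frac) / n_reps), time = grid,
    survivor_mean = if (any(rescued)) {
      colMeans(totals[rescued, , drop = FALSE])
    } else NULL,
    survivor_trajectories = if (any(rescued)) {
      totals[rescued, , drop = FALSE]
    } else NULL,
    mean_first_success = if (any(rescued)) {
      mean(tfirst[rescued])
    } else NA_real_,
    outcomes = data.frame(replicate = seq_len(n_reps), outcome = outc,
                          rescued = rescued, first_success_time = tfirst,
                          n_mutations = nmut),
    truncated = sum(outc == "truncated")
  )
}

#' Late-time growth rate of surviving populations
#'
#' Log-linear fit of the survivor-conditioned mean population size over
#' the tail of the recording grid; an empirical counterpart to
#' [rescued_growth_rate()].
#'
#' @param experiment Result of [replicate_experiment()].
#' @param window Fraction of the grid (from the end) used for the fit.
#' @return Slope of `log(mean population)` against time.
#' @export
empirical_growth_rate <- function(experiment, window = 0.4) {
  if (is.null(experiment$survivor_mean)) {
    stop("no surviving replicates: growth rate undefined")
  }
  m <- length(experiment$time)
  keep <- seq(ceiling(m * (1 - window)), m)
  y <- experiment$survivor_mean[keep]
  if (any(y <= 0)) stop("survivor mean hits zero in the fit window")
  unname(stats::coef(stats::lm(log(y) ~ experiment$time[keep]))[2L])
}
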