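# Rejection-sampling approximate likelihood over a parameter grid,
# profile-likelihood confidence intervals, and the zero-acceptance bound.

#' Rejection-sampling configuration
#'
#' @param epsilon_pct Acceptance tolerance, percent of the observed
#'   value(s).
#' @param n_sims Simulations per grid point.
#' @param acceptance_mode `"per_component"` applies the tolerance to each
#'   of the four across-locus sums; `"total_sum"` applies it to the
#'   single grand total.
#' @param rng_seed Master seed; per-grid-point child seeds are derived
#'   from it and the parameter values.
#' @param migration_convention Passed to [coalescent_scaling()].
#' @return An object of class `rejection_config`.
#' @export
rejection_config <- function(epsilon_pct = 25, n_sims = 40000,
                             acceptance_mode = c("per_component", "total_sum"),
                             rng_seed = 1,
                             migration_convention = c("wright", "direct")) {
  if (epsilon_pct <= 0) stop("epsilon_pct must be > 0")
  if (n_sims < 1) stop("n_sims must be >= 1")
  structure(list(epsilon_pct = epsilon_pct,
                 n_sims = as.integer(n_sims),
                 acceptance_mode = match.arg(acceptance_mode),
                 rng_seed = as.integer(rng_seed),
                 migration_convention = match.arg(migration_convention)),
            class = "rejection_config")
}

#' Acceptance rule of the rejection sampler
#'
#' A simulation is accepted when its summary statistics lie within
#' `epsilon_pct` percent of the observed: per component
#' (`|sim_k - obs_k| <= eps/100 * obs_k` for all four across-locus sums),
#' or on the grand total.  An observed component of zero degenerates to
#' requiring the simulated component to be zero (a warning is emitted).
#'
#' @param sim_stats Simulated statistics: a one-row tibble, a 4-vector,
#'   or an n x 4 tibble/matrix for vectorised evaluation.
#' @param obs_stats Observed statistics (one-row tibble or 4-vector).
#' @param cfg A [rejection_config()].
#' @return Logical vector, one element per simulated replicate.
#' @export
accept <- function(sim_stats, obs_stats, cfg = rejection_config()) {
  obs <- wh_as_vector(obs_stats)
  sim <- if (is.data.frame(sim_stats)) {
    as.matrix(sim_stats[, WH_CLASSES])
  } else if (is.matrix(sim_stats)) {
    sim_stats
  } else {
    matrix(wh_as_vector(sim_stats), nrow = 1)
  }
  eps <- cfg$epsilon_pct / 100
  if (cfg$acceptance_mode == "total_sum") {
    tot_obs <- sum(obs)
    if (tot_obs == 0) {
      warning("observed total is 0; acceptance requires simulated total 0")
    }
    return(abs(rowSums(sim) - tot_obs) <= eps * tot_obs)
  }
  if (any(obs == 0)) {
    warning("observed component(s) ",
            paste(WH_CLASSES[obs == 0], collapse = ", "),
            " are 0; acceptance requires the simulated component to be 0")
  }
  ok <- abs(sweep(sim, 2, obs)) <= matrix(eps * obs, nrow(sim), 4, byrow = TRUE)
  rowSums(ok) == 4
}

#' Upper bound on the log-likelihood when nothing is accepted
#'
#' With zero acceptances out of `n_sims` simulations, the approximate
#' log-likelihood is bounded above by `ln(1 / n_sims)`.
#'
#' @param n_sims Number of simulations (>= 1).
#' @return The bound in log-likelihood units.
#' @export
zero_acceptance_bound <- function(n_sims) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  log(1 / n_sims)
}

#' Approximate log-likelihood of one parameter combination
#'
#' Runs `cfg$n_sims` multi-locus simulations at `params`, applies the
#' acceptance rule against the observed across-locus sums, and returns
#' `ln(accepted / n_sims)`.  When nothing is accepted the
#' zero-acceptance bound is returned with `is_bound = TRUE`.
#'
#' @param obs Observed Wakeley-Hey sums (from [wakeley_hey()]).
#' @param params A [model_params()].
#' @param specs A [locus_spec()] table.
#' @param mu A [mutation_rate()].
#' @param cfg A [rejection_config()].
#' @param rng_seed Seed for this evaluation; defaults to `cfg$rng_seed`.
#' @return A one-row tibble: `model`, `theta`, `T_gen`, `m`, `tau`,
#'   `n_accepted`, `n_sims`, `lnL`, `is_bound`.
#' @export
approx_lnL <- function(obs, params, specs, mu, cfg = rejection_config(),
                       rng_seed = cfg$rng_seed) {
  sims <- simulate_wh(params, specs, mu, cfg$n_sims, rng_seed = rng_seed,
                      migration_convention = cfg$migration_convention)
  n_acc <- sum(accept(sims, obs, cfg))
  tibble::tibble(
    model = params$model, theta = params$theta, T_gen = params$T_gen,
    m = params$m, tau = params$tau,
    n_accepted = n_acc, n_sims = cfg$n_sims,
    lnL = if (n_acc == 0) zero_acceptance_bound(cfg$n_sims)
          else log(n_acc / cfg$n_sims),
    is_bound = n_acc == 0
  )
}

#' Parameter grid specification
#'
#' Defaults reproduce the study grid: `T_gen` every 1e6 generations in
#' \[0, 2e7\]; `theta` every 0.001 in \[0.001, 0.01\] and every 0.01 in
#' \[0.01, 0.1\] (19 unique values); `tau` every 10% in \[10%, 100%\];
#' `m` every 0.1 in \[0, 1\] and every integer in \[1, 10\] (20 unique
#' values).  Axes not free under `model` are fixed (m = 0 under
#' isolation, tau = 1 unless secondary contact).
#'
#' @param model Model kind; controls which axes are free.
#' @param T_gen,theta,m,tau Optional axis overrides.
#' @return An object of class `grid_spec` (a list of axes).
#' @export
grid_spec <- function(model = MODEL_KINDS,
                      T_gen = seq(0, 2e7, by = 1e6),
                      theta = unique(c(seq(0.001, 0.01, by = 0.001),
                                       seq(0.01, 0.1, by = 0.01))),
                      m = unique(c(seq(0, 1, by = 0.1), 1:10)),
                      tau = seq(0.1, 1, by = 0.1)) {
  model <- match.arg(model)
  if (model == "isolation") m <- 0
  if (model != "secondary_contact") tau <- 1
  axes <- list(model = model, T_gen = T_gen, theta = theta, m = m, tau = tau)
  if (any(lengths(axes[-1]) == 0)) stop("empty grid axis")
  structure(axes, class = "grid_spec")
}

# deterministic child seed from the master seed and the parameter values
child_seed <- function(master, theta, T_gen, m, tau) {
  v <- (as.double(master) + 7 * round(theta * 1e6) + 11 * round(T_gen / 1e5) +
          13 * round(m * 100) + 17 * round(tau * 100))
  as.integer(v %% 2147483647)
}

#' Grid search of the approximate likelihood surface
#'
#' Evaluates [approx_lnL()] at every grid point.  Each point gets a child
#' seed derived from the master seed and its parameter values, so the
#' same point evaluated inside two different (nested) grids sees the same
#' simulation stream.
#'
#' @inheritParams approx_lnL
#' @param model Model kind.
#' @param grid A [grid_spec()]; defaults to the study grid for `model`.
#' @return A `lik_surface`: a tibble with one row per grid point and
#'   attributes `model`, `cfg`, `mle` (the first row attaining the
#'   maximum `lnL`).
#' @export
grid_search <- function(obs, model = MODEL_KINDS, grid = grid_spec(model),
                        specs, mu, cfg = rejection_config()) {
  model <- match.arg(model)
  if (grid$model != model) stop("grid was built for model ", grid$model)
  pts <- tidyr::crossing(T_gen = grid$T_gen, theta = grid$theta,
                         m = grid$m, tau = grid$tau)
  if (nrow(pts) == 0) stop("empty grid")
  rows <- purrr::pmap(pts, function(T_gen, theta, m, tau) {
    p <- model_params(model, theta = theta, T_gen = T_gen, m = m, tau = tau)
    seed <- child_seed(cfg$rng_seed, theta, T_gen, m, tau)
    out <- approx_lnL(obs, p, specs, mu, cfg, rng_seed = seed)
    out$child_seed <- seed
    out
  })
  surface <- dplyr::bind_rows(rows)
  mle_idx <- which.max(surface$lnL)
  structure(surface,
            model = model, cfg = cfg, mle = surface[mle_idx, ],
            class = c("lik_surface", class(surface)))
}

#' Maximum-likelihood row of a surface
#'
#' @param surface A `lik_surface` from [grid_search()].
#' @return The first grid row attaining the maximum `lnL`.
#' @export
surface_mle <- function(surface) {
  attr(surface, "mle") %||% surface[which.max(surface$lnL), ]
}

#' Profile-likelihood confidence interval along one axis
#'
#' Profiles the surface over `axis` (maximum `lnL` over the other axes at
#' each value) and returns the outermost axis values whose profile lies
#' within 1.92 log-likelihood units of the maximum (the chi-square 95%
#' cutoff for one parameter).  An interval touching the grid boundary is
#' flagged censored.
#'
#' @param surface A `lik_surface` (or any tibble with the parameter
#'   columns and `lnL`).
#' @param axis One of `"theta"`, `"T_gen"`, `"m"`, `"tau"`.
#' @param drop_lnL Log-likelihood drop defining the interval (1.92 for a
#'   95% CI).
#' @return A one-row tibble: `axis`, `mle`, `low`, `high`,
#'   `censored_low`, `censored_high`.
#' @export
profile_ci <- function(surface, axis = c("theta", "T_gen", "m", "tau"),
                       drop_lnL = 1.92) {
  axis <- match.arg(axis)
  if (nrow(surface) == 0) stop("empty surface")
  prof <- dplyr::summarise(dplyr::group_by(surface, .data[[axis]]),
                           lnL = max(.data$lnL), .groups = "drop")
  prof <- dplyr::arrange(prof, .data[[axis]])
  vals <- prof[[axis]]
  max_lnL <- max(prof$lnL)
  keep <- prof$lnL >= max_lnL - drop_lnL
  tibble::tibble(
    axis = axis,
    mle = vals[which.max(prof$lnL)],
    low = min(vals[keep]),
    high = max(vals[keep]),
    censored_low = min(vals[keep]) == min(vals),
    censored_high = max(vals[keep]) == max(vals)
  )
}

#' @export
tidy.lik_surface <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.lik_surface <- function(x, ...) {
  mle <- surface_mle(x)
  tibble::tibble(model = attr(x, "model"),
                 n_points = nrow(x),
                 max_lnL = mle$lnL,
                 theta = mle$theta, T_gen = mle$T_gen,
                 m = mle$m, tau = mle$tau,
                 is_bound = mle$is_bound)
}

#' @export
autoplot.lik_surface <- function(object, x = "T_gen", y = "theta", ...) {
  df <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data[[x]], .data[[y]]),
    lnL = max(.data$lnL), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], factor(.data[[y]]),
                                   fill = .data$lnL)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = x, y = y, fill = "lnL",
                  title = paste("Approximate log-likelihood surface:",
                                attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' Write / read a likelihood surface as tidy delimited text
#'
#' @param surface A `lik_surface`.
#' @param path Output TSV path.
#' @return `path` invisibly; `read_surface()` returns the tibble.
#' @export
write_surface <- function(surface, path) {
  utils::write.table(tibble::as_tibble(surface), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
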