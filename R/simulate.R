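#' Simulation settings for the Langevin integrator
#'
#' The time step must resolve the fastest drift scale:
#' `dt * max(|lambda|)` is checked at run time — a warning is issued above
#' 0.1 and an error above 0.5 (Euler-Maruyama accuracy/stability guard).
#'
#' @param dt Positive real integration step.
#' @param n_steps Positive integer, total number of integration steps.
#' @param burn_in Nonnegative integer, initial steps discarded.
#' @param seed Integer RNG seed; all randomness (initial draw and noise)
#'   flows from it.
#' @param initial `"stationary"` (default; initial field drawn from the
#'   Lyapunov covariance, avoiding transient bias in stationary estimators),
#'   `"zero"`, or an explicit numeric vector.
#' @param save_stride Positive integer; every `save_stride`-th post-burn-in
#'   configuration is stored. Keep 1 for path-entropy estimation (the
#'   Stratonovich sum needs consecutive integration steps).
#' @return An object of class `amari_sim_config`.
#' @export
simulation_config <- function(dt, n_steps, burn_in = 0L, seed = 1L,
                              initial = "stationary", save_stride = 1L) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(n_steps), n_steps >= 1,
            is.numeric(burn_in), burn_in >= 0, burn_in < n_steps,
            is.numeric(save_stride), save_stride >= 1)
  if (is.character(initial)) {
    initial <- match.arg(initial, c("stationary", "zero"))
  } else {
    stopifnot(is.numeric(initial))
  }
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 initial = initial, save_stride = as.integer(save_stride)),
            class = "amari_sim_config")
}

#' Integrate the linear Langevin field dynamics
#'
#' Euler-Maruyama integration of `deta = Lambda eta dt + dW`, with spatial
#' noise covariance `Gamma` (`dW = sqrt(dt) B z`, `B t(B) = Gamma`, `z`
#' i.i.d. standard normal). With additive noise the SDE itself has no
#' Ito/Stratonovich ambiguity; the Stratonovich subtlety enters only in the
#' entropy-production functional ([lebowitz_spohn_estimate()]). Trajectories
#' are bit-reproducible given the config seed.
#'
#' @param model An [build_model()] object, or a bare drift matrix.
#' @param noise An [build_noise()] object, or a symmetric positive-definite
#'   covariance matrix.
#' @param config An [simulation_config()].
#' @return An object of class `amari_trajectory`: list with `times`,
#'   `fields` (matrix, one row per saved configuration), `dt` (integration
#'   step), `save_stride`, `seed`, and `model_fingerprint`.
#' @examples
#' g <- discrete_grid(4)
#' m <- build_model(g, 1, sigmoid(2, 0.5), kernel_spec("zero"))
#' nz <- build_noise(noise_spec("white"), g)
#' tr <- simulate_field(m, nz, simulation_config(0.01, 500, seed = 7))
#' dim(tr$fields)
#' @export
simulate_field <- function(model, noise, config) {
  stopifnot(inherits(config, "amari_sim_config"))
  drift <- if (inherits(model, "amari_model")) model$drift_matrix else model
  assert_square(drift, "drift")
  if (inherits(noise, "amari_noise")) {
    G <- noise$covariance
    B <- noise$factor
  } else {
    G <- noise
    assert_symmetric(G, "noise covariance", tol = 1e-8)
    B <- spd_factor(G, "noise covariance")
  }
  n <- nrow(drift)
  if (nrow(G) != n) stop("model and noise grids do not match", call. = FALSE)
  ev_scale <- max(Mod(eigen(drift, only.values = TRUE)$values))
  guard <- config$dt * ev_scale
  if (guard > 0.5) {
    stop(sprintf("dt * max|eigenvalue| = %.3g > 0.5: integration unstable",
                 guard), call. = FALSE)
  }
  if (guard > 0.1) {
    warning(sprintf("dt * max|eigenvalue| = %.3g > 0.1: poorly resolved",
                    guard))
  }
  set.seed(config$seed)
  eta0 <- if (is.numeric(config$initial)) {
    stopifnot(length(config$initial) == n)
    as.numeric(config$initial)
  } else if (config$initial == "zero") {
    numeric(n)
  } else {
    st <- solve_lyapunov(drift, G)
    as.numeric(t(chol(st$covariance)) %*% rnorm(n))
  }
  step_matrix <- diag(n) + config$dt * drift
  fields <- em_integrate(step_matrix, B, eta0,
                         config$n_steps, config$burn_in, config$save_stride,
                         sqrt(config$dt))
  dt_save <- config$dt * config$save_stride
  structure(
    list(times = config$dt * config$burn_in + dt_save * seq_len(nrow(fields)),
         fields = fields, dt = config$dt, save_stride = config$save_stride,
         seed = config$seed,
         model_fingerprint = model_fingerprint(drift, G)),
    class = "amari_trajectory")
}

#' @export
print.amari_trajectory <- function(x, ...) {
  cat(sprintf(
    "Langevin trajectory: %d saved configurations x %d sites, dt = %g (stride %d)\n",
    nrow(x$fields), ncol(x$fields), x$dt, x$save_stride))
  invisible(x)
}

#' Time-reversed trajectory
#'
#' Returns the backward trajectory `etabar(s) = eta(t - s)`: the same
#' configurations in reversed order, with identical time step. Applying it
#' twice reproduces the input exactly (involution).
#'
#' @param traj An [simulate_field()] trajectory.
#' @return An `amari_trajectory` with reversed configuration order.
#' @export
time_reverse <- function(traj) {
  stopifnot(inherits(traj, "amari_trajectory"))
  traj$fields <- traj$fields[rev(seq_len(nrow(traj$fields))), , drop = FALSE]
  traj
}

#' Empirical stationary mode correlators from a trajectory
#'
#' Transforms each saved configuration to mode amplitudes
#' `eta_k = sqrt(dx / N) * sum_j eta_j exp(-i k x_j)` (the normalization
#' under which the mode noise amplitude is exactly the noise transform
#' `gamma_k` of [spectral_entropy_production()]), and estimates the
#' stationary variance `<|eta_k|^2>` and the Stratonovich velocity-field
#' correlator `<etadot_k eta_k*>` (finite-difference velocity paired with
#' the midpoint amplitude). Standard errors come from non-overlapping block
#' means with block length `>= 10` relaxation times of the slowest mode,
#' resampled by a block bootstrap.
#'
#' @param traj An [simulate_field()] trajectory (post burn-in, stationary).
#' @param grid The [discrete_grid()] the fields live on.
#' @param relax_time Optional slowest relaxation time `1 / min|Re lambda|`
#'   used to set the block length; default infers nothing and uses
#'   `max(100 * dt, T / 50)`.
#' @param n_boot Bootstrap replicates (default 200).
#' @return A data frame with one row per mode `m`: variance and correlator
#'   estimates with standard errors (`var_hat`, `var_se`, `cds_re`,
#'   `cds_im`, `cds_re_se`, `cds_im_se`).
#' @export
empirical_mode_correlators <- function(traj, grid, relax_time = NULL,
                                       n_boot = 200L) {
  stopifnot(inherits(traj, "amari_trajectory"), inherits(grid, "amari_grid"))
  F <- traj$fields
  T_n <- nrow(F)
  n <- ncol(F)
  stopifnot(n == grid$n_points)
  dt <- traj$dt * traj$save_stride
  # mode amplitudes: rows of F transformed across space
  amps <- sqrt(grid$spacing / n) * t(stats::mvfft(t(F)))   # T x n complex
  m_fft <- 0:(n - 1)
  m_signed <- ((m_fft + n %/% 2) %% n) - n %/% 2
  ord <- order(m_signed)

  horizon <- T_n * dt
  block_len <- if (is.null(relax_time)) {
    max(100 * dt, horizon / 50)
  } else {
    max(10 * relax_time, 100 * dt)
  }
  steps_per_block <- max(1L, floor(block_len / dt))
  n_blocks <- floor((T_n - 1) / steps_per_block)
  if (n_blocks < 20L) {
    stop(sprintf(
      "trajectory too short for blocking: %d blocks < 20 (block length %g)",
      n_blocks, block_len), call. = FALSE)
  }

  block_boot_se <- function(x) {
    # x: numeric series; returns SE of its mean via block bootstrap
    usable <- n_blocks * steps_per_block
    bm <- colMeans(matrix(x[seq_len(usable)], steps_per_block, n_blocks))
    reps <- vapply(seq_len(n_boot), function(i) {
      mean(bm[sample.int(n_blocks, n_blocks, replace = TRUE)])
    }, numeric(1))
    stats::sd(reps)
  }

  out <- vector("list", n)
  for (j in seq_len(n)) {
    a <- amps[, ord[j]]
    v2 <- Mod(a)^2
    adot <- (a[-1] - a[-T_n]) / dt
    amid <- (a[-1] + a[-T_n]) / 2
    cds <- adot * Conj(amid)
    out[[j]] <- data.frame(
      m = m_signed[ord][j],
      var_hat = mean(v2), var_se = block_boot_se(v2),
      cds_re = mean(Re(cds)), cds_re_se = block_boot_se(Re(cds)),
      cds_im = mean(Im(cds)), cds_im_se = block_boot_se(Im(cds)))
  }
  res <- do.call(rbind, out)
  attr(res, "n_blocks") <- n_blocks
  res
}
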