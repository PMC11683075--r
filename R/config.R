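# Run configuration: every free parameter of the simulator in one nested
# list, with validation, YAML round-trip, and override resolution.

#' Default simulator configuration
#'
#' All free parameters of the simulator, grouped by section:
#' \describe{
#'   \item{homeostat}{setpoint \eqn{H^*} = 200, exponents (m, n) = (3, 4),
#'     interoceptive gain eta = 1, decay constant tau = 100.}
#'   \item{agent}{per-task learning parameters. The two tasks use different
#'     inverse temperatures because their reward ranges differ once values
#'     have propagated across the mountain's eight states. With rewards on
#'     the scale of \eqn{|H^*-H|^3} (up to ~1e6), beta must be of order
#'     1e-6 to 1e-4 for the softmax to stay out of saturation.}
#'   \item{tasks}{intake task: k_intake = 40, 100-step episodes; mountain:
#'     k_small = 20, k_large = 120, climb_cost = 10, 5000-step episode cap,
#'     15 episodes per trial.}
#'   \item{experiment}{replicate counts (40 intake episodes, 30 mountain
#'     trials), base seed, and the manipulated condition values: eta = 0.3
#'     (blunted) / 1.7 (exaggerated interoception), low beta = control/4,
#'     low gamma = 0.2.}
#'   \item{output}{output directory and per-timestep logging switch.}
#' }
#'
#' Each task section carries its own decay constant \code{tau}: nutrient
#' turnover is fast in the intake task (tau = 25), so one 100-step episode
#' spans many intake cycles and a non-learning agent settles in mild deficit,
#' while the mountain task uses slow turnover (tau = 100) so a trial's climbs
#' drain the internal state gradually.
#'
#' @return nested configuration list of class \code{hrl_config}.
#' @export
default_config <- function() {
  structure(list(
    homeostat = list(setpoint = 200, m = 3, n = 4, eta = 1, tau = 100),
    agent = list(
      intake   = list(alpha_q = 0.05, alpha_k = 0.5, beta = 1.6e-05, gamma = 0.9),
      mountain = list(alpha_q = 0.1, alpha_k = 0.5, beta = 2e-07, gamma = 0.9)),
    tasks = list(
      intake   = list(k_intake = 12, episode_length = 100, tau = 25),
      mountain = list(k_small = 20, k_large = 120, climb_cost = 10,
                      step_cap = 5000, n_episodes = 15, tau = 100)),
    experiment = list(
      n_replicates_intake = 40, n_trials_mountain = 30, base_seed = 1,
      conditions = list(low_eta = 0.3, high_eta = 1.7,
                        low_beta_factor = 0.25, low_gamma = 0.2)),
    output = list(dir = "results", per_timestep_log = FALSE)
  ), class = "hrl_config")
}

check_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(names(ref), names(cfg))
  if (length(missing))
    stop("missing config key(s): ",
         paste0(path, missing, collapse = ", "), call. = FALSE)
  for (k in names(ref)) {
    if (is.list(ref[[k]])) {
      if (!is.list(cfg[[k]]))
        stop("config section `", path, k, "` must be a list", call. = FALSE)
      check_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Validate a configuration
#'
#' Rejects unknown or missing keys (compared against
#' \code{\link{default_config}}'s skeleton) and checks parameter ranges.
#'
#' @param config configuration list.
#' @return \code{TRUE} invisibly; errors list the offending keys.
#' @export
validate_config <- function(config) {
  check_keys(config, default_config())
  h <- config$homeostat
  if (h$tau <= 1) stop("homeostat.tau must be > 1")
  if (h$m <= 0 || h$n <= 0) stop("homeostat exponents m, n must be positive")
  if (h$eta < 0) stop("homeostat.eta must be non-negative")
  for (tk in c("intake", "mountain")) {
    a <- config$agent[[tk]]
    if (a$alpha_q <= 0 || a$alpha_q > 1 || a$alpha_k <= 0 || a$alpha_k > 1)
      stop("agent.", tk, " learning rates must be in (0, 1]")
    if (a$beta < 0) stop("agent.", tk, ".beta must be >= 0")
    if (a$gamma < 0 || a$gamma > 1) stop("agent.", tk, ".gamma must be in [0, 1]")
  }
  if (config$tasks$intake$k_intake <= 0) stop("tasks.intake.k_intake must be > 0")
  if (config$tasks$intake$episode_length < 1)
    stop("tasks.intake.episode_length must be >= 1")
  if (config$tasks$intake$tau <= 1 || config$tasks$mountain$tau <= 1)
    stop("task decay constants tau must be > 1")
  if (config$tasks$mountain$step_cap <= 0)
    stop("tasks.mountain.step_cap must be > 0")
  if (config$experiment$n_replicates_intake < 2 ||
      config$experiment$n_trials_mountain < 2)
    stop("experiment replicate counts must be >= 2")
  invisible(TRUE)
}

#' Apply overrides onto a configuration
#'
#' @param config base configuration.
#' @param overrides nested list of replacements; keys must already exist.
#' @return the resolved (and validated) configuration.
#' @export
resolve_config <- function(config = default_config(), overrides = list()) {
  merge_into <- function(base, ov, path = "") {
    for (k in names(ov)) {
      if (!k %in% names(base))
        stop("unknown config key: ", path, k, call. = FALSE)
      if (is.list(ov[[k]])) base[[k]] <- merge_into(base[[k]], ov[[k]],
                                                    paste0(path, k, "."))
      else base[[k]] <- ov[[k]]
    }
    base
  }
  out <- merge_into(config, overrides)
  class(out) <- "hrl_config"
  validate_config(out)
  out
}

#' Read / write a configuration as YAML
#'
#' The fully-resolved configuration is echoed into every output directory so
#' a run's provenance is a diffable text file.
#'
#' @param path file path.
#' @param config configuration list.
#' @return \code{read_config}: validated \code{hrl_config};
#'   \code{write_config}: the path, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- resolve_config(default_config(), cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
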