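# Conditions, replicate execution with seed management, behavioral metrics.

#' Trajectory metrics (intake task)
#'
#' \code{avg_reward_per_intake}: total reward obtained on intake timesteps
#' divided by the number of intakes; \code{NA} when no intake occurred. This
#' uses the agent's interoceptively modulated reward — it quantifies reward
#' system activity, which scales with the gain eta.
#'
#' \code{sum_punishment} (\eqn{\sum_t \max(0, -r_t)}) and \code{sum_drive}
#' (\eqn{\sum_t D(H_t)}, drive before each action) are computed from the
#' veridical (eta = 1) drive recorded on the trajectory: they quantify actual
#' homeostatic failure — time spent away from the setpoint and transitions
#' that truly worsened the internal state — independent of how strongly the
#' agent perceives it. With eta = 1 the modulated and veridical streams
#' coincide.
#'
#' \code{total_intake}: number of intake actions.
#'
#' @param traj a trajectory data frame from \code{\link{run_episode}}.
#' @param intake_actions action label(s) counting as an intake.
#' @return scalar metric value.
#' @name intake-metrics
NULL

#' @rdname intake-metrics
#' @export
avg_reward_per_intake <- function(traj, intake_actions = "intake") {
  stopifnot(nrow(traj) > 0)
  is_intake <- traj$action %in% intake_actions
  if (!any(is_intake)) return(NA_real_)
  sum(traj$reward[is_intake]) / sum(is_intake)
}

#' @rdname intake-metrics
#' @export
sum_punishment <- function(traj) sum(pmax(0, -traj$reward_true))

#' @rdname intake-metrics
#' @export
sum_drive <- function(traj) sum(traj$drive_true)

#' @rdname intake-metrics
#' @export
total_intake <- function(traj, intake_actions = "intake") {
  sum(traj$action %in% intake_actions)
}

#' Trial metrics (mountain task)
#'
#' \code{s7_rate}: timesteps whose pre-action state is the summit S7, divided
#' by the trial's total timesteps. \code{total_timesteps}: sum of all episode
#' lengths in the trial. \code{a00_timesteps}: number of small-intake actions
#' across the trial. High summit rate, few timesteps and few small intakes
#' characterise a preference for the large delayed reward.
#'
#' @param trial an \code{hrl_trial} from \code{\link{run_trial}}.
#' @return scalar metric value.
#' @name mountain-metrics
NULL

#' @rdname mountain-metrics
#' @export
s7_rate <- function(trial) {
  tr <- bind_trial(trial)
  sum(tr$state == "S7") / nrow(tr)
}

#' @rdname mountain-metrics
#' @export
total_timesteps <- function(trial) {
  sum(vapply(trial$episodes, nrow, integer(1)))
}

#' @rdname mountain-metrics
#' @export
a00_timesteps <- function(trial) {
  tr <- bind_trial(trial)
  sum(tr$action == "small_intake")
}

#' Define an experimental condition
#'
#' A condition names a set of parameter overrides applied on top of the base
#' configuration: the interoceptive gain \code{eta}, the inverse temperature
#' \code{beta}, the discount rate \code{gamma} (and, if needed, the learning
#' rates). \code{NULL} leaves the base value untouched.
#'
#' @param name condition label.
#' @param eta,beta,gamma,alpha_q,alpha_k optional overrides.
#' @param n_replicates number of independent replicates (>= 2).
#' @param base_seed integer; replicate \code{i} is seeded with
#'   \code{base_seed + i}.
#' @return an object of class \code{hrl_condition}.
#' @export
condition <- function(name, eta = NULL, beta = NULL, gamma = NULL,
                      alpha_q = NULL, alpha_k = NULL,
                      n_replicates = 40, base_seed = 1) {
  stopifnot(is.character(name), length(name) == 1,
            n_replicates >= 2, is.finite(base_seed))
  ov <- list(eta = eta, beta = beta, gamma = gamma,
             alpha_q = alpha_q, alpha_k = alpha_k)
  ov <- ov[!vapply(ov, is.null, logical(1))]
  structure(list(name = name, overrides = ov,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed)),
            class = "hrl_condition")
}

#' @export
print.hrl_condition <- function(x, ...) {
  ov <- if (length(x$overrides))
    paste(names(x$overrides), unlist(x$overrides), sep = "=", collapse = ", ")
  else "none"
  cat("<hrl_condition>", x$name, "| overrides:", ov,
      "| n =", x$n_replicates, "| base_seed =", x$base_seed, "\n")
  invisible(x)
}

#' The standard condition set
#'
#' Control plus the four manipulations studied with the simulator: blunted
#' interoception (eta = 0.3), exaggerated interoception (eta = 1.7), low
#' inverse temperature (beta = control/4), and low discount rate
#' (gamma = 0.2). The manipulated values are package defaults chosen inside
#' the ranges explored with each manipulation; all are overridable.
#'
#' @param config base configuration (see \code{\link{default_config}}).
#' @param task \code{"intake"} or \code{"mountain"} (selects replicate count
#'   and the task-specific base beta).
#' @param base_seed seed offset handed to each condition; conditions get
#'   disjoint seed blocks so arms are independent samples.
#' @return named list of \code{\link{condition}} objects.
#' @export
default_conditions <- function(config = default_config(),
                               task = c("intake", "mountain"),
                               base_seed = config$experiment$base_seed) {
  task <- match.arg(task)
  n <- if (task == "intake") config$experiment$n_replicates_intake
       else config$experiment$n_trials_mountain
  beta0 <- config$agent[[task]]$beta
  cc <- config$experiment$conditions
  block <- function(k) as.integer(base_seed + k * 10000L)
  list(
    control   = condition("control",                       n_replicates = n, base_seed = block(0L)),
    low_eta   = condition("low_eta",  eta = cc$low_eta,    n_replicates = n, base_seed = block(1L)),
    high_eta  = condition("high_eta", eta = cc$high_eta,   n_replicates = n, base_seed = block(2L)),
    low_beta  = condition("low_beta", beta = beta0 * cc$low_beta_factor,
                          n_replicates = n, base_seed = block(3L)),
    low_gamma = condition("low_gamma", gamma = cc$low_gamma,
                          n_replicates = n, base_seed = block(4L))
  )
}

build_space <- function(config, overrides = list(), task = NULL) {
  h <- config$homeostat
  tau <- if (!is.null(task) && !is.null(config$tasks[[task]]$tau))
    config$tasks[[task]]$tau else h$tau
  homeostatic_space(
    setpoint = h$setpoint, m = h$m, n = h$n,
    eta = if (!is.null(overrides$eta)) overrides$eta else h$eta,
    tau = tau)
}

build_params <- function(config, task, overrides = list()) {
  a <- config$agent[[task]]
  pick <- function(key) if (!is.null(overrides[[key]])) overrides[[key]] else a[[key]]
  agent_params(alpha_q = pick("alpha_q"), alpha_k = pick("alpha_k"),
               beta = pick("beta"), gamma = pick("gamma"))
}

build_task <- function(config, task) {
  if (task == "intake") {
    tc <- config$tasks$intake
    build_intake_task(k_intake = tc$k_intake, episode_length = tc$episode_length)
  } else {
    tc <- config$tasks$mountain
    build_mountain_task(k_small = tc$k_small, k_large = tc$k_large,
                        climb_cost = tc$climb_cost, step_cap = tc$step_cap)
  }
}

#' Run all replicates of a condition
#'
#' Each replicate is an independent fresh agent in a fresh environment,
#' seeded with \code{base_seed + i}. For the intake task a replicate is one
#' 100-step episode; for the mountain task a replicate is one trial of
#' consecutive episodes with values carried over. Metrics are assembled into
#' one row per replicate.
#'
#' @param cond an \code{\link{condition}}.
#' @param task \code{"intake"} or \code{"mountain"}.
#' @param config base configuration list (see \code{\link{default_config}}).
#' @return data frame of class \code{condition_result}, one row per
#'   replicate: intake task columns \code{avg_reward_per_intake},
#'   \code{sum_punishment}, \code{sum_drive}, \code{total_intake}; mountain
#'   task columns \code{s7_rate}, \code{total_timesteps},
#'   \code{a00_timesteps}, \code{censored_episodes}.
#' @export
run_condition <- function(cond, task = c("intake", "mountain"),
                          config = default_config()) {
  stopifnot(inherits(cond, "hrl_condition"))
  task <- match.arg(task)
  validate_config(config)
  space  <- build_space(config, cond$overrides, task)
  params <- build_params(config, task, cond$overrides)
  tsk    <- build_task(config, task)
  n <- cond$n_replicates
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed <- cond$base_seed + i
    set.seed(seed)
    row <- tryCatch({
      if (task == "intake") {
        res <- run_episode(tsk, space, params)
        tr <- res$trajectory
        data.frame(condition = cond$name, replicate = i, seed = seed,
                   avg_reward_per_intake = avg_reward_per_intake(tr),
                   sum_punishment = sum_punishment(tr),
                   sum_drive = sum_drive(tr),
                   total_intake = total_intake(tr),
                   stringsAsFactors = FALSE)
      } else {
        trial <- run_trial(tsk, space, params,
                           n_episodes = config$tasks$mountain$n_episodes)
        data.frame(condition = cond$name, replicate = i, seed = seed,
                   s7_rate = s7_rate(trial),
                   total_timesteps = total_timesteps(trial),
                   a00_timesteps = a00_timesteps(trial),
                   censored_episodes = sum(trial$censored),
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      stop("replicate ", i, " (seed ", seed, ") of condition '", cond$name,
           "' failed: ", conditionMessage(e))
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("condition_result", "data.frame")
  attr(out, "task") <- task
  out
}

#' Summarise a condition result
#'
#' @param result a \code{condition_result} from \code{\link{run_condition}}.
#' @return named list per metric: mean, sd, n (NA metric values dropped,
#'   with the drop count reported).
#' @export
summarize_condition <- function(result) {
  stopifnot(inherits(result, "condition_result"))
  metrics <- setdiff(names(result), c("condition", "replicate", "seed"))
  out <- lapply(metrics, function(mname) {
    v <- result[[mname]]
    ok <- !is.na(v)
    list(mean = mean(v[ok]), sd = stats::sd(v[ok]), n = sum(ok),
         n_dropped = sum(!ok))
  })
  names(out) <- metrics
  out
}
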