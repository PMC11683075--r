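# The two environments: intake-after-food-restriction and mountain climbing,
# plus the episode/trial simulation loop.

new_task <- function(name, states, actions, next_state, intake, cost, terminal,
                     initial_state, initial_H, episode_length = NA_integer_,
                     step_cap = NA_integer_) {
  n_actions <- apply(actions, 1, function(r) sum(!is.na(r)))
  for (s in seq_along(states)) for (a in seq_len(n_actions[s])) {
    if (is.na(next_state[s, a]) || is.na(intake[s, a]) || is.na(cost[s, a]))
      stop("incomplete transition table for (", states[s], ", ", actions[s, a], ")")
    if (intake[s, a] < 0 || cost[s, a] < 0)
      stop("intake and cost must be non-negative")
  }
  structure(
    list(name = name, states = states, actions = actions,
         n_actions = n_actions, next_state = next_state, intake = intake,
         cost = cost, terminal = terminal,
         initial_state = initial_state, initial_H = initial_H,
         episode_length = episode_length, step_cap = step_cap),
    class = "hrl_task")
}

#' @export
print.hrl_task <- function(x, ...) {
  cat("<hrl_task>", x$name, "-", length(x$states), "state(s), actions:",
      paste(unique(stats::na.omit(as.vector(x$actions))), collapse = "/"), "\n")
  invisible(x)
}

#' Intake-after-food-restriction task
#'
#' One external state \code{S0} and two actions: \code{nothing} (K = 0) and
#' \code{intake} (K = \code{k_intake}). The agent starts in nutrient deficit
#' (H = \code{initial_H}, below the setpoint) and an episode runs for a fixed
#' number of timesteps; there is no terminal action.
#'
#' @param k_intake nutrient amount delivered by one intake action (> 0).
#'   Default 12.
#' @param episode_length fixed episode horizon in timesteps. Default 100.
#' @param initial_H internal state at episode start. Default 100 (the
#'   food-restricted state, with setpoint 200).
#' @return an object of class \code{hrl_task}.
#' @export
build_intake_task <- function(k_intake = 12, episode_length = 100, initial_H = 100) {
  if (!is.numeric(k_intake) || length(k_intake) != 1 || k_intake <= 0)
    stop("`k_intake` must be positive")
  if (!is.numeric(episode_length) || length(episode_length) != 1 || episode_length < 1)
    stop("`episode_length` must be >= 1")
  states <- "S0"
  actions <- matrix(c("nothing", "intake"), 1, 2, dimnames = list(states, NULL))
  new_task("intake_after_food_restriction", states, actions,
           next_state = matrix(c(1L, 1L), 1, 2),
           intake     = matrix(c(0, k_intake), 1, 2),
           cost       = matrix(c(0, 0), 1, 2),
           terminal   = matrix(c(FALSE, FALSE), 1, 2),
           initial_state = 1L, initial_H = initial_H,
           episode_length = as.integer(episode_length))
}

#' Mountain-climbing task
#'
#' Eight states \code{S0}..\code{S7} with two actions each, probing the
#' balance between a small immediate reward and a large delayed one:
#' \itemize{
#'   \item \code{S0} (bottom): \code{small_intake} (K = \code{k_small},
#'     stays in S0) or \code{move} (to S1).
#'   \item \code{S1}: \code{climb} (to S2, costing \code{climb_cost}) or
#'     \code{move} (back to S0).
#'   \item \code{S2}..\code{S6}: \code{climb} (up, with cost) or
#'     \code{descend} (down, cost-free).
#'   \item \code{S7} (summit): \code{large_intake} (K = \code{k_large}) ends
#'     the episode and returns the agent to S0, or \code{descend} (to S6).
#' }
#' Climb actions drain the internal state by \code{climb_cost} on top of the
#' natural decay, acting as an immediate punishment on the way to the summit
#' reward. (The summit intake is labelled a70 in the task's state diagram and
#' a71 in some renderings; here it is canonically \code{large_intake}.)
#'
#' @param k_small small intake at the bottom state. Default 20.
#' @param k_large large intake at the summit. Default 120.
#' @param climb_cost nutrient cost of each climb action. Default 10.
#' @param step_cap per-episode cap on timesteps; an episode that has not
#'   reached the summit intake by then is censored (recorded, not an error).
#'   Default 5000.
#' @param initial_H internal state at episode start. Default 100.
#' @return an object of class \code{hrl_task}.
#' @export
build_mountain_task <- function(k_small = 20, k_large = 120, climb_cost = 10,
                                step_cap = 5000, initial_H = 100) {
  stopifnot(k_small > 0, k_large > 0, climb_cost >= 0)
  if (!is.numeric(step_cap) || length(step_cap) != 1 || step_cap <= 0)
    stop("`step_cap` must be positive")
  states <- paste0("S", 0:7)
  actions <- matrix(NA_character_, 8, 2, dimnames = list(states, NULL))
  nxt  <- matrix(NA_integer_, 8, 2)
  intk <- matrix(NA_real_, 8, 2)
  cst  <- matrix(NA_real_, 8, 2)
  term <- matrix(FALSE, 8, 2)
  # rows are S0..S7 = indices 1..8
  actions[1, ] <- c("small_intake", "move");  nxt[1, ] <- c(1L, 2L)
  intk[1, ] <- c(k_small, 0); cst[1, ] <- c(0, 0)
  actions[2, ] <- c("climb", "move");         nxt[2, ] <- c(3L, 1L)
  intk[2, ] <- c(0, 0); cst[2, ] <- c(climb_cost, 0)
  for (s in 3:7) {                            # S2..S6
    actions[s, ] <- c("climb", "descend");    nxt[s, ] <- c(s + 1L, s - 1L)
    intk[s, ] <- c(0, 0); cst[s, ] <- c(climb_cost, 0)
  }
  actions[8, ] <- c("large_intake", "descend"); nxt[8, ] <- c(1L, 7L)
  intk[8, ] <- c(k_large, 0); cst[8, ] <- c(0, 0)
  term[8, 1] <- TRUE
  new_task("mountain_climbing", states, actions, nxt, intk, cst, term,
           initial_state = 1L, initial_H = initial_H,
           step_cap = as.integer(step_cap))
}

#' Run one episode
#'
#' Starting at the task's initial state with H = \code{initial_H}, repeats the
#' decision cycle: softmax probabilities from the Q-row -> draw an action ->
#' reward from the \emph{predicted} intake (including the action's cost) ->
#' apply the actual transition -> TD update of Q -> delta-rule update of
#' \eqn{\hat K}. The episode ends when a terminal (state, action) pair fires,
#' when the fixed horizon is reached (intake task), or at the step cap
#' (mountain task; flagged as censored, not an error). Terminal transitions
#' bootstrap from the successor state (S0) because values are carried over
#' into the next episode rather than reset.
#'
#' Besides the agent's (interoceptively modulated) drive and reward, each
#' step also records the veridical quantities computed with gain eta = 1
#' (\code{drive_true}, \code{reward_true}): the modulated signal is what the
#' agent learns from, the veridical signal measures what actually happened
#' to its physiology. The two coincide when eta = 1.
#'
#' @param task an \code{hrl_task}.
#' @param space a \code{\link{homeostatic_space}}.
#' @param params an \code{\link{agent_params}}.
#' @param agent an \code{agent_state} covering the task's (state, action)
#'   pairs; defaults to a fresh zero-initialised agent.
#' @param episode_index episode number recorded in the trajectory.
#' @return a list with components \code{trajectory} (data frame of class
#'   \code{hrl_trajectory}, one row per timestep), \code{agent} (updated
#'   tables) and \code{censored} (logical).
#' @export
run_episode <- function(task, space, params, agent = init_agent(task),
                        episode_index = 1L) {
  stopifnot(inherits(task, "hrl_task"), inherits(space, "homeostatic_space"),
            inherits(params, "agent_params"), inherits(agent, "agent_state"))
  if (nrow(agent$q) != length(task$states))
    stop("agent tables do not cover the task's states")
  if (length(task$initial_H) != length(space$setpoint))
    stop("task initial_H dimension does not match the homeostatic space")

  n_max <- if (!is.na(task$episode_length)) task$episode_length else task$step_cap
  st  <- integer(n_max);  ac <- integer(n_max); nx <- integer(n_max)
  hb  <- numeric(n_max);  ha <- numeric(n_max)
  db  <- numeric(n_max);  da <- numeric(n_max); rw <- numeric(n_max)
  dt  <- numeric(n_max);  rt <- numeric(n_max)
  p1  <- numeric(n_max);  p2 <- numeric(n_max)
  q1  <- numeric(n_max);  q2 <- numeric(n_max)
  kh  <- numeric(n_max)
  space_true <- space
  space_true$eta <- 1

  beta <- params$beta; gamma <- params$gamma
  s <- task$initial_state
  H <- task$initial_H
  censored <- FALSE
  t <- 0L
  repeat {
    t <- t + 1L
    na_s <- task$n_actions[s]
    qs <- agent$q[s, seq_len(na_s)]
    probs <- action_probabilities(qs, beta)
    a <- select_action(probs)

    k_hat <- agent$k_hat[s, a]
    cost  <- task$cost[s, a]
    K     <- task$intake[s, a]
    d_before <- drive(H, space)
    H_pred <- (1 - 1 / space$tau) * H + k_hat - cost
    r <- d_before - drive(H_pred, space)
    d_true <- drive(H, space_true)
    r_true <- d_true - drive(H_pred, space_true)
    H_next <- next_internal(H, K, cost, space)
    s_next <- task$next_state[s, a]

    max_next <- max(agent$q[s_next, seq_len(task$n_actions[s_next])])
    delta <- td_error(r, gamma, max_next, qs[a])
    agent <- update_q(agent, s, a, delta, params)
    agent <- update_k_hat(agent, s, a, K, params)

    st[t] <- s; ac[t] <- a; nx[t] <- s_next
    hb[t] <- H; ha[t] <- H_next
    db[t] <- d_before; da[t] <- drive(H_next, space); rw[t] <- r
    dt[t] <- d_true; rt[t] <- r_true
    p1[t] <- probs[1]; p2[t] <- if (na_s >= 2) probs[2] else NA_real_
    q1[t] <- qs[1];    q2[t] <- if (na_s >= 2) qs[2] else NA_real_
    kh[t] <- k_hat

    if (task$terminal[s, a]) break
    s <- s_next; H <- H_next
    if (t == n_max) {
      censored <- is.na(task$episode_length)  # only the capped task censors
      break
    }
  }

  idx <- seq_len(t)
  traj <- data.frame(
    episode = episode_index, t = idx,
    state = task$states[st[idx]],
    action = task$actions[cbind(st[idx], ac[idx])],
    next_state = task$states[nx[idx]],
    H_before = hb[idx], H_after = ha[idx],
    drive_before = db[idx], drive_after = da[idx],
    reward = rw[idx], drive_true = dt[idx], reward_true = rt[idx],
    k_hat = kh[idx],
    p_action1 = p1[idx], p_action2 = p2[idx],
    q_action1 = q1[idx], q_action2 = q2[idx],
    stringsAsFactors = FALSE)
  class(traj) <- c("hrl_trajectory", "data.frame")
  attr(traj, "task") <- task$name
  attr(traj, "censored") <- censored
  list(trajectory = traj, agent = agent, censored = censored)
}

#' Run a trial of consecutive episodes
#'
#' A mountain-climbing trial is a sequence of episodes run back-to-back: at
#' each episode start the external state resets to S0 and the internal state
#' to \code{initial_H}, while the Q and \eqn{\hat K} tables are carried over.
#' A trial is complete after \code{n_episodes} summit intakes (or censored
#' episodes).
#'
#' @inheritParams run_episode
#' @param n_episodes number of episodes per trial (>= 1). Default 15.
#' @return a list of class \code{hrl_trial}: \code{episodes} (list of
#'   trajectory data frames), \code{agent}, and \code{censored} (logical
#'   vector, one flag per episode).
#' @export
run_trial <- function(task, space, params, n_episodes = 15,
                      agent = init_agent(task)) {
  stopifnot(n_episodes >= 1)
  episodes <- vector("list", n_episodes)
  censored <- logical(n_episodes)
  for (e in seq_len(n_episodes)) {
    res <- run_episode(task, space, params, agent, episode_index = e)
    episodes[[e]] <- res$trajectory
    censored[e] <- res$censored
    agent <- res$agent
  }
  structure(list(episodes = episodes, agent = agent, censored = censored),
            class = "hrl_trial")
}

#' Stack a trial's episodes into one trajectory table
#'
#' @param trial an \code{hrl_trial} from \code{\link{run_trial}}.
#' @return a single data frame with all episodes' timesteps.
#' @export
bind_trial <- function(trial) {
  stopifnot(inherits(trial, "hrl_trial"))
  out <- do.call(rbind, trial$episodes)
  rownames(out) <- NULL
  out
}
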