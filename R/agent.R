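# Tabular Q-learning agent with softmax policy and learned intake prediction.

#' Agent learning parameters
#'
#' @param alpha_q learning rate for the Q-table, \eqn{\alpha^Q \in [0, 1]}
#'   (0 freezes the table, useful for probing a fixed policy).
#' @param alpha_k learning rate for the intake prediction \eqn{\hat K},
#'   \eqn{\alpha^{\hat K} \in [0, 1]}.
#' @param beta inverse temperature \eqn{\beta \ge 0} of the softmax policy.
#'   Rewards here scale like \eqn{|H^* - H|^m} (up to ~1e6 with the default
#'   space), so useful \eqn{\beta} values are small (order 1e-6 to 1e-4).
#' @param gamma discount rate \eqn{\gamma \in [0, 1]} of the TD target.
#' @return an object of class \code{agent_params}.
#' @export
agent_params <- function(alpha_q = 0.05, alpha_k = 0.5, beta = 1.6e-05, gamma = 0.9) {
  stopifnot(is.numeric(alpha_q), length(alpha_q) == 1, alpha_q >= 0, alpha_q <= 1,
            is.numeric(alpha_k), length(alpha_k) == 1, alpha_k >= 0, alpha_k <= 1,
            is.numeric(beta), length(beta) == 1, is.finite(beta), beta >= 0,
            is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1)
  structure(list(alpha_q = alpha_q, alpha_k = alpha_k, beta = beta, gamma = gamma),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params> alpha_q =", x$alpha_q, " alpha_k =", x$alpha_k,
      " beta =", format(x$beta), " gamma =", x$gamma, "\n")
  invisible(x)
}

#' Initialise agent value tables for a task
#'
#' Builds the Q-table and the intake-prediction table \eqn{\hat K}, one entry
#' per (state, action) pair of the task, all initialised to 0 so the first
#' actions are chosen at random and the first reward estimates are
#' conservative.
#'
#' @param task a task specification from \code{\link{build_intake_task}} or
#'   \code{\link{build_mountain_task}}.
#' @return an object of class \code{agent_state}: list with matrices \code{q}
#'   and \code{k_hat} (rows = states, columns = action slots; \code{NA} marks
#'   a slot the state does not have).
#' @export
init_agent <- function(task) {
  stopifnot(inherits(task, "hrl_task"))
  n_s <- length(task$states)
  n_a <- ncol(task$actions)
  tmpl <- matrix(NA_real_, n_s, n_a, dimnames = list(task$states, NULL))
  for (s in seq_len(n_s)) tmpl[s, seq_len(task$n_actions[s])] <- 0
  structure(list(q = tmpl, k_hat = tmpl), class = "agent_state")
}

#' Softmax action probabilities
#'
#' \eqn{P(a^k) = \exp(\beta Q(a^k)) / \sum_j \exp(\beta Q(a^j))}, computed
#' with max-subtraction so large \eqn{\beta Q} products cannot overflow.
#' \eqn{\beta = 0} gives the uniform distribution.
#'
#' @param q_values finite numeric vector of action values.
#' @param beta inverse temperature, \eqn{\beta \ge 0}.
#' @return probability vector of the same length (sums to 1).
#' @export
action_probabilities <- function(q_values, beta) {
  if (length(q_values) == 0) stop("`q_values` must be non-empty")
  stopifnot(is.numeric(q_values), all(is.finite(q_values)),
            is.numeric(beta), length(beta) == 1, is.finite(beta), beta >= 0)
  z <- beta * q_values
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sample an action index from a probability vector
#'
#' Inverse-CDF draw using one uniform variate from R's RNG stream, so a fixed
#' \code{set.seed()} gives reproducible trajectories.
#'
#' @param probs probability vector (must sum to 1 within 1e-8).
#' @return integer action index in \code{1:length(probs)}.
#' @export
select_action <- function(probs) {
  stopifnot(is.numeric(probs), all(is.finite(probs)), all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-08)
    stop("`probs` must sum to 1 (got ", format(sum(probs)), ")")
  u <- stats::runif(1)
  cs <- cumsum(probs)
  cs[length(cs)] <- 1  # guard against cumulative rounding
  which(u <= cs)[1L]
}

#' Temporal-difference error
#'
#' \eqn{\delta = r + \gamma \max_{a'} Q(a') - Q(a)}.
#'
#' @param r scalar reward.
#' @param gamma discount rate.
#' @param max_next_q maximum Q-value over the successor state's actions.
#' @param current_q Q-value of the taken (state, action) pair.
#' @return the TD error \eqn{\delta}.
#' @export
td_error <- function(r, gamma, max_next_q, current_q) {
  stopifnot(is.finite(r), is.finite(gamma), is.finite(max_next_q), is.finite(current_q))
  r + gamma * max_next_q - current_q
}

resolve_state <- function(agent, state) {
  if (is.character(state)) {
    i <- match(state, rownames(agent$q))
    if (is.na(i)) stop("unknown state: ", state)
    i
  } else as.integer(state)
}

check_pair <- function(agent, s, a) {
  if (s < 1 || s > nrow(agent$q) || a < 1 || a > ncol(agent$q) ||
      is.na(agent$q[s, a]))
    stop("unknown (state, action) pair: (", s, ", ", a, ")")
  invisible(TRUE)
}

#' Q-table update
#'
#' \eqn{Q(s, a) \leftarrow Q(s, a) + \alpha^Q \delta}. Only the addressed
#' entry changes.
#'
#' @param agent an \code{agent_state}.
#' @param state state index or name.
#' @param action action slot index.
#' @param delta TD error from \code{\link{td_error}}.
#' @param params an \code{\link{agent_params}}.
#' @return the updated \code{agent_state}.
#' @export
update_q <- function(agent, state, action, delta, params) {
  s <- resolve_state(agent, state); a <- as.integer(action)
  check_pair(agent, s, a)
  agent$q[s, a] <- agent$q[s, a] + params$alpha_q * delta
  agent
}

#' Intake-prediction update
#'
#' Delta rule toward the observed intake:
#' \eqn{\hat K(s, a) \leftarrow \hat K(s, a) + \alpha^{\hat K} (K - \hat K(s, a))},
#' with fixed point \eqn{\hat K = K} and geometric error contraction
#' \eqn{(1 - \alpha^{\hat K})^t}.
#'
#' @inheritParams update_q
#' @param actual_k the actual intake \eqn{K} delivered on this step.
#' @return the updated \code{agent_state}.
#' @export
update_k_hat <- function(agent, state, action, actual_k, params) {
  s <- resolve_state(agent, state); a <- as.integer(action)
  check_pair(agent, s, a)
  agent$k_hat[s, a] <- agent$k_hat[s, a] +
    params$alpha_k * (actual_k - agent$k_hat[s, a])
  agent
}
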