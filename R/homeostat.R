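# Homeostatic space: drive, decay, internal-state transition, drive-reduction reward.

#' Define a homeostatic space
#'
#' A homeostatic space is a metric space whose axes are internal physiological
#' variables (here, nutrient levels). The distance between the current internal
#' state \eqn{H} and the ideal state (setpoint) \eqn{H^*} defines the drive the
#' agent seeks to minimise; the reduction of that drive is the reward.
#'
#' The drive is
#' \deqn{D(H) = \left(\sum_i \eta\,|H^*_i - H_i|^{\,n}\right)^{m/n}}
#' where \eqn{\eta} is an interoceptive gain scaling the perceived deviation
#' from the setpoint (\eqn{\eta = 1} is veridical interoception, \eqn{\eta < 1}
#' blunted, \eqn{\eta > 1} exaggerated). \eqn{\eta} multiplies the deviation
#' term inside the sum, after raising to \eqn{n}.
#'
#' @param setpoint numeric vector of ideal internal states \eqn{H^*}
#'   (nutrient units), length \eqn{N \ge 1}. Default 200.
#' @param m positive exponent shaping the outer distance. Default 3.
#' @param n positive exponent shaping the per-dimension deviation. Default 4.
#' @param eta non-negative interoceptive gain \eqn{\eta}. Default 1.
#' @param tau decay constant \eqn{\tau > 1} of the natural nutrient loss
#'   per timestep, \eqn{H \leftarrow (1 - 1/\tau) H}. Default 100.
#'
#' @return an object of class \code{homeostatic_space}.
#' @examples
#' sp <- homeostatic_space(setpoint = 200, m = 3, n = 4, eta = 1, tau = 100)
#' drive(100, sp)   # 1e6 = |200 - 100|^3
#' @export
homeostatic_space <- function(setpoint = 200, m = 3, n = 4, eta = 1, tau = 100) {
  stopifnot(is.numeric(setpoint), length(setpoint) >= 1, all(is.finite(setpoint)))
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m <= 0)
    stop("`m` must be a positive finite number")
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n <= 0)
    stop("`n` must be a positive finite number")
  if (!is.numeric(eta) || length(eta) != 1 || !is.finite(eta) || eta < 0)
    stop("`eta` must be a non-negative finite number")
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 1)
    stop("`tau` must be > 1 (tau <= 1 would zero or flip the state in one step)")
  structure(
    list(setpoint = as.numeric(setpoint), m = as.numeric(m), n = as.numeric(n),
         eta = as.numeric(eta), tau = as.numeric(tau)),
    class = "homeostatic_space"
  )
}

#' @export
print.homeostatic_space <- function(x, ...) {
  cat("<homeostatic_space>\n")
  cat("  H* =", paste(x$setpoint, collapse = ", "),
      " (m, n) = (", x$m, ",", x$n, ")  eta =", x$eta, " tau =", x$tau, "\n")
  invisible(x)
}

check_state <- function(H, space) {
  if (!is.numeric(H) || !all(is.finite(H)))
    stop("internal state `H` must be finite numeric")
  if (length(H) != length(space$setpoint))
    stop("internal state has length ", length(H),
         " but the homeostatic space has ", length(space$setpoint), " dimension(s)")
  invisible(TRUE)
}

#' Drive: distance from the setpoint in the homeostatic space
#'
#' \eqn{D(H) = (\sum_i \eta |H^*_i - H_i|^n)^{m/n}}. Zero exactly at the
#' setpoint (for \eqn{\eta > 0}) and strictly increasing in each deviation
#' \eqn{|H^*_i - H_i|}.
#'
#' @param H numeric vector, current internal state (same length as the
#'   space's setpoint).
#' @param space a \code{\link{homeostatic_space}}.
#' @return non-negative scalar drive.
#' @export
drive <- function(H, space) {
  check_state(H, space)
  s <- sum(space$eta * abs(space$setpoint - H)^space$n)
  s^(space$m / space$n)
}

#' Natural decay of the internal state
#'
#' One timestep of nutrient loss: \eqn{H \leftarrow (1 - 1/\tau) H}.
#' Sign-preserving contraction toward zero.
#'
#' @inheritParams drive
#' @return the decayed internal state.
#' @export
decay_state <- function(H, space) {
  check_state(H, space)
  (1 - 1 / space$tau) * H
}

#' Internal-state transition for one timestep
#'
#' Applies, in this fixed order: natural decay, then addition of the nutrient
#' intake \eqn{K}, then subtraction of any action cost:
#' \eqn{H' = (1 - 1/\tau) H + K - \mathrm{cost}}. The state is not clamped:
#' the dynamics impose no bounds and clamping would distort drive gradients.
#'
#' @inheritParams drive
#' @param K actual nutrient intake delivered by the action (\eqn{K \ge 0}).
#' @param cost non-negative nutrient cost of the action (e.g. a climb).
#' @return the next internal state.
#' @export
next_internal <- function(H, K, cost = 0, space) {
  check_state(H, space)
  stopifnot(is.numeric(K), length(K) == 1, is.finite(K), K >= 0,
            is.numeric(cost), length(cost) == 1, is.finite(cost), cost >= 0)
  (1 - 1 / space$tau) * H + K - cost
}

#' Drive-reduction reward
#'
#' The reward of an action is the predicted reduction in drive it causes:
#' \deqn{r = D(H_t) - D\big((1 - 1/\tau) H_t + \hat K - \mathrm{cost}\big)}
#' Note the \emph{predicted} intake \eqn{\hat K} (the agent's learned
#' estimate), not the actual intake, enters the reward; the actual intake
#' enters the state transition. Negative rewards are "punishments": the
#' predicted post-action state is further from the setpoint than doing the
#' action was worth.
#'
#' @inheritParams next_internal
#' @param k_hat predicted intake \eqn{\hat K} for the action (nutrient units).
#' @return scalar reward (may be negative).
#' @export
drive_reward <- function(H, k_hat, cost = 0, space) {
  check_state(H, space)
  stopifnot(is.numeric(k_hat), length(k_hat) == 1, is.finite(k_hat),
            is.numeric(cost), length(cost) == 1, is.finite(cost), cost >= 0)
  drive(H, space) - drive((1 - 1 / space$tau) * H + k_hat - cost, space)
}
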