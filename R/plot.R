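# Minimal trajectory panel: internal state, selected action, reward.

#' Plot a trajectory
#'
#' Three stacked base-graphics panels over timesteps: internal state H with
#' the setpoint as a dashed line, the selected actions, and the reward trace.
#'
#' @param x a trajectory data frame from \code{\link{run_episode}}.
#' @param setpoint optional setpoint to mark on the H panel.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
plot.hrl_trajectory <- function(x, setpoint = NULL, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  tt <- seq_len(nrow(x))
  ylim <- range(c(x$H_before, x$H_after, setpoint))
  graphics::plot(tt, x$H_after, type = "l", xlab = "", ylab = "H",
                 ylim = ylim)
  if (!is.null(setpoint)) graphics::abline(h = setpoint, lty = 2)
  acts <- factor(x$action)
  graphics::plot(tt, as.integer(acts), type = "p", pch = 20, cex = 0.5,
                 yaxt = "n", xlab = "", ylab = "action")
  graphics::axis(2, at = seq_along(levels(acts)), labels = levels(acts),
                 las = 1, cex.axis = 0.7)
  graphics::plot(tt, x$reward, type = "h", xlab = "t", ylab = "reward")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
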