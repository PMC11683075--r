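# Shared fixtures: small spaces, tasks and replicate runners used across files.

space_1d <- function(eta = 1, tau = 100, setpoint = 200, m = 3, n = 4) {
  homeostatic_space(setpoint = setpoint, m = m, n = n, eta = eta, tau = tau)
}

# one intake-task replicate under the package's default study conditions
run_control_episode <- function(seed, eta = 1, config = default_config()) {
  task <- build_task_from(config, "intake")
  space <- homeostatic_space(
    setpoint = config$homeostat$setpoint, m = config$homeostat$m,
    n = config$homeostat$n, eta = eta, tau = config$tasks$intake$tau)
  a <- config$agent$intake
  params <- agent_params(a$alpha_q, a$alpha_k, a$beta, a$gamma)
  set.seed(seed)
  run_episode(task, space, params)
}

build_task_from <- function(config, which) {
  if (which == "intake")
    build_intake_task(config$tasks$intake$k_intake,
                      config$tasks$intake$episode_length)
  else
    build_mountain_task(config$tasks$mountain$k_small,
                        config$tasks$mountain$k_large,
                        config$tasks$mountain$climb_cost,
                        config$tasks$mountain$step_cap)
}

# minimal fake trajectory for metric unit tests
fake_traj <- function(actions, reward, reward_true = reward,
                      drive_true = abs(reward), state = "S0") {
  data.frame(episode = 1L, t = seq_along(actions), state = state,
             action = actions, next_state = state,
             H_before = 0, H_after = 0, drive_before = drive_true,
             drive_after = 0, reward = reward, drive_true = drive_true,
             reward_true = reward_true, k_hat = 0,
             p_action1 = 0.5, p_action2 = 0.5, q_action1 = 0, q_action2 = 0,
             stringsAsFactors = FALSE)
}

fake_trial <- function(...) {
  structure(list(episodes = list(...), agent = NULL,
                 censored = logical(length(list(...)))),
            class = "hrl_trial")
}
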