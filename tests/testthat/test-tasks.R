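test_that("the intake task has one state, two actions and a fixed horizon", {
  task <- build_intake_task(k_intake = 12, episode_length = 100)
  expect_identical(task$states, "S0")
  expect_identical(task$actions[1, ], c("nothing", "intake"))
  expect_identical(task$intake[1, ], c(0, 12))
  expect_true(all(task$cost == 0))
  expect_false(any(task$terminal))
  res <- run_episode(task, space_1d(tau = 25), agent_params())
  expect_identical(nrow(res$trajectory), 100L)
  expect_false(res$censored)
  expect_error(build_intake_task(k_intake = 0), "positive")
  expect_error(build_intake_task(episode_length = 0), ">= 1")
})

test_that("the mountain task wires 8 states with two actions each", {
  task <- build_mountain_task(k_small = 20, k_large = 120, climb_cost = 10)
  expect_identical(task$states, paste0("S", 0:7))
  expect_identical(task$n_actions, setNames(rep(2L, 8), task$states))
  # S3: climb -> S4 with cost, descend -> S2 free
  expect_identical(task$actions[4, ], c("climb", "descend"))
  expect_identical(task$next_state[4, ], c(5L, 3L))
  expect_identical(task$cost[4, ], c(10, 0))
  # summit intake is terminal and returns to the bottom
  expect_true(task$terminal[8, 1])
  expect_identical(unname(task$actions[8, 1]), "large_intake")
  expect_identical(task$next_state[8, 1], 1L)
  # small intake self-loops at the bottom
  expect_identical(task$next_state[1, ], c(1L, 2L))
  expect_identical(task$intake[1, 1], 20)
  expect_error(build_mountain_task(step_cap = 0), "positive")
})

test_that("the shortest path from S0 to the summit intake takes 8 steps", {
  task <- build_mountain_task()
  # breadth-first search over (state) nodes; terminal action is the goal edge
  dist <- rep(Inf, length(task$states)); dist[task$initial_state] <- 0
  frontier <- task$initial_state
  goal <- Inf
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in frontier) for (a in seq_len(task$n_actions[s])) {
      if (task$terminal[s, a]) goal <- min(goal, dist[s] + 1)
      s2 <- task$next_state[s, a]
      if (dist[s2] > dist[s] + 1) { dist[s2] <- dist[s] + 1; nxt <- c(nxt, s2) }
    }
    frontier <- unique(nxt)
  }
  expect_identical(goal, 8)
})

test_that("every transition satisfies the internal-state identity", {
  cfg <- default_config()
  for (which in c("intake", "mountain")) {
    task <- build_task_from(cfg, which)
    tau <- cfg$tasks[[which]]$tau
    set.seed(5)
    res <- run_episode(task, space_1d(tau = tau), agent_params(beta = 1e-6))
    tr <- res$trajectory
    s <- match(tr$state, task$states)
    a <- mapply(function(si, lbl) match(lbl, task$actions[si, ]), s, tr$action)
    K <- task$intake[cbind(s, a)]
    cost <- task$cost[cbind(s, a)]
    expect_equal(tr$H_after, (1 - 1 / tau) * tr$H_before + K - cost,
                 tolerance = 1e-12)
    # and H chains within the episode
    expect_equal(tr$H_before[-1], tr$H_after[-nrow(tr)])
  }
})

test_that("episodes are deterministic for a fixed seed and leave no trace without learning", {
  task <- build_intake_task()
  sp <- space_1d(tau = 25)
  pr <- agent_params(alpha_q = 0.05, alpha_k = 0.5, beta = 1.6e-5, gamma = 0.9)
  set.seed(123); r1 <- run_episode(task, sp, pr)
  set.seed(123); r2 <- run_episode(task, sp, pr)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$agent, r2$agent)
  # zero learning rates freeze the tables
  pr0 <- agent_params(alpha_q = 0, alpha_k = 0, beta = 1e-5, gamma = 0.9)
  ag <- init_agent(task)
  set.seed(4)
  res <- run_episode(task, sp, pr0, ag)
  expect_identical(res$agent, ag)
})

test_that("intake-task reward signs are sane under deficit", {
  sp <- space_1d(tau = 25)
  for (H in c(80, 120, 150, 170)) {
    expect_gt(drive_reward(H, k_hat = 12, cost = 0, space = sp), 0)
    expect_lt(drive_reward(H, k_hat = 0, cost = 0, space = sp), 0)
  }
})

test_that("a trial chains episodes with value carry-over and state reset", {
  cfg <- default_config()
  task <- build_task_from(cfg, "mountain")
  sp <- space_1d(tau = 100)
  pr <- agent_params(alpha_q = 0.1, alpha_k = 0.5, beta = 2e-7, gamma = 0.9)
  set.seed(21)
  trial <- run_trial(task, sp, pr, n_episodes = 15)
  expect_length(trial$episodes, 15)
  expect_length(trial$censored, 15)
  for (e in seq_len(15)) {
    tr <- trial$episodes[[e]]
    expect_identical(tr$state[1], "S0")
    expect_identical(tr$H_before[1], 100)
    last <- tr[nrow(tr), ]
    expect_true(trial$censored[e] ||
                  (last$state == "S7" && last$action == "large_intake"))
  }
  # carry-over: rerunning episode 1 alone yields the same table that the
  # trial's second episode started from (incremental replay)
  set.seed(21)
  res1 <- run_episode(task, sp, pr, init_agent(task), episode_index = 1L)
  expect_identical(res1$trajectory, trial$episodes[[1]])
  # step cap censoring is flagged, not an error
  tiny <- build_mountain_task(step_cap = 5)
  set.seed(3)
  res <- run_episode(tiny, sp, pr)
  expect_true(res$censored)
  expect_identical(nrow(res$trajectory), 5L)
})

test_that("trial tables stack into one trajectory", {
  cfg <- default_config()
  task <- build_task_from(cfg, "mountain")
  set.seed(2)
  trial <- run_trial(task, space_1d(tau = 100),
                     agent_params(beta = 2e-7), n_episodes = 3)
  tab <- bind_trial(trial)
  expect_identical(nrow(tab), sum(vapply(trial$episodes, nrow, integer(1))))
  expect_identical(sort(unique(tab$episode)), 1:3)
})
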