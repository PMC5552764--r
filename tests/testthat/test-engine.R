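test_that("the wired network at rest stays silent without stimulus", {
  net <- build_lgn(lgn_config())
  tr <- run_trial(net, NULL, duration = 2000, seed = 1)
  expect_equal(nrow(tr$spikes), 0)
  expect_equal(ncol(tr$v_mean), 20000)           # duration / dt columns
  expect_true(all(tr$v_mean <= 30))
})

test_that("the compiled engine reproduces the reference single-neuron stepping exactly", {
  # one TCR cell, constant drive: engine vs pure-R step_neuron loop
  eng <- tonic_demo(i_dc = 5, duration = 500, n_per_pop = 1)$TCR[[1]]
  p <- izh_presets(i_dc = 5)$TCR
  s <- neuron_state(v = p$v_init, u = p$u_init)
  ref <- numeric(0)
  for (i in 1:5000) {
    r <- step_neuron(s, p, dt = 0.1)
    s <- r$state
    if (r$spiked) ref <- c(ref, (i - 1) * 0.1)
  }
  expect_equal(eng, ref)
})

test_that("every emitted spike is delivered once per outgoing edge", {
  net <- build_lgn(lgn_config())
  dt <- 0.1
  duration <- 1000
  n_steps <- duration / dt
  edges <- realize_network(net, 5, dt)
  stim <- periodic_train(20, duration)
  tr <- run_trial(net, stim, duration = duration, dt = dt, edges = edges)
  # expected deliveries: per stimulus event and per spike, the number of
  # outgoing edges whose arrival falls inside the simulation
  stim_step <- round(stim$time_ms / dt)
  src <- edges[edges$from_source, ]
  exp_src <- sum(vapply(seq_len(nrow(stim)), function(i)
    sum(src$pre == stim$channel[i] &
          stim_step[i] + src$delay_steps < n_steps), 1.0))
  neu <- edges[!edges$from_source, ]
  sp_step <- round(tr$spikes$time_ms / dt)
  exp_neu <- sum(vapply(seq_len(nrow(tr$spikes)), function(i)
    sum(neu$pre == tr$spikes$neuron[i] &
          sp_step[i] + neu$delay_steps < n_steps), 1.0))
  expect_equal(tr$n_delivered, exp_src + exp_neu)
})

test_that("the network is time-translation invariant under delayed stimulus", {
  # start every population at its quiescent fixed point (v = -70, u = -14,
  # where both derivatives vanish at I = 0) so the pre-stimulus state is
  # stationary and a stimulus delay shifts the trajectory exactly
  net <- build_lgn(lgn_config())
  for (nm in names(net$params)) {
    net$params[[nm]]$v_init <- -70
    net$params[[nm]]$u_init <- -14
  }
  edges <- realize_network(net, 9)
  stim <- periodic_train(20, 400)
  delayed <- spike_events(stim$channel, stim$time_ms + 100, 144, 500)
  a <- run_trial(net, stim, duration = 400, edges = edges)
  b <- run_trial(net, delayed, duration = 500, edges = edges)
  expect_equal(b$spikes$time_ms, a$spikes$time_ms + 100)
  expect_equal(b$spikes$neuron, a$spikes$neuron)
})

test_that("simulation is bit-exactly reproducible from its seeds", {
  net <- build_lgn(lgn_config())
  stim <- list(type = "poisson", rate = 30)
  a <- run_trials(net, stim, n_trials = 2, base_seed = 21, duration = 500)
  b <- run_trials(net, stim, n_trials = 2, base_seed = 21, duration = 500)
  expect_identical(a$v_mean, b$v_mean)
  c <- run_trials(net, stim, n_trials = 2, base_seed = 22, duration = 500)
  expect_false(identical(a$v_mean, c$v_mean))
})

test_that("trial averaging and the model-output designation behave as defined", {
  net <- build_lgn(lgn_config())
  one <- run_trials(net, list(type = "periodic", freq = 20), n_trials = 1,
                    base_seed = 3, duration = 500)
  expect_equal(one$v_mean, one$trial_means[[1]])
  # deterministic stimulus + frozen wiring: every trial mean identical
  frozen <- run_trials(net, list(type = "periodic", freq = 20), n_trials = 3,
                       base_seed = 3, duration = 500, redraw_wiring = FALSE)
  expect_identical(frozen$trial_means[[2]], frozen$trial_means[[1]])
  expect_identical(frozen$trial_means[[3]], frozen$trial_means[[1]])
  expect_equal(frozen$v_mean, frozen$trial_means[[1]])
  # averaging identity: mean of per-trial means
  varying <- run_trials(net, list(type = "poisson", rate = 30), n_trials = 3,
                        base_seed = 3, duration = 500)
  expect_equal(varying$v_mean,
               (varying$trial_means[[1]] + varying$trial_means[[2]] +
                  varying$trial_means[[3]]) / 3)
  # single node: output is the TCR row
  expect_equal(as.numeric(model_output(one)), unname(one$v_mean["TCR", ]))
  # multi-node: output is the elementwise mean of the per-node TCR series
  fake <- structure(list(
    v_mean = rbind(`TCR@1` = c(1, 2), `TCR@2` = c(3, 4), `TCR@3` = c(5, 6),
                   `IN@1` = c(9, 9)),
    pops = data.frame(name = c("TCR@1", "TCR@2", "TCR@3", "IN@1"),
                      role = c("TCR", "TCR", "TCR", "IN")),
    dt = 0.1), class = "lgn_avg")
  expect_equal(as.numeric(model_output(fake)), c(3, 4))
  fake$pops$role <- "IN"
  expect_error(model_output(fake), "TCR")
})

test_that("full-state recording obeys the declared invariants", {
  net <- build_lgn(lgn_config())
  tr <- run_trial(net, periodic_train(40, 300), duration = 300, seed = 2,
                  record = "full")
  expect_equal(dim(tr$v_full$TCR), c(80, 3000))
  expect_true(all(vapply(tr$v_full, max, 1.0) <= 30))
  # neuron-means of the full record reproduce the mean record
  expect_equal(unname(colMeans(tr$v_full$TCR)), unname(tr$v_mean["TCR", ]))
  # spike steps carry the clamped value in the full record
  sp <- tr$spikes[tr$spikes$neuron <= 80, ]
  if (nrow(sp))
    expect_true(all(abs(tr$v_full$TCR[cbind(sp$neuron,
      round(sp$time_ms / 0.1) + 1)] - 30) < 1e-12))
})
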