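test_that("population presets match the published tonic-firing parameterization", {
  p <- izh_presets()
  expect_equal(unname(unlist(p$TCR[c("a", "b", "c", "d", "v_init", "u_init")])),
               c(0.02, 0.2, -65, 6, -65, -13))
  expect_equal(unname(unlist(p$IN[c("a", "b", "c", "d", "v_init", "u_init")])),
               c(0.1, 0.2, -65, 6, -70, -14))
  expect_equal(unname(unlist(p$TRN[c("a", "b", "c", "d", "v_init", "u_init")])),
               c(0.02, 0.2, -65, 6, -75, -15))
  expect_error(izh_params(a = -0.1, b = 0.2, c = -65, d = 6), "a")
  expect_error(izh_params(a = 0.02, b = 0.2, c = 31, d = 6), "threshold")
})

test_that("spike reset is exact and the recorded potential is clamped", {
  p <- izh_presets()$TCR
  # drive hard enough that the advanced v crosses the threshold this step
  s <- neuron_state(v = 29, u = -13, g_e = 200)
  k <- syn_kinetics()
  res <- step_neuron(s, p, dt = 0.1)
  expect_true(res$spiked)
  expect_identical(res$state$v, p$c)       # v <- c exactly
  expect_identical(res$v_rec, 30)          # clamped for recording
  # u incremented by exactly d relative to the advanced value
  s2 <- s; s2$g_e <- 200
  I <- s2$g_e - s2$g_i + p$i_dc
  k1v <- 0.04 * s2$v^2 + 5 * s2$v + 140 - s2$u + I
  k1u <- p$a * (p$b * s2$v - s2$u)
  um <- s2$u + 0.05 * k1u; vm <- s2$v + 0.05 * k1v
  un <- s2$u + 0.1 * p$a * (p$b * vm - um)
  expect_equal(res$state$u, un + p$d, tolerance = 1e-12)
})

test_that("the resting state stays subthreshold indefinitely", {
  p <- izh_presets()$TCR
  s <- neuron_state(v = p$v_init, u = p$u_init)
  spiked_any <- FALSE
  for (i in 1:10000) {            # 1 s at dt = 0.1 ms
    r <- step_neuron(s, p, dt = 0.1)
    s <- r$state
    spiked_any <- spiked_any || r$spiked
  }
  expect_false(spiked_any)
  expect_true(abs(s$v + 70) < 1)  # settles at the stable fixed point
  # independent fine-step oracle agrees
  orc <- euler_oracle(p, I = 0, dt = 1e-3, duration = 1000)
  expect_length(orc$spikes, 0)
  expect_equal(orc$v, s$v, tolerance = 1e-3)
})

test_that("tonic firing under constant current matches a fine-step Euler oracle", {
  p <- izh_presets(i_dc = 5)$TCR
  eng <- tonic_demo(i_dc = 5, duration = 1000, n_per_pop = 1)$TCR[[1]]
  orc <- euler_oracle(p, I = 5, dt = 1e-4, duration = 1000)$spikes
  expect_lte(abs(length(eng) - length(orc)), 1)   # counts +-1
  n <- min(length(eng), length(orc))
  d <- abs(eng[1:n] - orc[1:n])
  expect_true(all(d[1:min(5, n)] < 1))          # sub-ms over early spikes
  # timing drift of the fixed-step scheme accumulates linearly, ~0.2 ms/period
  expect_true(all(d <= 0.3 + 0.25 * (seq_len(n) - 1)))
})

test_that("synaptic kinetics decay exponentially and superpose linearly", {
  k <- syn_kinetics(tau_e = 2, tau_i = 6)
  s <- neuron_state(v = -65, u = -13)
  s <- decay_and_inject(s, k, dt = 0.1, arrivals_e = 5)
  expect_identical(s$g_e, 5)                     # weight lands instantly
  # decay over exactly tau_e leaves w/e
  n <- 2 / 0.001
  s2 <- neuron_state(v = -65, u = -13, g_e = 5)
  for (i in seq_len(n)) s2 <- decay_and_inject(s2, k, dt = 0.001)
  expect_equal(s2$g_e, 5 / exp(1), tolerance = 1e-9)
  # two arrivals w=2 at t=0 and t=tau: g_e(tau+) = 2/e + 2
  s3 <- neuron_state(v = -65, u = -13)
  s3 <- decay_and_inject(s3, k, dt = 0.001, arrivals_e = 2)
  for (i in seq_len(n - 1)) s3 <- decay_and_inject(s3, k, dt = 0.001)
  s3 <- decay_and_inject(s3, k, dt = 0.001, arrivals_e = 2)
  expect_equal(s3$g_e, 2 * exp(-1) + 2, tolerance = 1e-6)
  # linearity: arbitrary arrival pattern equals the closed-form superposition
  set.seed(7)
  arrival_step <- sort(sample(1:500, 20))
  weights <- runif(20, 0.5, 8)
  s4 <- neuron_state(v = -65, u = -13)
  for (i in 1:500)
    s4 <- decay_and_inject(s4, k, dt = 0.1,
                           arrivals_e = sum(weights[arrival_step == i]))
  expect_equal(s4$g_e,
               exp_superposition(arrival_step * 0.1, weights, tau = 2,
                                 at = 500 * 0.1),
               tolerance = 1e-9)
  expect_error(decay_and_inject(s, k, 0.1, arrivals_e = -1), ">= 0")
})

test_that("unconnected populations fire homogeneously, FS faster than RS, rates monotone in drive", {
  demo <- tonic_demo(i_dc = 5, duration = 1000, n_per_pop = 3)
  for (pop in names(demo))
    for (j in 2:3)
      expect_identical(demo[[pop]][[j]], demo[[pop]][[1]])
  rates5 <- attr(demo, "rates_hz")
  expect_gt(rates5[["IN"]], rates5[["TCR"]])    # fast-spiking vs regular
  rates <- sapply(c(3, 5, 7), function(idc)
    attr(tonic_demo(i_dc = idc, duration = 1000, n_per_pop = 1), "rates_hz"))
  for (r in 1:3) expect_true(all(diff(rates[r, ]) >= 0))
})
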