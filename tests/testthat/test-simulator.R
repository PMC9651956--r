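test_that("empty input produces an empty output raster", {
  liq <- tiny_liquid(n = 40, channels = 6, seed = 1)
  empty <- spike_raster(NULL, n_sources = 6, duration_ms = 100)
  sim <- simulate_liquid(liq, empty, sim_config(seed = 1))
  expect_equal(nrow(sim$raster), 0)
  expect_equal(spikes_per_neuron(sim), 0)
})

test_that("input kicks arrive one delay after the source spike", {
  # single neuron, single channel, weight too small to fire
  liq <- hand_liquid(
    neurons = data.frame(is_excitatory = TRUE),
    synapses = data.frame(pre = 1L, post = 1L, weight = 0.05,
                          delay_ms = 1.0, type = "input-E"),
    n_channels = 1
  )
  inp <- spike_raster(data.frame(source = 1, t_ms = 10),
                      n_sources = 1, duration_ms = 20)
  sim <- simulate_liquid(liq, inp, sim_config(record = "all", seed = 1))
  ge <- sim$trace$g_e[, 1] # indexed by t = 0..20 ms
  expect_true(all(ge[1:11] == 0)) # t = 0..10: nothing yet
  expect_gt(ge[12], 0) # first increase at the step covering t = 11 ms
})

test_that("a hand-built chain spikes step-for-step as computed by hand", {
  # channel -> N1 (delay 1 ms) -> N2 (EE delay 1.5 ms -> 2 steps at dt 1)
  # weights are far above threshold so each kick fires its target at the
  # arrival step: input at 5 ms => N1 at 6 ms => N2 at 8 ms.
  liq <- hand_liquid(
    neurons = data.frame(is_excitatory = c(TRUE, TRUE)),
    synapses = data.frame(pre = c(1L, 1L), post = c(1L, 2L),
                          weight = c(50, 50), delay_ms = c(1.0, 1.5),
                          type = c("input-E", "EE")),
    n_channels = 1
  )
  inp <- spike_raster(data.frame(source = 1, t_ms = 5),
                      n_sources = 1, duration_ms = 20)
  sim <- simulate_liquid(liq, inp, sim_config(seed = 1))
  ev <- as.data.frame(sim$raster)
  expect_equal(ev$t_ms[ev$source == 1][1], 6)
  expect_equal(ev$t_ms[ev$source == 2][1], 8)
})

test_that("every input spike delivers exactly fan-in many kicks", {
  # no recurrence: the total conductance injected equals the sum of the
  # spiking channel's weight column
  spec <- liquid_spec(n_neurons = 30, C = c(EE = 0, EI = 0, IE = 0, II = 0),
                      input_in_degree = 5)
  liq <- build_liquid(spec, n_channels = 6, seed = 2)
  inp <- spike_raster(data.frame(source = 3, t_ms = 4),
                      n_sources = 6, duration_ms = 10)
  sim <- simulate_liquid(liq, inp, sim_config(record = "all", seed = 1))
  syn3 <- dplyr::filter(liq$synapses, pre == 3,
                        startsWith(type, "input"))
  # at the arrival step (t = 5) g_e jumps by the full column, then decays
  ge_jump <- sim$trace$g_e[6, ] # row for t = 5 ms, post-decay
  expect_equal(sum(ge_jump), sum(syn3$weight) * exp(-1 / 3),
               tolerance = 1e-10)
  targets <- sort(liq$neurons$id[ge_jump > 0])
  expect_equal(targets, sort(syn3$post))
})

test_that("simulation is deterministic and respects refractoriness", {
  liq <- tiny_liquid(n = 100, channels = 10, seed = 4)
  inp <- regular_input(10, 300, period = 5)
  a <- simulate_liquid(liq, inp, sim_config(seed = 9))
  b <- simulate_liquid(liq, inp, sim_config(seed = 9))
  expect_identical(as.data.frame(a$raster), as.data.frame(b$raster))
  expect_gt(nrow(a$raster), 0)
  # network-wide refractory invariant
  t_ref <- ifelse(liq$neurons$is_excitatory, 3, 2)
  ev <- as.data.frame(a$raster)
  for (id in unique(ev$source)) {
    isi <- diff(ev$t_ms[ev$source == id])
    if (length(isi)) expect_true(all(isi >= t_ref[id]))
  }
})

test_that("channel mismatch errors and unsorted events are sorted", {
  liq <- tiny_liquid(n = 20, channels = 8, seed = 1)
  wrong <- spike_raster(NULL, n_sources = 5, duration_ms = 10)
  expect_error(simulate_liquid(liq, wrong, sim_config()), "5 channels")
  r <- spike_raster(data.frame(source = c(2, 1), t_ms = c(9, 3)),
                    n_sources = 8, duration_ms = 10)
  expect_equal(r$t_ms, c(3, 9))
})

test_that("spikes-per-neuron statistic agrees with per-neuron counts", {
  expect_equal(spikes_per_neuron(
    spike_raster(NULL, n_sources = 10, duration_ms = 1), 2000
  ), 0)
  # format of the sparseness statistic: 17120 events over 2000 neurons
  fake <- spike_raster(
    data.frame(source = rep(1:2000, length.out = 17120),
               t_ms = rep(1, 17120)),
    n_sources = 2000, duration_ms = 10
  )
  expect_equal(spikes_per_neuron(fake, 2000), 8.56)
  liq <- tiny_liquid(n = 50, channels = 10, seed = 2)
  sim <- simulate_liquid(liq, regular_input(10, 200, 8),
                         sim_config(seed = 1))
  per_neuron <- tabulate(sim$raster$source, nbins = 50)
  expect_equal(spikes_per_neuron(sim), mean(per_neuron))
  expect_equal(sim$spike_counts, per_neuron)
})

test_that("net-current statistics match hand arithmetic and both paths", {
  # hand-built traces
  tr <- structure(
    list(neuron_ids = 1:2, t_ms = 0:4,
         V = matrix(13.5, 5, 2),
         g_e = cbind(rep(0, 5), rep(0.2, 5)),
         g_i = cbind(rep(0, 5), rep(0.05, 5)),
         theta_sfa = matrix(0, 5, 2)),
    class = "state_trace"
  )
  st <- net_current_stats(tr)
  expect_equal(st$per_neuron$mean_net, c(0, 0.15))
  expect_equal(st$per_neuron$sd_net, c(0, 0))
  # perfectly balanced conductances give zero net current
  tr$g_i <- tr$g_e
  expect_equal(net_current_stats(tr)$mean_net_current, 0)
  expect_error(net_current_stats(structure(list(g_e = NULL),
                                           class = "state_trace")),
               "No recorded states")

  # accumulator path vs recorded-trace path on a real simulation
  liq <- tiny_liquid(n = 60, channels = 10, seed = 6)
  sim <- simulate_liquid(liq, regular_input(10, 150, 6),
                         sim_config(record = "all", seed = 3))
  from_acc <- net_current_stats(sim, neurons = "all")
  tr2 <- sim$trace
  # drop t = 0 so both summarize the same K end-of-step samples
  for (f in c("V", "g_e", "g_i", "theta_sfa")) {
    tr2[[f]] <- tr2[[f]][-1, , drop = FALSE]
  }
  from_trace <- net_current_stats(tr2)
  expect_equal(from_acc$per_neuron$mean_net, from_trace$per_neuron$mean_net,
               tolerance = 1e-10)
  expect_equal(from_acc$per_neuron$sd_net, from_trace$per_neuron$sd_net,
               tolerance = 1e-10)
})

test_that("state traces have duration/dt + 1 samples and tidy cleanly", {
  liq <- tiny_liquid(n = 25, channels = 5, seed = 1)
  sim <- simulate_liquid(liq, regular_input(5, 80, 10),
                         sim_config(record = "exc", seed = 1))
  n_exc <- sum(liq$neurons$is_excitatory)
  expect_equal(dim(sim$trace$V), c(81, n_exc))
  td <- tidy(sim$trace)
  expect_equal(nrow(td), 81 * n_exc)
  expect_named(td, c("neuron", "t_ms", "V", "g_e", "g_i", "theta_sfa"))
})

test_that("stronger input inhibition never raises excitatory activity", {
  inp <- regular_input(12, 200, 6)
  for (s in 1:5) {
    liq <- build_liquid(liquid_spec(n_neurons = 80), 12, seed = s)
    low <- simulate_liquid(liq, inp, sim_config(seed = s))
    high <- simulate_liquid(set_inhib_factor(liq, 3), inp,
                            sim_config(seed = s))
    exc <- liq$neurons$is_excitatory
    expect_lte(sum(high$spike_counts[exc]), sum(low$spike_counts[exc]))
  }
})
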