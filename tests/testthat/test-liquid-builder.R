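test_that("grid placement fills distinct sites in raster order", {
  pos <- place_on_grid(8, c(2, 2, 2))
  expect_equal(nrow(pos), 8)
  expect_equal(nrow(dplyr::distinct(pos, x, y, z)), 8)
  expect_setequal(
    paste(pos$x, pos$y, pos$z),
    paste(rep(0:1, 4), rep(rep(0:1, each = 2), 2), rep(0:1, each = 4))
  )

  line <- place_on_grid(5, c(1, 1, 5))
  expect_equal(line$x, rep(0, 5))
  expect_equal(line$y, rep(0, 5))
  expect_equal(line$z, 0:4)
  d <- as.vector(dist(cbind(line$x, line$y, line$z)))
  expect_setequal(round(d, 10), 1:4)

  big <- place_on_grid(2000, c(10, 10, 20))
  expect_equal(nrow(dplyr::distinct(big, x, y, z)), 2000)
  expect_true(all(big$x < 10 & big$y < 10 & big$z < 20))

  expect_error(place_on_grid(9, c(2, 2, 2)), "9.*8")
})

test_that("E/I split is exact after rounding and seed-randomized", {
  expect_equal(sum(split_ei(2000, 0.8, seed = 1)), 1600)
  expect_true(all(split_ei(10, 1.0, seed = 1)))
  expect_equal(sum(split_ei(5, 0.8, seed = 1)), 4)
  a <- split_ei(100, 0.8, seed = 1)
  b <- split_ei(100, 0.8, seed = 2)
  expect_equal(sum(a), sum(b))
  expect_false(identical(a, b))
})

test_that("connection probability follows the distance kernel", {
  expect_equal(connection_probability(0, "EE", lambda = 2), 0.3)
  expect_equal(connection_probability(2, "EE", lambda = 2), 0.3 * exp(-1))
  expect_equal(connection_probability(1, "IE", lambda = 2),
               0.4 * exp(-0.25))
  # clamped for extreme C
  expect_equal(connection_probability(0, "EE", lambda = 2, C = c(EE = 3)), 1)
  expect_error(connection_probability(1, "XX"), "Unknown synapse type")
  expect_error(connection_probability(-1, "EE"), ">= 0")
})

test_that("recurrent wiring matches a brute-force expectation oracle", {
  spec0 <- liquid_spec(n_neurons = 8, dims = c(2, 2, 2),
                       C = c(EE = 0, EI = 0, IE = 0, II = 0))
  pop <- place_on_grid(8, c(2, 2, 2))
  pop$is_excitatory <- rep(TRUE, 8)
  expect_equal(nrow(build_recurrent_synapses(pop, spec0, seed = 1)), 0)

  # all-excitatory cube: expected synapse count by exhaustive enumeration
  spec <- liquid_spec(n_neurons = 8, dims = c(2, 2, 2), exc_fraction = 1)
  m <- as.matrix(pop[, c("x", "y", "z")])
  expected <- 0
  for (i in 1:8) {
    for (j in 1:8) {
      if (i != j) {
        d <- sqrt(sum((m[i, ] - m[j, ])^2))
        expected <- expected + 0.3 * exp(-(d / 2)^2)
      }
    }
  }
  counts <- vapply(1:2000, function(s) {
    nrow(build_recurrent_synapses(pop, spec, seed = s))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("realization frequency matches the stated probability", {
  # two neurons at distance 1: P(EE) = 0.3 * exp(-0.25)
  pop <- place_on_grid(2, c(1, 1, 2))
  pop$is_excitatory <- c(TRUE, TRUE)
  spec <- liquid_spec(n_neurons = 2, dims = c(1, 1, 2), exc_fraction = 1)
  n_trials <- 3000
  hits <- vapply(seq_len(n_trials), function(s) {
    tab <- build_recurrent_synapses(pop, spec, seed = s)
    sum(tab$pre == 1 & tab$post == 2)
  }, numeric(1))
  p <- connection_probability(1, "EE", spec$lambda, spec$C)
  se <- sqrt(p * (1 - p) / n_trials)
  expect_lt(abs(mean(hits) - p), 3 * se)
})

test_that("synapse table obeys the structural invariants", {
  liq <- tiny_liquid(n = 150, channels = 12, seed = 7)
  rec <- dplyr::filter(liq$synapses, type %in% c("EE", "EI", "IE", "II"))
  expect_true(all(rec$pre != rec$post))
  expect_true(all(liq$synapses$weight >= 0))
  expected_delay <- c(EE = 1.5, EI = 0.8, IE = 0.8, II = 0.8)
  expect_equal(rec$delay_ms, unname(expected_delay[rec$type]))
  # type labels consistent with the populations
  is_exc <- liq$neurons$is_excitatory
  expect_equal(substr(rec$type, 1, 1), ifelse(is_exc[rec$pre], "E", "I"))
  expect_equal(substr(rec$type, 2, 2), ifelse(is_exc[rec$post], "E", "I"))
})

test_that("recurrent weights are uniform on the per-type support", {
  set.seed(1)
  w <- sample_recurrent_weight(rep("EE", 1e5))
  expect_true(all(w >= 0 & w <= 0.6))
  se <- 0.6 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(w) - 0.3), 3 * se)
  expect_equal(sample_recurrent_weight("EE", upper = c(EE = 0)), 0)
})

test_that("input wiring gives exact fan-in from distinct channels", {
  liq <- tiny_liquid(n = 80, channels = 9, seed = 3)
  inp <- dplyr::filter(liq$synapses, startsWith(type, "input"))
  per_neuron <- dplyr::count(inp, post)
  expect_equal(nrow(per_neuron), 80)
  expect_true(all(per_neuron$n == 7))
  dup <- dplyr::count(inp, post, pre)
  expect_true(all(dup$n == 1)) # no duplicate channel within one in-set

  spec0 <- liquid_spec(n_neurons = 10, input_in_degree = 0)
  pop <- place_on_grid(10, spec0$dims)
  pop$is_excitatory <- split_ei(10, 0.8, seed = 1)
  expect_equal(nrow(build_input_synapses(20, pop, spec0, seed = 1)), 0)
  expect_error(build_input_synapses(3, pop, liquid_spec(n_neurons = 10),
                                    seed = 1),
               "in-degree 7 exceeds")
})

test_that("input weight supports honour the inhibitory factor", {
  liq <- tiny_liquid(n = 400, channels = 20, seed = 5)
  inp <- dplyr::filter(liq$synapses, startsWith(type, "input"))
  w_e <- inp$weight[inp$type == "input-E"]
  w_i <- inp$weight[inp$type == "input-I"]
  expect_true(all(w_e >= 0 & w_e <= 0.4))
  expect_true(all(w_i >= 0 & w_i <= 0.2)) # factor 0.5 baseline
  expect_gt(max(w_i), 0.2 * 0.9) # empirical max approaches the bound
  expect_true(all(inp$delay_ms == 1.0))
})

test_that("time-constant assignment follows the configured regimes", {
  spec_f <- liquid_spec(n_neurons = 50)
  pop <- place_on_grid(50, spec_f$dims)
  pop$is_excitatory <- split_ei(50, 0.8, seed = 1)
  fixed <- assign_time_constants(pop, spec_f, seed = 1)
  expect_true(all(fixed$tau_m == 30))
  expect_true(all(is.na(fixed$tau_sfa)))

  spec_u <- liquid_spec(n_neurons = 1e5, tau_mode = "uniform",
                        sfa_mode = "uniform")
  pop_u <- tibble::tibble(id = seq_len(1e5),
                          is_excitatory = split_ei(1e5, 0.8, seed = 2))
  uni <- assign_time_constants(pop_u, spec_u, seed = 2)
  expect_true(all(uni$tau_m >= 5 & uni$tau_m <= 55))
  se_tau <- 50 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(uni$tau_m) - 30), 3 * se_tau)
  expect_true(all(is.na(uni$tau_sfa[!uni$is_excitatory])))
  sfa <- uni$tau_sfa[uni$is_excitatory]
  expect_true(all(sfa >= 50 & sfa <= 1050))
  se_sfa <- 1000 / sqrt(12) / sqrt(length(sfa))
  expect_lt(abs(mean(sfa) - 550), 3 * se_sfa)
})

test_that("weight quantization snaps to per-type levels within bound", {
  liq <- tiny_liquid(n = 300, channels = 15, seed = 11)
  q <- quantize_weights(liq, bits = 4)
  uppers <- c(`input-E` = 0.4, `input-I` = 0.2,
              EE = 0.6, EI = 0.4, IE = 1.2, II = 0.4)
  for (tp in unique(q$synapses$type)) {
    wq <- q$synapses$weight[q$synapses$type == tp]
    expect_lte(length(unique(wq)), 16)
    w0 <- liq$synapses$weight[liq$synapses$type == tp]
    bound <- uppers[[tp]] / (2 * (2^4 - 1))
    expect_true(all(abs(w0 - wq) <= bound + 1e-12))
  }
  # idempotence and full-precision identity
  expect_identical(quantize_weights(q, bits = 4)$synapses, q$synapses)
  expect_identical(quantize_weights(liq, bits = 64)$synapses, liq$synapses)
})

test_that("liquid builds are reproducible and serializable", {
  a <- tiny_liquid(n = 70, channels = 8, seed = 42)
  b <- tiny_liquid(n = 70, channels = 8, seed = 42)
  expect_identical(a$synapses, b$synapses)
  expect_identical(a$neurons, b$neurons)

  dir <- withr::local_tempdir()
  write_liquid(a, dir)
  back <- read_liquid(dir)
  expect_equal(back$synapses$weight, a$synapses$weight, tolerance = 1e-12)
  expect_equal(back$neurons$is_excitatory, a$neurons$is_excitatory)
  expect_equal(back$spec$inhib_factor, a$spec$inhib_factor)
})
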