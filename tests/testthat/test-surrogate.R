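# small configs keep the spiking tests fast; dynamics-level properties are
# checked at n = 400 in the acceptance suite
small_cfg <- function(n = 200, ...) circuit_config(n_total = n, ...)

test_that("population counts follow the proportions and survival scaling", {
  circ <- build_circuit(circuit_config(n_total = 1000),
                        make_profile("middle_age"), seed = 1)
  expect_equal(unname(circ$counts), c(800, 50, 70, 80))

  older <- build_circuit(circuit_config(n_total = 1000),
                         make_profile("older", 20), seed = 1)
  # round-half-up of 50 * 0.758 = 37.9
  expect_equal(unname(older$counts["sst"]), 38)
  expect_equal(unname(older$counts["vip"]), round(80 * 0.824))
  expect_equal(unname(older$counts["pyr"]), 800)
})

test_that("aging profile scales NMDA weights and passive parameters", {
  cfg <- small_cfg()
  mid <- build_circuit(cfg, make_profile("middle_age"), seed = 3)
  nmda <- build_circuit(cfg, make_profile("nmda_loss", 20), seed = 3)
  # same connectivity realization under the same seed
  expect_identical(mid$synapses$post, nmda$synapses$post)
  w_mid <- mid$synapses$w
  w_nmda <- nmda$synapses$w
  is_nmda_on_pyr <- mid$synapses$chan == 1L &
    mid$pop[mid$synapses$post + 1L] == "pyr"
  expect_equal(w_nmda[is_nmda_on_pyr], 0.5 * w_mid[is_nmda_on_pyr])
  expect_equal(w_nmda[!is_nmda_on_pyr], w_mid[!is_nmda_on_pyr])

  spine <- build_circuit(cfg, make_profile("spine_loss", 20), seed = 3)
  pyr <- spine$pop == "pyr"
  expect_equal(spine$neurons$gL[pyr],
               mid$neurons$gL[pyr] * spine$profile$passive_multiplier)
  # fewer edges overall under the reduced Pyr->Pyr connection probability
  expect_lt(length(spine$synapses$w), length(mid$synapses$w))
})

test_that("circuit construction is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- build_circuit(cfg, make_profile("older"), seed = 11)
  b <- build_circuit(cfg, make_profile("older"), seed = 11)
  expect_identical(a$synapses, b$synapses)
  c2 <- build_circuit(cfg, make_profile("older"), seed = 12)
  expect_false(identical(a$synapses$post, c2$synapses$post))
})

test_that("survival scaling that empties a population floors at one cell", {
  cfg <- circuit_config(n_total = 100) # 5 SST cells
  prof <- make_profile("older", 20)
  prof$sst_survival <- 0.01
  expect_warning(circ <- build_circuit(cfg, prof, seed = 1), "flooring")
  expect_equal(unname(circ$counts["sst"]), 1)
})

test_that("no background drive produces no spikes", {
  cfg <- small_cfg(100)
  cfg$ou$mean[] <- 0
  cfg$ou$sd[] <- 0
  out <- simulate_circuit(build_circuit(cfg, seed = 1), duration = 500,
                          seed = 1)
  expect_length(out$spikes$time, 0)
})

test_that("simulation is bit-identical under a fixed seed", {
  circ <- build_circuit(small_cfg(), seed = 5)
  a <- simulate_circuit(circ, duration = 1000, seed = 7)
  b <- simulate_circuit(circ, duration = 1000, seed = 7)
  expect_identical(a$spikes$time, b$spikes$time)
  expect_identical(a$spikes$neuron, b$spikes$neuron)
  expect_identical(a$dipole$x, b$dipole$x)
  c2 <- simulate_circuit(circ, duration = 1000, seed = 8)
  expect_false(identical(a$spikes$time, c2$spikes$time))
})

test_that("baseline regime is sparse and irregular at the default drive", {
  circ <- build_circuit(circuit_config(n_total = 400), seed = 1)
  out <- simulate_circuit(circ, duration = 4000, seed = 1)
  rate <- population_rate(out$spikes)
  expect_gt(rate, 0.1)
  expect_lt(rate, 10)
  expect_gt(isi_cv(out$spikes), 0.5)
})

test_that("removing all inhibitory synapses raises the Pyr baseline rate", {
  cfg <- small_cfg()
  no_inh <- cfg
  no_inh$connections$w_gaba[] <- 0
  r_ctrl <- population_rate(
    simulate_circuit(build_circuit(cfg, seed = 2), duration = 1500,
                     seed = 2)$spikes)
  r_free <- population_rate(
    simulate_circuit(build_circuit(no_inh, seed = 2), duration = 1500,
                     seed = 2)$spikes)
  expect_gt(r_free, r_ctrl)
})

test_that("the replayed dipole is linear in the synaptic conductances", {
  cfg <- small_cfg()
  circ <- build_circuit(cfg, seed = 4)
  out <- simulate_circuit(circ, duration = 800, seed = 4)
  expect_gt(length(out$spikes$time), 0)
  doubled <- circ
  doubled$synapses$w <- 2 * circ$synapses$w
  d1 <- replay_dipole(circ, out$spikes)
  d2 <- replay_dipole(doubled, out$spikes)
  expect_equal(d2$x, 2 * d1$x, tolerance = 1e-12)
})

test_that("stimulus protocols carry the published parameters", {
  b <- brief_stimulus()
  pyr <- b[b$population == "pyr", ]
  expect_equal(c(pyr$n_targets, pyr$delay_min, pyr$delay_max, pyr$gmax),
               c(55, 2, 4, 4))
  late <- b[b$population == "vip" & b$phase == "late", ]
  expect_equal(c(late$n_targets, late$delay_min, late$delay_max, late$gmax),
               c(80, 7, 12, 2.2))
  expect_equal(b[b$population == "pv", "gmax"], 2)
  expect_equal(b[b$population == "vip" & b$phase == "early", "gmax"], 2.8)

  s <- strong_stimulus()
  expect_false("pv" %in% s$population)
  expect_equal(s[s$population == "vip" & s$phase == "early", "gmax"], 5.6)
  expect_equal(s[s$population == "vip" & s$phase == "late", "gmax"], 4.4)
  spyr <- s[s$population == "pyr", ]
  expect_equal(c(spyr$n_targets, spyr$delay_min, spyr$delay_max, spyr$gmax,
                 spyr$n_synapses), c(55, 2, 22, 2, 2))
})

test_that("stimulated counts are capped at the available population size", {
  # n_total = 200 has only 16 VIP cells, fewer than the 80 the protocol asks
  circ <- build_circuit(small_cfg(200), seed = 1)
  ev <- agecircuit:::with_seed(
    1, agecircuit:::make_stim_events(circ, brief_stimulus(), 0))
  vip_idx <- circ$idx_of_pop$vip - 1L
  vip_targets <- unique(ev$target[ev$target %in% vip_idx])
  expect_lte(length(vip_targets), length(vip_idx))
  expect_gt(length(vip_targets), 0)
})

test_that("a stimulus evokes a clear pyramidal response", {
  circ <- build_circuit(circuit_config(n_total = 400), seed = 1)
  out <- simulate_circuit(circ, stimulus = brief_stimulus(), n_trials = 5,
                          pre_span = 1500, trial_interval = 250, seed = 1)
  rec <- recurrent_rate_distribution(out$spikes, trials = 5)
  base_rate <- population_rate(out$spikes, t_start = 0, t_end = 1500)
  expect_gt(mean(rec$rates), 3 * base_rate)
})
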