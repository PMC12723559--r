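#' Brief-stimulus protocol
#'
#' Thalamic-like feedforward volley: excitatory AMPA/NMDA synapses onto 55
#' Pyr neurons (delay 2-4 ms, 4 nS), 35 PV interneurons (2-2.5 ms, 2 nS),
#' and VIP interneurons in two phases - early (65 cells, 2-2.5 ms, 2.8 nS)
#' and late (80 cells, 7-12 ms, 2.2 nS).
#'
#' @return An object of class `stimulus_spec` (data frame of per-target
#'   entries: population, phase, number stimulated, delay window ms,
#'   conductance nS, synapse count per target).
#' @examples
#' brief_stimulus()
#' @export
brief_stimulus <- function() {
  structure(data.frame(
    population = c("pyr", "pv", "vip", "vip"),
    phase = c("main", "main", "early", "late"),
    n_targets = c(55, 35, 65, 80),
    delay_min = c(2, 2, 2, 7),
    delay_max = c(4, 2.5, 2.5, 12),
    gmax = c(4, 2, 2.8, 2.2),
    n_synapses = c(1, 1, 1, 1)
  ), class = c("stimulus_spec", "data.frame"))
}

#' Stronger-stimulus protocol promoting recurrent activity
#'
#' Modifies the brief stimulus to enhance recurrent activation: PV
#' stimulation is removed (less feedforward inhibition), VIP stimulation
#' is doubled in conductance (early 5.6 nS, late 4.4 nS; more
#' disinhibition), and Pyr excitation is prolonged - delay window widened
#' to 2-22 ms, synapse count doubled, with conductance halved to 2 nS.
#'
#' @return An object of class `stimulus_spec`.
#' @examples
#' strong_stimulus()
#' @export
strong_stimulus <- function() {
  structure(data.frame(
    population = c("pyr", "vip", "vip"),
    phase = c("main", "early", "late"),
    n_targets = c(55, 65, 80),
    delay_min = c(2, 2, 7),
    delay_max = c(22, 2.5, 12),
    gmax = c(2, 5.6, 4.4),
    n_synapses = c(2, 1, 1)
  ), class = c("stimulus_spec", "data.frame"))
}

# expand a stimulus spec into per-synapse conductance events
make_stim_events <- function(circuit, stimulus, stim_times) {
  if (is.null(stimulus) || length(stim_times) == 0L) {
    return(list(time = numeric(0), target = integer(0),
                chan = integer(0), w = numeric(0)))
  }
  nm <- circuit$profile$nmda_multiplier
  sg <- circuit$config$stimulus_gain
  if (is.null(sg)) sg <- 1
  time <- numeric(0); target <- integer(0); chan <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(stimulus))) {
    entry <- stimulus[r, ]
    avail <- circuit$idx_of_pop[[entry$population]]
    n_t <- min(entry$n_targets, length(avail))
    if (n_t == 0L) next
    targets <- if (length(avail) == 1L) avail else
      sample(avail, n_t) # fixed target set across trials
    for (tt in stim_times) {
      for (s in seq_len(entry$n_synapses)) {
        delays <- stats::runif(n_t, entry$delay_min, entry$delay_max)
        ev_t <- tt + delays
        g_ampa <- sg * entry$gmax
        g_nmda <- if (entry$population == "pyr") g_ampa * nm else g_ampa
        time <- c(time, ev_t, ev_t)
        target <- c(target, targets - 1L, targets - 1L)
        chan <- c(chan, rep(0L, n_t), rep(1L, n_t))
        w <- c(w, rep(g_ampa, n_t), rep(g_nmda, n_t))
      }
    }
  }
  ord <- order(time)
  list(time = time[ord], target = as.integer(target[ord]),
       chan = as.integer(chan[ord]), w = w[ord])
}

#' Simulate a circuit at baseline or under a stimulus protocol
#'
#' Integrates the conductance-based network with fixed step `dt` under
#' independent per-neuron Ornstein-Uhlenbeck background drive. With a
#' stimulus, `n_trials` stimulus presentations are delivered after a
#' `pre_span` baseline period, spaced `trial_interval` apart; each
#' presentation activates the specified synapses at per-neuron delays drawn
#' uniformly from the entry's delay window. Returns the spike trains and
#' the decimated current-dipole proxy trace.
#'
#' @param circuit A [build_circuit()] object.
#' @param duration Total simulated time, ms. Defaults to `pre_span` plus
#'   the stimulus train length (stimulus runs) or must be given for
#'   baseline runs.
#' @param stimulus A `stimulus_spec` from [brief_stimulus()] /
#'   [strong_stimulus()], or `NULL` for baseline.
#' @param n_trials Number of stimulus presentations.
#' @param pre_span Pre-stimulus baseline span, ms.
#' @param trial_interval Spacing between stimulus presentations, ms.
#' @param seed Integer seed for the OU drive and stimulus delays.
#'
#' @return List with elements `spikes` (class `spike_data`: `time` ms,
#'   `neuron`, per-neuron `pop` labels, `duration`, `stim_times`) and
#'   `dipole` (class `dipole_trace`: `x` in nA*um, `fs` Hz).
#' @examples
#' circ <- build_circuit(circuit_config(n_total = 200), seed = 1)
#' out <- simulate_circuit(circ, duration = 1000, seed = 1)
#' @export
simulate_circuit <- function(circuit, duration = NULL, stimulus = NULL,
                             n_trials = 20, pre_span = 3000,
                             trial_interval = 300, seed = 1) {
  stopifnot(inherits(circuit, "circuit"))
  stim_times <- numeric(0)
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_spec"))
    stim_times <- pre_span + (seq_len(n_trials) - 1) * trial_interval
    if (is.null(duration)) duration <- pre_span + n_trials * trial_interval
  }
  if (is.null(duration) || duration <= 0)
    stop("'duration' must be a positive time in ms")
  events <- with_seed(seed + 1L, make_stim_events(circuit, stimulus,
                                                  stim_times))
  cfg <- circuit$config
  res <- sim_core(circuit$neurons, circuit$synapses,
                  list(tau_rise = c(cfg$kinetics$ampa["tau_rise"],
                                    cfg$kinetics$nmda["tau_rise"],
                                    cfg$kinetics$gaba["tau_rise"],
                                    cfg$kinetics$gaba["tau_rise"]),
                       tau_decay = c(cfg$kinetics$ampa["tau_decay"],
                                     cfg$kinetics$nmda["tau_decay"],
                                     cfg$kinetics$gaba["tau_decay"],
                                     cfg$kinetics$gaba["tau_decay"])),
                  list(mean = ou_vector(circuit, "mean"),
                       sd = ou_vector(circuit, "sd"),
                       tau = cfg$ou_tau),
                  events, duration, cfg$dt, cfg$delay,
                  1000 / cfg$record_fs, as.integer(seed), FALSE,
                  list(time = numeric(0), neuron = integer(0)), -65)
  spikes <- structure(list(
    time = res$spike_time, neuron = res$spike_neuron + 1L,
    pop = circuit$pop, n = circuit$n, counts = circuit$counts,
    duration = duration, stim_times = stim_times,
    condition = circuit$profile$label
  ), class = "spike_data")
  dipole <- structure(list(x = res$dipole, fs = res$fs,
                           units = "nA*um"), class = "dipole_trace")
  list(spikes = spikes, dipole = dipole)
}

ou_vector <- function(circuit, field) {
  tab <- circuit$config$ou
  rownames(tab) <- tab$pop
  as.numeric(tab[circuit$pop, field])
}

#' Replay frozen spike trains through the synapses (open-loop dipole)
#'
#' Drives the circuit's synaptic machinery from a fixed spike list with the
#' membrane held at a reference potential, so the resulting dipole trace is
#' exactly linear in the synaptic conductances. Used to verify dipole
#' linearity and to decompose dipole contributions.
#'
#' @param circuit A [build_circuit()] object.
#' @param spikes A `spike_data` object (its `time`/`neuron` drive the
#'   synapses).
#' @param duration Replay duration, ms (defaults to the spike data's).
#' @param v_ref Membrane potential at which driving forces are evaluated,
#'   mV.
#' @return A `dipole_trace`.
#' @export
replay_dipole <- function(circuit, spikes, duration = NULL, v_ref = -65) {
  stopifnot(inherits(circuit, "circuit"), inherits(spikes, "spike_data"))
  if (is.null(duration)) duration <- spikes$duration
  cfg <- circuit$config
  ord <- order(spikes$time)
  res <- sim_core(circuit$neurons, circuit$synapses,
                  list(tau_rise = c(cfg$kinetics$ampa["tau_rise"],
                                    cfg$kinetics$nmda["tau_rise"],
                                    cfg$kinetics$gaba["tau_rise"],
                                    cfg$kinetics$gaba["tau_rise"]),
                       tau_decay = c(cfg$kinetics$ampa["tau_decay"],
                                     cfg$kinetics$nmda["tau_decay"],
                                     cfg$kinetics$gaba["tau_decay"],
                                     cfg$kinetics$gaba["tau_decay"])),
                  list(mean = ou_vector(circuit, "mean"),
                       sd = ou_vector(circuit, "sd"),
                       tau = cfg$ou_tau),
                  list(time = numeric(0), target = integer(0),
                       chan = integer(0), w = numeric(0)),
                  duration, cfg$dt, cfg$delay, 1000 / cfg$record_fs,
                  0L, TRUE,
                  list(time = spikes$time[ord],
                       neuron = as.integer(spikes$neuron[ord] - 1L)),
                  v_ref)
  structure(list(x = res$dipole, fs = res$fs, units = "nA*um"),
            class = "dipole_trace")
}

#' Population firing rate from spike data
#'
#' @param spikes A `spike_data` object.
#' @param population Population label (default `"pyr"`).
#' @param t_start,t_end Analysis window, ms (defaults to the full run).
#' @return Mean rate in Hz per neuron of that population.
#' @export
population_rate <- function(spikes, population = "pyr", t_start = 0,
                            t_end = NULL) {
  stopifnot(inherits(spikes, "spike_data"))
  if (is.null(t_end)) t_end <- spikes$duration
  members <- which(spikes$pop == population)
  sel <- spikes$neuron %in% members & spikes$time >= t_start &
    spikes$time <= t_end
  sum(sel) / (length(members) * (t_end - t_start) / 1000)
}

#' Coefficient of variation of inter-spike intervals
#'
#' Mean CV of ISI over neurons of a population with at least `min_spikes`
#' spikes; `NA` if no neuron qualifies.
#'
#' @inheritParams population_rate
#' @param min_spikes Minimum spikes per neuron to enter the average.
#' @return Mean CV of the inter-spike-interval distribution.
#' @export
isi_cv <- function(spikes, population = "pyr", min_spikes = 3) {
  stopifnot(inherits(spikes, "spike_data"))
  members <- which(spikes$pop == population)
  sel <- spikes$neuron %in% members
  by_neuron <- split(spikes$time[sel], spikes$neuron[sel])
  cvs <- vapply(by_neuron, function(tt) {
    if (length(tt) < min_spikes) return(NA_real_)
    isi <- diff(sort(tt))
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  if (all(is.na(cvs))) return(NA_real_)
  mean(cvs, na.rm = TRUE)
}

#' @export
print.spike_data <- function(x, ...) {
  cat("Spike data:", length(x$time), "spikes from", x$n, "neurons over",
      x$duration, "ms\n")
  if (length(x$stim_times))
    cat("  ", length(x$stim_times), "stimulus presentations\n")
  invisible(x)
}
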