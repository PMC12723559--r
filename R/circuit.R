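POPULATIONS <- c("pyr", "sst", "pv", "vip")

round_half_up <- function(x) floor(x + 0.5)

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration of the surrogate cortical microcircuit
#'
#' Defines the four-population network: population proportions (80% Pyr,
#' 5% SST, 7% PV, 8% VIP), leaky integrate-and-fire neuron parameters,
#' the connectivity motif (Pyr excites all populations; SST and PV inhibit
#' Pyr on the apical and basal compartment classes respectively; VIP
#' disinhibits by targeting SST and PV), synaptic kinetics (NMDA 2/65 ms,
#' AMPA 0.3/3 ms, GABA 1/10 ms rise/decay), per-population
#' Ornstein-Uhlenbeck background drive, and integration settings.
#'
#' Connection probabilities and synaptic conductances are configuration,
#' not constants; the defaults were calibrated so that the middle-age
#' circuit fires irregularly near ~1 Hz in the Pyr population with a
#' network rhythm at the alpha/low-beta boundary in the dipole trace.
#'
#' @param n_total Total number of neurons (default 1000).
#' @param proportions Named fractions per population; must sum to 1.
#' @param neuron_params Data frame of per-population LIF parameters
#'   (capacitance `C` pF, leak `gL` nS, rest `EL` mV, threshold `Vth` mV,
#'   reset `Vreset` mV, refractory `tref` ms, spike-triggered adaptation
#'   increment `adapt_b` pA).
#' @param adapt_tau Decay time of the spike-triggered adaptation current,
#'   ms. Adaptation on Pyr cells terminates stimulus-evoked persistent
#'   activity so the network returns to baseline between trials.
#' @param connections Data frame of connection rules: `pre`, `post`
#'   populations, probability `p`, conductances `w_ampa`, `w_nmda`,
#'   `w_gaba` (nS), and the GABA compartment class `gaba_chan`
#'   (`"apical"` or `"basal"`).
#' @param ou Data frame of per-population OU drive (`mean`, `sd` in nS).
#' @param ou_tau OU correlation time, ms.
#' @param kinetics Named list of `tau_rise`/`tau_decay` (ms) for channels
#'   `ampa`, `nmda`, `gaba`.
#' @param dt Integration step, ms.
#' @param delay Synaptic transmission delay, ms.
#' @param record_fs Sampling rate of the decimated dipole trace, Hz.
#' @param z_apical,z_basal Signed depth offsets (micrometers) of the two
#'   compartment classes used by the dipole proxy.
#' @param stimulus_gain Factor mapping the stimulus protocols' dendritic
#'   conductances onto the point neurons. The published conductances are
#'   delivered to basal/apical dendrites of morphological neurons, where
#'   dendritic attenuation reduces their somatic impact; a gain below 1
#'   stands in for that attenuation.
#' @param E_exc,E_inh Synaptic reversal potentials, mV.
#' @param mg Extracellular magnesium for the NMDA block, mM.
#'
#' @return An object of class `circuit_config`.
#' @examples
#' cfg <- circuit_config(n_total = 200)
#' @export
circuit_config <- function(
    n_total = 1000,
    proportions = c(pyr = 0.80, sst = 0.05, pv = 0.07, vip = 0.08),
    neuron_params = data.frame(
      pop = POPULATIONS,
      C = c(200, 100, 100, 80),
      gL = c(10, 5, 10, 5),
      EL = c(-70, -70, -70, -70),
      Vth = c(-50, -52, -50, -52),
      Vreset = c(-60, -60, -60, -60),
      tref = c(3, 2, 1.5, 2),
      adapt_b = c(100, 0, 0, 0)
    ),
    adapt_tau = 150,
    connections = data.frame(
      pre = c("pyr", "pyr", "pyr", "pyr", "sst", "pv", "vip", "vip"),
      post = c("pyr", "sst", "pv", "vip", "pyr", "pyr", "sst", "pv"),
      p = c(0.15, 0.20, 0.20, 0.10, 0.30, 0.35, 0.30, 0.30),
      w_ampa = c(1.53, 0.50, 1.34, 0.30, 0, 0, 0, 0),
      w_nmda = c(1.53, 0.30, 0.30, 0.20, 0, 0, 0, 0),
      w_gaba = c(0, 0, 0, 0, 3.0, 7.75, 1.0, 1.0),
      gaba_chan = c(NA, NA, NA, NA, "apical", "basal", "basal", "basal")
    ),
    ou = data.frame(
      pop = POPULATIONS,
      mean = c(3.2, 1.3, 2.8, 1.2),
      sd = c(1.6, 0.8, 1.2, 0.6)
    ),
    ou_tau = 3,
    kinetics = list(
      ampa = c(tau_rise = 0.3, tau_decay = 3),
      nmda = c(tau_rise = 2, tau_decay = 65),
      gaba = c(tau_rise = 1, tau_decay = 10)
    ),
    stimulus_gain = 0.4,
    dt = 0.025,
    delay = 1,
    record_fs = 2000,
    z_apical = 300,
    z_basal = -150,
    E_exc = 0,
    E_inh = -80,
    mg = 1) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9,
            setequal(names(proportions), POPULATIONS))
  for (k in names(kinetics)) {
    if (kinetics[[k]]["tau_rise"] >= kinetics[[k]]["tau_decay"])
      stop("tau_rise must be < tau_decay for ", k)
  }
  structure(list(
    n_total = n_total, proportions = proportions,
    neuron_params = neuron_params, adapt_tau = adapt_tau,
    connections = connections,
    ou = ou, ou_tau = ou_tau, kinetics = kinetics,
    stimulus_gain = stimulus_gain,
    dt = dt, delay = delay, record_fs = record_fs,
    z_apical = z_apical, z_basal = z_basal,
    E_exc = E_exc, E_inh = E_inh, mg = mg
  ), class = "circuit_config")
}

#' Build a randomized circuit under an aging profile
#'
#' Draws one realization of the network: population counts (interneuron
#' counts scaled by the profile's survival fractions with round-half-up),
#' Bernoulli connectivity per connection rule (Pyr to Pyr probability
#' scaled by the profile's connection multiplier), synaptic weights (NMDA
#' conductance onto Pyr scaled by the NMDA multiplier), and Pyr passive
#' parameters (leak conductance and capacitance scaled by the passive
#' multiplier).
#'
#' @param config A [circuit_config()].
#' @param profile An [make_profile()] aging profile.
#' @param seed Integer seed controlling connectivity and cell deletion.
#'
#' @return An object of class `circuit`: neuron tables, compressed edge
#'   list, and the originating config/profile/seed.
#' @examples
#' circ <- build_circuit(circuit_config(n_total = 200),
#'                       make_profile("older", 20), seed = 1)
#' @export
build_circuit <- function(config, profile = make_profile("middle_age"),
                          seed = 1) {
  stopifnot(inherits(config, "circuit_config"),
            inherits(profile, "aging_profile"))
  with_seed(seed, {
    counts <- round_half_up(config$proportions[POPULATIONS] * config$n_total)
    survival <- c(pyr = 1, sst = profile$sst_survival,
                  pv = profile$pv_survival, vip = profile$vip_survival)
    aged_counts <- round_half_up(counts * survival[POPULATIONS])
    low <- aged_counts < 1 & counts >= 1
    if (any(low)) {
      warning("survival scaling left < 1 cell for: ",
              paste(POPULATIONS[low], collapse = ", "), "; flooring at 1")
      aged_counts[low] <- 1
    }

    pop_of <- rep(POPULATIONS, times = aged_counts)
    n <- length(pop_of)
    idx_of_pop <- split(seq_len(n), factor(pop_of, levels = POPULATIONS))

    np <- config$neuron_params
    rownames(np) <- np$pop
    C <- np[pop_of, "C"]
    gL <- np[pop_of, "gL"]
    is_pyr <- pop_of == "pyr"
    C[is_pyr] <- C[is_pyr] * profile$passive_multiplier
    gL[is_pyr] <- gL[is_pyr] * profile$passive_multiplier

    # channels: 0 AMPA, 1 NMDA, 2 GABA apical, 3 GABA basal
    pre_l <- list(); post_l <- list(); chan_l <- list(); w_l <- list()
    k <- 0L
    for (r in seq_len(nrow(config$connections))) {
      rule <- config$connections[r, ]
      pre_idx <- idx_of_pop[[rule$pre]]
      post_idx <- idx_of_pop[[rule$post]]
      p <- rule$p
      if (rule$pre == "pyr" && rule$post == "pyr")
        p <- p * profile$pyr_pyr_connection_multiplier
      pairs <- expand.grid(pre = pre_idx, post = post_idx)
      pairs <- pairs[pairs$pre != pairs$post, , drop = FALSE]
      keep <- stats::runif(nrow(pairs)) < p
      pairs <- pairs[keep, , drop = FALSE]
      if (nrow(pairs) == 0L) next
      if (rule$w_ampa > 0) {
        k <- k + 1L
        pre_l[[k]] <- pairs$pre; post_l[[k]] <- pairs$post
        chan_l[[k]] <- rep(0L, nrow(pairs))
        w_l[[k]] <- rep(rule$w_ampa, nrow(pairs))
      }
      if (rule$w_nmda > 0) {
        wn <- rep(rule$w_nmda, nrow(pairs))
        wn[pop_of[pairs$post] == "pyr"] <-
          rule$w_nmda * profile$nmda_multiplier
        k <- k + 1L
        pre_l[[k]] <- pairs$pre; post_l[[k]] <- pairs$post
        chan_l[[k]] <- rep(1L, nrow(pairs)); w_l[[k]] <- wn
      }
      if (rule$w_gaba > 0) {
        ch <- if (identical(rule$gaba_chan, "apical")) 2L else 3L
        k <- k + 1L
        pre_l[[k]] <- pairs$pre; post_l[[k]] <- pairs$post
        chan_l[[k]] <- rep(ch, nrow(pairs))
        w_l[[k]] <- rep(rule$w_gaba, nrow(pairs))
      }
    }
    pre <- unlist(pre_l); post <- unlist(post_l)
    chan <- unlist(chan_l); w <- unlist(w_l)
    ord <- order(pre, post, chan)
    pre <- pre[ord]; post <- post[ord]; chan <- chan[ord]; w <- w[ord]
    ptr <- c(0L, cumsum(tabulate(pre, nbins = n)))

    structure(list(
      config = config, profile = profile, seed = seed,
      n = n, counts = aged_counts, pop = pop_of,
      idx_of_pop = idx_of_pop,
      neurons = list(
        C = C, gL = gL,
        EL = np[pop_of, "EL"], Vth = np[pop_of, "Vth"],
        Vreset = np[pop_of, "Vreset"], tref = np[pop_of, "tref"],
        adapt_b = np[pop_of, "adapt_b"], adapt_tau = config$adapt_tau,
        pop = ifelse(is_pyr, 0L, match(pop_of, POPULATIONS) - 1L),
        z_apical = config$z_apical, z_basal = config$z_basal,
        E_exc = config$E_exc, E_inh = config$E_inh, mg = config$mg
      ),
      synapses = list(
        ptr = as.integer(ptr), post = as.integer(post - 1L),
        chan = as.integer(chan), w = as.numeric(w)
      )
    ), class = "circuit")
  })
}

#' @export
print.circuit <- function(x, ...) {
  cat("Surrogate microcircuit:", x$n, "neurons (",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      ")\n")
  cat("  condition:", x$profile$label, " seed:", x$seed,
      " synaptic edges:", length(x$synapses$post), "\n")
  invisible(x)
}
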