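# Desk-scale laminar rate network. Populations are threshold-linear rate
# units with a soma depth and dendritic extents; every synaptic projection
# deposits inward membrane current over a depth-resolved placement kernel and
# an equal-magnitude return current over a soma-centred kernel (polarity
# reversed for inhibitory sources), so the depth integral of the total CSD is
# zero at every instant by construction. Distal placement attenuates the
# drive entering the rate equation but NOT the deposited current -- this
# asymmetry is what decouples synaptic placement (strong CSD effect, weak
# rate effect) from synaptic weights (strong rate effect, weak normalized-CSD
# effect).

default_populations <- function() {
  data.frame(
    name = c("E23", "I23", "E4", "I4", "E5", "I5", "E6", "I6"),
    layer = c("2/3", "2/3", "4", "4", "5", "5", "6", "6"),
    sign = c("excitatory", "inhibitory")[c(1, 2, 1, 2, 1, 2, 1, 2)],
    n_neurons = c(1000, 150, 1000, 150, 1000, 150, 1000, 150),
    soma_depth = c(210, 210, 370, 370, 520, 520, 740, 740),
    basal_lo = c(150, 150, 310, 310, 460, 460, 680, 680),
    basal_hi = c(270, 270, 430, 430, 580, 580, 800, 800),
    apical_lo = c(60, NA, 220, NA, 60, NA, 340, NA),
    apical_hi = c(200, NA, 360, NA, 510, NA, 730, NA),
    stringsAsFactors = FALSE)
}

proj_row <- function(source, target, weight, scheme, d_lo = 0, d_hi = 150,
                     kind) {
  data.frame(id = paste0(source, "->", target),
             source = source, target = target, weight = weight,
             scheme = scheme, d_lo = d_lo, d_hi = d_hi, kind = kind,
             stringsAsFactors = FALSE)
}

default_projections <- function(feedback = FALSE, l6_restrict = FALSE) {
  p <- rbind(
    # thalamocortical: L4-centred, basal+apical within 150 um (E targets);
    # soma/basal for inhibitory targets
    proj_row("LGN", "E4", 1.56, "both", 0, 150, "lgn"),
    proj_row("LGN", "I4", 1.17, "basal", 0, 150, "lgn"),
    proj_row("LGN", "E6", 0.46, "both", 0, 150, "lgn"),
    # background drive to every population
    proj_row("BKG", "E23", 0.45, "basal", 0, 150, "background"),
    proj_row("BKG", "I23", 0.35, "basal", 0, 150, "background"),
    proj_row("BKG", "E4", 0.40, "basal", 0, 150, "background"),
    proj_row("BKG", "I4", 0.30, "basal", 0, 150, "background"),
    proj_row("BKG", "E5", 0.50, "basal", 0, 150, "background"),
    proj_row("BKG", "I5", 0.35, "basal", 0, 150, "background"),
    proj_row("BKG", "E6", 0.45, "basal", 0, 150, "background"),
    proj_row("BKG", "I6", 0.30, "basal", 0, 150, "background"),
    # recurrent excitation (L2/3 and L4 targets limited to 200 um; L5/L6
    # targets free in the base configuration)
    proj_row("E4", "E23", 0.33, "both", 0, 200, "recurrent"),
    proj_row("E4", "E4", 0.12, "both", 0, 200, "recurrent"),
    proj_row("E4", "I4", 0.25, "basal", 0, 150, "recurrent"),
    proj_row("E23", "E23", 0.11, "both", 0, 200, "recurrent"),
    proj_row("E23", "I23", 0.25, "basal", 0, 150, "recurrent"),
    proj_row("E23", "E5", 0.30, "both", 0, 400, "recurrent"),
    proj_row("E5", "E5", 0.11, "both", 0, 400, "recurrent"),
    proj_row("E5", "I5", 0.25, "basal", 0, 150, "recurrent"),
    proj_row("E5", "E6", 0.28, "both", 0,
             if (l6_restrict) 150 else 400, "recurrent"),
    proj_row("E6", "E6", 0.10, "both", 0,
             if (l6_restrict) 150 else 400, "recurrent"),
    proj_row("E6", "I6", 0.22, "basal", 0, 150, "recurrent"),
    # inhibition: perisomatic
    proj_row("I23", "E23", 0.47, "soma", 0, 50, "recurrent"),
    proj_row("I23", "I23", 0.14, "soma", 0, 50, "recurrent"),
    proj_row("I4", "E4", 0.47, "soma", 0, 50, "recurrent"),
    proj_row("I4", "I4", 0.14, "soma", 0, 50, "recurrent"),
    proj_row("I5", "E5", 0.47, "soma", 0, 50, "recurrent"),
    proj_row("I5", "I5", 0.14, "soma", 0, 50, "recurrent"),
    proj_row("I6", "E6", 0.47, "soma", 0, 50, "recurrent"),
    proj_row("I6", "I6", 0.14, "soma", 0, 50, "recurrent"))
  if (feedback) {
    p <- rbind(p,
      proj_row("LM", "E23", 0.50, "apical", 0, 150, "feedback"),
      proj_row("LM", "E5", 0.35, "apical", 300, 460, "feedback"),
      proj_row("LM", "E5", 0.20, "basal", 0, 150, "feedback"),
      proj_row("LM", "I23", 0.40, "basal", 0, 150, "feedback"),
      proj_row("LM", "I5", 0.30, "basal", 0, 150, "feedback"))
    p$id <- make.unique(p$id, sep = "#")
  }
  p
}

external_sources <- function() c("LGN", "BKG", "LM")

#' Build the default V1-like laminar network
#'
#' Excitatory and inhibitory populations in layers 2/3-6 with soma depths
#' and dendritic extents spanning the 0-860 um column; thalamocortical input
#' onto L4 (basal + apical within 150 um), background drive to every
#' population, recurrent excitation and perisomatic inhibition, and optional
#' feedback from a higher visual area (LM) onto L2/3 apical dendrites,
#' L5 apical tufts (> 300 um) and basal dendrites, and L2/3 / L5
#' interneurons. Three presets capture the qualitative model configurations:
#' `"original"` (no feedback), `"intermediate"` (no feedback, recurrent
#' weights adjusted: excitatory-to-inhibitory scaled down 30%, inhibition
#' compensated up), `"final"` (feedback on, background drive to
#' feedback-targeted populations scaled into the 0.2-0.5 range, and
#' excitatory synapses onto L6 excitatory cells restricted to within 150 um
#' of the soma).
#'
#' @param preset `"original"`, `"intermediate"` or `"final"`.
#' @param feedback override the preset's feedback flag.
#' @param attenuation drive attenuation factor per 100 um of
#'   placement-to-soma distance, in `[0, 1]` (default 0.9; deposited
#'   currents are never attenuated, only the drive into the rate equation).
#' @param pitch depth grid pitch in um (default 20, spanning 0-860 um).
#' @return A `laminar_network`: list with `populations`, `projections`,
#'   `depth_axis` and `params`.
#' @export
build_default_network <- function(preset = c("final", "original",
                                             "intermediate"),
                                  feedback = NULL, attenuation = 0.9,
                                  pitch = 20) {
  preset <- match.arg(preset)
  if (attenuation < 0 || attenuation > 1)
    invalid_argument("attenuation must lie in [0, 1]")
  fb <- feedback %||% (preset == "final")
  proj <- default_projections(feedback = fb,
                              l6_restrict = preset == "final")
  if (preset == "intermediate") {
    ei <- proj$kind == "recurrent" & grepl("^E", proj$source) &
      grepl("^I", proj$target)
    proj$weight[ei] <- proj$weight[ei] * 0.7
    ie <- proj$kind == "recurrent" & grepl("^I", proj$source)
    proj$weight[ie] <- proj$weight[ie] * 1.15
  }
  if (preset == "final") {
    fb_targets <- c("E23", "I23", "E5", "I5")
    sel <- proj$kind == "background" & proj$target %in% fb_targets
    proj$weight[sel] <- proj$weight[sel] * 0.35   # factor in [0.2, 0.5]
  }
  pops <- default_populations()
  depth_axis <- seq(0, 860, by = pitch)
  net <- structure(list(populations = pops, projections = proj,
                        depth_axis = depth_axis,
                        params = list(tau = 10, attenuation = attenuation,
                                      soma_kernel_sd = 30,
                                      place_kernel_sd = 40,
                                      active_return = 0,
                                      rate_max = 1e4),
                        preset = preset),
                   class = "laminar_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  pops <- net$populations
  if (max(pops$soma_depth) > max(net$depth_axis) ||
      min(pops$soma_depth) < min(net$depth_axis))
    invalid_argument("population soma depths fall outside the depth grid")
  for (i in seq_len(nrow(net$projections))) {
    pr <- net$projections[i, ]
    if (pr$weight < 0) invalid_argument("projection weights must be >= 0")
    if (!(pr$target %in% pops$name))
      invalid_argument(sprintf("unknown target population %s", pr$target))
    tgt <- pops[pops$name == pr$target, ]
    if (pr$scheme %in% c("apical", "both") && !is.finite(tgt$apical_lo))
      invalid_argument(sprintf(
        "projection %s requests apical placement on %s, which has no apical dendrite",
        pr$id, pr$target))
    if (pr$d_lo < 0 || pr$d_hi < pr$d_lo)
      invalid_argument("placement distance bounds must be nonnegative and ordered")
  }
  invisible(net)
}

#' @export
print.laminar_network <- function(x, ...) {
  cat(sprintf("<laminar_network> preset '%s': %d populations, %d projections\n",
              x$preset, nrow(x$populations), nrow(x$projections)))
  invisible(x)
}

# truncated-Gaussian depth kernel on the grid, normalized to sum exactly 1
depth_kernel <- function(depth_axis, centre, sd, lo = -Inf, hi = Inf) {
  k <- exp(-(depth_axis - centre)^2 / (2 * sd^2))
  k[depth_axis < lo | depth_axis > hi] <- 0
  if (sum(k) == 0) k[which.min(abs(depth_axis - centre))] <- 1
  k / sum(k)
}

# placement + soma kernels and the drive attenuation factor of a projection
projection_geometry <- function(net, pr) {
  pops <- net$populations
  tgt <- pops[pops$name == pr$target, ]
  z <- net$depth_axis
  sdp <- net$params$place_kernel_sd
  basal_k <- depth_kernel(z, tgt$soma_depth, sdp, tgt$basal_lo, tgt$basal_hi)
  apical_k <- NULL
  if (is.finite(tgt$apical_lo)) {
    band_lo <- max(tgt$apical_lo, tgt$soma_depth - pr$d_hi)
    band_hi <- min(tgt$apical_hi, tgt$soma_depth - pr$d_lo)
    if (band_hi < band_lo) band_hi <- band_lo
    apical_k <- depth_kernel(z, (band_lo + band_hi) / 2,
                             (band_hi - band_lo) / 4 + 10, band_lo, band_hi)
  }
  place <- switch(pr$scheme,
                  soma = depth_kernel(z, tgt$soma_depth, 15),
                  basal = basal_k,
                  apical = apical_k,
                  both = 0.5 * basal_k + 0.5 * apical_k)
  if (is.null(place))
    invalid_argument(sprintf("scheme %s unavailable for target %s",
                             pr$scheme, pr$target))
  soma_k <- depth_kernel(z, tgt$soma_depth, net$params$soma_kernel_sd)
  mean_dist <- sum(place * abs(z - tgt$soma_depth))
  att <- net$params$attenuation^(mean_dist / 100)
  list(place = place, soma = soma_k, att = att)
}

#' Default flash-driven external input schedule
#'
#' Thalamocortical (LGN) drive: baseline, a transient peak near 40 ms and a
#' sustained plateau; background (BKG): constant; feedback (LM): a delayed
#' sustained drive arriving near 60 ms. Units are arbitrary drive rates.
#'
#' @param t time axis in ms relative to flash onset.
#' @return List with `t` and numeric vectors `LGN`, `BKG`, `LM`.
#' @export
default_flash_inputs <- function(t) {
  on <- function(x) stats::plogis(x / 3)
  list(t = t,
       LGN = 1 + 11 * exp(-(t - 40)^2 / (2 * 6^2)) +
         3.5 * on(t - 45) * on(250 - t),
       BKG = rep(5, length(t)),
       LM = 6 * on(t - 58) * on(250 - t))
}

#' Simulate the laminar network
#'
#' Integrates the threshold-linear rate equations
#' `tau * dr/dt = -r + [sum w * att * r_pre + external]_+` with forward
#' Euler, and accumulates depth-resolved current deposits: each projection
#' deposits its (unattenuated) presynaptic current `w * r_pre` as an inward
#' current over its placement kernel and an equal return current over a
#' soma-centred kernel, polarity reversed for inhibitory sources. The depth
#' integral of the total CSD is zero at every time step by construction.
#'
#' @param network a [build_default_network()] object.
#' @param inputs external drives, as produced by [default_flash_inputs()]
#'   (or `NULL` for the defaults on the simulation time axis).
#' @param duration end of the simulation window (ms after flash onset).
#' @param dt Euler step (ms).
#' @param t_start start of the window (ms, negative = pre-stimulus).
#' @param seed unused by the deterministic dynamics, accepted for interface
#'   stability.
#' @return A `sim_result`: list with `t`, `rates` (populations x time,
#'   spikes/s-scale), `csd_by_population` (deposit grids per target
#'   population), `csd_by_source` (deposit grids per presynaptic source),
#'   `csd_total` ([csd_pattern()]), `lfp_total` ([grid_pattern()] via the
#'   model-context disc operator) and `depth_axis`.
#' @export
simulate_network <- function(network, inputs = NULL, duration = 150,
                             dt = 0.5, t_start = -50, seed = NULL) {
  if (dt <= 0) invalid_argument("dt must be positive")
  tt <- seq(t_start, duration, by = dt)
  nt <- length(tt)
  inputs <- inputs %||% default_flash_inputs(tt)
  ext <- list()
  for (nm in external_sources()) {
    v <- inputs[[nm]]
    if (is.null(v)) v <- rep(0, nt)
    else if (length(v) != nt)
      v <- approx(inputs$t, v, xout = tt, rule = 2)$y
    ext[[nm]] <- v
  }
  pops <- network$populations
  npop <- nrow(pops)
  pidx <- setNames(seq_len(npop), pops$name)
  proj <- network$projections
  geom <- lapply(seq_len(nrow(proj)), function(i)
    projection_geometry(network, proj[i, ]))
  src_sign <- ifelse(proj$source %in% external_sources(), 1,
                     ifelse(grepl("^I", proj$source), -1, 1))
  src_internal <- match(proj$source, pops$name)   # NA for external

  nz <- length(network$depth_axis)
  rates <- matrix(0, npop, nt, dimnames = list(pops$name, NULL))
  csd_by <- setNames(lapply(seq_len(npop),
                            function(i) matrix(0, nz, nt)), pops$name)
  src_names <- unique(proj$source)
  csd_src <- setNames(lapply(src_names,
                             function(i) matrix(0, nz, nt)), src_names)
  tau <- network$params$tau
  for (k in seq_len(nt)) {
    r <- rates[, k]
    pre <- vapply(seq_len(nrow(proj)), function(i) {
      if (is.na(src_internal[i])) ext[[proj$source[i]]][k]
      else r[src_internal[i]]
    }, 1.0)
    syn <- proj$weight * pre                       # deposited current
    drive <- rep(0, npop)
    for (i in seq_len(nrow(proj))) {
      tg <- pidx[[proj$target[i]]]
      drive[tg] <- drive[tg] + src_sign[i] * syn[i] * geom[[i]]$att
      dep <- src_sign[i] * syn[i] * (geom[[i]]$soma - geom[[i]]$place)
      csd_by[[tg]][, k] <- csd_by[[tg]][, k] + dep
      csd_src[[proj$source[i]]][, k] <- csd_src[[proj$source[i]]][, k] + dep
    }
    if (network$params$active_return > 0) {
      for (p in which(pops$sign == "excitatory")) {
        amp <- network$params$active_return * r[p]
        gb <- depth_kernel(network$depth_axis, pops$soma_depth[p],
                           network$params$place_kernel_sd,
                           pops$basal_lo[p], pops$basal_hi[p])
        gs <- depth_kernel(network$depth_axis, pops$soma_depth[p], 15)
        csd_by[[p]][, k] <- csd_by[[p]][, k] + amp * (gb - gs)
      }
    }
    if (k < nt)
      rates[, k + 1] <- r + dt / tau * (-r + pmax(drive, 0))
    if (any(!is.finite(rates[, min(k + 1, nt)])) ||
        any(rates[, min(k + 1, nt)] > network$params$rate_max))
      numerical_failure(sprintf(
        "rate divergence in population %s",
        pops$name[which.max(rates[, min(k + 1, nt)])]))
  }
  csd_total <- Reduce(`+`, csd_by)
  fwd <- build_forward(network$depth_axis, context = "model")
  structure(list(t = tt, rates = rates, csd_by_population = csd_by,
                 csd_by_source = csd_src,
                 csd_total = csd_pattern(csd_total, network$depth_axis, tt),
                 lfp_total = grid_pattern(fwd$F %*% csd_total,
                                          network$depth_axis, tt,
                                          units = "LFP"),
                 depth_axis = network$depth_axis, network = network),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d populations, t = %g..%g ms (%d steps)\n",
              nrow(x$rates), min(x$t), max(x$t), length(x$t)))
  invisible(x)
}

#' Change the dendritic placement of matching projections
#'
#' Replaces the placement scheme of every projection onto `target` from the
#' given sources (default: all excitatory populations plus LGN); weights are
#' untouched.
#'
#' @param network a `laminar_network`.
#' @param target target population name.
#' @param scheme `"basal"`, `"apical"` or `"both"`.
#' @param sources source names to match (default: excitatory + LGN).
#' @return The modified network.
#' @export
set_placement <- function(network, target, scheme = c("basal", "apical",
                                                      "both"),
                          sources = NULL) {
  scheme <- match.arg(scheme)
  pops <- network$populations
  sources <- sources %||% c(pops$name[pops$sign == "excitatory"], "LGN")
  tgt <- pops[pops$name == target, ]
  if (nrow(tgt) == 0) invalid_argument("unknown target population")
  if (scheme %in% c("apical", "both") && !is.finite(tgt$apical_lo))
    invalid_argument(sprintf("target %s has no apical dendrite", target))
  sel <- network$projections$target == target &
    network$projections$source %in% sources
  network$projections$scheme[sel] <- scheme
  validate_network(network)
}

#' Scale synaptic weights of matching projections
#'
#' @param network a `laminar_network`.
#' @param factors either a single positive factor (applied to projections
#'   matched by `kind`, `source`, `target`) or a named vector of factors
#'   keyed by projection id.
#' @param kind optional projection class filter: `"recurrent"`,
#'   `"background"`, `"feedback"`, `"lgn"`.
#' @param source,target optional name filters.
#' @return The modified network (placements untouched).
#' @export
scale_weights <- function(network, factors, kind = NULL, source = NULL,
                          target = NULL) {
  if (any(factors <= 0)) invalid_argument("weight factors must be positive")
  pr <- network$projections
  if (!is.null(names(factors))) {
    idx <- match(names(factors), pr$id)
    if (anyNA(idx)) invalid_argument("unknown projection id in factor map")
    pr$weight[idx] <- pr$weight[idx] * unname(factors)
  } else {
    if (length(factors) != 1)
      invalid_argument("unnamed factors must be a single value")
    sel <- rep(TRUE, nrow(pr))
    if (!is.null(kind)) sel <- sel & pr$kind %in% kind
    if (!is.null(source)) sel <- sel & pr$source %in% source
    if (!is.null(target)) sel <- sel & pr$target %in% target
    pr$weight[sel] <- pr$weight[sel] * factors
  }
  network$projections <- pr
  network
}

#' Remove classes of projections
#'
#' @param network a `laminar_network`.
#' @param which `"recurrent"` (all intracortical connections),
#'   `"inhibitory"` (connections from inhibitory populations),
#'   `"feedback"` (LM input) or `"lgn"` (thalamocortical input).
#' @return The ablated network.
#' @export
ablate <- function(network, which = c("recurrent", "inhibitory", "feedback",
                                      "lgn")) {
  which <- match.arg(which)
  pr <- network$projections
  drop <- switch(which,
                 recurrent = !(pr$source %in% external_sources()),
                 inhibitory = grepl("^I", pr$source) &
                   !(pr$source %in% external_sources()),
                 feedback = pr$source == "LM",
                 lgn = pr$source == "LGN")
  network$projections <- pr[!drop, , drop = FALSE]
  network
}

#' One population's contribution to the simulated CSD
#'
#' Deposits are bookkept per target population; contributions sum exactly to
#' the total CSD.
#'
#' @param result a `sim_result`.
#' @param population population name.
#' @return A [csd_pattern()] of that population's deposit grid.
#' @export
population_csd_contribution <- function(result, population) {
  g <- result$csd_by_population[[population]]
  if (is.null(g)) invalid_argument("unknown population")
  csd_pattern(g, result$depth_axis, result$t)
}

#' Input schedule with the feedback drive switched off at a given time
#'
#' @param network a `laminar_network` (used only for interface symmetry).
#' @param off_time time (ms) after which the LM drive is zeroed;
#'   `off_time >= duration` leaves the schedule unchanged, `off_time <=
#'   t_start` removes feedback input entirely.
#' @param duration,dt,t_start simulation window parameters (must match the
#'   subsequent [simulate_network()] call).
#' @return An input schedule for [simulate_network()].
#' @export
feedback_switch <- function(network, off_time, duration = 150, dt = 0.5,
                            t_start = -50) {
  if (off_time < t_start - 1e-9)
    invalid_argument("off_time lies before the simulation window")
  tt <- seq(t_start, duration, by = dt)
  inputs <- default_flash_inputs(tt)
  inputs$LM[tt > off_time] <- 0
  inputs
}
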