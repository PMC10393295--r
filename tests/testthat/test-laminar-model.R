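# Laminar rate network: construction, conservation, placement and weight
# manipulations, ablations, contributions, feedback switching.

model_grid_pattern <- function(sim) {
  interpolate_grid(crop_time(sim$csd_total, c(0, 100)), 30, 100)
}

sim_wd <- function(s1, s2) {
  a <- split_normalize(model_grid_pattern(s1))
  b <- split_normalize(model_grid_pattern(s2))
  wasserstein_2d(a$sink_mass, b$sink_mass) +
    wasserstein_2d(a$source_mass, b$source_mass)
}

peak_rates <- function(sim) apply(sim$rates, 1, max)

test_that("default builds satisfy the projection invariants", {
  for (preset in c("original", "intermediate", "final")) {
    net <- build_default_network(preset)
    expect_s3_class(net, "laminar_network")
    expect_true(all(net$projections$weight >= 0))
    expect_true(all(net$projections$target %in% net$populations$name))
  }
  # no feedback projections without the flag
  expect_false(any(build_default_network("original")$projections$source == "LM"))
  expect_true(any(build_default_network("final")$projections$source == "LM"))
  # final preset restricts excitatory synapses onto L6 E cells to 150 um
  fin <- build_default_network("final")$projections
  e_to_e6 <- fin[fin$target == "E6" & grepl("^E", fin$source), ]
  expect_true(all(e_to_e6$d_hi <= 150))
  org <- build_default_network("original")$projections
  expect_gt(max(org[org$target == "E6" & grepl("^E", org$source), "d_hi"]), 150)
})

test_that("zero input produces zero rates and zero CSD", {
  net <- build_default_network("original")
  tt <- seq(-50, 150, by = 0.5)
  off <- list(t = tt, LGN = rep(0, length(tt)), BKG = rep(0, length(tt)),
              LM = rep(0, length(tt)))
  sim <- simulate_network(net, inputs = off)
  expect_true(all(sim$rates == 0))
  expect_true(all(sim$csd_total$values == 0))
})

test_that("total CSD depth integral vanishes at every time step", {
  for (preset in c("original", "final")) {
    sim <- simulate_network(build_default_network(preset))
    col_tot <- colSums(sim$csd_total$values)
    scale <- max(colSums(abs(sim$csd_total$values)))
    expect_lt(max(abs(col_tot)) / scale, 1e-6)
  }
})

test_that("population contributions are additive and input-linear", {
  net <- build_default_network("final")
  sim <- simulate_network(net)
  tot <- Reduce(`+`, sim$csd_by_population)
  expect_equal(tot, sim$csd_total$values, tolerance = 1e-12)
  expect_error(population_csd_contribution(sim, "E99"),
               class = "lamcsd_invalid_argument")
  # a population with no incoming projections deposits nothing
  net0 <- net
  net0$projections <- net0$projections[net0$projections$target != "E23", ]
  sim0 <- simulate_network(net0)
  expect_true(all(sim0$csd_by_population$E23 == 0))
  # doubling the external input doubles the isolated pathway's deposits
  iso <- ablate(net, "recurrent")
  iso$projections <- iso$projections[iso$projections$source == "LGN", ]
  s1 <- simulate_network(iso)
  tt <- s1$t
  dbl <- default_flash_inputs(tt)
  dbl$LGN <- 2 * dbl$LGN
  s2 <- simulate_network(iso, inputs = dbl)
  expect_equal(s2$csd_by_source$LGN, 2 * s1$csd_by_source$LGN,
               tolerance = 1e-9)
})

test_that("a basal-only pulse deposits the hand-computed two-kernel dipole", {
  net <- build_default_network("original")
  keep <- net$projections$id == "LGN->E4"
  net$projections <- net$projections[keep, , drop = FALSE]
  net$projections$scheme <- "basal"
  tt <- seq(0, 10, by = 0.5)
  inp <- list(t = tt, LGN = rep(2, length(tt)), BKG = rep(0, length(tt)),
              LM = rep(0, length(tt)))
  sim <- simulate_network(net, inputs = inp, duration = 10, t_start = 0)
  geom <- lamcsd:::projection_geometry(net, net$projections[1, ])
  expected <- net$projections$weight[1] * 2 * (geom$soma - geom$place)
  expect_equal(sim$csd_by_population$E4[, 1], expected, tolerance = 1e-9)
  # with apical placement the sink (placement) / source (soma) dipole is
  # spatially resolved: deposits are negative around the placement kernel
  # and positive around the soma kernel
  net$projections$scheme <- "apical"
  sim_a <- simulate_network(net, inputs = inp, duration = 10, t_start = 0)
  geom_a <- lamcsd:::projection_geometry(net, net$projections[1, ])
  dep <- sim_a$csd_by_population$E4[, 1]
  expect_lt(sum(dep * geom_a$place), 0)
  expect_gt(sum(dep * geom_a$soma), 0)
})

test_that("set_placement changes kernels but not weights", {
  net <- build_default_network("final")
  net_b <- set_placement(net, "E4", "basal")
  expect_equal(net_b$projections$weight, net$projections$weight)
  sel <- net$projections$target == "E4" & net$projections$source == "LGN"
  expect_true(all(net_b$projections$scheme[sel] == "basal"))
  # basal -> basal is the identity
  net_bb <- set_placement(net_b, "E4", "basal")
  expect_identical(net_bb$projections, net_b$projections)
  # apical placement on an inhibitory target is rejected
  expect_error(set_placement(net, "I4", "apical"),
               class = "lamcsd_invalid_argument")
  # moving drive to the attenuated apical tuft lowers the target rate
  sim_b <- simulate_network(set_placement(net, "E4", "basal"))
  sim_a <- simulate_network(set_placement(net, "E4", "apical"))
  expect_lt(max(sim_a$rates["E4", ]), max(sim_b$rates["E4", ]))
})

test_that("weight scaling changes rates in the expected directions", {
  net <- build_default_network("final")
  sim <- simulate_network(net)
  # all factors 1 -> identical result
  sim_id <- simulate_network(scale_weights(net, 1, kind = "recurrent"))
  expect_identical(sim_id$rates, sim$rates)
  # E -> I down-scaling disinhibits excitatory populations
  net_ei <- scale_weights(net, 0.7, source = c("E23", "E4", "E5", "E6"),
                          target = c("I23", "I4", "I5", "I6"))
  sim_ei <- simulate_network(net_ei)
  expect_lt(max(sim_ei$rates["I4", ]), max(sim$rates["I4", ]))
  expect_gt(max(sim_ei$rates["E4", ]), max(sim$rates["E4", ]))
  # named factor map and validation
  net_named <- scale_weights(net, c("LGN->E4" = 2))
  expect_equal(net_named$projections$weight[net$projections$id == "LGN->E4"],
               2 * net$projections$weight[net$projections$id == "LGN->E4"])
  expect_error(scale_weights(net, 0), class = "lamcsd_invalid_argument")
  expect_error(scale_weights(net, c(nope = 2)),
               class = "lamcsd_invalid_argument")
})

test_that("ablations remove exactly the matching deposits", {
  net <- build_default_network("final")
  # recurrent ablation leaves only external-synapse deposits
  sim_ff <- simulate_network(ablate(net, "recurrent"))
  expect_setequal(names(sim_ff$csd_by_source),
                  intersect(c("LGN", "BKG", "LM"),
                            names(sim_ff$csd_by_source)))
  # inhibitory ablation removes every interneuron-sourced projection
  net_noi <- ablate(net, "inhibitory")
  expect_false(any(grepl("^I", net_noi$projections$source)))
  # feedback ablation removes the upper-layer feedback deposits
  sim_full <- simulate_network(net)
  sim_nofb <- simulate_network(ablate(net, "feedback"))
  expect_true("LM" %in% names(sim_full$csd_by_source))
  expect_false("LM" %in% names(sim_nofb$csd_by_source))
  expect_gt(max(abs(sim_full$csd_by_source$LM)), 0)
  # lgn ablation
  expect_false(any(ablate(net, "lgn")$projections$source == "LGN"))
})

test_that("feedback switching zeroes LM-attributed deposits after cutoff", {
  net <- build_default_network("final")
  inp <- feedback_switch(net, off_time = 60)
  sim <- simulate_network(net, inputs = inp)
  lm_dep <- sim$csd_by_source$LM
  after <- sim$t > 60.5
  expect_true(all(lm_dep[, after] == 0))
  expect_gt(max(abs(lm_dep[, !after])), 0)
  # off at the start is equivalent to ablating the feedback drive
  inp0 <- feedback_switch(net, off_time = -50)
  sim0 <- simulate_network(net, inputs = inp0)
  expect_equal(sim0$rates, simulate_network(ablate(net, "feedback"))$rates,
               tolerance = 1e-9)
  # off at/after the end changes nothing
  inp_end <- feedback_switch(net, off_time = 150)
  sim_end <- simulate_network(net, inputs = inp_end)
  expect_equal(sim_end$rates, simulate_network(net)$rates)
  expect_error(feedback_switch(net, off_time = -500),
               class = "lamcsd_invalid_argument")
})

test_that("LFP output equals the forward operator applied to total CSD", {
  sim <- simulate_network(build_default_network("original"))
  fwd <- build_forward(sim$depth_axis, context = "model")
  expect_equal(sim$lfp_total$values, fwd$F %*% sim$csd_total$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})
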