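# Model definition: sigmoid response, parameter structures, derivative
# functions, and their stated properties.

test_that("sigmoid response matches its closed form and boundary values", {
  gE <- sigmoid_spec(1.3, 4)
  expect_identical(sigmoid_response(0, gE), 0)
  # independent hand evaluation at x = theta: 1/2 - 1/(1 + e^{lambda*theta})
  expect_equal(sigmoid_response(4, gE), 0.5 - 1 / (1 + exp(1.3 * 4)),
               tolerance = 1e-12)
  expect_equal(sigmoid_response(4, gE), 0.49451, tolerance = 1e-5)
  # strictly increasing
  x <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(sigmoid_response(x, gE)) > 0))
  expect_error(sigmoid_response(Inf, gE), "finite")
  expect_error(sigmoid_spec(-1, 4), "slope")
})

test_that("response ceilings reproduce the published maxima", {
  expect_equal(round(response_ceiling(sigmoid_spec(1.3, 4)), 4), 0.9945)
  expect_equal(round(response_ceiling(sigmoid_spec(2, 3.7)), 4), 0.9994)
  expect_equal(response_ceiling(sigmoid_spec(5, 0)), 0.5)
  # ceiling equals the sigmoid evaluated far to the right
  for (par in list(c(1.3, 4), c(2, 3.7), c(0.7, 1.2))) {
    sg <- sigmoid_spec(par[1], par[2])
    expect_equal(response_ceiling(sg), sigmoid_response(1000, sg),
                 tolerance = 1e-9)
  }
})

test_that("default spec reproduces the published parameter table exactly", {
  sp <- cpg_spec()
  expect_identical(sp$n_segments, 8L)
  expect_identical(sp$segment$self_excitation, 16)
  expect_identical(sp$segment$i_to_e, -12)
  expect_identical(sp$segment$e_to_i, 15)
  expect_identical(sp$segment$i_to_i, -3)
  expect_identical(sp$chain$e_ascending, rep(20, 7))
  expect_identical(sp$chain$i_ascending, rep(-20, 7))
  expect_identical(sp$excitatory$time_constant, 0.5)
  expect_identical(sp$inhibitory$time_constant, 0.5)
  expect_identical(sp$excitatory$sigmoid$slope, 1.3)
  expect_identical(sp$excitatory$sigmoid$threshold, 4)
  expect_identical(sp$inhibitory$sigmoid$slope, 2)
  expect_identical(sp$inhibitory$sigmoid$threshold, 3.7)
  expect_error(cpg_spec(n_segments = 8, chain = chain_coupling(20, -20, 5)),
               "n_segments")
})

test_that("drive pulses superpose and vanish outside their window", {
  p <- drive_protocol(segment = 8, strength = 1.7, onset = 0, duration = 2)
  expect_identical(drive_value(p, 1, 8), 1.7)
  expect_identical(drive_value(p, 2.5, 8), 0)
  expect_identical(drive_value(p, 1, 7), 0)
  p2 <- drive_protocol(segment = c(8, 8), strength = c(1.7, 0.5),
                       onset = c(0, 0.5), duration = c(2, 2))
  expect_identical(drive_value(p2, 1, 8), 2.2)
  expect_error(drive_protocol(segment = 8, strength = -1, duration = 2),
               "strength")
})

test_that("rest state is an equilibrium of every model variant", {
  variants <- list(
    cpg_spec(),
    cpg_spec(sensory = sensory_spec(25, 20, 17)),
    cpg_spec(contralateral = contralateral_spec("EE", 2)),
    cpg_spec(sensory = sensory_spec(25, 20, 0),
             contralateral = contralateral_spec("IE", -5)))
  for (sp in variants) {
    d <- cpg_rhs(rest_state(sp), 0, sp)
    expect_identical(unname(d), rep(0, length(d)))
  }
})

test_that("derivative at rest under drive matches the hand-evaluated form", {
  sp <- cpg_spec()
  d <- cpg_rhs(rest_state(sp), 1, sp, forward_drive())
  # independent evaluation: dE8 = (kE / tauE) * G_E(1.7), everything else 0
  kE <- 1 - 1 / (1 + exp(1.3 * 4))
  GE17 <- 1 / (1 + exp(-1.3 * (1.7 - 4))) - 1 / (1 + exp(1.3 * 4))
  expect_equal(unname(d["E8"]), kE * GE17 / 0.5, tolerance = 1e-12)
  expect_equal(unname(d["E8"]), 0.084, tolerance = 1e-2)
  expect_identical(unname(d[setdiff(names(d), "E8")]), rep(0, 15))
})

test_that("the ceiling factor caps excitatory growth", {
  sp <- cpg_spec()
  kE <- sp$excitatory$ceiling
  st <- rest_state(sp)
  st[paste0("E", 1:8)] <- kE
  d <- cpg_rhs(st, 0, sp, forward_drive())
  expect_true(all(d[paste0("E", 1:8)] < 0))
  expect_equal(unname(d["E8"]), -kE / 0.5, tolerance = 1e-12)
})

test_that("sensory drive implements rectified neighbour differences", {
  sen <- sensory_spec(25, 20, 17)
  expect_identical(sensory_drive(rep(0.3, 8), sen), rep(0, 8))
  E <- c(rep(0, 7), 0.4)
  inp <- sensory_drive(E, sen)
  expect_identical(inp[7], 25 * 0.4)
  expect_identical(inp[8], 0)
  expect_identical(inp[1:6], rep(0, 6))
  # rectification: posterior neighbour more active gives no signal there
  E2 <- c(rep(0, 6), 0.2, 0.5)
  expect_identical(sensory_drive(E2, sen)[8], 0)
  # interior segments sum both neighbours
  E3 <- c(0, 0.5, 0, 0.4, 0, 0, 0, 0)
  expect_identical(sensory_drive(E3, sen)[3], 25 * (0.5 + 0.4))
})

test_that("zero sensory gains reduce exactly to the plain model", {
  sp0 <- cpg_spec()
  sps <- cpg_spec(sensory = sensory_spec(0, 0, 0))
  set.seed(7)
  for (i in 1:5) {
    st <- runif(16, 0, 0.9)
    sts <- c(st, runif(8, 0, 0.9))
    d0 <- cpg_rhs(st, 0.7, sp0, forward_drive())
    ds <- cpg_rhs(sts, 0.7, sps, forward_drive())
    expect_identical(unname(ds[1:16]), unname(d0))
  }
})

test_that("two-sided dynamics decouple at weight zero and swap symmetrically", {
  sp0 <- cpg_spec()
  sp2 <- cpg_spec(contralateral = contralateral_spec("EE", 0))
  proto1 <- forward_drive()
  proto2 <- drive_protocol(segment = c(8, 8), strength = c(1.7, 1.7),
                           duration = 2, side = c("left", "right"))
  set.seed(11)
  st <- runif(16, 0, 0.9)
  d1 <- cpg_rhs(st, 0.5, sp0, proto1)
  d2 <- cpg_rhs(c(st, st), 0.5, sp2, proto2)
  expect_identical(unname(d2[1:16]), unname(d1))
  expect_identical(unname(d2[17:32]), unname(d1))
  # left/right exchange symmetry for every coupling kind
  stL <- runif(16, 0, 0.9); stR <- runif(16, 0, 0.9)
  protoS <- drive_protocol(segment = c(8, 8), strength = c(1.5, 1.5),
                           duration = 2, side = c("left", "right"))
  for (kind in c("EE", "IE", "EI", "II")) {
    spk <- cpg_spec(contralateral = contralateral_spec(kind, -4))
    da <- cpg_rhs(c(stL, stR), 0.5, spk, protoS)
    db <- cpg_rhs(c(stR, stL), 0.5, spk, protoS)
    expect_identical(unname(da[1:16]), unname(db[17:32]))
    expect_identical(unname(da[17:32]), unname(db[1:16]))
  }
  expect_error(contralateral_spec("XX", 1))
})

test_that("compiled and reference derivatives agree on random states", {
  specs <- list(
    cpg_spec(),
    cpg_spec(sensory = sensory_spec(25, 20, 17)),
    cpg_spec(contralateral = contralateral_spec("IE", -5)),
    cpg_spec(n_segments = 5, chain = chain_coupling(18, -15, 5)))
  set.seed(3)
  for (sp in specs) {
    proto <- if (is_two_sided(sp))
      drive_protocol(segment = c(sp$n_segments, sp$n_segments),
                     strength = c(1.7, 1.72), duration = 5,
                     side = c("left", "right"))
    else drive_protocol(segment = sp$n_segments, strength = 1.7,
                        duration = 5)
    par <- crawlwave:::as_model_params(sp, proto)
    for (i in 1:10) {
      st <- runif(length(rest_state(sp)), -0.1, 1)
      t <- runif(1, 0, 8)
      expect_equal(unname(cpg_rhs(st, t, sp, proto)),
                   as.numeric(crawlwave:::cpp_rhs(st, t, par)),
                   tolerance = 1e-14)
    }
  }
})

test_that("state dimension mismatches are rejected", {
  sp <- cpg_spec()
  expect_error(cpg_rhs(rep(0, 10), 0, sp, forward_drive()), "dimension")
  expect_error(simulate_cpg(sp, forward_drive(), 5, initial_state = rep(0, 3)),
               "dimension")
})
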