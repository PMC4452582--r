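test_that("extinction is a fixed point and Monod growth is recovered in isolation", {
  p <- plankton_params()
  expect_equal(community_rhs(community_state()), setNames(rep(0, 8),
               c("H", "I", "P", "D", "A", "C", "R", "N")))
  # hosts alone with plentiful nitrate: pure Monod-limited growth
  y <- community_state(H = 1.48e5, N = 36)
  d <- community_rhs(y, p, community_mask(parasites = FALSE, diatoms = FALSE,
                                          nanophytoplankton = FALSE,
                                          microciliates = FALSE,
                                          rotifers = FALSE))
  expect_equal(d[["H"]], 0.7 * (36 / 38.3) * 1.48e5)
  expect_equal(d[["I"]], 0)
  expect_equal(d[["P"]], 0)
  expect_lt(d[["N"]], 0)
})

test_that("flux decomposition sums exactly to the right-hand side", {
  p <- plankton_params()
  for (y in random_states(25)) {
    fx <- decompose_fluxes(y, p)
    d <- community_rhs(y, p)
    sums <- vapply(split(fx$rate, fx$variable),
                   function(v) Reduce(`+`, v), numeric(1))
    expect_identical(sums[names(d)], d)
  }
})

test_that("right-hand side agrees with an independently coded reference", {
  p <- plankton_params()
  for (y in random_states(25, seed = 7)) {
    expect_equal(community_rhs(y, p), reference_rhs(y, p), tolerance = 1e-12)
  }
})

test_that("grazing partitions close and nitrate never increases", {
  p <- plankton_params()
  for (y in random_states(25, seed = 11)) {
    fx <- decompose_fluxes(y, p)
    rate <- function(v, tm) fx$rate[fx$variable == v & fx$term == tm]
    preyC <- y[["H"]] + y[["I"]] + y[["D"]]
    if (preyC > 0) {
      Gc <- ciliate_ingestion_rate(preyC, p)
      expect_equal(rate("H", "ciliate_grazing") + rate("I", "ciliate_grazing") +
                     rate("D", "ciliate_grazing"), -y[["C"]] * Gc)
    }
    preyR <- y[["A"]] + y[["P"]]
    if (preyR > 0) {
      Gr <- rotifer_ingestion_rate(preyR, params = p)
      expect_equal(rate("P", "rotifer_grazing") + rate("A", "rotifer_grazing"),
                   -y[["R"]] * Gr)
    }
    expect_lte(community_rhs(y, p)[["N"]], 0)
  }
})

test_that("zero pools yield zero source terms", {
  p <- plankton_params()
  # no dinospores: every dinospore loss pathway is silent
  fx <- decompose_fluxes(community_state(H = 1e5, I = 1e3, D = 1e4, A = 1e6,
                                         C = 1e3, R = 20, N = 10), p)
  pr <- fx[fx$variable == "P", ]
  for (tm in c("infection_attachment_loss", "natural_mortality",
               "rotifer_grazing")) {
    expect_equal(pr$rate[pr$term == tm], 0)
  }
  # no infected hosts: no dinospore release
  expect_equal(pr$rate[pr$term == "release_gain"], 1e3 * p$eps / p$h)
  fx0 <- decompose_fluxes(community_state(H = 1e5, P = 1e5, N = 10), p)
  expect_equal(fx0$rate[fx0$variable == "P" & fx0$term == "release_gain"], 0)
})

test_that("masked members and frozen variables have zero derivatives and cross terms", {
  p <- plankton_params()
  y <- community_state(H = 1e5, I = 1e3, P = 1e5, D = 1e4, A = 1e6,
                       C = 1e3, R = 20, N = 10)
  # masking grazers silences their growth and all their grazing terms
  d <- community_rhs(y, p, community_mask(microciliates = FALSE,
                                          rotifers = FALSE))
  expect_equal(d[["C"]], 0)
  expect_equal(d[["R"]], 0)
  fx <- decompose_fluxes(y, p, community_mask(microciliates = FALSE,
                                              rotifers = FALSE))
  expect_true(all(fx$rate[fx$term %in%
                            c("ciliate_grazing", "rotifer_grazing")] == 0))
  # freezing nitrate pins dN/dt at zero but leaves growth nutrient-limited
  dfz <- community_rhs(y, p, community_mask(frozen = "N"))
  expect_equal(dfz[["N"]], 0)
  expect_equal(dfz[["H"]], community_rhs(y, p)[["H"]])
})

test_that("the self-scaled nitrate variant charges each producer its own uptake", {
  p <- plankton_params()
  y <- community_state(H = 1e5, P = 1e3, D = 1e6, A = 1e8, N = 10)
  printed <- community_rhs(y, p)[["N"]]
  self_scaled <- community_rhs(y, p,
    options = model_options(nitrate_uptake = "self_scaled"))[["N"]]
  fh <- 10 / (p$K_h + 10); fd <- 10 / (p$K_d + 10); fa <- 10 / (p$K_a + 10)
  expect_equal(printed,
               -(1e5 * p$r_h * fh * p$Q_h + 1e5 * p$r_d * fd * p$Q_d +
                   1e5 * p$r_a * fa * p$Q_a))
  expect_equal(self_scaled,
               -(1e5 * p$r_h * fh * p$Q_h + 1e6 * p$r_d * fd * p$Q_d +
                   1e8 * p$r_a * fa * p$Q_a))
})

test_that("the printed rotifer-reproduction variant couples dR/dt to ciliates", {
  p <- plankton_params()
  y <- community_state(H = 1e5, I = 1e3, P = 1e5, D = 1e4, A = 1e7,
                       C = 5e3, R = 20, N = 10)
  rr <- rotifer_growth_rate(1e7 + 1e5, p)
  expect_equal(community_rhs(y, p)[["R"]], rr * 20)
  expect_equal(community_rhs(y, p,
    options = model_options(rotifer_reproduction = "printed_ciliate"))[["R"]],
    rr * 5e3)
})
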