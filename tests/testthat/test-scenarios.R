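test_that("published defaults are returned verbatim", {
  defs <- table1_defaults()
  p <- defs$params
  expect_equal(p$eps, 150)
  expect_equal(p$m, 0.26)
  expect_equal(p$a, 1.34e-8)
  expect_equal(p$h, 2.46)
  expect_equal(p$K_d, 1.2)
  expect_equal(p$G_cmax, 168)
  expect_equal(p$K_Gr, 1.59e8)
  init <- defs$initial
  expect_equal(init[["H"]], 1.48e5)
  expect_equal(init[["I"]], 3e3)
  expect_equal(init[["P"]], 1.16e5)
  expect_equal(init[["R"]], 20)
})

test_that("parameters round-trip through tidy serialization bit-exactly", {
  p <- plankton_params()
  tb <- tidy(p)
  back <- do.call(plankton_params, as.list(setNames(tb$value, tb$parameter)))
  expect_identical(unclass(back), unclass(p))
})

test_that("community-complexity scenarios nest as designed", {
  s1 <- build_scenario(1, "eutro")
  expect_false(any(s1$mask$members[c("diatoms", "nanophytoplankton",
                                     "microciliates", "rotifers")]))
  expect_equal(s1$initial[["N"]], 36)
  expect_equal(s1$initial[["D"]], 0)
  s2 <- build_scenario(2, "eutro")
  expect_true(all(s2$mask$members[c("microciliates", "rotifers")]))
  expect_equal(s2$initial[["A"]], 0)
  expect_equal(s2$initial[["C"]], 3.2e3)
  s3 <- build_scenario(3, "oligo")
  expect_true(all(s3$mask$members))
  expect_equal(s3$initial[["N"]], 1)
  expect_equal(s3$horizon, 30)
  expect_error(build_scenario(4, "eutro"), "level")
})

test_that("the nutrient x competitor grid has the designed cardinality and splits", {
  grid <- nutrient_competition_grid()
  expect_equal(nrow(grid), 96)
  one <- grid$spec[[which(grid$total == 1e6 & grid$nitrate == 5 &
                            grid$parasites)[1]]]
  expect_equal(one$initial[["A"]], 9.9e5)
  expect_equal(one$initial[["D"]], 1e4)
  expect_equal(one$initial[["H"]], 2.5e5)
  expect_equal(one$initial[["P"]], 1.25e5)
  expect_equal(one$initial[["I"]], 0)
  off <- grid$spec[[which(grid$total == 1e6 & grid$nitrate == 5 &
                            !grid$parasites)[1]]]
  expect_equal(off$initial[["P"]], 0)
  expect_false(off$mask$members[["parasites"]])
})

test_that("removal designs produce a baseline plus one exclusion per member", {
  des <- removal_designs(1e4)
  expect_equal(nrow(des), 7)
  expect_equal(des$removed[1], "none")
  no_par <- des$spec[[which(des$removed == "parasites")]]
  expect_equal(no_par$initial[["P"]], 0)
  expect_equal(no_par$initial[["I"]], 0)
  no_rot <- des$spec[[which(des$removed == "rotifers")]]
  expect_equal(no_rot$initial[["R"]], 0)
  expect_equal(no_rot$initial[["H"]], 2.5e5)
  expect_equal(no_rot$initial[["N"]], 36)
  expect_error(removal_designs(1e6), "1e4 or 1e8")
})

test_that("every generated scenario satisfies the mask/initial consistency invariant", {
  specs <- c(
    lapply(1:3, build_scenario, trophic = "oligo"),
    nutrient_competition_grid()$spec[1:10],
    removal_designs(1e8)$spec,
    list(grazing_assay_design(1e6, "24h"), grazing_assay_design(1e5, "30d"))
  )
  for (sp in specs) {
    active <- c(H = sp$mask$members[["dinoflagellates"]],
                I = sp$mask$members[["dinoflagellates"]] &&
                  sp$mask$members[["parasites"]],
                P = sp$mask$members[["parasites"]],
                D = sp$mask$members[["diatoms"]],
                A = sp$mask$members[["nanophytoplankton"]],
                C = sp$mask$members[["microciliates"]],
                R = sp$mask$members[["rotifers"]], N = TRUE)
    expect_true(all(sp$initial[!active] == 0), label = sp$label)
  }
})

test_that("grazing assay designs realize the host-free and embedded protocols", {
  a24 <- grazing_assay_design(1e7, "24h")
  expect_equal(a24$horizon, 1)
  expect_equal(a24$initial[["H"]], 0)
  expect_equal(a24$initial[["P"]], 1.25e5)
  expect_true(a24$mask$frozen[["A"]])
  # frozen alternative prey really does not grow
  sim <- simulate_community(a24)
  expect_equal(sim$trajectory$A, rep(1e7, nrow(sim$trajectory)))
  # rotifer growth below threshold at sparse prey, near max when saturated
  p <- plankton_params()
  expect_lt(rotifer_growth_rate(1e4 + 1.25e5, p), 0)
  expect_gt(rotifer_growth_rate(1e9 + 1.25e5, p), 0.99 * p$r_rmax)
  a30 <- grazing_assay_design(1e7, "30d")
  expect_equal(a30$initial[["D"]], 2.9e4)
  expect_equal(a30$horizon, 30)
  expect_equal(a30$initial[["N"]], 36)
})
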