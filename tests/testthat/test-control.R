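# control-coefficient computation: theorems, oracles, invariances

glyModel <- fixtureGlycolysis()
glyNet <- glyModel@network
glyExact <- exactElasticities(glyModel)

test_that("theorem suite holds for sampled elasticities on several topologies", {
  nets <- list(fixtureChain(2)@network, fixtureChain(3)@network,
               fixtureBranch()@network, glyNet)
  for (net in nets) {
    for (seed in 1:40) {
      s <- sampleElasticities(net, seed)
      C <- computeControlMatrix(net, s)
      rep <- checkTheorems(C, s, net)
      expect_true(all(rep$pass),
                  info = sprintf("seed %d: %s", seed,
                                 paste(rep$identity[!rep$pass], collapse = ",")))
      expect_lt(max(rep$max_residual), 1e-8)
    }
  }
})

test_that("matrix control coefficients match the finite-difference oracle", {
  for (model in list(fixtureChain(3), fixtureBranch(), glyModel)) {
    C <- computeControlMatrix(model@network, exactElasticities(model))
    Cfd <- controlCoefficientsFD(model)
    expect_lt(max(abs(C@flux - Cfd@flux) / pmax(abs(Cfd@flux), 1)), 1e-4)
    expect_lt(max(abs(C@conc - Cfd@conc) / pmax(abs(Cfd@conc), 1)), 1e-4)
  }
})

test_that("the two-enzyme chain reproduces the closed-form control split", {
  # supply step with product elasticity -e1, demand step with substrate
  # elasticity +e2 on the shared metabolite:
  # C^J_supply = e2/(e1+e2), C^J_demand = e1/(e1+e2)
  mets <- data.frame(id = "x")
  S <- matrix(c(1, -1), 1, 2, dimnames = list("x", c("sup", "dem")))
  rx <- data.frame(id = c("sup", "dem"), net_flux = 1, rho = 0,
                   boundary = c(TRUE, TRUE))
  net <- metabolicNetwork(mets, rx, S)
  for (pars in list(c(0.4, 0.7), c(0.9, 0.1), c(0.5, 0.5))) {
    e1 <- pars[1]; e2 <- pars[2]
    eps <- matrix(c(-e1, e2), 2, 1, dimnames = list(c("sup", "dem"), "x"))
    s <- new("ElasticitySample", forward = eps, reverse = eps * 0, net = eps,
             seed = NA_integer_, rhoUsed = rhoValues(net))
    C <- computeControlMatrix(net, s)
    expect_equal(unname(C@flux["sup", c("sup", "dem")]),
                 c(e2, e1) / (e1 + e2), tolerance = 1e-12)
    expect_equal(unname(C@conc["x", ]), c(1, -1) / (e1 + e2),
                 tolerance = 1e-12)
  }
})

test_that("conserved pairs satisfy the ratio-weighted row identity", {
  C <- computeControlMatrix(glyNet, glyExact)
  rel <- mcaBounds:::moietyRatios(glyNet, "NADPpool")
  r <- rel["NADP"] / rel["NADPH"]
  expect_lt(max(abs(r * C@conc["NADP", ] + C@conc["NADPH", ])), 1e-10)
})

test_that("scaled control coefficients are invariant to flux rescaling", {
  net2 <- glyNet
  net2@reactions$net_flux <- net2@reactions$net_flux * 37.5
  C1 <- computeControlMatrix(glyNet, glyExact)
  C2 <- computeControlMatrix(net2, glyExact)
  expect_equal(C2@flux, C1@flux, tolerance = 1e-12)
  expect_equal(C2@conc, C1@conc, tolerance = 1e-12)
})

test_that("a corrupted matrix is flagged by the theorem report", {
  C <- computeControlMatrix(glyNet, glyExact)
  C@flux[2, 3] <- C@flux[2, 3] + 0.1
  rep <- checkTheorems(C, glyExact, glyNet)
  expect_false(rep$pass[rep$identity == "flux_summation"])
})

test_that("magnitude filtering accepts and rejects around the bound", {
  C <- computeControlMatrix(glyNet, glyExact)
  C@maxAbs <- 3.4
  expect_true(filterByMagnitude(C, 3.5))
  C@maxAbs <- 3.6
  expect_false(filterByMagnitude(C, 3.5))
  expect_true(filterByMagnitude(C, Inf))
})

test_that("structurally singular systems raise a discardable error", {
  # two strictly parallel reactions between the same pools with identical
  # elasticities leave the system matrix rank deficient
  mets <- data.frame(id = "x")
  S <- matrix(c(1, 1, -2), 1, 3, dimnames = list("x", c("in1", "in2", "out")))
  rx <- data.frame(id = c("in1", "in2", "out"), net_flux = c(1, 1, 1), rho = 0,
                   boundary = TRUE)
  net <- metabolicNetwork(mets, rx, S)
  eps <- matrix(0, 3, 1, dimnames = list(c("in1", "in2", "out"), "x"))
  s <- new("ElasticitySample", forward = eps, reverse = eps, net = eps,
           seed = 99L, rhoUsed = rhoValues(net))
  expect_error(computeControlMatrix(net, s), "singular")
})

test_that("response coefficients follow the control-elasticity decomposition", {
  C <- computeControlMatrix(glyNet, glyExact)
  m <- nReactions(glyNet)
  # unit parameter elasticity on one activity picks out that column
  r <- responseCoefficients(C, c(PFK = 1))
  expect_equal(unname(r$flux), unname(C@flux[, "PFK"]))
  expect_equal(unname(r$conc), unname(C@conc[, "PFK"]))
  # uniform activity scaling moves all fluxes equally, no concentration moves
  rAll <- responseCoefficients(C, setNames(rep(1, m), reactionIds(glyNet)))
  expect_equal(unname(rAll$flux), rep(1, m), tolerance = 1e-10)
  expect_equal(unname(rAll$conc), rep(0, nMetabolites(glyNet)),
               tolerance = 1e-10)
  # zero vector gives zeros
  r0 <- responseCoefficients(C, c(PFK = 0))
  expect_true(all(r0$flux == 0) && all(r0$conc == 0))
  expect_error(responseCoefficients(C, c(nope = 1)), "unknown reaction")
})

test_that("linearized predictions converge at first order", {
  C <- computeControlMatrix(glyNet, glyExact)
  errAt <- function(h) {
    fac <- setNames(2^h, "PFK")
    sim <- simulateAdaptation(glyModel, fac,
                              noise = list(cv_flux = 0, cv_conc = 0), seed = 1)
    pred <- linearizedPrediction(C, c(PFK = h))
    max(abs(pred$flux - sim$dlog$flux), abs(pred$conc - sim$dlog$conc))
  }
  e1 <- errAt(0.2); e2 <- errAt(0.1)
  expect_lt(e2, e1)               # error shrinks with the perturbation
  expect_lt(abs(e2 / e1 - 0.25), 0.2 * 0.25 + 0.05)  # roughly quadratically
  expect_lt(errAt(0.01), 1e-3)
})

test_that("control matrices round-trip through CSV", {
  C <- computeControlMatrix(glyNet, glyExact)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeControlMatrix(C, f1, f2)
  C2 <- readControlMatrix(f1, f2)
  expect_equal(C2@conc, C@conc)
  expect_equal(C2@flux, C@flux)
})
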