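# elasticity sampling: thermodynamic transform, saturation bounds, linkage,
# competitive pairs, modifiers, determinism

test_that("forward/reverse split follows the disequilibrium ratio", {
  expect_equal(forwardReverseSplit(1, 0.9), c(vf = 10, vr = 9))
  expect_equal(forwardReverseSplit(1, 0), c(vf = 1, vr = 0))
  expect_equal(forwardReverseSplit(2, 0.5), c(vf = 4, vr = 2))
  r <- forwardReverseSplit(1.7, 0.35)
  expect_equal(unname(r["vf"] - r["vr"]), 1.7)
  expect_error(forwardReverseSplit(1, 1), "rho")
  expect_error(forwardReverseSplit(1, -0.1), "rho")
})

test_that("net elasticity adds the thermodynamic term to the sampled part", {
  expect_equal(netElasticityFromForward(0.4, 0, "substrate"), 0.4)
  expect_equal(netElasticityFromForward(0.5, 0.9, "substrate"), 9.5)
  expect_equal(netElasticityFromForward(-0.5, 0.9, "product"), -9.5)
  expect_error(netElasticityFromForward(0.5, 1, "substrate"), "indeterminate")
  expect_error(netElasticityFromForward(-0.5, 0.3, "substrate"), "positive")
  # |net| grows monotonically toward equilibrium
  rhos <- seq(0, 0.99, by = 0.01)
  sub <- netElasticityFromForward(0.5, rhos[1], "substrate")
  for (r in rhos[-1]) {
    nxt <- netElasticityFromForward(0.5, r, "substrate")
    expect_gt(nxt, sub); sub <- nxt
  }
})

test_that("samples respect bounds, linkage and keep product effects at rho = 0", {
  net <- fixtureGlycolysis()@network
  S <- stoichMatrix(net)
  rho <- unname(rhoValues(net))
  for (seed in 1:25) {
    s <- sampleElasticities(net, seed)
    for (j in seq_len(nReactions(net))) {
      rid <- reactionIds(net)[j]
      for (m in metaboliteIds(net)) {
        co <- S[m, j]
        if (co == 0) next
        h <- mcaBounds:::elasticityBound(net, rid, m)
        if (co < 0) {
          expect_gt(s@forward[j, m], 0); expect_lt(s@forward[j, m], h)
          expect_equal(s@forward[j, m] - s@reverse[j, m], 1)
          expect_equal(s@net[j, m],
                       rho[j] / (1 - rho[j]) + s@forward[j, m])
        } else {
          expect_lt(s@forward[j, m], 0); expect_gt(s@forward[j, m], -h)
          expect_equal(s@forward[j, m] - s@reverse[j, m], -1)
          expect_equal(s@net[j, m],
                       -rho[j] / (1 - rho[j]) + s@forward[j, m])
          # product elasticity nonzero even for irreversible reactions
          if (rho[j] == 0) expect_lt(s@net[j, m], 0)
        }
      }
    }
  }
})

test_that("the Hill bound widens the PFK substrate elasticity range", {
  net <- fixtureGlycolysis()@network
  hit <- FALSE
  for (seed in 1:300) {
    s <- sampleElasticities(net, seed)
    expect_lt(s@forward["PFK", "F6P"], 2)
    if (s@forward["PFK", "F6P"] > 1) hit <- TRUE
  }
  expect_true(hit)  # the (1, 2) part of the range is actually used
})

test_that("competitive pairs keep the elasticity sum in (0, 1) at any rho", {
  mets <- data.frame(id = c("S", "P"))
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("S", "P"), c("Rin", "Rx", "Rout")))
  for (rho in c(0, 0.3, 0.9)) {
    rx <- data.frame(id = c("Rin", "Rx", "Rout"), net_flux = 1,
                     rho = c(0, rho, 0), boundary = c(TRUE, FALSE, TRUE))
    net <- metabolicNetwork(mets, rx, S,
      competitive = data.frame(reaction = "Rx", substrate = "S", product = "P"))
    for (seed in 1:400) {
      s <- sampleElasticities(net, seed)
      sumNet <- s@net["Rx", "S"] + s@net["Rx", "P"]
      sumFwd <- s@forward["Rx", "S"] + s@forward["Rx", "P"]
      expect_gt(sumNet, 0); expect_lt(sumNet, 1)
      # thermodynamic terms cancel: net sum equals forward sum exactly
      expect_equal(sumNet, sumFwd, tolerance = 1e-12)
    }
  }
})

test_that("modifier elasticities are bounded and add to reactant terms", {
  mets <- data.frame(id = c("x1", "x2"))
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("x1", "x2"), c("R1", "R2", "R3")))
  rx <- data.frame(id = c("R1", "R2", "R3"), net_flux = 1, rho = 0,
                   boundary = c(TRUE, FALSE, TRUE))
  net <- metabolicNetwork(mets, rx, S,
    modifiers = data.frame(reaction = c("R3", "R2"),
                           metabolite = c("x1", "x2"),
                           role = c("activator", "inhibitor")))
  for (seed in 1:50) {
    s <- sampleElasticities(net, seed)
    expect_gt(s@net["R3", "x1"], 0); expect_lt(s@net["R3", "x1"], 1)
    # x2 is both product of R2 (negative) and inhibitor of R2 (negative):
    # contributions add
    expect_lt(s@net["R2", "x2"], s@forward["R2", "x2"])
  }
})

test_that("sampling is reproducible and reaction substreams are stable", {
  net <- fixtureGlycolysis()@network
  s1 <- sampleElasticities(net, 123)
  s2 <- sampleElasticities(net, 123)
  expect_identical(s1@net, s2@net)
  expect_false(identical(sampleElasticities(net, 124)@net, s1@net))

  # dropping a reaction does not perturb the others' draws
  sub <- net
  keep <- setdiff(reactionIds(net), "NADPase")
  sub@reactions <- net@reactions[net@reactions$id %in% keep, ]
  sub@stoich <- net@stoich[, keep]
  s3 <- sampleElasticities(sub, 123)
  expect_equal(s3@forward[keep, ], s1@forward[keep, ])
})

test_that("elasticity samples round-trip through CSV", {
  net <- fixtureGlycolysis()@network
  s <- sampleElasticities(net, 7)
  f <- withr::local_tempfile(fileext = ".csv")
  writeElasticities(s, f)
  s2 <- readElasticities(f, net)
  expect_equal(s2@forward, s@forward)
  expect_equal(s2@net, s@net)
})
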