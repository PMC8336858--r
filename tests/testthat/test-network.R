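# network model, validation and JSON round trip

chainJSON <- function(path, fluxes = c(1, 1, 1)) {
  doc <- list(
    metabolites = list(list(id = "x1"), list(id = "x2")),
    reactions = list(
      list(id = "R1", stoichiometry = list(x1 = 1), net_flux = fluxes[1],
           boundary = TRUE),
      list(id = "R2", stoichiometry = list(x1 = -1, x2 = 1), net_flux = fluxes[2]),
      list(id = "R3", stoichiometry = list(x2 = -1), net_flux = fluxes[3],
           boundary = TRUE)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

test_that("a balanced open chain loads with N.J = 0", {
  f <- withr::local_tempfile(fileext = ".json")
  net <- loadNetwork(chainJSON(f))
  expect_s4_class(net, "MetabolicNetwork")
  expect_equal(nMetabolites(net), 2)
  expect_equal(nReactions(net), 3)
  expect_equal(max(abs(stoichMatrix(net) %*% netFluxes(net))), 0)
})

test_that("an unbalanced chain is rejected naming the offending metabolite", {
  f <- withr::local_tempfile(fileext = ".json")
  expect_error(loadNetwork(chainJSON(f, fluxes = c(1, 2, 1))),
               "steady-state violation.*x1")
})

test_that("schema violations are reported with the offending field", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list(list(id = "a"))), f,
                       auto_unbox = TRUE)
  expect_error(loadNetwork(f), "missing top-level field 'reactions'")
  doc <- list(metabolites = list(list(id = "a")),
              reactions = list(list(id = "R1", stoichiometry = list(b = -1),
                                    net_flux = 1)))
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(loadNetwork(f), "unknown metabolite b")
})

test_that("invalid thermodynamics and zero internal fluxes are rejected", {
  mets <- data.frame(id = c("x1"))
  S <- matrix(c(1, -1), 1, 2, dimnames = list("x1", c("R1", "R2")))
  rx <- data.frame(id = c("R1", "R2"), net_flux = c(1, 1), rho = c(0, 1))
  expect_error(metabolicNetwork(mets, rx, S), "rho < 1")
  rx2 <- data.frame(id = c("R1", "R2"), net_flux = c(0, 0), rho = 0)
  expect_error(metabolicNetwork(mets, rx2, S), "zero net flux")
  # zero flux allowed on boundary reactions
  rx3 <- data.frame(id = c("R1", "R2"), net_flux = c(0, 0), rho = 0,
                    boundary = TRUE)
  expect_s4_class(metabolicNetwork(mets, rx3, S), "MetabolicNetwork")
})

test_that("negative net fluxes are flipped to the positive orientation", {
  mets <- data.frame(id = c("x1"))
  S <- matrix(c(1, -1), 1, 2, dimnames = list("x1", c("R1", "R2")))
  rx <- data.frame(id = c("R1", "R2"), net_flux = c(-1, -1), rho = 0)
  net <- metabolicNetwork(mets, rx, S)
  expect_true(all(netFluxes(net) > 0))
  expect_equal(unname(stoichMatrix(net)["x1", ]), c(-1, 1))
})

test_that("undeclared conservations fail the rank check; declared ones pass", {
  mets <- data.frame(id = c("A", "B"))
  S <- matrix(c(-1, 1, 1, -1), 2, 2, dimnames = list(c("A", "B"), c("R1", "R2")))
  rx <- data.frame(id = c("R1", "R2"), net_flux = c(1, 1), rho = 0)
  expect_error(metabolicNetwork(mets, rx, S), "rank deficiency")
  mets2 <- data.frame(id = c("A", "B"), moiety_group = "pool")
  net <- metabolicNetwork(mets2, rx, S,
    moieties = list(list(id = "pool", members = c("A", "B"),
                         ratios = list("A/B" = 4))))
  expect_equal(unname(mcaBounds:::moietyRatios(net, "pool")["A"]), 4)
})

test_that("moiety ratio graphs must connect all members", {
  mets <- data.frame(id = c("A", "B", "C"), moiety_group = "pool")
  S <- matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("R1", "R2", "R3")))
  rx <- data.frame(id = c("R1", "R2", "R3"), net_flux = 1, rho = 0)
  expect_error(
    metabolicNetwork(mets, rx, S,
      moieties = list(list(id = "pool", members = c("A", "B", "C"),
                           ratios = list("A/B" = 2)))),
    "does not connect")
  net <- metabolicNetwork(mets, rx, S,
    moieties = list(list(id = "pool", members = c("A", "B", "C"),
                         ratios = list("A/B" = 2, "B/C" = 3))))
  rel <- mcaBounds:::moietyRatios(net, "pool")
  expect_equal(unname(rel[c("A", "B", "C")]), c(6, 3, 1))
})

test_that("competitive pairs must pair a substrate with a product", {
  mets <- data.frame(id = c("x1", "x2"))
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("x1", "x2"), c("R1", "R2", "R3")))
  rx <- data.frame(id = c("R1", "R2", "R3"), net_flux = 1, rho = 0,
                   boundary = c(TRUE, FALSE, TRUE))
  expect_error(
    metabolicNetwork(mets, rx, S,
      competitive = data.frame(reaction = "R2", substrate = "x2", product = "x1")),
    "not a substrate")
  net <- metabolicNetwork(mets, rx, S,
    competitive = data.frame(reaction = "R2", substrate = "x1", product = "x2"))
  expect_equal(nrow(net@competitive), 1)
})

test_that("network JSON round-trips losslessly", {
  net <- fixtureGlycolysis()@network
  f <- withr::local_tempfile(fileext = ".json")
  writeNetwork(net, f)
  net2 <- loadNetwork(f)
  expect_equal(netFluxes(net2), netFluxes(net))
  expect_equal(rhoValues(net2), rhoValues(net))
  expect_equal(stoichMatrix(net2), stoichMatrix(net))
  expect_equal(length(net2@moieties), length(net@moieties))
  expect_equal(net2@elasticityUpper$h, net@elasticityUpper$h)
})
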