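# LP bound contraction: problem assembly, projections vs the vertex oracle,
# soundness properties, signs and gains

glyModel <- fixtureGlycolysis()
glyNet <- glyModel@network
glyC <- computeControlMatrix(glyNet, exactElasticities(glyModel))

test_that("the equality system has n + m + c rows and n + 2m variables", {
  dom <- buildInitialDomains(glyNet)
  p <- buildProblem(glyC, dom)                      # n = 5, m = 6
  expect_equal(dim(p@A), c(11, 17))
  expect_equal(p@nCouplingRows, 0L)
  p2 <- buildProblem(glyC, dom, couplings = list(c("HK", "GPI"),
                                                 c("PFK", "ALD", "G6PD", "NADPase")))
  expect_equal(nrow(p2@A), 11 + 1 + 3)
  expect_error(buildProblem(glyC, dom, couplings = list(c("HK", "nope"))),
               "unknown reaction")
})

test_that("the assembled rows encode the control-coefficient equalities", {
  dom <- buildInitialDomains(glyNet)
  p <- buildProblem(glyC, dom)
  v <- rnorm(6)
  z <- c(as.numeric(glyC@conc %*% v), as.numeric(glyC@flux %*% v), v)
  expect_lt(max(abs(p@A %*% z)), 1e-12)
})

test_that("an all-enclosure problem is feasible; contradictions are not", {
  dom <- buildInitialDomains(glyNet)
  expect_true(checkFeasible(buildProblem(glyC, dom)))

  # one-reaction toy where C^J = 1 forces dlogJ = dlogv: flux in [1, 2]
  # with activity pinned to 0 is infeasible
  mets <- data.frame(id = character(0))
  S <- matrix(0, 0, 1, dimnames = list(NULL, "R1"))
  rx <- data.frame(id = "R1", net_flux = 1, rho = 0, boundary = TRUE)
  toy <- metabolicNetwork(mets, rx, S)
  Ct <- new("ControlMatrix", conc = matrix(0, 0, 1, dimnames = list(NULL, "R1")),
            flux = matrix(1, 1, 1, dimnames = list("R1", "R1")),
            provenance = "manual", maxAbs = 1)
  ent <- data.frame(kind = c("flux", "act"), id = "R1",
                    lb = c(1, 0), ub = c(2, 0), restricted = TRUE)
  domT <- mcaBounds:::newDomainTable(ent, 3, 0)
  pT <- buildProblem(Ct, domT)
  expect_false(checkFeasible(pT))
  resT <- contractBounds(pT)
  expect_false(resT@feasible)
  expect_equal(resT@lpCount, 0L)
  expect_equal(nrow(contractionTable(resT)), 0)
})

test_that("contraction executes 2n + 4m LPs and stays inside initial domains", {
  dom <- buildInitialDomains(glyNet)
  res <- contractBounds(buildProblem(glyC, dom))
  expect_equal(res@lpCount, 2 * 5 + 4 * 6)          # 34
  tab <- contractionTable(res)
  expect_true(all(tab$lb_final >= tab$lb_init - 1e-9))
  expect_true(all(tab$ub_final <= tab$ub_init + 1e-9))
})

test_that("final domains equal the vertex-enumeration projection", {
  withr::local_seed(2024)
  for (model in list(fixtureChain(1), fixtureChain(2))) {
    net <- model@network
    C <- computeControlMatrix(net, exactElasticities(model))
    for (rep in 1:30) {
      dom <- randomDomains(net)
      p <- buildProblem(C, dom)
      vm <- vertexMinMax(p@A, rep(0, nrow(p@A)), p@lb, p@ub)
      res <- contractBounds(p)
      if (is.null(vm)) {
        expect_false(res@feasible)
      } else {
        expect_true(res@feasible)
        tab <- contractionTable(res)
        expect_lt(max(abs(tab$lb_final - vm$lo)), 1e-6)
        expect_lt(max(abs(tab$ub_final - vm$hi)), 1e-6)
      }
    }
  }
})

test_that("contraction agrees with the reference simplex backend", {
  withr::local_seed(7)
  net <- fixtureBranch()@network
  C <- computeControlMatrix(net, sampleElasticities(net, 5))
  dom <- randomDomains(net)
  p <- buildProblem(C, dom)
  res <- contractBounds(p)
  skip_if_not_installed("boot")
  if (res@feasible) {
    tab <- contractionTable(res)
    for (j in sample(ncol(p@A), 4)) {
      cc <- replace(numeric(ncol(p@A)), j, 1)
      up <- bootLP(p@A, rep(0, nrow(p@A)), p@lb, p@ub, cc, maximize = TRUE)
      dn <- bootLP(p@A, rep(0, nrow(p@A)), p@lb, p@ub, cc, maximize = FALSE)
      if (!is.null(up)) expect_equal(tab$ub_final[j], up$value, tolerance = 1e-6)
      if (!is.null(dn)) expect_equal(tab$lb_final[j], dn$value, tolerance = 1e-6)
    }
  }
})

test_that("contraction is idempotent and monotone in the initial domains", {
  dom <- buildInitialDomains(glyNet,
    data.frame(kind = "flux", id = "HK", before = 1, after_lo = 1.8,
               after_hi = 2.6))
  p1 <- buildProblem(glyC, dom)
  r1 <- contractionTable(contractBounds(p1))

  # idempotence: contracting the final domains reproduces them
  ent <- domainEntries(dom)
  ent$lb <- r1$lb_final; ent$ub <- r1$ub_final
  dom2 <- mcaBounds:::newDomainTable(ent, dom@enclosure, dom@sigma)
  r2 <- contractionTable(contractBounds(buildProblem(glyC, dom2)))
  expect_equal(r2$lb_final, r1$lb_final, tolerance = 1e-7)
  expect_equal(r2$ub_final, r1$ub_final, tolerance = 1e-7)

  # monotonicity: tightening an initial domain never widens any final domain
  ent3 <- domainEntries(dom)
  k <- which(ent3$kind == "act" & ent3$id == "GPI")
  ent3$lb[k] <- -1; ent3$ub[k] <- 1
  dom3 <- mcaBounds:::newDomainTable(ent3, dom@enclosure, dom@sigma)
  r3 <- contractionTable(contractBounds(buildProblem(glyC, dom3)))
  expect_true(all(r3$lb_final >= r1$lb_final - 1e-9))
  expect_true(all(r3$ub_final <= r1$ub_final + 1e-9))
})

test_that("coupled activities share one final domain, with or without dedupe", {
  dom <- buildInitialDomains(glyNet,
    data.frame(kind = "flux", id = "HK", before = 1, after_lo = 1.8,
               after_hi = 2.6))
  p <- buildProblem(glyC, dom, couplings = list(c("GPI", "PFK")))
  rFull <- contractBounds(p)
  rDed <- contractBounds(p, dedupe = TRUE)
  tF <- contractionTable(rFull); tD <- contractionTable(rDed)
  iG <- which(tF$kind == "act" & tF$id == "GPI")
  iP <- which(tF$kind == "act" & tF$id == "PFK")
  expect_equal(tF$lb_final[iG], tF$lb_final[iP], tolerance = 1e-9)
  expect_equal(tF$ub_final[iG], tF$ub_final[iP], tolerance = 1e-9)
  expect_equal(tD$lb_final, tF$lb_final, tolerance = 1e-7)
  expect_equal(tD$ub_final, tF$ub_final, tolerance = 1e-7)
  expect_equal(rFull@lpCount, 34L)      # redundant LPs still executed
  expect_lt(rDed@lpCount, 34L)
})

test_that("variables pinned by their initial domain keep a zero gain", {
  ent <- domainEntries(buildInitialDomains(glyNet))
  k <- which(ent$kind == "act" & ent$id == "NADPase")
  ent$lb[k] <- 0.5; ent$ub[k] <- 0.5
  dom <- mcaBounds:::newDomainTable(ent, 3, 0)
  tab <- contractionTable(contractBounds(buildProblem(glyC, dom)))
  expect_equal(tab$lb_final[k], 0.5)
  expect_equal(tab$ub_final[k], 0.5)
  expect_equal(tab$gain_pct[k], 0)
})

test_that("sign classification and percent gain follow their definitions", {
  expect_equal(classifySign(0.2, 1.5), "positive")
  expect_equal(classifySign(-2, -0.1), "negative")
  expect_equal(classifySign(-0.5, 0.3), "none")
  expect_equal(classifySign(0, 1), "none")          # zero bound: no fixed sign
  expect_equal(classifySign(c(1e-7, 2e-6), c(1, 1)), c("none", "positive"))
  expect_equal(percentageGain(-3, 3, -1, 2), 50)
  expect_equal(percentageGain(-3, 3, -3, 3), 0)
  expect_equal(percentageGain(-3, 3, 1, 1), 100)
})

test_that("contraction results round-trip through TSV", {
  res <- contractBounds(buildProblem(glyC, buildInitialDomains(glyNet)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeContraction(res, f)
  res2 <- readContraction(f)
  expect_equal(contractionTable(res2), contractionTable(res))
})
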