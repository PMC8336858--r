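# Kinetic fixture models: small networks with explicit rate laws, used to
# produce steady states, exact elasticities, ground-truth control
# coefficients and simulated "measured" adaptations for end-to-end checks of
# the sampling-based pipeline.

# ---- rate laws -------------------------------------------------------------

# v(x) and the forward/reverse decomposition for one reaction.
# law$type: "mass_action" (kf, kr), "michaelis_menten" (Vf, Vr, Km named per
# reactant), "hill" (V, K, h, single substrate). Stoichiometric coefficients
# give the mass-action orders.
rateSplit <- function(law, stoichCol, x) {
  subs <- names(stoichCol)[stoichCol < 0]
  prods <- names(stoichCol)[stoichCol > 0]
  if (law$type == "mass_action") {
    vf <- law$kf * prod(x[subs]^abs(stoichCol[subs]))
    vr <- (law$kr %||% 0) * prod(x[prods]^stoichCol[prods])
  } else if (law$type == "michaelis_menten") {
    # only species with a Km bind the enzyme; others (e.g. external products
    # of an irreversible step) do not enter the law
    subs <- intersect(subs, names(law$Km))
    prods <- intersect(prods, names(law$Km))
    s <- x[subs] / law$Km[subs]
    p <- if (length(prods)) x[prods] / law$Km[prods] else numeric(0)
    D <- prod(1 + s) + prod(1 + p) - 1
    vf <- law$Vf * prod(s) / D
    vr <- (law$Vr %||% 0) * prod(p) / D
  } else if (law$type == "hill") {
    S <- x[subs[1]]
    vf <- law$V * S^law$h / (law$K^law$h + S^law$h)
    vr <- 0
  } else stopf("unknown rate law type '%s'", law$type)
  c(vf = unname(vf), vr = unname(vr))
}

rateValue <- function(law, stoichCol, x) {
  fr <- rateSplit(law, stoichCol, x)
  fr[["vf"]] - fr[["vr"]]
}

# analytic scaled elasticities of vf, vr and v w.r.t. one metabolite
rateElasticity <- function(law, stoichCol, x, met) {
  coef <- stoichCol[met]
  fr <- rateSplit(law, stoichCol, x)
  vf <- fr[["vf"]]; vr <- fr[["vr"]]; v <- vf - vr
  subs <- names(stoichCol)[stoichCol < 0]
  prods <- names(stoichCol)[stoichCol > 0]
  ef <- er <- 0
  if (law$type == "mass_action") {
    if (coef < 0) ef <- abs(coef) else er <- coef
  } else if (law$type == "michaelis_menten") {
    subs <- intersect(subs, names(law$Km))
    prods <- intersect(prods, names(law$Km))
    if (!(met %in% c(subs, prods)))
      return(c(forward = 0, reverse = 0, net = 0))
    s <- x[subs] / law$Km[subs]
    p <- if (length(prods)) x[prods] / law$Km[prods] else numeric(0)
    D <- prod(1 + s) + prod(1 + p) - 1
    if (coef < 0) {
      share <- (s[met] / (1 + s[met])) * prod(1 + s) / D
      ef <- 1 - share; er <- -share
    } else {
      share <- (p[met] / (1 + p[met])) * prod(1 + p) / D
      ef <- -share; er <- 1 - share
    }
  } else if (law$type == "hill") {
    if (coef < 0) {
      S <- x[met]
      ef <- law$h * law$K^law$h / (law$K^law$h + S^law$h)
    }
  }
  en <- if (v != 0) (vf * ef - vr * er) / v else NA_real_
  c(forward = unname(ef), reverse = unname(er), net = unname(en))
}

# ---- steady-state solving --------------------------------------------------

# Damped Newton in log-concentration space on the reduced (independent
# metabolite) balances, with an ODE-integration fallback for poor starts.
solveSteadyStateCore <- function(stoichInt, laws, moieties, totals, externals,
                                 x0, activity = NULL, tol = 1e-11,
                                 maxit = 200) {
  mets <- rownames(stoichInt); rxns <- colnames(stoichInt)
  if (is.null(activity)) activity <- setNames(rep(1, length(rxns)), rxns)
  dep <- vapply(moieties, function(g) g$members[length(g$members)], "")
  indep <- setdiff(mets, dep)

  fullX <- function(xi) {
    x <- c(xi, externals)
    for (g in moieties) {
      d <- g$members[length(g$members)]
      x[d] <- totals[g$id] - sum(xi[setdiff(g$members, d)])
    }
    x
  }
  # stoichiometry including external species, for rate-law evaluation only
  stoichAll <- rbind(stoichInt,
                     matrix(0, length(externals), length(rxns),
                            dimnames = list(names(externals), rxns)))
  for (r in rxns) {
    ext <- laws[[r]]$external_stoich %||% numeric(0)
    if (length(ext)) stoichAll[names(ext), r] <- ext
  }
  rates <- function(x) {
    vapply(rxns, function(r) {
      col <- setNames(stoichAll[, r], rownames(stoichAll))
      activity[[r]] * rateValue(laws[[r]], col[col != 0], x)
    }, 0)
  }
  Sred <- stoichInt[indep, , drop = FALSE]
  resid <- function(z) {
    xi <- setNames(exp(z), indep)
    x <- fullX(xi)
    if (anyNA(x) || !all(is.finite(x)) || any(x <= 0))
      return(rep(NA_real_, length(indep)))
    as.numeric(Sred %*% rates(x))
  }

  z <- log(pmax(x0[indep], 1e-9))
  newton <- function(z, maxit) {
    for (it in seq_len(maxit)) {
      f0 <- resid(z)
      if (anyNA(f0)) return(list(z = z, ok = FALSE))
      vscale <- max(abs(rates(fullX(setNames(exp(z), indep)))), 1e-12)
      if (max(abs(f0)) < tol * vscale) return(list(z = z, ok = TRUE))
      h <- 1e-6
      Jm <- vapply(seq_along(z), function(j) {
        zp <- z; zp[j] <- zp[j] + h
        zm <- z; zm[j] <- zm[j] - h
        (resid(zp) - resid(zm)) / (2 * h)
      }, numeric(length(z)))
      Jm <- matrix(Jm, nrow = length(z))
      step <- tryCatch(-solve(Jm, f0), error = function(e) NULL)
      if (is.null(step) || anyNA(step)) return(list(z = z, ok = FALSE))
      lam <- 1; improved <- FALSE
      for (half in 1:40) {
        zn <- z + lam * step
        fn <- resid(zn)
        if (!anyNA(fn) && sum(fn^2) < sum(f0^2)) { z <- zn; improved <- TRUE; break }
        lam <- lam / 2
      }
      if (!improved) return(list(z = z, ok = FALSE))
    }
    list(z = z, ok = FALSE)
  }

  out <- newton(z, maxit)
  if (!out$ok) {
    # integrate toward the attractor, then retry Newton
    deriv <- function(t, xx, parms) {
      xi <- setNames(pmax(xx, 1e-12), indep)
      x <- fullX(xi)
      if (anyNA(x) || any(!is.finite(x))) return(list(rep(0, length(indep))))
      x <- pmax(x, 1e-12)
      list(as.numeric(Sred %*% rates(x)))
    }
    traj <- tryCatch(deSolve::lsoda(y = setNames(exp(out$z), indep),
                                    times = c(0, 10, 100, 1000), func = deriv,
                                    parms = NULL, rtol = 1e-8, atol = 1e-10),
                     error = function(e) NULL)
    if (!is.null(traj)) {
      end <- as.numeric(traj[nrow(traj), -1])
      if (all(is.finite(end)) && all(end > 0)) {
        out2 <- newton(log(end), maxit)
        if (out2$ok) out <- out2
      }
    }
    if (!out$ok)
      stopf("steady-state solver did not converge (final residual %.3g); try another initial condition",
            max(abs(resid(out$z)), na.rm = TRUE))
  }
  xi <- setNames(exp(out$z), indep)
  x <- fullX(xi)
  v <- rates(x)
  list(x = x[mets], J = setNames(v, rxns),
       residual = max(abs(Sred %*% v)))
}

# ---- model construction ----------------------------------------------------

#' Construct a kinetic fixture model
#'
#' Solves the model to steady state and assembles the matching
#' [MetabolicNetwork-class] with net fluxes and disequilibrium ratios taken
#' from the solved state (\eqn{\rho = v_r/v_f} from the rate-law
#' decomposition). External species are held at fixed concentrations and do
#' not enter the mass balance.
#'
#' @param metabolites data.frame as for [metabolicNetwork()]; only internal
#'   metabolites appear here.
#' @param stoich internal stoichiometric matrix (metabolites x reactions).
#' @param rateLaws named list of rate laws, one per reaction; each law may
#'   carry `external_stoich`, a named vector of coefficients for external
#'   species.
#' @param externals named numeric of fixed external concentrations.
#' @param moieties,couplings as for [metabolicNetwork()].
#' @param totals named numeric, conserved total per moiety group.
#' @param x0 named numeric, initial internal concentrations.
#' @param elasticityUpper optional data.frame passed through to the network.
#' @return a [KineticModel-class] whose network is steady-state consistent.
#' @export
kineticModel <- function(metabolites, stoich, rateLaws, externals = numeric(0),
                         moieties = list(), couplings = list(),
                         totals = numeric(0), x0,
                         elasticityUpper = NULL) {
  moieties <- lapply(moieties, normalizeMoiety)
  stoich <- as.matrix(stoich)
  ss <- solveSteadyStateCore(stoich, rateLaws, moieties, totals, externals, x0)
  if (any(ss$J <= 0))
    stopf("fixture parameters give nonpositive steady-state flux for %s; reorient or reparametrise",
          paste(names(ss$J)[ss$J <= 0], collapse = ", "))
  rho <- vapply(colnames(stoich), function(r) {
    col <- fullStoichCol(stoich, rateLaws[[r]], r)
    fr <- rateSplit(rateLaws[[r]], col, c(ss$x, externals))
    if (fr[["vf"]] <= 0) 0 else min(fr[["vr"]] / fr[["vf"]], 1 - 1e-9)
  }, 0)
  # moiety ratios measured at the solved steady state
  moieties2 <- lapply(moieties, function(g) {
    d <- g$members[length(g$members)]
    oth <- setdiff(g$members, d)
    g$ratios <- data.frame(a = oth, b = d, value = ss$x[oth] / ss$x[d])
    g
  })
  net <- metabolicNetwork(
    metabolites,
    data.frame(id = colnames(stoich), net_flux = unname(ss$J),
               rho = unname(rho), boundary = FALSE),
    stoich, moieties = moieties2, couplings = couplings,
    elasticityUpper = elasticityUpper)
  new("KineticModel", network = net, rateLaws = rateLaws, totals = totals,
      externals = externals)
}

fullStoichCol <- function(stoich, law, r) {
  col <- setNames(stoich[, r], rownames(stoich))
  ext <- law$external_stoich %||% numeric(0)
  c(col[col != 0], ext)
}

#' Solve a kinetic model to steady state
#'
#' Damped Newton iteration in log-concentration space on the reduced mass
#' balances (moiety totals respected exactly), with an ODE-integration
#' fallback for far-off starting points. Converges to
#' \eqn{\|N v(x)\| < 10^{-11}} relative to the flux scale.
#'
#' @param model a [KineticModel-class].
#' @param x0 named numeric initial internal concentrations (default: the
#'   model network's recorded steady state scaled by 1).
#' @param activity named numeric multiplicative factors on the limiting
#'   rates (default all 1).
#' @return list with `x` (internal concentrations), `J` (fluxes),
#'   `residual`.
#' @export
solveSteadyState <- function(model, x0 = NULL, activity = NULL) {
  net <- model@network
  stoich <- stoichMatrix(net)
  if (is.null(x0)) {
    x0 <- setNames(rep(1, nMetabolites(net)), metaboliteIds(net))
    for (g in net@moieties) x0[g$members] <- model@totals[g$id] / length(g$members)
  }
  act <- setNames(rep(1, nReactions(net)), reactionIds(net))
  if (!is.null(activity)) act[names(activity)] <- activity
  solveSteadyStateCore(stoich, model@rateLaws, net@moieties, model@totals,
                       model@externals, x0, activity = act)
}

#' Exact scaled elasticities of a kinetic model
#'
#' Evaluates the scaled elasticities of the forward, reverse and net rates
#' from the rate laws at a steady state, analytically (`method =
#' "analytic"`) or by central finite differences in log space (`method =
#' "fd"`, relative step 1e-7, used as an independent cross-check).
#'
#' @param model a [KineticModel-class].
#' @param state optional output of [solveSteadyState()]; defaults to the
#'   steady state stored in the model network.
#' @param method "analytic" or "fd".
#' @return an [ElasticitySample-class] (seed `NA`).
#' @export
exactElasticities <- function(model, state = NULL,
                              method = c("analytic", "fd")) {
  method <- match.arg(method)
  net <- model@network
  if (is.null(state)) state <- solveSteadyState(model)
  x <- c(state$x, model@externals)
  mets <- metaboliteIds(net); rxns <- reactionIds(net)
  stoich <- stoichMatrix(net)
  fwd <- rev_ <- netm <- matrix(0, length(rxns), length(mets),
                                dimnames = list(rxns, mets))
  rho <- setNames(numeric(length(rxns)), rxns)
  for (r in rxns) {
    col <- fullStoichCol(stoich, model@rateLaws[[r]], r)
    fr <- rateSplit(model@rateLaws[[r]], col, x)
    rho[r] <- if (fr[["vf"]] > 0) fr[["vr"]] / fr[["vf"]] else 0
    for (met in intersect(names(col), mets)) {
      e <- if (method == "analytic") {
        rateElasticity(model@rateLaws[[r]], col, x, met)
      } else {
        fdElasticity(model@rateLaws[[r]], col, x, met)
      }
      fwd[r, met] <- e[["forward"]]; rev_[r, met] <- e[["reverse"]]
      netm[r, met] <- e[["net"]]
    }
  }
  new("ElasticitySample", forward = fwd, reverse = rev_, net = netm,
      seed = NA_integer_, rhoUsed = rho)
}

fdElasticity <- function(law, col, x, met, relStep = 1e-7) {
  evalAt <- function(f) {
    xp <- x; xp[met] <- x[met] * f
    rateSplit(law, col, xp)
  }
  up <- evalAt(1 + relStep); dn <- evalAt(1 - relStep)
  dl <- log((1 + relStep) / (1 - relStep))
  base <- rateSplit(law, col, x)
  e1 <- function(a, b, v0) if (v0 == 0) 0 else (log(a) - log(b)) / dl
  fwd <- if (base[["vf"]] > 0) (log(up[["vf"]]) - log(dn[["vf"]])) / dl else 0
  rv <- if (base[["vr"]] > 0) (log(up[["vr"]]) - log(dn[["vr"]])) / dl else 0
  vn <- base[["vf"]] - base[["vr"]]
  nt <- if (vn != 0) (log(up[["vf"]] - up[["vr"]]) - log(dn[["vf"]] - dn[["vr"]])) / dl else NA_real_
  c(forward = fwd, reverse = rv, net = nt)
}

#' Ground-truth control coefficients by finite differences
#'
#' Perturbs each limiting rate by a relative factor, re-solves the steady
#' state and differences the logs: an oracle for [computeControlMatrix()]
#' that shares no code path with the matrix computation.
#'
#' @param model a [KineticModel-class].
#' @param rel relative perturbation (default 1e-6).
#' @return a [ControlMatrix-class].
#' @export
controlCoefficientsFD <- function(model, rel = 1e-6) {
  net <- model@network
  rxns <- reactionIds(net); mets <- metaboliteIds(net)
  base <- solveSteadyState(model)
  Cx <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  Cj <- matrix(0, length(rxns), length(rxns), dimnames = list(rxns, rxns))
  for (k in rxns) {
    up <- solveSteadyState(model, x0 = base$x, activity = setNames(1 + rel, k))
    dn <- solveSteadyState(model, x0 = base$x, activity = setNames(1 / (1 + rel), k))
    dl <- 2 * log(1 + rel)
    Cx[, k] <- (log(up$x[mets]) - log(dn$x[mets])) / dl
    Cj[, k] <- (log(up$J) - log(dn$J)) / dl
  }
  new("ControlMatrix", conc = Cx, flux = Cj, provenance = "finite-difference",
      maxAbs = max(abs(Cx), abs(Cj)))
}

#' Simulate a measured metabolic adaptation on a fixture model
#'
#' Scales the limiting rates by the given factors, re-solves the steady
#' state, and reports the exact log2 fold changes plus a measurement table
#' in the format consumed by [buildInitialDomains()]. The noise model is
#' lognormal relative error on the post-perturbation values: fluxes get
#' 95-percent confidence intervals, concentrations mean +/- 1 SD intervals;
#' with `cv = 0` the intervals are exact points.
#'
#' @param model a [KineticModel-class].
#' @param perturbation named numeric, reaction -> multiplicative activity
#'   factor (> 0); reactions not named keep factor 1.
#' @param noise list with `cv_flux` (default 0.10) and `cv_conc`
#'   (default 0.20); set both 0 for noiseless data.
#' @param seed integer seed for the noise draws.
#' @param measuredConc character vector of metabolite ids whose
#'   concentrations are reported (default: all).
#' @return list with `dlog` (named log2 fold changes `conc`, `flux`, `act`),
#'   `before`/`after` steady states, and `measurements` (data.frame).
#' @export
simulateAdaptation <- function(model, perturbation = numeric(0),
                               noise = list(cv_flux = 0.10, cv_conc = 0.20),
                               seed = 1, measuredConc = NULL) {
  if (any(perturbation <= 0)) stopf("perturbation factors must be positive")
  net <- model@network
  rxns <- reactionIds(net); mets <- metaboliteIds(net)
  fac <- setNames(rep(1, length(rxns)), rxns)
  fac[names(perturbation)] <- perturbation
  before <- solveSteadyState(model)
  after <- solveSteadyState(model, x0 = before$x, activity = fac)
  dlog <- list(conc = log2(after$x[mets]) - log2(before$x[mets]),
               flux = log2(after$J) - log2(before$J),
               act = log2(fac))
  if (is.null(measuredConc)) measuredConc <- mets
  cvf <- noise$cv_flux %||% 0; cvc <- noise$cv_conc %||% 0
  rows <- withSeed(as.integer(seed), {
    mkrow <- function(kind, id, b, a, cv) {
      sdlog <- sqrt(log(1 + cv^2))
      obs <- a * exp(rnorm(1, 0, sdlog))
      half <- if (kind == "flux") 1.96 * sdlog else sdlog
      data.frame(kind = kind, id = id, before = b,
                 after_lo = obs * exp(-half), after_hi = obs * exp(half))
    }
    c(lapply(rxns, function(r) mkrow("flux", r, before$J[r], after$J[r], cvf)),
      lapply(measuredConc, function(mm) mkrow("conc", mm, before$x[mm], after$x[mm], cvc)))
  })
  list(dlog = dlog, before = before, after = after,
       measurements = do.call(rbind, rows))
}

# ---- shipped fixture topologies -------------------------------------------

#' Fixture models
#'
#' Small kinetic models with known steady states used throughout the test
#' suite and documentation:
#' * `fixtureChain(k)`: open chain of `k` internal metabolites and `k + 1`
#'   reversible mass-action reactions between two fixed external pools.
#' * `fixtureBranch()`: one input splitting into two exit branches
#'   (3 internal metabolites, 4 reactions).
#' * `fixtureGlycolysis()`: an upper-glycolysis-like model with 5 internal
#'   metabolites and 6 reactions - input, a reversible isomerase, a Hill
#'   (h = 2) kinase step, a sink, and an oxidative branch coupled to a
#'   NADP/NADPH moiety cycle.
#'
#' The parameter values are package-chosen so that a strictly positive
#' steady state exists; they are not literature values.
#'
#' @param k number of internal metabolites in the chain.
#' @return a [KineticModel-class].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixtureChain <- function(k = 3) {
  mets <- sprintf("x%d", seq_len(k))
  rxns <- sprintf("R%d", seq_len(k + 1))
  S <- matrix(0, k, k + 1, dimnames = list(mets, rxns))
  for (i in seq_len(k)) { S[i, i] <- 1; S[i, i + 1] <- -1 }
  laws <- list()
  laws[["R1"]] <- list(type = "mass_action", kf = 1, kr = 0.3,
                       external_stoich = c(S0 = -1))
  for (i in seq_len(k - 1) + 1)
    laws[[sprintf("R%d", i)]] <- list(type = "mass_action", kf = 2, kr = 0.8)
  laws[[sprintf("R%d", k + 1)]] <- list(type = "mass_action", kf = 1.5, kr = 0,
                                        external_stoich = c(P0 = 1))
  kineticModel(data.frame(id = mets), S, laws,
               externals = c(S0 = 2, P0 = 0.5),
               x0 = setNames(rep(1, k), mets))
}

#' @rdname fixtures
#' @export
fixtureBranch <- function() {
  mets <- c("a", "b", "c")
  rxns <- c("Rin", "Rb", "Rc", "RoutB", "RoutC")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["a", "Rin"] <- 1
  S["a", "Rb"] <- -1; S["b", "Rb"] <- 1
  S["a", "Rc"] <- -1; S["c", "Rc"] <- 1
  S["b", "RoutB"] <- -1
  S["c", "RoutC"] <- -1
  laws <- list(
    Rin = list(type = "mass_action", kf = 1, kr = 0.2, external_stoich = c(S0 = -1)),
    Rb = list(type = "michaelis_menten", Vf = 3, Vr = 0.5, Km = c(a = 1, b = 1)),
    Rc = list(type = "mass_action", kf = 0.8, kr = 0.1),
    RoutB = list(type = "mass_action", kf = 1.2, kr = 0, external_stoich = c(P1 = 1)),
    RoutC = list(type = "mass_action", kf = 0.9, kr = 0, external_stoich = c(P2 = 1)))
  kineticModel(data.frame(id = mets), S, laws,
               externals = c(S0 = 2, P1 = 0.2, P2 = 0.2),
               x0 = c(a = 1, b = 1, c = 1))
}

#' @rdname fixtures
#' @export
fixtureGlycolysis <- function() {
  mets <- c("G6P", "F6P", "FBP", "NADP", "NADPH")
  rxns <- c("HK", "GPI", "PFK", "ALD", "G6PD", "NADPase")
  S <- matrix(0, 5, 6, dimnames = list(mets, rxns))
  S["G6P", "HK"] <- 1
  S["G6P", "GPI"] <- -1; S["F6P", "GPI"] <- 1
  S["F6P", "PFK"] <- -1; S["FBP", "PFK"] <- 1
  S["FBP", "ALD"] <- -1
  S["G6P", "G6PD"] <- -1; S["NADP", "G6PD"] <- -1; S["NADPH", "G6PD"] <- 1
  S["NADPH", "NADPase"] <- -1; S["NADP", "NADPase"] <- 1
  laws <- list(
    HK = list(type = "mass_action", kf = 0.6, kr = 0.15,
              external_stoich = c(GLC = -1)),
    GPI = list(type = "michaelis_menten", Vf = 6, Vr = 5,
               Km = c(G6P = 0.8, F6P = 0.6)),
    PFK = list(type = "hill", V = 4, K = 1.2, h = 2,
               external_stoich = numeric(0)),
    ALD = list(type = "michaelis_menten", Vf = 5, Vr = 0, Km = c(FBP = 1),
               external_stoich = c(GAP = 2)),
    G6PD = list(type = "michaelis_menten", Vf = 2.5, Vr = 0,
                Km = c(G6P = 1, NADP = 0.15),
                external_stoich = c(PG6 = 1)),
    NADPase = list(type = "mass_action", kf = 3, kr = 0))
  kineticModel(
    data.frame(id = mets,
               moiety_group = c(NA, NA, NA, "NADPpool", "NADPpool")),
    S, laws, externals = c(GLC = 5, GAP = 0.1, PG6 = 0.1),
    moieties = list(list(id = "NADPpool", members = c("NADP", "NADPH"),
                         ratios = list())),
    totals = c(NADPpool = 1),
    x0 = c(G6P = 1, F6P = 1, FBP = 1, NADP = 0.5, NADPH = 0.5),
    elasticityUpper = data.frame(reaction = "PFK", metabolite = "F6P", h = 2))
}
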