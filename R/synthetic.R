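# Synthetic central-carbon-scale study system.
#
# The published cancer study this package's method targets was run on a
# 53-metabolite / 76-reaction central-carbon network whose exact
# stoichiometry, fluxes and disequilibrium ratios are distributed as
# supplementary PDF tables. This file generates a SYNTHETIC network of the
# same scale and structural character (six conserved cofactor pairs with
# literature concentration ratios, a near-equilibrium reaction subset,
# substrate/product competitive pairs, allosteric modifiers, a two-reaction
# coupled pair and a four-reaction coordinately regulated block, and a shell
# of simplified boundary processes) so that the full pipeline can be
# exercised at realistic size. It is NOT a transcription of the published
# network.

#' Synthetic central-carbon-scale network
#'
#' Builds a deterministic synthetic metabolic network with 53 internal
#' metabolites and 76 reactions: a 41-step pathway backbone with shortcut
#' branches, six conserved cofactor pairs (concentration ratios 0.019, 0.33,
#' 8, 120, 6, 0.52 - the literature values for the AcCoA/CoA (cytosolic and
#' mitochondrial), ATP/ADP, NAD/NADH (cytosolic and mitochondrial) and
#' NADP/NADPH pools) attached to twelve backbone reactions with matching
#' recycling processes, twenty boundary exchange processes, fourteen
#' near-equilibrium reactions (rho = 0.9), eight competitive
#' substrate/product pairs, ten allosteric modifier assignments, one
#' two-reaction activity coupling and one four-reaction coordinately
#' regulated block. A strictly positive steady-state flux distribution is
#' found by linear programming over the mass-balance null space.
#'
#' @param seed integer controlling the flux-selection objective (default 1;
#'   the topology is fixed).
#' @return a [MetabolicNetwork-class] with n = 53, m = 76.
#' @export
syntheticCancerNetwork <- function(seed = 1) {
  pmets <- sprintf("P%02d", 1:41)
  pairs <- list(
    list(a = "ACoA.c", b = "CoA.c", ratio = 0.019),
    list(a = "ACoA.m", b = "CoA.m", ratio = 0.33),
    list(a = "ATP", b = "ADP", ratio = 8),
    list(a = "NAD.c", b = "NADH.c", ratio = 120),
    list(a = "NAD.m", b = "NADH.m", ratio = 6),
    list(a = "NADP", b = "NADPH", ratio = 0.52))
  cmets <- unlist(lapply(pairs, function(p) c(p$a, p$b)))
  mets <- data.frame(id = c(pmets, cmets),
                     moiety_group = c(rep(NA_character_, 41),
                                      rep(sprintf("pool%d", 1:6), each = 2)))

  rxn <- character(0)
  S <- matrix(0, length(mets$id), 0, dimnames = list(mets$id, NULL))
  addRxn <- function(id, st) {
    col <- matrix(0, nrow(S), 1, dimnames = list(rownames(S), id))
    col[names(st), 1] <- st
    S <<- cbind(S, col); rxn <<- c(rxn, id)
  }

  # backbone chain R01..R40: P_i -> P_{i+1}
  for (i in 1:40)
    addRxn(sprintf("R%02d", i),
           setNames(c(-1, 1), c(pmets[i], pmets[i + 1])))
  # boundary input / output
  addRxn("R41", setNames(1, "P01"))
  addRxn("R42", setNames(-1, "P41"))
  # shortcut branches R43..R52
  short <- list(c(3, 15), c(5, 22), c(10, 30), c(2, 12), c(18, 35),
                c(7, 28), c(14, 40), c(20, 33), c(25, 38), c(9, 19))
  for (k in seq_along(short))
    addRxn(sprintf("R%02d", 42 + k),
           setNames(c(-1, 1), pmets[short[[k]]]))
  # cofactor attachment: two backbone reactions per pair consume A, make B
  attach <- list(c(2, 6), c(11, 16), c(21, 26), c(31, 36), c(4, 13), c(8, 14))
  for (p in seq_along(pairs)) {
    for (i in attach[[p]]) {
      rid <- sprintf("R%02d", i)
      S[pairs[[p]]$a, rid] <- -1
      S[pairs[[p]]$b, rid] <- 1
    }
    # recycling process B -> A
    addRxn(sprintf("R%02d", 52 + p),
           setNames(c(1, -1), c(pairs[[p]]$a, pairs[[p]]$b)))
  }
  # boundary exchanges R59..R76 (alternating uptake / release)
  exch <- c(4, 8, 11, 13, 16, 19, 22, 24, 27, 29, 31, 33, 35, 36, 37, 38, 39, 40)
  for (k in seq_along(exch))
    addRxn(sprintf("R%02d", 58 + k),
           setNames(if (k %% 2 == 1) 1 else -1, pmets[exch[k]]))

  m <- length(rxn)
  # flux distribution: any strictly positive point of {N J = 0, J in [lo, hi]},
  # selected deterministically by a pseudo-random linear objective
  Nint <- S
  # core central-carbon fluxes span about one order of magnitude; a wider
  # spread across parallel routes gives unrealistically extreme scaled
  # flux control coefficients on the minor branch
  lo <- rep(0.5, m); hi <- rep(5, m)
  obj <- withSeed(childSeed(seed, "flux-objective"), runif(m, -1, 1))
  sol <- .lp_solve_cpp(Nint, rep(0, nrow(Nint)), lo, hi, obj, FALSE)
  if (!identical(sol$status, "optimal"))
    stopf("internal error: synthetic network flux polytope empty")
  J <- setNames(round(sol$x, 6), rxn)
  # interior-ward nudge away from exact vertex degeneracy is not needed: the
  # sampler and control computation use ratios only

  rho <- setNames(rep(0, m), rxn)
  nearEq <- sprintf("R%02d", c(3, 5, 9, 12, 17, 22, 24, 27, 32, 34, 37, 39, 43, 53))
  rho[nearEq] <- 0.9

  boundary <- setNames(rep(FALSE, m), rxn)
  boundary[c("R41", "R42", sprintf("R%02d", 59:76))] <- TRUE

  competitive <- rbind(
    data.frame(reaction = sprintf("R%02d", c(6, 16, 26, 36)),
               substrate = pmets[c(6, 16, 26, 36)],
               product = pmets[c(7, 17, 27, 37)]),
    data.frame(reaction = sprintf("R%02d", c(2, 11, 21, 31)),
               substrate = vapply(c(1, 2, 3, 4), function(p) pairs[[p]]$a, ""),
               product = vapply(c(1, 2, 3, 4), function(p) pairs[[p]]$b, "")))

  modifiers <- data.frame(
    reaction = c("R04", "R04", "R09", "R09", "R19", "R21", "R30", "R30", "R36", "R40"),
    metabolite = c("ATP", "ADP", "P30", "P18", "NADH.m", "ATP", "P05", "ADP", "P41", "NADP"),
    role = c("inhibitor", "activator", "inhibitor", "activator", "inhibitor",
             "inhibitor", "inhibitor", "activator", "activator", "inhibitor"))

  moieties <- lapply(seq_along(pairs), function(p)
    list(id = sprintf("pool%d", p),
         members = c(pairs[[p]]$a, pairs[[p]]$b),
         ratios = setNames(list(pairs[[p]]$ratio),
                           paste(pairs[[p]]$a, pairs[[p]]$b, sep = "/"))))

  metabolicNetwork(
    mets,
    data.frame(id = rxn, net_flux = unname(J), rho = unname(rho),
               boundary = unname(boundary)),
    S, modifiers = modifiers, competitive = competitive,
    moieties = moieties,
    couplings = list(c("R13", "R14"), c("R01", "R02", "R04", "R08")))
}

#' Synthetic measured adaptation for the paper-scale network
#'
#' Generates a self-consistent "measured" adaptation: one reference control
#' matrix is sampled (and magnitude-filtered) from the network, a ground
#' truth activity reprogramming is fixed - the coordinately regulated
#' glycolysis-like block down 1 log2 unit, the coupled two-reaction pair up
#' 0.5, one oxidative activity down 0.7 and one anaplerotic activity up 0.8
#' - and the implied flux/concentration log2 fold changes are obtained from
#' the linearized response. Measurement intervals get half-widths of 0.15
#' log2 units for fluxes (confidence-interval style: all fluxes measured)
#' and 0.25 for the eight reported metabolite concentrations.
#'
#' @param network the [syntheticCancerNetwork()] network.
#' @param seed integer seed for the reference matrix.
#' @return list with `measurements` (data.frame for
#'   [buildInitialDomains()]), `truth` (named log2 activity changes) and
#'   `expectations` (driver-scoring table: gene, activity, expected).
#' @export
syntheticCancerMeasurements <- function(network, seed = 1) {
  rxns <- reactionIds(network)
  dv <- setNames(rep(0, length(rxns)), rxns)
  dv[c("R01", "R02", "R04", "R08")] <- -1      # coordinated block down
  dv[c("R13", "R14")] <- 0.5                   # coupled pair up
  dv["R21"] <- -0.7                            # oxidative step down
  dv["R30"] <- 0.8                             # anaplerotic step up

  # reference behaviour: first accepted matrix (from a substream separate
  # from the ensemble's) whose implied systemic changes fit the enclosure -
  # the emulated study reports measured changes within +/-3 log2 units
  C <- NULL; resp <- NULL; g <- 0L
  while (is.null(C)) {
    g <- g + 1L
    if (g > 500) stopf("could not sample an acceptable reference matrix")
    s <- childSeed(seed, sprintf("truth-%d", g))
    C0 <- tryCatch(computeControlMatrix(network, sampleElasticities(network, s)),
                   error = function(e) NULL)
    if (is.null(C0) || !filterByMagnitude(C0, 3.5)) next
    r0 <- linearizedPrediction(C0, dv)
    if (max(abs(c(r0$conc, r0$flux))) <= 2.7) { C <- C0; resp <- r0 }
  }

  J <- netFluxes(network)
  mets <- metaboliteIds(network)
  measuredConc <- c("P05", "P12", "P20", "P28", "P35", "P41", "NADPH", "ATP")
  halfFlux <- 0.15; halfConc <- 0.25
  # observed interval centers scatter around the true response. Flux
  # estimates from a joint stoichiometric fit satisfy the flux dependencies
  # by construction, so their scatter is correlated: it is generated by a
  # small random jitter of all activities propagated through the reference
  # matrix, plus a little independent per-measurement error. Concentration
  # measurements are independent assays and scatter independently.
  etaV <- withSeed(childSeed(seed, "obs-eta"), rnorm(length(rxns), 0, 0.1))
  corr <- linearizedPrediction(C, setNames(etaV, rxns))
  obsFlux <- resp$flux + corr$flux +
    withSeed(childSeed(seed, "obs-flux"), rnorm(length(rxns), 0, 0.06))
  obsConc <- resp$conc[measuredConc] + corr$conc[measuredConc] +
    withSeed(childSeed(seed, "obs-conc"),
             rnorm(length(measuredConc), 0, 0.15))

  fluxRows <- data.frame(kind = "flux", id = rxns, before = unname(J),
                         after_lo = unname(J * 2^(obsFlux - halfFlux)),
                         after_hi = unname(J * 2^(obsFlux + halfFlux)))
  concRows <- data.frame(kind = "conc", id = measuredConc, before = 1,
                         after_lo = 2^(obsConc - halfConc),
                         after_hi = 2^(obsConc + halfConc))
  expectations <- data.frame(
    gene = c("GLYC-block", "OXID", "ANAP", "PAIR"),
    activity = c("R01", "R21", "R30", "R13"),
    expected = c("-", "-", "+", "+"),
    stringsAsFactors = FALSE)
  list(measurements = rbind(fluxRows, concRows),
       truth = dv, expectations = expectations)
}
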