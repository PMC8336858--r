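#' Compute scaled control coefficients from a network and elasticities
#'
#' Uses the link-matrix formulation of the MCA structural equations. With
#' \eqn{N_R} the reduced stoichiometric matrix over independent internal
#' metabolites, \eqn{\varepsilon} the m x n matrix of scaled net-rate
#' elasticities, and \eqn{L_s} the scaled link matrix expressing moiety
#' conservation (its dependent rows carry minus the member concentration
#' ratios, so only ratios are ever needed), the scaled control matrices are
#' \deqn{C^x = -L_s\,(M \varepsilon L_s)^{-1} M, \qquad
#'       C^J = I_m + \varepsilon\, C^x, \qquad M = N_R\,\mathrm{diag}(J).}
#' Only flux ratios and moiety concentration ratios enter: rescaling all net
#' fluxes leaves the result unchanged, and absolute concentrations of
#' metabolites outside moiety groups never appear. The summation,
#' connectivity, moiety and flux-dependency theorems hold by construction up
#' to roundoff and are checked by [checkTheorems()].
#'
#' @param network a [MetabolicNetwork-class] (steady-state consistent).
#' @param sample an [ElasticitySample-class] for the same network.
#' @param condMax condition-number threshold above which the sample is
#'   rejected as numerically singular (default 1e12).
#' @return a [ControlMatrix-class].
#' @export
computeControlMatrix <- function(network, sample, condMax = 1e12) {
  n <- nMetabolites(network); m <- nReactions(network)
  mets <- metaboliteIds(network); rxns <- reactionIds(network)
  eps <- sample@net
  stopifnot(identical(dim(eps), c(m, n)))

  dep <- vapply(network@moieties, function(g) g$members[length(g$members)], "")
  indep <- setdiff(mets, dep)
  n0 <- length(indep)

  # scaled link matrix (n x n0)
  Ls <- matrix(0, n, n0, dimnames = list(mets, indep))
  Ls[cbind(indep, indep)] <- 1
  for (g in network@moieties) {
    rel <- moietyRatios(network, g$id)        # member / dependent member
    d <- g$members[length(g$members)]
    for (a in setdiff(g$members, d)) Ls[d, a] <- -rel[a]
  }

  NR <- stoichMatrix(network)[indep, , drop = FALSE]
  J <- netFluxes(network)
  M <- NR %*% diag(J, m)
  G <- M %*% eps %*% Ls
  kappa <- tryCatch(kappa(G, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > condMax)
    stopf("singular system matrix (condition number %.3g) for sample seed %s: discard this sample",
          kappa, ifelse(is.na(sample@seed), "exact", sample@seed))
  Ginv <- tryCatch(solve(G), error = function(e)
    stopf("singular system matrix for sample seed %s: discard this sample",
          ifelse(is.na(sample@seed), "exact", sample@seed)))

  Cx <- -Ls %*% Ginv %*% M
  Cj <- diag(m) + eps %*% Cx
  dimnames(Cx) <- list(mets, rxns)
  dimnames(Cj) <- list(rxns, rxns)
  new("ControlMatrix", conc = Cx, flux = Cj,
      provenance = sprintf("seed=%s", ifelse(is.na(sample@seed), "exact", sample@seed)),
      maxAbs = max(abs(Cx), abs(Cj)))
}

#' Check the MCA theorems on a control matrix
#'
#' Reports the maximum residual of each structural identity:
#' flux summation (rows of \eqn{C^J} sum to 1), concentration summation
#' (rows of \eqn{C^x} sum to 0), connectivity
#' (\eqn{C^J \varepsilon L_s = 0} and \eqn{C^x \varepsilon L_s = -L_s};
#' for metabolites outside moiety groups this is the classical
#' per-metabolite form, for moiety members the generalized link-matrix form
#' applies and the classical form is not reported), moiety rows
#' (ratio-weighted rows of \eqn{C^x} over each conserved group sum to 0) and
#' flux dependencies (\eqn{N\,\mathrm{diag}(J)\,C^J = 0}).
#'
#' @param C a [ControlMatrix-class].
#' @param sample the [ElasticitySample-class] used to build it.
#' @param network the [MetabolicNetwork-class].
#' @param tol residual tolerance (default 1e-8).
#' @return data.frame with columns `identity`, `max_residual`, `pass`.
#' @export
checkTheorems <- function(C, sample, network, tol = 1e-8) {
  eps <- sample@net
  Cx <- C@conc; Cj <- C@flux
  m <- nrow(Cj); mets <- rownames(Cx)

  dep <- vapply(network@moieties, function(g) g$members[length(g$members)], "")
  indep <- setdiff(mets, dep)
  Ls <- matrix(0, length(mets), length(indep), dimnames = list(mets, indep))
  Ls[cbind(indep, indep)] <- 1
  for (g in network@moieties) {
    rel <- moietyRatios(network, g$id)
    d <- g$members[length(g$members)]
    for (a in setdiff(g$members, d)) Ls[d, a] <- -rel[a]
  }

  res <- list(
    flux_summation = max(abs(rowSums(Cj) - 1)),
    conc_summation = if (nrow(Cx)) max(abs(rowSums(Cx))) else 0,
    connectivity_flux = max(abs(Cj %*% eps %*% Ls)),
    connectivity_conc = max(abs(Cx %*% eps %*% Ls + Ls)),
    flux_dependencies = max(abs(stoichMatrix(network) %*% diag(netFluxes(network), m) %*% Cj))
  )
  if (length(network@moieties)) {
    mr <- 0
    for (g in network@moieties) {
      rel <- moietyRatios(network, g$id)
      mr <- max(mr, max(abs(rel[g$members] %*% Cx[g$members, , drop = FALSE])))
    }
    res$moiety_rows <- mr
  }
  data.frame(identity = names(res), max_residual = unlist(res),
             pass = unlist(res) <= tol, row.names = NULL)
}

#' Accept or reject a control matrix by magnitude
#'
#' Ensembles keep only matrices whose control coefficients all lie within
#' `bound` in absolute value; extreme sensitivities are taken as unrealistic.
#'
#' @param C a [ControlMatrix-class].
#' @param bound positive scalar (default 3.5).
#' @return TRUE iff `max(|C|) <= bound`.
#' @export
filterByMagnitude <- function(C, bound = 3.5) {
  stopifnot(bound > 0)
  C@maxAbs <= bound
}

#' Response coefficients for a parameter acting through known elasticities
#'
#' \deqn{R^{x}_p = C^x \varepsilon_p, \qquad R^{J}_p = C^J \varepsilon_p}
#' where \eqn{\varepsilon_p} collects the parameter elasticities of every
#' activity (missing reactions count as 0).
#'
#' @param C a [ControlMatrix-class].
#' @param parameterElasticities named numeric, reaction -> parameter
#'   elasticity.
#' @return list with components `conc` (n-vector) and `flux` (m-vector).
#' @export
responseCoefficients <- function(C, parameterElasticities) {
  rxns <- colnames(C@flux)
  ep <- setNames(numeric(length(rxns)), rxns)
  known <- intersect(names(parameterElasticities), rxns)
  unknown <- setdiff(names(parameterElasticities), rxns)
  if (length(unknown)) stopf("parameter elasticity for unknown reaction %s", unknown[1])
  ep[known] <- parameterElasticities[known]
  if (any(!is.finite(ep))) stopf("parameter elasticities must be finite")
  list(conc = as.numeric(C@conc %*% ep) |> setNames(rownames(C@conc)),
       flux = as.numeric(C@flux %*% ep) |> setNames(rxns))
}

#' First-order prediction of a response to activity changes
#'
#' Propagates log-fold activity changes through the control matrices:
#' \deqn{\Delta\log x = C^x\, \Delta\log v, \qquad
#'       \Delta\log J = C^J\, \Delta\log v.}
#' Exact for infinitesimal changes; the error grows quadratically with the
#' perturbation size.
#'
#' @param C a [ControlMatrix-class].
#' @param dlog_v named numeric of activity log-fold changes (any base, the
#'   output is in the same base; missing reactions count as 0).
#' @return list with components `conc` and `flux`.
#' @export
linearizedPrediction <- function(C, dlog_v) {
  responseCoefficients(C, dlog_v)
}

#' Write / read a control matrix as two CSV files
#'
#' @param C a [ControlMatrix-class].
#' @param concPath,fluxPath CSV paths for the concentration (n x m) and flux
#'   (m x m) blocks, with id headers.
#' @name control-io
NULL

#' @rdname control-io
#' @export
writeControlMatrix <- function(C, concPath, fluxPath) {
  utils::write.csv(as.data.frame(C@conc), concPath, row.names = TRUE)
  utils::write.csv(as.data.frame(C@flux), fluxPath, row.names = TRUE)
  invisible(c(concPath, fluxPath))
}

#' @rdname control-io
#' @export
readControlMatrix <- function(concPath, fluxPath) {
  Cx <- as.matrix(utils::read.csv(concPath, row.names = 1, check.names = FALSE))
  Cj <- as.matrix(utils::read.csv(fluxPath, row.names = 1, check.names = FALSE))
  new("ControlMatrix", conc = Cx, flux = Cj, provenance = "file",
      maxAbs = max(abs(Cx), abs(Cj)))
}

#' @describeIn ControlMatrix-class compact display
#' @param object a ControlMatrix
#' @export
setMethod("show", "ControlMatrix", function(object) {
  cat(sprintf("ControlMatrix: conc %d x %d, flux %d x %d, max|C| = %.3g (%s)\n",
              nrow(object@conc), ncol(object@conc), nrow(object@flux),
              ncol(object@flux), object@maxAbs, object@provenance))
})
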