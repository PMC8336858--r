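#' Split a net flux into forward and reverse rates
#'
#' At steady state the forward and reverse rates of a reversible reaction
#' follow from the net flux \eqn{v > 0} and the disequilibrium ratio
#' \eqn{\rho = v_r/v_f}:
#' \deqn{v_f = v/(1-\rho), \qquad v_r = \rho v/(1-\rho).}
#'
#' @param net_flux net rate, nonnegative.
#' @param rho disequilibrium ratio in \[0, 1).
#' @return named numeric `c(vf, vr)`.
#' @export
forwardReverseSplit <- function(net_flux, rho) {
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stopf("disequilibrium ratio must satisfy 0 <= rho < 1, got %s", format(rho))
  if (net_flux < 0) stopf("net flux must be oriented nonnegative")
  c(vf = net_flux / (1 - rho), vr = rho * net_flux / (1 - rho))
}

#' Net-rate elasticity from a forward-rate elasticity
#'
#' Converts a sampled forward-rate elasticity into the elasticity of the net
#' rate, adding the thermodynamic (mass-action) term that diverges as the
#' reaction approaches equilibrium:
#' \deqn{\varepsilon^v_S = \frac{\rho}{1-\rho} + \varepsilon^{v_f}_S, \qquad
#'       \varepsilon^v_P = -\frac{\rho}{1-\rho} + \varepsilon^{v_f}_P.}
#' At \eqn{\rho = 0} (irreversible) the net elasticity equals the sampled
#' forward elasticity; products keep a nonzero elasticity there because the
#' sampled \eqn{\varepsilon^{v_f}_P} term remains.
#'
#' @param eps_f forward-rate elasticity (positive for substrates, negative
#'   for products).
#' @param rho disequilibrium ratio in \[0, 1).
#' @param role `"substrate"` or `"product"`.
#' @return net-rate elasticity (scalar).
#' @export
netElasticityFromForward <- function(eps_f, rho, role = c("substrate", "product")) {
  role <- match.arg(role)
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stopf("disequilibrium ratio must satisfy 0 <= rho < 1 (rho = 1 is equilibrium: indeterminate)")
  if (role == "substrate") {
    if (any(eps_f <= 0)) stopf("substrate forward elasticity must be positive")
    rho / (1 - rho) + eps_f
  } else {
    if (any(eps_f >= 0)) stopf("product forward elasticity must be negative")
    -rho / (1 - rho) + eps_f
  }
}

# saturation bound h for (reaction, metabolite), default 1
elasticityBound <- function(network, rid, mid) {
  eu <- network@elasticityUpper
  k <- which(eu$reaction == rid & eu$metabolite == mid)
  if (length(k)) eu$h[k[1]] else 1
}

#' Sample one set of scaled metabolite elasticities
#'
#' For every reaction, forward-rate elasticities of substrates and products
#' are drawn uniformly on the open saturation intervals \eqn{(0, h)} and
#' \eqn{(-h, 0)} (h = 1 for Michaelis-Menten-type saturation, the Hill
#' coefficient where declared). Reverse-rate elasticities are derived from
#' the linkage \eqn{\varepsilon^{v_f} - \varepsilon^{v_r} = +1} (substrates)
#' / \eqn{-1} (products), never sampled independently. Net-rate elasticities
#' add the thermodynamic term \eqn{\pm\rho/(1-\rho)}
#' ([netElasticityFromForward()]). Declared competitive substrate/product
#' pairs are drawn by direct construction so that
#' \eqn{0 < \varepsilon^{v_f}_S + \varepsilon^{v_f}_P < 1} (the thermodynamic
#' terms cancel in the sum, so the constraint holds for the net rate at any
#' \eqn{\rho}). Allosteric modifiers are sampled directly on the net rate in
#' \eqn{(0, 1)} for activators and \eqn{(-1, 0)} for inhibitors; a metabolite
#' that is both reactant and modifier of one reaction contributes the sum of
#' both terms.
#'
#' Sampling is reproducible: each reaction draws from its own substream
#' seeded by a stable hash of the reaction id combined with `seed`, so adding
#' a reaction leaves other reactions' draws unchanged.
#'
#' @param network a [MetabolicNetwork-class].
#' @param seed integer root seed.
#' @param margin open-interval margin delta keeping draws away from exact
#'   saturation bounds (default 1e-3).
#' @return an [ElasticitySample-class].
#' @export
sampleElasticities <- function(network, seed, margin = 1e-3) {
  seed <- as.integer(seed)
  n <- nMetabolites(network); m <- nReactions(network)
  mets <- metaboliteIds(network); rxns <- reactionIds(network)
  S <- stoichMatrix(network)
  fwd <- rev_ <- net <- matrix(0, m, n, dimnames = list(rxns, mets))
  rho <- rhoValues(network)

  for (j in seq_len(m)) {
    rid <- rxns[j]
    withSeed(childSeed(seed, rid), {
      subs <- mets[S[, j] < 0]
      prods <- mets[S[, j] > 0]
      cp <- network@competitive[network@competitive$reaction == rid, , drop = FALSE]
      paired <- c(cp$substrate, cp$product)

      # competitive pairs: draw the sum u in (0,1), then split
      for (i in seq_len(nrow(cp))) {
        sId <- cp$substrate[i]; pId <- cp$product[i]
        if (!(sId %in% subs) || !(pId %in% prods)) next # external species: skip
        hs <- elasticityBound(network, rid, sId)
        hp <- elasticityBound(network, rid, pId)
        u <- runif(1, margin, 1 - margin)
        lo <- max(u, margin); hi <- min(hs - margin, u + hp - margin)
        if (lo >= hi)
          stopf("reaction %s: competitive pair (%s, %s) unsatisfiable with bounds h_S=%g, h_P=%g",
                rid, sId, pId, hs, hp)
        es <- runif(1, lo, hi)
        fwd[j, sId] <- es
        fwd[j, pId] <- u - es   # negative
      }

      for (mid in setdiff(subs, paired))
        if (mid %in% mets)
          fwd[j, mid] <- runif(1, margin, elasticityBound(network, rid, mid) - margin)
      for (mid in setdiff(prods, paired))
        if (mid %in% mets)
          fwd[j, mid] <- -runif(1, margin, elasticityBound(network, rid, mid) - margin)

      # forward/reverse linkage and thermodynamic transform
      for (mid in intersect(subs, mets)) {
        rev_[j, mid] <- fwd[j, mid] - 1
        net[j, mid] <- netElasticityFromForward(fwd[j, mid], rho[j], "substrate")
      }
      for (mid in intersect(prods, mets)) {
        rev_[j, mid] <- fwd[j, mid] + 1
        net[j, mid] <- netElasticityFromForward(fwd[j, mid], rho[j], "product")
      }

      # modifiers act on the net rate directly
      md <- network@modifiers[network@modifiers$reaction == rid, , drop = FALSE]
      for (i in seq_len(nrow(md))) {
        mid <- md$metabolite[i]
        if (!(mid %in% mets)) next
        drawn <- runif(1, margin, 1 - margin)
        net[j, mid] <- net[j, mid] + if (md$role[i] == "activator") drawn else -drawn
      }
    })
  }
  new("ElasticitySample", forward = fwd, reverse = rev_, net = net,
      seed = seed, rhoUsed = rho)
}

#' @describeIn ElasticitySample-class net-rate elasticity matrix (m x n)
#' @param x an ElasticitySample
#' @export
netElasticities <- function(x) x@net

#' Write / read an elasticity sample as CSV
#'
#' Long format with columns `reaction`, `metabolite`, `eps_forward`,
#' `eps_reverse`, `eps_net`; only nonzero entries are stored.
#' @param sample an [ElasticitySample-class].
#' @param path file path.
#' @param network the network the sample refers to.
#' @name elasticities-io
NULL

#' @rdname elasticities-io
#' @export
writeElasticities <- function(sample, path) {
  idx <- which(sample@net != 0 | sample@forward != 0, arr.ind = TRUE)
  df <- data.frame(reaction = rownames(sample@net)[idx[, 1]],
                   metabolite = colnames(sample@net)[idx[, 2]],
                   eps_forward = sample@forward[idx],
                   eps_reverse = sample@reverse[idx],
                   eps_net = sample@net[idx])
  df <- df[order(df$reaction, df$metabolite), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname elasticities-io
#' @export
readElasticities <- function(path, network) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- nReactions(network); n <- nMetabolites(network)
  dn <- list(reactionIds(network), metaboliteIds(network))
  fwd <- rev_ <- net <- matrix(0, m, n, dimnames = dn)
  ij <- cbind(match(df$reaction, dn[[1]]), match(df$metabolite, dn[[2]]))
  if (anyNA(ij)) stopf("%s: unknown reaction/metabolite id", path)
  fwd[ij] <- df$eps_forward; rev_[ij] <- df$eps_reverse; net[ij] <- df$eps_net
  new("ElasticitySample", forward = fwd, reverse = rev_, net = net,
      seed = NA_integer_, rhoUsed = rhoValues(network))
}

#' @describeIn ElasticitySample-class compact display
#' @param object an ElasticitySample
#' @export
setMethod("show", "ElasticitySample", function(object) {
  cat(sprintf("ElasticitySample: %d reactions x %d metabolites, %d nonzero net elasticities (seed %s)\n",
              nrow(object@net), ncol(object@net), sum(object@net != 0),
              ifelse(is.na(object@seed), "exact", object@seed)))
})
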