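#' Construct a MetabolicNetwork
#'
#' Validates and assembles a metabolic network at a reference steady state.
#' Reactions with negative net flux are flipped (substrates and products
#' exchanged, competitive-pair roles swapped) so that all oriented net fluxes
#' are nonnegative; the disequilibrium ratio is interpreted in the oriented
#' direction.
#'
#' @param metabolites data.frame with columns `id` and optionally `name`,
#'   `internal` (default TRUE), `moiety_group` (default NA).
#' @param reactions data.frame with columns `id`, `net_flux` and optionally
#'   `rho` (default 0), `boundary` (default FALSE).
#' @param stoich numeric matrix (metabolites x reactions) of signed
#'   stoichiometric coefficients; negative = substrate.
#' @param modifiers data.frame (`reaction`, `metabolite`, `role`) or NULL.
#' @param competitive data.frame (`reaction`, `substrate`, `product`) or NULL.
#' @param elasticityUpper data.frame (`reaction`, `metabolite`, `h`) or NULL.
#' @param moieties list of `list(id, members, ratios)`; `ratios` is a
#'   data.frame (`a`, `b`, `value`) of concentration ratios a/b, or a named
#'   list like `list("ATP/ADP" = 8)`.
#' @param couplings list of character vectors of reaction ids.
#' @return a validated [MetabolicNetwork-class] object.
#' @export
metabolicNetwork <- function(metabolites, reactions, stoich,
                             modifiers = NULL, competitive = NULL,
                             elasticityUpper = NULL, moieties = list(),
                             couplings = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  nm <- nrow(metabolites); nr <- nrow(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$internal)) metabolites$internal <- rep(TRUE, nm)
  if (is.null(metabolites$moiety_group))
    metabolites$moiety_group <- rep(NA_character_, nm)
  if (is.null(reactions$rho)) reactions$rho <- rep(0, nr)
  if (is.null(reactions$boundary)) reactions$boundary <- rep(FALSE, nr)
  metabolites <- metabolites[, c("id", "name", "internal", "moiety_group")]
  reactions <- reactions[, c("id", "net_flux", "rho", "boundary")]

  stoich <- as.matrix(stoich)
  if ((nrow(stoich) > 0 && is.null(rownames(stoich))) || is.null(colnames(stoich)))
    stopf("stoichiometric matrix must carry metabolite row names and reaction column names")
  stoich <- stoich[match(metabolites$id, rownames(stoich)),
                   match(reactions$id, colnames(stoich)), drop = FALSE]
  rownames(stoich) <- metabolites$id

  empty <- function(cols) as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  modifiers <- if (is.null(modifiers) || !nrow(as.data.frame(modifiers)))
    empty(c("reaction", "metabolite", "role")) else as.data.frame(modifiers)
  competitive <- if (is.null(competitive) || !nrow(as.data.frame(competitive)))
    empty(c("reaction", "substrate", "product")) else as.data.frame(competitive)
  elasticityUpper <- if (is.null(elasticityUpper) || !nrow(as.data.frame(elasticityUpper))) {
    data.frame(reaction = character(0), metabolite = character(0), h = numeric(0))
  } else as.data.frame(elasticityUpper)

  moieties <- lapply(moieties, normalizeMoiety)

  # orient reactions to nonnegative net flux
  flip <- which(reactions$net_flux < 0)
  if (length(flip)) {
    stoich[, flip] <- -stoich[, flip, drop = FALSE]
    reactions$net_flux[flip] <- -reactions$net_flux[flip]
    fl <- reactions$id[flip]
    sw <- competitive$reaction %in% fl
    if (any(sw)) {
      tmp <- competitive$substrate[sw]
      competitive$substrate[sw] <- competitive$product[sw]
      competitive$product[sw] <- tmp
    }
  }

  net <- new("MetabolicNetwork", metabolites = metabolites,
             reactions = reactions, stoich = stoich,
             modifiers = modifiers, competitive = competitive,
             elasticityUpper = elasticityUpper, moieties = moieties,
             couplings = couplings)
  validateNetwork(net)
  net
}

normalizeMoiety <- function(g) {
  ratios <- g$ratios %||% g$concentration_ratios %||% list()
  if (!is.data.frame(ratios)) {
    if (length(ratios)) {
      parts <- strsplit(names(ratios), "/", fixed = TRUE)
      ratios <- data.frame(a = vapply(parts, `[`, "", 1L),
                           b = vapply(parts, `[`, "", 2L),
                           value = as.numeric(unlist(ratios)))
    } else {
      ratios <- data.frame(a = character(0), b = character(0), value = numeric(0))
    }
  }
  list(id = g$id, members = as.character(unlist(g$members)), ratios = ratios)
}

validateNetwork <- function(net, tol = 1e-9) {
  met <- net@metabolites; rxn <- net@reactions; S <- net@stoich
  if (anyDuplicated(met$id)) stopf("duplicate metabolite ids: %s",
    paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (anyDuplicated(rxn$id)) stopf("duplicate reaction ids: %s",
    paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  if (any(!is.finite(rxn$net_flux))) stopf("non-finite net flux")
  if (any(rxn$rho < 0 | rxn$rho >= 1))
    stopf("disequilibrium ratio must satisfy 0 <= rho < 1 (reaction %s)",
          paste(rxn$id[rxn$rho < 0 | rxn$rho >= 1], collapse = ", "))
  zero <- rxn$net_flux == 0 & !rxn$boundary
  if (any(zero))
    stopf("zero net flux on internal (non-boundary) reaction %s: scaled control coefficients undefined",
          paste(rxn$id[zero], collapse = ", "))

  groupIds <- vapply(net@moieties, function(g) g$id, "")
  bad <- !is.na(met$moiety_group) & !(met$moiety_group %in% groupIds)
  if (any(bad)) stopf("metabolite %s references undeclared moiety group %s",
                      met$id[bad][1], met$moiety_group[bad][1])
  for (g in net@moieties) {
    if (length(g$members) < 2) stopf("moiety group %s needs >= 2 members", g$id)
    if (!all(g$members %in% met$id))
      stopf("moiety group %s references unknown metabolite", g$id)
    # connected ratio graph reaching every member
    moietyRatios(net, g$id)
  }

  # regulation references must be reactants or declared modifiers
  for (i in seq_len(nrow(net@modifiers))) {
    m <- net@modifiers[i, ]
    if (!(m$reaction %in% rxn$id)) stopf("modifier row references unknown reaction %s", m$reaction)
    if (!(m$metabolite %in% met$id)) stopf("modifier metabolite %s unknown", m$metabolite)
    if (!(m$role %in% c("activator", "inhibitor")))
      stopf("modifier role must be activator or inhibitor, got %s", m$role)
  }
  for (i in seq_len(nrow(net@competitive))) {
    cp <- net@competitive[i, ]
    j <- match(cp$reaction, rxn$id)
    if (is.na(j)) stopf("competitive pair references unknown reaction %s", cp$reaction)
    if (!(cp$substrate %in% met$id && S[cp$substrate, j] < 0))
      stopf("competitive pair on %s: %s is not a substrate", cp$reaction, cp$substrate)
    if (!(cp$product %in% met$id && S[cp$product, j] > 0))
      stopf("competitive pair on %s: %s is not a product", cp$reaction, cp$product)
  }
  for (i in seq_len(nrow(net@elasticityUpper))) {
    e <- net@elasticityUpper[i, ]
    j <- match(e$reaction, rxn$id)
    if (is.na(j)) stopf("elasticity bound references unknown reaction %s", e$reaction)
    ok <- (e$metabolite %in% met$id && S[e$metabolite, j] != 0) ||
      any(net@modifiers$reaction == e$reaction & net@modifiers$metabolite == e$metabolite)
    if (!ok) stopf("elasticity bound on %s: %s is neither reactant nor modifier",
                   e$reaction, e$metabolite)
    if (e$h <= 0) stopf("elasticity upper bound must be positive")
  }
  for (grp in net@couplings) {
    if (!all(grp %in% rxn$id))
      stopf("activity coupling references unknown reaction: %s",
            paste(setdiff(grp, rxn$id), collapse = ", "))
    if (length(grp) < 2) stopf("activity coupling group needs >= 2 reactions")
  }

  # steady-state consistency of internal mass balances
  Ni <- S[met$internal, , drop = FALSE]
  imbal <- as.numeric(Ni %*% rxn$net_flux)
  scale <- max(abs(Ni) %*% abs(rxn$net_flux), 1)
  off <- abs(imbal) > tol * scale
  if (any(off))
    stopf("steady-state violation: nonzero balance for metabolite(s) %s (residual %s)",
          paste(met$id[met$internal][off], collapse = ", "),
          paste(signif(imbal[off], 4), collapse = ", "))

  # rank deficiency must equal number of independent conservations
  nCons <- length(net@moieties)
  def <- sum(met$internal) - qr(Ni)$rank
  if (def != nCons)
    stopf("rank deficiency of the stoichiometric matrix (%d) does not match the number of declared moiety conservations (%d)",
          def, nCons)
  invisible(TRUE)
}

# ---- accessors -------------------------------------------------------------

#' Network accessors
#'
#' `nMetabolites()`/`nReactions()` give the number of internal metabolites
#' (n) and reactions (m); `metaboliteIds()` and `reactionIds()` the
#' corresponding identifiers; `stoichMatrix()` the stoichiometric matrix
#' (internal rows by default); `netFluxes()` and `rhoValues()` the oriented
#' net fluxes and disequilibrium ratios.
#'
#' @param network a [MetabolicNetwork-class].
#' @param internal logical; restrict to internal metabolites.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
nMetabolites <- function(network) sum(network@metabolites$internal)

#' @rdname network-accessors
#' @export
nReactions <- function(network) nrow(network@reactions)

#' @rdname network-accessors
#' @export
metaboliteIds <- function(network, internal = TRUE) {
  if (internal) network@metabolites$id[network@metabolites$internal]
  else network@metabolites$id
}

#' @rdname network-accessors
#' @export
reactionIds <- function(network) network@reactions$id

#' @rdname network-accessors
#' @export
stoichMatrix <- function(network, internal = TRUE) {
  if (internal) network@stoich[network@metabolites$internal, , drop = FALSE]
  else network@stoich
}

#' @rdname network-accessors
#' @export
netFluxes <- function(network) setNames(network@reactions$net_flux, network@reactions$id)

#' @rdname network-accessors
#' @export
rhoValues <- function(network) setNames(network@reactions$rho, network@reactions$id)

# concentration of each group member relative to the LAST member (the
# dependent species), resolved through the connected ratio graph
moietyRatios <- function(network, groupId) {
  g <- NULL
  for (gg in network@moieties) if (gg$id == groupId) g <- gg
  if (is.null(g)) stopf("unknown moiety group %s", groupId)
  members <- g$members
  ref <- members[length(members)]
  rel <- setNames(rep(NA_real_, length(members)), members)
  rel[ref] <- 1
  edges <- g$ratios
  repeat {
    progressed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$a[i]; b <- edges$b[i]; v <- edges$value[i]
      if (v <= 0) stopf("moiety ratio %s/%s must be positive", a, b)
      if (is.na(rel[a]) && !is.na(rel[b])) { rel[a] <- v * rel[b]; progressed <- TRUE }
      if (is.na(rel[b]) && !is.na(rel[a])) { rel[b] <- rel[a] / v; progressed <- TRUE }
    }
    if (!progressed) break
  }
  if (anyNA(rel))
    stopf("moiety group %s: ratio graph does not connect member(s) %s",
          groupId, paste(names(rel)[is.na(rel)], collapse = ", "))
  rel
}

#' @describeIn MetabolicNetwork-class compact display
#' @param object a MetabolicNetwork
#' @export
setMethod("show", "MetabolicNetwork", function(object) {
  cat(sprintf("MetabolicNetwork: %d internal metabolites (%d total), %d reactions\n",
              nMetabolites(object), nrow(object@metabolites), nReactions(object)))
  cat(sprintf("  moiety groups: %d | couplings: %d | modifiers: %d | competitive pairs: %d\n",
              length(object@moieties), length(object@couplings),
              nrow(object@modifiers), nrow(object@competitive)))
  nearEq <- sum(object@reactions$rho > 0)
  cat(sprintf("  boundary reactions: %d | reactions with rho > 0: %d\n",
              sum(object@reactions$boundary), nearEq))
})
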