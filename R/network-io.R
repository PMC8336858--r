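#' Read a metabolic network from JSON
#'
#' The JSON document carries top-level keys `metabolites`, `reactions`,
#' `moieties` and `couplings`; the schema shipped at
#' `system.file("extdata", "network-schema.json", package = "mcaBounds")`
#' documents every field. Reaction stoichiometry is a map from metabolite id
#' to signed coefficient (negative = substrate). All invariants of
#' [metabolicNetwork()] are checked on load; a steady-state violation is
#' reported with the offending metabolite balances.
#'
#' @param path path to the JSON file.
#' @return a [MetabolicNetwork-class].
#' @export
loadNetwork <- function(path) {
  if (!file.exists(path)) stopf("network file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e)))
  for (key in c("metabolites", "reactions"))
    if (is.null(doc[[key]])) stopf("network JSON %s: missing top-level field '%s'", path, key)

  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stopf("network JSON: metabolite without 'id'")
    data.frame(id = m$id, name = m$name %||% m$id,
               internal = isTRUE(m$internal %||% TRUE),
               moiety_group = m$moiety_group %||% NA_character_)
  }))

  rxnRows <- list(); stoichList <- list()
  modifiers <- list(); competitive <- list(); elUpper <- list()
  for (r in doc$reactions) {
    if (is.null(r$id)) stopf("network JSON: reaction without 'id'")
    if (is.null(r$stoichiometry) || !length(r$stoichiometry))
      stopf("network JSON: reaction %s has no stoichiometry", r$id)
    if (is.null(r$net_flux)) stopf("network JSON: reaction %s missing 'net_flux'", r$id)
    rxnRows[[r$id]] <- data.frame(id = r$id, net_flux = as.numeric(r$net_flux),
                                  rho = as.numeric(r$rho %||% 0),
                                  boundary = isTRUE(r$boundary %||% FALSE))
    stoichList[[r$id]] <- unlist(r$stoichiometry)
    for (m in r$modifiers %||% list())
      modifiers[[length(modifiers) + 1]] <-
        data.frame(reaction = r$id, metabolite = m$metabolite %||% m[[1]],
                   role = m$role %||% m[[2]])
    for (cp in r$competitive_pairs %||% list())
      competitive[[length(competitive) + 1]] <-
        data.frame(reaction = r$id, substrate = cp$substrate %||% cp[[1]],
                   product = cp$product %||% cp[[2]])
    eu <- r$elasticity_upper %||% list()
    for (met in names(eu))
      elUpper[[length(elUpper) + 1]] <-
        data.frame(reaction = r$id, metabolite = met, h = as.numeric(eu[[met]]))
  }
  rxns <- do.call(rbind, rxnRows)

  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (rid in names(stoichList)) {
    st <- stoichList[[rid]]
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stopf("reaction %s: stoichiometry references unknown metabolite %s",
            rid, paste(unknown, collapse = ", "))
    S[names(st), rid] <- st
  }

  moieties <- lapply(doc$moieties %||% list(), function(g) {
    list(id = g$id, members = unlist(g$members),
         ratios = g$concentration_ratios %||% g$ratios %||% list())
  })
  couplings <- lapply(doc$couplings %||% list(), unlist)

  metabolicNetwork(mets, rxns, S,
                   modifiers = if (length(modifiers)) do.call(rbind, modifiers),
                   competitive = if (length(competitive)) do.call(rbind, competitive),
                   elasticityUpper = if (length(elUpper)) do.call(rbind, elUpper),
                   moieties = moieties, couplings = couplings)
}

#' Write a metabolic network to JSON
#'
#' Inverse of [loadNetwork()]; the written file round-trips.
#'
#' @param network a [MetabolicNetwork-class].
#' @param path output path.
#' @export
writeNetwork <- function(network, path) {
  met <- network@metabolites
  mets <- lapply(seq_len(nrow(met)), function(i) {
    out <- list(id = met$id[i], name = met$name[i], internal = met$internal[i])
    if (!is.na(met$moiety_group[i])) out$moiety_group <- met$moiety_group[i]
    out
  })
  rxn <- network@reactions
  rxns <- lapply(seq_len(nrow(rxn)), function(j) {
    st <- network@stoich[, j]
    st <- as.list(st[st != 0])
    out <- list(id = rxn$id[j], stoichiometry = st,
                net_flux = rxn$net_flux[j], rho = rxn$rho[j],
                boundary = rxn$boundary[j])
    md <- network@modifiers[network@modifiers$reaction == rxn$id[j], , drop = FALSE]
    if (nrow(md)) out$modifiers <- lapply(seq_len(nrow(md)), function(i)
      list(metabolite = md$metabolite[i], role = md$role[i]))
    cp <- network@competitive[network@competitive$reaction == rxn$id[j], , drop = FALSE]
    if (nrow(cp)) out$competitive_pairs <- lapply(seq_len(nrow(cp)), function(i)
      list(substrate = cp$substrate[i], product = cp$product[i]))
    eu <- network@elasticityUpper[network@elasticityUpper$reaction == rxn$id[j], , drop = FALSE]
    if (nrow(eu)) out$elasticity_upper <- as.list(setNames(eu$h, eu$metabolite))
    out
  })
  moieties <- lapply(network@moieties, function(g) {
    rt <- g$ratios
    list(id = g$id, members = as.list(g$members),
         concentration_ratios = as.list(setNames(rt$value, paste(rt$a, rt$b, sep = "/"))))
  })
  doc <- list(metabolites = mets, reactions = rxns, moieties = moieties,
              couplings = lapply(network@couplings, as.list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
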