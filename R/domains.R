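#' Canonical variable table for a network
#'
#' Ordering used everywhere: internal metabolite concentrations, then
#' reaction fluxes, then individual activities.
#' @param network a [MetabolicNetwork-class].
#' @return data.frame with columns `kind`, `id`.
#' @export
variableTable <- function(network) {
  data.frame(
    kind = c(rep("conc", nMetabolites(network)),
             rep("flux", nReactions(network)),
             rep("act", nReactions(network))),
    id = c(metaboliteIds(network), reactionIds(network), reactionIds(network)),
    stringsAsFactors = FALSE)
}

newDomainTable <- function(entries, enclosure, sigma) {
  stopifnot(all(c("kind", "id", "lb", "ub", "restricted") %in% names(entries)))
  bad <- entries$lb > entries$ub + 1e-12
  if (any(bad))
    stopf("empty domain (lb > ub) for %s %s", entries$kind[bad][1], entries$id[bad][1])
  new("DomainTable", entries = entries[, c("kind", "id", "lb", "ub", "restricted")],
      enclosure = enclosure, sigma = sigma)
}

#' Build initial log2 fold-change domains from measurements
#'
#' Every variable (concentration, flux, activity) starts from the generic
#' enclosure \[-E, +E\]. Measured variables are restricted to
#' \deqn{[\log_2(\mathrm{after}_{lo}) - \log_2(\mathrm{before}) + \sigma,\;
#'        \log_2(\mathrm{after}_{hi}) - \log_2(\mathrm{before}) + \sigma]}
#' clipped to the enclosure (clipping is reported with a warning: the
#' enclosure is an assumption, not data). Activities of boundary reactions
#' are slaved to their flux domains, so that the lightly modelled boundary
#' processes are forced to follow their measured fluxes.
#'
#' @param network a [MetabolicNetwork-class].
#' @param measurements data.frame with columns `kind` ("conc" or "flux"),
#'   `id`, `before` (pre-perturbation point value), `after_lo`, `after_hi`
#'   (post-perturbation interval: confidence-interval bounds for fluxes,
#'   mean +/- SD for concentrations). May also carry `act` rows for directly
#'   restricted activities. NULL for no measurements.
#' @param enclosure generic bound E in log2 units (default 3).
#' @param sigma additive volume-correction applied to every
#'   measurement-derived bound (default 0).
#' @return a [DomainTable-class].
#' @export
buildInitialDomains <- function(network, measurements = NULL, enclosure = 3,
                                sigma = 0) {
  stopifnot(enclosure > 0)
  vars <- variableTable(network)
  ent <- cbind(vars, lb = -enclosure, ub = enclosure, restricted = FALSE)

  if (!is.null(measurements) && nrow(measurements)) {
    for (i in seq_len(nrow(measurements))) {
      m <- measurements[i, ]
      k <- which(ent$kind == m$kind & ent$id == m$id)
      if (!length(k))
        stopf("measurement for unknown variable (%s, %s)", m$kind, m$id)
      if (!is.finite(m$before) || m$before <= 0)
        stopf("measurement (%s, %s): pre-perturbation value must be positive", m$kind, m$id)
      if (!is.finite(m$after_lo) || m$after_lo <= 0 || m$after_hi < m$after_lo)
        stopf("measurement (%s, %s): post-perturbation interval invalid (log undefined)", m$kind, m$id)
      lb <- log2(m$after_lo) - log2(m$before) + sigma
      ub <- log2(m$after_hi) - log2(m$before) + sigma
      if (lb < -enclosure || ub > enclosure)
        warnf("measurement (%s, %s): interval [%.3g, %.3g] clipped to the enclosure +/-%g",
              m$kind, m$id, lb, ub, enclosure)
      lb <- max(lb, -enclosure); ub <- min(ub, enclosure)
      if (lb > ub)
        stopf("measurement (%s, %s): domain empty after clipping to the enclosure", m$kind, m$id)
      ent$lb[k] <- lb; ent$ub[k] <- ub; ent$restricted[k] <- TRUE
    }
  }

  # boundary reactions: activity domains copy flux domains
  bnd <- network@reactions$id[network@reactions$boundary]
  for (rid in bnd) {
    kf <- which(ent$kind == "flux" & ent$id == rid)
    ka <- which(ent$kind == "act" & ent$id == rid)
    ent$lb[ka] <- ent$lb[kf]; ent$ub[ka] <- ent$ub[kf]
    ent$restricted[ka] <- ent$restricted[kf]
  }
  newDomainTable(ent, enclosure, sigma)
}

#' @describeIn DomainTable-class entries as a data.frame
#' @param x a DomainTable
#' @export
domainEntries <- function(x) x@entries

#' Write / read a DomainTable as TSV
#'
#' Columns: `kind`, `id`, `lb`, `ub`, `restricted` (0/1). The round trip is
#' lossless. On read, variables of the network missing from the file default
#' to the enclosure bounds with a warning; malformed rows are reported with
#' their line number.
#'
#' @param domains a [DomainTable-class].
#' @param path file path.
#' @param network the [MetabolicNetwork-class] the table refers to.
#' @param enclosure,sigma enclosure and volume-correction recorded in the
#'   rebuilt table.
#' @name domains-io
NULL

#' @rdname domains-io
#' @export
writeDomains <- function(domains, path) {
  ent <- domains@entries
  ent$restricted <- as.integer(ent$restricted)
  utils::write.table(ent, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname domains-io
#' @export
readDomains <- function(path, network, enclosure = 3, sigma = 0) {
  if (!file.exists(path)) stopf("domain file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("kind", "id", "lb", "ub", "restricted")
  if (!all(need %in% names(raw)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  for (i in seq_len(nrow(raw))) {
    if (!(raw$kind[i] %in% c("conc", "flux", "act")))
      stopf("%s line %d: unknown kind '%s'", path, i + 1L, raw$kind[i])
    if (!is.finite(raw$lb[i]) || !is.finite(raw$ub[i]))
      stopf("%s line %d: non-numeric bound", path, i + 1L)
    if (raw$lb[i] > raw$ub[i])
      stopf("%s line %d: lb > ub", path, i + 1L)
  }
  vars <- variableTable(network)
  key <- paste(vars$kind, vars$id)
  rkey <- paste(raw$kind, raw$id)
  unknown <- !(rkey %in% key)
  if (any(unknown))
    stopf("%s line %d: variable (%s, %s) not in network", path,
          which(unknown)[1] + 1L, raw$kind[unknown][1], raw$id[unknown][1])
  idx <- match(key, rkey)
  missing <- is.na(idx)
  if (any(missing))
    warnf("%s: %d variable(s) missing, defaulting to enclosure bounds [-%g, %g]",
          path, sum(missing), enclosure, enclosure)
  ent <- cbind(vars,
               lb = ifelse(missing, -enclosure, raw$lb[idx]),
               ub = ifelse(missing, enclosure, raw$ub[idx]),
               restricted = ifelse(missing, FALSE, as.logical(raw$restricted[idx])))
  newDomainTable(ent, enclosure, sigma)
}

#' Read a measurement table (TSV)
#'
#' Columns: `kind` (conc|flux|act), `id`, `before`, `after_lo`, `after_hi`.
#' @param path file path.
#' @return data.frame consumable by [buildInitialDomains()].
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path)) stopf("measurement file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("kind", "id", "before", "after_lo", "after_hi")
  if (!all(need %in% names(raw)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  raw
}

#' Write a measurement table (TSV)
#' @param measurements data.frame as produced by [simulateAdaptation()].
#' @param path file path.
#' @export
writeMeasurements <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn DomainTable-class compact display
#' @param object a DomainTable
#' @export
setMethod("show", "DomainTable", function(object) {
  ent <- object@entries
  cat(sprintf("DomainTable: %d variables (%d restricted), enclosure +/-%g, sigma %g (log2)\n",
              nrow(ent), sum(ent$restricted), object@enclosure, object@sigma))
})
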