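#' Run the sampling + contraction pipeline over an ensemble
#'
#' Repeats elasticity sampling until `nProblems` control matrices pass the
#' magnitude filter (`max|C| <= ccBound`; numerically singular samples are
#' discarded but counted as generated), formulates one bound-contraction
#' problem per accepted matrix using the shared initial domains and the
#' network's activity couplings, contracts each, and aggregates sign
#' percentages, interval unions/intersections and gains. Fully reproducible
#' from `seed`: each generated sample draws from a substream derived from
#' the root seed and the sample index, so problems are independent and any
#' execution order yields identical aggregates.
#'
#' @param network a [MetabolicNetwork-class].
#' @param domains a [DomainTable-class] of initial domains.
#' @param nProblems number of problems to formulate (default 100).
#' @param ccBound control-coefficient magnitude filter (default 3.5).
#' @param seed root seed.
#' @param eps sign tolerance passed to [contractBounds()].
#' @param maxGenerated budget of generated matrices before aborting
#'   (default `200 * nProblems`).
#' @param keepResults keep per-problem [ContractionResult-class]s in the
#'   returned list (default TRUE).
#' @return list with `summary` (an [EnsembleSummary-class]), `results`
#'   (list of ContractionResults, if kept) and `acceptedSeeds`.
#' @export
runEnsemble <- function(network, domains, nProblems = 100, ccBound = 3.5,
                        seed = 1, eps = 1e-6, maxGenerated = 200 * nProblems,
                        keepResults = TRUE) {
  nGenerated <- 0L
  accepted <- list(); acceptedSeeds <- integer(0)
  g <- 0L
  while (length(accepted) < nProblems) {
    g <- g + 1L
    if (g > maxGenerated)
      stopf("matrix acceptance rate too low: %d accepted of %d generated (budget %d); loosen ccBound or revisit the network",
            length(accepted), nGenerated, maxGenerated)
    sseed <- childSeed(seed, sprintf("sample-%d", g))
    nGenerated <- nGenerated + 1L
    sample <- sampleElasticities(network, sseed)
    C <- tryCatch(computeControlMatrix(network, sample),
                  error = function(e) NULL)
    if (is.null(C)) next  # singular: counts toward the generation tally
    if (!filterByMagnitude(C, ccBound)) next
    accepted[[length(accepted) + 1L]] <- C
    acceptedSeeds <- c(acceptedSeeds, sseed)
  }

  results <- lapply(accepted, function(C) {
    contractBounds(buildProblem(C, domains, network@couplings), eps = eps)
  })
  summary <- aggregateResults(results, nGenerated = nGenerated)
  list(summary = summary,
       results = if (keepResults) results,
       acceptedSeeds = acceptedSeeds)
}

#' Aggregate contraction results into ensemble statistics
#'
#' Sign percentages are taken over solved (feasible) problems; the mean
#' percent gain is taken over all variables and all formulated problems,
#' with infeasible problems contributing zero gain. Interval unions and
#' intersections of the final domains are coordinatewise over solved
#' problems; a union equal to the intersection marks a variable whose final
#' domain does not depend on the elasticity sampling.
#'
#' @param results list of [ContractionResult-class].
#' @param nGenerated total control matrices generated to obtain the
#'   ensemble (optional bookkeeping; defaults to the number of results).
#' @return an [EnsembleSummary-class].
#' @export
aggregateResults <- function(results, nGenerated = length(results)) {
  stopifnot(length(results) >= 1)
  feas <- vapply(results, function(r) r@feasible, TRUE)
  if (!any(feas)) stopf("no feasible problem in the ensemble")
  solved <- results[feas]
  tab0 <- solved[[1]]@table
  nv <- nrow(tab0)
  sameShape <- vapply(solved, function(r)
    identical(paste(r@table$kind, r@table$id), paste(tab0$kind, tab0$id)), TRUE)
  if (!all(sameShape)) stopf("results refer to different variable sets")

  lows <- vapply(solved, function(r) r@table$lb_final, numeric(nv))
  highs <- vapply(solved, function(r) r@table$ub_final, numeric(nv))
  signs <- vapply(solved, function(r) r@table$sign, character(nv))
  lows <- matrix(lows, nrow = nv); highs <- matrix(highs, nrow = nv)
  signs <- matrix(signs, nrow = nv)

  interLb <- apply(lows, 1, max); interUb <- apply(highs, 1, min)
  emptyInter <- interLb > interUb + 1e-12
  perVar <- data.frame(
    kind = tab0$kind, id = tab0$id,
    pct_negative = 100 * rowMeans(signs == "negative"),
    pct_positive = 100 * rowMeans(signs == "positive"),
    union_lb = apply(lows, 1, min), union_ub = apply(highs, 1, max),
    inter_lb = ifelse(emptyInter, NA_real_, interLb),
    inter_ub = ifelse(emptyInter, NA_real_, interUb),
    always_fixed = apply(signs, 1, function(s) length(unique(s)) == 1 && s[1] != "none"),
    stringsAsFactors = FALSE)

  gains <- vapply(solved, function(r) mean(r@table$gain_pct), 0)
  meanGain <- sum(gains) / length(results)  # infeasible problems: zero gain

  new("EnsembleSummary", perVariable = perVar,
      nFormulated = length(results), nSolved = length(solved),
      nDiscardedInfeasible = length(results) - length(solved),
      nGeneratedMatrices = as.integer(nGenerated),
      nAcceptedMatrices = length(results),
      meanGainPct = meanGain)
}

#' @describeIn EnsembleSummary-class per-variable statistics table
#' @param x an EnsembleSummary
#' @export
ensembleTable <- function(x) x@perVariable

#' Score a gene's driver role against the ensemble signs
#'
#' Compares the change direction expected from differential gene expression
#' with the percentages of fixed signs predicted for the affected activity.
#' With defaults `strong = 80` and `oppositeMax = 0`: the role is
#' `"supported"` when at least `strong` percent of solved problems fix the
#' expected sign and no problem fixes the opposite; `"contradicted"` when
#' the opposite sign reaches `strong`; otherwise `"supported, but sampling
#' dependent"` when the expected sign is the more frequent one and
#' `"not supported, but sampling dependent"` when it is not.
#'
#' @param summary an [EnsembleSummary-class].
#' @param activity reaction id of the affected individual activity.
#' @param expected `"-"` or `"+"`, from the expression data.
#' @param gene gene identifier carried through to the output.
#' @param strong,oppositeMax percentage thresholds.
#' @return one-row data.frame: `gene`, `activity`, `expected`, `pct_same`,
#'   `pct_opposite`, `verdict`.
#' @export
scoreDriver <- function(summary, activity, expected = c("-", "+"),
                        gene = activity, strong = 80, oppositeMax = 0) {
  expected <- match.arg(expected)
  pv <- summary@perVariable
  k <- which(pv$kind == "act" & pv$id == activity)
  if (!length(k)) stopf("activity %s not present in the ensemble summary", activity)
  pctSame <- if (expected == "-") pv$pct_negative[k] else pv$pct_positive[k]
  pctOpp <- if (expected == "-") pv$pct_positive[k] else pv$pct_negative[k]
  verdict <- if (pctOpp >= strong) "contradicted"
  else if (pctSame >= strong && pctOpp <= oppositeMax) "supported"
  else if (pctSame > pctOpp) "supported, but sampling dependent"
  else "not supported, but sampling dependent"
  data.frame(gene = gene, activity = activity, expected = expected,
             pct_same = pctSame, pct_opposite = pctOpp, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Driver report for a table of expectations
#'
#' @param summary an [EnsembleSummary-class].
#' @param expectations data.frame with columns `gene`, `activity`,
#'   `expected` ("-" or "+").
#' @param strong,oppositeMax thresholds passed to [scoreDriver()].
#' @return data.frame, one row per gene.
#' @export
driverReport <- function(summary, expectations, strong = 80, oppositeMax = 0) {
  do.call(rbind, lapply(seq_len(nrow(expectations)), function(i)
    scoreDriver(summary, expectations$activity[i], expectations$expected[i],
                gene = expectations$gene[i], strong = strong,
                oppositeMax = oppositeMax)))
}

#' Write an ensemble summary as TSV
#' @param summary an [EnsembleSummary-class].
#' @param path file path.
#' @export
writeEnsembleSummary <- function(summary, path) {
  utils::write.table(summary@perVariable, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn EnsembleSummary-class compact display
#' @param object an EnsembleSummary
#' @export
setMethod("show", "EnsembleSummary", function(object) {
  pv <- object@perVariable
  cat(sprintf("EnsembleSummary: %d formulated, %d solved, %d infeasible (matrices: %d generated, %d accepted)\n",
              object@nFormulated, object@nSolved, object@nDiscardedInfeasible,
              object@nGeneratedMatrices, object@nAcceptedMatrices))
  cat(sprintf("  mean %% gain over formulated problems: %.1f\n", object@meanGainPct))
  fixedAny <- pv$pct_negative + pv$pct_positive > 0
  cat(sprintf("  variables with a fixed sign in >=1 solved problem: %d (in all: %d)\n",
              sum(fixedAny), sum(pv$always_fixed)))
})
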