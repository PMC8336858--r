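#' Assemble the bound-contraction linear program
#'
#' Builds the equality system linking the n + 2m log2 fold-change variables:
#' one row per internal metabolite
#' (\eqn{-\Delta\log x_i + \sum_k C^{x_i}_{v_k}\Delta\log v_k = 0}),
#' one per flux
#' (\eqn{-\Delta\log J_j + \sum_k C^{J_j}_{v_k}\Delta\log v_k = 0}),
#' and one per activity-coupling equality
#' (\eqn{\Delta\log v_a - \Delta\log v_b = 0}), with the initial domains as
#' box bounds.
#'
#' @param C a [ControlMatrix-class].
#' @param domains a [DomainTable-class] (canonical variable order).
#' @param couplings list of character vectors of reaction ids; defaults to
#'   the empty list. Pass `network@couplings` to use the network's groups.
#' @return an [LPProblem-class].
#' @export
buildProblem <- function(C, domains, couplings = list()) {
  ent <- domains@entries
  mets <- rownames(C@conc) %||% character(0); rxns <- colnames(C@flux)
  n <- length(mets); m <- length(rxns)
  expected <- c(if (n) paste("conc", mets), paste("flux", rxns),
                paste("act", rxns))
  if (!identical(paste(ent$kind, ent$id), expected))
    stopf("domain table does not match the control matrix (expect %d conc + %d flux + %d act rows in canonical order)",
          n, m, m)

  nc <- sum(lengths(couplings) - 1L)
  A <- matrix(0, n + m + nc, n + 2 * m)
  if (n) {
    A[seq_len(n), seq_len(n)] <- -diag(n)
    A[seq_len(n), n + m + seq_len(m)] <- C@conc
  }
  A[n + seq_len(m), n + seq_len(m)] <- -diag(m)
  A[n + seq_len(m), n + m + seq_len(m)] <- C@flux
  row <- n + m
  for (grp in couplings) {
    idx <- match(grp, rxns)
    if (anyNA(idx))
      stopf("activity coupling references unknown reaction %s", grp[is.na(idx)][1])
    for (k in idx[-1]) {
      row <- row + 1L
      A[row, n + m + idx[1]] <- 1
      A[row, n + m + k] <- -1
    }
  }
  new("LPProblem", variables = ent[, c("kind", "id")], A = A,
      lb = ent$lb, ub = ent$ub, nCouplingRows = as.integer(nc))
}

#' Is the constraint polytope nonempty?
#'
#' Decides feasibility of the complete problem with one phase-1 LP. A
#' formulation whose measurements are incompatible with the control
#' coefficients and couplings is infeasible and discarded by the ensemble.
#'
#' @param problem an [LPProblem-class].
#' @return logical.
#' @export
checkFeasible <- function(problem) {
  r <- .lp_solve_cpp(problem@A, rep(0, nrow(problem@A)), problem@lb,
                     problem@ub, rep(0, ncol(problem@A)), FALSE)
  if (identical(r$status, "numerical")) stopf("LP solver failure (not an infeasibility)")
  identical(r$status, "optimal")
}

#' Contract every variable's domain to its tightest interval
#'
#' For each of the n + 2m variables the LP is solved twice, minimising then
#' maximising that variable over the constraint polytope: 2n + 4m
#' optimisations in total, each to proven optimality. The final interval of
#' a variable is the exact projection of the polytope onto that coordinate,
#' so final domains are always contained in initial ones and a second
#' contraction run reproduces them.
#'
#' @param problem an [LPProblem-class].
#' @param eps sign-classification tolerance in log2 units (default 1e-6): a
#'   fixed sign must exclude zero by more than `eps`.
#' @param dedupe if TRUE, activities made redundant by coupling rows are
#'   solved once per coupling group and copied; default FALSE executes every
#'   LP.
#' @return a [ContractionResult-class]; infeasible problems are flagged with
#'   an empty table.
#' @export
contractBounds <- function(problem, eps = 1e-6, dedupe = FALSE) {
  A <- problem@A; b <- rep(0, nrow(A))
  vars <- problem@variables
  N <- ncol(A)

  if (!dedupe) {
    r <- .lp_contract_cpp(A, b, problem@lb, problem@ub)
    if (!isTRUE(r$feasible))
      return(new("ContractionResult", table = emptyContractionTable(),
                 feasible = FALSE, lpCount = 0L))
    lo <- r$lo; hi <- r$hi; lpCount <- r$lp_count
  } else {
    if (!checkFeasible(problem))
      return(new("ContractionResult", table = emptyContractionTable(),
                 feasible = FALSE, lpCount = 0L))
    # leader of each coupled activity group solves; members copy
    leader <- seq_len(N)
    n <- sum(vars$kind == "conc"); m <- sum(vars$kind == "flux")
    crows <- which(seq_len(nrow(A)) > n + m)
    for (rw in crows) {
      cols <- which(A[rw, ] != 0)
      leader[max(cols)] <- leader[min(cols)]
    }
    lo <- hi <- numeric(N); lpCount <- 0L
    for (j in seq_len(N)) {
      if (leader[j] != j) { lo[j] <- lo[leader[j]]; hi[j] <- hi[leader[j]]; next }
      cj <- replace(numeric(N), j, 1)
      rmin <- .lp_solve_cpp(A, b, problem@lb, problem@ub, cj, FALSE)
      rmax <- .lp_solve_cpp(A, b, problem@lb, problem@ub, cj, TRUE)
      if (!identical(rmin$status, "optimal") || !identical(rmax$status, "optimal"))
        stopf("internal error: per-variable LP not optimal on a feasible problem")
      lo[j] <- rmin$value; hi[j] <- rmax$value; lpCount <- lpCount + 2L
    }
  }

  # guard roundoff: the projection is contained in the box by construction
  lo <- pmax(lo, problem@lb); hi <- pmin(hi, problem@ub)
  tab <- data.frame(kind = vars$kind, id = vars$id,
                    lb_init = problem@lb, ub_init = problem@ub,
                    lb_final = lo, ub_final = hi,
                    gain_pct = percentageGain(problem@lb, problem@ub, lo, hi),
                    sign = classifySign(lo, hi, eps),
                    stringsAsFactors = FALSE)
  new("ContractionResult", table = tab, feasible = TRUE,
      lpCount = as.integer(lpCount))
}

emptyContractionTable <- function() {
  data.frame(kind = character(0), id = character(0), lb_init = numeric(0),
             ub_init = numeric(0), lb_final = numeric(0), ub_final = numeric(0),
             gain_pct = numeric(0), sign = character(0))
}

#' Classify the sign of a final domain
#'
#' A domain is a required increase ("positive") if its lower bound exceeds
#' `eps`, a required decrease ("negative") if its upper bound is below
#' `-eps`, and unsigned otherwise; a bound exactly at zero does not fix a
#' sign, since a required change must exclude zero.
#'
#' @param lb,ub interval bounds (vectorised).
#' @param eps tolerance in log2 units (default 1e-6).
#' @return character vector in `{"negative", "positive", "none"}`.
#' @export
classifySign <- function(lb, ub, eps = 1e-6) {
  stopifnot(all(lb <= ub + 1e-12))
  ifelse(lb > eps, "positive", ifelse(ub < -eps, "negative", "none"))
}

#' Percent reduction of a domain after contraction
#'
#' `100 * (initial width - final width) / initial width`; a variable whose
#' initial domain is already a point has gain 0.
#'
#' @param lb_init,ub_init,lb_final,ub_final interval bounds (vectorised).
#' @return percent gains in \[0, 100\].
#' @export
percentageGain <- function(lb_init, ub_init, lb_final, ub_final) {
  wi <- ub_init - lb_init
  wf <- pmax(ub_final - lb_final, 0)
  ifelse(wi <= 0, 0, pmin(pmax(100 * (wi - wf) / wi, 0), 100))
}

#' Write / read a contraction result as TSV
#'
#' Columns: `kind`, `id`, `lb_init`, `ub_init`, `lb_final`, `ub_final`,
#' `gain_pct`, `sign`.
#' @param result a [ContractionResult-class].
#' @param path file path.
#' @name contraction-io
NULL

#' @rdname contraction-io
#' @export
writeContraction <- function(result, path) {
  utils::write.table(result@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname contraction-io
#' @export
readContraction <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  new("ContractionResult", table = tab, feasible = nrow(tab) > 0,
      lpCount = NA_integer_)
}

#' @describeIn ContractionResult-class final-domain table
#' @param x a ContractionResult
#' @export
contractionTable <- function(x) x@table

#' @describeIn ContractionResult-class compact display
#' @param object a ContractionResult
#' @export
setMethod("show", "ContractionResult", function(object) {
  if (!object@feasible) {
    cat("ContractionResult: infeasible problem (no final domains)\n")
    return(invisible(NULL))
  }
  tab <- object@table
  cat(sprintf("ContractionResult: %d variables, %d LPs, mean gain %.1f%%\n",
              nrow(tab), object@lpCount, mean(tab$gain_pct)))
  fixed <- tab[tab$sign != "none", ]
  cat(sprintf("  fixed signs: %d negative, %d positive\n",
              sum(fixed$sign == "negative"), sum(fixed$sign == "positive")))
})

#' @describeIn LPProblem-class compact display
#' @param object an LPProblem
#' @export
setMethod("show", "LPProblem", function(object) {
  cat(sprintf("LPProblem: %d variables, %d equality rows (%d coupling)\n",
              ncol(object@A), nrow(object@A), object@nCouplingRows))
})
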