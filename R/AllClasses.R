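#' @import methods
NULL

#' MetabolicNetwork: stoichiometry, fluxes, thermodynamics and regulation
#'
#' Container for a metabolic network at a reference steady state: the
#' stoichiometric matrix over all metabolites (internal metabolites enter the
#' mass balance, external ones are fixed boundary species), net fluxes and
#' disequilibrium ratios per reaction, allosteric modifiers, declared
#' substrate/product competitive pairs, per-reactant elasticity upper bounds
#' (Hill coefficients), moiety-conservation groups with literature
#' concentration ratios, and activity-coupling groups (sets of reactions whose
#' log-fold activity changes are constrained to be equal).
#'
#' Reactions are oriented so that every net flux is nonnegative; input with a
#' negative net flux is flipped at load time. The disequilibrium ratio
#' \eqn{\rho = v_r/v_f} always refers to the oriented (positive-flux)
#' direction and must satisfy \eqn{0 \le \rho < 1}; \eqn{\rho \to 1} is
#' chemical equilibrium, where net-rate elasticities diverge.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `internal`
#'   (logical), `moiety_group` (character, `NA` if none).
#' @slot reactions data.frame with columns `id`, `net_flux`, `rho`,
#'   `boundary` (logical: simplified boundary process whose activity domain is
#'   slaved to its flux domain).
#' @slot stoich numeric matrix, all metabolites x reactions; negative
#'   coefficients are substrates of the oriented reaction.
#' @slot modifiers data.frame with columns `reaction`, `metabolite`, `role`
#'   (`"activator"` or `"inhibitor"`).
#' @slot competitive data.frame with columns `reaction`, `substrate`,
#'   `product`: declared competitive substrate/product pairs.
#' @slot elasticityUpper data.frame with columns `reaction`, `metabolite`,
#'   `h`: saturation bound overrides (default 1 elsewhere).
#' @slot moieties list; each element `list(id, members, ratios)` where
#'   `ratios` is a data.frame with columns `a`, `b`, `value` meaning
#'   concentration ratio a/b.
#' @slot couplings list of character vectors of reaction ids whose activity
#'   changes are equal.
#' @export
setClass("MetabolicNetwork",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoich = "matrix",
    modifiers = "data.frame",
    competitive = "data.frame",
    elasticityUpper = "data.frame",
    moieties = "list",
    couplings = "list"
  )
)

#' ElasticitySample: one draw of scaled metabolite elasticities
#'
#' Scaled elasticities \eqn{\partial \log v / \partial \log x} of the
#' forward, reverse and net rates of every reaction with respect to every
#' internal metabolite. Matrices are reactions x internal metabolites, with
#' zero entries for metabolites that do not act on a reaction. Net-rate
#' elasticities include allosteric modifier contributions.
#'
#' @slot forward,reverse,net numeric matrices (m x n).
#' @slot seed integer seed the sample was drawn from (NA for exact samples
#'   computed from a kinetic model).
#' @slot rhoUsed named numeric, disequilibrium ratio per reaction.
#' @export
setClass("ElasticitySample",
  representation(forward = "matrix", reverse = "matrix", net = "matrix",
                 seed = "integer", rhoUsed = "numeric")
)

#' ControlMatrix: scaled concentration and flux control coefficients
#'
#' @slot conc numeric n x m matrix; entry (i, k) is the scaled control
#'   coefficient of activity k over concentration i.
#' @slot flux numeric m x m matrix; entry (j, k) is the scaled control
#'   coefficient of activity k over flux j.
#' @slot provenance character, free-form note on how the matrix was obtained
#'   (seed / sample id).
#' @slot maxAbs numeric, largest absolute control coefficient.
#' @export
setClass("ControlMatrix",
  representation(conc = "matrix", flux = "matrix",
                 provenance = "character", maxAbs = "numeric")
)

#' DomainTable: per-variable log2 fold-change intervals
#'
#' One row per variable of the contraction problem, in canonical order:
#' internal metabolite concentrations, then reaction fluxes, then individual
#' activities. Bounds are log2 fold changes between the states before and
#' after the adaptation. `restricted` marks experimentally restricted
#' domains, as opposed to the generic enclosure \[-E, +E\].
#'
#' @slot entries data.frame with columns `kind` ("conc", "flux", "act"),
#'   `id`, `lb`, `ub`, `restricted` (logical).
#' @slot enclosure numeric scalar E, the generic bound (default 3).
#' @slot sigma numeric scalar, additive volume-correction applied to all
#'   measurement-derived bounds (default 0).
#' @export
setClass("DomainTable",
  representation(entries = "data.frame", enclosure = "numeric",
                 sigma = "numeric")
)

#' LPProblem: the assembled bound-contraction linear program
#'
#' Variables are the n + 2m log2 fold changes (concentrations, fluxes,
#' activities). Equality rows encode, for every internal metabolite i and
#' flux j,
#' \deqn{-\Delta\log x_i + \sum_k C^{x_i}_{v_k} \Delta\log v_k = 0, \qquad
#'       -\Delta\log J_j + \sum_k C^{J_j}_{v_k} \Delta\log v_k = 0,}
#' plus one row per activity-coupling equality. Box bounds come from the
#' initial DomainTable.
#'
#' @slot variables data.frame with columns `kind`, `id` (length n + 2m).
#' @slot A numeric equality matrix, (n + m + c) x (n + 2m).
#' @slot lb,ub numeric box bounds per variable.
#' @slot nCouplingRows integer, number of coupling rows appended.
#' @export
setClass("LPProblem",
  representation(variables = "data.frame", A = "matrix",
                 lb = "numeric", ub = "numeric", nCouplingRows = "integer")
)

#' ContractionResult: final domains, gains and signs for one problem
#'
#' @slot table data.frame with one row per variable: `kind`, `id`,
#'   `lb_init`, `ub_init`, `lb_final`, `ub_final`, `gain_pct`, `sign`
#'   ("negative", "positive" or "none").
#' @slot feasible logical; if FALSE the table slot is empty.
#' @slot lpCount integer, number of LP optimisations executed (2n + 4m for a
#'   feasible problem).
#' @export
setClass("ContractionResult",
  representation(table = "data.frame", feasible = "logical",
                 lpCount = "integer")
)

#' EnsembleSummary: aggregated contraction statistics over an ensemble
#'
#' @slot perVariable data.frame: `kind`, `id`, `pct_negative`,
#'   `pct_positive` (percent of solved problems with that fixed sign),
#'   `union_lb`, `union_ub`, `inter_lb`, `inter_ub` (coordinatewise union and
#'   intersection of final domains over solved problems; the intersection is
#'   `NA` when empty), `always_fixed` (fixed sign in every solved problem).
#' @slot nFormulated,nSolved,nDiscardedInfeasible integer problem counts.
#' @slot nGeneratedMatrices,nAcceptedMatrices integer tallies of the
#'   control-matrix screening.
#' @slot meanGainPct numeric: mean percent gain over all variables and all
#'   formulated problems (infeasible problems contribute zero gain).
#' @export
setClass("EnsembleSummary",
  representation(perVariable = "data.frame",
                 nFormulated = "integer", nSolved = "integer",
                 nDiscardedInfeasible = "integer",
                 nGeneratedMatrices = "integer",
                 nAcceptedMatrices = "integer",
                 meanGainPct = "numeric")
)

#' KineticModel: a small kinetic model with explicit rate laws
#'
#' Fixture models pair a MetabolicNetwork with mass-action, reversible
#' Michaelis-Menten or Hill rate laws so that steady states, exact
#' elasticities, ground-truth control coefficients and simulated adaptations
#' can be computed and used as oracles for the sampling-based pipeline.
#'
#' @slot network a MetabolicNetwork (net fluxes are filled in from the solved
#'   steady state).
#' @slot rateLaws named list, one per reaction:
#'   `list(type = "mass_action"|"michaelis_menten"|"hill", ...params)`.
#' @slot totals named numeric, conserved total per moiety group id.
#' @slot externals named numeric, fixed concentrations of external species.
#' @export
setClass("KineticModel",
  representation(network = "MetabolicNetwork", rateLaws = "list",
                 totals = "numeric", externals = "numeric")
)
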