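# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# all vertices of {A z = b, lb <= z <= ub} by enumerating active-bound sets;
# returns per-coordinate min/max, or NULL if the polytope is empty
vertexMinMax <- function(A, b, lb, ub, tol = 1e-9) {
  nv <- ncol(A)
  r <- qr(A)$rank
  free <- nv - r
  verts <- list()
  fixSets <- if (free == 0) list(integer(0)) else
    utils::combn(nv, free, simplify = FALSE)
  for (fix in fixSets) {
    rest <- setdiff(seq_len(nv), fix)
    Ar <- A[, rest, drop = FALSE]
    if (qr(Ar)$rank < length(rest)) next
    nmask <- if (length(fix)) 2^length(fix) else 1
    for (mask in seq_len(nmask) - 1) {
      zf <- if (length(fix)) {
        ifelse(bitwAnd(mask, 2^(seq_along(fix) - 1)) > 0, ub[fix], lb[fix])
      } else numeric(0)
      rhs <- b - if (length(fix)) A[, fix, drop = FALSE] %*% zf else 0
      zr <- tryCatch(qr.solve(Ar, rhs), error = function(e) NULL)
      if (is.null(zr)) next
      z <- numeric(nv); z[fix] <- zf; z[rest] <- zr
      if (all(z >= lb - tol) && all(z <= ub + tol) &&
          max(abs(A %*% z - b)) < 1e-7)
        verts[[length(verts) + 1]] <- pmin(pmax(z, lb), ub)
    }
  }
  if (!length(verts)) return(NULL)
  V <- do.call(rbind, verts)
  list(lo = apply(V, 2, min), hi = apply(V, 2, max))
}

# LP via boot::simplex (demonstration-quality reference backend):
# max/min c'z s.t. A z = b, lb <= z <= ub. Requires nonnegative RHS after
# the shift, handled by row negation.
bootLP <- function(A, b, lb, ub, cc, maximize = TRUE) {
  nv <- ncol(A)
  b2 <- as.numeric(b - A %*% lb)
  s <- ifelse(b2 < 0, -1, 1)
  r <- tryCatch(boot::simplex(a = cc, A1 = diag(nv), b1 = ub - lb,
                              A3 = A * s, b3 = b2 * s, maxi = maximize),
                error = function(e) NULL)
  if (is.null(r) || r$solved != 1) return(NULL)
  list(value = unname(r$value + sum(cc * lb)),
       x = unname(r$soln[seq_len(nv)] + lb))
}

# random box domains around zero for a network's contraction problem
randomDomains <- function(network, enclosure = 3) {
  dom <- buildInitialDomains(network, enclosure = enclosure)
  ent <- domainEntries(dom)
  pick <- sample(nrow(ent), max(1, nrow(ent) %/% 3))
  for (k in pick) {
    c0 <- runif(1, -1, 1); w <- runif(1, 0.05, 1.5)
    ent$lb[k] <- max(c0 - w, -enclosure); ent$ub[k] <- min(c0 + w, enclosure)
    ent$restricted[k] <- TRUE
  }
  dm <- dom
  dm@entries <- ent
  dm
}
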