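# Independent oracles used across the test files.

# Brute-force structural rank: maximum over all subsets of entries that
# share no row or column (recursive matching enumeration).
brute_structural_rank <- function(P) {
  P <- P != 0
  recurse <- function(rows, cols) {
    if (length(rows) == 0 || length(cols) == 0) return(0L)
    r <- rows[1]
    best <- recurse(rows[-1], cols)  # skip this row
    for (ci in seq_along(cols)) {
      if (P[r, cols[ci]]) {
        best <- max(best, 1L + recurse(rows[-1], cols[-ci]))
      }
    }
    best
  }
  recurse(seq_len(nrow(P)), seq_len(ncol(P)))
}

# Enumerate the vertices of {v : S v = 0, extra fixed rows, lb <= v <= ub}
# by fixing (n - rank) variables at a bound and solving for the rest.
enumerate_vertices <- function(network, fixed = NULL, tol = 1e-8) {
  S <- network$S
  lb <- unname(network$lb)
  ub <- unname(network$ub)
  A <- S
  b <- rep(0, nrow(S))
  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      row <- rep(0, ncol(S))
      row[match(nm, network$rxns)] <- 1
      A <- rbind(A, row)
      b <- c(b, fixed[[nm]])
    }
  }
  n <- ncol(A)
  r <- qr(A)$rank
  nfix <- n - r
  verts <- list()
  if (nfix == 0) {
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(sol) && all(sol >= lb - tol) && all(sol <= ub + tol)) {
      verts[[1]] <- sol
    }
  } else {
    combos <- utils::combn(n, nfix)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      bounds_grid <- expand.grid(rep(list(c("lb", "ub")), nfix),
                                 stringsAsFactors = FALSE)
      for (gi in seq_len(nrow(bounds_grid))) {
        vfix <- ifelse(unlist(bounds_grid[gi, ]) == "lb", lb[idx], ub[idx])
        free <- setdiff(seq_len(n), idx)
        Af <- A[, free, drop = FALSE]
        if (qr(Af)$rank < length(free)) next
        rhs <- b - as.numeric(A[, idx, drop = FALSE] %*% vfix)
        sol_free <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
        if (is.null(sol_free)) next
        v <- numeric(n)
        v[idx] <- vfix
        v[free] <- sol_free
        if (max(abs(A %*% v - b)) > tol) next
        if (all(v >= lb - tol) && all(v <= ub + tol)) {
          verts[[length(verts) + 1]] <- v
        }
      }
    }
  }
  if (length(verts) == 0) return(NULL)
  out <- unique(round(do.call(rbind, verts), 9))
  colnames(out) <- network$rxns
  out
}

# small fully-determined linear chain network used in several FBA tests
chain_network <- function(uptake_ub = 10) {
  metabolic_network(data.frame(
    id = c("up", "conv", "bio"),
    equation = c("-> A", "A -> B", "B ->"),
    lb = 0, ub = c(uptake_ub, 1000, 1000),
    stringsAsFactors = FALSE), biomass = "bio", uptakes = "up")
}

default_truth <- list(Keq = 0.02, K5 = 654.6, k4 = 154.763368675,
                      pp = c(CAA = 1.0, CAA_fructose = 0.49,
                             CAA_glucose = 0.05))
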