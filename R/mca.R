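# Metabolic control analysis utilities: structural rank of an elasticity
# pattern and concentration control coefficients for a network partitioned
# into unknown and measured (known) rates.

#' Structural rank of a zero/nonzero pattern
#'
#' The maximum rank any numeric matrix with the given sparsity pattern can
#' attain; equals the size of a maximum bipartite matching between rows and
#' columns over the nonzero entries.  Used as a screen before inverting an
#' elasticity matrix whose entries are only known up to pattern.
#'
#' @param pattern_matrix numeric or logical matrix; nonzero/TRUE entries
#'   mark structurally nonzero positions.
#' @return Integer structural rank.
#' @examples
#' structural_rank(matrix(c(1, 1, 0, 0), 2))  # rank 1
#' structural_rank(diag(2))                   # rank 2
#' @export
structural_rank <- function(pattern_matrix) {
  P <- pattern_matrix != 0
  nr <- nrow(P); nc <- ncol(P)
  idx <- which(P, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)),
    edges = as.vector(t(cbind(idx[, 1], nr + idx[, 2]))))
  as.integer(igraph::max_bipartite_match(g)$matching_size)
}

#' Concentration control coefficients
#'
#' For a network split into unknown rates (stoichiometry `N_u`) and
#' measured rates (`N_kn`) whose derivative with respect to the chosen
#' input flux is `beta`, the steady-state concentration response to the
#' input satisfies `epsilon %*% dc/du = -solve(N_u) %*% N_kn %*% beta`,
#' where `epsilon` is the elasticity matrix of the unknown rates.  The
#' elasticity matrix must have full structural rank (screened) and be
#' numerically invertible.
#'
#' @param problem a list with elements `epsilon` (elasticities, rates x
#'   concentrations), `N_u` (stoichiometry of unknown rates), `N_kn`
#'   (stoichiometry of known rates), `beta` (derivative of the known rates
#'   with respect to the input).
#' @return Numeric vector `dc/du` of concentration control coefficients
#'   (named by `colnames(epsilon)` when present).
#' @export
concentration_control <- function(problem) {
  eps <- as.matrix(problem$epsilon)
  N_u <- as.matrix(problem$N_u)
  N_kn <- as.matrix(problem$N_kn)
  beta <- as.numeric(problem$beta)
  if (nrow(eps) != ncol(eps)) {
    stop("elasticity matrix must be square", call. = FALSE)
  }
  sr <- structural_rank(eps)
  if (sr < ncol(eps)) {
    stop("elasticity matrix is structurally singular (structural rank ",
         sr, " < ", ncol(eps), "); control coefficients not computable",
         call. = FALSE)
  }
  rhs <- -solve(N_u, N_kn %*% beta)
  out <- tryCatch(solve(eps, rhs), error = function(e) {
    stop("elasticity matrix is numerically singular despite passing the ",
         "structural-rank screen", call. = FALSE)
  })
  stats::setNames(as.numeric(out), colnames(eps))
}

#' The reduced PEP/pyruvate node as an MCA problem
#'
#' Builds the two-metabolite problem for the lumped node: unknown rates
#' `rc` (pyruvate -> PEP, PEP synthase) and `rd` (PEP -> upper glycolysis),
#' known rates `ra` (input via oxaloacetate) and `rb = rb_s + k (ra - ra_s)`
#' (lumped pyruvate drain, slope `k`).  Elasticities follow the power-law
#' rate laws `rc = kc * Pyr^nc`, `rd = kd * PEP^nd` at the steady state for
#' input `ra` (so `eps_c = nc * rc / Pyr`, `eps_d = nd * rd / PEP`).
#'
#' @param fit a [fit_powerlaw_two_points()] result.
#' @param ra input flux.
#' @param k drain slope in `[0, 1)`.
#' @return A problem list for [concentration_control()]; concentrations
#'   are ordered `(PEP, Pyr)`.
#' @export
reduced_node_problem <- function(fit, ra, k) {
  ss <- reduced_steady_state(ra, k, fit)
  rc <- (1 - k) * ra
  eps_c <- fit$nc * rc / ss$Pyr
  eps_d <- fit$nd * rc / ss$PEP
  list(
    epsilon = matrix(c(0, eps_d, eps_c, 0), 2, 2,
                     dimnames = list(c("rc", "rd"), c("PEP", "Pyr"))),
    N_u = matrix(c(1, -1, -1, 0), 2, 2,
                 dimnames = list(c("PEP", "Pyr"), c("rc", "rd"))),
    N_kn = matrix(c(0, 1, 0, -1), 2, 2,
                  dimnames = list(c("PEP", "Pyr"), c("ra", "rb"))),
    beta = c(ra = 1, rb = k))
}
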