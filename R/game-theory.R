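#' Payoff matrices and the temporal-network game transform
#'
#' A symmetric n-strategy pairwise game is an n x n matrix A with
#' `A[i, j]` the payoff to a row player using strategy i against strategy j.
#' On activity-driven temporal networks, weak-selection dynamics are governed
#' not by A but by the transformed matrix A' = alpha1 * A + alpha2 * B, where
#' B = A - t(A) is the antisymmetric local-competition matrix (a zero-sum
#' "spite" component: what one strategy gains in a local pairwise comparison
#' the other loses) and the weights alpha1, alpha2 depend only on the
#' selection intensity and the network parameters.
#'
#' @name game_theory
NULL

#' Construct a payoff matrix
#'
#' @param entries square numeric matrix (payoff to row against column).
#' @param labels optional strategy names (defaults to s1, s2, ...).
#' @return a `payoff_matrix` (a classed matrix with dimnames).
#' @export
payoff_matrix <- function(entries, labels = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries))
    stop("payoff matrix must be square, got ", nrow(entries), " x ",
         ncol(entries))
  if (nrow(entries) < 2) stop("need at least 2 strategies")
  if (!all(is.finite(entries))) stop("payoff entries must be finite")
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(entries)))
  if (length(labels) != nrow(entries))
    stop("need one label per strategy")
  dimnames(entries) <- list(labels, labels)
  class(entries) <- c("payoff_matrix", class(entries))
  entries
}

as_payoff <- function(A) {
  if (inherits(A, "payoff_matrix")) A else payoff_matrix(A)
}

#' Local-competition matrix B = A - t(A)
#'
#' Antisymmetric part (times two) of the game: b_ij = a_ij - a_ji measures
#' the net payoff advantage of strategy i over j in their direct pairwise
#' encounter. B satisfies B = -t(B) and x' B x = 0 for every frequency
#' vector x, so it never changes the population mean payoff.
#'
#' @param A square payoff matrix.
#' @return matrix B of the same dimension.
#' @export
local_competition_matrix <- function(A) {
  A <- as_payoff(A)
  B <- unclass(A) - t(unclass(A))
  B
}

#' Selection weights alpha1, alpha2 for the temporal-network transform
#'
#' With selection intensity beta, links-per-activation m, window length
#' delta and activity moments <a>, <a^2>:
#' \deqn{\alpha_1 = \beta (3 m \delta \langle a\rangle^2 +
#'   m \delta \langle a^2\rangle - 2\langle a\rangle)/2, \qquad
#'   \alpha_2 = \beta \langle a\rangle.}
#' The normalized weight \eqn{\bar\alpha_2 = \alpha_2/(\alpha_1+\alpha_2)
#'   = 2\langle a\rangle / (m\delta(3\langle a\rangle^2 +
#'   \langle a^2\rangle))} is beta-free and alone fixes the phase portrait
#' (only the direction of A' matters, not its scale). Both forms are
#' computed and cross-checked.
#'
#' @param beta selection intensity (>= 0).
#' @param m links per activation.
#' @param delta window length.
#' @param dist an [activity_dist].
#' @return list with `alpha1`, `alpha2`, `alpha2_norm`.
#' @export
selection_weights <- function(beta, m, delta, dist) {
  stopifnot(beta >= 0, m >= 1, delta >= 1)
  mu1 <- activity_moment(dist, 1)
  mu2 <- activity_moment(dist, 2)
  alpha1 <- beta * (3 * m * delta * mu1^2 + m * delta * mu2 - 2 * mu1) / 2
  alpha2 <- beta * mu1
  if (alpha1 + alpha2 == 0) {
    warning("alpha1 + alpha2 = 0 (beta = 0?): normalized weight undefined")
    norm <- NaN
  } else {
    norm <- alpha2 / (alpha1 + alpha2)
    closed <- 2 * mu1 / (m * delta * (3 * mu1^2 + mu2))
    if (abs(norm - closed) > 1e-10 * max(1, abs(norm)))
      stop("internal inconsistency in normalized weight: ", norm, " vs ",
           closed)
  }
  list(alpha1 = alpha1, alpha2 = alpha2, alpha2_norm = norm)
}

#' Transformed payoff matrix A' = alpha1 A + alpha2 B
#'
#' Off-diagonal entries are (alpha1 + alpha2) a_ij - alpha2 a_ji and the
#' diagonal is alpha1 * diag(A); this is identical, entry by entry, to
#' alpha1 * A + alpha2 * (A - t(A)), and both routes are computed and
#' compared internally.
#'
#' @param A payoff matrix.
#' @param alpha1,alpha2 selection weights (see [selection_weights()]), or
#'   any reals when studying the dynamics abstractly.
#' @return object of class `transformed_game` with fields `base`, `alpha1`,
#'   `alpha2`, `B`, `A_prime`, `alpha2_norm`.
#' @export
transformed_matrix <- function(A, alpha1, alpha2) {
  A <- as_payoff(A)
  B <- local_competition_matrix(A)
  Ap_lin <- alpha1 * unclass(A) + alpha2 * B
  Ap_ent <- (alpha1 + alpha2) * unclass(A) - alpha2 * t(unclass(A))
  diag(Ap_ent) <- alpha1 * diag(unclass(A))
  if (max(abs(Ap_lin - Ap_ent)) > 1e-12 * max(1, max(abs(Ap_lin))))
    stop("internal inconsistency building transformed matrix")
  structure(list(base = A, alpha1 = alpha1, alpha2 = alpha2, B = B,
                 A_prime = Ap_lin,
                 alpha2_norm = if (alpha1 + alpha2 != 0)
                   alpha2 / (alpha1 + alpha2) else NaN),
            class = "transformed_game")
}

#' @export
print.transformed_game <- function(x, ...) {
  cat("transformed game A' = alpha1*A + alpha2*B  (alpha1 =", x$alpha1,
      ", alpha2 =", x$alpha2, ", normalized alpha2 =",
      format(x$alpha2_norm, digits = 5), ")\n")
  print(x$A_prime)
  invisible(x)
}

#' Evolutionary stability in a well-mixed population
#'
#' Strategy i is an ESS iff for every rival j: a_ii > a_ji, or
#' a_ii = a_ji and a_ij > a_jj (the classical two-clause condition).
#'
#' @param A payoff matrix.
#' @param i focal strategy index.
#' @return list with `ess` (logical) and a per-rival data frame `report`
#'   (columns: rival, first_clause, second_clause, holds).
#' @export
ess_well_mixed <- function(A, i) {
  A <- as_payoff(A)
  n <- nrow(A)
  stopifnot(i >= 1, i <= n)
  rivals <- setdiff(seq_len(n), i)
  first <- unclass(A)[i, i] - unclass(A)[rivals, i]      # a_ii - a_ji
  second <- unclass(A)[i, rivals] - diag(unclass(A))[rivals]  # a_ij - a_jj
  holds <- first > 0 | (first == 0 & second > 0)
  list(ess = all(holds),
       report = data.frame(rival = rivals, first_clause = first,
                           second_clause = second, holds = holds))
}

#' Evolutionary stability on temporal networks
#'
#' Strategy i resists invasion by every rare mutant j on an activity-driven
#' temporal network iff
#' \deqn{\alpha_1 a_{ii} + \alpha_2 a_{ij} > (\alpha_1+\alpha_2) a_{ji}
#'   \quad \forall j \ne i.}
#' Margins within `tol` of zero are ungeneric: the verdict is then
#' `"undecided"` rather than a boolean, so equality-degenerate cases cannot
#' be silently misread.
#'
#' @param A payoff matrix.
#' @param alpha1,alpha2 selection weights.
#' @param i focal strategy index.
#' @param tol ungeneric (equality) band for the margins.
#' @return list with `verdict` in `c("ESS", "not-ESS", "undecided")` and a
#'   per-rival data frame `report` (columns: rival, margin).
#' @export
ess_temporal <- function(A, alpha1, alpha2, i, tol = 0) {
  A <- as_payoff(A)
  n <- nrow(A)
  stopifnot(i >= 1, i <= n)
  rivals <- setdiff(seq_len(n), i)
  Au <- unclass(A)
  margin <- alpha1 * Au[i, i] + alpha2 * Au[i, rivals] -
    (alpha1 + alpha2) * Au[rivals, i]
  verdict <- if (any(margin < -tol)) "not-ESS"
  else if (all(margin > tol)) "ESS"
  else "undecided"
  list(verdict = verdict,
       report = data.frame(rival = rivals, margin = margin))
}

#' The mini-ultimatum game
#'
#' Two offer/acceptance levels l < h (both below 1/2) reduce the ultimatum
#' game to four strategies [offer, threshold]: reasonable R = [l, l],
#' generous G = [h, l], fair F = [h, h] and immoral I = [l, h]. Each entry
#' sums the focal player's proposer-role and responder-role payoffs against
#' the column strategy (an offer is accepted iff it is >= the responder's
#' threshold; a rejected split pays both players 0). Every row satisfies
#' the sum rule a(s,R) + a(s,F) = a(s,G) + a(s,I), which the transformed
#' game inherits and which produces the constant of motion of the dynamics.
#'
#' @param h high offer/threshold level.
#' @param l low offer/threshold level; requires 0 < l < h < 1/2.
#' @return a 4 x 4 `payoff_matrix` with labels R, G, F, I.
#' @export
mug_matrix <- function(h, l) {
  if (!(0 < l)) stop("mini-ultimatum game requires l > 0, got l = ", l)
  if (!(l < h)) stop("mini-ultimatum game requires l < h, got l = ", l,
                     ", h = ", h)
  if (!(h < 1 / 2)) stop("mini-ultimatum game requires h < 1/2, got h = ", h)
  payoff_matrix(rbind(
    c(1,             1 - l + h, h, l),
    c(1 - h + l,     1,         1, 1 - h + l),
    c(1 - h,         1,         1, 1 - h),
    c(1 - l,         1 - l + h, h, 0)),
    labels = c("R", "G", "F", "I"))
}

#' Read / write payoff matrices
#'
#' JSON files use `{labels, rows}`; CSV files carry the labels as header
#' row and first column.
#'
#' @param A payoff matrix.
#' @param file path ending in `.json` or `.csv`.
#' @export
write_payoff_matrix <- function(A, file) {
  A <- as_payoff(A)
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(list(labels = rownames(A),
                              rows = unclass(unname(A))),
                         file, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(unclass(A)), file)
  }
  invisible(file)
}

#' @rdname write_payoff_matrix
#' @export
read_payoff_matrix <- function(file) {
  if (grepl("\\.json$", file)) {
    x <- jsonlite::fromJSON(file)
    payoff_matrix(x$rows, x$labels)
  } else {
    x <- utils::read.csv(file, row.names = 1L, check.names = FALSE)
    payoff_matrix(as.matrix(x), rownames(x))
  }
}
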