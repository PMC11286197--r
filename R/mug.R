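#' Mini-ultimatum game on temporal networks
#'
#' Analysis of how edge temporality shifts the evolutionary outcome of the
#' mini-ultimatum game from the rational low offer towards fairness: the
#' critical offer threshold below which the reasonable strategy R = [l, l]
#' loses evolutionary stability, the closed-form boundary fixed points of
#' the replicator-like dynamics on the strategy simplex S4, the constant of
#' motion that foliates the interior into invariant surfaces, and the
#' stability phase diagram in the (alpha2/alpha1, l) plane. The well-mixed
#' baseline is the special case (alpha1, alpha2) = (1, 0) of the same code
#' paths.
#'
#' @name mug_analysis
NULL

#' Critical offer threshold for destabilizing the reasonable strategy
#'
#' The reasonable strategy R is evolutionarily unstable on a temporal
#' network iff the low offer satisfies l < alpha2 / (alpha1 + 2 alpha2).
#' The binding rival is the immoral strategy I; the fair strategy F is then
#' the unique pure stable state.
#'
#' @param alpha1,alpha2 selection weights (alpha1 + 2 alpha2 != 0).
#' @return the threshold alpha2 / (alpha1 + 2 alpha2).
#' @export
critical_offer <- function(alpha1, alpha2) {
  den <- alpha1 + 2 * alpha2
  if (any(den == 0)) stop("degenerate weights: alpha1 + 2*alpha2 = 0")
  alpha2 / den
}

#' Closed-form edge fixed points of the temporal mini-ultimatum game
#'
#' Returns the three non-vertex boundary rest points of the dynamics under
#' A' = alpha1 A_MUG + alpha2 B:
#' \describe{
#'   \item{R-F}{interior edge point
#'     [(alpha1(1-h) + alpha2(1-2h))/alpha1, 0,
#'      (alpha1 h - alpha2(1-2h))/alpha1, 0]; the edge is bistable with
#'     this point as basin boundary when it exists.}
#'   \item{G-I}{interior edge point
#'     [0, (alpha1(1-h+l) - 2 alpha2(h-l))/alpha1, 0,
#'      (alpha1 + 2 alpha2)(h-l)/alpha1].}
#'   \item{G-F endpoint}{the split point of the G-F line of rest points,
#'     [0, (alpha1(1-h) + alpha2(1-2h))/D, (alpha1 + 2 alpha2)(h-l)/D, 0]
#'     with D = alpha1(1-l) + alpha2(1-2l); points between F and this
#'     endpoint are stable, the rest are invadable.}
#' }
#' Existence is decided by strict interior membership of the closed-form
#' coordinates on their edge (all coordinates in (0, 1)). Each existing
#' point is verified to be a root of the replicator right-hand side and
#' classified via its tangent-space Jacobian.
#'
#' @param h,l mini-ultimatum game levels (0 < l < h < 1/2).
#' @param alpha1,alpha2 selection weights.
#' @param classify also run [classify_fixed_point()] on existing points?
#' @return list of `edge_fixed_point` entries with fields `edge`,
#'   `location`, `exists`, `stability` (report or NULL).
#' @export
edge_fixed_points <- function(h, l, alpha1, alpha2, classify = TRUE) {
  mug_matrix(h, l)   # validates 0 < l < h < 1/2
  Ap <- transformed_matrix(mug_matrix(h, l), alpha1, alpha2)$A_prime
  pts <- list(
    list(edge = "R-F",
         location = c((alpha1 * (1 - h) + alpha2 * (1 - 2 * h)) / alpha1, 0,
                      (alpha1 * h - alpha2 * (1 - 2 * h)) / alpha1, 0)),
    list(edge = "G-I",
         location = c(0,
                      (alpha1 * (1 - h + l) - 2 * alpha2 * (h - l)) / alpha1,
                      0,
                      (alpha1 + 2 * alpha2) * (h - l) / alpha1)),
    list(edge = "G-F",
         location = {
           D <- alpha1 * (1 - l) + alpha2 * (1 - 2 * l)
           c(0, (alpha1 * (1 - h) + alpha2 * (1 - 2 * h)) / D,
             (alpha1 + 2 * alpha2) * (h - l) / D, 0)
         })
  )
  lapply(pts, function(p) {
    on_edge <- p$location[p$location != 0]
    p$exists <- all(p$location >= 0) && all(on_edge > 0 & on_edge < 1) &&
      abs(sum(p$location) - 1) < 1e-9
    p$stability <- if (p$exists && classify)
      classify_fixed_point(Ap, p$location, tol = 1e-7) else NULL
    structure(p, class = "edge_fixed_point")
  })
}

#' Constant of motion of the mini-ultimatum replicator dynamics
#'
#' K = (x_R x_F) / (x_G x_I), invariant along every interior trajectory
#' because each row of A' satisfies a'(s,R) + a'(s,F) = a'(s,G) + a'(s,I).
#' Defined only in the interior of the simplex.
#'
#' @param x interior frequency vector ordered (R, G, F, I).
#' @return K in (0, Inf).
#' @export
constant_of_motion <- function(x) {
  stopifnot(length(x) == 4)
  if (any(x <= 0))
    stop("constant of motion is undefined on the boundary (all components ",
         "must be > 0)")
  (x[1] * x[3]) / (x[2] * x[4])
}

#' Stability phase diagram for the reasonable strategy
#'
#' Classifies each cell of an (alpha2/alpha1, l) grid by the temporal ESS
#' condition for R, using a representative high level h in (l, 1/2). The
#' verdict away from the boundary l = alpha2/(alpha1 + 2 alpha2) is
#' independent of the representative h (checked per cell with a second h);
#' cells whose margin falls inside `band` of the boundary are labelled
#' `"boundary"` rather than forced into either phase.
#'
#' @param alpha_ratio vector of alpha2/alpha1 values (> 0).
#' @param l vector of low-offer levels in (0, 1/2).
#' @param band half-width of the boundary band (on the l scale).
#' @return data frame with columns `alpha_ratio`, `l`, `threshold`,
#'   `verdict` (factor: R-stable / R-unstable / boundary).
#' @export
phase_diagram <- function(alpha_ratio, l, band = 0) {
  stopifnot(all(is.finite(alpha_ratio)), all(alpha_ratio > 0),
            all(l > 0), all(l < 0.5))
  grid <- expand.grid(alpha_ratio = alpha_ratio, l = l,
                      KEEP.OUT.ATTRS = FALSE)
  grid$threshold <- critical_offer(1, grid$alpha_ratio)
  verdict <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    lr <- grid$l[r]; ar <- grid$alpha_ratio[r]
    if (abs(lr - grid$threshold[r]) <= band) { verdict[r] <- "boundary"; next }
    h1 <- (lr + 0.5) / 2
    h2 <- lr + 0.9 * (0.5 - lr)
    v1 <- ess_temporal(mug_matrix(h1, lr), 1, ar, i = 1L)$verdict
    v2 <- ess_temporal(mug_matrix(h2, lr), 1, ar, i = 1L)$verdict
    if (!identical(v1, v2))
      stop("verdict depends on the representative h at alpha2/alpha1 = ",
           ar, ", l = ", lr)
    verdict[r] <- switch(v1, "ESS" = "R-stable", "not-ESS" = "R-unstable",
                         "boundary")
  }
  grid$verdict <- factor(verdict,
                         levels = c("R-stable", "R-unstable", "boundary"))
  grid
}
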