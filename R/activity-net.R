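#' Activity-driven temporal network generator
#'
#' In each instantaneous snapshot G(tau) every node u becomes active with
#' probability a_u and, if active, creates m undirected links to distinct
#' uniformly chosen partners; self-links and multi-edges are prohibited.
#' The integrated network G_delta(t) is the simple-graph union of delta
#' consecutive snapshots and defines the interaction neighbourhood for one
#' evolutionary step. Edges are discarded between windows (memoryless).
#'
#' Graphs are lightweight lists of class `activity_graph` holding a 2-column
#' integer edge matrix (1-based node ids, smaller id first), the node count,
#' and window metadata.
#'
#' @name activity_net
NULL

new_activity_graph <- function(edges, N, window = NULL, weights = NULL) {
  structure(list(edges = edges, N = N, window = window, weights = weights),
            class = "activity_graph")
}

#' @export
print.activity_graph <- function(x, ...) {
  cat("activity-driven graph: N =", x$N, " edges =", nrow(x$edges))
  if (!is.null(x$window))
    cat("  window (t =", x$window[["t"]], ", delta =", x$window[["delta"]], ")")
  cat("\n")
  invisible(x)
}

check_net_args <- function(N, m) {
  if (N < 2) stop("need at least N = 2 nodes, got ", N)
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  if (m > N - 1) stop("m = ", m, " exceeds N - 1 = ", N - 1,
                      ": an active node cannot find m distinct partners")
}

#' Generate one instantaneous activity-driven graph
#'
#' @param activities numeric vector of activity potentials in [0, 1].
#' @param m links created per activation (1 <= m <= N - 1).
#' @param seed optional integer seed.
#' @param step time index tau stored in the result.
#' @return an `activity_graph` (simple, undirected).
#' @export
generate_instantaneous <- function(activities, m, seed = NULL, step = 1L) {
  N <- length(activities)
  check_net_args(N, m)
  stopifnot(all(activities >= 0), all(activities <= 1))
  if (!is.null(seed)) set.seed(seed)
  e <- cpp_snapshot_edges(activities, as.integer(m))
  g <- new_activity_graph(e, N)
  g$step <- step
  g
}

#' Integrate a delta-step window of instantaneous graphs
#'
#' Builds delta fresh snapshots and returns their union. With
#' `multigraph = TRUE` the per-edge snapshot multiplicity is preserved in
#' `weights` (the graph itself stays simple) for sensitivity checks.
#'
#' @inheritParams generate_instantaneous
#' @param delta window length (>= 1).
#' @param t evolutionary time step label for the window.
#' @param multigraph keep edge multiplicities across snapshots?
#' @return an `activity_graph` for the window.
#' @export
integrate_window <- function(activities, m, delta, seed = NULL, t = 1L,
                             multigraph = FALSE) {
  N <- length(activities)
  check_net_args(N, m)
  if (delta < 1 || delta != round(delta))
    stop("delta must be a positive integer, got ", delta)
  if (!is.null(seed)) set.seed(seed)
  e <- cpp_window_edges(activities, as.integer(m), as.integer(delta),
                        isTRUE(multigraph))
  if (isTRUE(multigraph)) {
    new_activity_graph(e[, 1:2, drop = FALSE], N,
                       window = c(t = t, delta = delta), weights = e[, 3L])
  } else {
    new_activity_graph(e, N, window = c(t = t, delta = delta))
  }
}

#' Node degrees of an activity graph
#'
#' @param g an `activity_graph`.
#' @return integer vector of degrees (length N).
#' @export
graph_degrees <- function(g) {
  tabulate(c(g$edges[, 1L], g$edges[, 2L]), g$N)
}

#' Theoretical mean degree on the integrated network
#'
#' Average degree accumulated over a delta-step window by a node with
#' activity a. In the infinite-population limit this is (a + <a>) m delta:
#' the node's own activations contribute a*m*delta links and it receives
#' <a>*m*delta on average. At finite N the collision-corrected value
#' N(1 - exp(-a m delta / N)) + <a> m delta exp(-a m delta / N) is used,
#' which tends to the infinite-N law as N grows.
#'
#' @param a activity of the focal node (in (0, 1]).
#' @param dist an [activity_dist] for the population.
#' @param m links per activation.
#' @param delta window length.
#' @param N population size, or `Inf` for the thermodynamic limit.
#' @return expected degree of an activity-a node on G_delta.
#' @export
mean_degree_theory <- function(a, dist, m, delta, N = Inf) {
  stopifnot(a >= 0, a <= 1, m >= 1, delta >= 1)
  abar <- activity_moment(dist, 1)
  if (is.infinite(N)) return((a + abar) * m * delta)
  N * (1 - exp(-a * m * delta / N)) + abar * m * delta * exp(-a * m * delta / N)
}

#' Write / read an activity graph as an edge-list text file
#'
#' Two tab-separated integer columns (1-based ids, smaller first), preceded
#' by a single `#`-prefixed JSON header with N, m, delta, t and seed.
#'
#' @param g an `activity_graph`.
#' @param file path.
#' @param m,seed metadata recorded in the header.
#' @export
write_edgelist <- function(g, file, m = NA, seed = NA) {
  hdr <- jsonlite::toJSON(list(
    N = g$N, m = m,
    delta = if (!is.null(g$window)) unname(g$window[["delta"]]) else 1,
    t = if (!is.null(g$window)) unname(g$window[["t"]]) else NA,
    seed = seed, ids = "1-based"), auto_unbox = TRUE, na = "null")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.table(g$edges, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(file) {
  first <- readLines(file, n = 1L)
  hdr <- jsonlite::fromJSON(sub("^#\\s*", "", first))
  e <- as.matrix(utils::read.table(file, sep = "\t", comment.char = "#",
                                   col.names = c("u", "v")))
  dimnames(e) <- NULL
  g <- new_activity_graph(e, hdr$N,
                          window = c(t = hdr$t %||% NA, delta = hdr$delta))
  g
}
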