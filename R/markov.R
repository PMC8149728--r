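# Markov-chain signaling model: an expression-weighted random walk on the
# signaling network whose stationary distribution ranks signaling hotspots.
# Edge signs are deliberately excluded here (a traversal probability cannot
# be negative); signs re-enter downstream in path-compatibility testing.

#' Expression weights for signaling nodes
#'
#' The traversal probability toward a node is driven by how reliably the node
#' is expressed in the population. `mode = "fraction"` (default) uses the
#' expressed-cell fraction, which is robust to sequencing-depth differences;
#' `mode = "mean"` uses mean expression over expressing cells. A small
#' epsilon keeps unmeasured or silent nodes at near-zero but positive weight
#' so transition rows stay normalizable.
#'
#' @param profile a `population_profile`.
#' @param nodes signaling node symbols.
#' @param mode `"fraction"` or `"mean"`.
#' @param eps additive floor, default `1e-6`.
#' @return named numeric weight vector over `nodes`.
#' @export
node_weights <- function(profile, nodes, mode = c("fraction", "mean"), eps = 1e-6) {
  mode <- match.arg(mode)
  col <- if (mode == "fraction") "expressed_fraction" else "mean_expressing"
  w <- rep(eps, length(nodes))
  names(w) <- nodes
  measured <- intersect(nodes, profile$gene)
  w[measured] <- profile[measured, col] + eps
  w
}

#' Build the state-transition matrix of the signaling walk
#'
#' For node `i` with outgoing neighbors `N(i)`, the transition probability is
#' `P[i, j] = (1 - damping) * w(j) / sum(w over N(i)) + damping / n` for
#' `j` in `N(i)` and `damping / n` otherwise. Dangling nodes (no outgoing
#' edge, typically terminal TFs) restart uniformly. With `damping > 0` the
#' chain is irreducible and aperiodic.
#'
#' @param network a `signaling_network`.
#' @param weights named weight vector covering all network nodes (see
#'   [node_weights()]).
#' @param damping restart probability in `[0, 1)`, default 0.
#' @return object of class `transition_matrix`: list with `nodes`, row-
#'   stochastic matrix `P`, and `damping`.
#' @export
build_transition_matrix <- function(network, weights, damping = 0) {
  stopifnot(inherits(network, "signaling_network"), damping >= 0, damping < 1)
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0L) abort_validation("signaling network is empty")
  if (!all(nodes %in% names(weights))) {
    abort_validation("weights missing for some signaling nodes")
  }
  w <- weights[nodes]
  if (any(w <= 0)) stop("internal error: non-positive node weight")
  P <- matrix(damping / n, nrow = n, ncol = n, dimnames = list(nodes, nodes))
  out_nb <- split(network$edges$target, network$edges$source)
  for (i in seq_len(n)) {
    nb <- out_nb[[nodes[i]]]
    if (is.null(nb) || length(nb) == 0L) {
      P[i, ] <- 1 / n  # dangling: uniform restart
    } else {
      P[i, nb] <- (1 - damping) * w[nb] / sum(w[nb]) + damping / n
    }
  }
  structure(list(nodes = nodes, P = P, damping = damping),
            class = "transition_matrix")
}

#' Stationary distribution by power iteration
#'
#' Evolves a start distribution (uniform by default) through the chain until
#' the L1 change drops below `tol`. Periodic chains at `damping = 0` may not
#' converge; the error advises a positive damping.
#'
#' @param tm a `transition_matrix`.
#' @param tol L1 convergence tolerance, default `1e-10`.
#' @param max_iter iteration cap, default 10000.
#' @param start optional start distribution over `tm$nodes`.
#' @return object of class `stationary_distribution`: list with `nodes`,
#'   probability vector `pi`, `iterations`, and final L1 `residual`.
#' @export
stationary_distribution <- function(tm, tol = 1e-10, max_iter = 10000L, start = NULL) {
  stopifnot(inherits(tm, "transition_matrix"))
  n <- length(tm$nodes)
  pi_vec <- if (is.null(start)) rep(1 / n, n) else {
    stopifnot(length(start) == n, all(start >= 0))
    start / sum(start)
  }
  P <- tm$P
  for (it in seq_len(max_iter)) {
    nxt <- as.numeric(pi_vec %*% P)
    resid <- sum(abs(nxt - pi_vec))
    pi_vec <- nxt
    if (resid <= tol) {
      names(pi_vec) <- tm$nodes
      return(structure(list(nodes = tm$nodes, pi = pi_vec,
                            iterations = it, residual = resid),
                       class = "stationary_distribution"))
    }
  }
  names(pi_vec) <- tm$nodes
  abort_convergence(
    sprintf("power iteration did not converge in %d iterations (residual %.3g); try damping > 0",
            max_iter, resid),
    last_iterate = pi_vec)
}

#' Select signaling hotspots from the stationary distribution
#'
#' Keeps the nodes whose steady-state probability is at least the `quantile`
#' quantile (type 7) of all probabilities; ties at the cut are all kept.
#'
#' @param sd_ a `stationary_distribution`.
#' @param quantile upper-tail cut, default 0.90.
#' @return object of class `hotspot_set`: list with `intermediates` (sorted
#'   by probability descending, ties by symbol), `quantile_cut`, and the full
#'   `pi` vector.
#' @export
select_intermediates <- function(sd_, quantile = 0.90) {
  stopifnot(inherits(sd_, "stationary_distribution"))
  keep <- quantile_keep(sd_$pi, quantile)
  kept <- sd_$nodes[keep]
  ord <- order(-sd_$pi[kept], kept)
  structure(list(intermediates = kept[ord],
                 quantile_cut = quantile,
                 pi = sd_$pi),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("hotspot_set:", length(x$intermediates), "node(s) at pi quantile >=",
      x$quantile_cut, "\n")
  invisible(x)
}
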