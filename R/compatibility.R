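# Signed-path enumeration, hypergeometric compatibility testing, and the
# functional-receptor decision.

#' Interface transcription factors reachable by signaling
#'
#' The preserved TFs that can actually ground a signal: they own a regulon
#' and have at least one incoming signaling edge (the first TFs in the
#' transduction chain).
#'
#' @param network a `signaling_network`.
#' @param regulons named regulon list.
#' @param preserved a `preserved_tfs` object.
#' @return character vector of interface TF symbols.
#' @export
interface_tfs <- function(network, regulons, preserved) {
  stopifnot(inherits(preserved, "preserved_tfs"))
  has_incoming <- preserved$tfs %in% network$edges$target
  has_regulon <- preserved$tfs %in% names(regulons)
  out <- preserved$tfs[has_incoming & has_regulon]
  if (length(out) == 0L) {
    abort_validation("no preserved TF has both a regulon and an incoming signaling edge in population %s",
                     preserved$population %||% "?")
  }
  out
}

# Adjacency list with per-edge signs, keyed by source node.
adjacency_signed <- function(network) {
  split(network$edges[c("target", "sign")], network$edges$source)
}

#' Enumerate signed simple paths to a target set
#'
#' Depth-first enumeration of all simple paths from `source` to each gene in
#' `targets` with at most `max_path_len` edges. A path may pass through one
#' target on its way to another. Each path carries the product of its edge
#' signs. Enumeration stops with a warning after `max_paths` paths.
#'
#' @param network a `signaling_network`.
#' @param source start node (must be in the network).
#' @param targets character vector of end nodes.
#' @param max_path_len maximum number of edges per path, default 5.
#' @param max_paths enumeration cap per source, default 10000.
#' @return list of paths; each element is a list with `nodes` (node sequence
#'   including both endpoints), `length` (edge count), and `sign` (+1/-1).
#' @export
signed_paths <- function(network, source, targets, max_path_len = 5L,
                         max_paths = 10000L) {
  stopifnot(inherits(network, "signaling_network"))
  if (!source %in% network$nodes) {
    abort_validation("source node %s not in signaling network", source)
  }
  targets <- intersect(unique(targets), network$nodes)
  if (length(targets) == 0L) return(list())
  adj <- adjacency_signed(network)
  paths <- vector("list", 64L)
  n_found <- 0L
  capped <- FALSE

  visit <- function(node, depth, sign, trail) {
    if (capped) return(invisible(NULL))
    if (node %in% targets && depth > 0L) {
      n_found <<- n_found + 1L
      if (n_found > max_paths) {
        capped <<- TRUE
        n_found <<- max_paths
        return(invisible(NULL))
      }
      if (n_found > length(paths)) length(paths) <<- 2L * n_found  # grow
      paths[[n_found]] <<- list(nodes = trail, length = depth, sign = sign)
    }
    if (depth == max_path_len) return(invisible(NULL))
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible(NULL))
    for (j in seq_len(nrow(nb))) {
      nxt <- nb$target[j]
      if (nxt %in% trail) next  # simple paths only
      visit(nxt, depth + 1L, sign * nb$sign[j], c(trail, nxt))
    }
    invisible(NULL)
  }
  visit(source, 0L, 1L, source)
  if (capped) {
    warning(sprintf("path enumeration from %s capped at %d paths", source, max_paths),
            call. = FALSE)
  }
  paths[seq_len(n_found)]
}

# Distinct signs among signed paths source -> target (length <= max_path_len).
path_signs <- function(network, source, target, max_path_len = 5L,
                       max_paths = 10000L) {
  ps <- signed_paths(network, source, target, max_path_len, max_paths)
  sort(unique(vapply(ps, `[[`, integer(1), "sign")))
}

# Bounded reachability (any sign): is there a simple path from -> to with at
# most max_len edges? BFS over nodes is sufficient because a shortest path is
# always simple.
reachable_within <- function(network, from, to, max_len = 5L) {
  if (!from %in% network$nodes || !to %in% network$nodes) return(FALSE)
  adj <- split(network$edges$target, network$edges$source)
  frontier <- from
  seen <- from
  for (d in seq_len(max_len)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    if (length(nxt) == 0L) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Hypergeometric compatibility between a signaling state and a regulon
#'
#' Predicts each regulon target's activity as
#' `intermediate_state * path_sign * regulon_sign` and tests whether the
#' predicted-active targets are over-represented among the observed-active
#' targets. With `N` measured targets, `K` observed active, `n` predicted
#' active, and `k` in the overlap, the p-value is the upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; compatibility requires
#' `p < alpha` (one-sided).
#'
#' @param intermediate_state observed activity of the intermediate, +1 or -1.
#' @param path_sign product of edge signs along the path, +1 or -1.
#' @param regulon data.frame with columns `target`, `sign`.
#' @param binary_targets named +1/-1 vector of observed target states; only
#'   regulon targets present here count as measured.
#' @param alpha significance level, default 0.05.
#' @return one-row data.frame: `path_sign`, `N`, `K`, `n`, `k`, `p`,
#'   `compatible`, `reason` (`"ok"` or `"no_measured_targets"`).
#' @export
compatibility_test <- function(intermediate_state, path_sign, regulon,
                               binary_targets, alpha = 0.05) {
  stopifnot(intermediate_state %in% c(-1L, 1L), path_sign %in% c(-1L, 1L))
  measured <- regulon$target %in% names(binary_targets)
  N <- sum(measured)
  if (N == 0L) {
    return(data.frame(path_sign = path_sign, N = 0L, K = 0L, n = 0L, k = 0L,
                      p = 1, compatible = FALSE, reason = "no_measured_targets",
                      stringsAsFactors = FALSE))
  }
  reg <- regulon[measured, , drop = FALSE]
  observed <- binary_targets[reg$target]
  predicted <- intermediate_state * path_sign * reg$sign
  K <- sum(observed == 1L)
  n <- sum(predicted == 1L)
  k <- sum(predicted == 1L & observed == 1L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(path_sign = path_sign, N = N, K = K, n = n, k = k, p = p,
             compatible = p < alpha, reason = "ok", stringsAsFactors = FALSE)
}

# All compatibility results for one population: hotspots x interface TFs,
# testing every distinct path sign (a pair is compatible if ANY sign works).
population_compatibility <- function(network, hotspots, itfs, regulons, profile,
                                     alpha = 0.05, max_path_len = 5L,
                                     max_paths = 10000L) {
  states <- stats::setNames(profile$consensus_state, profile$gene)
  rows <- list()
  for (interm in hotspots$intermediates) {
    istate <- if (interm %in% names(states)) states[[interm]] else -1L
    for (tf in itfs) {
      if (interm == tf) next
      signs <- path_signs(network, interm, tf, max_path_len, max_paths)
      if (length(signs) == 0L) next
      for (s in signs) {
        res <- compatibility_test(istate, s, regulons[[tf]], states, alpha)
        res$intermediate <- interm
        res$tf <- tf
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(intermediate = character(0), tf = character(0),
                      path_sign = integer(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      compatible = logical(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[c("intermediate", "tf", "path_sign", "N", "K", "n", "k", "p",
        "compatible", "reason")]
}

#' Decide the functional receptors of a population
#'
#' A receptor is functional when (a) it is, or is linked by a signaling path
#' (at most `max_path_len` edges) to, a hotspot intermediate that is
#' transcriptionally compatible with some interface TF, and (b) the fraction
#' of cells jointly expressing (count >= 1) the receptor, that interface TF,
#' and at least one of the TF's observed-active regulon targets is at least
#' `min_cofrac`.
#'
#' @param network a `signaling_network`.
#' @param hotspots a `hotspot_set`.
#' @param compat compatibility table from the hotspot stage (columns
#'   `intermediate`, `tf`, `compatible`).
#' @param receptors candidate receptor symbols (scaffold receptors).
#' @param counts the population's cells x genes count submatrix.
#' @param profile the population's `population_profile`.
#' @param regulons named regulon list.
#' @param min_cofrac joint co-expression floor, default 0.05 (inclusive).
#' @param max_path_len path length bound for receptor-to-hotspot linkage.
#' @return object of class `functional_receptors`: list with `population`,
#'   `receptors`, and `evidence` (data.frame receptor/intermediate/tf).
#' @export
functional_receptors <- function(network, hotspots, compat, receptors, counts,
                                 profile, regulons, min_cofrac = 0.05,
                                 max_path_len = 5L) {
  ok <- compat[compat$compatible, c("intermediate", "tf"), drop = FALSE]
  ok <- ok[!duplicated(ok), , drop = FALSE]
  evidence <- list()
  states <- stats::setNames(profile$consensus_state, profile$gene)
  receptors <- intersect(unique(receptors), network$nodes)
  bin <- counts >= 1
  for (r in receptors) {
    if (!r %in% colnames(bin)) next
    for (i in seq_len(nrow(ok))) {
      interm <- ok$intermediate[i]
      tf <- ok$tf[i]
      linked <- (r == interm) || reachable_within(network, r, interm, max_path_len)
      if (!linked) next
      if (!tf %in% colnames(bin)) next
      reg <- regulons[[tf]]
      active <- reg$target[reg$target %in% names(states) & states[reg$target] == 1L]
      active <- intersect(active, colnames(bin))
      if (length(active) == 0L) next
      any_target <- Matrix::rowSums(bin[, active, drop = FALSE]) > 0
      joint <- bin[, r] & bin[, tf] & any_target
      if (mean(joint) >= min_cofrac) {
        evidence[[length(evidence) + 1L]] <-
          data.frame(receptor = r, intermediate = interm, tf = tf,
                     joint_fraction = mean(joint), stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(receptor = character(0), intermediate = character(0),
               tf = character(0), joint_fraction = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(population = attr(profile, "population"),
                 receptors = sort(unique(ev$receptor)),
                 evidence = ev),
            class = "functional_receptors")
}

#' @export
print.functional_receptors <- function(x, ...) {
  cat("functional_receptors[", x$population %||% "?", "]: ",
      length(x$receptors), " receptor(s)\n", sep = "")
  invisible(x)
}
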