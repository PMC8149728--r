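# Independent test oracles, shared by the unit and acceptance suites. These
# deliberately share no code with the package implementations they check.

# Exhaustive simple-path enumeration by iterative frontier extension over the
# raw edge list.
oracle_paths <- function(network, source, targets, max_len) {
  e <- network$edges
  sig <- stats::setNames(e$sign, paste(e$source, e$target))
  out <- list()
  frontier <- list(source)
  for (len in seq_len(max_len)) {
    nxt <- list()
    for (p in frontier) {
      last <- p[length(p)]
      for (t in e$target[e$source == last]) {
        if (t %in% p) next
        q <- c(p, t)
        nxt[[length(nxt) + 1L]] <- q
        if (t %in% targets) {
          s <- prod(sig[paste(q[-length(q)], q[-1])])
          out[[length(out) + 1L]] <- list(nodes = q, length = len,
                                          sign = as.integer(s))
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  out
}

path_key <- function(paths) {
  sort(vapply(paths, function(p) paste(paste(p$nodes, collapse = ">"), p$sign),
              character(1)))
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of N targets
# and count how often the overlap with the K observed-active targets reaches k.
oracle_hyper <- function(N, K, n, k) {
  if (n == 0L) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  overlaps <- apply(subsets, 2, function(s) sum(s <= K))
  mean(overlaps >= k)
}
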