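# Markov stage: weighting, transition construction, stationary distribution,
# hotspot selection. Oracles: explicit arithmetic, brute-force matrix powers,
# and eigen decomposition.

mat_power <- function(P, k) {
  out <- diag(nrow(P))
  base <- P
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2
  }
  out
}

test_that("node weights are expressed fractions plus epsilon", {
  m <- counts_matrix(cbind(c(1, 0), c(1, 1)), genes = c("gA", "gB"))
  prof <- one_pop_profile(m)
  w <- node_weights(prof, c("gA", "gB", "gZ"))
  expect_equal(unname(w["gA"]), 0.5 + 1e-6)
  expect_equal(unname(w["gB"]), 1 + 1e-6)
  expect_equal(unname(w["gZ"]), 1e-6)  # unmeasured gene keeps epsilon mass
  wm <- node_weights(prof, c("gA", "gB"), mode = "mean")
  expect_equal(unname(wm["gA"]), 1 + 1e-6)
})

test_that("transition rows follow the weighted-neighbor rule", {
  # forced 2-cycle
  net <- signaling_network(edges_df(c("A", "B"), c("B", "A"), c(1, 1)))
  tm <- build_transition_matrix(net, c(A = 1, B = 1))
  expect_equal(unname(tm$P), rbind(c(0, 1), c(1, 0)))

  # dangling node gets a uniform row
  net4 <- signaling_network(edges_df(c("A", "A", "B"), c("B", "C", "D"), c(1, 1, -1)))
  tm4 <- build_transition_matrix(net4, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(unname(tm4$P["C", ]), rep(0.25, 4))
  expect_equal(unname(tm4$P["D", ]), rep(0.25, 4))

  # normalization over outgoing neighborhood weights
  eps <- 1e-6
  netw <- signaling_network(edges_df(c("A", "A"), c("B", "C"), c(1, -1)))
  tmw <- build_transition_matrix(netw, c(A = 1, B = 0.75 + eps, C = 0.25 + eps))
  expect_equal(unname(tmw$P["A", "B"]), (0.75 + eps) / (1 + 2 * eps))
  expect_equal(unname(tmw$P["A", "C"]), (0.25 + eps) / (1 + 2 * eps))
})

test_that("rows are stochastic for every random fixture", {
  set.seed(5)
  for (i in 1:1000) {
    net <- random_network(sample(3:12, 1))
    w <- stats::setNames(runif(length(net$nodes)) + 1e-6, net$nodes)
    d <- sample(c(0, 0.1, 0.5), 1)
    tm <- build_transition_matrix(net, w, damping = d)
    expect_true(all(abs(rowSums(tm$P) - 1) <= 1e-12))
    expect_true(all(tm$P >= 0))
  }
})

test_that("stationary distribution matches closed forms and brute force", {
  # doubly stochastic: uniform is stationary
  nodes <- c("A", "B", "C")
  P <- matrix(c(0.2, 0.3, 0.5, 0.5, 0.2, 0.3, 0.3, 0.5, 0.2), 3, byrow = TRUE,
              dimnames = list(nodes, nodes))
  tm <- structure(list(nodes = nodes, P = P, damping = 0), class = "transition_matrix")
  sd_ <- stationary_distribution(tm)
  expect_equal(unname(sd_$pi), rep(1 / 3, 3), tolerance = 1e-9)

  # 2-cycle from the uniform start: uniform is already stationary
  net <- signaling_network(edges_df(c("A", "B"), c("B", "A"), c(1, 1)))
  tm2 <- build_transition_matrix(net, c(A = 1, B = 1))
  sd2 <- stationary_distribution(tm2)
  expect_equal(unname(sd2$pi), c(0.5, 0.5))
  expect_equal(sd2$iterations, 1L)

  # but a perturbed start oscillates forever at damping 0
  expect_error(stationary_distribution(tm2, start = c(0.6, 0.4), max_iter = 500),
               class = "intercom_convergence_error")

  # random 5-state chains with damping: row of P^1000 is the oracle
  set.seed(31)
  for (i in 1:10) {
    net5 <- random_network(5, p_edge = 0.4)
    w <- stats::setNames(runif(length(net5$nodes)) + 1e-6, net5$nodes)
    tm5 <- build_transition_matrix(net5, w, damping = 0.1)
    sd5 <- stationary_distribution(tm5)
    oracle <- mat_power(tm5$P, 1000)[1, ]
    expect_equal(unname(sd5$pi), unname(oracle), tolerance = 1e-8)
    # fixed point within 10x tolerance
    expect_lte(sum(abs(as.numeric(sd5$pi %*% tm5$P) - sd5$pi)), 10 * 1e-10)
  }
})

test_that("power iteration agrees with the principal left eigenvector", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    net <- random_network(n, p_edge = 0.15)
    w <- stats::setNames(runif(length(net$nodes)) + 1e-6, net$nodes)
    tm <- build_transition_matrix(net, w, damping = 0.1)
    sd_ <- stationary_distribution(tm)
    ev <- eigen(t(tm$P))
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    v <- v / sum(v)
    expect_lte(sum(abs(v - unname(sd_$pi))), 1e-7)
  }
})

test_that("hotspot selection keeps the inclusive top quantile with ties", {
  nodes <- sprintf("n%02d", 1:10)
  sd_ <- structure(list(nodes = nodes,
                        pi = stats::setNames(seq(0.01, 0.19, length.out = 10) /
                                               sum(seq(0.01, 0.19, length.out = 10)), nodes),
                        iterations = 1L, residual = 0),
                   class = "stationary_distribution")
  hot <- select_intermediates(sd_, quantile = 0.90)
  expect_equal(hot$intermediates, "n10")  # 10 distinct values -> one node

  sd_tie <- structure(list(nodes = nodes, pi = stats::setNames(rep(0.1, 10), nodes),
                           iterations = 1L, residual = 0),
                      class = "stationary_distribution")
  expect_setequal(select_intermediates(sd_tie, 0.90)$intermediates, nodes)

  # 20 nodes against a brute-force sort-and-cut
  set.seed(99)
  nodes20 <- sprintf("m%02d", 1:20)
  pi20 <- runif(20); pi20 <- pi20 / sum(pi20); names(pi20) <- nodes20
  sd20 <- structure(list(nodes = nodes20, pi = pi20, iterations = 1L, residual = 0),
                    class = "stationary_distribution")
  s <- sort(pi20)
  cut <- s[18] + 0.1 * (s[19] - s[18])  # h = (20 - 1) * 0.9 + 1 = 18.1
  expect_setequal(select_intermediates(sd20, 0.90)$intermediates,
                  nodes20[pi20 >= cut])
})

test_that("raising a node's weight never lowers its stationary probability in a star", {
  # center C feeds leaves L1..L4; leaves dangle (uniform restart), so the
  # closed form is pi proportional to restart + center flow, monotone in the
  # leaf weight.
  net <- signaling_network(edges_df(rep("C", 4), paste0("L", 1:4), rep(1L, 4)))
  base <- c(C = 0.5, L1 = 0.2, L2 = 0.2, L3 = 0.2, L4 = 0.2)
  pis <- sapply(c(0.2, 0.4, 0.6, 0.8), function(wl) {
    w <- base; w["L1"] <- wl
    stationary_distribution(build_transition_matrix(net, w, damping = 0))$pi[["L1"]]
  })
  expect_true(all(diff(pis) > 0))
})
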