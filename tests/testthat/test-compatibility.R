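# Signed paths, hypergeometric compatibility, functional receptors. The
# independent oracles live in helper-oracles.R.

test_that("interface TFs need a regulon and an incoming signaling edge", {
  net <- chain_network()
  regs <- list(T = data.frame(target = "x", sign = 1L),
               T2 = data.frame(target = "y", sign = 1L))
  pres <- structure(list(population = "p", tfs = c("T", "T2"),
                         threshold_fraction = 0.5), class = "preserved_tfs")
  expect_equal(interface_tfs(net, regs, pres), "T")  # T2 isolated in the net

  pres_bad <- structure(list(population = "p", tfs = "T2",
                             threshold_fraction = 0.5), class = "preserved_tfs")
  expect_error(interface_tfs(net, regs, pres_bad),
               class = "intercom_validation_error")
})

test_that("signed paths carry the product of edge signs", {
  net <- chain_network(1L, -1L)  # R -(+)-> I -(-)-> T
  ps <- signed_paths(net, "R", "T")
  expect_length(ps, 1L)
  expect_equal(ps[[1]]$nodes, c("R", "I", "T"))
  expect_equal(ps[[1]]$sign, -1L)

  # two parallel paths with opposite signs are both returned
  net2 <- signaling_network(edges_df(c("R", "R", "I1", "I2"),
                                     c("I1", "I2", "T", "T"),
                                     c(1, 1, 1, -1)))
  expect_setequal(vapply(signed_paths(net2, "R", "T"), `[[`, integer(1), "sign"),
                  c(1L, -1L))

  # length bound excludes the long route
  chain6 <- signaling_network(edges_df(sprintf("n%d", 1:6), sprintf("n%d", 2:7),
                                       rep(1L, 6)))
  expect_length(signed_paths(chain6, "n1", "n7", max_path_len = 5L), 0L)
  expect_length(signed_paths(chain6, "n1", "n7", max_path_len = 6L), 1L)
})

test_that("signed paths match the exhaustive oracle on random graphs", {
  set.seed(17)
  for (i in 1:40) {
    net <- random_network(sample(4:8, 1), p_edge = 0.3)
    source <- sample(net$nodes, 1)
    targets <- sample(setdiff(net$nodes, source), min(2, length(net$nodes) - 1))
    got <- signed_paths(net, source, targets, max_path_len = 5L)
    want <- oracle_paths(net, source, targets, 5L)
    expect_equal(path_key(got), path_key(want))
  }
})

test_that("compatibility p-values reproduce enumeration and the worked case", {
  # worked case: N=5, K=3, n=3, k=3 -> p = 1/10
  regulon <- data.frame(target = sprintf("t%d", 1:5),
                        sign = c(1L, 1L, 1L, -1L, -1L))
  obs <- stats::setNames(c(1L, 1L, 1L, -1L, -1L), sprintf("t%d", 1:5))
  res <- compatibility_test(1L, 1L, regulon, obs)
  expect_equal(res[, c("N", "K", "n", "k")],
               data.frame(N = 5L, K = 3L, n = 3L, k = 3L))
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_false(res$compatible)  # 0.1 is not below alpha = 0.05
  expect_equal(res$p, oracle_hyper(5, 3, 3, 3), tolerance = 1e-12)

  # n = 0: nothing predicted active -> p = 1
  res0 <- compatibility_test(1L, 1L,
                             data.frame(target = c("a", "b"), sign = c(-1L, -1L)),
                             c(a = 1L, b = -1L))
  expect_equal(res0$n, 0L)
  expect_equal(res0$p, 1)
  expect_false(res0$compatible)

  # N = K = n = k = 1: the single outcome always has overlap 1 -> p = 1
  res1 <- compatibility_test(1L, 1L, data.frame(target = "a", sign = 1L),
                             c(a = 1L))
  expect_equal(res1$p, 1)
  expect_equal(res1$p, oracle_hyper(1, 1, 1, 1))

  # untestable regulon
  resu <- compatibility_test(1L, 1L, data.frame(target = "zz", sign = 1L),
                             c(a = 1L))
  expect_equal(resu$reason, "no_measured_targets")
  expect_equal(resu$p, 1)
})

test_that("flipping intermediate state is equivalent to flipping the path sign", {
  set.seed(3)
  for (i in 1:30) {
    N <- sample(2:8, 1)
    regulon <- data.frame(target = sprintf("t%d", 1:N),
                          sign = sample(c(-1L, 1L), N, replace = TRUE))
    obs <- stats::setNames(sample(c(-1L, 1L), N, replace = TRUE), regulon$target)
    a <- compatibility_test(1L, 1L, regulon, obs)
    b <- compatibility_test(-1L, -1L, regulon, obs)
    expect_equal(a[c("N", "K", "n", "k", "p")], b[c("N", "K", "n", "k", "p")])
  }
})

test_that("raising alpha never shrinks the compatible set", {
  set.seed(8)
  for (i in 1:20) {
    N <- sample(4:10, 1)
    regulon <- data.frame(target = sprintf("t%d", 1:N),
                          sign = sample(c(-1L, 1L), N, replace = TRUE))
    obs <- stats::setNames(sample(c(-1L, 1L), N, replace = TRUE), regulon$target)
    lo <- compatibility_test(1L, 1L, regulon, obs, alpha = 0.01)$compatible
    hi <- compatibility_test(1L, 1L, regulon, obs, alpha = 0.2)$compatible
    expect_true(hi >= lo)
  }
})

test_that("functional receptors respect the joint co-expression floor", {
  w08 <- cofrac_world(8)   # joint fraction 0.08 -> retained
  expect_true(all(w08$compat$compatible))
  fr08 <- functional_receptors(w08$network, forged_hotspots("I"), w08$compat,
                               "R", w08$counts, w08$profile,
                               list(T = w08$regulon))
  expect_equal(fr08$receptors, "R")
  expect_equal(fr08$evidence$joint_fraction, 0.08)

  fr04 <- with(cofrac_world(4), functional_receptors(
    network, forged_hotspots("I"), compat, "R", counts, profile,
    list(T = regulon)))
  expect_length(fr04$receptors, 0L)  # 0.04 is below the inclusive 0.05 floor

  fr05 <- with(cofrac_world(5), functional_receptors(
    network, forged_hotspots("I"), compat, "R", counts, profile,
    list(T = regulon)))
  expect_equal(fr05$receptors, "R")  # exactly 0.05 is retained

  # no path to any hotspot -> dropped regardless of expression
  w <- cofrac_world(50)
  disconnected <- signaling_network(edges_df("I", "T", 1L))
  # receptor R is not even a node of this network
  fr_nc <- functional_receptors(disconnected, forged_hotspots("I"), w$compat,
                                "R", w$counts, w$profile, list(T = w$regulon))
  expect_length(fr_nc$receptors, 0L)
})

test_that("raising the co-expression floor never grows the receptor set", {
  w <- cofrac_world(20)
  sets <- lapply(c(0.05, 0.15, 0.3), function(f) {
    functional_receptors(w$network, forged_hotspots("I"), w$compat, "R",
                         w$counts, w$profile, list(T = w$regulon),
                         min_cofrac = f)$receptors
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})
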