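test_that("construction validates, drops zero states, preserves order", {
  d <- joint_dist(data.frame(A = c("0", "1", "1"), B = c("x", "x", "y"),
                             p = c(0.5, 0.5, 0)))
  expect_s3_class(d, "joint_dist")
  expect_equal(nrow(d), 2L)          # zero-mass state dropped
  expect_equal(var_names(d), c("A", "B"))
  expect_equal(sum(d$p), 1)
  expect_equal(alphabets(d)$B, "x")  # default alphabet = observed support

  expect_error(joint_dist(data.frame(A = "0", p = 0.9)),
               class = "infodecomp_error_invalid")
  expect_error(joint_dist(data.frame(A = c("0", "0"), p = c(0.5, 0.5))),
               class = "infodecomp_error_invalid")
  expect_error(joint_dist(data.frame(A = c("0", "1"), p = c(0.5, 0.5)),
                          alphabets = list(A = "0")),
               class = "infodecomp_error_invalid")
})

test_that("marginalization matches hand sums and the chain rule", {
  xor <- logic_gate("XOR")
  m1 <- marginalize(xor, "X1")
  expect_equal(sort(m1$p), c(0.5, 0.5))

  # marginalizing over all variables is the identity
  mall <- marginalize(xor, 1:3)
  expect_equal(
    mall$p[match(.okey(as.data.frame(xor), var_names(xor)),
                 .okey(as.data.frame(mall), var_names(xor)))],
    xor$p
  )

  # uniformity is preserved
  u <- uniform_dist(3)
  m12 <- marginalize(u, c(1, 2))
  expect_equal(m12$p, rep(0.25, 4))

  # chain rule on a seeded random distribution, state by state
  r <- random_dist(3, 3, seed = 11)
  ab <- marginalize(r, c(1, 2))
  a_direct <- marginalize(r, 1)
  a_chain <- marginalize(ab, 1)
  expect_equal(
    a_chain$p[match(a_direct[[1]], a_chain[[1]])], a_direct$p,
    tolerance = 1e-12
  )

  expect_error(marginalize(xor, integer(0)), class = "infodecomp_error_invalid")
  expect_error(marginalize(xor, 5), class = "infodecomp_error_invalid")
})

test_that("conditioning enumerates the right states and respects total probability", {
  xor <- logic_gate("XOR")
  c0 <- condition_on(xor, "T", "0")
  expect_equal(nrow(c0), 2L)
  expect_equal(sort(.okey(as.data.frame(c0), c("X1", "X2"))), c("0|0", "1|1"))
  expect_equal(c0$p, c(0.5, 0.5))

  # conditioning a product distribution leaves the others unchanged
  u <- uniform_dist(3)
  cu <- condition_on(u, 3, "1")
  expect_equal(cu$p, rep(0.25, 4))

  # law of total probability: sum_t P(t) * P(rest | t) = P(rest)
  r <- random_dist(3, 2, seed = 7)
  tm <- marginalize(r, 3)
  rest <- marginalize(r, c(1, 2))
  acc <- stats::setNames(rep(0, nrow(rest)), .okey(as.data.frame(rest), c("X1", "X2")))
  for (i in seq_len(nrow(tm))) {
    ci <- condition_on(r, 3, tm[[1]][i])
    k <- .okey(as.data.frame(ci), c("X1", "X2"))
    acc[k] <- acc[k] + tm$p[i] * ci$p
  }
  expect_equal(unname(acc[.okey(as.data.frame(rest), c("X1", "X2"))]), rest$p,
               tolerance = 1e-12)

  expect_error(condition_on(xor, "T", "2"), class = "infodecomp_error_support")
})

test_that("product of marginals and uniform prior build the stated priors", {
  xor <- logic_gate("XOR")
  pm <- product_of_marginals(xor)
  expect_equal(nrow(pm), 8L)
  expect_equal(pm$p, rep(0.125, 8))     # XOR marginals are fair coins

  gb <- giant_bit(3)
  expect_equal(product_of_marginals(gb)$p, rep(0.125, 8))

  # idempotence on a product distribution
  u <- uniform_dist(2, 3)
  pu <- product_of_marginals(u)
  expect_equal(sort(.okey(as.data.frame(pu), var_names(u))),
               sort(.okey(as.data.frame(u), var_names(u))))
  expect_equal(pu$p, u$p)

  up <- uniform_prior(xor)
  expect_equal(up$p, rep(0.125, 8))
  expect_equal(kl_divergence(xor, up), 1, tolerance = 1e-12)
  # fixed point
  expect_equal(uniform_prior(u)$p, u$p)
})

test_that("surprisal and entropy match closed forms", {
  u <- uniform_dist(3)
  expect_equal(local_surprisal(u, c("1", "0", "1")), 3)
  xor <- logic_gate("XOR")
  expect_equal(local_surprisal(xor, c("0", "0", "0"), subset = 1), 1)
  expect_equal(local_surprisal(xor, c("0", "0", "0")), 2)
  expect_error(local_surprisal(xor, c("0", "0", "1")),
               class = "infodecomp_error_support")

  expect_equal(shannon_entropy(xor), 2)
  expect_equal(shannon_entropy(u), 3)
  one <- joint_dist(data.frame(A = "0", B = "1", p = 1))
  expect_equal(shannon_entropy(one), 0)

  # entropy equals the expectation of full-state surprisal
  r <- random_dist(2, 3, seed = 5)
  h <- sum(r$p * vapply(seq_len(nrow(r)), function(i) {
    local_surprisal(r, unlist(r[i, var_names(r)]))
  }, numeric(1)))
  expect_equal(h, shannon_entropy(r), tolerance = 1e-12)
})

test_that("KL divergence agrees with both defining forms and is non-negative", {
  xor <- logic_gate("XOR")
  expect_equal(kl_divergence(xor, xor), 0)
  expect_equal(kl_divergence(xor, product_of_marginals(xor)), 1)

  for (seed in 1:10) {
    P <- random_dist(3, 2, seed = seed)
    Q <- random_dist(3, 2, seed = seed + 500, concentration = 2)
    direct <- kl_divergence(P, Q)
    # oracle 1: direct sum on raw tables
    expect_equal(direct, oracle_kl(as.data.frame(P), as.data.frame(Q),
                                   var_names(P)), tolerance = 1e-9)
    # oracle 2: expected difference of local surprisals
    viah <- sum(P$p * vapply(seq_len(nrow(P)), function(i) {
      x <- unlist(P[i, var_names(P)])
      local_surprisal(Q, x) - local_surprisal(P, x)
    }, numeric(1)))
    expect_equal(direct, viah, tolerance = 1e-9)
    expect_gte(direct, -1e-9)
    # independence bound: the product of marginals never has less entropy
    expect_gte(shannon_entropy(product_of_marginals(P)) - shannon_entropy(P),
               -1e-9)
  }
})

test_that("support policies behave as documented", {
  # P has a state of mass 0.1 that Q lacks
  P <- joint_dist(data.frame(A = c("0", "1", "2"), p = c(0.5, 0.4, 0.1)),
                  alphabets = list(A = c("0", "1", "2")))
  Q <- joint_dist(data.frame(A = c("0", "1"), p = c(0.5, 0.5)),
                  alphabets = list(A = c("0", "1", "2")))

  expect_error(apply_support_policy(P, Q, "strict"),
               class = "infodecomp_error_support")

  ok <- apply_support_policy(Q, P, "strict")   # supp(Q) within supp(P)
  expect_identical(ok$P, Q)
  expect_identical(ok$Q, P)

  r <- apply_support_policy(P, Q, "restrict")
  expect_equal(nrow(r$P), 2L)
  expect_equal(sort(r$P$p), c(0.4, 0.5) / 0.9, tolerance = 1e-12)

  ps <- apply_support_policy(P, Q, "pseudocount", epsilon = 1e-6)
  expect_equal(nrow(ps$Q), 3L)    # the missing state now has mass
  expect_equal(sum(ps$Q$p), 1, tolerance = 1e-12)
  expect_equal(min(ps$Q$p), 1e-6 / (1 + 3e-6), tolerance = 1e-9)
  expect_error(apply_support_policy(P, Q, "pseudocount", epsilon = -1),
               class = "infodecomp_error_invalid")

  # mismatched spaces are rejected outright
  R <- joint_dist(data.frame(B = c("0", "1"), p = c(0.5, 0.5)))
  expect_error(apply_support_policy(P, R, "strict"),
               class = "infodecomp_error_invalid")
})
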