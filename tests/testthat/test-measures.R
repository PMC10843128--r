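test_that("total correlation and its decomposition match hand values", {
  xor <- logic_gate("XOR")
  expect_equal(total_correlation(xor), 1, tolerance = 1e-12)
  expect_equal(total_correlation(uniform_dist(3)), 0, tolerance = 1e-12)
  expect_equal(total_correlation(giant_bit(3)), 2, tolerance = 1e-12)

  tcx <- tc_decomposition(xor)
  expect_equal(atom_bits(tcx, "{X1,X2,T}"), 1, tolerance = 1e-9)
  expect_equal(sum(abs(tcx$bits)), 1, tolerance = 1e-9)

  # product distribution: all-zero table
  expect_equal(tc_decomposition(uniform_dist(3))$bits, rep(0, 18),
               tolerance = 1e-12)

  # giant bit: pairwise-joint redundancy plus top synergy
  tcg <- tc_decomposition(giant_bit(3))
  expect_equal(atom_bits(tcg, "{X1,X2}{X1,X3}{X2,X3}"), 1, tolerance = 1e-9)
  expect_equal(atom_bits(tcg, "{X1,X2,X3}"), 1, tolerance = 1e-9)
  expect_equal(sum(abs(tcg$bits)), 2, tolerance = 1e-9)

  # conservation on random distributions
  for (P in random_panel(3, 5, first_seed = 800L)) {
    expect_equal(sum(tc_decomposition(P)$bits), total_correlation(P),
                 tolerance = 1e-9)
  }
})

test_that("negentropy decomposition measures distance from maximum entropy", {
  expect_equal(negentropy_decomposition(uniform_dist(3))$bits, rep(0, 18),
               tolerance = 1e-12)
  xor <- logic_gate("XOR")
  expect_equal(sum(negentropy_decomposition(xor)$bits), 1, tolerance = 1e-9)
  one <- joint_dist(data.frame(A = "0", B = "0", C = "0", p = 1),
                    alphabets = list(A = c("0", "1"), B = c("0", "1"),
                                     C = c("0", "1")))
  expect_equal(sum(negentropy_decomposition(one)$bits), 3, tolerance = 1e-9)
})

test_that("O-information separates redundancy- from synergy-dominance", {
  expect_equal(o_information(logic_gate("XOR")), -1, tolerance = 1e-12)
  expect_equal(o_information(giant_bit(3)), 1, tolerance = 1e-12)
  expect_equal(o_information(uniform_dist(3)), 0, tolerance = 1e-12)
  expect_error(o_information(uniform_dist(2)),
               class = "infodecomp_error_invalid")
})

test_that("TSE complexity matches hand values and the product baseline", {
  expect_equal(tse_complexity(uniform_dist(3)), 0, tolerance = 1e-12)
  expect_equal(tse_complexity(logic_gate("XOR")), 1, tolerance = 1e-12)
  expect_equal(tse_complexity(giant_bit(3)), 1, tolerance = 1e-12)
})

test_that("atom expansions reproduce O-information and TSE at n = 3", {
  fixtures <- list(logic_gate("XOR"), giant_bit(3), uniform_dist(3))
  expected_o <- c(-1, 1, 0)
  expected_tse <- c(1, 1, 0)
  for (i in seq_along(fixtures)) {
    atoms <- tc_decomposition(fixtures[[i]])
    expect_equal(o_information_from_atoms(atoms), expected_o[i],
                 tolerance = 1e-8)
    expect_equal(tse_from_atoms(atoms), expected_tse[i], tolerance = 1e-8)
  }

  for (P in random_panel(3, 12, first_seed = 900L)) {
    atoms <- tc_decomposition(P)
    expect_equal(o_information_from_atoms(atoms), o_information(P),
                 tolerance = 1e-8)
    expect_equal(tse_from_atoms(atoms), tse_complexity(P), tolerance = 1e-8)
  }

  expect_error(o_information_from_atoms(tc_decomposition(uniform_dist(2))),
               class = "infodecomp_error_invalid")
  expect_error(tse_from_atoms(expected_ped(uniform_dist(2))),
               class = "infodecomp_error_invalid")
})

test_that("single-target PID recovers the pointwise decomposition", {
  # XOR: all mutual information is synergistic
  pid_xor <- pid_single_target(logic_gate("XOR"), "T")
  expect_atoms_equal(pid_xor, c("{X1}{X2}" = 0, "{X1}" = 0, "{X2}" = 0,
                                "{X1,X2}" = 1))

  # COPY (T = X1): the h_min decomposition is the informative/misinformative
  # one — 1 bit of pointwise redundancy offset by -1 bit unique to X2,
  # plus 1 bit of synergy. Oracle: r = E[min_i h(a_i)] - E[min_i h(a_i | t)]
  # computed directly, uniques from the marginal constraints, synergy from
  # the total.
  copy <- logic_gate("COPY")
  r_plus <- 1   # min(h(x1), h(x2)) = 1 at every state
  r_minus <- 0  # conditioned on t, x1 is certain: min(0, 1) = 0
  redundancy <- r_plus - r_minus
  i1 <- oracle_mutual_information(as.data.frame(copy), "X1", "T")
  i2 <- oracle_mutual_information(as.data.frame(copy), "X2", "T")
  itot <- oracle_mutual_information(as.data.frame(copy), c("X1", "X2"), "T")
  u1 <- i1 - redundancy
  u2 <- i2 - redundancy
  syn <- itot - redundancy - u1 - u2
  pid_copy <- pid_single_target(copy, "T")
  expect_atoms_equal(pid_copy, c("{X1}{X2}" = redundancy, "{X1}" = u1,
                                 "{X2}" = u2, "{X1,X2}" = syn))
  expect_equal(unname(c(redundancy, u1, u2, syn)), c(1, 0, -1, 1))

  # target independent of the inputs: nothing to decompose
  ind <- uniform_dist(3, var_names = c("X1", "X2", "T"))
  expect_equal(pid_single_target(ind, "T")$bits, rep(0, 4), tolerance = 1e-12)

  # conservation and the marginal constraints on random distributions
  for (P in random_panel(3, 8, first_seed = 950L)) {
    tab <- pid_single_target(P, 3)
    df <- as.data.frame(P)
    expect_equal(sum(tab$bits),
                 oracle_mutual_information(df, c("X1", "X2"), "X3"),
                 tolerance = 1e-9)
    expect_equal(atom_bits(tab, "{X1}{X2}") + atom_bits(tab, "{X1}"),
                 oracle_mutual_information(df, "X1", "X3"), tolerance = 1e-9)
    expect_equal(atom_bits(tab, "{X1}{X2}") + atom_bits(tab, "{X2}"),
                 oracle_mutual_information(df, "X2", "X3"), tolerance = 1e-9)
  }
})

test_that("the joint 18-atom decomposition of mutual information conserves it", {
  xor <- logic_gate("XOR")
  tab <- mi_joint_decomposition(xor, "T")
  expect_equal(nrow(tab), 18L)
  expect_equal(sum(tab$bits), 1, tolerance = 1e-9)

  ind <- uniform_dist(3, var_names = c("X1", "X2", "T"))
  expect_equal(mi_joint_decomposition(ind, "T")$bits, rep(0, 18),
               tolerance = 1e-12)

  for (P in random_panel(3, 5, first_seed = 980L)) {
    tab <- mi_joint_decomposition(P, 3)
    expect_equal(sum(tab$bits),
                 oracle_mutual_information(as.data.frame(P),
                                           c("X1", "X2"), "X3"),
                 tolerance = 1e-9)
  }
})
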