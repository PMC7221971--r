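# Graph-energy descriptors, dipeptide composition and feature fusion.

test_that("adjacency encoding maps residues to substitution-matrix columns", {
  A <- unit_matrix()
  M <- encode_adjacency("D", A)
  expect_equal(dim(M), c(20L, 1L))
  expect_equal(unname(M[, 1]), c(1, rep(0, 19)))  # D is first in the order

  M2 <- encode_adjacency("DD", A)
  expect_equal(M2[, 1], M2[, 2])

  B <- default_contact_matrix()
  M3 <- encode_adjacency("DK", B)
  expect_equal(unname(M3[, 1]), unname(B[, 1]))   # D: first column
  expect_equal(unname(M3[, 2]), unname(B[, 20]))  # K: last column
})

test_that("window energy matches closed forms and the eigenvalue oracle", {
  expect_equal(window_energy(matrix(0, 20, 20)), 0)

  # complete bipartite K_{a,b}: energy 2*sqrt(a*b)
  M <- matrix(0, 20, 20); M[1:3, 1:2] <- 1
  expect_equal(window_energy(M), 2 * sqrt(6), tolerance = 1e-12)

  # 20 identical residues under the unit matrix: single row of ones
  M <- matrix(0, 20, 20); M[5, ] <- 1
  expect_equal(window_energy(M), 2 * sqrt(20), tolerance = 1e-12)

  withr::with_seed(41, {
    for (i in 1:30) {
      Mr <- if (i %% 2) matrix(rbinom(400, 1, 0.2), 20, 20)
            else matrix(rnorm(400), 20, 20)
      expect_equal(window_energy(Mr), bipartite_energy_eig(Mr),
                   tolerance = 1e-8)
    }
  })

  expect_error(window_energy(matrix(c(NA, 1:399), 20, 20)), "non-finite")
})

test_that("window energy is symmetric, permutation invariant and homogeneous", {
  withr::with_seed(42, {
    for (i in 1:10) {
      M <- matrix(rnorm(400), 20, 20)
      e <- window_energy(M)
      expect_equal(window_energy(t(M)), e, tolerance = 1e-10)
      expect_equal(window_energy(M[sample(20), sample(20)]), e,
                   tolerance = 1e-10)
      cc <- rnorm(1)
      expect_equal(window_energy(cc * M), abs(cc) * e, tolerance = 1e-8)
    }
  })
})

test_that("identity-matrix window energy equals 2 * sum sqrt(residue counts)", {
  A <- unit_matrix()
  withr::with_seed(43, {
    for (i in 1:25) {
      s <- rand_seq(20)
      M <- encode_adjacency(s, A)
      counts <- table(strsplit(s, "")[[1]])
      expect_equal(window_energy(M), 2 * sum(sqrt(counts)),
                   tolerance = 1e-10)
    }
  })
})

test_that("energy profiles pad, truncate and window as specified", {
  A <- unit_matrix()
  e <- energy_profile(strrep("D", 219), A)
  expect_length(e, 200L)
  expect_equal(unname(e), rep(2 * sqrt(20), 200), tolerance = 1e-10)

  expect_warning(e19 <- energy_profile(strrep("D", 19), A), "window")
  expect_equal(e19, numeric(200))

  withr::with_seed(44, s21 <- rand_seq(21))
  e21 <- energy_profile(s21, A)
  expect_true(all(e21[1:2] > 0))
  expect_equal(e21[3:200], numeric(198))

  # truncation: profile of a longer sequence is the profile of its prefix
  withr::with_seed(45, s230 <- rand_seq(230))
  e230 <- energy_profile(s230, A)
  e_prefix <- energy_profile(substr(s230, 1, 219), A)
  expect_equal(e230, e_prefix)

  # entries beyond the available window count are exactly zero
  withr::with_seed(46, s60 <- rand_seq(60))
  e60 <- energy_profile(s60, A)
  expect_true(all(e60[1:41] > 0))
  expect_identical(e60[42:200], numeric(159))
})

test_that("dipeptide composition gives exact rational frequencies", {
  f <- dipeptide_composition("AAA")
  expect_length(f, 400L)
  expect_equal(unname(f["AA"]), 1)
  expect_equal(sum(f), 1)

  f2 <- dipeptide_composition("ACAC")
  expect_equal(unname(f2["AC"]), 2 / 3)
  expect_equal(unname(f2["CA"]), 1 / 3)
  expect_equal(sum(f2 != 0), 2L)

  withr::with_seed(47, {
    for (len in c(2, 5, 50, 300)) {
      fr <- dipeptide_composition(rand_seq(len))
      expect_equal(sum(fr), 1)
      # all entries rational with denominator L - 1
      expect_equal(fr * (len - 1), round(fr * (len - 1)), tolerance = 1e-9)
    }
  })

  expect_warning(f1 <- dipeptide_composition("A"), "no dipeptides")
  expect_equal(f1, stats::setNames(numeric(400), names(f1)))
})

test_that("fused descriptors concatenate the three blocks deterministically", {
  B <- default_contact_matrix()
  withr::with_seed(48, s <- rand_seq(19))
  v <- suppressWarnings(fuse_features(s, B = B))
  expect_length(v, 800L)
  expect_equal(unname(v[1:400]), numeric(400))  # no windows at length 19
  expect_equal(sum(v[401:800]), 1)

  hp <- strrep("D", 219)
  vh <- fuse_features(hp, B = B)
  expect_equal(unname(vh[1:200]), rep(2 * sqrt(20), 200), tolerance = 1e-10)
  expect_equal(unname(vh["dp_DD"]), 1)
  expect_identical(fuse_features(hp, B = B), vh)  # deterministic

  withr::with_seed(49, prot <- c(a = rand_seq(40), b = rand_seq(60)))
  X <- feature_matrix(prot, B = B)
  expect_equal(dim(X), c(2L, 800L))
  expect_equal(X["a", ], fuse_features(prot[["a"]], B = B))
})

test_that("contact matrices load with re-indexing and survive re-export", {
  B <- default_contact_matrix()
  expect_equal(dim(B), c(20L, 20L))
  expect_equal(rownames(B), aa_order())
  expect_equal(unname(B), unname(t(B)))  # stand-in is symmetric

  f <- tempfile()
  write_contact_matrix(B, f)
  expect_equal(unname(load_contact_matrix(f)), unname(B))

  # a tagged matrix in alphabetical order must be permuted correctly:
  # cell value encodes (row code, column code)
  alpha <- sort(aa_order())
  enc <- function(x) match(x, LETTERS)
  tag <- outer(alpha, alpha, function(r, c) 100 * enc(r) + enc(c))
  dimnames(tag) <- list(alpha, alpha)
  ft <- tempfile()
  utils::write.table(data.frame(aa = alpha, tag, check.names = FALSE), ft,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  got <- load_contact_matrix(ft)
  expect_equal(matrix(got, 20, 20),
               outer(aa_order(), aa_order(),
                     function(r, c) 100 * enc(r) + enc(c)))

  # shape and label validation
  bad <- tempfile()
  utils::write.table(data.frame(aa = alpha[1:19], tag[1:19, ],
                                check.names = FALSE),
                     bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_contact_matrix(bad), "20x20")
})
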