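test_that("worked four-haplotype example gives the exact textbook values", {
  m <- example_matrix()
  b <- basic_stats(m)
  expect_identical(b$S, 2L)
  expect_equal(b$pi, 7 / 6)
  expect_equal(b$hap_div, 5 / 6)
  # single site pair: p_A = 3/4, p_B = 1/2, p_AB = 1/2 -> D = 1/8, r2 = 1/3
  ld <- ld_stats(m)
  expect_equal(ld$kellys_zns, 1 / 3)
  expect_equal(ld$rozas_za, 1 / 3)
  expect_equal(ld$rozas_zz, 0)
  # partitions {1 | 234} vs {12 | 34} are incongruent -> B' = 0
  wq <- walls_b_q(m)
  expect_equal(wq$walls_b, 0)
  expect_equal(wq$walls_q, 0)
  # Tajima's D from first principles at n = 4, S = 2, pi = 7/6
  expect_equal(tajimas_d(m), oracle_tajimas_d(as.matrix(m)))
})

test_that("degenerate and small-S inputs follow the documented conventions", {
  mono <- hap_matrix(matrix(0L, 4, 0), integer(0), c(0L, 100L))
  b <- basic_stats(mono)
  expect_equal(b$S, 0L)
  expect_equal(b$pi, 0)
  expect_equal(b$hap_div, 0)
  expect_true(is.na(tajimas_d(mono)))
  ws <- window_stats(mono)
  expect_true(ws$degenerate)
  # S = 1: Wall's B undefined, Q = 0, LD undefined
  one <- hap_matrix(matrix(c(0L, 1L, 1L, 0L), 4, 1), 5L, c(0L, 100L))
  expect_true(is.na(walls_b_q(one)$walls_b))
  expect_equal(walls_b_q(one)$walls_q, 0)
  expect_true(is.na(ld_stats(one)$kellys_zns))
  expect_false(window_stats(one)$degenerate)
})

test_that("statistics match brute-force enumeration on random matrices", {
  set.seed(401)
  for (rep in 1:200) {
    m <- random_hap_matrix(S = sample(1:8, 1))
    mm <- as.matrix(m)
    expect_equal(basic_stats(m)$pi, oracle_pi(mm), tolerance = 1e-12)
    expect_equal(basic_stats(m)$hap_div, oracle_hap_div(mm), tolerance = 1e-12)
    expect_equal(tajimas_d(m), oracle_tajimas_d(mm), tolerance = 1e-12)
    fl <- fu_li_d_f(m)
    or <- oracle_fu_li(mm)
    expect_equal(fl$fu_li_d, or$d, tolerance = 1e-12)
    expect_equal(fl$fu_li_f, or$f, tolerance = 1e-12)
    wq <- walls_b_q(m)
    ow <- oracle_walls(mm)
    expect_equal(wq$walls_b, ow$b, tolerance = 1e-12)
    expect_equal(wq$walls_q, ow$q, tolerance = 1e-12)
    if (ncol(m) >= 2) {
      ld <- ld_stats(m)
      ol <- oracle_ld(mm)
      expect_equal(ld$kellys_zns, ol$zns, tolerance = 1e-12)
      expect_equal(ld$rozas_za, ol$za, tolerance = 1e-12)
      expect_equal(ld$rozas_zz, ol$zz, tolerance = 1e-12)
    }
  }
})

test_that("row permutation leaves all statistics unchanged", {
  set.seed(402)
  m <- random_hap_matrix(n = 8, S = 6)
  perm <- hap_matrix(as.matrix(m)[sample(8), ], positions(m), span(m))
  expect_equal(window_stats(m)[, summary_stat_names()],
               window_stats(perm)[, summary_stat_names()])
})

test_that("frequency-based statistics are invariant to duplicating every haplotype twice over", {
  # duplicating rows leaves per-site frequencies unchanged
  set.seed(403)
  m <- random_hap_matrix(n = 5, S = 4)
  dup <- as.matrix(m)[rep(1:5, 2), ]
  expect_equal(colMeans(dup), colMeans(as.matrix(m)))
})

test_that("structural identities: duplicate columns, S = 2 implies ZZ = 0, singletons push Fu & Li negative", {
  # two identical adjacent columns are congruent and in perfect LD
  m <- hap_matrix(cbind(c(0L, 1L, 1L, 0L), c(0L, 1L, 1L, 0L)),
                  c(10L, 20L), c(0L, 100L))
  expect_equal(walls_b_q(m)$walls_b, 1)
  expect_equal(ld_stats(m)$kellys_zns, 1)
  # with S = 2 the adjacent-pair set equals the all-pair set
  set.seed(404)
  for (i in 1:20) {
    m2 <- random_hap_matrix(S = 2)
    expect_equal(ld_stats(m2)$rozas_zz, 0)
  }
  # all-singleton matrix: strongly negative D and F, agreeing in sign
  n <- 12
  sing <- diag(1L, n)[, 1:6]
  ms <- hap_matrix(sing, seq(0L, 50L, by = 10L), c(0L, 100L))
  fl <- fu_li_d_f(ms)
  expect_lt(fl$fu_li_d, -1)
  expect_lt(fl$fu_li_f, -1)
  expect_equal(sign(fl$fu_li_d), sign(fl$fu_li_f))
})

test_that("window restriction is consistent and additive in S", {
  set.seed(405)
  m <- random_hap_matrix(n = 10, S = 8, span_len = 1000)
  whole <- window_stats(m)
  again <- window_stats(m, 0, 1000)
  expect_equal(whole[, summary_stat_names()], again[, summary_stat_names()])
  # two disjoint windows partition the sites
  left <- window_stats(m, 0, 500)
  right <- window_stats(m, 500, 1000)
  expect_equal(left$S + right$S, whole$S)
  # ranges hold on random windows
  eps <- 1e-12
  for (i in 1:50) {
    r <- random_hap_matrix()
    w <- window_stats(r)
    expect_true(w$hap_div >= 0 && w$hap_div <= 1 + eps)
    if (!is.na(w$walls_b)) expect_true(w$walls_b >= 0 && w$walls_b <= 1)
    if (!is.na(w$walls_q)) expect_true(w$walls_q >= 0 && w$walls_q <= 1)
    if (!is.na(w$kellys_zns))
      expect_true(w$kellys_zns >= 0 && w$kellys_zns <= 1 + eps)
  }
})
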