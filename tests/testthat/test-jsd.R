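test_that("JSD matches hand-computed and limiting values", {
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2))
  # M = (0.75, 0.25); D_KL(P||M) = 0.1438410, D_KL(Q||M) = 0.2876821
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.2157616, tolerance = 1e-6)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0), base = 2),
               0.2157616 / log(2), tolerance = 1e-6)
  expect_error(jsd(c(0.5, 0.5), c(0.7, 0.2)), "sum to 1")
  expect_error(jsd(c(1.5, -0.5), c(0.5, 0.5)), "non-negative")
})

test_that("JSD is symmetric and bounded on random compositions", {
  set.seed(12)
  for (k in 1:25) {
    p <- stats::rgamma(6, 1); p <- p / sum(p)
    q <- stats::rgamma(6, 1); q <- q / sum(q)
    v <- jsd(p, q)
    expect_equal(v, jsd(q, p))
    expect_gte(v, 0)
    expect_lte(v, log(2) + 1e-12)
  }
})

test_that("named profiles outer-join on the taxon set", {
  p <- c(a = 0.5, b = 0.5)
  q <- c(b = 0.5, c = 0.5)
  expect_equal(jsd(p, q), jsd(c(0.5, 0.5, 0), c(0, 0.5, 0.5)))
})

test_that("pairwise matrix is symmetric, zero-diagonal, and consistent", {
  set.seed(13)
  m <- matrix(stats::rgamma(12, 1), 3)
  m <- m / rowSums(m)
  rownames(m) <- paste0("s", 1:3)
  dm <- pairwise_jsd(m)
  expect_identical(dm, t(dm))
  expect_equal(diag(dm), stats::setNames(rep(0, 3), rownames(m)))
  expect_equal(dm[1, 2], jsd(m[1, ], m[2, ]))
  expect_equal(dm[2, 3], jsd(m[2, ], m[3, ]))
  # identical samples give an all-zero matrix
  expect_true(all(pairwise_jsd(rbind(m[1, ], m[1, ])) == 0))
})

test_that("site grouping yields the right pair counts and U p-values", {
  prof <- list(base = c(a = 0.6, b = 0.3, c = 0.1),
               tip = c(a = 0.1, b = 0.3, c = 0.6))
  tab <- gen_abundance_table(prof, concentration = 200, n_per_site = 3,
                             seed = 14)
  dm <- pairwise_jsd(as.matrix(tab[, -(1:2)]))
  gc <- grouped_comparison(dm, tab$site, alternative = "less")
  expect_length(gc$groups$base_base, 3)
  expect_length(gc$groups$tip_tip, 3)
  expect_length(gc$groups$base_tip, 9)
  # distinct site compositions: within < between
  expect_lt(stats::median(gc$groups$base_base),
            stats::median(gc$groups$base_tip))
  # p-values agree with an exact enumeration oracle
  p_oracle <- exact_mwu_less(gc$groups$base_base, gc$groups$base_tip)
  row <- gc$tests[gc$tests$group1 == "base_base" &
                    gc$tests$group2 == "base_tip", ]
  expect_equal(row$p_value, p_oracle, tolerance = 1e-12)
  # all-tied distances carry no evidence
  flat <- matrix(0.2, 6, 6); diag(flat) <- 0
  gflat <- grouped_comparison(flat, rep(c("base", "tip"), each = 3),
                              alternative = "less")
  expect_equal(nrow(gflat$tests), 3L)
  expect_true(all(gflat$tests$p_value == 1))
})

test_that("undersized site groups are skipped with a warning", {
  dm <- pairwise_jsd(rbind(c(0.5, 0.5), c(0.4, 0.6), c(0.1, 0.9)))
  warns <- capture_warnings(
    gc <- grouped_comparison(dm, c("base", "base", "tip"),
                             alternative = "greater"))
  expect_true(length(warns) >= 1 && all(grepl("fewer than 2", warns)))
  expect_false(any(grepl("tip_tip", gc$tests$group1)))
})
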