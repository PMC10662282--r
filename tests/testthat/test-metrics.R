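test_that("Flux-Ninorg is the trapezoidal integral of the six
           transformation fluxes", {
  expect_equal(flux_ninorg(fake_traj(0:10, flux_total = 0)), 0)
  expect_equal(flux_ninorg(fake_traj(0:10, flux_total = 2)), 20)
  # piecewise-linear series against a hand trapezoid
  t <- c(0, 1, 3, 6)
  v <- c(0, 2, 2, 5)
  hand <- (0 + 2) / 2 * 1 + (2 + 2) / 2 * 2 + (2 + 5) / 2 * 3
  expect_equal(flux_ninorg(fake_traj(t, flux_total = v)), hand)
})

test_that("Enz-Ninorg production reading integrates the synthesis budget", {
  tr <- fake_traj(0:10, pEP = 0.01)
  e <- enz_ninorg(tr, const_forcing(10, B = 100), "production")
  expect_equal(e$total, 10)               # 0.01 * 100 * 10 d
  expect_equal(unname(e$per_group), rep(10 / 6, 6))
})

test_that("the grand enzyme production total is allocation-invariant", {
  su <- quick_setup(years = 1)
  cfg <- simulation_config(t0 = 0, t1 = 365, dt_out = 1, scheme = "A1")
  e1 <- enz_ninorg(run_simulation(cfg, su$params, su$forcing), su$forcing)
  cfg$scheme <- "A2"
  e2 <- enz_ninorg(run_simulation(cfg, su$params, su$forcing), su$forcing)
  expect_equal(e1$total, e2$total, tolerance = 1e-8)
  # but the per-group split differs strongly
  expect_gt(max(abs(e1$per_group - e2$per_group)) / e1$total, 0.05)
})

test_that("percent bias and NSE match hand arithmetic", {
  expect_equal(percent_bias(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(percent_bias(rep(110, 4), rep(100, 7)), 10)
  expect_equal(percent_bias(c(30, 50), c(40, 60)), -20)
  expect_error(percent_bias(1:3, c(-1, 0, 1)), "zero")

  expect_equal(nse(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(nse(rep(2, 3), c(1, 2, 3)), 0)
  # worse than the mean predictor: hand value
  expect_equal(nse(c(0, 4, 8), c(1, 2, 3)), 1 - 30 / 2)
  expect_error(nse(1:3, rep(2, 3)), "constant")
  expect_error(nse(1:3, 1:4), "equal-length")
})

test_that("percent bias is directional, not symmetric", {
  expect_equal(percent_bias(c(40), c(50)), -20)
  expect_equal(percent_bias(c(50), c(40)), 25)  # not +20: denominator swaps
})

test_that("signed-rank statistic and exact p match the enumeration
           oracle on canonical cases", {
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
  # five positive (distinct) differences, one-sided
  w <- wilcoxon_signed_rank(1:5 + 1:5, 1:5, alternative = "greater")
  expect_equal(w$W_minus, 0)
  expect_equal(w$p.value, 1 / 32)
  expect_equal(w$method, "exact")
  # mixed-sign hand case
  d <- c(1, -2, 3, -4, 5, 6)
  w2 <- wilcoxon_signed_rank(d, rep(0, 6))
  expect_equal(w2$W_plus, 15)
  expect_equal(w2$p.value, enum_signrank_p(d, "two.sided"))
})

test_that("the exact branch equals full 2^n enumeration on randomized
           tie-free inputs", {
  set.seed(99)
  for (n in 2:10) {
    for (rep in 1:6) {
      d <- round(runif(n, 0.5, 20), 3) * sample(c(-1, 1), n, TRUE)
      while (any(duplicated(abs(d)))) d <- d + runif(n, 0, 1e-3)
      for (alt in c("two.sided", "greater", "less")) {
        w <- wilcoxon_signed_rank(d, rep(0, n), alternative = alt)
        expect_equal(w$method, "exact")
        expect_equal(w$p.value, enum_signrank_p(d, alt),
                     info = paste(n, alt))
      }
      # independent cross-check against the stats implementation
      ref <- stats::wilcox.test(d, alternative = "two.sided", exact = TRUE)
      expect_equal(wilcoxon_signed_rank(d, rep(0, n))$p.value,
                   unname(ref$p.value))
    }
  }
})

test_that("tied or long inputs fall back to the corrected normal
           approximation", {
  set.seed(4)
  d <- c(2, -2, 3, 3, -5, 7, 8, -8, 10, 12)   # ties in |d|
  w <- wilcoxon_signed_rank(d, rep(0, 10))
  expect_equal(w$method, "normal")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(w$p.value, unname(ref$p.value), tolerance = 1e-10)
  long <- runif(30, 1, 50) * sample(c(-1, 1), 30, TRUE)
  expect_equal(wilcoxon_signed_rank(long, rep(0, 30))$method, "normal")
})

test_that("zero differences: drop-zeros default and Pratt variant", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 1, 1)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$n_used, 2)
  wp <- wilcoxon_signed_rank(x, y, zero_method = "pratt")
  expect_equal(wp$n_used, 2)
  expect_gt(wp$W_plus, w$W_plus)   # pratt keeps zero ranks in the scale
})

test_that("compact letters separate exactly the significant pairs", {
  lab <- c("A0", "A1", "A2")
  pm <- function(v) {
    m <- matrix(1, 3, 3, dimnames = list(lab, lab))
    m[lower.tri(m)] <- v; m[upper.tri(m)] <- t(m)[upper.tri(m)]; m
  }
  all_sig <- pm(c(1e-5, 1e-5, 1e-5))
  expect_equal(unname(letter_groups(all_sig, alpha = 0.001)),
               c("a", "b", "c"))
  none_sig <- pm(c(0.5, 0.9, 0.2))
  expect_equal(unname(letter_groups(none_sig, alpha = 0.001)),
               rep("a", 3))
  one_ns <- pm(c(1e-5, 1e-5, 0.8))  # (A1,A2) not significant
  lg <- letter_groups(one_ns, alpha = 0.001)
  shares <- function(a, b)
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  expect_false(shares(lg["A0"], lg["A1"]))
  expect_false(shares(lg["A0"], lg["A2"]))
  expect_true(shares(lg["A1"], lg["A2"]))
  # brute-force: sharing relation reproduces the p >= alpha relation
  set.seed(12)
  for (i in 1:20) {
    m <- pm(sample(c(1e-6, 0.5), 3, TRUE))
    lg <- letter_groups(m, alpha = 0.001)
    for (a in 1:2) for (b in (a + 1):3)
      expect_equal(shares(lg[a], lg[b]), m[a, b] >= 0.001)
  }
  expect_error(letter_groups(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
})

test_that("scheme comparison aggregates metrics, pairwise tests and
           letters coherently", {
  su <- quick_setup(years = 2, cv = 0.1, n_rep = 4)
  obs <- make_observations(su$spec, su$params, su$config, su$forcing)
  rep_out <- compare_schemes(su$config, su$params, su$forcing, obs = obs,
                             n_rep = 8, seed = 3)
  m <- rep_out$metrics
  expect_setequal(m$scheme, c("A0", "A1", "A2"))
  expect_equal(m$efficiency, m$flux_ninorg / m$enz_production)
  # production budget identity across schemes
  expect_lt(diff(range(m$enz_production)) / mean(m$enz_production), 1e-8)
  # paired replicates: same parameter draw per row across schemes
  expect_equal(dim(rep_out$replicates), c(8, 3))
  expect_true(isSymmetric(rep_out$pairwise_p))
  expect_named(rep_out$letters, c("A0", "A1", "A2"))
  expect_equal(dim(rep_out$pbias), c(6L, 3L))
  # engineered symmetry: one shared substrate saturation collapses all
  # three schemes onto identical trajectories
  p <- kinetic_params(Ks = rep(1, 6), N2_boundary = "dynamic",
                      bnf_inhibition = FALSE, gNO = 0, gN2O = 0)
  cfg <- simulation_config(t0 = 0, t1 = 100, dt_out = 10, scheme = "A0",
                           state0 = initial_state(N = rep(2, 6),
                                                  E = rep(0.5, 6),
                                                  ON = 10))
  frc <- dead_forcing(t1 = 100)
  tA0 <- run_simulation(cfg, p, frc)
  cfg$scheme <- "A1"
  tA1 <- run_simulation(cfg, p, frc)
  expect_equal(tA0$state, tA1$state, tolerance = 1e-7)
})
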