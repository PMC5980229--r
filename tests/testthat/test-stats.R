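test_that("chi-square reproduces hand-checkable structure", {
  # identical row proportions -> statistic exactly 0
  expect_equal(chi_square(rbind(c(10, 20), c(20, 40)))$statistic, 0)
  # df = (r-1)(c-1)
  expect_equal(chi_square(rbind(c(5, 6, 7), c(8, 9, 10)))$df, 2L)
  # zero marginals are named errors
  expect_error(chi_square(rbind(c(0, 0), c(3, 5))), "row 1")
  expect_error(chi_square(rbind(c(0, 5), c(0, 3))), "column 1")
  expect_error(chi_square(matrix(1:3, ncol = 1)), "2 x 2")
})

test_that("2x2 chi-square equals the squared two-proportion z statistic", {
  set.seed(510)
  for (rep in 1:50) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
    p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
    pp <- sum(tab[, 1]) / sum(tab)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(chi_square(tab)$statistic, z^2, tolerance = 1e-10)
  }
})

test_that("chi-square is invariant under row and column permutation", {
  set.seed(511)
  tab <- matrix(sample(5:40, 6), 3)
  s <- chi_square(tab)$statistic
  expect_equal(chi_square(tab[c(3, 1, 2), ])$statistic, s)
  expect_equal(chi_square(tab[, 2:1])$statistic, s)
})

test_that("fisher exact matches enumeration and the reference routine", {
  # brute force: enumerate every table with the observed margins
  brute_fisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    supp <- max(0, k - n):min(k, m)
    pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
    obs <- pr[supp == tab[1, 1]]
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  tab <- rbind(c(1, 9), c(9, 1))
  expect_equal(fisher_exact_2x2(tab)$p, brute_fisher(tab), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tab)$p,
               fisher.test(tab)$p.value, tolerance = 1e-9)
  # identical proportions -> p = 1; symmetric under row swap
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$p, 1)
  set.seed(512)
  for (rep in 1:100) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)$p
    expect_equal(p, brute_fisher(tab), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p, p, tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U matches full permutation enumeration at n = 5", {
  brute_mw <- function(a, b) {
    n1 <- length(a); N <- n1 + length(b)
    r <- rank(c(a, b))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- combn(N, n1)
    us <- apply(combos, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p_le <- mean(us <= u_obs + 1e-9)
    p_ge <- mean(us >= u_obs - 1e-9)
    list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
  }
  set.seed(513)
  for (rep in 1:100) {
    a <- round(runif(5, 0, 10), sample(0:1, 1))  # ties likely at 0 digits
    b <- round(runif(5, 0, 10), 1)
    got <- mann_whitney_u(a, b)
    want <- brute_mw(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # tie-free case agrees with the exact reference implementation
  for (rep in 1:20) {
    a <- rnorm(6); b <- rnorm(8)
    expect_equal(mann_whitney_u(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney degenerate and asymptotic branches behave", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4)
  got <- mann_whitney_u(a, b)
  expect_equal(got$U, 8)            # n1 n2 / 2
  expect_equal(got$p, 1)
  # complete separation gives the minimal U
  sep <- mann_whitney_u(1:5, 11:15)
  expect_equal(sep$U, 0)
  # large samples: normal approximation with tie correction, no
  # continuity correction, matches the reference routine
  set.seed(514)
  a <- round(rnorm(30, 0, 2)); b <- round(rnorm(40, 1, 2))
  got <- mann_whitney_u(a, b)
  expect_false(got$exact)
  want <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(got$p, want, tolerance = 1e-9)
})

test_that("Wilcoxon signed-rank matches 2^n sign enumeration at n = 10", {
  brute_wsr <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    ws <- apply(signs, 1, function(s) sum(r[unlist(s)]))
    p_le <- mean(ws <= w_obs + 1e-9)
    p_ge <- mean(ws >= w_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(515)
  for (rep in 1:60) {
    d <- round(rnorm(10, 0.3, 1), sample(0:1, 1))
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p, brute_wsr(d), tolerance = 1e-12)
  }
  # tie-free case agrees with the exact reference implementation
  for (rep in 1:20) {
    d <- rnorm(12, 0.5)
    expect_equal(wilcoxon_signed_rank(d)$p,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-9)
  }
})

test_that("Wilcoxon handles degenerate inputs per contract", {
  # all zero differences: abstain
  got <- wilcoxon_signed_rank(rep(0, 6))
  expect_true(is.na(got$p))
  expect_equal(got$n, 0L)
  # a single nonzero difference can never reach significance: p = 1
  expect_equal(wilcoxon_signed_rank(c(0, 0, 0.7))$p, 1)
  # asymptotic branch matches the reference without continuity correction
  set.seed(516)
  d <- rnorm(40, 0.2)
  got <- wilcoxon_signed_rank(d)
  expect_false(got$exact)
  expect_equal(got$p, wilcox.test(d, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("laser modulation classifies constructed units correctly", {
  set.seed(517)
  onsets <- seq(100, by = 20, length.out = 10)  # 10 s OFF / 10 s ON
  mk_unit <- function(off_rate, on_rate) {
    st <- sort(unlist(lapply(onsets, function(o)
      c(poisson_train(off_rate, o - 10, o), poisson_train(on_rate, o, o + 10)))))
    make_unit(st[c(TRUE, diff(st) > 0)])
  }
  drop <- classify_laser_modulation(mk_unit(6, 1), onsets, "ArchT")
  expect_equal(drop$label, "decrease")
  expect_lt(drop$on_rate_hz, drop$off_rate_hz)
  up <- classify_laser_modulation(mk_unit(4, 8), onsets, "ArchT")
  expect_equal(up$label, "increase")
})

test_that("laser test holds its nominal size on invariant units", {
  set.seed(518)
  onsets <- seq(100, by = 20, length.out = 10)
  labels <- vapply(1:200, function(i) {
    st <- poisson_train(6, 80, 310)
    classify_laser_modulation(st, onsets, "ArchT")$label
  }, character(1))
  expect_gte(mean(labels == "none"), 0.9)
})
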