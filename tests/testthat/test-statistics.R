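test_that("BH step-up matches hand-stepped examples and p.adjust", {
  expect_equal(fdr_correct(c(0.001, 0.02, 0.03, 0.04), q = 0.05),
               rep(TRUE, 4))
  expect_equal(fdr_correct(rep(1, 6), q = 0.05), rep(FALSE, 6))
  expect_true(fdr_correct(0.004, q = 0.01))    # m = 1: raw threshold
  expect_identical(fdr_correct(numeric(0), 0.05), logical(0))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
  withr::with_seed(2, {
    for (i in 1:5) {
      p <- runif(200)^2
      q <- runif(1, 0.01, 0.2)
      expect_identical(fdr_correct(p, q),
                       p.adjust(p, method = "BH") <= q)
    }
  })
})

test_that("identical condition maps yield no significant points", {
  maps <- random_maps(6, seed = 1)
  mask <- compare_maps_permutation(maps, maps, n_perm = 200, alpha = 0.05)
  expect_false(any(mask$mask))
  expect_true(all(mask$p == 1))
})

test_that("mismatched grids and unpaired inputs are rejected", {
  a <- random_maps(5, seed = 2)
  b <- random_maps(5, nf = 9, seed = 3)
  expect_error(compare_maps_permutation(a, b, n_perm = 100), "grids")
  expect_error(compare_maps_permutation(a[1:3], a[1:2], n_perm = 100),
               "paired")
})

test_that("permutation p-values ignore a common additive offset", {
  a <- random_maps(8, seed = 4)
  b <- random_maps(8, seed = 5)
  shift <- function(maps, c) lapply(maps, function(m) {
    m$values <- m$values + c
    m
  })
  m1 <- compare_maps_permutation(a, b, n_perm = 500, alpha = 0.05, seed = 9)
  m2 <- compare_maps_permutation(shift(a, 3.7), shift(b, 3.7),
                                 n_perm = 500, alpha = 0.05, seed = 9)
  expect_equal(m2$p, m1$p, tolerance = 1e-12)
})

test_that("small samples switch to exhaustive sign enumeration", {
  a <- random_maps(5, nf = 2, nt = 2, seed = 6)
  b <- random_maps(5, nf = 2, nt = 2, seed = 7)
  m <- compare_maps_permutation(a, b, n_perm = 100, alpha = 0.05)
  expect_equal(m$n_permutations, 2^5)
  ## exhaustive p-values are multiples of 1/32, never below 1/32
  expect_true(all(abs(m$p * 32 - round(m$p * 32)) < 1e-9))
  expect_true(all(m$p >= 1 / 32))
})

test_that("an injected localized difference is localized by the mask", {
  withr::with_seed(8, {
    nf <- 10; nt <- 20
    a <- lapply(1:12, function(s) {
      v <- matrix(rnorm(nf * nt, sd = 0.3), nf, nt)
      v[7:9, 13:16] <- v[7:9, 13:16] + 1.5
      ersp_map(v, seq_len(nf), seq_len(nt))
    })
    b <- lapply(1:12, function(s)
      ersp_map(matrix(rnorm(nf * nt, sd = 0.3), nf, nt),
               seq_len(nf), seq_len(nt)))
    ## n_perm >= 2^12 triggers exhaustive enumeration: the p floor of
    ## 2/4096 can pass the Benjamini-Hochberg threshold at q = 0.01
    m <- compare_maps_permutation(a, b, n_perm = 4096, alpha = 0.01,
                                  seed = 3)
    inside <- matrix(FALSE, nf, nt); inside[7:9, 13:16] <- TRUE
    expect_gt(sum(m$mask & inside) / max(1, sum(m$mask)), 0.9)
    expect_gt(mean(m$mask[inside]), 0.8)
  })
})

test_that("contrast-based F equals the squared paired t of the contrast", {
  cells <- random_cells(seed = 10)
  res <- rm_anova_2x2x2(cells, factors = c("A", "B", "C"))
  ## rebuild each contrast score and its paired t by hand
  lv <- lapply(cells[c("A", "B", "C")], function(v) sort(unique(v)))
  for (i in seq_len(nrow(res$table))) {
    vars <- strsplit(res$table$effect[i], ":", fixed = TRUE)[[1]]
    w <- rep(1, nrow(cells))
    for (v in vars) w <- w * ifelse(cells[[v]] == lv[[v]][1], -1, 1)
    score <- tapply(cells$value * w, cells$subject, mean)
    tv <- mean(score) / (sd(score) / sqrt(length(score)))
    expect_equal(res$table$F[i], tv^2, tolerance = 1e-10)
    expect_equal(res$table$df2[i], length(score) - 1)
  }
})

test_that("contrast-based F matches the sums-of-squares oracle", {
  for (seed in c(21, 22, 23)) {
    cells <- random_cells(n_subjects = 12, seed = seed, effects = 0.8)
    res <- rm_anova_2x2x2(cells, factors = c("A", "B", "C"))
    oracle <- ss_anova_oracle(cells, c("A", "B", "C"))
    for (i in seq_len(nrow(res$table))) {
      expect_equal(res$table$F[i], oracle[[res$table$effect[i]]],
                   tolerance = 1e-8)
    }
  }
})

test_that("F agrees with stats::aov under an Error(subject) stratum", {
  cells <- random_cells(n_subjects = 8, seed = 30, effects = 1)
  cells$subject <- factor(cells$subject)
  fit <- summary(stats::aov(value ~ A * B * C + Error(subject / (A * B * C)),
                            data = cells))
  res <- rm_anova_2x2x2(cells, factors = c("A", "B", "C"))
  get_f <- function(stratum, term) {
    tab <- fit[[paste0("Error: subject:", stratum)]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(res$table$F[res$table$effect == "A"], get_f("A", "A"),
               tolerance = 1e-8)
  expect_equal(res$table$F[res$table$effect == "A:B"], get_f("A:B", "A:B"),
               tolerance = 1e-8)
  expect_equal(res$table$F[res$table$effect == "A:B:C"],
               get_f("A:B:C", "A:B:C"), tolerance = 1e-8)
})

test_that("ANOVA F is invariant to affine rescaling of the cell values", {
  cells <- random_cells(seed = 12, effects = 0.5)
  r1 <- rm_anova_2x2x2(cells, factors = c("A", "B", "C"))
  cells$value <- cells$value * -3.2 + 11
  r2 <- rm_anova_2x2x2(cells, factors = c("A", "B", "C"))
  expect_equal(r2$table$F, r1$table$F, tolerance = 1e-9)
})

test_that("degenerate and incomplete ANOVA inputs are rejected", {
  cells <- random_cells(seed = 13)
  expect_error(rm_anova_2x2x2(cells[-1, ], factors = c("A", "B", "C")),
               "missing")
  same <- random_cells(seed = 14)
  same$value <- 5
  res <- rm_anova_2x2x2(same, factors = c("A", "B", "C"))
  expect_true(all(res$table$F == 0))
})

test_that("Bonferroni post-hocs scale the per-test threshold", {
  withr::with_seed(15, {
    x <- rnorm(12); y <- x - 1.2 + rnorm(12, sd = 0.3)
    ph2 <- posthoc_bonferroni(list(a = list(x = x, y = y),
                                   b = list(x = x, y = x + rnorm(12))),
                              family_alpha = 0.05)
    expect_equal(unique(ph2$alpha_adj), 0.025)
    expect_true(ph2$significant[ph2$comparison == "a"])
    ph1 <- posthoc_bonferroni(list(a = list(x = x, y = y)),
                              family_alpha = 0.05)
    expect_equal(ph1$alpha_adj, 0.05)
    ## identical samples: t = 0, not significant
    expect_warning(
      ph0 <- posthoc_bonferroni(list(z = list(x = x, y = x + 2))),
      "zero-variance")
    expect_equal(ph0$t, 0)
    expect_equal(ph0$p, 1)
  })
})

test_that("band/window extraction averages the selected grid cells", {
  m <- ersp_map(matrix(2.5, 10, 10), seq(10, 28, by = 2),
                seq(100, 1000, by = 100))
  for (bw in list(band_window_spec(c(13, 28), c(600, 800), "beta ERS"),
                  band_window_spec(c(10, 12), c(200, 400), "mu ERD"))) {
    expect_equal(extract_band_window_means(m, bw), 2.5)
  }
  ## a hand-computed non-constant case
  m2 <- ersp_map(matrix(seq_len(100), 10, 10), seq(10, 28, by = 2),
                 seq(100, 1000, by = 100))
  bw <- band_window_spec(c(12, 14), c(200, 300), "x")
  expect_equal(extract_band_window_means(m2, bw),
               mean(m2$values[2:3, 2:3]))
  expect_error(
    extract_band_window_means(m2, band_window_spec(c(12, 14), c(900, 1100))),
    "outside")
})

test_that("BH-FDR controls the empirical FDR on an 80/20 mixture", {
  withr::with_seed(16, {
    q <- 0.1
    fdp <- replicate(200, {
      m <- 500
      is_null <- runif(m) < 0.8
      p <- ifelse(is_null, runif(m),
                  pnorm(rnorm(m, mean = 3), lower.tail = FALSE))
      rej <- fdr_correct(p, q)
      if (any(rej)) sum(rej & is_null) / sum(rej) else 0
    })
    expect_lt(mean(fdp), q + 0.02)
  })
})
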