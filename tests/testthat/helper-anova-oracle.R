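# Brute-force within-subject ANOVA oracle: full sums-of-squares
# decomposition of the 2x2x2xS table; F_effect = MS_effect / MS_effect:subject.
ss_anova_oracle <- function(cells, factors) {
  y <- cells$value
  gm <- mean(y)
  subj <- factor(cells$subject)
  fl <- lapply(cells[factors], factor)
  effect_ss <- function(vars) {
    ## SS of the interaction term = SS of cell means minus lower-order terms
    terms_of <- function(vs) {
      if (length(vs) == 0) return(0)
      key <- interaction(fl[vs], drop = TRUE)
      means <- tapply(y, key, mean)
      counts <- table(key)
      sum(counts * (means - gm)^2) -
        sum(vapply(seq_len(length(vs) - 1), function(k) {
          sum(vapply(utils::combn(vs, k, simplify = FALSE),
                     function(sub) terms_of(sub), numeric(1)))
        }, numeric(1)))
    }
    terms_of(vars)
  }
  err_ss <- function(vars) {
    ## SS of effect x subject, by the same decomposition with subject added
    key_full <- interaction(c(fl[vars], list(subj)), drop = TRUE)
    means <- tapply(y, key_full, mean)
    counts <- table(key_full)
    total <- sum(counts * (means - gm)^2)
    lower <- effect_ss(vars) + err_ss_cache[["S"]]
    if (length(vars) > 1) {
      for (k in seq_len(length(vars) - 1)) {
        for (sub in utils::combn(vars, k, simplify = FALSE)) {
          lower <- lower + effect_ss(sub) + err_ss(sub)
        }
      }
    } else if (length(vars) == 0) {
      return(err_ss_cache[["S"]])
    }
    total - lower
  }
  smeans <- tapply(y, subj, mean)
  err_ss_cache <- list(S = sum(table(subj) * (smeans - gm)^2))
  n <- nlevels(subj)
  out <- list()
  for (k in 1:3) {
    for (vars in utils::combn(factors, k, simplify = FALSE)) {
      ssx <- effect_ss(vars)
      sse <- err_ss(vars)
      df1 <- 1
      df2 <- n - 1
      out[[paste(vars, collapse = ":")]] <-
        (ssx / df1) / (sse / df2)
    }
  }
  out
}

random_cells <- function(n_subjects = 12, seed = 1, effects = 0) {
  withr::with_seed(seed, {
    grid <- expand.grid(subject = seq_len(n_subjects),
                        A = c("a1", "a2"), B = c("b1", "b2"),
                        C = c("c1", "c2"), stringsAsFactors = FALSE)
    grid$value <- rnorm(nrow(grid)) +
      effects * (grid$A == "a2") * (grid$B == "b2") * (grid$C == "c2")
    grid
  })
}
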