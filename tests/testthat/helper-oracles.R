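# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with R/: statistics are recomputed from
# first principles by enumeration or brute-force loops on tiny inputs.

# all distinct assignments of `values` to groups with the given sizes,
# as a list of group-lists
oracle_assignments <- function(values, sizes) {
  n <- length(values)
  stopifnot(sum(sizes) == n)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  lapply(perms(seq_len(n)), function(ix) {
    split(values[ix], rep(seq_along(sizes), sizes))
  })
}

# umbrella statistic recomputed by direct double loop: classes in linear
# order g1..gK, peak position q; count pairs consistent with rise to q then
# fall (ties half)
oracle_umbrella_stat <- function(groups, q) {
  K <- length(groups)
  A <- 0
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    if (j <= q) {
      for (x in groups[[i]]) for (y in groups[[j]])
        A <- A + (x < y) + 0.5 * (x == y)
    } else if (i >= q) {
      for (x in groups[[j]]) for (y in groups[[i]])
        A <- A + (x < y) + 0.5 * (x == y)
    }
  }
  A
}

# exact permutation p-value for one candidate arrangement by enumerating
# every assignment of the observed values to the classes
oracle_umbrella_p <- function(groups, q) {
  obs <- oracle_umbrella_stat(groups, q)
  values <- unlist(groups)
  sizes <- lengths(groups)
  stats <- vapply(oracle_assignments(values, sizes),
                  oracle_umbrella_stat, 0, q = q)
  mean(stats >= obs - 1e-9)
}

# full test oracle: cyclic symmetric umbrella per candidate peak class,
# Bonferroni across candidates (mirrors the documented combination rule,
# with the per-phase p-values from enumeration instead of convolution)
oracle_umbrella_test <- function(values, cls) {
  cls <- factor(cls)
  K <- nlevels(cls)
  groups <- split(values, cls)
  q <- floor(K / 2) + 1
  pk <- vapply(1:K, function(k) {
    ord <- (((k - 1 + ceiling(K / 2)) + 0:(K - 1)) %% K) + 1
    oracle_umbrella_p(groups[ord], q)
  }, 0)
  min(1, K * min(pk))
}

# ANOSIM R recomputed independently (midranks over the lower triangle)
oracle_anosim_R <- function(dmat, g) {
  n <- nrow(dmat)
  pairs <- which(lower.tri(dmat), arr.ind = TRUE)
  dv <- dmat[pairs]
  rk <- rank(dv)
  within <- g[pairs[, 1]] == g[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 2 / 2)
}

# exhaustive relabeling p for ANOSIM at small n
oracle_anosim <- function(dmat, g) {
  R <- oracle_anosim_R(dmat, g)
  n <- length(g)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  Rs <- vapply(perms(seq_len(n)), function(ix) oracle_anosim_R(dmat, g[ix]),
               0)
  list(R = R, p = mean(Rs >= R - 1e-9))
}

# lognormal multiplicative noise with unit mean and the requested CV,
# written independently of the package internals
rlnorm_cv_oracle <- function(n, cv) {
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -s^2 / 2, s))
}

# small helper: long concentration table -> classify_signals input
as_series <- function(conc, value_col = "pmol_per_L") {
  s <- conc
  names(s)[names(s) == "compound"] <- "signal_id"
  names(s)[names(s) == value_col] <- "value"
  s
}

# truth expected concentrations for every field sample of a study
truth_concentrations <- function(study) {
  fld <- study$samples[study$samples$sample_class == "smp", ]
  do.call(rbind, lapply(seq_len(nrow(study$truth)), function(i) {
    data.frame(compound = study$truth$signal_id[i],
               sample_id = fld$sample_id,
               truth = diel_signal(fld$t_hours, study$truth[i, ],
                                   study$design),
               stringsAsFactors = FALSE)
  }))
}
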