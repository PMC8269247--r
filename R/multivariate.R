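#' Standardize a metabolite matrix and compute sample dissimilarities
#'
#' For \code{metric = "euclidean_zscore"} each compound is z-scored across
#' samples before Euclidean distances; \code{"bray_curtis"} operates on the
#' raw non-negative values.  Missing values are imputed as the compound's
#' minimum over samples (logged); zero-variance compounds are dropped with
#' a warning.
#'
#' @param mat Numeric matrix, samples in rows, compounds in columns.
#' @param metric "euclidean_zscore" (default) or "bray_curtis".
#' @return List of class \code{dissimilarity_matrix}: \code{d} (a
#'   \code{dist}), \code{metric}, \code{n_imputed}, \code{dropped}
#'   (zero-variance compound names).
#' @export
standardize_and_distance <- function(mat,
                                     metric = c("euclidean_zscore",
                                                "bray_curtis")) {
  metric <- match.arg(metric)
  mat <- as.matrix(mat)
  if (any(colSums(!is.na(mat)) == 0)) stop("compound with all values missing")
  n_imp <- 0L
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (any(miss)) {
      mat[miss, j] <- min(mat[, j], na.rm = TRUE)
      n_imp <- n_imp + sum(miss)
    }
  }
  if (n_imp > 0)
    message("imputed ", n_imp, " missing values as compound minima")
  v <- apply(mat, 2, stats::sd)
  dropped <- colnames(mat)[v == 0]
  if (length(dropped) > 0) {
    warning("dropped zero-variance compounds: ",
            paste(dropped, collapse = ", "))
    mat <- mat[, v > 0, drop = FALSE]
  }
  d <- switch(metric,
    euclidean_zscore = stats::dist(scale(mat)),
    bray_curtis = {
      if (any(mat < 0)) stop("Bray-Curtis needs non-negative values")
      n <- nrow(mat)
      out <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        s <- sum(mat[i, ] + mat[j, ])
        out[i, j] <- out[j, i] <- if (s > 0)
          sum(abs(mat[i, ] - mat[j, ])) / s else 0
      }
      stats::as.dist(out)
    })
  structure(list(d = d, metric = metric, n_imputed = n_imp,
                 dropped = dropped),
            class = "dissimilarity_matrix")
}

# all permutations of a label vector's indices; recursion over multiset
# would dedupe, but averaging over all n! index permutations gives the
# same null probabilities and is simpler to reason about
#' @noRd
all_index_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_index_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities:
#' \code{R = (mean between-group rank - mean within-group rank) / (M / 2)}
#' with \code{M = n (n - 1) / 2} off-diagonal dissimilarities (midranks
#' for ties).  The p-value is \code{(1 + #permuted R >= observed) /
#' (1 + n_permutations)} under random relabeling, or the exact enumeration
#' fraction when \code{exact = TRUE}.
#'
#' @param d A \code{dist}, a \code{dissimilarity_matrix}, or a square
#'   matrix.
#' @param groups Group label per sample; every group needs >= 2 members.
#' @param n_permutations Number of random relabelings (default 999,
#'   minimum 99).
#' @param seed Optional seed for the permutation stream.
#' @param exact If TRUE, enumerate all relabelings (n <= 9) and report the
#'   exact tail fraction instead of the permutation estimate.
#' @return List: \code{R}, \code{p_value}, \code{n_permutations},
#'   \code{exact}.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = NULL,
                   exact = FALSE) {
  if (inherits(d, "dissimilarity_matrix")) d <- d$d
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups length must match the matrix")
  if (nlevels(groups) < 2) stop("ANOSIM needs >= 2 groups")
  if (any(table(groups) < 2)) stop("ANOSIM cannot handle singleton groups")
  lower <- lower.tri(dm)
  rk <- matrix(0, n, n)
  rk[lower] <- rank(dm[lower])
  rk <- rk + t(rk)
  M <- n * (n - 1) / 2
  stat <- function(g) {
    same <- outer(g, g, "==") & lower
    diff <- (!outer(g, g, "==")) & lower
    (mean(rk[diff]) - mean(rk[same])) / (M / 2)
  }
  R <- stat(as.integer(groups))
  if (exact) {
    if (n > 9) stop("exact enumeration limited to n <= 9")
    perms <- all_index_permutations(n)
    g0 <- as.integer(groups)
    Rs <- apply(perms, 1, function(ix) stat(g0[ix]))
    return(list(R = R, p_value = mean(Rs >= R - 1e-12),
                n_permutations = nrow(perms), exact = TRUE))
  }
  if (n_permutations < 99) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  g0 <- as.integer(groups)
  for (b in seq_len(n_permutations))
    if (stat(sample(g0)) >= R - 1e-12) hits <- hits + 1L
  list(R = R, p_value = (1 + hits) / (1 + n_permutations),
       n_permutations = n_permutations, exact = FALSE)
}

#' Pairwise ANOSIM between group levels with BH correction
#'
#' @inheritParams anosim
#' @return Data.frame: one row per group pair with \code{R}, \code{p_value},
#'   \code{q_fdr}.
#' @export
pairwise_anosim <- function(d, groups, n_permutations = 999, seed = NULL) {
  if (inherits(d, "dissimilarity_matrix")) d <- d$d
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  lev <- levels(groups)
  rows <- list()
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1):length(lev)) {
    sel <- groups %in% c(lev[i], lev[j])
    a <- anosim(stats::as.dist(dm[sel, sel]), droplevels(groups[sel]),
                n_permutations = n_permutations)
    rows[[length(rows) + 1]] <- data.frame(
      group_a = lev[i], group_b = lev[j], R = a$R, p_value = a$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_fdr <- bh_fdr(out$p_value)
  out
}
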