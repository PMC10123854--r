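#' One-way PERMANOVA on Euclidean distances
#'
#' Permutational multivariate analysis of variance for a one-way design,
#' computed from the pairwise Euclidean distance matrix by the standard
#' partitioning of squared interpoint distances: the total sum of squares
#' is the sum of all squared pairwise distances divided by the number of
#' samples, the within-group sum of squares is the within-group analogue
#' divided by each group size, and the among-group sum of squares is their
#' difference. The pseudo-F statistic is
#' `(SS_among / (a - 1)) / (SS_within / (N - a))` and its probability is
#' obtained by permuting group labels, with the observed configuration
#' counted once: `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' A constant data matrix has no variance to partition; the statistic is
#' then defined as 0 with p = 1.
#'
#' @param x Numeric matrix or data frame, samples in rows, variables in
#'   columns; no missing values.
#' @param groups Group labels, length `nrow(x)`, at least two groups.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Optional integer seed for the permutation stream.
#' @return Object of class `permanova_fit`: `f_statistic`, `p_value`,
#'   `n_permutations`, `group_sizes`, `seed`, and the sums of squares and
#'   degrees of freedom.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' permanova(x, rep(c("a", "b"), each = 10), n_perm = 199, seed = 7)
#' @export
permanova <- function(x, groups, n_perm = 9999, seed = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (anyNA(x)) stop("x must not contain missing values")
  groups <- factor(groups)
  groups <- droplevels(groups)
  N <- nrow(x)
  if (length(groups) != N) stop("length(groups) must equal nrow(x)")
  a <- nlevels(groups)
  if (a < 2) stop("PERMANOVA requires at least two groups")
  sizes <- table(groups)

  D2 <- as.matrix(stats::dist(x))^2
  sst <- sum(D2) / (2 * N)
  g_int <- as.integer(groups)

  f_stat <- function(g) {
    ssw <- 0
    for (lev in seq_len(a)) {
      i <- which(g == lev)
      ssw <- ssw + sum(D2[i, i]) / (2 * length(i))
    }
    ssa <- sst - ssw
    list(f = (ssa / (a - 1)) / (ssw / (N - a)), ssw = ssw, ssa = ssa)
  }

  if (sst < .Machine$double.eps * N) {
    return(structure(list(f_statistic = 0, p_value = 1,
                          n_permutations = n_perm,
                          group_sizes = as.integer(sizes),
                          seed = seed, ss_total = 0, ss_within = 0,
                          ss_among = 0, df_among = a - 1, df_within = N - a),
                     class = "permanova_fit"))
  }

  obs <- f_stat(g_int)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    fp <- f_stat(g_int[sample.int(N)])$f
    if (fp >= obs$f - 1e-12) count <- count + 1L
  }
  structure(list(f_statistic = obs$f,
                 p_value = (count + 1) / (n_perm + 1),
                 n_permutations = n_perm,
                 group_sizes = as.integer(sizes),
                 seed = seed,
                 ss_total = sst, ss_within = obs$ssw, ss_among = obs$ssa,
                 df_among = a - 1, df_within = N - a),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat("One-way PERMANOVA (Euclidean distance)\n")
  cat(sprintf("  groups: %s | permutations: %d\n",
              paste(x$group_sizes, collapse = "/"), x$n_permutations))
  cat(sprintf("  pseudo-F = %.4g (df %d, %d), permuted p = %.4g\n",
              x$f_statistic, x$df_among, x$df_within, x$p_value))
  invisible(x)
}

#' Pairwise one-way PERMANOVA
#'
#' Runs [permanova()] for every pair of group levels. No multiplicity
#' adjustment is applied; the per-pair probabilities are reported as-is.
#'
#' @inheritParams permanova
#' @return Data frame with one row per pair: the levels, pseudo-F and p.
#' @export
permanova_pairwise <- function(x, groups, n_perm = 9999, seed = NULL) {
  groups <- factor(groups)
  levs <- levels(droplevels(groups))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    sel <- groups %in% pr
    fit <- permanova(as.matrix(x)[sel, , drop = FALSE],
                     droplevels(groups[sel]), n_perm = n_perm, seed = seed)
    data.frame(group1 = pr[1], group2 = pr[2],
               f_statistic = fit$f_statistic, p_value = fit$p_value,
               stringsAsFactors = FALSE)
  }))
}

#' Spearman rank correlation with permuted probability
#'
#' Spearman's rho computed from average ranks (ties shared), with a
#' two-sided permutation probability obtained by permuting one vector:
#' `p = (#\{|rho_perm| >= |rho_obs|\} + 1) / (n_perm + 1)`. A constant
#' vector leaves the rank correlation undefined; the result is then
#' flagged with `rho = NA` and `p = 1`.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return Object of class `spearman_perm`: `rho`, `p_value`,
#'   `n_permutations`, `seed`, `constant_input`.
#' @examples
#' spearman_perm(1:10, (1:10)^2, n_perm = 199, seed = 3)
#' @export
spearman_perm <- function(x, y, n_perm = 9999, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(rho = NA_real_, p_value = 1,
                          n_permutations = n_perm, seed = seed,
                          constant_input = TRUE),
                     class = "spearman_perm"))
  }
  rx <- rank(x)
  ry <- rank(y)
  a <- rx - mean(rx); a <- a / sqrt(sum(a^2))
  b <- ry - mean(ry); b <- b / sqrt(sum(b^2))
  rho <- sum(a * b)

  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  thr <- abs(rho) - 1e-12
  for (k in seq_len(n_perm)) {
    if (abs(sum(a * b[sample.int(n)])) >= thr) count <- count + 1L
  }
  structure(list(rho = rho, p_value = (count + 1) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed,
                 constant_input = FALSE),
            class = "spearman_perm")
}

#' @export
print.spearman_perm <- function(x, ...) {
  if (isTRUE(x$constant_input)) {
    cat("Spearman correlation: undefined (constant input); p = 1\n")
  } else {
    cat(sprintf("Spearman rho = %.4f, permuted p = %.4g (%d permutations)\n",
                x$rho, x$p_value, x$n_permutations))
  }
  invisible(x)
}
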