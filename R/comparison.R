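#' Permutation (randomization) test for a mean shift in motif counts
#'
#' Compares the mean of a gene group's per-gene motif counts to a background
#' universe that contains the group. The null distribution is built by
#' repeatedly drawing uniform random subsets of size `|group|` from the
#' background and recomputing the statistic, matching the nesting of the data
#' (the disease group is a subset of the background universe), rather than
#' exchanging labels between disjoint samples. The statistic is the
#' difference of means (group minus background); the p-value is two-sided
#' with the add-one convention `p = (1 + #{|T*| >= |T_obs|}) / (n_perm + 1)`,
#' which bounds p away from 0.
#'
#' @param group_values Numeric vector of per-gene counts for the group.
#' @param background_values Numeric vector of per-gene counts for the
#'   background universe (must be at least as large as the group).
#' @param n_perm Number of random subsets; default 9999.
#' @param seed Integer seed; the test is bit-reproducible given the seed.
#' @return Object of class `permutation_test`: `statistic_name`, `observed`,
#'   `n_perm`, `p_value`, `seed`, `group_size`, `background_size`.
#' @export
permutation_test <- function(group_values, background_values,
                             n_perm = 9999L, seed) {
  if (!is.numeric(group_values) || length(group_values) == 0L) {
    stop("'group_values' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(background_values) || length(background_values) == 0L) {
    stop("'background_values' must be a non-empty numeric vector", call. = FALSE)
  }
  g <- length(group_values)
  b <- length(background_values)
  if (g > b) {
    stop("group cannot be larger than the background universe", call. = FALSE)
  }
  n_perm <- check_int(n_perm, "n_perm")
  if (n_perm < 1L) stop("'n_perm' must be >= 1", call. = FALSE)
  seed <- check_int(seed, "seed")

  bg_mean <- mean(background_values)
  observed <- mean(group_values) - bg_mean
  tstar <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    mean(background_values[sample.int(b, g)]) - bg_mean
  }, numeric(1)))
  tol <- 1e-12 * max(1, abs(observed))
  p <- (1 + sum(abs(tstar) >= abs(observed) - tol)) / (n_perm + 1)
  structure(list(statistic_name = "mean difference (group - background)",
                 observed = observed, n_perm = n_perm, p_value = p,
                 seed = seed, group_size = g, background_size = b),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s)\n", x$statistic_name))
  cat(sprintf("  group n = %d, background n = %d, permutations = %d (seed %d)\n",
              x$group_size, x$background_size, x$n_perm, x$seed))
  cat(sprintf("  observed = %.4g, two-sided p = %.4g\n", x$observed, x$p_value))
  invisible(x)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test used to compare promoter GC content between a gene
#' group and the universe background:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom, two-sided p.
#'
#' @param a,b Numeric vectors, each of length >= 2; at least one must have
#'   nonzero variance.
#' @return Object of class `welch_t`: `t`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (!is.numeric(a) || length(a) < 2L || !is.numeric(b) || length(b) < 2L) {
    stop("both samples must be numeric with at least 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance; Welch's t is undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_a = mean(a), mean_b = mean(b)),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch's t test: t = %.4g, df = %.2f, two-sided p = %.4g\n",
              x$t, x$df, x$p_value))
  cat(sprintf("  mean_a = %.4g, mean_b = %.4g\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' Classical one-way ANOVA
#'
#' Equal-variance one-way analysis of variance across two or more gene
#' groups (for two groups, F equals the square of the pooled-variance t).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with elements `F` and `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of at least 2 numeric vectors", call. = FALSE)
  }
  if (any(!vapply(groups, is.numeric, logical(1))) ||
      any(lengths(groups) < 2L)) {
    stop("every group must be numeric with at least 2 values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) {
    stop("all values identical; ANOVA is undefined", call. = FALSE)
  }
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ht$statistic), p_value = ht$p.value)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
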