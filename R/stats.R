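#' Kruskal--Wallis omnibus test
#'
#' Tie-corrected Kruskal--Wallis rank test across two or more groups, with a
#' chi-squared reference on k - 1 degrees of freedom. The degenerate case of
#' all observations identical returns H = 0, p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length as `values`.
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("Need at least 2 groups.", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1,
                n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values))
}

#' Steel--Dwass all-pairs comparisons (asymptotic)
#'
#' For every pair of groups the pooled pair is midranked, the standardized
#' Wilcoxon-type statistic with tie correction is computed, and its absolute
#' value times sqrt(2) is referred to the studentized-range distribution
#' with `k` (the total number of groups) means and infinite degrees of
#' freedom. With k = 2 this reduces exactly to the tie-corrected two-sided
#' normal-approximation Wilcoxon test. This joint-ranking-free, pairwise
#' procedure controls the family-wise error across all pairs.
#'
#' @inheritParams kruskal_wallis
#' @return Symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
steel_dwass <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("Need at least 2 groups.", call. = FALSE)
  ns <- table(groups)
  if (any(ns < 2)) {
    stop("Group(s) with n < 2: ",
         paste(names(ns)[ns < 2], collapse = ", "), call. = FALSE)
  }
  lev <- levels(groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      x <- values[groups == lev[i]]
      y <- values[groups == lev[j]]
      n1 <- length(x); n2 <- length(y); N <- n1 + n2
      r <- rank(c(x, y))
      W <- sum(r[seq.int(n1 + 1, N)])
      E <- n2 * (N + 1) / 2
      V <- n1 * n2 / (N * (N - 1)) * sum((r - (N + 1) / 2)^2)
      p <- if (V <= 0) 1 else
        stats::ptukey(sqrt(2) * abs(W - E) / sqrt(V), nmeans = k, df = Inf,
                      lower.tail = FALSE)
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  pmat
}

#' Brunner--Munzel two-sample test
#'
#' Rank-based test of the relative effect `p = P(X < Y) + 0.5 P(X = Y)`
#' against 0.5, using the studentized statistic with a Satterthwaite-type
#' t approximation. Robust to unequal variances and to outliers, which makes
#' it the appropriate two-sample test for skewed posture indices. The
#' statistic is positive when `y` tends to be larger than `x`.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param correction_family_size Number of planned comparisons in the
#'   Bonferroni family (default 1: no correction).
#' @return List with `statistic`, `df`, `relative_effect`, `p_value`,
#'   `p_bonferroni`, `family_size` and `degenerate` (TRUE when both samples
#'   are internally constant so the variance estimate is 0).
#' @export
brunner_munzel <- function(x, y, correction_family_size = 1) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("Both samples need n >= 2.", call. = FALSE)
  m <- as.integer(correction_family_size)
  if (is.na(m) || m < 1) stop("`correction_family_size` must be >= 1.",
                              call. = FALSE)
  N <- n1 + n2
  r <- rank(c(x, y))
  r1 <- rank(x); r2 <- rank(y)
  m1 <- mean(r[seq_len(n1)]); m2 <- mean(r[seq.int(n1 + 1, N)])
  pst <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r[seq_len(n1)] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[seq.int(n1 + 1, N)] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  denom <- n1 * v1 + n2 * v2
  if (denom <= 0) {
    # both samples internally constant
    if (isTRUE(all.equal(pst, 0.5))) {
      out <- list(statistic = 0, df = NA_real_, relative_effect = pst,
                  p_value = 1, degenerate = TRUE)
    } else {
      out <- list(statistic = sign(pst - 0.5) * Inf, df = NA_real_,
                  relative_effect = pst, p_value = 0, degenerate = TRUE)
    }
  } else {
    stat <- n1 * n2 * (m2 - m1) / (N * sqrt(denom))
    df <- denom^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
    p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
    out <- list(statistic = stat, df = df, relative_effect = pst,
                p_value = p, degenerate = FALSE)
  }
  out$p_bonferroni <- min(1, out$p_value * m)
  out$family_size <- m
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level, in (0, 1) (default 0.05).
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1).", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer.", call. = FALSE)
  }
  alpha / m
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: two groups share at least one letter
#' if and only if their pairwise p-value is >= `alpha`. Missing (`NA`)
#' off-diagonal entries are treated as not significant.
#'
#' @param pairwise_p Symmetric matrix of pairwise p-values with group names
#'   as dimnames.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pairwise_p, alpha = 0.05) {
  stopifnot(is.matrix(pairwise_p), nrow(pairwise_p) == ncol(pairwise_p))
  k <- nrow(pairwise_p)
  grp <- rownames(pairwise_p)
  if (is.null(grp)) grp <- paste0("g", seq_len(k))
  # columns = candidate letters, as logical membership vectors
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      p <- pairwise_p[i, j]
      if (!is.na(p) && p < alpha) {
        for (ci in seq_along(cols)) {
          col <- cols[[ci]]
          if (col[i] && col[j]) {
            a <- col; a[i] <- FALSE
            b <- col; b[j] <- FALSE
            cols[[ci]] <- a
            cols[[length(cols) + 1]] <- b
          }
        }
        # absorb columns that are subsets of another
        keep <- rep(TRUE, length(cols))
        for (ci in seq_along(cols)) {
          for (cj in seq_along(cols)) {
            if (ci != cj && keep[ci] && keep[cj] &&
                all(cols[[ci]] <= cols[[cj]]) &&
                any(cols[[ci]] < cols[[cj]])) {
              keep[ci] <- FALSE
            }
          }
        }
        # drop exact duplicates too
        sig <- vapply(cols, paste, "", collapse = "")
        keep <- keep & !duplicated(sig)
        cols <- cols[keep]
      }
    }
  }
  # stable letter order: by first member
  ord <- order(vapply(cols, function(c) which(c)[1], 1L))
  cols <- cols[ord]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(seq_len(k), function(g) {
    paste(letters_used[vapply(cols, `[`, TRUE, g)], collapse = "")
  }, "")
  stats::setNames(out, grp)
}

#' Compare groups on one index
#'
#' Omnibus Kruskal--Wallis test plus all-pairs post hoc comparisons
#' (Steel--Dwass by default, or pairwise Brunner--Munzel with Bonferroni
#' correction over all pairs), with a compact letter display at `alpha`.
#'
#' @param data Data frame with one row per root.
#' @param index_name Column to compare (e.g. `"SI"`, `"ci_mean"`,
#'   `"angle_deg"`).
#' @param group_col Grouping column (default `"group"`).
#' @param method `"steel_dwass"` (default) or `"brunner_munzel"`.
#' @param alpha Level for the letter display (default 0.05).
#' @param family_size Bonferroni family size for the omnibus p-value ledger
#'   (and, for `method = "brunner_munzel"`, the pairwise correction); by
#'   default the number of pairs for Brunner--Munzel and 1 otherwise.
#' @return `group_comparison` object: list with `index_name`, `omnibus_p`,
#'   `H`, `pairwise` (adjusted p matrix), `method`, `letters`, `alpha`,
#'   `family_size`, `n_per_group`.
#' @export
compare_groups <- function(data, index_name, group_col = "group",
                           method = c("steel_dwass", "brunner_munzel"),
                           alpha = 0.05, family_size = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data),
            index_name %in% names(data), group_col %in% names(data))
  values <- data[[index_name]]
  groups <- factor(data[[group_col]])
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  lev <- levels(groups)
  k <- length(lev)
  if (k < 2) stop("Need at least 2 groups with data.", call. = FALSE)
  n_pairs <- k * (k - 1) / 2
  kw <- kruskal_wallis(values, groups)
  if (method == "steel_dwass") {
    if (is.null(family_size)) family_size <- 1L
    pmat <- steel_dwass(values, groups)
  } else {
    if (is.null(family_size)) family_size <- n_pairs
    pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        bm <- brunner_munzel(values[groups == lev[i]],
                             values[groups == lev[j]],
                             correction_family_size = family_size)
        pmat[i, j] <- pmat[j, i] <- bm$p_bonferroni
      }
    }
  }
  structure(
    list(index_name = index_name, omnibus_p = kw$p_value, H = kw$H,
         pairwise = pmat, method = method,
         letters = compact_letters(pmat, alpha = alpha), alpha = alpha,
         family_size = as.integer(family_size),
         n_per_group = as.integer(table(groups))),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat("<group_comparison> index:", x$index_name, "\n")
  cat("  Kruskal-Wallis H =", signif(x$H, digits), " p =",
      format.pval(x$omnibus_p, digits = digits), "\n")
  cat("  post hoc:", x$method, " alpha =", x$alpha, "\n")
  print(signif(x$pairwise, digits))
  cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                          collapse = "  "), "\n")
  invisible(x)
}
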