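# Group comparisons: unpaired Student's t (pooled variance), one-way ANOVA
# and Dunnett's many-to-one post-hoc test. Two-sided throughout.

#' Unpaired Student's t-test
#'
#' Pooled-variance two-sample t with a two-sided p-value (Welch's variant
#' behind a flag). Zero pooled variance is handled without error: equal
#' means give `t = 0, p = 1`; unequal means give `p = 0` with
#' `degenerate = TRUE`.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @param welch use Welch's unequal-variance t instead.
#' @return list with `t`, `df`, `p`, `estimate` (mean difference) and
#'   `degenerate`.
#' @export
studentsT <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- mean(a) == mean(b)
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0, estimate = mean(a) - mean(b),
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = mean(a) - mean(b), degenerate = FALSE)
}

#' One-way ANOVA
#'
#' Standard between/within sums-of-squares decomposition via [stats::aov()].
#' All group means exactly equal gives `F = 0, p = 1`; zero within-group
#' variance with unequal means gives `p = 0` flagged degenerate.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @return list with `F`, `df_between`, `df_within`, `p`, `degenerate`.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  dfb <- nlevels(df$group) - 1L
  dfw <- nrow(df) - nlevels(df$group)
  withinVar <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (withinVar == 0) {
    eq <- length(unique(vapply(groups, mean, numeric(1)))) == 1L
    return(list(F = if (eq) 0 else Inf, df_between = dfb, df_within = dfw,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  tab <- anova(aov(value ~ group, data = df))
  list(F = tab[["F value"]][1L], df_between = tab$Df[1L],
       df_within = tab$Df[2L], p = tab[["Pr(>F)"]][1L], degenerate = FALSE)
}

#' Dunnett's many-to-one comparisons versus a control group
#'
#' Each non-control group is compared with the control by a pooled-variance
#' t statistic; the family-wise adjustment uses the single-step Dunnett
#' (multivariate t) distribution, evaluated by seeded Monte-Carlo
#' integration (default 1e5 draws, accuracy about +-0.002 in p). Adjusted
#' p-values never fall below the unadjusted ones, and with a single
#' comparison the adjusted p equals the unadjusted two-sided t-test p
#' exactly.
#'
#' @param groups named list of numeric vectors.
#' @param control name of the control group.
#' @param nDraws Monte-Carlo draws.
#' @param seed RNG seed for the integration.
#' @return data.frame: `comparison`, `estimate`, `statistic`, `df`,
#'   `p_raw`, `p_adjusted`.
#' @export
dunnettTest <- function(groups, control, nDraws = 1e5, seed = 1) {
  if (is.null(names(groups))) stop("groups must be named")
  if (!control %in% names(groups))
    stopTyped("ecms_no_control", "control group '%s' not found", control)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values")
  g0 <- groups[[control]]
  others <- groups[names(groups) != control]
  k <- length(others)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  dfree <- N - length(groups)
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    dfree
  est <- vapply(others, mean, numeric(1)) - mean(g0)
  se <- sqrt(s2 * (1 / vapply(others, length, integer(1)) + 1 / length(g0)))
  tstat <- est / se
  praw <- 2 * pt(-abs(tstat), dfree)
  if (k == 1L) {
    padj <- praw
  } else {
    lam <- sqrt(vapply(others, length, integer(1)) /
                  (vapply(others, length, integer(1)) + length(g0)))
    padj <- withSeed(seed, {
      z0 <- rnorm(nDraws)
      wchi <- sqrt(rchisq(nDraws, dfree) / dfree)
      maxabs <- rep(0, nDraws)
      for (j in seq_len(k)) {   # sequential draws: adding a group never
        zj <- rnorm(nDraws)     # perturbs earlier comparisons' draws
        tj <- (lam[j] * z0 + sqrt(1 - lam[j]^2) * zj) / wchi
        maxabs <- pmax(maxabs, abs(tj))
      }
      vapply(abs(tstat), function(ti) mean(maxabs >= ti), numeric(1))
    })
    padj <- pmax(padj, praw)
  }
  data.frame(comparison = paste(names(others), "-", control),
             estimate = unname(est), statistic = unname(tstat), df = dfree,
             p_raw = unname(praw), p_adjusted = unname(pmin(padj, 1)))
}
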