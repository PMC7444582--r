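#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration over all tables with the
#' observed margins, using the probability-mass rule: the two-sided p is
#' the sum of the probabilities of every table at most as probable as the
#' observed one (within a relative tolerance of 1e-7 for floating-point
#' ties). Used here on condition-versus-control tables of unoccupied
#' spermathecae against all other phenotypes (population assays), and of
#' successful exits against all other transit phenotypes.
#'
#' The p-value is invariant under swapping rows, swapping columns, and
#' transposition.
#'
#' @param x 2x2 matrix of non-negative integer counts (rows = condition,
#'   columns = outcome).
#' @return list with \code{p_value}, the observed table probability
#'   (\code{p_table}), and the table.
#' @export
fisher_exact <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) stop("x must be a 2x2 table")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integers")
  a <- x[1, 1]
  r1 <- sum(x[1, ]); r2 <- sum(x[2, ])
  c1 <- sum(x[, 1])
  if (sum(x) == 0) stop("empty table: all margins zero")
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p), p_table = p_obs, table = x)
}

#' One-way ANOVA (omnibus F)
#'
#' Standard between/within decomposition:
#' \code{F = (SSB/df_B) / (SSW/df_W)} with \code{df_B = k - 1} and
#' \code{df_W = n - k}; the p-value is the upper tail of the F
#' distribution. When the groups are internally constant but differ
#' (SSW = 0, SSB > 0), F is reported as \code{Inf} with p = 0 and a
#' degeneracy flag. F is invariant under shifting all values by a
#' constant or scaling them by a nonzero factor.
#'
#' @param groups list of numeric vectors, one per condition; at least two
#'   groups, each non-empty, total n greater than the number of groups,
#'   and not all values identical.
#' @return object of class \code{anova_result}: list with \code{F},
#'   \code{df_between}, \code{df_within}, \code{p_value},
#'   \code{degenerate}.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 1))
    stop("every group needs at least one value")
  all_x <- unlist(groups)
  k <- length(groups)
  n <- length(all_x)
  if (n <= k) stop("total n must exceed the number of groups")
  if (all(all_x == all_x[1])) stop("all values identical: no variance")
  grand <- mean(all_x)
  means <- vapply(groups, mean, 1)
  sizes <- vapply(groups, length, 1L)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - means[i])^2), 1))
  df_b <- k - 1L
  df_w <- n - k
  if (ssw == 0) {
    res <- list(F = Inf, df_between = df_b, df_within = df_w,
                p_value = 0, degenerate = TRUE)
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
    res <- list(F = f, df_between = df_b, df_within = df_w,
                p_value = pf(f, df_b, df_w, lower.tail = FALSE),
                degenerate = FALSE)
  }
  structure(res, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> F(", x$df_between, ",", x$df_within, ") = ",
      format(x$F, digits = 5), ", p = ", format(x$p_value, digits = 4),
      if (x$degenerate) " [degenerate: SSW = 0]", "\n", sep = "")
  invisible(x)
}

#' Significance stars at the reporting thresholds
#'
#' \code{****} p < 0.0001, \code{***} p < 0.005, \code{**} p < 0.01,
#' \code{*} p < 0.05, else \code{ns}.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.0001) "****"
    else if (pp < 0.005) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Pairwise exact tests of a population table against a control
#'
#' Each condition is compared with the control on unoccupied versus the
#' sum of all other phenotypes, by [fisher_exact()]; an optional
#' Bonferroni correction multiplies each p by the number of comparisons.
#'
#' @param pop a [score_population()] table.
#' @param control name of the control condition.
#' @param bonferroni apply a Bonferroni correction?
#' @return data frame: condition, counts, \code{p_value},
#'   \code{significance}.
#' @export
compare_population <- function(pop, control, bonferroni = FALSE) {
  stopifnot(inherits(pop, "population_table"))
  if (!control %in% pop$condition)
    stop("control condition '", control, "' not in table")
  ctrl <- pop[pop$condition == control, ]
  others <- pop[pop$condition != control, ]
  if (nrow(others) == 0) stop("no conditions to compare against control")
  m <- nrow(others)
  rows <- lapply(seq_len(m), function(i) {
    r <- others[i, ]
    tab <- matrix(c(r$unoccupied, r$n - r$unoccupied,
                    ctrl$unoccupied, ctrl$n - ctrl$unoccupied),
                  nrow = 2, byrow = TRUE)
    p <- fisher_exact(tab)$p_value
    if (bonferroni) p <- min(1, p * m)
    data.frame(condition = r$condition, unoccupied = r$unoccupied,
               other = r$n - r$unoccupied, n = r$n, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$significance <- significance_stars(out$p_value)
  out
}

#' Compare a pulse metric across conditions
#'
#' Omnibus one-way ANOVA over all conditions, plus (optionally) pairwise
#' ANOVAs of each condition against a control with a Bonferroni option.
#'
#' @param groups named list of numeric vectors (one per condition).
#' @param control optional control condition name for pairwise tests.
#' @param bonferroni apply a Bonferroni correction to the pairwise p's?
#' @return list with \code{omnibus} ([anova_oneway()] result) and
#'   \code{pairwise} (data frame or NULL).
#' @export
compare_metric <- function(groups, control = NULL, bonferroni = FALSE) {
  omni <- anova_oneway(groups)
  pw <- NULL
  if (!is.null(control)) {
    if (!control %in% names(groups))
      stop("control condition '", control, "' not in groups")
    others <- setdiff(names(groups), control)
    m <- length(others)
    pw <- do.call(rbind, lapply(others, function(g) {
      a <- anova_oneway(groups[c(control, g)])
      p <- if (bonferroni) min(1, a$p_value * m) else a$p_value
      data.frame(condition = g, F = a$F, p_value = p)
    }))
    pw$significance <- significance_stars(pw$p_value)
  }
  list(omnibus = omni, pairwise = pw)
}
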