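## group_stats: the reported-statistics layer — Tukey compact letter
## displays, one-sample t-tests against the +/-2 rule, Pearson correlation
## panels with significance stars, and quadratic yield fits.

## Insert-absorb compact letter display from a logical "significantly
## different" pair matrix. Groups must be supplied in display order.
.insert_absorb <- function(signif_pair, groups) {
  cols <- list(groups)  # start: one letter containing every group
  pairs <- which(signif_pair & upper.tri(signif_pair), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      gi <- groups[pairs[r, 1L]]
      gj <- groups[pairs[r, 2L]]
      new_cols <- list()
      for (col in cols) {
        if (all(c(gi, gj) %in% col)) {
          new_cols <- c(new_cols, list(setdiff(col, gi)), list(setdiff(col, gj)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b))
          keep[a] <- FALSE
      }
      cols <- new_cols[keep]
    }
  }
  # order letters by the position of their first member for stable output
  first <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    lab <- letters[(i - 1L) %% 26L + 1L]
    if (i > 26L) lab <- paste0(lab, (i - 1L) %/% 26L)
    for (g in cols[[i]]) letters_out[g] <- paste0(letters_out[g], lab)
  }
  letters_out
}

#' Tukey HSD compact letter display
#'
#' One-way ANOVA followed by Tukey's honest significant difference test;
#' groups sharing a letter are not significantly different at `alpha`.
#' Letters are assigned by the insert-absorb algorithm, with groups
#' ordered by decreasing mean (ties by label). Shapiro-Wilk normality (on
#' residuals) and Bartlett homogeneity checks are run and reported as
#' advisory attributes, not enforced.
#'
#' @param values numeric response.
#' @param groups group labels (same length).
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `letter_display`: `group`, `n`, `mean`,
#'   `sd`, `letters`; attributes `p_matrix` (Tukey-adjusted pairwise
#'   p-values), `shapiro_p`, `bartlett_p`.
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("need at least 2 groups")
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stopf("group(s) with fewer than 2 values: %s", paste(small, collapse = ", "))
  d <- data.frame(y = values, g = factor(groups))
  fit <- stats::aov(y ~ g, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  lv <- levels(d$g)
  P <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(cmp)) {
    a <- cmp[[i]][1L]; b <- cmp[[i]][2L]
    P[a, b] <- P[b, a] <- tk[i, "p adj"]
  }
  diag(P) <- 1
  means <- tapply(d$y, d$g, mean)
  ord <- names(means)[order(-means, names(means))]  # ties broken by label
  Pw <- P[ord, ord, drop = FALSE]
  letts <- .insert_absorb(Pw < alpha, ord)
  shapiro_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                        error = function(e) NA_real_)
  bartlett_p <- tryCatch(stats::bartlett.test(y ~ g, data = d)$p.value,
                         error = function(e) NA_real_)
  if (!is.na(shapiro_p) && shapiro_p < alpha)
    warnf("residual normality check failed (Shapiro p = %.3g); Tukey letters are advisory", shapiro_p)
  if (!is.na(bartlett_p) && bartlett_p < alpha)
    warnf("variance homogeneity check failed (Bartlett p = %.3g); Tukey letters are advisory", bartlett_p)
  out <- data.frame(group = ord,
                    n = as.integer(sizes[ord]),
                    mean = as.numeric(means[ord]),
                    sd = as.numeric(tapply(d$y, d$g, stats::sd)[ord]),
                    letters = unname(letts[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p_matrix") <- P
  attr(out, "shapiro_p") <- shapiro_p
  attr(out, "bartlett_p") <- bartlett_p
  attr(out, "alpha") <- alpha
  class(out) <- c("letter_display", class(out))
  out
}

#' One-sample t-test against a fixed threshold
#'
#' Two-tailed test of whether the mean differs from `threshold`; used for
#' the +/-2 decision rule on NRI and betaNRI values. Zero-variance input
#' is handled by comparing the common value with the threshold directly,
#' with the p-value flagged degenerate (`NA`).
#'
#' @param values numeric vector (n >= 2).
#' @param threshold the constant to test against (e.g. 2 or -2).
#' @return list: `t`, `p`, `mean`, `threshold`, `verdict`, `degenerate`.
#' @export
ttest_vs_threshold <- function(values, threshold) {
  if (length(values) < 2L) stopf("need at least 2 values")
  m <- mean(values)
  if (stats::sd(values) == 0) {
    verdict <- if (m > threshold) sprintf("all values above %g (degenerate: zero variance)", threshold)
      else if (m < threshold) sprintf("all values below %g (degenerate: zero variance)", threshold)
      else sprintf("all values equal to %g", threshold)
    return(list(t = if (m == threshold) 0 else sign(m - threshold) * Inf,
                p = NA_real_, mean = m, threshold = threshold,
                verdict = verdict, degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = threshold)
  verdict <- if (tt$p.value < 0.05 && m > threshold) sprintf("significantly above %g", threshold)
    else if (tt$p.value < 0.05 && m < threshold) sprintf("significantly below %g", threshold)
    else sprintf("not distinguishable from %g", threshold)
  list(t = unname(tt$statistic), p = tt$p.value, mean = m,
       threshold = threshold, verdict = verdict, degenerate = FALSE)
}

#' Pairwise Pearson correlation panel
#'
#' Pearson r and two-sided p for every variable pair, with the usual
#' significance stars (`*` for p < 0.05, `**` for p < 0.01) and the
#' number of complete observations per pair. Pairs with fewer than 3
#' complete observations or a constant variable are flagged with `NA` r.
#'
#' @param data data.frame holding the variables.
#' @param variables character vector of column names (default: all
#'   numeric columns).
#' @return data.frame of class `correlation_panel`: `var1`, `var2`, `n`,
#'   `r`, `p`, `stars`, `flag`; the symmetric r matrix is attached as
#'   attribute `r_matrix`.
#' @export
pearson_panel <- function(data, variables = NULL) {
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars))
    stopf("variables not in data: %s", paste(missing_vars, collapse = ", "))
  k <- length(variables)
  R <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(R) <- 1
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    x <- data[[variables[i]]]; y <- data[[variables[j]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    flag <- ""
    r <- p <- NA_real_
    if (n < 3L) {
      flag <- "fewer than 3 complete observations"
    } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      flag <- "constant variable"
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
      R[i, j] <- R[j, i] <- r
    }
    stars <- if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    rows[[length(rows) + 1L]] <-
      data.frame(var1 = variables[i], var2 = variables[j], n = n,
                 r = r, p = p, stars = stars, flag = flag,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "r_matrix") <- R
  class(out) <- c("correlation_panel", class(out))
  out
}

#' Quadratic least-squares fit with an interior optimum
#'
#' Fits `y = a + b x + c x^2`, reports the multiple R (square root of
#' R-squared, signed by the sign of `c` so a concave fit with an interior
#' maximum reads negative), the model F-test p-value, and the vertex
#' `-b / (2c)` when `c < 0` (an interior maximum). Also fits the nested
#' linear model for comparison.
#'
#' @param x,y numeric vectors (>= 4 points, >= 3 distinct x).
#' @return list: `coefficients` (a, b, c), `R`, `R_unsigned`,
#'   `r_squared`, `p`, `vertex` (`NA` unless `c < 0`), `linear_R`,
#'   `model` (the `lm` fit).
#' @export
quadratic_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need at least 4 points")
  if (length(unique(x)) < 3L) stopf("degenerate design: need >= 3 distinct x values")
  fit <- stats::lm(y ~ x + I(x^2))
  sm <- summary(fit)
  cf <- stats::setNames(stats::coef(fit), c("a", "b", "c"))
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  lin <- summary(stats::lm(y ~ x))
  vertex <- if (!is.na(cf["c"]) && cf["c"] < 0) -cf[["b"]] / (2 * cf[["c"]]) else NA_real_
  R_unsigned <- sqrt(r2)
  list(coefficients = cf,
       R = if (!is.na(cf["c"]) && cf["c"] < 0) -R_unsigned else R_unsigned,
       R_unsigned = R_unsigned, r_squared = r2, p = unname(p),
       vertex = vertex, linear_R = sqrt(lin$r.squared), model = fit)
}
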