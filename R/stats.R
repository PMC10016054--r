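# Inference: fully-within rmANOVA for 2-level factorials via paired
# contrasts, paired t with Cohen's d, Pearson correlation, and Fisher
# r-to-z comparison of two correlations.

#' Partial eta squared from an F ratio
#'
#' `eta_p2 = (F * df1) / (F * df1 + df2)`; for 1-df effects this reduces
#' to `F / (F + df2)`, e.g. `F(1,37) = 9.19` gives 0.199.
#'
#' @param f F ratio.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
partial_eta_sq <- function(f, df1 = 1, df2) (f * df1) / (f * df1 + df2)

#' Cohen's d for a paired contrast from its t value
#'
#' `d_z = t / sqrt(n)`, the mean difference in units of the SD of the
#' paired differences. With t(37) = 2.99 and n = 38 this gives 0.49.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return Cohen's d (d_z).
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Repeated-measures ANOVA for fully-within 2-level factorial designs
#'
#' Every factor has exactly 2 levels, so each main effect and interaction
#' reduces to a single within-participant contrast: the contrast score is
#' tested against zero with a paired t and reported as `F = t^2` on
#' `(1, n - 1)` degrees of freedom, with two-tailed p and partial eta
#' squared `F / (F + n - 1)`. Sphericity is trivially satisfied at two
#' levels, so no correction is needed or applied. Participants missing
#' any cell are dropped listwise (with a message).
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of 2 or 3 within-participant factor
#'   names (each column must have exactly 2 levels).
#' @param id Name of the participant identifier column.
#' @return Data frame of class `duet_anova` with columns `effect`, `F`,
#'   `df1`, `df2`, `p`, `eta_p2`, one row per main effect and
#'   interaction. Degenerate contrasts (zero variance across
#'   participants) yield `F = Inf` (non-zero mean) or `NaN`, `p = NA`,
#'   with a warning.
#' @export
#' @examples
#' d <- expand.grid(id = factor(1:8), A = c("a1", "a2"), B = c("b1", "b2"))
#' set.seed(1); d$y <- rnorm(nrow(d)) + (d$A == "a2") * 1.5
#' rm_anova(d, "y", c("A", "B"), "id")
rm_anova <- function(data, dv, within, id = "participant") {
  stopifnot(all(c(dv, within, id) %in% names(data)))
  if (!length(within) %in% 2:3)
    stop("`within` must name 2 or 3 factors", call. = FALSE)
  for (w in within) {
    if (length(unique(data[[w]])) != 2L)
      stop(sprintf("factor `%s` must have exactly 2 levels", w),
           call. = FALSE)
  }
  k <- length(within)
  data <- data[!is.na(data[[dv]]), ]
  cellkey <- do.call(paste, c(data[within], sep = "\r"))
  n_cells <- 2^k

  # listwise deletion of participants with missing or duplicated cells
  ok_tab <- table(data[[id]], cellkey)
  complete <- rownames(ok_tab)[rowSums(ok_tab == 1L) == n_cells]
  dropped <- setdiff(unique(as.character(data[[id]])), complete)
  if (length(dropped)) {
    message("rm_anova: dropping ", length(dropped),
            " participant(s) with incomplete cells")
    data <- data[as.character(data[[id]]) %in% complete, ]
  }
  n <- length(complete)
  if (n < 3L)
    stop("fewer than 3 participants with complete cells", call. = FALSE)

  # per-participant cell matrix, columns in a fixed cell order
  ckey <- do.call(paste, c(data[within], sep = "\r"))
  o <- order(data[[id]], ckey)
  y <- matrix(data[[dv]][o], nrow = n, byrow = TRUE)
  cells <- sort(unique(ckey))
  lev <- do.call(rbind, strsplit(cells, "\r", fixed = TRUE))
  codes <- matrix(0, n_cells, k)
  for (j in seq_len(k))
    codes[, j] <- ifelse(lev[, j] == sort(unique(lev[, j]))[1L], -1, 1)

  effects <- unlist(lapply(seq_len(k), function(m)
    utils::combn(seq_len(k), m, simplify = FALSE)), recursive = FALSE)
  res <- lapply(effects, function(ef) {
    w <- apply(codes[, ef, drop = FALSE], 1L, prod)
    contrast <- as.vector(y %*% w) / 2^(k - 1)
    mbar <- mean(contrast)
    s <- stats::sd(contrast)
    name <- paste(within[ef], collapse = ":")
    if (s == 0) {
      warning(sprintf("effect %s: zero contrast variance across %s",
                      name, "participants"), call. = FALSE)
      f <- if (mbar != 0) Inf else NaN
      return(data.frame(effect = name, F = f, df1 = 1, df2 = n - 1,
                        p = NA_real_, eta_p2 = NA_real_))
    }
    t <- mbar / (s / sqrt(n))
    f <- t^2
    data.frame(effect = name, F = f, df1 = 1, df2 = n - 1,
               p = 2 * stats::pt(-abs(t), n - 1),
               eta_p2 = partial_eta_sq(f, 1, n - 1))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("duet_anova", "data.frame")
  attr(out, "n") <- n
  attr(out, "dropped") <- length(dropped)
  out
}

#' @export
print.duet_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d)\n", attr(x, "n")))
  df <- as.data.frame(x)
  df$F <- sprintf("%.2f", df$F)
  df$p <- sprintf("%.3f", df$p)
  df$eta_p2 <- sprintf("%.2f", df$eta_p2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Paired t test with Cohen's d
#'
#' Standard two-tailed paired t ([stats::t.test()]) augmented with the
#' paired-contrast effect size `d = t / sqrt(n)` (equivalently the mean
#' difference divided by the SD of the differences).
#'
#' @param x,y Paired numeric vectors of equal length (>= 3).
#' @return List with `t`, `df`, `p`, `d`, `mean_diff`, `n`. Zero-variance
#'   differences give `NA` statistics with a warning.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  if (stats::sd(x - y) == 0) {
    warning("zero variance of paired differences; t undefined",
            call. = FALSE)
    return(list(t = NA_real_, df = n - 1, p = NA_real_, d = NA_real_,
                mean_diff = mean(x - y), n = n))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  t <- unname(ht$statistic)
  list(t = t, df = unname(ht$parameter), p = ht$p.value,
       d = cohens_d_from_t(t, n), mean_diff = unname(ht$estimate), n = n)
}

#' Pearson correlation with R squared
#'
#' Sample Pearson correlation via [stats::cor.test()] (two-tailed p from
#' `t = r * sqrt((n - 2) / (1 - r^2))`), reporting `r_squared = r^2`.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite.
#' @return List with `r`, `n`, `p`, `r_squared`; `NA` on zero variance.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = length(x), p = NA_real_,
                r_squared = NA_real_))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  list(r = r, n = length(x), p = ht$p.value, r_squared = r^2)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, treating
#' the two correlations as independent. Both one- and two-tailed normal
#' p-values are reported.
#'
#' @param r1,r2 The two correlation coefficients (|r| < 1; values at
#'   exactly +/-1 are clipped with a warning).
#' @param n1,n2 Their sample sizes (>= 4).
#' @return List with `z`, `p_one_tailed`, `p_two_tailed`.
#' @export
#' @examples
#' fisher_z_compare(-0.515, 37, -0.106, 37)$z  # -1.909
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4L, n2 >= 4L, abs(r1) <= 1, abs(r2) <= 1)
  clip <- function(r) {
    if (abs(r) == 1) {
      warning("correlation of exactly +/-1 clipped before atanh",
              call. = FALSE)
      sign(r) * (1 - 1e-12)
    } else r
  }
  z <- (atanh(clip(r1)) - atanh(clip(r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_one_tailed = stats::pnorm(-abs(z)),
       p_two_tailed = 2 * stats::pnorm(-abs(z)))
}
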