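#' 2x2 group summary (mean, SEM, n per cell)
#'
#' Container for the per-cell summary statistics of a two-factor design with
#' two levels each (e.g. age x genotype), as printable from a figure legend.
#'
#' @param age,genotype Character vectors (length 4) of factor levels per
#'   cell.
#' @param mean,sem,n Numeric vectors (length 4); n >= 2 and sem > 0.
#' @param measure Label for the summarized quantity.
#' @param units Units label.
#' @return An object of class \code{group_summary_2x2} (a data frame).
#' @export
group_summary_2x2 <- function(age, genotype, mean, sem, n,
                              measure = "", units = "") {
  d <- data.frame(age = as.character(age), genotype = as.character(genotype),
                  mean = mean, sem = sem, n = n)
  if (nrow(d) != 4) stop_invalid("a 2x2 summary needs exactly 4 cells")
  if (length(unique(d$age)) != 2 || length(unique(d$genotype)) != 2 ||
      anyDuplicated(d[c("age", "genotype")]))
    stop_invalid("cells must cover a full 2x2 crossing")
  if (any(d$n < 2)) stop_invalid("each cell needs n >= 2")
  if (any(d$sem <= 0)) stop_invalid("each cell needs sem > 0")
  structure(d, measure = measure, units = units,
            class = c("group_summary_2x2", "data.frame"))
}

#' Two-way ANOVA from 2x2 summary statistics
#'
#' Computes the two main effects and the interaction of an (unbalanced)
#' 2x2 design from per-cell means, SEMs and sample sizes alone. Cell SDs are
#' reconstructed as \code{sem * sqrt(n)}, giving
#' \deqn{SS_{within} = \sum_i (n_i - 1)(sem_i \sqrt{n_i})^2,}
#' with \eqn{df = \sum n_i - 4}. Effects are unweighted marginal-mean
#' (Type III) contrasts of the cell means,
#' \deqn{F = (\sum c_i \bar y_i)^2 / (MS_{within} \sum c_i^2 / n_i)}
#' with \eqn{c = (\pm\frac12)} patterns for the main effects and
#' \eqn{(\frac12, -\frac12, -\frac12, \frac12)} for the interaction. On a
#' balanced design this equals the classical two-way decomposition exactly;
#' on unbalanced designs it matches a Type III analysis of the raw data.
#'
#' @param summary A [group_summary_2x2()] object.
#' @return An object of class \code{anova2_summary}: a data frame with one
#'   row per effect (\code{age} = first factor, \code{genotype} = second,
#'   \code{interaction}) and columns \code{F}, \code{df1}, \code{df2},
#'   \code{p}; MS_within is attached as an attribute.
#' @examples
#' gs <- group_summary_2x2(
#'   age = c("young", "young", "aged", "aged"),
#'   genotype = c("WT", "VGAT", "WT", "VGAT"),
#'   mean = c(14695, 15410, 5358, 1655),
#'   sem = c(2387, 1740, 1744, 382.7), n = c(6, 6, 10, 10))
#' anova2_from_summary(gs)  # age effect F(1,28) ~ 51
#' @export
anova2_from_summary <- function(summary) {
  stopifnot(inherits(summary, "group_summary_2x2"))
  # fix a cell order: (a1,b1), (a1,b2), (a2,b1), (a2,b2)
  a_lv <- unique(summary$age)
  b_lv <- unique(summary$genotype)
  key <- paste(summary$age, summary$genotype)
  ord <- match(paste(rep(a_lv, each = 2), rep(b_lv, 2)), key)
  m <- summary$mean[ord]; sem <- summary$sem[ord]; n <- summary$n[ord]
  sd <- sem * sqrt(n)
  ss_within <- sum((n - 1) * sd^2)
  df2 <- sum(n) - 4
  if (df2 < 1) stop_invalid("insufficient residual degrees of freedom")
  ms_within <- ss_within / df2
  contrasts <- list(age = c(0.5, 0.5, -0.5, -0.5),
                    genotype = c(0.5, -0.5, 0.5, -0.5),
                    interaction = c(0.5, -0.5, -0.5, 0.5))
  Fs <- vapply(contrasts, function(cc)
    sum(cc * m)^2 / (ms_within * sum(cc^2 / n)), numeric(1))
  out <- data.frame(effect = names(contrasts), F = unname(Fs), df1 = 1,
                    df2 = df2, p = stats::pf(unname(Fs), 1, df2,
                                             lower.tail = FALSE))
  structure(out, ms_within = ms_within,
            measure = attr(summary, "measure"),
            class = c("anova2_summary", "data.frame"))
}

#' @export
print.anova2_summary <- function(x, ...) {
  msr <- attr(x, "measure")
  cat("Two-way ANOVA from summary statistics",
      if (nzchar(msr)) paste0(" (", msr, ")"), "\n", sep = "")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test on within-pair differences, delegating to
#' [stats::t.test()]. Zero-variance differences (which \code{t.test}
#' refuses) are handled explicitly: identical pairs give t = 0, p = 1; a
#' constant nonzero difference gives an infinite t flagged as degenerate
#' with p = 0.
#'
#' @param x,y Paired measurements (equal length, n >= 2).
#' @return A list with \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{degenerate}.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("'x' and 'y' must be paired")
  n <- length(x)
  if (n < 2) stop_invalid("at least 2 pairs required")
  d <- x - y
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf, df = n - 1,
                p = if (md == 0) 1 else 0, mean_diff = md,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Wrapper around [stats::ks.test()] returning the statistic
#' \eqn{D = \sup|F_x - F_y|} and the two-sided p-value. \code{exact = NULL}
#' (default) uses the stats-package rule (exact when the product of sample
#' sizes is below 10000, asymptotic otherwise); note that with equal sample
#' sizes D lives on a coarse lattice and the attainable test levels can sit
#' well below the nominal alpha (see the package vignette).
#'
#' @param x,y Nonempty numeric samples.
#' @param exact Logical or NULL, passed to [stats::ks.test()].
#' @return A list with \code{D} and \code{p}.
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop_invalid("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}
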