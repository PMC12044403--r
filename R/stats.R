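#' Kolmogorov-Smirnov normality screen (Lilliefors Monte-Carlo p)
#'
#' One-sample KS statistic of the data against a normal distribution with
#' the sample's own mean and SD. Because the reference parameters are
#' estimated from the sample, the classical KS p-value is anti-conservative;
#' the p-value is therefore calibrated by Monte-Carlo simulation of the
#' null (Lilliefors correction): \code{nrep} standard-normal samples of the
#' same size, each refit the same way.
#'
#' @param values numeric sample, n >= 5, nonzero variance.
#' @param nrep Monte-Carlo replicates (default 10000).
#' @param seed seed for the null simulation (default 1).
#' @return list(statistic, p).
#' @export
ksNormality <- function(values, nrep = 10000, seed = 1) {
  n <- length(values)
  if (n < 5) stop("need at least 5 observations")
  if (stats::sd(values) == 0) stop("zero-variance sample")
  dstat <- function(x) {
    x <- sort(x)
    F0 <- stats::pnorm(x, mean(x), stats::sd(x))
    max(seq_len(n) / n - F0, F0 - (seq_len(n) - 1) / n)
  }
  D <- dstat(values)
  null <- withSeed(seed, {
    vapply(seq_len(nrep), function(i) dstat(stats::rnorm(n)), numeric(1))
  })
  list(statistic = D, p = (1 + sum(null >= D)) / (nrep + 1))
}

.checkCells <- function(table) {
  need <- c("subject", "condition", "task", "value")
  stopifnot(all(need %in% names(table)))
  cells <- with(table, tapply(value, list(subject, paste(condition, task)),
                              mean))
  if (anyNA(cells)) {
    bad <- which(is.na(cells), arr.ind = TRUE)
    stop(sprintf("missing cell for subject %s, cell '%s'",
                 rownames(cells)[bad[1, 1]], colnames(cells)[bad[1, 2]]))
  }
  # columns ordered: negative elevator, negative plank, neutral elevator,
  # neutral plank (alphabetical); reorder to a fixed layout
  cells[, c("neutral elevator", "neutral plank",
            "negative elevator", "negative plank"), drop = FALSE]
}

.pairedF <- function(d, df_den) {
  # F = t^2 of the one-sample t on the contrast values d
  if (stats::sd(d) < 1e-300 || !is.finite(stats::sd(d)) ||
      stats::sd(d) == 0) {
    return(list(F = 0, p = 1))
  }
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  F <- t^2
  list(F = F, p = stats::pf(F, 1, df_den, lower.tail = FALSE))
}

#' 2x2 fully within-subject repeated-measures ANOVA
#'
#' Both factors (condition: neutral/negative; task: elevator/plank) have
#' two levels, so each effect is exactly a paired contrast: the main effect
#' of a factor is the paired t-test on subject means across its levels
#' (F = t^2 on 1 and n-1 df) and the interaction is the paired test on the
#' double difference. This closed form is identical to the classical
#' repeated-measures decomposition for a 2x2 design. Partial eta squared is
#' \code{F/(F + df_den)} per effect. Degenerate zero-variance contrasts are
#' reported as F = 0, p = 1 rather than an error.
#'
#' @param table data.frame with columns subject, condition, task, value;
#'   every subject must have all four cells (replicates within a cell are
#'   averaged first).
#' @return data.frame (one row per effect: condition, task,
#'   condition:task) with F, df_num, df_den, p, eta_p_sq, and the contrast
#'   mean (level-2 minus level-1 coding: negative - neutral,
#'   plank - elevator).
#' @export
rmAnova2x2 <- function(table) {
  cells <- .checkCells(table)
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 subjects")
  df_den <- n - 1
  # cells columns: neutral.elev, neutral.plank, negative.elev, negative.plank
  d_cond <- (cells[, 3] + cells[, 4]) / 2 - (cells[, 1] + cells[, 2]) / 2
  d_task <- (cells[, 2] + cells[, 4]) / 2 - (cells[, 1] + cells[, 3]) / 2
  d_int <- (cells[, 4] - cells[, 3]) - (cells[, 2] - cells[, 1])
  rows <- lapply(list(condition = d_cond, task = d_task,
                      `condition:task` = d_int), .pairedF, df_den = df_den)
  data.frame(
    effect = names(rows),
    F = vapply(rows, `[[`, 0, "F"),
    df_num = 1L,
    df_den = df_den,
    p = vapply(rows, `[[`, 0, "p"),
    eta_p_sq = vapply(rows, function(r) partialEtaSquared(r$F, 1, df_den), 0),
    contrast_mean = c(mean(d_cond), mean(d_task), mean(d_int)),
    row.names = NULL
  )
}

#' Partial eta squared from F and degrees of freedom
#'
#' \code{eta_p^2 = F * df_num / (F * df_num + df_den)}, the standard
#' effect-size measure SS_effect / (SS_effect + SS_error) expressed through
#' the F ratio.
#'
#' @param F F statistic (>= 0).
#' @param df_num numerator degrees of freedom.
#' @param df_den denominator (error) degrees of freedom.
#' @return partial eta squared in [0, 1).
#' @examples
#' partialEtaSquared(25.01, 1, 74)  # ~0.25
#' @export
partialEtaSquared <- function(F, df_num, df_den) {
  stopifnot(all(F >= 0), df_num >= 1, df_den >= 1)
  F * df_num / (F * df_num + df_den)
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Runs a paired t-test for each requested cell contrast and multiplies the
#' raw p-values by the number of comparisons (capped at 1).
#'
#' @param table data.frame with columns subject, cell, value (one value per
#'   subject per cell; replicates averaged).
#' @param comparisons list of length-2 character vectors naming cell pairs.
#' @return data.frame with cell_a, cell_b, mean_diff, t, df, p_raw, p_adj.
#' @export
bonferroniPairwise <- function(table, comparisons) {
  stopifnot(all(c("subject", "cell", "value") %in% names(table)),
            length(comparisons) >= 1)
  cells <- with(table, tapply(value, list(subject, cell), mean))
  m <- length(comparisons)
  out <- lapply(comparisons, function(cp) {
    stopifnot(length(cp) == 2)
    if (!all(cp %in% colnames(cells)))
      stop("unknown cell(s): ", paste(setdiff(cp, colnames(cells)),
                                      collapse = ", "))
    d <- cells[, cp[1]] - cells[, cp[2]]
    d <- d[!is.na(d)]
    n <- length(d)
    if (stats::sd(d) == 0) {
      t <- 0; p <- 1
    } else {
      t <- mean(d) / (stats::sd(d) / sqrt(n))
      p <- 2 * stats::pt(-abs(t), n - 1)
    }
    data.frame(cell_a = cp[1], cell_b = cp[2], mean_diff = mean(d),
               t = t, df = n - 1, p_raw = p, p_adj = min(1, m * p))
  })
  do.call(rbind, out)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with the
#' p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric samples of equal length, n >= 4, non-constant.
#' @return list(rho, p).
#' @export
spearmanCorrelation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no rank correlation")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p)
}
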