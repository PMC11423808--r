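#' Polar histogram of canal orientations
#'
#' Bins canal angles into right-closed bins over `(-180, 180]` and computes
#' anterior/posterior counts by the `|theta| > 90` rule (90 degrees exactly is
#' anterior).
#'
#' @param records canal-record data frame (rows with `class == "canal"` are
#'   used when a `class` column is present) or a numeric vector of angles.
#' @param bin_deg bin width; must divide 360 evenly.
#' @param specimen optional specimen identifier carried into the summary.
#' @return list of class `polar_summary`: `breaks_deg`, `counts`,
#'   `anterior_count`, `posterior_count`, `anterior_pct`, `posterior_pct`,
#'   `n`, `specimen`.
#' @export
polar_histogram <- function(records, bin_deg = 15, specimen = NA_character_) {
  if (360 %% bin_deg != 0) stop("bin_deg must divide 360 evenly")
  theta <- if (is.numeric(records)) records else {
    df <- records
    if (!is.null(df$class)) df <- df[df$class == "canal", , drop = FALSE]
    df$theta_deg
  }
  if (length(theta) == 0) stop("no canals to bin")
  if (any(theta <= -180 | theta > 180)) stop("angles must lie in (-180, 180]")
  breaks <- seq(-180, 180, by = bin_deg)
  counts <- as.vector(table(cut(theta, breaks = breaks, right = TRUE)))
  post <- sum(abs(theta) > 90)
  n <- length(theta)
  structure(list(
    breaks_deg = breaks, counts = counts,
    anterior_count = n - post, posterior_count = post,
    anterior_pct = 100 * (n - post) / n, posterior_pct = 100 * post / n,
    n = n, specimen = specimen
  ), class = "polar_summary")
}

#' @export
print.polar_summary <- function(x, ...) {
  cat(sprintf(
    "<polar_summary%s> n = %d; anterior %d (%.1f%%), posterior %d (%.1f%%)\n",
    if (!is.na(x$specimen)) paste0(":", x$specimen) else "",
    x$n, x$anterior_count, x$anterior_pct, x$posterior_count, x$posterior_pct))
  invisible(x)
}

#' Plot a polar summary as a rose diagram
#'
#' Radial bars per bin, annotated with the anterior/posterior percentages.
#'
#' @param x a `polar_summary`.
#' @param file optional PNG or SVG path; plots to the active device when NULL.
#' @param main plot title.
#' @return `file` (or NULL), invisibly.
#' @export
plot_polar_summary <- function(x, file = NULL, main = "Canal orientation") {
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
      png = grDevices::png(file, width = 640, height = 640),
      svg = grDevices::svg(file, width = 7, height = 7),
      stop("file must be .png or .svg"))
    on.exit(grDevices::dev.off())
  }
  rmax <- max(x$counts, 1)
  graphics::plot(0, 0, type = "n", xlim = c(-rmax, rmax) * 1.3,
                 ylim = c(-rmax, rmax) * 1.3, asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  nb <- length(x$counts)
  for (i in seq_len(nb)) {
    a0 <- x$breaks_deg[i] * pi / 180
    a1 <- x$breaks_deg[i + 1] * pi / 180
    r <- x$counts[i]
    if (r == 0) next
    aa <- seq(a0, a1, length.out = 16)
    graphics::polygon(c(0, r * cos(aa), 0), c(0, r * sin(aa), 0),
                      col = if (abs((x$breaks_deg[i] + x$breaks_deg[i + 1]) / 2) > 90)
                        "darkseagreen3" else "grey70", border = "grey30")
  }
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::text(rmax * 1.2, 0, sprintf("anterior %.0f%%", x$anterior_pct))
  graphics::text(-rmax * 1.2, 0, sprintf("posterior %.0f%%", x$posterior_pct))
  invisible(file)
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling. The two-sided p-value is exact (full
#' enumeration of rank assignments) when the combined sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used. The method used
#' is recorded in the result.
#'
#' @param sample_a,sample_b numeric samples (each >= 1 value).
#' @return list of class `canal_test` with `statistic` (U of the first
#'   sample), `p_value`, `n`, `method`, `exact`, `ties`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  exact <- (n <= 12) && !ties
  if (exact) {
    combos <- utils::combn(n, na)
    rank_sums <- colSums(matrix(seq_len(n)[combos], nrow = na))
    Us <- rank_sums - na * (na + 1) / 2
    p_lo <- mean(Us <= U)
    p_hi <- mean(Us >= U)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      method <- "degenerate (all values tied)"
    } else {
      z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
      p <- min(1, 2 * (1 - pnorm(z)))
      method <- "normal approximation, tie-corrected, continuity-corrected"
    }
  }
  structure(list(statistic = c(U = U), p_value = p, n = c(n_a = na, n_b = nb),
                 test = "Mann-Whitney U", method = method,
                 exact = exact, ties = ties),
            class = "canal_test")
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the pairwise differences, with the
#' (n - 1)-denominator standard deviation; two-sided p from the t distribution
#' with n - 1 degrees of freedom.
#'
#' @param sample_a,sample_b numeric vectors of equal length (n >= 2);
#'   differences must not all be zero.
#' @return list of class `canal_test` with `statistic` (t), `df`, `p_value`,
#'   `n`, `method`.
#' @export
paired_t_test <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  if (all(d == 0)) stop("degenerate pairing: all differences are zero")
  s <- sd(d)
  if (s == 0) stop("degenerate pairing: zero variance of differences")
  t_stat <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  structure(list(statistic = c(t = t_stat), df = n - 1, p_value = p,
                 n = c(n_pairs = n), test = "paired t",
                 method = "closed-form t distribution", exact = TRUE,
                 ties = FALSE),
            class = "canal_test")
}

#' @export
print.canal_test <- function(x, ...) {
  cat(sprintf("<canal_test:%s> %s = %.4f, p = %.4g (%s)\n",
              x$test, names(x$statistic)[1], x$statistic[1], x$p_value,
              x$method))
  invisible(x)
}
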