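#' Regional gray-scale statistics of a VOI
#'
#' Exact voxel count, mean and standard deviation (denominator `N_v - 1`) of
#' the gray values composing a VOI's support.
#'
#' @param volume a [vox_volume].
#' @param voi a [voi].
#' @param region region label for the output row.
#' @return a one-row tibble: `region`, `N_v`, `Avg`, `SD`.
#' @export
region_gray_stats <- function(volume, voi, region = voi$label) {
  if (length(voi$support) == 0) stop("domain error: empty VOI")
  g <- volume$data[voi$support]
  tibble(region = region, N_v = length(g), Avg = mean(g),
         SD = if (length(g) > 1) sd(g) else 0)
}

#' One-way ANOVA with Tukey post hoc from summary statistics or raw voxels
#'
#' Computes the one-way ANOVA from group sufficiency `(N, mean, SD)` -- the
#' between-group sum of squares from the means and the within-group sum from
#' the SDs, algebraically identical to the raw-data ANOVA -- and Tukey HSD
#' (Tukey-Kramer for unequal N) comparisons using the studentized-range
#' distribution at `alpha`, with `k` = number of groups and
#' `df = sum(N_v) - k`.
#'
#' @param groups a tibble with columns `region`, `N_v`, `Avg`, `SD`
#'   (e.g. rows of [region_gray_stats()]), or a named list of raw numeric
#'   vectors.
#' @param alpha significance level for the critical studentized range.
#' @param reference optional region name: restrict the comparison table to
#'   pairs involving this region (e.g. "rest of membrane" vs each band
#'   region). All pairs are returned when `NULL`.
#' @return a `stain_anova` object: tibble of comparisons (`group1`,
#'   `group2`, `diff`, `q`, `q_crit`, `significant`) with the ANOVA `F`,
#'   `df1`, `df2`, `p` and `MSW` as attributes.
#' @export
anova_tukey <- function(groups, alpha = 0.05, reference = NULL) {
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- tibble(region = names(groups),
                     N_v = vapply(groups, length, 1L),
                     Avg = vapply(groups, mean, 1),
                     SD = vapply(groups, sd, 1))
  }
  stopifnot(all(c("region", "N_v", "Avg", "SD") %in% names(groups)))
  if (nrow(groups) < 2) stop("need at least 2 groups")
  if (any(groups$N_v < 2)) stop("domain error: every group needs N_v >= 2")
  if (any(!is.finite(groups$SD))) stop("domain error: undefined SD")
  k <- nrow(groups)
  N <- sum(groups$N_v)
  grand <- sum(groups$N_v * groups$Avg) / N
  ssb <- sum(groups$N_v * (groups$Avg - grand)^2)
  ssw <- sum((groups$N_v - 1) * groups$SD^2)
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  Fstat <- msb / msw
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  q_crit <- qtukey(1 - alpha, k, df2)
  cmb <- utils::combn(k, 2)
  comp <- tibble(
    group1 = groups$region[cmb[1, ]], group2 = groups$region[cmb[2, ]],
    diff = groups$Avg[cmb[1, ]] - groups$Avg[cmb[2, ]],
    se = sqrt(msw / 2 * (1 / groups$N_v[cmb[1, ]] + 1 / groups$N_v[cmb[2, ]])),
    q = abs(groups$Avg[cmb[1, ]] - groups$Avg[cmb[2, ]]) /
      sqrt(msw / 2 * (1 / groups$N_v[cmb[1, ]] + 1 / groups$N_v[cmb[2, ]])),
    q_crit = q_crit)
  comp$significant <- comp$q > comp$q_crit
  if (!is.null(reference))
    comp <- comp[comp$group1 == reference | comp$group2 == reference, ]
  structure(comp, class = c("stain_anova", class(comp)),
            F = Fstat, df1 = df1, df2 = df2, p = p, MSW = msw, alpha = alpha)
}

#' @export
print.stain_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g; Tukey alpha = %g\n",
              attr(x, "df1"), attr(x, "df2"), attr(x, "F"), attr(x, "p"),
              attr(x, "alpha")))
  NextMethod()
}

#' @method tidy stain_anova
#' @export
tidy.stain_anova <- function(x, ...) {
  tibble(group1 = x$group1, group2 = x$group2, estimate = x$diff,
         statistic = x$q, q_crit = x$q_crit, significant = x$significant)
}

#' @method glance stain_anova
#' @export
glance.stain_anova <- function(x, ...) {
  tibble(statistic = attr(x, "F"), df1 = attr(x, "df1"), df2 = attr(x, "df2"),
         p.value = attr(x, "p"), MSW = attr(x, "MSW"))
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Two-tailed Student t test with pooled variance, computed from
#' `(mean, SD, n)` summaries.
#'
#' @param statsA,statsB numeric vectors `c(mean, sd, n)`.
#' @return list with `t`, `df`, `p` and an `overflow` flag (zero pooled
#'   variance with unequal means).
#' @export
pooled_t_test <- function(statsA, statsB) {
  ma <- statsA[1]; sa <- statsA[2]; na <- statsA[3]
  mb <- statsB[1]; sb <- statsB[2]; nb <- statsB[3]
  if (na < 2 || nb < 2) stop("need n >= 2 in each group")
  df <- na + nb - 2
  sp2 <- ((na - 1) * sa^2 + (nb - 1) * sb^2) / df
  if (sp2 <= 0) {
    if (ma != mb)
      return(list(t = Inf, df = df, p = 0, overflow = TRUE))
    return(list(t = 0, df = df, p = 1, overflow = FALSE))
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), overflow = FALSE)
}

#' Table-1-style stain-density comparisons from a summary CSV
#'
#' Reads a CSV with columns `vesicle`, `region`, `N_v`, `Avg`, `SD` and runs
#' the per-vesicle ANOVA + Tukey comparisons of every region against the
#' reference region, treating each vesicle as an individual experiment.
#'
#' @param path CSV path.
#' @param reference reference region name (default "rest").
#' @return tibble of per-vesicle comparisons with ANOVA F and p columns.
#' @export
stain_density_from_summary <- function(path, reference = "rest") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("vesicle", "region", "N_v", "Avg", "SD") %in% names(df)))
  out <- lapply(split(df, df$vesicle), function(d) {
    a <- anova_tukey(tibble(region = d$region, N_v = d$N_v,
                            Avg = d$Avg, SD = d$SD), reference = reference)
    tibble(vesicle = d$vesicle[1], tidy(a),
           F = attr(a, "F"), p = attr(a, "p"))
  })
  bind_rows(out)
}
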