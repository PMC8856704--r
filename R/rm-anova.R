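# Two-way mixed-design (split-plot) ANOVA: one between-subjects factor
# (group) and one within-subjects factor (day). Sums of squares are computed
# directly from cell/marginal means rather than through a fitted linear
# model, so the decomposition is auditable:
#
#   between-subjects stratum: SS_group tested against SS_subj(group)
#   within-subjects stratum:  SS_day, SS_day:group tested against the
#                             day x subject(group) residual
#
# An optional Greenhouse-Geisser correction multiplies the within-stratum
# degrees of freedom by the sphericity epsilon estimated from the pooled
# within-group covariance of the subject x day matrix.

#' Mixed-design repeated-measures ANOVA (group x day)
#'
#' @param data data frame with one row per subject-day observation.
#' @param measure name of the response column (e.g. `"commission_rate"`).
#' @param subject,group,day names of the subject id, between-group and
#'   within-day columns.
#' @param gg_correction apply the Greenhouse-Geisser sphericity
#'   correction to the within-subject tests (reported as
#'   corrected df and p alongside the uncorrected ones).
#' @param arcsine apply the arcsine-square-root variance-stabilizing
#'   transform to the response (useful for proportions) before the analysis.
#' @return A `gonogo_rm_anova` object: the ANOVA table (data frame with
#'   `effect`, `df1`, `df2`, `ss`, `ms`, `F`, `p`, and when requested
#'   `df1_gg`, `df2_gg`, `p_gg`) plus design metadata in attributes
#'   (`epsilon_gg`, `n_per_group`, `n_days`). Missing or duplicated cells
#'   are an error; no silent imputation.
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), day = 1:4)
#' d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 3,
#'                   "control", "defeated")
#' set.seed(1); d$y <- rnorm(nrow(d))
#' rm_anova(d, "y")
#' @export
rm_anova <- function(data, measure, subject = "subject", group = "group",
                     day = "day", gg_correction = FALSE, arcsine = FALSE) {
  for (col in c(measure, subject, group, day)) {
    if (!col %in% names(data)) {
      stop("anova error: column `", col, "` not found", call. = FALSE)
    }
  }
  y <- as.numeric(data[[measure]])
  if (anyNA(y)) {
    stop("anova error: missing values in `", measure,
         "`; no silent imputation", call. = FALSE)
  }
  if (arcsine) {
    if (any(y < 0 | y > 1)) {
      stop("anova error: arcsine transform requires values in [0, 1]",
           call. = FALSE)
    }
    y <- asin(sqrt(y))
  }
  subj <- factor(data[[subject]])
  grp <- factor(data[[group]])
  dy <- factor(data[[day]])

  # design checks: complete, balanced, equal group sizes
  tab <- table(subj, dy)
  if (any(tab != 1L)) {
    stop("anova error: each subject must have exactly one value per day ",
         "(missing or duplicated cells found)", call. = FALSE)
  }
  subj_group <- tapply(as.character(grp), subj, function(g) {
    u <- unique(g)
    if (length(u) != 1L) stop("anova error: subject in multiple groups",
                              call. = FALSE)
    u
  })
  g <- nlevels(grp)
  d <- nlevels(dy)
  if (g < 2L) stop("anova error: need >= 2 groups", call. = FALSE)
  if (d < 2L) stop("anova error: need >= 2 days", call. = FALSE)
  n_per <- table(factor(subj_group, levels = levels(grp)))
  if (length(unique(n_per)) != 1L) {
    stop("anova error: groups must have equal numbers of subjects",
         call. = FALSE)
  }
  n <- as.integer(n_per[1])
  if (n < 2L) stop("anova error: need >= 2 subjects per group",
                   call. = FALSE)

  # wide matrix: subjects x days, plus group of each subject
  X <- matrix(NA_real_, nrow = nlevels(subj), ncol = d,
              dimnames = list(levels(subj), levels(dy)))
  X[cbind(as.integer(subj), as.integer(dy))] <- y
  g_of <- factor(subj_group[levels(subj)], levels = levels(grp))

  M <- mean(X)
  m_s <- rowMeans(X)                       # subject means
  m_d <- colMeans(X)                       # day means
  m_g <- tapply(m_s, g_of, mean)           # group means
  m_gd <- apply(X, 2, function(col) tapply(col, g_of, mean))  # g x d cells

  ss_total <- sum((X - M)^2)
  ss_between_subj <- d * sum((m_s - M)^2)
  ss_group <- d * n * sum((m_g - M)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_day <- g * n * sum((m_d - M)^2)
  cell_dev <- sweep(sweep(m_gd, 1, as.numeric(m_g)), 2, m_d) + M
  ss_int <- n * sum(cell_dev^2)
  ss_within_subj <- ss_total - ss_between_subj
  ss_err <- ss_within_subj - ss_day - ss_int
  ss_err <- max(ss_err, 0)

  df_group <- g - 1L
  df_subj <- g * (n - 1L)
  df_day <- d - 1L
  df_int <- (g - 1L) * (d - 1L)
  df_err <- (d - 1L) * g * (n - 1L)

  safe_f <- function(ss_eff, df_eff, ss_e, df_e) {
    ms_eff <- ss_eff / df_eff
    ms_e <- ss_e / df_e
    if (ms_e <= 0) {
      if (ms_eff <= 0) return(c(F = NA_real_, p = NA_real_))  # degenerate
      return(c(F = Inf, p = 0))
    }
    f <- ms_eff / ms_e
    c(F = f, p = stats::pf(f, df_eff, df_e, lower.tail = FALSE))
  }
  f_group <- safe_f(ss_group, df_group, ss_subj_within, df_subj)
  f_day <- safe_f(ss_day, df_day, ss_err, df_err)
  f_int <- safe_f(ss_int, df_int, ss_err, df_err)

  tab_out <- data.frame(
    effect = c("group", "day", "day:group"),
    df1 = c(df_group, df_day, df_int),
    df2 = c(df_subj, df_err, df_err),
    ss = c(ss_group, ss_day, ss_int),
    ms = c(ss_group / df_group, ss_day / df_day, ss_int / df_int),
    F = c(f_group["F"], f_day["F"], f_int["F"]),
    p = c(f_group["p"], f_day["p"], f_int["p"]),
    stringsAsFactors = FALSE)

  eps <- NA_real_
  if (gg_correction) {
    eps <- .gg_epsilon(X, g_of)
    gg_p <- function(frow, df1, df2) {
      if (is.na(frow["F"]) || !is.finite(frow["F"])) return(frow["p"])
      stats::pf(frow["F"], eps * df1, eps * df2, lower.tail = FALSE)
    }
    tab_out$df1_gg <- c(df_group, eps * df_day, eps * df_int)
    tab_out$df2_gg <- c(df_subj, eps * df_err, eps * df_err)
    tab_out$p_gg <- c(f_group["p"],
                      gg_p(f_day, df_day, df_err),
                      gg_p(f_int, df_int, df_err))
  }

  structure(tab_out,
            class = c("gonogo_rm_anova", "data.frame"),
            measure = measure,
            epsilon_gg = eps,
            n_per_group = n, n_groups = g, n_days = d,
            ss_error_within = ss_err, ss_subjects = ss_subj_within,
            degenerate = ss_err == 0 && ss_subj_within == 0)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x day matrix; equals (tr S*)^2 / ((d-1) tr(S*^2)) where S* is the
# double-centered covariance matrix. Bounded to [1/(d-1), 1].
.gg_epsilon <- function(X, g_of) {
  d <- ncol(X)
  groups <- levels(g_of)
  S <- matrix(0, d, d)
  wsum <- 0
  for (g in groups) {
    Xg <- X[g_of == g, , drop = FALSE]
    if (nrow(Xg) > 1L) {
      S <- S + stats::cov(Xg) * (nrow(Xg) - 1L)
      wsum <- wsum + (nrow(Xg) - 1L)
    }
  }
  S <- S / wsum
  rm_ <- rowMeans(S); gm <- mean(S)
  Sdc <- S - outer(rm_, rep(1, d)) - outer(rep(1, d), rm_) + gm
  tr <- sum(diag(Sdc))
  denom <- (d - 1) * sum(Sdc^2)
  if (denom <= 0) return(1)
  min(max(tr^2 / denom, 1 / (d - 1)), 1)
}

#' @export
print.gonogo_rm_anova <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA on `%s` (%d groups x %d days, n = %d/group)\n",
              attr(x, "measure"), attr(x, "n_groups"), attr(x, "n_days"),
              attr(x, "n_per_group")))
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  [degenerate: zero error variance]\n")
  }
  for (i in seq_len(nrow(x))) {
    if ("p_gg" %in% names(x)) {
      cat(sprintf("  %-10s F(%.2f, %.2f) = %s, p = %s  [GG-corrected]\n",
                  x$effect[i], x$df1_gg[i], x$df2_gg[i],
                  .fmt_stat(x$F[i]), .fmt_stat(x$p_gg[i])))
    } else {
      cat(sprintf("  %-10s F(%d, %d) = %s, p = %s\n",
                  x$effect[i], x$df1[i], x$df2[i],
                  .fmt_stat(x$F[i]), .fmt_stat(x$p[i])))
    }
  }
  invisible(x)
}

.fmt_stat <- function(v) {
  if (is.na(v)) "NA" else if (!is.finite(v)) "Inf" else sprintf("%.4g", v)
}
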