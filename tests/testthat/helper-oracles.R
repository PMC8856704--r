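# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Exact two-sided rank-sum p by full enumeration of all assignments of the
# pooled ranks to the first sample (feasible for n1 + n2 <= 16). Mirrors
# the doubled one-tail convention for the two-sided p.
exact_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  p <- if (u_obs > mid) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(p, 1)
}

# Brute-force mixed-design ANOVA through stats::aov error strata
aov_oracle <- function(data, measure) {
  d <- data
  d$subject <- factor(d$subject)
  d$group <- factor(d$group)
  d$day <- factor(d$day)
  d$y <- d[[measure]]
  fit <- stats::aov(y ~ group * day + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  list(F_group = between["group", "F value"],
       p_group = between["group", "Pr(>F)"],
       F_day = within["day", "F value"],
       p_day = within["day", "Pr(>F)"],
       F_int = within["group:day", "F value"],
       p_int = within["group:day", "Pr(>F)"])
}

# Greenhouse-Geisser epsilon via the orthonormal-contrast eigenvalue form:
# eps = (sum lambda)^2 / ((d-1) sum lambda^2), lambda eigenvalues of C S C'
gg_epsilon_oracle <- function(X, g_of) {
  d <- ncol(X)
  S <- matrix(0, d, d); w <- 0
  for (g in levels(g_of)) {
    Xg <- X[g_of == g, , drop = FALSE]
    S <- S + stats::cov(Xg) * (nrow(Xg) - 1L)
    w <- w + nrow(Xg) - 1L
  }
  S <- S / w
  C <- stats::contr.helmert(d)
  C <- qr.Q(qr(C))  # orthonormal basis of the contrast space
  lam <- eigen(t(C) %*% S %*% C, symmetric = TRUE, only.values = TRUE)$values
  sum(lam)^2 / ((d - 1) * sum(lam^2))
}

# small deterministic aligned tensor built directly (no generator): one
# neuron per row of `values_by_trial`, arbitrary sample grid
toy_tensor <- function(values, time_s) {
  # values: neurons x trials x samples array
  structure(list(z = values, time_s = time_s,
                 trials = data.frame(trial_type = rep("go", dim(values)[2]),
                                     outcome = rep("hit", dim(values)[2]),
                                     day = 1L),
                 onset_index = which(time_s == 0)[1],
                 frame_rate_hz = 1 / diff(time_s[1:2]),
                 n_dropped = 0L),
            class = "aligned_tensor")
}
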