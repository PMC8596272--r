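# Group-level inference: rest-subtracted responses, hemisphere contrasts,
# Wilks' lambda MANOVA with Rao's F approximation and partial eta squared,
# assumption checks (Levene, Lilliefors-corrected Kolmogorov-Smirnov) and
# post-hoc machinery (Tukey HSD, Games-Howell, two-sided Dunnett by seeded
# Monte Carlo, Bonferroni-corrected pairwise t).

#' Rest-subtracted stimulus responses
#'
#' For every (subject, band, channel), subtracts the resting-state HFD from
#' the HFD of each stimulus state: `delta_hfd = hfd(stimulus) - hfd(rest)`.
#' Rest records are consumed, not emitted.
#'
#' @param table An `hfd_table` (see [hfd_table()]).
#' @return Data frame of class `delta_table` with columns `subject`,
#'   `group`, `stimulus`, `band`, `channel`, `hemisphere`, `locus`,
#'   `delta_hfd`.
#' @export
rest_difference <- function(table) {
  need <- c("subject", "state", "band", "channel", "hfd")
  if (!all(need %in% names(table))) {
    fe_stop("fe_param_error", "`table` must carry subject/state/band/channel/hfd")
  }
  rest <- table[table$state == "rest",
                c("subject", "band", "channel", "hfd")]
  names(rest)[names(rest) == "hfd"] <- "rest_hfd"
  stim <- table[table$state != "rest", , drop = FALSE]
  out <- merge(stim, rest, by = c("subject", "band", "channel"),
               all.x = TRUE, sort = FALSE)
  if (any(is.na(out$rest_hfd))) {
    bad <- out[is.na(out$rest_hfd), ][1L, ]
    fe_stop("fe_data_error",
            sprintf("missing rest record for subject %s, band %s, channel %s",
                    bad$subject, bad$band, bad$channel))
  }
  out$delta_hfd <- out$hfd - out$rest_hfd
  out$stimulus <- out$state
  keep <- c("subject", "group", "stimulus", "band", "channel",
            "hemisphere", "locus", "delta_hfd")
  keep <- intersect(keep, c(names(out), "delta_hfd"))
  out <- out[, keep]
  out <- out[order(out$subject, out$band, out$stimulus, out$channel), ]
  rownames(out) <- NULL
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Left-minus-right hemisphere contrast
#'
#' Mean value in the left hemisphere minus mean value in the right, per
#' (group, band, state) cell; positive means the left hemisphere carries the
#' higher complexity.  Accepts both raw HFD tables (value column `hfd`,
#' state column `state`) and rest-subtracted tables (`delta_hfd`,
#' `stimulus`).
#'
#' @param table An `hfd_table` or `delta_table` with populated `hemisphere`.
#' @return Data frame with columns `group`, `band`, `state`, `contrast`.
#' @export
hemisphere_contrast <- function(table) {
  value_col <- if ("delta_hfd" %in% names(table)) "delta_hfd" else "hfd"
  state_col <- if ("stimulus" %in% names(table)) "stimulus" else "state"
  if (!"hemisphere" %in% names(table) || any(is.na(table$hemisphere))) {
    fe_stop("fe_data_error", "`hemisphere` must be populated")
  }
  agg <- stats::aggregate(table[[value_col]],
                          by = list(group = table$group,
                                    band = table$band,
                                    state = table[[state_col]],
                                    hemisphere = table$hemisphere),
                          FUN = mean)
  left <- agg[agg$hemisphere == "left", ]
  right <- agg[agg$hemisphere == "right", ]
  out <- merge(left[, c("group", "band", "state", "x")],
               right[, c("group", "band", "state", "x")],
               by = c("group", "band", "state"), suffixes = c("_l", "_r"))
  out$contrast <- out$x_l - out$x_r
  out <- out[order(out$group, out$band, out$state),
             c("group", "band", "state", "contrast")]
  rownames(out) <- NULL
  out
}

#' MANOVA via Wilks' lambda
#'
#' One-way (factor `group`) or two-way crossed (`group`, `stimulus`,
#' interaction; sequential sums of squares) multivariate analysis of
#' variance.  For each term, Wilks'
#' \eqn{\Lambda = \det(E)/\det(E + H)} is computed from the within (E) and
#' hypothesis (H) SSCP matrices, converted to an F statistic by Rao's
#' approximation (exact when \eqn{\min(p, q) \le 2}), with partial
#' \eqn{\eta^2 = 1 - \Lambda^{1/s}}.
#'
#' @param responses Numeric matrix (observations x response variables) or
#'   data frame.
#' @param group Factor (or coercible) of group labels, length `nrow(responses)`.
#' @param stimulus Optional second crossed factor.
#' @return A `manova_result` (one-way) or named list of `manova_result`
#'   objects (`group`, `stimulus`, `group:stimulus`).  Fields: `factor`,
#'   `wilks_lambda`, `f_stat`, `df_num`, `df_den`, `p`, `partial_eta_sq`.
#' @export
wilks_manova <- function(responses, group, stimulus = NULL) {
  Y <- as.matrix(responses)
  if (!is.numeric(Y)) fe_stop("fe_param_error", "responses must be numeric")
  group <- factor(group)
  n <- nrow(Y); p <- ncol(Y)
  if (nlevels(group) < 2L) {
    fe_stop("fe_param_error", "need at least 2 groups")
  }
  if (length(group) != n) {
    fe_stop("fe_param_error", "`group` must match the rows of `responses`")
  }
  if (is.null(stimulus)) {
    if (n <= p + nlevels(group)) {
      fe_stop("fe_param_error",
              sprintf("need n > responses + groups (%d <= %d + %d)",
                      n, p, nlevels(group)))
    }
    grand <- colMeans(Y)
    E <- matrix(0, p, p); H <- matrix(0, p, p)
    for (lev in levels(group)) {
      Yg <- Y[group == lev, , drop = FALSE]
      mg <- colMeans(Yg)
      E <- E + crossprod(sweep(Yg, 2L, mg))
      H <- H + nrow(Yg) * tcrossprod(mg - grand)
    }
    return(wilks_from_sscp(E, H, q = nlevels(group) - 1L,
                           v = n - nlevels(group), label = "group"))
  }
  stimulus <- factor(stimulus)
  X1 <- stats::model.matrix(~group)
  X2 <- stats::model.matrix(~group + stimulus)
  X3 <- stats::model.matrix(~group * stimulus)
  fit <- function(X) {
    qr_ <- qr(X)
    list(fitted = qr.fitted(qr_, Y), rank = qr_$rank)
  }
  f0 <- list(fitted = matrix(colMeans(Y), n, p, byrow = TRUE), rank = 1L)
  f1 <- fit(X1); f2 <- fit(X2); f3 <- fit(X3)
  E <- crossprod(Y - f3$fitted)
  v <- n - f3$rank
  terms <- list(
    group = list(H = crossprod(f1$fitted - f0$fitted), q = f1$rank - f0$rank),
    stimulus = list(H = crossprod(f2$fitted - f1$fitted), q = f2$rank - f1$rank),
    `group:stimulus` = list(H = crossprod(f3$fitted - f2$fitted),
                            q = f3$rank - f2$rank)
  )
  out <- lapply(names(terms), function(nm) {
    wilks_from_sscp(E, terms[[nm]]$H, q = terms[[nm]]$q, v = v, label = nm)
  })
  stats::setNames(out, names(terms))
}

wilks_from_sscp <- function(E, H, q, v, label) {
  p <- ncol(E)
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0 || rcond(E) < 1e-12) {
    fe_stop("fe_rank_error",
            "singular within-group SSCP matrix; reduce the response set")
  }
  lambda <- detE / det(E + H)
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * s - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  f_stat <- (1 - lam_s) / lam_s * df2 / df1
  structure(list(
    factor = label,
    wilks_lambda = lambda,
    f_stat = f_stat,
    df_num = df1,
    df_den = df2,
    p = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
    partial_eta_sq = 1 - lam_s
  ), class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("Wilks' lambda [%s] = %.4f, F(%g, %.1f) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$factor, x$wilks_lambda, x$df_num, x$df_den, x$f_stat, x$p,
              x$partial_eta_sq))
  invisible(x)
}

#' Bonferroni-style corrected significance threshold
#'
#' Divides the family residual (the alpha budget left for a family of `m`
#' comparisons) by `m` and rounds the way the thresholds are conventionally
#' printed: three decimal places, falling back to one significant digit for
#' values below 0.001.  With the conventional residual 0.05 this yields
#' 0.017 for 3 comparisons, 0.003 for 18 and 0.0003 for 162.
#'
#' @param family_residual Total alpha for the family, strictly in (0, 1);
#'   default 0.05.
#' @param m Number of comparisons.
#' @return The rounded threshold, with the unrounded value in attribute
#'   `"exact"`.
#' @export
corrected_alpha <- function(family_residual = 0.05, m) {
  stopifnot_prob_open(family_residual, "family_residual")
  stopifnot_scalar_count(m, "m", min = 1L)
  exact <- family_residual / m
  rounded <- round(exact, 3L)
  if (rounded == 0) rounded <- signif(exact, 1L)
  structure(rounded, exact = exact)
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations from the group center (mean by
#' default; `center = "median"` gives the Brown-Forsythe variant).
#'
#' @param groups List of numeric samples, one per group, each `n >= 2`.
#' @param center `"mean"` or `"median"`.
#' @return List with `statistic`, `p`, `df1`, `df2`, `center`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L) {
    fe_stop("fe_param_error", "need a list of at least 2 groups")
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) fe_stop("fe_param_error", "every group needs n >= 2")
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(groups, function(x) abs(x - cfun(x)))
  g <- length(z); N <- sum(ns)
  zbar <- mean(unlist(z))
  zbar_g <- vapply(z, mean, numeric(1L))
  ssb <- sum(ns * (zbar_g - zbar)^2)
  ssw <- sum(vapply(seq_len(g), function(i) sum((z[[i]] - zbar_g[i])^2),
                    numeric(1L)))
  df1 <- g - 1L; df2 <- N - g
  stat <- if (ssw == 0) 0 else (ssb / df1) / (ssw / df2)
  p <- if (ssw == 0 && ssb == 0) 1 else
    stats::pf(stat, df1, df2, lower.tail = FALSE)
  list(statistic = stat, p = p, df1 = df1, df2 = df2, center = center)
}

# cache of Monte-Carlo null tables for the Lilliefors statistic, keyed by n
.lillie_null_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  z <- sort((x - mean(x)) / s)
  Fz <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - Fz), max(Fz - (i - 1) / n))
}

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' One-sample KS statistic against a normal distribution with mean and SD
#' estimated from the data.  Because the null parameters are estimated, the
#' classical KS null distribution does not apply; the p-value is obtained
#' from a seeded Monte-Carlo null table (cached per sample size).
#'
#' @param x Numeric sample, `n >= 5`, non-constant.
#' @param nsim Monte-Carlo replicates for the null table (default 2000).
#' @return List with `statistic` (sup-distance, in `[0, 1]`) and `p`.
#' @export
ks_normality <- function(x, nsim = 2000L) {
  n <- length(x)
  if (n < 5L) fe_stop("fe_param_error", "need at least 5 observations")
  if (any(!is.finite(x))) fe_stop("fe_param_error", "`x` must be finite")
  if (stats::sd(x) == 0) {
    fe_stop("fe_degenerate_error", "constant sample has no defined KS statistic")
  }
  d <- lilliefors_stat(x)
  key <- sprintf("n%d_s%d", n, nsim)
  if (is.null(.lillie_null_cache[[key]])) {
    .lillie_null_cache[[key]] <- with_seed_opt(424243L, {
      vapply(seq_len(nsim), function(i) lilliefors_stat(stats::rnorm(n)),
             numeric(1L))
    })
  }
  null <- .lillie_null_cache[[key]]
  list(statistic = d, p = (1 + sum(null >= d)) / (nsim + 1))
}

#' Pairwise post-hoc comparisons
#'
#' @param groups Named list of numeric samples.
#' @param method `"tukey"` (studentized-range HSD, pooled variance),
#'   `"games_howell"` (Welch-adjusted studentized range for unequal
#'   variances), `"dunnett"` (two-sided many-to-one versus `control`,
#'   critical values from the multivariate t by seeded Monte Carlo), or
#'   `"bonferroni_t"` (pooled pairwise t with Bonferroni adjustment).
#' @param control Reference group label, required for `"dunnett"`.
#' @param seed Seed for the Dunnett Monte Carlo (default 1).
#' @param nsim Monte-Carlo draws for Dunnett (default `1e5`).
#' @return Object of class `posthoc_result`: `method` and a `pairs` data
#'   frame (`group_a`, `group_b`, `statistic`, `p_adjusted`).
#' @export
posthoc <- function(groups, method = c("tukey", "games_howell", "dunnett",
                                       "bonferroni_t"),
                    control = NULL, seed = 1L, nsim = 1e5L) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L) {
    fe_stop("fe_param_error", "need a list of at least 2 groups")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) fe_stop("fe_param_error", "every group needs n >= 2")
  g <- length(groups)
  means <- vapply(groups, mean, numeric(1L))
  vars <- vapply(groups, stats::var, numeric(1L))
  N <- sum(ns)
  df_pool <- N - g
  s2p <- sum((ns - 1L) * vars) / df_pool

  if (method == "dunnett") {
    if (is.null(control) || !control %in% names(groups)) {
      fe_stop("fe_param_error", "`control` must name one of the groups")
    }
    others <- setdiff(names(groups), control)
    n0 <- ns[[control]]
    tstat <- (means[others] - means[[control]]) /
      sqrt(s2p * (1 / ns[others] + 1 / n0))
    lam <- sqrt(ns[others] / (ns[others] + n0))
    maxT <- with_seed_opt(seed, {
      z0 <- stats::rnorm(nsim)
      zz <- matrix(stats::rnorm(nsim * length(others)), nsim)
      wden <- sqrt(stats::rchisq(nsim, df_pool) / df_pool)
      tt <- sweep(zz, 2L, sqrt(1 - lam^2), `*`) + outer(z0, lam)
      apply(abs(tt / wden), 1L, max)
    })
    pairs <- data.frame(
      group_a = others, group_b = control,
      statistic = unname(tstat),
      p_adjusted = vapply(abs(tstat), function(t0) mean(maxT >= t0),
                          numeric(1L)),
      stringsAsFactors = FALSE
    )
    rownames(pairs) <- NULL
    return(structure(list(method = method, pairs = pairs),
                     class = "posthoc_result"))
  }

  cmb <- utils::combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1L, j]; b <- cmb[2L, j]
    diff <- means[[a]] - means[[b]]
    if (method == "tukey") {
      se <- sqrt(s2p / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
      q <- abs(diff) / se
      p <- stats::ptukey(q, g, df_pool, lower.tail = FALSE)
      data.frame(group_a = a, group_b = b, statistic = q, p_adjusted = p,
                 stringsAsFactors = FALSE)
    } else if (method == "games_howell") {
      va <- vars[[a]] / ns[[a]]; vb <- vars[[b]] / ns[[b]]
      se <- sqrt(va + vb)
      df_w <- se^4 / (va^2 / (ns[[a]] - 1L) + vb^2 / (ns[[b]] - 1L))
      q <- abs(diff) / se * sqrt(2)
      p <- stats::ptukey(q, g, df_w, lower.tail = FALSE)
      data.frame(group_a = a, group_b = b, statistic = q, p_adjusted = p,
                 stringsAsFactors = FALSE)
    } else { # bonferroni_t
      se <- sqrt(s2p * (1 / ns[[a]] + 1 / ns[[b]]))
      t0 <- diff / se
      p <- min(1, ncol(cmb) * 2 *
                 stats::pt(abs(t0), df_pool, lower.tail = FALSE))
      data.frame(group_a = a, group_b = b, statistic = t0, p_adjusted = p,
                 stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(list(method = method, pairs = pairs), class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("Post-hoc comparisons (%s):\n", x$method))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
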