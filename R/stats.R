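#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] that enforces the valid sample
#' range and reports constant samples as missing instead of erroring.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return named numeric `c(W, p)`; both NA for a constant sample.
#' @export
shapiro_screen <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(x)) == 0) return(c(W = NA_real_, p = NA_real_))
  s <- stats::shapiro.test(x)
  c(W = unname(s$statistic), p = s$p.value)
}

row_midranks <- function(tab) t(apply(tab, 1, rank))

#' Friedman repeated-measures test with Kendall's W effect size
#'
#' Rank-based test of a condition effect across k repeated conditions on N
#' subjects. Ties within a subject are mid-ranked and the standard tie
#' correction is applied. Kendall's coefficient of concordance
#' `W = chi2 / (N (k - 1))` is reported with Cohen's interpretation bands:
#' small (< 0.3), moderate (< 0.5), large (>= 0.5). When the permutation
#' space is small enough (`(k!)^N <= 1e6`) an exact permutation p-value is
#' computed alongside the chi-square approximation.
#'
#' @param tab N x k numeric matrix, one row per subject, one column per
#'   condition (e.g. T1, T2, T3). Rows with missing cells are dropped with a
#'   warning.
#' @return list with chi2, df, p (chi-square), p_exact (NA when not
#'   enumerated), kendall_w, effect_label, n, k.
#' @export
friedman_w <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) {
    warning("rows with missing cells dropped (listwise deletion)")
    tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  }
  n <- nrow(tab); k <- ncol(tab)
  if (k < 2 || n < 3) stop("need at least 3 complete subjects and 2 conditions")
  R <- row_midranks(tab)
  Rj <- colSums(R)
  ties <- sum(apply(tab, 1, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  }))
  C <- 1 - ties / (n * (k^3 - k))
  if (C <= 0) return(list(chi2 = NA_real_, df = k - 1, p = NA_real_,
                          p_exact = NA_real_, kendall_w = NA_real_,
                          effect_label = NA_character_, n = n, k = k))
  chi2 <- (12 * sum(Rj^2) / (n * k * (k + 1)) - 3 * n * (k + 1)) / C
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  w <- chi2 / (n * (k - 1))
  lab <- effect_band(w)
  p_exact <- if (factorial(k)^n <= 1e6) friedman_exact_p(R) else NA_real_
  list(chi2 = chi2, df = k - 1, p = p, p_exact = p_exact, kendall_w = w,
       effect_label = lab, n = n, k = k)
}

effect_band <- function(w) {
  if (is.na(w)) NA_character_
  else if (w < 0.3) "small" else if (w < 0.5) "moderate" else "large"
}

# exact permutation p of the Friedman statistic: under H0 each subject's rank
# vector is equally likely in any column order; the statistic is monotone in
# sum(Rj^2), whose null distribution is built by convolving the per-subject
# column-sum contributions over all k! column permutations.
friedman_exact_p <- function(R) {
  n <- nrow(R); k <- ncol(R)
  perms <- permutations_of(k)
  # distribution over column-sum vectors, keyed by the first k-1 sums
  dist <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(rep(0, k), collapse = ","), 1, envir = dist)
  for (i in seq_len(n)) {
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    keys <- ls(dist)
    for (key in keys) {
      p0 <- get(key, envir = dist)
      base <- as.numeric(strsplit(key, ",", fixed = TRUE)[[1]])
      for (j in seq_len(nrow(perms))) {
        s <- base + R[i, perms[j, ]]
        k2 <- paste(s, collapse = ",")
        prev <- if (exists(k2, envir = nxt, inherits = FALSE))
          get(k2, envir = nxt) else 0
        assign(k2, prev + p0, envir = nxt)
      }
    }
    dist <- nxt
  }
  total <- factorial(k)^n
  obs <- sum(colSums(R)^2)
  cnt <- 0
  for (key in ls(dist)) {
    s <- as.numeric(strsplit(key, ",", fixed = TRUE)[[1]])
    if (sum(s^2) >= obs - 1e-9) cnt <- cnt + get(key, envir = dist)
  }
  cnt / total
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, nrow = 0, ncol = k)
  for (pos in seq_len(k)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                 sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, blk)
  }
  out
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Post hoc comparisons between all condition pairs. Zero differences are
#' dropped before testing (signed-rank convention); the exact distribution is
#' used for n <= 25 without ties in the absolute differences, the normal
#' approximation otherwise. Adjusted p = min(1, m * p) with m the number of
#' pairs (3 for three conditions).
#'
#' @param tab N x k numeric matrix as in [friedman_w()].
#' @param alpha significance levels flagged in the output.
#' @return data.frame with one row per pair: pair, statistic, p, p_adjusted,
#'   sig (significance marker "", "*", "**"), n_effective.
#' @export
wilcoxon_pairwise <- function(tab, alpha = c(0.05, 0.01)) {
  tab <- as.matrix(tab)
  k <- ncol(tab)
  labs <- colnames(tab)
  if (is.null(labs)) labs <- paste0("T", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- tab[, pairs[1, j]]; b <- tab[, pairs[2, j]]
    d <- b - a
    d <- d[!is.na(d) & d != 0]
    if (!length(d)) {
      return(data.frame(pair = paste(labs[pairs[1, j]], "-", labs[pairs[2, j]]),
                        statistic = NA_real_, p = 1, p_adjusted = 1,
                        sig = "", n_effective = 0L))
    }
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = exact, correct = !exact))
    data.frame(pair = paste(labs[pairs[1, j]], "-", labs[pairs[2, j]]),
               statistic = unname(wt$statistic), p = wt$p.value,
               p_adjusted = min(1, m * wt$p.value), sig = "",
               n_effective = length(d))
  })
  out <- do.call(rbind, rows)
  out$sig <- ifelse(out$p_adjusted < alpha[2], "**",
                    ifelse(out$p_adjusted < alpha[1], "*", ""))
  out
}

#' Full repeated-measures battery for one variable
#'
#' Shapiro-Wilk screen per condition, Friedman test with Kendall's W, and --
#' when the Friedman test is significant at `gate_alpha` (gatekeeping can be
#' disabled) -- Bonferroni-corrected pairwise Wilcoxon signed-rank tests.
#'
#' @param tab N x k matrix, one column per condition.
#' @param gate_alpha Friedman significance gate for the post hoc tests; NULL
#'   runs the pairwise tests unconditionally.
#' @return list with shapiro (data.frame), friedman (list), pairwise
#'   (data.frame or NULL when gated out).
#' @export
stats_battery <- function(tab, gate_alpha = 0.05) {
  tab <- as.matrix(tab)
  labs <- colnames(tab)
  if (is.null(labs)) labs <- paste0("T", seq_len(ncol(tab)))
  sw <- do.call(rbind, lapply(seq_len(ncol(tab)), function(j) {
    s <- shapiro_screen(tab[, j])
    data.frame(condition = labs[j], W = s[["W"]], p = s[["p"]])
  }))
  fr <- friedman_w(tab)
  pw <- if (is.null(gate_alpha) || (!is.na(fr$p) && fr$p < gate_alpha))
    wilcoxon_pairwise(tab) else NULL
  list(shapiro = sw, friedman = fr, pairwise = pw)
}

#' Endurance-time regression over metric maxima
#'
#' Ordinary least-squares simple regression of endurance time on each
#' metric's per-subject maximum, reporting R^2 and the slope F-test p-value.
#'
#' @param maxima data.frame or matrix, one row per subject, one column per
#'   metric.
#' @param endurance numeric vector of endurance times, s (one per subject).
#' @return data.frame with columns metric, r2, p, slope, n; metrics with a
#'   zero-variance predictor are reported as NA.
#' @export
endurance_regression <- function(maxima, endurance) {
  maxima <- as.data.frame(maxima)
  stopifnot(nrow(maxima) == length(endurance))
  rows <- lapply(names(maxima), function(v) {
    x <- maxima[[v]]
    ok <- !is.na(x) & !is.na(endurance)
    if (sum(ok) < 3 || stats::var(x[ok]) == 0)
      return(data.frame(metric = v, r2 = NA_real_, p = NA_real_,
                        slope = NA_real_, n = sum(ok)))
    fit <- stats::lm(endurance[ok] ~ x[ok])
    sm <- summary(fit)
    pf <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE)
    data.frame(metric = v, r2 = unname(sm$r.squared), p = unname(pf),
               slope = unname(stats::coef(fit)[2]), n = sum(ok))
  })
  do.call(rbind, rows)
}
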