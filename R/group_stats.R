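#' Wilks-lambda MANOVA with Rao's F approximation
#'
#' One-way multivariate analysis of variance comparing group mean vectors of
#' the larval-stage features.  The statistic is Wilks'
#' \eqn{\Lambda = \det(E) / \det(E + H)} with `E`/`H` the within-/
#' between-group sums-of-squares-and-cross-products matrices, converted to
#' an F statistic by Rao's approximation:
#' \deqn{F = \frac{1 - \Lambda^{1/t}}{\Lambda^{1/t}}\cdot\frac{df_2}{df_1}}
#' with \eqn{df_1 = p(k-1)},
#' \eqn{t = \sqrt{(p^2(k-1)^2 - 4) / (p^2 + (k-1)^2 - 5)}} (taken as 1 when
#' the denominator is non-positive), and
#' \eqn{df_2 = t[(n-1) - (p+k)/2] - (p(k-1)-2)/2}.  For `p = 1` this reduces
#' exactly to the classical one-way ANOVA F; the approximation is exact also
#' for `k = 2`.
#'
#' @param X numeric matrix (n x p) of features; rows with any `NA` are
#'   dropped (complete-case analysis).
#' @param groups length-n group labels (2 or more groups, each with more
#'   than p members).
#' @return A list: `lambda`, `F`, `df1`, `df2`, `p_value`, `n`, `k`, `p`.
#' @export
manova_wilks <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  cc <- stats::complete.cases(X) & !is.na(groups)
  X <- X[cc, , drop = FALSE]; groups <- groups[cc]
  k <- length(unique(groups)); n <- nrow(X); p <- ncol(X)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(groups) < p + 1))
    stop("every group needs at least p + 1 = ", p + 1, " members")
  gm <- colMeans(X)
  E <- matrix(0, p, p); H <- matrix(0, p, p)
  for (g in unique(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    mg <- colMeans(Xg)
    E <- E + crossprod(scale(Xg, center = mg, scale = FALSE))
    H <- H + nrow(Xg) * tcrossprod(mg - gm)
  }
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0)
    stop("within-group SSCP matrix is singular; check features for ",
         "collinearity")
  lambda <- detE / det(E + H)
  lambda <- min(max(lambda, 0), 1)
  df1 <- p * (k - 1)
  denom <- p^2 + (k - 1)^2 - 5
  t_r <- if (denom > 0) sqrt((p^2 * (k - 1)^2 - 4) / denom) else 1
  df2 <- t_r * ((n - 1) - (p + k) / 2) - (p * (k - 1) - 2) / 2
  lam_t <- lambda^(1 / t_r)
  Fstat <- if (lam_t == 0) Inf else (1 - lam_t) / lam_t * df2 / df1
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
       p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
       n = n, k = k, p = p)
}

#' Pre-MANOVA assumption battery
#'
#' Runs the standard checks before a MANOVA on small-group field data:
#' * Shapiro--Wilk per variable and group (univariate normality);
#' * Mardia's multivariate skewness and kurtosis per group;
#' * pairwise feature correlations and variance-inflation factors
#'   (multicollinearity; a VIF is `Inf` under perfect collinearity);
#' * Box's M with its chi-square approximation (homogeneity of covariance
#'   matrices);
#' * Brown--Forsythe (median-centered) Levene test per variable
#'   (homogeneity of variances).
#'
#' Cells that cannot be computed for a too-small group are `NA`, never an
#' error.
#'
#' @inheritParams manova_wilks
#' @return A list with elements `shapiro`, `mardia`, `correlations`, `vif`,
#'   `box_m`, `levene`.
#' @export
assumption_battery <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  cc <- stats::complete.cases(X) & !is.na(groups)
  X <- X[cc, , drop = FALSE]; groups <- groups[cc]
  p <- ncol(X)
  vars <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- vars
  gl <- sort(unique(groups))

  shapiro <- do.call(rbind, lapply(gl, function(g) {
    do.call(rbind, lapply(vars, function(v) {
      x <- X[groups == g, v]
      if (length(x) >= 3 && length(unique(x)) > 1) {
        sw <- shapiro.test(x)
        data.frame(group = g, variable = v, W = unname(sw$statistic),
                   p_value = sw$p.value, stringsAsFactors = FALSE)
      } else data.frame(group = g, variable = v, W = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE)
    }))
  }))

  mardia <- do.call(rbind, lapply(gl, function(g) {
    Xg <- X[groups == g, , drop = FALSE]
    n <- nrow(Xg)
    if (n <= p + 1) return(data.frame(
      group = g, skewness = NA_real_, skew_p = NA_real_,
      kurtosis = NA_real_, kurt_p = NA_real_, stringsAsFactors = FALSE))
    S <- cov(Xg) * (n - 1) / n
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si)) return(data.frame(
      group = g, skewness = NA_real_, skew_p = NA_real_,
      kurtosis = NA_real_, kurt_p = NA_real_, stringsAsFactors = FALSE))
    Xc <- scale(Xg, scale = FALSE)
    D <- Xc %*% Si %*% t(Xc)
    b1 <- mean(D^3)
    b2 <- mean(diag(D)^2)
    skew_stat <- n * b1 / 6
    skew_df <- p * (p + 1) * (p + 2) / 6
    kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
    data.frame(group = g, skewness = b1,
               skew_p = pchisq(skew_stat, skew_df, lower.tail = FALSE),
               kurtosis = b2, kurt_p = 2 * pnorm(-abs(kurt_z)),
               stringsAsFactors = FALSE)
  }))

  R <- cor(X)
  vif <- tryCatch({
    Ri <- solve(R)
    setNames(diag(Ri), vars)
  }, error = function(e) setNames(rep(Inf, p), vars))
  if (any(!is.finite(vif)) || any(vif > 1e12))
    vif[!is.finite(vif) | vif > 1e12] <- Inf

  box_m <- box_m_test(X, groups)
  levene <- do.call(rbind, lapply(vars, function(v)
    cbind(variable = v, levene_bf(X[, v], groups))))

  list(shapiro = shapiro, mardia = mardia, correlations = R, vif = vif,
       box_m = box_m, levene = levene)
}

# Box's M statistic with the chi-square approximation
box_m_test <- function(X, groups) {
  gl <- unique(groups)
  k <- length(gl); p <- ncol(X); n <- nrow(X)
  ni <- vapply(gl, function(g) sum(groups == g), 0L)
  if (any(ni <= p))
    return(list(M = NA_real_, chi_square = NA_real_, df = NA_real_,
                p_value = NA_real_))
  Sp <- matrix(0, p, p)
  lds <- numeric(k)
  for (j in seq_len(k)) {
    Sj <- cov(X[groups == gl[j], , drop = FALSE])
    Sp <- Sp + (ni[j] - 1) * Sj
    d <- determinant(Sj, logarithm = TRUE)
    if (d$sign <= 0) return(list(M = NA_real_, chi_square = NA_real_,
                                 df = NA_real_, p_value = NA_real_))
    lds[j] <- as.numeric(d$modulus)
  }
  Sp <- Sp / (n - k)
  dp <- determinant(Sp, logarithm = TRUE)
  M <- (n - k) * as.numeric(dp$modulus) - sum((ni - 1) * lds)
  c1 <- (sum(1 / (ni - 1)) - 1 / (n - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi2 <- M * (1 - c1)
  df <- p * (p + 1) * (k - 1) / 2
  list(M = M, chi_square = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE))
}

# Brown-Forsythe variant of Levene's test (median-centered deviations)
levene_bf <- function(x, groups) {
  g <- factor(groups)
  z <- abs(x - stats::ave(x, g, FUN = median))
  fit <- stats::anova(lm(z ~ g))
  data.frame(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
             p_value = fit$`Pr(>F)`[1], stringsAsFactors = FALSE)
}

#' Kruskal--Wallis rank test with mid-rank tie correction
#'
#' \deqn{H = \frac{\frac{12}{N(N+1)}\sum_i R_i^2/n_i - 3(N+1)}
#'   {1 - \sum_j (t_j^3 - t_j)/(N^3 - N)}}
#' with mid-ranks for ties (`t_j` the tie-group sizes); `df = k - 1` and the
#' p-value from the chi-square distribution.  All-identical values give
#' `H = 0, p = 1` (not an error).
#'
#' @param x numeric vector of observations.
#' @param groups group labels (2 or more nonempty groups).
#' @return A list: `H`, `df`, `p_value`, `tie_correction`.
#' @export
kruskal_wallis <- function(x, groups) {
  ok <- !is.na(x) & !is.na(groups)
  x <- x[ok]; groups <- as.character(groups)[ok]
  k <- length(unique(groups))
  if (k < 2) stop("need at least 2 nonempty groups")
  N <- length(x)
  r <- rank(x)
  Rsum <- tapply(r, groups, sum)
  ni <- tapply(r, groups, length)
  H0 <- 12 / (N * (N + 1)) * sum(Rsum^2 / ni) - 3 * (N + 1)
  tj <- table(x)
  C <- 1 - sum(tj^3 - tj) / (N^3 - N)
  if (C <= 0) return(list(H = 0, df = as.integer(k - 1), p_value = 1,
                          tie_correction = C))   # all values identical
  H <- H0 / C
  H <- max(H, 0)
  list(H = H, df = as.integer(k - 1),
       p_value = pchisq(H, k - 1, lower.tail = FALSE),
       tie_correction = C)
}

#' Games--Howell pairwise comparisons
#'
#' Post-hoc pairwise tests that assume neither equal variances nor equal
#' group sizes.  For each pair (i, j):
#' \deqn{q = \frac{|\bar x_i - \bar x_j|}
#'   {\sqrt{(s_i^2/n_i + s_j^2/n_j)/2}}}
#' with the Welch--Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(s_i^2/n_i + s_j^2/n_j)^2}
#'   {(s_i^2/n_i)^2/(n_i-1) + (s_j^2/n_j)^2/(n_j-1)}}
#' and the adjusted p-value \eqn{P(Q_{k,\nu} \ge q)} from the studentized
#' range distribution over all `k` groups.  With `k = 2`,
#' \eqn{Q_{2,\nu} = \sqrt2\,|t|} and the adjusted p equals the two-sided
#' Welch t-test p.
#'
#' Degenerate inputs: identical groups give `q = 0, p = 1`; unequal means
#' with both variances zero give `p = 0` and are flagged `degenerate`.
#'
#' @param x numeric vector of observations.
#' @param groups group labels; every group needs `n >= 2`.
#' @return Data frame with one row per unordered pair: `group1`, `group2`,
#'   `mean_diff`, `se`, `df`, `q`, `p_adj`, `degenerate`.
#' @export
games_howell <- function(x, groups) {
  ok <- !is.na(x) & !is.na(groups)
  x <- x[ok]; groups <- as.character(groups)[ok]
  gl <- sort(unique(groups))
  k <- length(gl)
  if (k < 2) stop("need at least 2 groups")
  ni <- vapply(gl, function(g) sum(groups == g), 0L)
  if (any(ni < 2)) stop("every group needs at least 2 observations")
  mi <- vapply(gl, function(g) mean(x[groups == g]), 0)
  vi <- vapply(gl, function(g) var(x[groups == g]), 0)
  rows <- list()
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    va <- vi[a] / ni[a]; vb <- vi[b] / ni[b]
    diff <- mi[a] - mi[b]
    se <- sqrt((va + vb) / 2)
    degenerate <- FALSE
    if (va + vb == 0) {
      if (abs(diff) < 1e-15) { q <- 0; nu <- ni[a] + ni[b] - 2; p <- 1 }
      else { q <- Inf; nu <- ni[a] + ni[b] - 2; p <- 0; degenerate <- TRUE }
    } else {
      q <- abs(diff) / se
      nu <- (va + vb)^2 / (va^2 / (ni[a] - 1) + vb^2 / (ni[b] - 1))
      p <- ptukey(q, nmeans = k, df = nu, lower.tail = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = gl[a], group2 = gl[b], mean_diff = diff, se = se, df = nu,
      q = q, p_adj = p, degenerate = degenerate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of first-differenced yearly series
#'
#' Correlates year-to-year *changes* of two annual series (e.g. recruitment
#' estimates of two stocks) rather than their levels, removing shared
#' trends.  Both series are first-differenced over their overlapping
#' consecutive years, then the Pearson correlation with the usual two-sided
#' t-transform p-value (n − 2 df) is computed.
#'
#' @param series_a,series_b data frames with columns `year` and `value`
#'   (or named numeric vectors with years as names).
#' @return A list: `r`, `p_value`, `n` (number of differenced pairs).
#'   A constant differenced series yields `r = NA` with `degenerate = TRUE`.
#' @export
differenced_pearson <- function(series_a, series_b) {
  as_df <- function(s) {
    if (is.data.frame(s)) data.frame(year = as.integer(s$year),
                                     value = as.numeric(s$value))
    else data.frame(year = as.integer(names(s)), value = as.numeric(s))
  }
  a <- as_df(series_a); b <- as_df(series_b)
  years <- intersect(a$year, b$year)
  years <- sort(years)
  # consecutive overlapping year pairs
  pairs <- years[which(diff(years) == 1)]
  if (length(pairs) < 3)
    stop("need at least 3 overlapping consecutive-year pairs")
  da <- a$value[match(pairs + 1L, a$year)] - a$value[match(pairs, a$year)]
  db <- b$value[match(pairs + 1L, b$year)] - b$value[match(pairs, b$year)]
  if (sd(da) == 0 || sd(db) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(da),
                degenerate = TRUE))
  ct <- cor.test(da, db, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(da),
       degenerate = FALSE)
}

#' Full group-statistics report
#'
#' Bundles the whole statistical battery on the larval features of locals,
#' nonlocals and Pacific-offshores (complete cases; fish lacking the
#' juvenile measurement or increments are excluded, as in the learning set,
#' except Pacific-offshores which enter on larval features alone when
#' complete): MANOVA, assumptions, per-variable Kruskal--Wallis and
#' Games--Howell tables.
#'
#' @param stage_values labeled `stage_values`.
#' @return A list of class `group_stats_report` with elements `manova`,
#'   `assumptions`, `kruskal_wallis` (per variable), `games_howell`
#'   (per variable), `n_by_group`.
#' @export
group_stats_report <- function(stage_values) {
  sv <- stage_values
  keep <- (sv$label %in% c("local", "nonlocal") &
             !is.na(sv$juvenile_d18O) & isTRUE_vec(sv$has_increments)) |
    sv$label == "pacific_offshore"
  sv <- sv[keep, , drop = FALSE]
  X <- lda_features(sv)
  cc <- stats::complete.cases(X)
  sv <- sv[cc, , drop = FALSE]; X <- X[cc, , drop = FALSE]
  g <- sv$label
  kw <- lapply(colnames(X), function(v) kruskal_wallis(X[, v], g))
  names(kw) <- colnames(X)
  gh <- lapply(colnames(X), function(v) games_howell(X[, v], g))
  names(gh) <- colnames(X)
  structure(list(manova = manova_wilks(X, g),
                 assumptions = assumption_battery(X, g),
                 kruskal_wallis = kw, games_howell = gh,
                 n_by_group = table(g)),
            class = "group_stats_report")
}

#' @export
print.group_stats_report <- function(x, ...) {
  m <- x$manova
  cat(sprintf("MANOVA (Wilks): Lambda = %.4f, F(%d, %.1f) = %.2f, p = %.3g\n",
              m$lambda, m$df1, m$df2, m$F, m$p_value))
  for (v in names(x$kruskal_wallis)) {
    k <- x$kruskal_wallis[[v]]
    cat(sprintf("  KW %-20s H = %.2f, df = %d, p = %.3g\n",
                v, k$H, k$df, k$p_value))
  }
  invisible(x)
}
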