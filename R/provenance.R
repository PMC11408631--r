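#' Juvenile delta-18O threshold separating locals from nonlocals
#'
#' For one year-class, the threshold is the highest juvenile-stage otolith
#' delta-18O observed in the reference set: age-0 fish captured in the
#' SJ-ECS coastal regions plus age-1 fish from West Kyushu.  Fish at or
#' below the threshold grew under the seasonal-warming (ontogenetically
#' decreasing delta-18O) regime of the sampled coastal system and are
#' "locals"; fish above it are "nonlocals".  Pacific-offshore fish never
#' enter the reference set.
#'
#' @param stage_values a `stage_values` data frame
#'   (see [extract_stage_values()]).
#' @param year_class integer year-class.
#' @return A one-row data frame `year_class`, `threshold_permil`,
#'   `n_reference`.
#' @export
compute_threshold <- function(stage_values, year_class) {
  sv <- stage_values
  ref <- sv$year_class == year_class & !is.na(sv$juvenile_d18O) &
    ((sv$age == 0L & sv$region %in% SJECS_REGIONS) |
       (sv$age == 1L & sv$region == "WestKyushu"))
  if (!any(ref))
    stop("no reference fish with a juvenile delta-18O for year-class ",
         year_class)
  data.frame(year_class = year_class,
             threshold_permil = max(sv$juvenile_d18O[ref]),
             n_reference = sum(ref))
}

#' @rdname compute_threshold
#' @description `compute_thresholds()` computes the rule for every
#'   year-class present among SJ-ECS fish.
#' @export
compute_thresholds <- function(stage_values) {
  ycs <- sort(unique(stage_values$year_class[
    stage_values$region %in% SJECS_REGIONS]))
  do.call(rbind, lapply(ycs, function(y) compute_threshold(stage_values, y)))
}

#' Label fish by the juvenile delta-18O threshold rule
#'
#' Per year-class: SJ-ECS fish with a juvenile delta-18O lower than or equal
#' to the threshold are `local`; higher, `nonlocal`.  Age-0 SJ-ECS fish
#' without the juvenile measurement are `local` (they were captured inside
#' the system during the juvenile stage).  Age-1 SJ-ECS fish without the
#' measurement stay `unclassified` for the discriminant step.
#' Pacific-offshore fish are `pacific_offshore` by definition.  The
#' operation is idempotent and order-independent.
#'
#' @param stage_values a `stage_values` data frame.
#' @param rules threshold table from [compute_thresholds()].
#' @return `stage_values` with `label` and `label_source`
#'   (`threshold` / `fixed` / `NA`) filled.
#' @export
assign_by_threshold <- function(stage_values, rules) {
  sv <- stage_values
  sjecs <- sv$region %in% SJECS_REGIONS
  need <- unique(sv$year_class[sjecs])
  missing_rule <- setdiff(need, rules$year_class)
  if (length(missing_rule))
    stop("no threshold rule for year-class ",
         paste(missing_rule, collapse = ", "))
  thr <- rules$threshold_permil[match(sv$year_class, rules$year_class)]
  sv$label[!sjecs] <- "pacific_offshore"
  sv$label_source[!sjecs] <- "fixed"
  has_j <- sjecs & !is.na(sv$juvenile_d18O)
  sv$label[has_j] <- ifelse(sv$juvenile_d18O[has_j] <= thr[has_j],
                            "local", "nonlocal")
  sv$label_source[has_j] <- "threshold"
  no_j0 <- sjecs & is.na(sv$juvenile_d18O) & sv$age == 0L
  sv$label[no_j0] <- "local"
  sv$label_source[no_j0] <- "threshold"
  no_j1 <- sjecs & is.na(sv$juvenile_d18O) & sv$age == 1L
  sv$label[no_j1] <- "unclassified"
  sv$label_source[no_j1] <- NA_character_
  sv
}

# learning-set rows: threshold-labeled locals/nonlocals with complete
# features; fish lacking the juvenile measurement or the increment reading
# are excluded from learning
lda_features <- function(stage_values) {
  X <- as.matrix(stage_values[, c("larval_d18O", "larval_d13C",
                                  "radius_at_60dph_um")])
  colnames(X) <- c("larval_d18O", "larval_d13C", "radius_at_60dph_um")
  X
}

learning_set <- function(stage_values) {
  sv <- stage_values
  keep <- sv$label %in% c("local", "nonlocal") &
    !is.na(sv$juvenile_d18O) & isTRUE_vec(sv$has_increments) &
    !is.na(sv$larval_d18O) & !is.na(sv$larval_d13C) &
    !is.na(sv$radius_at_60dph_um)
  sv[keep, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Fit a two-class linear discriminant on larval otolith features
#'
#' Classic pooled-covariance (homoscedastic Gaussian) linear discriminant on
#' the three larval-stage features — larval delta-18O, larval delta-13C and
#' otolith radius at 60 dph — of threshold-labeled locals and nonlocals of
#' all year-classes.  Priors default to the training class frequencies.
#' The class score is the usual linear form
#' \deqn{\ln\pi_c + \mu_c^\top\Sigma^{-1}x - \tfrac12\mu_c^\top\Sigma^{-1}\mu_c}
#' and a fish is assigned to the class with the larger score, ties going to
#' `local` for determinism.
#'
#' @param stage_values labeled `stage_values`; only complete-feature
#'   locals/nonlocals with a juvenile measurement and increment reading
#'   enter the learning set.
#' @param priors optional named numeric `c(local = , nonlocal = )` summing
#'   to 1; default: class frequencies.
#' @return An object of class `otl_lda` with elements `means`, `cov`
#'   (pooled), `priors`, `coef`, `intercept`, `classes`, `n`.
#' @export
fit_lda <- function(stage_values, priors = NULL) {
  train <- learning_set(stage_values)
  cls <- c("local", "nonlocal")
  n_c <- table(factor(train$label, levels = cls))
  if (any(n_c < 2))
    stop("need at least 2 learning fish per class; got ",
         paste(n_c, collapse = "/"))
  X <- lda_features(train)
  p <- ncol(X)
  means <- t(vapply(cls, function(cl) colMeans(X[train$label == cl, ,
                                                 drop = FALSE]),
                    numeric(p)))
  Sw <- matrix(0, p, p)
  for (cl in cls) {
    Xc <- scale(X[train$label == cl, , drop = FALSE], center = means[cl, ],
                scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(X) - length(cls))
  Sinv <- tryCatch(solve(Sw), error = function(e)
    stop("pooled within-class covariance is singular; check the features ",
         "for collinearity or constant columns"))
  if (is.null(priors)) priors <- as.numeric(n_c) / sum(n_c)
  else priors <- as.numeric(priors[cls])
  stopifnot(abs(sum(priors) - 1) < 1e-8)
  coefs <- Sinv %*% t(means)                    # p x k
  icpt <- log(priors) - 0.5 * diag(means %*% Sinv %*% t(means))
  structure(list(means = means, cov = Sw, priors = setNames(priors, cls),
                 coef = coefs, intercept = setNames(icpt, cls),
                 classes = cls, n = as.integer(n_c)),
            class = "otl_lda")
}

#' @export
print.otl_lda <- function(x, ...) {
  cat("Linear discriminant (pooled covariance), classes:",
      paste(sprintf("%s (n=%d, prior=%.3f)", x$classes, x$n, x$priors),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict class scores and labels from a fitted discriminant
#'
#' @param object an `otl_lda` model.
#' @param newdata a `stage_values` data frame or a numeric matrix with the
#'   three feature columns.
#' @param ... unused.
#' @return A data frame with `score_local`, `score_nonlocal`, `class`.
#'   Exact score ties resolve to `local`.
#' @export
predict.otl_lda <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else lda_features(newdata)
  S <- X %*% object$coef
  S <- sweep(S, 2, object$intercept, "+")
  cls <- object$classes[ifelse(S[, 1] >= S[, 2], 1L, 2L)]  # tie -> local
  data.frame(score_local = S[, 1], score_nonlocal = S[, 2], class = cls,
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validation of the discriminant
#'
#' Refits the model n times, each time excluding one learning fish
#' (re-deriving priors from the fold's training labels), and reports the
#' overall fraction correct together with per-predicted-class counts: of the
#' fish *predicted* local, how many truly were, and likewise for nonlocal.
#' Folds whose removal leaves a class with fewer than two members are
#' skipped with a warning.
#'
#' @param stage_values labeled `stage_values`.
#' @return A list with `n`, `n_correct`, `accuracy`, and `by_predicted`
#'   (data frame: `predicted`, `n_predicted`, `n_correct`, `precision`).
#' @export
loocv_lda <- function(stage_values) {
  train <- learning_set(stage_values)
  n <- nrow(train)
  pred <- rep(NA_character_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    fold <- train[-i, , drop = FALSE]
    if (any(table(factor(fold$label,
                         levels = c("local", "nonlocal"))) < 2)) {
      skipped <- skipped + 1L
      next
    }
    m <- fit_lda(fold)
    pred[i] <- predict(m, train[i, , drop = FALSE])$class
  }
  if (skipped) warning(skipped, " LOOCV fold(s) skipped: a class would ",
                       "have fewer than two training members")
  ok <- !is.na(pred)
  correct <- pred[ok] == train$label[ok]
  by_pred <- do.call(rbind, lapply(c("local", "nonlocal"), function(cl) {
    sel <- ok & pred == cl
    sel[is.na(sel)] <- FALSE
    data.frame(predicted = cl, n_predicted = sum(sel),
               n_correct = sum(train$label[sel] == cl),
               precision = if (sum(sel)) mean(train$label[sel] == cl) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(n = sum(ok), n_correct = sum(correct),
       accuracy = mean(correct), by_predicted = by_pred)
}

#' Classify threshold-unclassified fish with the discriminant
#'
#' Applies a fitted discriminant to every `unclassified` fish with complete
#' features; threshold-derived labels are never overwritten.  Fish with a
#' missing feature are skipped with a warning and stay unclassified.
#'
#' @param model an `otl_lda`.
#' @param stage_values labeled `stage_values`.
#' @return `stage_values` with discriminant labels filled
#'   (`label_source = "lda"`) and score columns `lda_score_local`,
#'   `lda_score_nonlocal` for the relabeled fish.
#' @export
classify_unlabeled <- function(model, stage_values) {
  sv <- stage_values
  if (!"lda_score_local" %in% names(sv)) {
    sv$lda_score_local <- NA_real_
    sv$lda_score_nonlocal <- NA_real_
  }
  cand <- sv$label == "unclassified"
  complete <- !is.na(sv$larval_d18O) & !is.na(sv$larval_d13C) &
    !is.na(sv$radius_at_60dph_um)
  if (any(cand & !complete))
    warning(sum(cand & !complete), " unclassified fish lack a feature and ",
            "were skipped")
  use <- cand & complete
  if (any(use)) {
    pr <- predict(model, sv[use, , drop = FALSE])
    sv$label[use] <- pr$class
    sv$label_source[use] <- "lda"
    sv$lda_score_local[use] <- pr$score_local
    sv$lda_score_nonlocal[use] <- pr$score_nonlocal
  }
  sv
}

#' Tabulate local/nonlocal proportions by grouping keys
#'
#' Per group: counts of locals, nonlocals and still-unclassified fish,
#' the percentage of nonlocals among classified fish
#' (`100 * n_nonlocal / (n_local + n_nonlocal)`), and the count of labels
#' that came from the discriminant rather than the threshold (the analogue
#' of the shaded bars in seasonal-proportion figures).  Pacific-offshore
#' fish are excluded.
#'
#' @param stage_values labeled `stage_values`.
#' @param by character subset of `c("region", "year_class", "month")`;
#'   `month` is the capture month and requires a `capture_month` column
#'   (added by [run_pipeline()] / [generate_cohort()] joins) or is derived
#'   from `capture_date` when present.
#' @return A data frame with one row per group; groups with no classified
#'   fish get `pct_nonlocal = NA` (flagged undefined).
#' @export
proportions_by_group <- function(stage_values,
                                 by = c("region", "year_class")) {
  sv <- stage_values[stage_values$label != "pacific_offshore", , drop = FALSE]
  if ("month" %in% by && !"capture_month" %in% names(sv)) {
    if ("capture_date" %in% names(sv))
      sv$capture_month <- as.integer(format(sv$capture_date, "%m"))
    else stop("grouping by month needs a capture_month or capture_date column")
  }
  keycols <- ifelse(by == "month", "capture_month", by)
  if (!nrow(sv)) {
    out <- data.frame(matrix(ncol = length(keycols), nrow = 0))
    names(out) <- keycols
    out$n_local <- integer(); out$n_nonlocal <- integer()
    out$n_unclassified <- integer(); out$n_lda_labeled <- integer()
    out$pct_nonlocal <- numeric()
    return(out)
  }
  key <- interaction(sv[, keycols, drop = FALSE], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(kv) {
    gi <- sv[key == kv, , drop = FALSE]
    n_l <- sum(gi$label == "local")
    n_n <- sum(gi$label == "nonlocal")
    cbind(gi[1, keycols, drop = FALSE],
          data.frame(n_local = n_l, n_nonlocal = n_n,
                     n_unclassified = sum(gi$label == "unclassified"),
                     n_lda_labeled = sum(gi$label_source %in% "lda"),
                     pct_nonlocal = if (n_l + n_n > 0)
                       100 * n_n / (n_l + n_n) else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[, keycols, drop = FALSE]), , drop = FALSE]
}
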