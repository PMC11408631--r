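test_that("threshold is the maximum juvenile d18O of the reference set", {
  sv <- rbind(
    make_sv(paste0("R", 1:4), "WestKyushu", 0, 2015,
            larval_d18O = -0.7, juvenile_d18O = c(-1.5, -0.9, -1.7, -1.2)),
    make_sv("P1", "PacificOffshore", 0, 2015, larval_d18O = -0.1,
            juvenile_d18O = 0.5, label = "pacific_offshore",
            label_source = "fixed"))
  rule <- compute_threshold(sv, 2015)
  expect_equal(rule$threshold_permil, -0.9)   # Pacific fish never enter
  expect_identical(rule$n_reference, 4L)
  single <- compute_threshold(sv[1, , drop = FALSE], 2015)
  expect_equal(single$threshold_permil, -1.5)
  expect_error(compute_threshold(sv, 1999), "1999")
})

test_that("thresholds are monotone in the reference set", {
  set.seed(5)
  base <- make_sv(paste0("R", 1:6), "OkiIslands", 0, 2014,
                  larval_d18O = -0.7,
                  juvenile_d18O = rnorm(6, -1.5, 0.4))
  sub <- compute_threshold(base[1:3, , drop = FALSE], 2014)
  sup <- compute_threshold(base, 2014)
  expect_gte(sup$threshold_permil, sub$threshold_permil)
  # raising any reference value can only move the threshold up
  bumped <- base
  bumped$juvenile_d18O[2] <- bumped$juvenile_d18O[2] + 1
  expect_gte(compute_threshold(bumped, 2014)$threshold_permil,
             sup$threshold_permil)
})

test_that("threshold assignment follows the lower-or-equal rule", {
  ref <- make_sv(paste0("R", 1:3), "WestKyushu", 0, 2015,
                 larval_d18O = -0.7, juvenile_d18O = c(-1.5, -1.0, -1.2))
  rules <- compute_thresholds(ref)
  expect_equal(rules$threshold_permil, -1.0)
  test_fish <- rbind(
    make_sv("T1", "OkiIslands", 1, 2015, -0.5, juvenile_d18O = -1.0),
    make_sv("T2", "OkiIslands", 1, 2015, -0.5, juvenile_d18O = -0.99),
    make_sv("T3", "OkiIslands", 0, 2015, -0.5),                # no juvenile
    make_sv("T4", "NotoPeninsula", 1, 2015, -0.5),             # no juvenile
    make_sv("P1", "PacificOffshore", 0, 2015, -0.1, juvenile_d18O = 0.2))
  out <- assign_by_threshold(rbind(ref, test_fish), rules)
  lab <- setNames(out$label, out$fish_id)
  expect_identical(unname(lab["T1"]), "local")      # exactly at threshold
  expect_identical(unname(lab["T2"]), "nonlocal")   # just above
  expect_identical(unname(lab["T3"]), "local")      # age-0 without juvenile
  expect_identical(unname(lab["T4"]), "unclassified")
  expect_identical(unname(lab["P1"]), "pacific_offshore")
  # idempotent and order-independent
  again <- assign_by_threshold(out, rules)
  expect_identical(again$label, out$label)
  perm <- sample(nrow(out))
  out2 <- assign_by_threshold(rbind(ref, test_fish)[perm, ], rules)
  expect_identical(out2$label[order(out2$fish_id)],
                   out$label[order(out$fish_id)])
  expect_error(assign_by_threshold(
    make_sv("X", "OkiIslands", 1, 1998, -0.5), rules), "1998")
})

test_that("the discriminant separates well-separated spherical classes", {
  set.seed(7)
  a <- make_sv(paste0("A", 1:20), "OkiIslands", 1, 2015,
               rnorm(20, 0, 0.5), rnorm(20, 0, 0.5),
               juvenile_d18O = -1.5, radius = rnorm(20, 0, 0.5),
               label = "local", label_source = "threshold")
  b <- make_sv(paste0("B", 1:20), "OkiIslands", 1, 2015,
               rnorm(20, 10, 0.5), rnorm(20, 10, 0.5),
               juvenile_d18O = -0.2, radius = rnorm(20, 10, 0.5),
               label = "nonlocal", label_source = "threshold")
  m <- fit_lda(rbind(a, b))
  pr <- predict(m, matrix(c(1, 1, 1), 1, 3,
                          dimnames = list(NULL, colnames(m$means))))
  expect_identical(pr$class, "local")
  expect_gt(pr$score_local, pr$score_nonlocal)
})

test_that("with identical class means the priors decide", {
  set.seed(8)
  X <- cbind(rnorm(40), rnorm(40), rnorm(40))
  sv <- make_sv(sprintf("F%02d", 1:40), "OkiIslands", 1, 2015,
                X[, 1], X[, 2], juvenile_d18O = -1, radius = X[, 3],
                label = rep(c("local", "nonlocal"), c(30, 10)),
                label_source = "threshold")
  # same means by construction: mirror the feature rows across classes
  sv$larval_d18O <- rep(X[1:10, 1], 4)
  sv$larval_d13C <- rep(X[1:10, 2], 4)
  sv$radius_at_60dph_um <- rep(X[1:10, 3], 4)
  m <- fit_lda(sv)
  pr <- predict(m, sv)
  expect_true(all(pr$class == "local"))  # majority prior wins everywhere
})

test_that("the discriminant matches MASS::lda on random datasets", {
  skip_if_not_installed("MASS")
  set.seed(13)
  agree <- 0L; total <- 0L
  for (rep in 1:10) {
    n1 <- sample(15:30, 1); n2 <- sample(15:30, 1)
    sv <- rbind(
      make_sv(sprintf("a%02d", 1:n1), "OkiIslands", 1, 2015,
              rnorm(n1, -0.7, 0.4), rnorm(n1, -6.2, 0.4),
              juvenile_d18O = -1.5, radius = rnorm(n1, 300, 30),
              label = "local", label_source = "threshold"),
      make_sv(sprintf("b%02d", 1:n2), "OkiIslands", 1, 2015,
              rnorm(n2, -0.4, 0.3), rnorm(n2, -6.1, 0.4),
              juvenile_d18O = -0.2, radius = rnorm(n2, 340, 30),
              label = "nonlocal", label_source = "threshold"))
    m <- fit_lda(sv)
    X <- as.matrix(sv[, c("larval_d18O", "larval_d13C",
                          "radius_at_60dph_um")])
    ref <- MASS::lda(X, grouping = factor(sv$label,
                                          c("local", "nonlocal")))
    ours <- predict(m, sv)$class
    theirs <- as.character(predict(ref, X)$class)
    agree <- agree + sum(ours == theirs); total <- total + length(ours)
  }
  expect_gte(agree / total, 0.99)
})

test_that("LOOCV is perfect on separated classes and chance on noise", {
  set.seed(17)
  sep <- rbind(
    make_sv(paste0("A", 1:15), "OkiIslands", 1, 2015, rnorm(15, 0, 0.3),
            rnorm(15, 0, 0.3), juvenile_d18O = -1.5,
            radius = rnorm(15, 0, 0.3), label = "local",
            label_source = "threshold"),
    make_sv(paste0("B", 1:15), "OkiIslands", 1, 2015, rnorm(15, 8, 0.3),
            rnorm(15, 8, 0.3), juvenile_d18O = -0.2,
            radius = rnorm(15, 8, 0.3), label = "nonlocal",
            label_source = "threshold"))
  cv <- loocv_lda(sep)
  expect_equal(cv$accuracy, 1.0)
  expect_identical(sum(cv$by_predicted$n_predicted), cv$n)
  # labels at random on identically distributed features: chance level
  noise <- make_sv(sprintf("N%03d", 1:200), "OkiIslands", 1, 2015,
                   rnorm(200), rnorm(200), juvenile_d18O = -1,
                   radius = rnorm(200),
                   label = sample(rep(c("local", "nonlocal"), 100)),
                   label_source = "threshold")
  cvn <- loocv_lda(noise)
  expect_identical(sum(cvn$by_predicted$n_predicted), cvn$n)
  # binomial band around 0.5 at n = 200 (about 4.3 sigma)
  expect_gt(cvn$accuracy, 0.35)
  expect_lt(cvn$accuracy, 0.65)
})

test_that("classify_unlabeled fills only unclassified complete-feature fish", {
  sv <- random_labeled_sv(seed = 19)
  m <- fit_lda(sv)
  un <- rbind(
    make_sv("U1", "OkiIslands", 1, 2015, -0.8, -6.2, radius = 290),
    make_sv("U2", "NotoPeninsula", 1, 2015, -0.25, -6.0, radius = 380),
    make_sv("U3", "NotoPeninsula", 1, 2015, -0.5, -6.0,
            radius = NA_real_))
  expect_warning(out <- classify_unlabeled(m, rbind(sv, un)),
                 "lack a feature")
  lab <- setNames(out$label, out$fish_id)
  expect_identical(unname(lab["U1"]), "local")
  expect_identical(unname(lab["U2"]), "nonlocal")
  expect_identical(unname(lab["U3"]), "unclassified")
  expect_identical(out$label_source[out$fish_id == "U1"], "lda")
  # threshold labels never overwritten
  expect_identical(out$label[out$fish_id %in% sv$fish_id], sv$label)
  # classifying the learning set reproduces fit-time predictions
  again <- suppressWarnings(classify_unlabeled(m, out))
  expect_identical(again$label, out$label)
  relabeled <- sum(out$label_source %in% "lda")
  expect_identical(relabeled, 2L)
})

test_that("proportion tables reproduce count arithmetic and flag gaps", {
  sv <- rbind(
    make_sv(paste0("F", 1:5), "OkiIslands", 1, 2015, -0.5,
            label = c("nonlocal", rep("local", 4)),
            label_source = "threshold"),
    make_sv(paste0("M", 1:13), "NotoPeninsula", 1, 2015, -0.3,
            label = "nonlocal", label_source = c("threshold", "lda")[
              c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2)]),
    make_sv("E1", "WestKyushu", 1, 2015, -0.6, label = "unclassified"),
    make_sv("P1", "PacificOffshore", 0, 2015, -0.1,
            label = "pacific_offshore", label_source = "fixed"))
  pr <- proportions_by_group(sv, by = "region")
  oki <- pr[pr$region == "OkiIslands", ]
  expect_equal(oki$pct_nonlocal, 20)      # one in 5
  noto <- pr[pr$region == "NotoPeninsula", ]
  expect_equal(noto$pct_nonlocal, 100)    # 13 in 13
  expect_identical(noto$n_lda_labeled, 7L)
  wk <- pr[pr$region == "WestKyushu", ]
  expect_true(is.na(wk$pct_nonlocal))     # no classified fish: undefined
  expect_identical(wk$n_unclassified, 1L)
  expect_false("PacificOffshore" %in% pr$region)
})
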