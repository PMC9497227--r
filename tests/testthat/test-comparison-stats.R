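# Difference scores, pattern correlations, mixed ANOVA, ranking.

mkSummary <- function(values, rois = paste0("r", seq_along(values))) {
  data.frame(roi = rois, value = values)
}

test_that("difference scores subtract per ROI with the right means", {
  self <- mkSummary(c(3, 4))
  alt <- mkSummary(c(2, 5))
  d <- differenceScores(self, alt)
  expect_equal(sort(d$differences$diff), c(-1, 1))
  expect_equal(d$mean, 0)
  expect_equal(differenceScores(self, self)$differences$diff, c(0, 0))
  expect_error(differenceScores(self, mkSummary(c(1, 2), c("a", "b"))),
               "ROI sets differ")
})

test_that("difference score means match a brute-force recomputation", {
  set.seed(31)
  self <- data.frame(roi = rep(paste0("r", 1:6), 2),
                     stim_class = rep(c("faces", "toys"), each = 6),
                     value = rnorm(12))
  alt <- self
  alt$value <- rnorm(12)
  d <- differenceScores(self, alt)
  merged <- merge(self, alt, by = c("roi", "stim_class"))
  expect_equal(d$mean, mean(merged$value.x - merged$value.y),
               tolerance = 1e-12)
  expect_equal(unname(d$byClass["faces"]),
               mean(merged$value.x[merged$stim_class == "faces"] -
                      merged$value.y[merged$stim_class == "faces"]),
               tolerance = 1e-12)
})

test_that("pattern correlation behaves like Pearson's r", {
  self <- mkSummary(c(1, 2, 3))
  expect_equal(headModelCorrelation(self, mkSummary(2 * c(1, 2, 3) + 1)), 1)
  expect_equal(headModelCorrelation(self, mkSummary(-c(1, 2, 3))), -1)
  r <- headModelCorrelation(self, mkSummary(c(1, 3, 2)))
  expect_equal(r, 0.5)   # textbook value for (1,2,3) vs (1,3,2)
  expect_true(is.na(headModelCorrelation(self, mkSummary(c(2, 2, 2)))))
  expect_true(is.na(headModelCorrelation(mkSummary(c(1, 2)),
                                         mkSummary(c(3, 4)))))
})

test_that("faces/toys concatenation doubles the pair count", {
  set.seed(8)
  self <- data.frame(roi = rep(paste0("r", 1:5), 2),
                     stim_class = rep(c("faces", "toys"), each = 5),
                     value = rnorm(10))
  alt <- self
  alt$value <- self$value + rnorm(10, sd = 0.2)
  r36 <- headModelCorrelation(self, alt, pool = "concatenate")
  r18 <- headModelCorrelation(self, alt, pool = "roi_only")
  m <- merge(self, alt, by = c("roi", "stim_class"))
  expect_equal(r36, cor(m$value.x, m$value.y), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r36, r18)))
})

test_that("the printed design degrees of freedom are reproduced exactly", {
  set.seed(1)
  d <- expand.grid(subject = 1:19, head_model = paste0("hm", 1:6),
                   roi = paste0("roi", 1:18),
                   stim_class = c("faces", "toys"))
  d$group <- ifelse(as.integer(d$subject) <= 8, "ASIB", "FXS")
  d$value <- rnorm(nrow(d))
  a <- mixedAnova(d, "value", "subject", between = "group",
                  within = c("head_model", "stim_class", "roi"))
  df <- function(eff) unlist(a[a$effect == eff, c("df1", "df2")])
  expect_equal(unname(df("head_model")), c(5, 85))
  expect_equal(unname(df("head_model x stim_class")), c(5, 85))
  expect_equal(unname(df("head_model x roi")), c(85, 1445))
  expect_equal(unname(df("group x head_model x roi")), c(85, 1445))
  expect_true(all(a$F >= 0))
})

test_that("a two-level within factor's F is the squared paired t", {
  set.seed(2)
  d <- expand.grid(subject = 1:14, w = c("a", "b"))
  d$value <- rnorm(nrow(d)) + rep(rnorm(14), 2)
  a <- mixedAnova(d, "value", "subject", within = "w")
  wide <- matrix(d$value, ncol = 2)
  tt <- t.test(wide[, 1], wide[, 2], paired = TRUE)
  expect_equal(a$F[a$effect == "w"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(a$p[a$effect == "w"], tt$p.value, tolerance = 1e-10)
})

test_that("unbalanced designs are rejected with the missing cells named", {
  d <- expand.grid(subject = 1:4, w = c("a", "b"))
  d$value <- rnorm(8)
  expect_error(mixedAnova(d[-1, ], "value", "subject", within = "w"),
               "missing or duplicated")
})

test_that("greenhouse-geisser epsilon is in (1/(p-1), 1] and shrinks p", {
  set.seed(3)
  d <- expand.grid(subject = 1:20, w = paste0("l", 1:4))
  d$value <- rnorm(nrow(d)) + rep(rnorm(20), 4)
  a <- mixedAnova(d, "value", "subject", within = "w")
  eps <- a$gg_epsilon[a$effect == "w"]
  expect_gt(eps, 1 / 3)
  expect_lte(eps, 1)
  expect_gte(a$p_gg[a$effect == "w"], a$p[a$effect == "w"])
})

test_that("ranking prefers small differences, breaking ties by correlation", {
  per <- data.frame(
    subject = rep("s1", 3), group = "g",
    head_model = c("A", "B", "C"),
    mean_diff = c(0, -1.02, -0.05),
    faces_diff = 0, toys_diff = 0,
    mean_abs_diff = c(0, 1.02, 0.05),
    r = c(1, 0.8, 0.9))
  rk <- rankHeadModels(per)
  expect_equal(rk$head_model, c("A", "C", "B"))
  # permutation invariance
  rk2 <- rankHeadModels(per[c(3, 1, 2), ])
  expect_equal(rk2$head_model, rk$head_model)
  # an alternative identical to Self dominates
  expect_equal(rk$mean_abs_diff[1], 0)
  expect_equal(rk$mean_r[1], 1)
})

test_that("compareHeadModels flags Self-identical alternatives as perfect", {
  set.seed(6)
  base <- expand.grid(subject = c("s1", "s2"), roi = paste0("r", 1:6),
                      condition = c("mother_face", "stranger_face",
                                    "own_toy", "novel_toy"))
  base$group <- "g1"
  base$value <- runif(nrow(base), 1, 5)
  tbl <- rbind(cbind(base, head_model = "Self"),
               cbind(base, head_model = "Twin"))
  noisy <- base
  noisy$value <- noisy$value + rnorm(nrow(base), sd = 0.5)
  tbl <- rbind(tbl, cbind(noisy, head_model = "Other"))
  cmp <- compareHeadModels(tbl)
  expect_equal(cmp$winner, "Twin")
  twin <- cmp$perSubject[cmp$perSubject$head_model == "Twin", ]
  expect_true(all(twin$mean_abs_diff == 0))
  expect_true(all(twin$r == 1))
  expect_true(all(abs(cmp$perSubject$r) <= 1, na.rm = TRUE))
})
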