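test_that("laterality index matches its definition and sign convention", {
  expect_equal(laterality_index(3, 1), 0.5)
  expect_equal(laterality_index(1, 3), -0.5)
  expect_equal(laterality_index(2, 2), 0)
  expect_equal(laterality_index(1, 3), -laterality_index(3, 1))
  expect_true(is.na(laterality_index(1e-13, -1e-13)))
  expect_true(is.na(laterality_index(NA, 2)))
})

test_that("LI algebra holds over random nonnegative pairs", {
  set.seed(14)
  L <- runif(2000, 0, 10)
  R <- runif(2000, 0, 10)
  li <- laterality_index(L, R)
  ok <- !is.na(li)
  expect_true(all(abs(li[ok]) <= 1))
  expect_equal(li, -laterality_index(R, L))
  expect_equal(laterality_index(L, L), rep(0, length(L)))
})

test_that("the laterality table has one cell per subject, pair and metric", {
  co <- tiny_cohort(n_subjects = 2, n_pairs = 3)
  nm <- compute_node_metrics(co$panel, co$atlas,
                             metrics = c("GE", "degree", "cost"))
  li <- build_laterality_table(nm, co$atlas)
  expect_equal(nrow(li), 2 * 3 * 3)
  expect_equal(li$li, laterality_index(li$L, li$R))
})

test_that("missing metric cells propagate and absent homologues are rejected", {
  co <- tiny_cohort(n_subjects = 3, n_pairs = 2)
  nm <- compute_node_metrics(co$panel, co$atlas, metrics = c("GE"))
  nm$value[nm$roi == "Region 001 L" & nm$subject == "sub-001"] <- NA
  li <- build_laterality_table(nm, co$atlas)
  expect_true(is.na(li$li[li$subject == "sub-001" & li$pair_id == 1]))
  nm2 <- nm[nm$roi != "Region 002 R", ]
  expect_error(build_laterality_table(nm2, co$atlas), "Region 002 R")
})

test_that("midline regions are skipped in the laterality table", {
  co_atlas <- make_toy_atlas(2, 2)
  cfg <- simulation_config(n_subjects = 3, n_timepoints = 80, n_pairs = 2,
                           n_unpaired = 2, seed = 15)
  co <- simulate_cohort(cfg, co_atlas)
  nm <- compute_node_metrics(co$panel, co$atlas, metrics = "degree")
  li <- build_laterality_table(nm, co$atlas)
  expect_equal(sort(unique(li$pair_id)), 1:2)
})

test_that("paired t-test matches the closed-form example", {
  # diffs [1,2,3,4]: mean 2.5, sd 1.29099, t 3.873, d 1.936
  atlas <- make_toy_atlas(1)
  metrics <- data.frame(
    subject = rep(sprintf("s%d", 1:4), each = 2),
    roi = rep(c("Region 001 L", "Region 001 R"), 4),
    metric = "GE",
    value = c(2, 1, 4, 2, 6, 3, 8, 4))  # L - R = 1, 2, 3, 4
  res <- paired_lr_tests(metrics, atlas, m = 1)
  expect_equal(res$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$cohens_d, 2.5 / sd(1:4), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-2.5 / (sd(1:4) / 2), 3), tolerance = 1e-12)
  expect_equal(res$direction, "left")
})

test_that("degenerate paired samples are flagged, not silently tested", {
  atlas <- make_toy_atlas(1)
  same <- data.frame(
    subject = rep(sprintf("s%d", 1:4), each = 2),
    roi = rep(c("Region 001 L", "Region 001 R"), 4),
    metric = "GE", value = rep(c(2, 2), 4))
  res <- paired_lr_tests(same, atlas)
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  expect_equal(res$cohens_d, 0)
  expect_equal(res$direction, "none")

  shifted <- same
  shifted$value <- rep(c(3, 2), 4)  # constant nonzero difference
  res2 <- paired_lr_tests(shifted, atlas)
  expect_equal(res2$p, 0)
  expect_equal(res2$direction, "left")
})

test_that("Bonferroni adjustment is the capped multiplication rule", {
  expect_equal(min(1, 132 * 0.0001), 0.0132)
  atlas <- make_toy_atlas(66)
  set.seed(16)
  metrics <- data.frame(
    subject = rep(sprintf("s%d", 1:10), each = 132),
    roi = rep(atlas$name, 10),
    metric = "GE",
    value = rnorm(1320))
  res <- paired_lr_tests(metrics, atlas)
  expect_equal(attr(res, "m"), 132)
  expect_equal(res$p_bonferroni, pmin(1, 132 * res$p))
})

test_that("one-sample LI test handles symmetric and missing cells", {
  atlas <- make_toy_atlas(2)
  li <- data.frame(
    subject = rep(sprintf("s%d", 1:4), 2),
    pair_id = rep(1:2, each = 4),
    metric = "GE",
    L = 1, R = 1,
    li = c(0.1, -0.1, 0.2, -0.2, NA, NA, NA, NA))
  class(li) <- c("laterality_table", "data.frame")
  res <- li_one_sample_tests(li, atlas)
  expect_equal(nrow(res), 1)  # all-missing pair 2 absent
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$direction, "none")
})

test_that("one-sample LI t matches the closed form", {
  x <- c(0.2, 0.3, 0.4, 0.3)
  atlas <- make_toy_atlas(1)
  li <- data.frame(subject = sprintf("s%d", 1:4), pair_id = 1,
                   metric = "fALFF", L = 1, R = 1, li = x)
  res <- li_one_sample_tests(li, atlas, m = 1)
  oracle <- oracle_one_sample_t(x)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$cohens_d, oracle$d, tolerance = 1e-12)
})

test_that("sign coherence: mean(L-R), d and mean LI agree in sign", {
  co <- tiny_cohort(n_subjects = 12, n_pairs = 4, seed = 17)
  nm <- compute_node_metrics(co$panel, co$atlas,
                             metrics = c("GE", "degree", "cost", "fALFF"))
  li <- build_laterality_table(nm, co$atlas)
  res <- paired_lr_tests(nm, co$atlas)
  for (i in seq_len(nrow(res))) {
    sel <- li$pair_id == res$pair_id[i] & li$metric == res$metric[i]
    if (all(li$L[sel] > 0 & li$R[sel] > 0) && res$cohens_d[i] != 0) {
      expect_equal(sign(mean(li$L[sel] - li$R[sel])), sign(res$cohens_d[i]))
      expect_equal(sign(mean(li$li[sel])), sign(res$cohens_d[i]))
    }
  }
})

test_that("concordance counts intersections and direction agreement", {
  mk <- function(pair, dir, p) data.frame(
    pair_id = pair, metric = "GE", test = "paired_LR", t = 1, df = 9,
    p = p, p_bonferroni = p, cohens_d = ifelse(dir == "left", 1, -1),
    direction = dir, n_used = 10, degenerate = FALSE)
  a <- rbind(mk(1, "left", 0.001), mk(2, "left", 0.001))
  b <- rbind(mk(1, "left", 0.001), mk(2, "right", 0.001))
  rep1 <- concordance(a, b)
  expect_equal(rep1$per_metric$n_intersection, 2)
  expect_equal(rep1$overall_agreement, 0.5)

  rep2 <- concordance(a, a)
  expect_equal(rep2$overall_agreement, 1.0)

  c_res <- rbind(mk(1, "left", 0.9), mk(2, "left", 0.9))  # nothing significant
  rep3 <- concordance(a, c_res)
  expect_true(is.na(rep3$overall_agreement))
})

test_that("direction-only regions are reported when metrics differ", {
  mk <- function(pair, metric, dir) data.frame(
    pair_id = pair, metric = metric, test = "paired_LR", t = 1, df = 9,
    p = 0.001, p_bonferroni = 0.001,
    cohens_d = ifelse(dir == "left", 1, -1),
    direction = dir, n_used = 10, degenerate = FALSE)
  a <- rbind(mk(1, "GE", "left"), mk(2, "GE", "left"))
  b <- rbind(mk(1, "APL", "left"), mk(2, "GE", "left"))
  rep <- concordance(a, b)
  expect_equal(rep$direction_only_regions, 1)
  expect_equal(rep$per_metric$agreement[rep$per_metric$metric == "GE"], 1)
})

test_that("demographic comparison matches the hand-computed oracles", {
  set.seed(18)
  a <- data.frame(age = rnorm(30, 66, 7), sex = rep(c("F", "M"), c(20, 10)),
                  education = rnorm(30, 16, 3), mmse = rnorm(30, 28, 1))
  b <- data.frame(age = rnorm(25, 68, 5), sex = rep(c("F", "M"), c(12, 13)),
                  education = rnorm(25, 16, 2), mmse = rnorm(25, 29, 1))
  res <- compare_demographics(a, b)
  o_age <- oracle_two_sample_t(a$age, b$age)
  expect_equal(res$statistic[res$variable == "age"], o_age$t,
               tolerance = 1e-12)
  expect_equal(res$p[res$variable == "age"], o_age$p, tolerance = 1e-12)
  expect_equal(res$effect_size[res$variable == "age"], o_age$d,
               tolerance = 1e-12)
  tab <- rbind(table(factor(a$sex, levels = c("F", "M"))),
               table(factor(b$sex, levels = c("F", "M"))))
  o_sex <- oracle_chisq(tab)
  expect_equal(res$statistic[res$variable == "sex"], o_sex$x2,
               tolerance = 1e-12)
  expect_equal(res$effect_size[res$variable == "sex"], o_sex$phi,
               tolerance = 1e-12)

  same <- compare_demographics(a, a)
  expect_equal(same$p, rep(1, 4), tolerance = 1e-12)
  expect_equal(same$effect_size, rep(0, 4), tolerance = 1e-12)
})

test_that("a cohort-size 2x2 sex table reproduces the worked chi-square", {
  tab <- rbind(c(69, 33), c(52, 34))
  o <- oracle_chisq(tab)
  expect_equal(o$x2, 1.0493, tolerance = 1e-3)
  expect_equal(o$phi, 0.0747, tolerance = 1e-3)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(o$x2, unname(ref$statistic), tolerance = 1e-12)
})

test_that("effect-size estimates converge to a known standardized gap", {
  set.seed(19)
  d_true <- 0.6
  a <- data.frame(age = rnorm(4000, 60 + d_true * 8, 8),
                  sex = rep(c("F", "M"), 2000),
                  education = rnorm(4000, 16, 3), mmse = rnorm(4000, 28, 1))
  b <- data.frame(age = rnorm(4000, 60, 8), sex = rep(c("F", "M"), 2000),
                  education = rnorm(4000, 16, 3), mmse = rnorm(4000, 28, 1))
  res <- compare_demographics(a, b)
  expect_equal(res$effect_size[res$variable == "age"], d_true,
               tolerance = 0.1)
})

test_that("laterality bar plot builds for one and two cohorts", {
  co <- tiny_cohort(n_subjects = 3, n_pairs = 2)
  nm <- compute_node_metrics(co$panel, co$atlas, metrics = c("GE", "degree"))
  li <- build_laterality_table(nm, co$atlas)
  p1 <- plot_laterality(li)
  p2 <- plot_laterality(list(local = li, public = li), metrics = "GE")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
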