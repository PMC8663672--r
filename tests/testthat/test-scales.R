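test_that("SUS scoring spans 0-100 and matches the written-out formula", {
  expect_equal(sus_score(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)), 100)
  expect_equal(sus_score(c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5)), 0)
  expect_equal(sus_score(rep(3, 10)), 50)

  set.seed(21)
  for (i in 1:200) {
    r <- sample(1:5, 10, replace = TRUE)
    s <- sus_score(r)
    expect_equal(s, sus_oracle(r))
    expect_true(s >= 0 && s <= 100 && (s / 2.5) == round(s / 2.5))
  }
  expect_error(sus_score(rep(3, 9)), "exactly 10")
  expect_error(sus_score(c(rep(3, 9), NA)), "exactly 10 non-missing")
  expect_error(sus_score(c(rep(3, 9), 6)), "\\[1, 5\\]")
})

test_that("SUS is monotone in positive items and antitone in negative items", {
  base <- rep(3, 10)
  for (i in 1:10) {
    up <- base; up[i] <- 4
    if (i %% 2 == 1) expect_gt(sus_score(up), sus_score(base))
    else expect_lt(sus_score(up), sus_score(base))
  }
})

long_table <- function(ids, timepoints, config, fill) {
  g <- expand.grid(respondent_id = ids, timepoint = timepoints,
                   item_id = config$items, stringsAsFactors = FALSE)
  g$instrument <- config$instrument
  g$response <- fill(nrow(g))
  g
}

test_that("uniform response patterns score at the response value itself", {
  cfgs <- default_scale_configs()
  aq <- long_table("p1", "T0", cfgs[["AQ-SF"]], function(n) rep(1, n))
  s <- scale_scores(aq, cfgs[["AQ-SF"]])
  expect_equal(s$score, rep(1, 5))  # total + 4 subscales
  expect_setequal(s$scale, c("total", "physical_aggression",
                             "verbal_aggression", "anger", "hostility"))

  ab <- long_table("p1", "T0", cfgs[["ABSQ"]], function(n) rep(5, n))
  expect_equal(scale_scores(ab, cfgs[["ABSQ"]])$score, 5)
})

test_that("scale scores equal independent per-subscale means, in any row order", {
  cfg <- default_scale_configs()[["AQ-SF"]]
  set.seed(31)
  tbl <- long_table(c("a", "b"), c("T0", "T1"), cfg,
                    function(n) sample(1:5, n, replace = TRUE))
  got <- scale_scores(tbl, cfg)
  for (id in c("a", "b")) {
    for (tp in c("T0", "T1")) {
      sub <- tbl[tbl$respondent_id == id & tbl$timepoint == tp, ]
      resp <- setNames(sub$response, sub$item_id)
      expect_equal(got$score[got$respondent_id == id & got$timepoint == tp &
                               got$scale == "total"],
                   mean(resp[cfg$items]))
      for (nm in names(cfg$subscales)) {
        expect_equal(got$score[got$respondent_id == id &
                                 got$timepoint == tp & got$scale == nm],
                     mean(resp[cfg$subscales[[nm]]]))
      }
    }
  }
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(scale_scores(shuffled, cfg), got)
})

test_that("reverse-keyed items are reflected before aggregation", {
  cfg <- scale_config("toy", c("i1", "i2"), range = c(1, 5),
                      reverse_keyed = "i2")
  tbl <- data.frame(respondent_id = "p", timepoint = "T0",
                    instrument = "toy", item_id = c("i1", "i2"),
                    response = c(5, 1))
  s <- scale_scores(tbl, cfg)
  expect_equal(s$score[s$scale == "total"], 5)  # 1 reflects to 5
})

test_that("missing items prorate above 80% answered and mark NA below", {
  cfg <- default_scale_configs()[["ABSQ"]]  # 18 items
  tbl <- long_table("p", "T0", cfg, function(n) rep(4, n))
  # drop 3 of 18 (83% answered): prorated score, still 4
  s <- scale_scores(tbl[-(1:3), ], cfg)
  expect_equal(s$score[s$scale == "total"], 4)
  # drop 4 of 18 (78% answered): below the proration threshold
  s2 <- scale_scores(tbl[-(1:4), ], cfg)
  expect_true(is.na(s2$score[s2$scale == "total"]))
  expect_error(scale_scores(transform(tbl, response = 9), cfg),
               "outside the configured range")
})

test_that("scale configs round-trip through JSON and YAML files", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(instrument = "toy",
                            items = c("i1", "i2", "i3"),
                            range = c(1, 5),
                            subscales = list(first = c("i1", "i2")),
                            reverse_keyed = "i3"),
                       f, auto_unbox = TRUE)
  cfg <- read_scale_config(f)
  expect_equal(cfg$instrument, "toy")
  expect_equal(cfg$subscales$first, c("i1", "i2"))
  expect_equal(cfg$reverse_keyed, "i3")
  expect_equal(cfg$min_answered_prop, 0.8)

  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("instrument: toy", "items: [i1, i2, i3]", "range: [1, 5]",
               "subscales:", "  first: [i1, i2]",
               "reverse_keyed: [i3]"), fy)
  cfgy <- read_scale_config(fy)
  expect_equal(cfgy$subscales, cfg$subscales)
  expect_equal(cfgy$range, cfg$range)
})

test_that("exact Wilcoxon p equals full sign enumeration and wilcox.test", {
  # all-positive distinct differences at n = 6: p = 2/2^6
  w6 <- wilcoxon_matched_pairs(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(w6$p, 2 / 64)
  expect_equal(w6$W, 0)
  expect_true(w6$exact)

  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    pre <- round(rnorm(n, 10, 2), 1)
    post <- round(pre + rnorm(n, 0, 1.5), 1)
    if (all(post == pre)) next
    got <- wilcoxon_matched_pairs(pre, post)
    expect_equal(got$p, wilcoxon_enumeration_oracle(pre, post),
                 tolerance = 1e-12)
    # zero- and tie-free instances also match the reference implementation
    # (wilcox.test abandons the exact computation when zeros are present)
    d <- post - pre
    if (all(d != 0) && anyDuplicated(abs(d)) == 0) {
      ref <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                                 exact = TRUE))
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon handles degenerate and zero-laden inputs", {
  deg <- wilcoxon_matched_pairs(c(1, 2, 3), c(1, 2, 3))
  expect_equal(deg$p, 1)
  expect_equal(deg$W, 0)
  expect_equal(deg$n_effective, 0L)
  expect_true(deg$degenerate)

  # zeros are dropped by default
  wd <- wilcoxon_matched_pairs(c(1, 2, 3, 4), c(1, 3, 5, 6))
  expect_equal(wd$n_effective, 3L)
  # Pratt keeps zeros in the ranking
  wp <- wilcoxon_matched_pairs(c(1, 2, 3, 4), c(1, 3, 5, 6),
                               zero_policy = "pratt")
  expect_equal(wp$n_effective, 3L)
  expect_gte(wp$W_plus, wd$W_plus)  # ranks shifted up by the ranked zero
})

test_that("the normal approximation converges to the exact p", {
  set.seed(51)
  pre <- rnorm(15, 20, 3)
  post <- pre + rnorm(15, 0.8, 1.2)
  exact <- wilcoxon_matched_pairs(pre, post)
  expect_true(exact$exact)
  # the tie-corrected continuity-corrected approximation at the same data
  d <- post - pre
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- sum(r) / 2; sigma <- sqrt(sum(r^2) / 4)
  w <- min(w_plus, sum(r) - w_plus)
  p_approx <- 2 * pnorm(-(mu - w - 0.5) / sigma)
  expect_lt(abs(p_approx - exact$p), 0.01)
})

test_that("correlation matches the covariance formula and affine invariance", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)

  set.seed(61)
  x <- rnorm(10); y <- rnorm(10)
  got <- pearson_r(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$df, 8)
  ref <- stats::cor.test(x, y)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  shifted <- pearson_r(3 * x + 7, 0.5 * y - 2)
  expect_equal(shifted$r, got$r, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")

  sp <- pearson_r(x, y, method = "spearman")
  expect_equal(sp$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("the summary report aggregates scores and runs paired tests per scale", {
  cfg <- default_scale_configs()[["AQ-SF"]]
  set.seed(71)
  tbl <- long_table(paste0("p", 1:8), c("T0", "T1"), cfg,
                    function(n) sample(1:5, n, replace = TRUE))
  scores <- scale_scores(tbl, cfg)
  rep <- scale_summary(scores)
  expect_setequal(unique(rep$summary$timepoint), c("T0", "T1"))
  tot_t0 <- scores$score[scores$scale == "total" & scores$timepoint == "T0"]
  row <- rep$summary[rep$summary$scale == "total" &
                       rep$summary$timepoint == "T0", ]
  expect_equal(row$mean, mean(tot_t0))
  expect_equal(row$sd, sd(tot_t0))
  expect_true(all(c("W", "Z", "p") %in% names(rep$tests)))
  expect_equal(rep$tests$n_pairs[rep$tests$scale == "total"], 8)
})
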