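fake_cm <- function(p, s, c) {
  structure(list(R_pres = p, R_smoo = s, R_circ = c, n = 40L),
            class = "case_metrics")
}

test_that("score cards average, scale and clip correctly", {
  sc <- make_scorecard(list(fake_cm(1, 1, 1)), "ideal")
  expect_equal(unname(sc$scores), c(100, 100, 100))
  sc2 <- make_scorecard(list(fake_cm(1.0, 1, 1), fake_cm(0.8, 1, 1),
                             fake_cm(0.6, 1, 1)), "op")
  expect_equal(sc2$scores[["preservation"]], 80)
  expect_equal(sc2$sd[["preservation"]], 100 * sd(c(1, 0.8, 0.6)))
  expect_error(make_scorecard(list()), "at least one")
  # permutation invariance
  sc3 <- make_scorecard(list(fake_cm(0.6, 1, 1), fake_cm(1.0, 1, 1),
                             fake_cm(0.8, 1, 1)), "op")
  expect_equal(sc3$scores, sc2$scores)
})

test_that("t statistic matches the pooled-variance closed form", {
  res <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  # hand check: means 2 and 3, pooled s^2 = 1, t = -1 / sqrt(2/3)
  t_manual <- (2 - 3) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$p, 2 * pt(t_manual, df = 4), tolerance = 1e-10)
  expect_equal(res$p, 0.288, tolerance = 0.002)
  expect_false(res$significant)
})

test_that("t-test closed form holds on random inputs", {
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    res <- compare_groups(a, b)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(res$t, t_manual, tolerance = 1e-10)
    expect_equal(res$p, 2 * pt(-abs(t_manual), na + nb - 2), tolerance = 1e-10)
  }
})

test_that("degenerate comparisons follow the stated conventions", {
  res <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_identical(res$t, 0)
  expect_identical(res$p, 1)
  expect_false(res$significant)
  expect_error(compare_groups(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  # identical samples with variance: t = 0, p = 1
  res2 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("welch option is recorded and used", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8, 10)
  res <- compare_groups(a, b, welch = TRUE)
  expect_identical(res$method, "welch")
  tt <- t.test(a, b)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)
})

test_that("radar export writes SVG and a CSV that round-trips", {
  cards <- list(make_scorecard(list(fake_cm(1, 1, 1)), "ideal"),
                make_scorecard(list(fake_cm(0.9, 0.8, 0.7)), "op2"))
  svg <- withr::local_tempfile(fileext = ".svg")
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- export_radar(cards, svg, csv)
  expect_true(file.exists(svg))
  txt <- readLines(svg)
  expect_true(any(grepl("<svg", txt)))
  # the all-100 polygon touches the axis tips (same points as the outer ring)
  outer_ring <- txt[grep("polygon", txt)[4]]   # 4 grid rings drawn first
  ideal_poly <- txt[grep("fill-opacity", txt)[1]]
  pts <- function(s) regmatches(s, gregexpr("[0-9.]+,[0-9.]+", s))[[1]]
  expect_true(all(pts(outer_ring) %in% pts(ideal_poly)))
  tab2 <- read.csv(csv)
  expect_equal(tab2$preservation, tab$preservation)
  expect_identical(as.character(tab2$operator), as.character(tab$operator))
})

test_that("cmd_score emits all pairwise comparisons", {
  metrics <- list(a = list(fake_cm(1, 1, 0.9), fake_cm(0.98, 1, 0.92)),
                  b = list(fake_cm(0.8, 0.9, 0.5), fake_cm(0.82, 0.88, 0.55)),
                  c = list(fake_cm(0.9, 0.95, 0.7), fake_cm(0.91, 0.94, 0.72)))
  res <- cmd_score(metrics)
  expect_identical(length(res$comparisons), 3L * 3L)
  expect_s3_class(res$comparisons[["a_vs_b_R_circ"]], "group_comparison")
})
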