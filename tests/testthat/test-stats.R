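test_that("median_iqr matches an order-statistic oracle", {
  expect_equal(unname(median_iqr(3)), c(3, 3, 3), ignore_attr = TRUE)
  expect_equal(median_iqr(1:5)[["median"]], 3)
  set.seed(81)
  v <- rnorm(100)
  got <- median_iqr(v)
  # independent sort-and-interpolate oracle at positions p*(n-1), 0-based
  s <- sort(v)
  interp <- function(p) {
    h <- p * (length(s) - 1)
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  }
  expect_equal(unname(got), c(interp(0.5), interp(0.25), interp(0.75)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(median_iqr(numeric(0)), "empty")
  expect_identical(attr(median_iqr(v, "spss"), "method"), "spss")
})

test_that("wilcoxon worked case: n = 5 all-positive differences", {
  res <- wilcoxon_signed_rank(pre = rep(0, 5), post = c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625)
  expect_identical(res$method, "exact")
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("wilcoxon exact path equals the 2^n enumeration oracle,
           including ties and zeros", {
  set.seed(82)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    pre <- round(rnorm(n, 10, 3), sample(0:1, 1))
    post <- round(pre + rnorm(n, 0.5, 2), sample(0:1, 1))
    if (all(post == pre)) post[1] <- post[1] + 1
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_signed_rank(pre, post, alt)$p_value,
                   oracle_signrank_p(pre, post, alt), tolerance = 1e-12,
                   info = sprintf("case %d alt %s", i, alt))
    }
  }
})

test_that("wilcoxon agrees with the reference implementation when no
           ties are present", {
  set.seed(83)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    d <- rnorm(n)
    ref <- stats::wilcox.test(d, exact = TRUE)
    got <- wilcoxon_signed_rank(rep(0, n), d)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxon large-n normal path approximates the exact p", {
  set.seed(84)
  d <- rnorm(30, 0.4)
  approx <- wilcoxon_signed_rank(rep(0, 30), d)
  exact <- wilcoxon_signed_rank(rep(0, 30), d, exact_limit = 30L)
  expect_identical(approx$method, "normal")
  expect_identical(exact$method, "exact")
  expect_lt(abs(approx$p_value - exact$p_value),
            0.15 * exact$p_value + 1e-4)
})

test_that("pratt zero handling ranks zeros before discarding them", {
  pre <- c(0, 0, 0, 0)
  post <- c(0, 1, 1, 2)
  w <- wilcoxon_signed_rank(pre, post, zero_method = "wilcoxon")
  p <- wilcoxon_signed_rank(pre, post, zero_method = "pratt")
  expect_equal(w$statistic, sum(rank(c(1, 1, 2))))
  expect_equal(p$statistic, sum(rank(c(0, 1, 1, 2))[2:4]))
})

test_that("spearman_rho handles monotone, antitone and tied data", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  expect_equal(spearman_rho(x, exp(x))$p_value, 0)
  set.seed(85)
  for (i in 1:20) {
    a <- sample(1:5, 12, TRUE)
    b <- a + sample(0:3, 12, TRUE)
    if (min(b) == max(b)) next
    got <- spearman_rho(a, b)
    expect_equal(got$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
    expect_equal(got$rho, cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
    # symmetry and monotone-transform invariance
    expect_equal(got$rho, spearman_rho(b, a)$rho, tolerance = 1e-14)
    expect_equal(spearman_rho(exp(a), b)$rho, got$rho, tolerance = 1e-14)
  }
  expect_error(spearman_rho(1:2, 1:2), "3 complete")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

make_table <- function(m = 6, effect = 1, seed = 86) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(m)) {
    das_pre <- rnorm(1, 4.8, 0.5)
    das_post <- das_pre - effect * 0.5 - rnorm(1, 0, 0.1)
    for (hand in c("L", "R")) {
      intra_pre <- rnorm(1, 0.2, 0.05)
      intra_post <- intra_pre + effect * 0.7 + rnorm(1, 0, 0.05)
      esr_pre <- rnorm(1, 30, 5)
      crp_pre <- abs(rnorm(1, 1.5, 0.5))
      for (visit in c("pre", "post")) {
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("S%02d", i), hand = hand, visit = visit,
          intra_hsisas = if (visit == "pre") intra_pre else intra_post,
          inter_hsisas = if (visit == "pre") intra_pre + 0.3
                         else intra_post + 0.1,
          das28 = if (visit == "pre") das_pre else das_post,
          esr_mm_per_h = if (visit == "pre") esr_pre else
            esr_pre - effect * (8 + abs(rnorm(1))),
          crp_mg_per_dl = if (visit == "pre") crp_pre else
            crp_pre - effect * (0.5 + abs(rnorm(1, 0, 0.2))))
      }
    }
  }
  do.call(rbind, rows)
}

test_that("improvement deltas apply the per-variable sign conventions", {
  tab <- data.frame(
    subject_id = rep("S1", 2), hand = rep("L", 2),
    visit = c("pre", "post"),
    das28 = c(4.8, 4.3), intra_hsisas = c(0.2, 0.9),
    esr_mm_per_h = c(31, 19), crp_mg_per_dl = c(1.5, 1.5))
  d <- improvement_deltas(tab)
  expect_equal(d$d_das28, 0.5)
  expect_equal(d$d_intra_hsisas, 0.7)
  expect_equal(d$d_esr_mm_per_h, 12)
  expect_equal(d$d_crp_mg_per_dl, 0)  # equal visits -> 0 either way
})

test_that("a uniform improvement yields positive deltas for every
           variable", {
  tab <- make_table(effect = 1)
  d <- improvement_deltas(tab)
  for (v in grep("^d_", names(d), value = TRUE)) {
    expect_true(all(d[[v]] > 0 | abs(d[[v]]) < 1e-9), info = v)
  }
})

test_that("DAS28 deltas are patient-level and missing visits excluded", {
  tab <- make_table(m = 5)
  tab$das28[tab$subject_id == "S02"] <- NA
  d <- improvement_deltas(tab)
  expect_identical(nrow(d), 10L)
  expect_true(all(is.na(d$d_das28[d$subject_id == "S02"])))
  # both wrists of a subject carry one DAS28 delta
  for (s in unique(d$subject_id)) {
    expect_length(unique(d$d_das28[d$subject_id == s]), 1L)
  }
  # a wrist missing a whole visit is dropped with a warning
  expect_warning(d2 <- improvement_deltas(
    tab[!(tab$subject_id == "S03" & tab$hand == "R" &
            tab$visit == "post"), ]), "S03")
  expect_identical(nrow(d2), 9L)
})

test_that("paper_tables flags effects where they exist and nowhere else", {
  tab <- make_table(m = 8, effect = 1)
  # strong effect only on the abundance scores and DAS28
  tab$esr_mm_per_h <- rnorm(nrow(tab), 30, 5)
  tab$crp_mg_per_dl <- abs(rnorm(nrow(tab), 1, 0.5))
  rep <- paper_tables(tab)
  s <- rep$summary
  expect_lt(s$p_value[s$variable == "intra_hsisas"], 0.05)
  expect_lt(s$p_value[s$variable == "inter_hsisas"], 0.05)
  expect_gt(s$p_value[s$variable == "esr_mm_per_h"], 0.05)
  # DAS28 paired at patient level
  expect_identical(s$n_pairs[s$variable == "das28"], 8L)
  expect_identical(s$n_pairs[s$variable == "intra_hsisas"], 16L)
  expect_true(any(rep$spearman_stars != ""))
  expect_output(print(rep), "Spearman")
})

test_that("duplicated wrists double n but keep the medians", {
  tab <- make_table(m = 6)
  single <- tab[tab$hand == "L", ]
  dup <- rbind(single, transform(single, hand = "R"))
  r1 <- paper_tables(single)$summary
  r2 <- paper_tables(dup)$summary
  expect_equal(r2$pre_median, r1$pre_median)
  expect_equal(r2$post_median, r1$post_median)
  wrist_vars <- r1$variable != "das28"
  expect_identical(r2$n_pairs[wrist_vars], 2L * r1$n_pairs[wrist_vars])
})

test_that("wilcoxon type-I error stays near nominal under the null", {
  set.seed(87)
  rejections <- vapply(1:500, function(i) {
    d <- rnorm(22)
    wilcoxon_signed_rank(rep(0, 22), d)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.10)
})
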