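test_that("normality gate routes by Shapiro-Wilk and sample size", {
  set.seed(11)
  normal <- tibble::tibble(group = rep(c("a", "b"), each = 40),
                           value = rnorm(80))
  expect_equal(as.character(normality_gate(normal)), "parametric")

  set.seed(12)
  skewed <- tibble::tibble(group = rep(c("a", "b"), each = 50),
                           value = c(rnorm(50), rlnorm(50, sdlog = 1)))
  expect_equal(as.character(normality_gate(skewed)), "nonparametric")

  tiny <- tibble::tibble(group = c("a", "a", "b", "b", "b"),
                         value = c(1, 2, 1, 2, 3))
  expect_warning(route <- normality_gate(tiny), "n < 3")
  expect_equal(as.character(route), "nonparametric")
})

test_that("normality routing rates match Shapiro-Wilk size and power", {
  set.seed(13)
  par_rate <- mean(replicate(60, {
    g <- tibble::tibble(group = rep(c("a", "b"), each = 30),
                        value = rnorm(60))
    as.character(normality_gate(g)) == "parametric"
  }))
  expect_gte(par_rate, 0.80)   # ~ (1 - alpha)^2 with alpha = 0.05/group
  nonpar_rate <- mean(replicate(40, {
    g <- tibble::tibble(group = rep(c("a", "b"), each = 50),
                        value = c(rnorm(50), rlnorm(50, sdlog = 1)))
    as.character(normality_gate(g)) == "nonparametric"
  }))
  expect_gte(nonpar_rate, 0.95)
})

test_that("identical or constant groups give omnibus p = 1 and no pairwise", {
  g <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4), value = 2)
  res <- compare_groups(g, route = "parametric")
  expect_equal(res$omnibus_p, 1)
  expect_equal(nrow(res$pairwise), 0)
})

test_that("two-group nonparametric route is the exact Mann-Whitney test", {
  g <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      value = c(1, 2, 3, 4, 5, 6))
  res <- compare_groups(g, route = "nonparametric")
  expect_equal(res$omnibus_p, 0.1)   # exact: 2 * 1/20 arrangements
  expect_equal(res$pairwise$adjusted_p, 0.1)
})

test_that("a 2-SD shifted group is detected by both routes", {
  set.seed(14)
  hits <- replicate(20, {
    g <- tibble::tibble(group = rep(c("a", "b", "c"), each = 20),
                        value = c(rnorm(20), rnorm(20), rnorm(20, mean = 2)))
    c(compare_groups(g, route = "parametric")$omnibus_p < 0.05,
      compare_groups(g, route = "nonparametric")$omnibus_p < 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})

test_that("parametric post-hoc families cover all pairs and stay in [0,1]", {
  set.seed(15)
  g <- tibble::tibble(group = rep(c("a", "b", "c"), each = 10),
                      value = c(rnorm(10), rnorm(10, 1), rnorm(10, 2)))
  for (ph in c("bonferroni", "tukey")) {
    res <- compare_groups(g, route = "parametric", posthoc = ph)
    expect_equal(nrow(res$pairwise), 3)
    expect_true(all(res$pairwise$adjusted_p >= 0 &
                      res$pairwise$adjusted_p <= 1))
  }
  resn <- compare_groups(g, route = "nonparametric")
  expect_equal(resn$test_name, "Kruskal-Wallis + Dunn")
  expect_equal(nrow(resn$pairwise), 3)
})

test_that("Dunn adjusted p-values dominate raw ones and detect the shift", {
  set.seed(16)
  g <- tibble::tibble(group = rep(c("a", "b", "c"), each = 15),
                      value = c(rnorm(15), rnorm(15), rnorm(15, 3)))
  d <- dunn_test(g)
  expect_true(all(d$adjusted_p >= d$p - 1e-12))
  expect_lt(d$adjusted_p[d$group_a == "a" & d$group_b == "c"], 0.05)
})

test_that("forcing the route changes only the test, not the data", {
  set.seed(17)
  g <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                      value = rnorm(20))
  rp <- compare_groups(g, route = "parametric")
  rn <- compare_groups(g, route = "nonparametric")
  expect_equal(rp$pairwise[c("group_a", "group_b")],
               rn$pairwise[c("group_a", "group_b")])
  expect_false(identical(rp$test_name, rn$test_name))
})

test_that("per-voltage comparisons adjust across voltages", {
  same <- tibble::tibble(group = rep(c("a", "b"), each = 12),
                         voltage = rep(rep(c(80, 120, 160), each = 4), 2),
                         value = rep(c(1, 2, 3, 4), 6))
  res <- per_voltage_compare(same)
  expect_true(all(res$adjusted_p == 1))

  one_v <- tibble::tibble(group = rep(c("a", "b"), each = 4),
                          voltage = 120,
                          value = c(1, 2, 3, 4, 5, 6, 7, 8))
  r1 <- per_voltage_compare(one_v)
  expect_equal(r1$adjusted_p, r1$p)    # single comparison: identity

  set.seed(18)
  many <- tibble::tibble(group = rep(c("a", "b"), each = 20),
                         voltage = rep(rep(c(40, 80, 120, 160), each = 5), 2),
                         value = c(rnorm(20), rnorm(20, 2)))
  rm_ <- per_voltage_compare(many)
  expect_true(all(rm_$adjusted_p >= rm_$p - 1e-12))

  # voltages with n < 3 in either group are skipped and recorded
  sparse <- dplyr::bind_rows(
    many, tibble::tibble(group = c("a", "b"), voltage = 200, value = c(1, 2)))
  rs <- per_voltage_compare(sparse)
  expect_equal(attr(rs, "skipped"), 200)
  expect_false(200 %in% rs$voltage)

  expect_error(per_voltage_compare(
    tibble::tibble(group = c("a", "b"), voltage = c(1, 2), value = c(1, 2))),
    "shared")
})

test_that("simulated GOF vs WT activation curves separate at high voltage", {
  mk_group <- function(scheme, label, n = 8, seed0 = 0) {
    purrr::map_dfr(seq_len(n), function(i) {
      purrr::map_dfr(c(-40, 0, 120, 160), function(v) {
        tibble::tibble(group = label, voltage = v,
                       value = path_open_fraction(
                         sample_path(scheme, v, 3,
                                     seed = seed0 + 137 * i + v)))
      })
    })
  }
  curves <- dplyr::bind_rows(
    mk_group(scheme_preset("wt"), "wt", seed0 = 3000),
    mk_group(scheme_preset("n999s"), "n999s", seed0 = 6000))
  res <- per_voltage_compare(curves, pair = c("wt", "n999s"))
  expect_true(all(res$adjusted_p[res$voltage >= 120] < 0.05))
  # below the activation range both presets are essentially silent
  low <- dplyr::filter(curves, voltage <= 0)
  expect_true(all(tapply(low$value, low$group, mean) < 0.01))
})
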