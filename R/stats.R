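#' Route a group table through the normality gate
#'
#' Applies the Shapiro-Wilk test to every group; the comparison is routed
#' nonparametric if any group rejects normality at `alpha`, and parametric
#' otherwise. Groups with fewer than 3 values cannot be tested and force the
#' nonparametric route with a warning.
#'
#' @param groups Tibble with columns `group` and `value` (optionally
#'   `patch_id`, `voltage`).
#' @param alpha Rejection level of the per-group Shapiro-Wilk test
#'   (default 0.05).
#' @return `"parametric"` or `"nonparametric"` with attribute
#'   `shapiro_p` (named per-group p values; `NA` where untestable).
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(all(c("group", "value") %in% names(groups)))
  ps <- groups |>
    dplyr::group_by(group) |>
    dplyr::summarise(p = if (dplyr::n() >= 3 && stats::sd(value) > 0)
                           stats::shapiro.test(value)$p.value
                         else NA_real_,
                     n = dplyr::n(), constant = stats::sd(value) == 0,
                     .groups = "drop")
  route <- "parametric"
  if (any(ps$n < 3)) {
    warning("group(s) with n < 3: routing nonparametric")
    route <- "nonparametric"
  } else if (any(ps$constant) || any(!is.na(ps$p) & ps$p < alpha)) {
    # a degenerate (constant) group is treated as failing the normality gate
    route <- "nonparametric"
  }
  structure(route, shapiro_p = stats::setNames(ps$p, ps$group))
}

#' Compare groups along the parametric or nonparametric ladder
#'
#' Parametric route: one-way ANOVA omnibus with Bonferroni-adjusted pairwise
#' Welch t tests (Tukey HSD available via `posthoc = "tukey"`). Nonparametric
#' route: Kruskal-Wallis omnibus with Dunn's pairwise comparisons. With
#' exactly two groups the omnibus collapses to the two-sample t test or exact
#' Mann-Whitney test. Constant data across all groups yields omnibus p = 1
#' and no pairwise results.
#'
#' @param groups Tibble with `group` and `value` columns.
#' @param route `"parametric"`, `"nonparametric"`, or `NULL` to apply
#'   [normality_gate()].
#' @param posthoc Parametric post-hoc family: `"bonferroni"` (default) or
#'   `"tukey"`.
#' @param alpha Significance threshold recorded on the result (default 0.05).
#' @return A list of class `comparison_result`: `test_name`, `omnibus_p`,
#'   `pairwise` (tibble group_a/group_b/adjusted_p), `route`, `alpha`.
#' @export
compare_groups <- function(groups, route = NULL,
                           posthoc = c("bonferroni", "tukey"),
                           alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  stopifnot(all(c("group", "value") %in% names(groups)))
  groups <- dplyr::mutate(groups, group = as.character(group))
  labs <- unique(groups$group)
  if (length(labs) < 2) stop("compare_groups() needs >= 2 groups")
  if (is.null(route)) route <- as.character(normality_gate(groups))
  route <- match.arg(route, c("parametric", "nonparametric"))

  if (stats::sd(groups$value) == 0) {
    return(structure(list(test_name = "degenerate (constant data)",
                          omnibus_p = 1,
                          pairwise = tibble::tibble(group_a = character(0),
                                                    group_b = character(0),
                                                    adjusted_p = numeric(0)),
                          route = route, alpha = alpha),
                     class = "comparison_result"))
  }

  two <- length(labs) == 2
  if (route == "parametric") {
    if (two) {
      p <- stats::t.test(value ~ group, data = groups)$p.value
      pw <- tibble::tibble(group_a = labs[1], group_b = labs[2],
                           adjusted_p = p)
      name <- "Welch t test"
    } else if (posthoc == "tukey") {
      fit <- stats::aov(value ~ group, data = groups)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$group
      pair <- strsplit(rownames(tk), "-", fixed = TRUE)
      pw <- tibble::tibble(group_a = vapply(pair, `[`, "", 2),
                           group_b = vapply(pair, `[`, "", 1),
                           adjusted_p = unname(tk[, "p adj"]))
      name <- "one-way ANOVA + Tukey HSD"
    } else {
      fit <- stats::aov(value ~ group, data = groups)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      pairs <- utils::combn(labs, 2, simplify = FALSE)
      raw <- vapply(pairs, function(pr) {
        a <- groups$value[groups$group == pr[1]]
        b <- groups$value[groups$group == pr[2]]
        tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      }, numeric(1))
      pw <- tibble::tibble(group_a = vapply(pairs, `[`, "", 1),
                           group_b = vapply(pairs, `[`, "", 2),
                           adjusted_p = stats::p.adjust(raw, "bonferroni"))
      name <- "one-way ANOVA + Bonferroni pairwise t"
    }
  } else {
    if (two) {
      a <- groups$value[groups$group == labs[1]]
      b <- groups$value[groups$group == labs[2]]
      p <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided"))$p.value
      pw <- tibble::tibble(group_a = labs[1], group_b = labs[2],
                           adjusted_p = p)
      name <- "Mann-Whitney (exact where possible)"
    } else {
      p <- stats::kruskal.test(value ~ group, data = groups)$p.value
      pw <- dunn_test(groups)
      name <- "Kruskal-Wallis + Dunn"
    }
  }
  structure(list(test_name = name, omnibus_p = unname(p), pairwise = pw,
                 route = route, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$test_name, " (", x$route, ")\n",
      "omnibus p = ", signif(x$omnibus_p, 4), "\n", sep = "")
  if (nrow(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Dunn's pairwise rank comparisons
#'
#' Post-hoc companion of the Kruskal-Wallis test: pairwise z statistics on
#' mean ranks with tie correction, with Bonferroni-style adjustment over all
#' pairs (the convention of common statistics packages; `method` accepts any
#' [stats::p.adjust()] method).
#'
#' @param groups Tibble with `group` and `value`.
#' @param method Multiplicity adjustment (default `"bonferroni"`).
#' @return Tibble `group_a`, `group_b`, `z`, `p`, `adjusted_p`.
#' @export
dunn_test <- function(groups, method = "bonferroni") {
  stopifnot(all(c("group", "value") %in% names(groups)))
  g <- as.character(groups$group)
  v <- groups$value
  labs <- unique(g)
  n_all <- length(v)
  r <- rank(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_all - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt((n_all * (n_all + 1) / 12 - tie_corr) *
                 (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble::tibble(group_a = a, group_b = b, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  dplyr::mutate(out, adjusted_p = stats::p.adjust(p, method = method))
}

#' Per-voltage two-group comparison of activation curves
#'
#' One two-sided Mann-Whitney test per shared voltage between two groups,
#' with the p values adjusted for multiplicity across voltages (Holm by
#' default, Sidak or any [stats::p.adjust()] method available). Voltages
#' where either group has fewer than 3 values are skipped (recorded in the
#' `skipped` attribute).
#'
#' @param curves Tibble with `group`, `voltage`, `value` (e.g. per-patch NPo
#'   by voltage).
#' @param pair Character vector of the two group labels to compare; `NULL`
#'   uses the only two groups present.
#' @param method Adjustment method: `"holm"` (default), `"sidak"`, or a
#'   [stats::p.adjust()] method name.
#' @return Tibble `voltage`, `p`, `adjusted_p`; attribute `skipped` lists
#'   voltages excluded for insufficient n.
#' @export
per_voltage_compare <- function(curves, pair = NULL, method = "holm") {
  stopifnot(all(c("group", "voltage", "value") %in% names(curves)))
  curves <- dplyr::mutate(curves, group = as.character(group))
  if (is.null(pair)) {
    pair <- unique(curves$group)
    if (length(pair) != 2)
      stop("specify `pair` when more than two groups are present")
  }
  a <- dplyr::filter(curves, group == pair[1])
  b <- dplyr::filter(curves, group == pair[2])
  shared <- intersect(unique(a$voltage), unique(b$voltage))
  if (length(shared) == 0) stop("no shared voltages between groups")
  shared <- sort(shared)
  na <- table(factor(a$voltage, levels = shared))
  nb <- table(factor(b$voltage, levels = shared))
  ok <- na >= 3 & nb >= 3
  skipped <- shared[!ok]
  use <- shared[ok]
  if (length(use) == 0) stop("no voltage with n >= 3 in both groups")
  ps <- vapply(use, function(v) {
    va <- a$value[a$voltage == v]; vb <- b$value[b$voltage == v]
    if (stats::sd(c(va, vb)) == 0) return(1)
    suppressWarnings(
      stats::wilcox.test(va, vb, alternative = "two.sided"))$p.value
  }, numeric(1))
  adj <- if (method == "sidak") pmin(1, 1 - (1 - ps)^length(ps))
         else stats::p.adjust(ps, method = method)
  structure(tibble::tibble(voltage = use, p = ps, adjusted_p = adj),
            skipped = skipped)
}
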