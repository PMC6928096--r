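#' Build a percentage score card for one operator
#'
#' Averages each aggregate ratio across an operator's cases, scales to
#' percent and clips to \[0, 100\]; error bars are standard deviations
#' across cases (also in percent).
#'
#' @param cases list of `case_metrics` objects
#' @param operator operator identifier
#' @return object of class `score_card`: list with `operator`, `scores`
#'   (named percentages), `sd` (named, NA for a single case),
#'   `per_case` (data.frame), `n_cases`
#' @export
#' @examples
#' # sc <- make_scorecard(list(cm1, cm2, cm3), "expert")
make_scorecard <- function(cases, operator = "operator") {
  if (!length(cases)) stop("need at least one case", call. = FALSE)
  per_case <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cm <- cases[[i]]
    data.frame(case = i, R_pres = cm$R_pres, R_smoo = cm$R_smoo,
               R_circ = cm$R_circ, n_slices = cm$n)
  }))
  agg <- colMeans(per_case[, c("R_pres", "R_smoo", "R_circ")])
  scores <- pmin(pmax(100 * agg, 0), 100)
  sds <- if (nrow(per_case) > 1L)
    100 * vapply(per_case[, c("R_pres", "R_smoo", "R_circ")], sd, 0)
  else c(R_pres = NA_real_, R_smoo = NA_real_, R_circ = NA_real_)
  names(scores) <- names(sds) <- c("preservation", "smoothness", "circularity")
  structure(list(operator = operator, scores = scores, sd = sds,
                 per_case = per_case, n_cases = nrow(per_case)),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %s (%d cases)\n", x$operator, x$n_cases))
  for (nm in names(x$scores))
    cat(sprintf("  %-12s %6.1f %%%s\n", nm, x$scores[[nm]],
                if (is.na(x$sd[[nm]])) "" else sprintf(" (sd %.1f)", x$sd[[nm]])))
  invisible(x)
}

#' Two-sample two-tailed t-test between operator groups
#'
#' Equal-variance Student's t by default (Welch optional and recorded in
#' the result); significance at `alpha` (default 0.01). When both groups
#' have zero variance and equal means the comparison returns t = 0,
#' p = 1 by convention; zero pooled variance with unequal means is an
#' error.
#'
#' @param a,b numeric vectors of per-case values, each of length >= 2
#' @param parameter label for the compared quantity
#' @param welch use Welch's unequal-variance t-test
#' @param alpha significance level
#' @return object of class `group_comparison`: parameter, group means
#'   and standard deviations, `t`, `df`, `p`, `significant`, `method`
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(2, 3, 4))
compare_groups <- function(a, b, parameter = "value", welch = FALSE,
                           alpha = 0.01) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2L, p = 1)
    } else {
      stop("degenerate groups: zero variance with unequal means", call. = FALSE)
    }
  } else {
    tt <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(list(parameter = parameter,
                 mean_a = mean(a), sd_a = sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = sd(b), n_b = length(b),
                 t = res$t, df = res$df, p = res$p,
                 significant = res$p < alpha, alpha = alpha,
                 method = if (welch) "welch" else "student"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: t = %.4f (df %.3g), p = %.4g %s\n",
              x$parameter, x$t, x$df, x$p,
              if (x$significant) sprintf("(significant at %.2g)", x$alpha)
              else "(n.s.)"))
  invisible(x)
}

#' @importFrom stats var
radar_points <- function(scores, cx, cy, r) {
  ang <- pi / 2 - 2 * pi * (seq_along(scores) - 1L) / length(scores)
  cbind(cx + r * (scores / 100) * cos(ang),
        cy - r * (scores / 100) * sin(ang))
}

#' Export a radar-chart scorecard
#'
#' Writes a three-axis radar chart (axes: preservation, smoothness,
#' circularity; range 0-100%) as a self-contained SVG, plus the
#' underlying score table as CSV. Axis order and scaling are identical
#' for all operators on one chart.
#'
#' @param scorecards list of [make_scorecard()] results
#' @param svg_file output SVG path (NULL to skip the figure)
#' @param csv_file output CSV path (NULL to skip the table)
#' @return invisibly, the score table data.frame
#' @export
export_radar <- function(scorecards, svg_file = NULL, csv_file = NULL) {
  if (!length(scorecards)) stop("need at least one scorecard", call. = FALSE)
  tab <- do.call(rbind, lapply(scorecards, function(sc) {
    data.frame(operator = sc$operator,
               preservation = sc$scores[["preservation"]],
               smoothness = sc$scores[["smoothness"]],
               circularity = sc$scores[["circularity"]],
               n_cases = sc$n_cases)
  }))
  if (!is.null(csv_file)) write.csv(tab, csv_file, row.names = FALSE)
  if (!is.null(svg_file)) {
    W <- 480; H <- 440; cx <- W / 2; cy <- H / 2 + 10; r <- 150
    cols <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e")
    axes <- c("preservation", "smoothness", "circularity")
    svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', W, H),
             sprintf('<rect width="%d" height="%d" fill="white"/>', W, H))
    for (frac in c(0.25, 0.5, 0.75, 1)) {
      ring <- radar_points(rep(100 * frac, 3), cx, cy, r)
      svg <- c(svg, sprintf('<polygon points="%s" fill="none" stroke="#cccccc"/>',
                            paste(sprintf("%.1f,%.1f", ring[, 1], ring[, 2]),
                                  collapse = " ")))
    }
    tips <- radar_points(rep(100, 3), cx, cy, r)
    for (i in 1:3) {
      svg <- c(svg,
               sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#999999"/>',
                       cx, cy, tips[i, 1], tips[i, 2]),
               sprintf('<text x="%.1f" y="%.1f" font-size="14" text-anchor="middle">%s</text>',
                       tips[i, 1], tips[i, 2] - 8 + 24 * (tips[i, 2] > cy), axes[i]))
    }
    for (j in seq_len(nrow(tab))) {
      pts <- radar_points(as.numeric(tab[j, axes]), cx, cy, r)
      col <- cols[(j - 1L) %% length(cols) + 1L]
      svg <- c(svg,
               sprintf('<polygon points="%s" fill="%s" fill-opacity="0.25" stroke="%s" stroke-width="2"/>',
                       paste(sprintf("%.1f,%.1f", pts[, 1], pts[, 2]),
                             collapse = " "), col, col),
               sprintf('<text x="20" y="%d" font-size="13" fill="%s">%s</text>',
                       20 + 18 * j, col, tab$operator[j]))
    }
    svg <- c(svg, "</svg>")
    writeLines(svg, svg_file)
  }
  invisible(tab)
}
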