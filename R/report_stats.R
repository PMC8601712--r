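#' Compare season-by-region group means of a flight metric
#'
#' Fits the response against season and region (with interaction) with a
#' per-bird random intercept, then reports per-group estimated marginal
#' means with 95% confidence intervals and compact letter displays from
#' Tukey-adjusted pairwise comparisons: groups sharing no letter differ
#' significantly. Designs that cannot support a random intercept (a single
#' bird, or too few groups) fall back to a fixed-effects linear model with
#' a warning; a response with no variance at all yields one shared letter.
#'
#' @param metrics data frame with columns `bird_id`, `season`, `region`
#'   and the response; typically from [flight_metrics()],
#'   [ascent_table()] or an event count table. Rows with region
#'   `"unknown"` or a missing response are dropped.
#' @param response name of the response column.
#' @param config a [pipeline_config()]; `alpha` sets the letter threshold.
#' @return Object of class `"group_comparison"`: a list with `table`
#'   (group, n, estimate, lower, upper, letter), `model` (`"lmm"` or
#'   `"lm"`), `pairwise` (Tukey-adjusted contrasts) and `response`.
#' @export
compare_groups <- function(metrics, response, config = pipeline_config()) {
  need <- c("bird_id", "season", "region", response)
  missing <- setdiff(need, names(metrics))
  if (length(missing))
    stopf("metrics table lacks column(s): %s", paste(missing, collapse = ", "))
  df <- metrics[metrics$region != "unknown" & !is.na(metrics[[response]]),
                need, drop = FALSE]
  names(df)[4] <- "y"
  df$season <- factor(df$season)
  df$region <- factor(df$region)
  df$group <- interaction(df$season, df$region, sep = ":", drop = TRUE)
  counts <- table(df$group)
  if (!length(counts) || any(counts == 0))
    stopf("empty stratum in '%s' comparison: %s", response,
          paste(names(counts)[counts == 0], collapse = ", "))
  if (nlevels(df$group) < 2)
    stopf("need at least 2 season:region groups, got %d", nlevels(df$group))

  form_fix <- if (nlevels(df$season) > 1 && nlevels(df$region) > 1)
    y ~ season * region else if (nlevels(df$season) > 1) y ~ season
  else y ~ region

  if (stats::var(df$y) == 0) {
    tab <- data.frame(group = levels(df$group),
                      n = as.integer(counts[levels(df$group)]),
                      estimate = df$y[1], lower = df$y[1], upper = df$y[1],
                      letter = "a", stringsAsFactors = FALSE)
    return(structure(list(table = tab, model = "constant", pairwise = NULL,
                          response = response),
                     class = "group_comparison"))
  }

  n_birds <- length(unique(df$bird_id))
  fit <- NULL
  model <- "lmm"
  if (n_birds >= 2) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(stats::update(form_fix, . ~ . + (1 | bird_id)),
                       data = df))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    model <- "lm"
    warnf("falling back to a fixed-effects model for '%s'", response)
    fit <- stats::lm(form_fix, data = df)
  }

  spec <- if (nlevels(df$season) > 1 && nlevels(df$region) > 1)
    ~ season:region else if (nlevels(df$season) > 1) ~ season else ~ region
  emm <- emmeans::emmeans(fit, spec, level = 0.95)
  cs <- as.data.frame(summary(emm, level = 0.95))
  grp <- if ("season" %in% names(cs) && "region" %in% names(cs))
    paste(cs$season, cs$region, sep = ":")
  else as.character(cs[[1]])
  lw <- cs[[grep("lower", names(cs))[1]]]
  up <- cs[[grep("upper", names(cs))[1]]]
  pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  sig <- pairwise_decisions(pw, grp, config$alpha)
  letter <- letter_display(sig, order(cs$emmean))
  n_of <- vapply(grp, function(g) {
    parts <- strsplit(g, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2)
      sum(df$season == parts[1] & df$region == parts[2])
    else sum(df$season == g | df$region == g)
  }, numeric(1))
  tab <- data.frame(group = grp,
                    n = as.integer(n_of),
                    estimate = cs$emmean, lower = lw, upper = up,
                    letter = letter,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$group), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, model = model, pairwise = pw,
                 response = response),
            class = "group_comparison")
}

# Significance matrix from emmeans pairwise contrasts. Contrast labels are
# "a b - c d" or "(a b) - (c d)" with space-joined factor levels; group
# labels use ":".
pairwise_decisions <- function(pw, grp, alpha) {
  k <- length(grp)
  sig <- matrix(FALSE, k, k)
  for (r in seq_len(nrow(pw))) {
    sides <- strsplit(pw$contrast[r], " - ", fixed = TRUE)[[1]]
    idx <- vapply(sides, function(s) {
      s <- gsub("[()]", "", s)
      match(gsub(" ", ":", trimws(s)), grp)
    }, integer(1))
    if (anyNA(idx))
      stopf("cannot match contrast '%s' to the groups", pw$contrast[r])
    sig[idx[1], idx[2]] <- sig[idx[2], idx[1]] <- pw$p.value[r] < alpha
  }
  sig
}

# Compact letter display by insert-and-absorb: start from one set holding
# every group; each significant pair splits every set containing both;
# sets nested inside others are absorbed. Letters are ordered by the
# estimate ranking so 'a' marks the lowest mean.
letter_display <- function(sig, est_order) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    out <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        out <- c(out, list(setdiff(s, i)), list(setdiff(s, j)))
      } else out <- c(out, list(s))
    }
    keep <- rep(TRUE, length(out))       # absorb nested duplicates
    for (a in seq_along(out)) {
      for (b in seq_along(out)) {
        if (a != b && keep[b] &&
            all(out[[a]] %in% out[[b]]) &&
            (length(out[[a]]) < length(out[[b]]) || a > b))
          keep[a] <- FALSE
      }
    }
    sets <- out[keep]
  }
  rank_of <- order(est_order)            # position of each group by mean
  first <- vapply(sets, function(s) min(rank_of[s]), numeric(1))
  sets <- sets[order(first)]
  lab <- rep("", k)
  for (m in seq_along(sets)) {
    for (g in sets[[m]]) lab[g] <- paste0(lab[g], letters[m])
  }
  lab
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s model)\n", x$response, x$model))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Paired seasonal test
#'
#' Two-sided paired t-test on per-bird seasonal values (spring minus
#' autumn), with n_birds - 1 degrees of freedom. Birds lacking either
#' season are dropped; several values per bird and season are averaged
#' first. A zero-variance non-zero difference is reported as a degenerate
#' infinite statistic rather than `NaN`.
#'
#' @param values data frame with columns `bird_id`, `season` and `value`.
#' @return List: `statistic`, `df`, `p.value`, `estimate` (mean spring -
#'   autumn difference), `n_pairs`, `degenerate`.
#' @export
paired_seasonal_test <- function(values) {
  need <- c("bird_id", "season", "value")
  if (!all(need %in% names(values)))
    stopf("values must have columns bird_id, season, value")
  agg <- stats::aggregate(value ~ bird_id + season, data = values, FUN = mean)
  sp <- agg[agg$season == "spring", ]
  au <- agg[agg$season == "autumn", ]
  common <- intersect(sp$bird_id, au$bird_id)
  if (length(common) < 2)
    stopf("need at least 2 birds with both seasons, got %d", length(common))
  d <- sp$value[match(common, sp$bird_id)] -
       au$value[match(common, au$bird_id)]
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(statistic = 0, df = n - 1, p.value = 1, estimate = 0,
                  n_pairs = n, degenerate = FALSE))
    }
    return(list(statistic = sign(mean(d)) * Inf, df = n - 1, p.value = 0,
                estimate = mean(d), n_pairs = n, degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, estimate = unname(tt$estimate),
       n_pairs = n, degenerate = FALSE)
}
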