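# Balanced synthetic metrics table: n_birds per group, m flights per bird.
mk_metrics <- function(group_means, n_birds = 4, m = 6, sd = 1,
                       bird_sd = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  bid <- 0
  for (g in seq_len(nrow(group_means))) {
    for (b in seq_len(n_birds)) {
      bid <- bid + 1
      eff <- rnorm(1, 0, bird_sd)
      rows[[length(rows) + 1]] <- data.frame(
        bird_id = sprintf("bird%02d", bid),
        season = group_means$season[g], region = group_means$region[g],
        y = rnorm(m, group_means$mean[g] + eff, sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Letters must share a letter iff the Tukey-adjusted pair is not significant.
check_letters <- function(cmp, alpha = 0.05) {
  tab <- cmp$table
  pw <- cmp$pairwise
  share <- function(a, b) {
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  }
  norm <- function(x) gsub(" ", ":", x)
  for (k in seq_len(nrow(pw))) {
    gg <- strsplit(pw$contrast[k], " - ")[[1]]
    g1 <- norm(gsub("[()]", "", gg[1]))
    g2 <- norm(gsub("[()]", "", gg[2]))
    l1 <- tab$letter[tab$group == g1]
    l2 <- tab$letter[tab$group == g2]
    if (!length(l1) || !length(l2)) return(FALSE)
    sig <- pw$p.value[k] < alpha
    if (sig && share(l1, l2)) return(FALSE)
    if (!sig && !share(l1, l2)) return(FALSE)
  }
  TRUE
}

test_that("identical group distributions share a letter", {
  gm <- data.frame(season = c("autumn", "spring"), region = "Sahara",
                   mean = c(5, 5))
  cmp <- compare_groups(mk_metrics(gm, seed = 2), "y")
  expect_identical(length(unique(cmp$table$letter)), 1L)
  expect_true(check_letters(cmp))
})

test_that("groups separated by ten pooled s.d. get different letters", {
  gm <- data.frame(season = c("autumn", "spring"), region = "Sahara",
                   mean = c(0, 10))
  cmp <- compare_groups(mk_metrics(gm, sd = 1, seed = 3), "y")
  la <- cmp$table$letter[grepl("autumn", cmp$table$group)]
  ls <- cmp$table$letter[grepl("spring", cmp$table$group)]
  expect_false(any(strsplit(la, "")[[1]] %in% strsplit(ls, "")[[1]]))
  expect_true(check_letters(cmp))
  expect_identical(cmp$model, "lmm")
})

test_that("a six-cell season-by-region design yields consistent letters and CIs", {
  gm <- expand.grid(season = c("autumn", "spring"),
                    region = c("Europe", "Sahara", "subSaharan"),
                    stringsAsFactors = FALSE)
  gm$mean <- c(1, 1, 1, 8, 1, 1)   # spring Sahara stands out
  cmp <- compare_groups(mk_metrics(gm, n_birds = 3, m = 4, seed = 4), "y")
  expect_true(check_letters(cmp))
  tab <- cmp$table
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
  sahara_spring <- tab$letter[tab$group == "spring:Sahara"]
  others <- tab$letter[tab$group != "spring:Sahara"]
  expect_false(any(strsplit(sahara_spring, "")[[1]] %in%
                     unlist(strsplit(others, ""))))
})

test_that("a constant response is handled as no differences, not a crash", {
  gm <- data.frame(season = c("autumn", "spring"), region = "Sahara",
                   mean = c(3, 3))
  df <- mk_metrics(gm, sd = 0, seed = 5)
  cmp <- compare_groups(df, "y")
  expect_identical(unique(cmp$table$letter), "a")
  expect_identical(cmp$model, "constant")
})

test_that("a single bird falls back to a fixed-effects model with a warning", {
  df <- data.frame(bird_id = "solo",
                   season = rep(c("autumn", "spring"), each = 10),
                   region = "Sahara", y = c(rnorm(10, 0), rnorm(10, 6)))
  expect_warning(cmp <- compare_groups(df, "y"), "fixed-effects")
  expect_identical(cmp$model, "lm")
})

test_that("empty or single strata are named errors", {
  df <- data.frame(bird_id = c("a", "b"), season = "spring",
                   region = "Sahara", y = c(1, 2))
  expect_error(compare_groups(df, "y"), "at least 2")
  expect_error(compare_groups(df, "nope"), "lacks column")
})

test_that("zero bird-level variance reduces the LMM means to plain group means", {
  gm <- expand.grid(season = c("autumn", "spring"),
                    region = c("Europe", "Sahara"),
                    stringsAsFactors = FALSE)
  gm$mean <- c(2, 4, 3, 6)
  df <- mk_metrics(gm, n_birds = 5, m = 4, sd = 1, bird_sd = 0, seed = 6)
  cmp <- suppressWarnings(compare_groups(df, "y"))
  plain <- tapply(df$y, paste(df$season, df$region, sep = ":"), mean)
  expect_equal(cmp$table$estimate[match(names(plain), cmp$table$group)],
               as.vector(plain), tolerance = 1e-6)
})

test_that("the paired seasonal test matches its contracts and a permutation oracle", {
  same <- data.frame(bird_id = rep(letters[1:5], 2),
                     season = rep(c("autumn", "spring"), each = 5),
                     value = rep(1:5, 2))
  r <- paired_seasonal_test(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  const <- same
  const$value[const$season == "spring"] <- const$value[
    const$season == "spring"] + 2
  r2 <- paired_seasonal_test(const)
  expect_true(is.infinite(r2$statistic) && r2$statistic > 0)
  expect_true(r2$degenerate)
  expect_equal(r2$df, 4)

  set.seed(31)
  n <- 12
  d <- rnorm(n, 0.6, 1)
  df <- data.frame(bird_id = rep(sprintf("b%02d", 1:n), 2),
                   season = rep(c("autumn", "spring"), each = n),
                   value = c(rnorm(n, 5, 2), rnorm(n, 5, 2)[1:n] * 0 + 5 + d))
  df$value[df$season == "autumn"] <- 5
  r3 <- paired_seasonal_test(df)
  expect_equal(r3$df, n - 1)
  # exact sign-flip permutation distribution of the mean difference
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm_means <- abs(flips %*% d) / n
  p_perm <- mean(perm_means >= abs(mean(d)) - 1e-12)
  expect_lt(abs(r3$p.value - p_perm), 0.06)

  expect_error(paired_seasonal_test(same[c(1, 6), ]), "at least 2")
})
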