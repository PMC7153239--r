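test_that("SAM d-statistics are null on duplicated groups and exact on small designs", {
  set.seed(81)
  x <- matrix(rexp(20 * 4, 1 / 50), nrow = 20,
              dimnames = list(sprintf("f%02d", 1:20), NULL))
  xx <- cbind(x, x)   # group A content == group B content
  labels <- rep(c("A", "B"), each = 4)
  res <- sam_two_class(xx, labels, n_perm = 100, seed = 1)
  expect_true(all(res$d == 0))
  expect_false(any(res$significant))
  # C(8,4) = 70 distinct arrangements < n_perm: exact enumeration
  expect_true(attr(res, "exact_enumeration"))
  expect_equal(attr(res, "n_perm_used"), choose(8, 4))

  expect_error(sam_two_class(xx, rep("A", 8), n_perm = 100), "two groups")
  expect_error(sam_two_class(xx, labels, n_perm = 10), "n_perm")
})

test_that("SAM q-values are monotone in |d| and control the null", {
  s <- simulate_expression_matrix(n_fragments = 120, n_per_group = 15,
                                  seed = 82)
  res <- sam_two_class(s$rpm, s$labels, n_perm = 200, seed = 82)
  o <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))

  calls <- vapply(1:10, function(r) {
    s <- simulate_expression_matrix(n_fragments = 120, n_per_group = 20,
                                    seed = 500 + r)
    sum(sam_two_class(s$rpm, s$labels, n_perm = 150, seed = r)$significant)
  }, numeric(1))
  expect_equal(median(calls), 0)
})

test_that("SAM detects a single planted four-fold shift at n = 40 per group", {
  s <- simulate_expression_matrix(n_fragments = 150, n_per_group = 40,
                                  effect_frac = 1 / 150, log2fc = 2,
                                  dispersion = 0.3, seed = 83)
  res <- sam_two_class(s$rpm, s$labels, n_perm = 300, seed = 83)
  expect_lte(res$q_value[res$feature == s$effect_features], 0.01)
  expect_true(res$significant[res$feature == s$effect_features])
})

test_that("VIP scores satisfy the mean-square identity and rank planted signal first", {
  s <- simulate_expression_matrix(n_fragments = 100, n_per_group = 20,
                                  effect_frac = 0.01, log2fc = 3, seed = 84)
  res <- plsda_vip(s$rpm, s$labels)
  expect_equal(mean(res$vip^2, na.rm = TRUE), 1, tolerance = 1e-9)
  top <- res$feature[which.max(res$vip)]
  expect_equal(top, s$effect_features)
  expect_gte(max(res$vip, na.rm = TRUE), 1.5)

  # constant features are dropped with a warning
  x <- s$rpm
  x[3, ] <- 7
  expect_warning(res2 <- plsda_vip(x, s$labels), "constant")
  expect_true(is.na(res2$vip[3]))
  expect_equal(mean(res2$vip^2, na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("VIP agrees with a hand-rolled NIPALS PLS implementation", {
  # independent oracle: two-component NIPALS PLS1 on autoscaled data
  nipals_vip <- function(x, labels, ncomp = 2) {
    X <- scale(t(x))
    y <- scale(as.numeric(labels == levels(labels)[1]))
    p <- ncol(X)
    W <- matrix(0, p, ncomp); SS <- numeric(ncomp)
    Xa <- X; ya <- y
    for (a in seq_len(ncomp)) {
      w <- crossprod(Xa, ya); w <- w / sqrt(sum(w^2))
      t_ <- Xa %*% w
      q <- sum(ya * t_) / sum(t_^2)
      SS[a] <- q^2 * sum(t_^2)
      pl <- crossprod(Xa, t_) / sum(t_^2)
      Xa <- Xa - t_ %*% t(pl)
      ya <- ya - q * t_
      W[, a] <- w
    }
    sqrt(p * colSums(t(W^2) * SS) / sum(SS))
  }
  s <- simulate_expression_matrix(n_fragments = 40, n_per_group = 12,
                                  effect_frac = 0.1, log2fc = 2, seed = 85)
  y <- log2(s$rpm + 0.5)
  got <- plsda_vip(s$rpm, s$labels)$vip
  want <- nipals_vip(y, s$labels)
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
})

test_that("iDARs are the intersection of the two call sets", {
  sam <- data.frame(feature = c("a", "b", "c", "d"),
                    d = c(3, 2.5, 2, 0.1), q_value = c(0, 0, 0.005, 0.8),
                    log2_fc = c(1, 1, 1, 0),
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  attr(sam, "comparison") <- "A vs B"
  pls <- data.frame(feature = c("a", "b", "c", "d"),
                    vip = c(0.2, 2.1, 1.9, 2.5),
                    significant = c(FALSE, TRUE, TRUE, TRUE))
  attr(pls, "comparison") <- "A vs B"
  id <- intersect_idars(sam, pls)
  expect_setequal(id$feature, c("b", "c"))
  expect_true(all(id$idar))

  pls_empty <- pls; pls_empty$significant <- FALSE
  expect_equal(nrow(intersect_idars(sam, pls_empty)), 0L)

  attr(pls, "comparison") <- "A vs C"
  expect_error(intersect_idars(sam, pls), "mismatched")
})

test_that("Jaccard index matches set arithmetic", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index("a", "b"), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_message(j0 <- jaccard_index(character(0), character(0)), "empty")
  expect_equal(j0, 0)
  # independent check on random sets via membership tables
  set.seed(86)
  for (i in 1:5) {
    a <- sample(letters, sample(5:15, 1))
    b <- sample(letters, sample(5:15, 1))
    u <- unique(c(a, b))
    want <- sum(u %in% a & u %in% b) / length(u)
    expect_equal(jaccard_index(a, b), want)
  }
})

test_that("comparison grids enumerate the population and sex designs", {
  set.seed(87)
  pops <- c("CEU", "FIN", "GBR", "TSI", "YRI")
  md <- expand.grid(population = pops, sex = c("F", "M"),
                    rep = 1:6, stringsAsFactors = FALSE)
  md$sample_id <- sprintf("%s_%s_%d", md$population, md$sex, md$rep)
  # one fragment strongly shifted in YRI (both sexes), low dispersion
  n_frag <- 25
  base <- exp(runif(n_frag, log(20), log(200)))
  x <- matrix(rnbinom(n_frag * nrow(md), mu = base, size = 20),
              nrow = n_frag, dimnames = list(sprintf("f%02d", 1:n_frag),
                                             md$sample_id))
  x[1, md$population == "YRI"] <- rnbinom(sum(md$population == "YRI"),
                                          mu = base[1] * 16, size = 20)

  grid <- pairwise_comparison_grid(x, md, mode = "population",
                                   n_perm = 100, seed = 87)
  expect_equal(nrow(grid$summary), 20L)   # 10 pairs x 2 sexes
  sig <- grid$summary[grid$summary$n_idar > 0, "comparison"]
  expect_true(length(sig) > 0)
  expect_true(all(grepl("YRI", sig)))
  yri_cells <- grepl("YRI", grid$summary$comparison)
  expect_true(any(grid$summary$n_idar[yri_cells] > 0))

  grid_sex <- pairwise_comparison_grid(x, md, mode = "sex",
                                       n_perm = 100, seed = 87)
  expect_equal(nrow(grid_sex$summary), 5L)
  expect_equal(sum(grid_sex$summary$n_idar), 0L)

  # undersized groups are skipped with a warning
  md2 <- md[!(md$population == "CEU" & md$sex == "F" & md$rep > 1), ]
  warns <- capture_warnings(
    g2 <- pairwise_comparison_grid(x[, md2$sample_id], md2,
                                   mode = "population", n_perm = 100,
                                   seed = 1))
  expect_true(all(grepl("skipping", warns)))
  expect_equal(length(warns), 4L)   # CEU|F against the four other populations
  expect_equal(nrow(g2$summary), 16L)
})

test_that("Welch's t matches the textbook formula and handles degeneracy", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1)
  got <- welch_t(a, b)
  # independent implementation from the definition
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_want <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_want <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_want <- 2 * pt(-abs(t_want), df_want)
  expect_equal(got$t, t_want, tolerance = 1e-12)
  expect_equal(got$df, df_want, tolerance = 1e-12)
  expect_equal(got$p_value, p_want, tolerance = 1e-12)

  expect_equal(welch_t(c(1, 1, 1), c(1, 1, 1)),
               list(t = 0, df = 4, p_value = 1))
  sep <- welch_t(c(0, 0, 0, 1e-9), c(1, 1, 1, 1 + 1e-9))
  expect_lt(sep$p_value, 1e-6)
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("log2 fold changes recover planted effects", {
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(400, 100), log2(400.5 / 100.5))
  expect_lt(abs(log2_fold_change(4000, 1000) - 2), 0.01)

  s <- simulate_expression_matrix(n_fragments = 60, n_per_group = 40,
                                  effect_frac = 0.1, log2fc = log2(5),
                                  base_rpm_range = c(100, 1000), seed = 88)
  mean_a <- rowMeans(s$rpm[, s$labels == "A"])
  mean_b <- rowMeans(s$rpm[, s$labels == "B"])
  fc <- log2_fold_change(mean_a, mean_b)[rownames(s$rpm) %in% s$effect_features]
  # the planted effect is recovered to within 0.2 log2 units on average;
  # individual fragments scatter with the NB noise at n = 40
  expect_lt(abs(mean(fc) - log2(5)), 0.2)
  expect_true(all(abs(fc - log2(5)) < 0.5))
})
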