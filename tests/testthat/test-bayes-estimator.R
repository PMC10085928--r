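test_that("reference table counts match hand enumeration", {
  # 4 individuals aged 20-24 with v1 = 0, 4 aged 40-44 with v1 = 1
  x <- skeletal_collection(
    individual_id = paste0("i", 1:8), population = "PT", sex = "M",
    age = c(20, 21, 22, 24, 40, 41, 43, 44),
    stages = data.frame(v1 = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)))
  tab <- build_reference_table(x)
  g <- tab$grid
  expect_equal(tab$n, 8)
  expect_equal(tab$class_count[g$label == "20-24"], 4L)
  expect_equal(tab$class_count[g$label == "40-44"], 4L)
  expect_equal(sum(tab$class_count), 8L)
  m <- tab$stage_count$v1
  expect_equal(m["20-24", "0"], 4L)
  expect_equal(m["40-44", "1"], 4L)
  expect_equal(sum(m), 8L)
  expect_error(build_reference_table(x[0, ]), "empty reference")
})

test_that("missing scores are excluded from stage counts but kept in the prior", {
  x <- toy_collection()  # v3 missing for individual b, aged 23
  tab <- build_reference_table(x)
  cls <- tab$grid$label[age_class_index(23, tab$grid)]
  expect_equal(sum(tab$stage_count$v3[cls, ]),
               tab$class_count[tab$grid$label == cls] - 1L)
  # per variable and class, stage counts sum to the scored class members
  for (v in paste0("v", 1:7)) {
    scored <- tapply(!is.na(x[[v]]), age_class_index(x$age, tab$grid), sum)
    expect_equal(unname(rowSums(tab$stage_count[[v]])[as.integer(names(scored))]),
                 as.vector(scored))
  }
})

test_that("class prior is the reference fraction per class", {
  x <- skeletal_collection(
    individual_id = paste0("i", 1:6), population = "PT", sex = "M",
    age = c(20, 22, 40, 41, 42, 44),
    stages = data.frame(v1 = rep(0L, 6)))
  tab <- build_reference_table(x)
  pr <- class_prior(tab)
  g <- tab$grid
  expect_equal(pr[g$label == "20-24"], 2 / 6)
  expect_equal(pr[g$label == "40-44"], 4 / 6)
  expect_equal(sum(pr), 1)
})

test_that("stage likelihood is the (smoothed) conditional stage fraction", {
  # one class, 4 scored individuals, 3 at stage 1
  x <- skeletal_collection(
    individual_id = paste0("i", 1:4), population = "PT", sex = "M",
    age = c(40, 41, 42, 43),
    stages = data.frame(v1 = c(1L, 1L, 1L, 0L)))
  tab <- build_reference_table(x)
  g <- tab$grid
  lik <- stage_likelihood(tab, "v1", 1)
  expect_equal(lik[g$label == "40-44"], 0.75)
  # stage never observed, alpha = 0 -> 0
  expect_equal(stage_likelihood(tab, "v1", 3)[g$label == "40-44"], 0)
  # additive smoothing: (0 + 1) / (4 + 1*4) = 1/8
  expect_equal(stage_likelihood(tab, "v1", 3, smoothing = 1)[g$label == "40-44"],
               1 / 8)
  # unpopulated classes return 0 even with smoothing
  expect_equal(stage_likelihood(tab, "v1", 1, smoothing = 1)[g$label == "15-19"],
               0)
})

test_that("posterior matches brute-force enumeration on random small settings", {
  for (seed in 1:200) {
    st <- random_small_setting(seed)
    tab <- build_reference_table(st$records, st$grid, st$catalog)
    post <- posterior(st$profile, tab)
    oracle <- oracle_posterior(st$records, st$grid, st$catalog, st$profile)
    if (is.null(oracle)) {
      expect_true(is_no_estimation(post))
    } else {
      expect_false(is_no_estimation(post))
      expect_equal(post$prob, oracle, tolerance = 1e-12)
      expect_equal(sum(post$prob), 1, tolerance = 1e-9)
    }
  }
})

test_that("uninformative likelihood leaves the posterior equal to the prior", {
  # stage distribution identical in every populated class
  x <- skeletal_collection(
    individual_id = paste0("i", 1:8), population = "PT", sex = "M",
    age = c(20, 21, 22, 23, 40, 41, 42, 43),
    stages = data.frame(v1 = rep(c(0L, 0L, 1L, 1L), 2)))
  tab <- build_reference_table(x)
  post <- posterior(list(v1 = 0), tab)
  expect_equal(post$prob, class_prior(tab), tolerance = 1e-12)
})

test_that("forced support gives a point mass and its central age", {
  x <- skeletal_collection(
    individual_id = paste0("i", 1:6), population = "PT", sex = "M",
    age = c(20, 21, 40, 41, 42, 44),
    stages = data.frame(v1 = c(0L, 0L, 2L, 2L, 2L, 2L)))
  tab <- build_reference_table(x)
  post <- posterior(list(v1 = 2), tab)
  g <- tab$grid
  expect_equal(post$prob[g$label == "40-44"], 1)
  expect_equal(point_estimate(post), 42)
})

test_that("point estimate is the posterior mean of central ages", {
  g <- age_class_grid()
  prob <- numeric(nrow(g))
  prob[g$label == "20-24"] <- 0.25
  prob[g$label == "40-44"] <- 0.75
  post <- structure(list(prob = prob, grid = g), class = "age_posterior")
  expect_equal(point_estimate(post), 0.25 * 22 + 0.75 * 42)  # 37
  # convexity: estimate inside the supported central-age range
  for (seed in 1:20) {
    p <- stats::runif(nrow(g)); p <- p / sum(p)
    post$prob <- p
    est <- point_estimate(post)
    expect_gte(est, min(g$central[p > 0]))
    expect_lte(est, max(g$central[p > 0]))
  }
})

test_that("impossible profiles yield no_estimation, all-missing profiles error", {
  x <- skeletal_collection(
    individual_id = paste0("i", 1:4), population = "PT", sex = "M",
    age = c(20, 21, 40, 41),
    stages = data.frame(v1 = c(0L, 0L, 1L, 1L), v2 = c(0L, 0L, 1L, 1L)))
  tab <- build_reference_table(x)
  # v1 = 0 only co-occurs with 20-24, v2 = 1 only with 40-44: zero joint mass
  expect_true(is_no_estimation(posterior(list(v1 = 0, v2 = 1), tab)))
  expect_error(posterior(list(v1 = NA, v2 = NA), tab), "no scored variables")
  # smoothing rescues the impossible profile
  expect_false(is_no_estimation(posterior(list(v1 = 0, v2 = 1), tab,
                                          smoothing = 0.5)))
})

test_that("smoothed posterior converges to the unsmoothed one as alpha -> 0", {
  st <- random_small_setting(42)
  tab <- build_reference_table(st$records, st$grid, st$catalog)
  p0 <- posterior(st$profile, tab)
  if (!is_no_estimation(p0)) {
    p_eps <- posterior(st$profile, tab, smoothing = 1e-10)
    expect_equal(p_eps$prob, p0$prob, tolerance = 1e-6)
  }
})

test_that("translating reference ages by one class translates estimates by 5", {
  x <- skeletal_collection(
    individual_id = paste0("i", 1:9), population = "PT", sex = "M",
    age = c(20, 21, 23, 40, 41, 44, 60, 62, 63),
    stages = data.frame(v1 = c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 3L, 3L),
                        v2 = c(0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L)))
  y <- x
  y$age <- x$age + 5L
  tab_x <- build_reference_table(x)
  tab_y <- build_reference_table(y)
  for (prof in list(list(v1 = 1, v2 = 2), list(v1 = 0), list(v2 = 3))) {
    ex <- point_estimate(posterior(prof, tab_x))
    ey <- point_estimate(posterior(prof, tab_y))
    expect_equal(ey, ex + 5, tolerance = 1e-12)
  }
})

test_that("batch estimation preserves order and counts failures", {
  x <- skeletal_collection(
    individual_id = paste0("i", 1:4), population = "PT", sex = "M",
    age = c(20, 21, 40, 41),
    stages = data.frame(v1 = c(0L, 0L, 1L, 1L), v2 = c(0L, 0L, 1L, 1L)))
  tab <- build_reference_table(x)
  test <- skeletal_collection(
    individual_id = c("t1", "t2", "t3"), population = "PT", sex = "M",
    age = c(20, 40, 30),
    stages = data.frame(v1 = c(0L, 1L, 0L), v2 = c(0L, 1L, 1L)))
  est <- estimate_batch(test, tab)
  expect_equal(est$individual_id, c("t1", "t2", "t3"))
  expect_equal(est$status, c("estimated", "estimated", "no_estimation"))
  expect_true(is.na(est$point_estimate[3]))
  expect_equal(sum(est$status == "no_estimation"), 1)
})

test_that("reference tables survive a JSON round trip", {
  x <- toy_collection()
  tab <- build_reference_table(x)
  tmp <- tempfile(fileext = ".json")
  write_reference_table(tab, tmp)
  tab2 <- read_reference_table(tmp)
  expect_equal(tab2$class_count, tab$class_count)
  expect_equal(tab2$stage_count, tab$stage_count)
  expect_equal(tab2$n, tab$n)
  post1 <- posterior(list(v1 = 1, v5 = 0), tab)
  post2 <- posterior(list(v1 = 1, v5 = 0), tab2)
  expect_equal(post2$prob, post1$prob)
})
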