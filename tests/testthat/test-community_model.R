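test_that("reciprocal ranks turn summed proportions into expected shares", {
  # distinct sums -> ranks 1,2,3 -> 1, 1/2, 1/3 normalised by 11/6
  p <- reciprocal_rank_proportions(c(a = 5, b = 3, c = 1))
  expect_equal(unname(p[c("a", "b", "c")]), c(6, 3, 2) / 11)
  # single guild takes everything
  expect_equal(unname(reciprocal_rank_proportions(c(a = 2))[["a"]]), 1)
  # tied sums share the average rank (1.5 each) -> equal shares
  p2 <- reciprocal_rank_proportions(c(a = 2, b = 2))
  expect_equal(unname(p2), c(0.5, 0.5))
  # absent guilds are excluded from ranking and get 0
  p3 <- reciprocal_rank_proportions(c(a = 4, b = 0, c = 1))
  expect_equal(p3[["b"]], 0)
  expect_equal(unname(p3[c("a", "c")]), c(2, 1) / 3)
  expect_equal(sum(p3), 1)
})

test_that("tfc sampling is seeded, order-invariant, and guarded", {
  set.seed(5)
  sites <- data.frame(site_id = sprintf("s%02d", 1:12),
                      g1 = runif(12), g2 = runif(12), g3 = runif(12))
  tot <- sites$g1 + sites$g2 + sites$g3
  sites[2:4] <- sites[2:4] / tot

  p1 <- tfc_expected_proportions(sites, c("g1", "g2", "g3"), n = 10, seed = 9)
  shuffled <- sites[sample(nrow(sites)), ]
  p2 <- tfc_expected_proportions(shuffled, c("g1", "g2", "g3"), n = 10,
                                 seed = 9)
  expect_equal(unclass(p1), unclass(p2))
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_error(
    tfc_expected_proportions(sites[1:5, ], c("g1", "g2", "g3"), n = 10),
    "at least 10")
})

test_that("gower and cityblock dissimilarities follow their definitions", {
  df <- data.frame(strahler = c(2, 2), catchment_km2 = c(10, 10),
                   geology = c("calcareous", "calcareous"))
  expect_warning(d0 <- site_dissimilarity(df, metric = "gower"), "zero-range")
  expect_equal(as.numeric(d0), 0)

  # sites differing only in geology: mismatch 1 averaged over v variables
  df2 <- data.frame(strahler = c(2, 4), catchment_km2 = c(10, 50),
                    geology = c("calcareous", "siliceous"))
  df3 <- df2; df3$geology <- "calcareous"
  d_mis <- site_dissimilarity(df2, metric = "gower")
  d_same <- site_dissimilarity(df3, metric = "gower")
  expect_equal(as.numeric(d_mis) - as.numeric(d_same), 1 / 3)
  expect_true(all(as.matrix(d_mis) >= 0 & as.matrix(d_mis) <= 1))

  gp <- data.frame(g1 = c(1, 0), g2 = c(0, 1))
  expect_equal(as.numeric(site_dissimilarity(gp, metric = "cityblock")), 2)
})

test_that("pam recovers separable groups and matches exhaustive search", {
  blobs <- two_blobs()
  d <- dist(blobs$x)
  fit <- pam_cluster(d, 2)
  expect_equal(length(unique(fit$labels[blobs$labels == 1])), 1)
  expect_equal(length(unique(fit$labels[blobs$labels == 2])), 1)
  expect_error(pam_cluster(d, 1), "k must")
  expect_error(pam_cluster(d, 20), "k must")

  # 5-point 1-D instance: objective equals brute-force optimum
  d5 <- dist(matrix(c(0, 1, 2, 10, 11)))
  f5 <- pam_cluster(d5, 2)
  expect_equal(f5$objective, pam_exhaustive(d5, 2))

  # identical points: any labelling is optimal with objective 0
  d3 <- dist(matrix(c(1, 1, 1)))
  expect_equal(pam_cluster(d3, 2)$objective, 0)
})

test_that("pam objective never exceeds a random medoid set's", {
  set.seed(21)
  for (i in 1:10) {
    x <- matrix(rnorm(24), ncol = 2)
    d <- dist(x)
    m <- as.matrix(d)
    fit <- pam_cluster(d, 3)
    rnd <- sample(nrow(x), 3)
    rnd_obj <- sum(apply(m[, rnd, drop = FALSE], 1, min))
    expect_lte(fit$objective, rnd_obj + 1e-12)
  }
})

test_that("silhouette-based k selection finds clean structure", {
  blobs <- two_blobs()
  sel <- choose_k(dist(blobs$x), 2:6)
  expect_equal(sel$k, 2)
  expect_equal(nrow(sel$table), 5)
  # tight separated clusters approach silhouette 1
  expect_gt(max(sel$table$avg_silhouette), 0.95)
})

test_that("anosim matches exhaustive enumeration on small instances", {
  set.seed(31)
  for (i in 1:5) {
    x <- matrix(rnorm(12), ncol = 2)
    labels <- rep(c("A", "B"), each = 3)
    d <- dist(x)
    got <- champ_anosim(d, labels, permutations = 10000)
    want <- anosim_oracle(d, labels)
    expect_true(got$exact)
    expect_equal(got$R, want$R, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
    expect_gt(got$p_value, 0)
    expect_lte(got$p_value, 1)
  }
})

test_that("anosim hits its limiting values", {
  blobs <- two_blobs(n_per = 6)
  d <- dist(blobs$x)
  res <- champ_anosim(d, blobs$labels, permutations = 499, seed = 1)
  expect_equal(res$R, 1)            # all between > all within
  expect_lt(res$p_value, 0.05)

  # labels random relative to structureless distances -> R near 0
  set.seed(32)
  rs <- replicate(40, {
    x <- matrix(rnorm(20), ncol = 2)
    champ_anosim(dist(x), rep(1:2, each = 5), permutations = 0, seed = 1)$R
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(champ_anosim(d, rep("A", 12)), "2 groups")
})

test_that("anosim R agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  x <- matrix(rnorm(40), ncol = 2)
  labels <- rep(c("A", "B", "C", "D"), each = 5)
  d <- dist(x)
  ours <- champ_anosim(d, labels, permutations = 99, seed = 2)
  ref <- vegan::anosim(d, grouping = labels, permutations = 99)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
})

test_that("cohen's kappa follows its closed form", {
  expect_equal(cohen_kappa(matrix(c(40, 10, 10, 40), 2)), 0.6)
  expect_equal(cohen_kappa(matrix(c(5, 0, 0, 5), 2)), 1)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
})

test_that("type classifier separates thresholded classes and rejects junk", {
  set.seed(41)
  n <- 40
  sites <- data.frame(
    strahler = sample(1:6, n, TRUE),
    catchment_km2 = c(runif(n / 2, 1, 50), runif(n / 2, 500, 5000)),
    geology = sample(c("calcareous", "siliceous"), n, TRUE),
    climate_zone = sample(c("atlantic", "boreal"), n, TRUE),
    type = rep(c("small", "large"), each = n / 2))
  clf <- fit_type_classifier(sites)
  expect_s3_class(clf, "champ_classifier")
  expect_equal(clf$kappa, 1)
  expect_equal(predict_type(clf, sites), sites$type)
  expect_error(predict_type(clf, transform(sites, geology = "organic")),
               "unseen level")
  expect_error(predict_type(clf, sites[, 1:2]), "missing attribute")

  # labels independent of attributes -> kappa near 0 on a pruned tree
  sites$type <- sample(sites$type)
  clf0 <- fit_type_classifier(sites, cp = 0.2)
  expect_lt(abs(clf0$kappa), 0.3)

  expect_warning(
    fit_type_classifier(transform(sites, type = "one")), "single-class")
})

test_that("classifier JSON round-trip reproduces rpart predictions", {
  set.seed(42)
  n <- 90
  sites <- data.frame(
    strahler = sample(1:8, n, TRUE),
    catchment_km2 = exp(runif(n, 0, 9)),
    geology = sample(c("calcareous", "siliceous", "organic"), n, TRUE),
    climate_zone = sample(c("atlantic", "boreal", "alpine"), n, TRUE))
  sites$type <- with(sites, ifelse(catchment_km2 > 400, "big",
                            ifelse(geology == "organic", "org", "small")))
  clf <- fit_type_classifier(sites, cp = 0.01)
  tmp <- withr::local_tempfile(fileext = ".json")
  classifier_to_json(clf, tmp)
  reloaded <- classifier_from_json(tmp)
  expect_equal(predict_type_json(reloaded, sites), predict_type(clf, sites))
  # fresh data through the same splits
  new <- sites[sample(n, 20), ]
  new$catchment_km2 <- new$catchment_km2 * 1.01
  expect_equal(predict_type_json(reloaded, new), predict_type(clf, new))
  expect_error(predict_type_json(reloaded,
                                 transform(sites, geology = "lava")),
               "unseen")
})

test_that("missing geology fills from the nearest upstream segment", {
  sites <- data.frame(site_id = c("a", "b", "c"),
                      geology = c(NA, NA, "siliceous"),
                      stringsAsFactors = FALSE)
  up <- c(a = "b", b = "c")
  filled <- fill_geology(sites, up)
  expect_equal(filled$geology, rep("siliceous", 3))
  expect_warning(fill_geology(sites), "missing")
})

test_that("two-step typology recovers synthetic structure", {
  cfg <- sim_config(seed = 8, n_types = 4, concentration = 250,
                    separation = 0.8)
  profiles <- generate_profiles(cfg)
  sites <- generate_sites(cfg, profiles, sites_per_type = 15)
  ts <- two_step_typology(sites, cfg$guilds, k_types = 4)
  tab <- table(sites$type, ts$types)
  # every true type maps to a single dominant cluster
  expect_true(all(apply(tab, 1, max) / rowSums(tab) >= 0.9))
})
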