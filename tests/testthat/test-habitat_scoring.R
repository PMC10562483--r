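test_that("altered habitat suitability is the HP x HA product", {
  expect_identical(compute_ahs(1, 0), 0)
  expect_identical(compute_ahs(0.5, 2), 1)
  expect_identical(compute_ahs(0, 2), 0)
  expect_error(compute_ahs(0.7, 1), "HP")
  expect_error(compute_ahs(1, 3), "HA")
})

test_that("PSI sums guild preference rows", {
  hp <- hp_matrix(matrix(1, 2, 21,
                         dimnames = list(c("a", "b"), paste0("c", 1:21))))
  expect_equal(unname(compute_psi(hp, "a")), 21)
  hp2 <- tiny_hp()
  expect_equal(unname(compute_psi(hp2, "g1")), 1.5)
  expect_equal(unname(compute_psi(hp2)), c(1.5, 1.5))
  expect_error(compute_psi(hp2, "nope"), "unknown guild")
})

test_that("RHp normalises composite AHS by PSI", {
  hp <- tiny_hp(); ha <- tiny_ha()
  # HP = (1, 0.5, 0), HA(dam) = (0.5, 1.5, 2) -> (0.5 + 0.75) / 1.5
  expect_equal(compute_rhp(hp, ha, "g1", "dam"), 1.25 / 1.5)
  # all-1 HA row leaves habitat unchanged; all-0 removes it
  expect_equal(unname(rhp_table(hp, ha)[, "ford"]), c(1, 1))
  expect_equal(unname(rhp_table(hp, ha)[, "weir"]), c(0, 0))
  # PSI = 0 is an explicit error, never a silent division by zero
  hp0 <- hp_matrix(matrix(c(1, 0, 1, 0, 0, 0), 2, byrow = TRUE,
                          dimnames = list(c("g1", "gz"), c("c1", "c2", "c3"))))
  expect_error(rhp_table(hp0, ha), "no habitat preferences")
})

test_that("RHp matches an elementwise-loop oracle on random matrices", {
  set.seed(101)
  for (i in 1:30) {
    m <- random_matrices(sample(2:4, 1), sample(2:6, 1))
    tab <- rhp_table(m$hp, m$ha)
    for (g in rownames(m$hp)) for (b in rownames(m$ha)) {
      expect_equal(tab[g, b], rhp_loop_oracle(m$hp, m$ha, g, b),
                   tolerance = 1e-12)
    }
    expect_true(all(tab >= 0 & tab <= 2))
  }
})

test_that("raising an HA cell never decreases RHp where HP is positive", {
  set.seed(102)
  for (i in 1:15) {
    m <- random_matrices(3, 5)
    ha <- unclass(m$ha)
    j <- sample(5, 1); b <- sample(rownames(ha), 1)
    if (ha[b, j] == 2) next
    ha2 <- ha
    ha2[b, j] <- min(2, ha[b, j] + 0.5)
    before <- rhp_table(m$hp, ha_matrix(ha))[, b]
    after <- rhp_table(m$hp, ha_matrix(ha2))[, b]
    expect_true(all(after - before >= -1e-12))
    pos <- unclass(m$hp)[, j] > 0
    expect_true(all(after[pos] - before[pos] > 0))
  }
})

test_that("macrohabitat sensitivity is the profile-weighted PSI share", {
  hp <- hp_matrix(matrix(rep(c(1, 0), each = 21), 2, 21, byrow = TRUE,
                         dimnames = list(c("spec", "gen"), paste0("c", 1:21))))
  all_spec <- champ_profile(c(spec = 1, gen = 0))
  expect_equal(compute_sensitivity(hp, all_spec)$sensitivity, 100)
  expect_equal(as.character(compute_sensitivity(hp, all_spec)$class), "highest")
  all_gen <- champ_profile(c(spec = 0, gen = 1))
  expect_equal(compute_sensitivity(hp, all_gen)$sensitivity, 0)
  expect_equal(as.character(compute_sensitivity(hp, all_gen)$class), "lowest")
  half <- champ_profile(c(spec = 0.5, gen = 0.5))
  s <- compute_sensitivity(hp, half)
  expect_equal(s$sensitivity, 50)
  expect_equal(as.character(s$class), "moderate")
})

test_that("sensitivity lies between min and max guild PSI share", {
  set.seed(103)
  for (i in 1:15) {
    m <- random_matrices(4, 6)
    w <- rgamma(4, 1); w <- w / sum(w)
    pf <- champ_profile(stats::setNames(w, rownames(m$hp)))
    s <- compute_sensitivity(m$hp, pf)$sensitivity
    share <- 100 * compute_psi(m$hp) / 6
    expect_gte(s, min(share) - 1e-9)
    expect_lte(s, max(share) + 1e-9)
  }
})

test_that("sensitivity classes use [45, 55] as the moderate band", {
  expect_equal(as.character(classify_sensitivity(c(44.999, 45, 55, 55.001))),
               c("lowest", "moderate", "moderate", "highest"))
})

test_that("wRHp is the profile-weighted RHp, classified by severity", {
  hp <- tiny_hp(); ha <- tiny_ha()
  tab <- rhp_table(hp, ha)
  single <- champ_profile(c(g1 = 1, g2 = 0))
  w <- compute_wrhp(tab, single, "dam")
  expect_equal(w$wRHp_percent, 100 * tab["g1", "dam"])
  # no-change barrier -> 100%, low alteration
  w_ford <- compute_wrhp(tab, champ_profile(c(g1 = 0.3, g2 = 0.7)), "ford")
  expect_equal(w_ford$wRHp_percent, 100)
  expect_equal(as.character(w_ford$severity), "low")
  # hand-weighted case: 0.6 * 0.2 + 0.4 * 0.9 = 0.48 -> major
  tab2 <- structure(matrix(c(0.2, 0.9), 2, 1,
                           dimnames = list(c("g1", "g2"), "dam")),
                    class = c("rhp_table", "matrix", "array"))
  w2 <- compute_wrhp(tab2, champ_profile(c(g1 = 0.6, g2 = 0.4)))
  expect_equal(w2$wRHp_percent, 48)
  expect_equal(as.character(w2$severity), "major")
  expect_error(compute_wrhp(tab, champ_profile(c(gx = 1))), "missing")
})

test_that("wRHp is a convex combination of guild RHp values", {
  set.seed(104)
  for (i in 1:15) {
    m <- random_matrices(4, 5)
    tab <- rhp_table(m$hp, m$ha)
    w <- rgamma(4, 1); w <- w / sum(w)
    pf <- champ_profile(stats::setNames(w, rownames(tab)))
    res <- compute_wrhp(tab, pf)
    for (k in seq_len(nrow(res))) {
      col <- tab[, res$barrier_type[k]]
      expect_gte(res$wRHp_percent[k] / 100, min(col) - 1e-12)
      expect_lte(res$wRHp_percent[k] / 100, max(col) + 1e-12)
    }
  }
})

test_that("severity bins follow the printed boundaries, half-open above", {
  x <- c(0, 25, 25.0001, 50, 50.0001, 75, 75.0001, 90, 90.0001, 120, 200)
  expect_equal(as.character(classify_alteration(x)),
               c("severe", "severe", "major", "major", "substantial",
                 "substantial", "moderate", "moderate", "low", "low", "low"))
  expect_error(classify_alteration(-1), "outside")
  expect_error(classify_alteration(201), "outside")
})

test_that("wrhp_grid produces the tidy round-trippable layout", {
  hp <- read_hp(fixture_path("hp_default.csv"))
  ha <- read_ha(fixture_path("ha_default.csv"))
  profiles <- read_profiles(fixture_path("profiles_synthetic.csv"))
  g <- wrhp_grid(rhp_table(hp, ha), profiles)
  expect_equal(nrow(g), length(profiles) * 6)
  expect_true(all(g$wRHp_percent >= 0 & g$wRHp_percent <= 200))
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(g, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$wRHp_percent, g$wRHp_percent)
})
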