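test_that("the landscape partitions species exclusively over patch types", {
  p <- tiny_params()
  w <- generate_world(p, seed = 11)
  expect_equal(nrow(w$types), 50)
  expect_true(all(w$types$Q >= 0)) # negative quality draws are redrawn
  expect_true(all(w$types$S %in% 1:4))
  expect_true(all(w$types$H > 0))
  # every species belongs to exactly one patch type
  expect_equal(sort(w$patch_types$type), 1:50)
  expect_equal(unname(table(w$patch_types$patch_type)), rep(5L, 10),
               ignore_attr = TRUE)
  expect_equal(nrow(w$patches), 50)
  expect_equal(nrow(w$items), 50 * 20)
  expect_true(all(w$items$available))
  # items of a patch only carry species from that patch's patch type, and
  # at most types_per_patch distinct ones
  pool <- split(w$patch_types$type, w$patch_types$patch_type)
  for (pa in sample(w$patches$patch, 10)) {
    pt <- w$patches$patch_type[w$patches$patch == pa]
    ty <- unique(w$items$type[w$items$patch == pa])
    expect_true(all(ty %in% pool[[pt]]))
    expect_lte(length(ty), p$types_per_patch)
  }
  # items lie within a patch radius of their patch centre
  i <- w$items[sample.int(nrow(w$items), 200), ]
  d <- torus_distance(i$x, i$y,
                      w$patches$x[i$patch], w$patches$y[i$patch], w$side)
  expect_true(all(d <= p$patch_diameter / 2 + 1e-9))
})

test_that("pure patches hold a single species; random worlds none", {
  p <- tiny_params(env_type = "pure")
  w <- generate_world(p, seed = 2)
  per_patch <- tapply(w$items$type, w$items$patch,
                      function(x) length(unique(x)))
  expect_true(all(per_patch == 1))
  wr <- generate_world(tiny_params(env_type = "random"), seed = 3)
  expect_equal(nrow(wr$patches), 0)
  expect_true(all(is.na(wr$items$patch)))
  expect_equal(nrow(wr$items), 50 * 20)
})

test_that("clamped quality draws are allowed as an alternative", {
  p <- tiny_params(negative_q = "clamp", Q_mean = 0, Q_sd = 0.1)
  w <- generate_world(p, seed = 4)
  expect_true(all(w$types$Q >= 0))
  expect_gt(mean(w$types$Q == 0), 0.2) # the clamp creates an atom at zero
})

test_that("regrowth restores consumed items in place at year boundaries", {
  p <- tiny_params()
  w <- generate_world(p, seed = 5)
  eaten <- sample.int(nrow(w$items), 10)
  w$items$available[eaten] <- FALSE
  pos <- w$items[eaten, c("x", "y", "type")]
  w2 <- regrow(w, t = year_minutes(p), params = p)
  expect_true(all(w2$items$available))
  expect_equal(w2$items[eaten, c("x", "y", "type")], pos)
  # nothing consumed: identity
  expect_equal(regrow(w2, t = 0, params = p), w2)
  expect_error(regrow(w, t = 1234, params = p), "year boundar")
})

test_that("environmental change replaces one living species at a time", {
  p <- tiny_params(EC = 1)
  w <- generate_world(p, seed = 6)
  # a zero rate changes nothing
  w0 <- generate_world(tiny_params(EC = 0), seed = 6)
  expect_equal(simulate_environmental_change(w0, tiny_params(EC = 0), 2),
               w0)
  # probability EC * dt / year-minutes reaches 1 for dt = one year
  set.seed(7)
  w1 <- environmental_change_step(w, p, dt = year_minutes(p))
  expect_equal(w1$n_replacements, 1L)
  expect_equal(nrow(w1$types), 51)
  retired <- which(!w1$types$alive)
  expect_length(retired, 1)
  expect_true(w1$types$alive[51])
  # every item of the retired species now carries the new one
  expect_false(any(w1$items$type == retired))
  expect_equal(sum(w1$items$type == 51),
               sum(w$items$type == retired))
  # the new species takes the retired one's slot in the patch-type map
  expect_equal(sum(w1$patch_types$type == 51), 1)
  expect_equal(sort(unique(c(w1$patch_types$type))),
               sort(c(setdiff(1:50, retired), 51)))
})

test_that("quality-change mode preserves identities and memory keys", {
  p <- tiny_params(EC = 1, change_mode = "quality_change")
  w <- generate_world(p, seed = 8)
  q0 <- w$types$Q
  set.seed(9)
  w1 <- environmental_change_step(w, p, dt = year_minutes(p))
  expect_equal(nrow(w1$types), 50)
  expect_true(all(w1$types$alive))
  expect_equal(sum(w1$types$Q != q0), 1)
  expect_equal(w1$items$type, w$items$type)
  expect_equal(w1$n_replacements, 1L)
})

test_that("realised replacement counts match the nominal rate", {
  # binomial process: total over Y years within 3 sd of EC * Y
  for (EC in c(1, 10)) {
    p <- tiny_params(EC = EC, change_mode = "quality_change")
    w <- generate_world(p, seed = EC)
    years <- 6
    set.seed(100 + EC)
    w2 <- simulate_environmental_change(w, p, years = years)
    expect_lt(abs(w2$n_replacements - EC * years), 3 * sqrt(EC * years) + 1)
  }
})

test_that("torus distances use the minimum image", {
  expect_equal(torus_distance(1, 1, 99, 1, 100), 2)
  expect_equal(torus_distance(0, 0, 50, 0, 100), 50)
  expect_equal(torus_distance(2, 98, 98, 2, 100), sqrt(32))
})

test_that("world snapshots serialise to CSV tables", {
  w <- generate_world(tiny_params(), seed = 10)
  dir <- tempfile()
  write_world_snapshot(w, dir)
  expect_true(all(file.exists(file.path(dir, c("types.csv", "patches.csv",
                                               "items.csv")))))
  back <- utils::read.csv(file.path(dir, "types.csv"))
  expect_equal(back$Q, w$types$Q)
  unlink(dir, recursive = TRUE)
})
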