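test_that("atom_distance is exact on constructed cases", {
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  toy <- toy_fixture()
  og <- select_atom(toy$model, "A", 68, "OG")
  nd1 <- select_atom(toy$model, "A", 69, "ND1")
  expect_equal(atom_distance(og, nd1), 2.55, tolerance = 1e-9)
})

test_that("atom_distance is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  for (i in 1:50) {
    p <- matrix(rnorm(9, sd = 5), 3, 3)
    dab <- atom_distance(p[1, ], p[2, ])
    expect_identical(dab, atom_distance(p[2, ], p[1, ]))
    expect_lte(dab, atom_distance(p[1, ], p[3, ]) +
                 atom_distance(p[3, ], p[2, ]) + 1e-12)
  }
})

test_that("ring geometry of a planar hexagon: centroid at center, normal on z", {
  hex <- hexagon_res(center = c(0, 0, 0))
  g <- ring_geometry(hex)
  expect_equal(g$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(g$normal[3]), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(g$normal^2)), 1, tolerance = 1e-12)
})

test_that("ring geometry transforms covariantly under rigid motion", {
  set.seed(21)
  hex <- hexagon_res(center = c(1, -2, 3))
  g0 <- ring_geometry(hex)
  for (i in 1:10) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 10)
    hex2 <- hex
    xyz <- apply_rigid(as.matrix(hex[, c("x", "y", "z")]), rot, shift)
    hex2$x <- xyz[, 1]; hex2$y <- xyz[, 2]; hex2$z <- xyz[, 3]
    g1 <- ring_geometry(hex2)
    expect_equal(g1$centroid, as.numeric(rot %*% g0$centroid + shift),
                 tolerance = 1e-9)
    # normal defined up to sign
    expect_equal(abs(sum(g1$normal * (rot %*% g0$normal))), 1,
                 tolerance = 1e-9)
  }
})

test_that("incomplete rings raise an error naming the missing atom", {
  hex <- hexagon_res()
  expect_error(ring_geometry(hex[hex$atom_name != "CZ", ]),
               regexp = "CZ", class = "wafer_error_incomplete_ring")
})

test_that("stacking classification distinguishes parallel, T-shaped, none", {
  base <- hexagon_res(center = c(0, 0, 0), seq_id = 1)
  par <- hexagon_res(center = c(0, 0, 3.6), seq_id = 2)
  s <- detect_stacking(base, par)
  expect_equal(s$class, "parallel")
  expect_equal(s$distance, 3.6, tolerance = 1e-12)
  expect_equal(s$angle, 0, tolerance = 1e-6)
  expect_equal(s$offset, 0, tolerance = 1e-9)

  far <- hexagon_res(center = c(0, 0, 12), seq_id = 3)
  expect_equal(detect_stacking(base, far)$class, "none")

  # perpendicular ring 5 A away: T-shaped
  tsh <- hexagon_res(center = c(0, 0, 0), seq_id = 4)
  xyz <- as.matrix(tsh[, c("x", "y", "z")])
  rot90 <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  xyz <- xyz %*% t(rot90)
  xyz[, 3] <- xyz[, 3] + 5.0
  tsh$x <- xyz[, 1]; tsh$y <- xyz[, 2]; tsh$z <- xyz[, 3]
  st <- detect_stacking(base, tsh)
  expect_equal(st$class, "t-shaped")
  expect_equal(st$angle, 90, tolerance = 1e-6)
})

test_that("stacking geometry is symmetric in its arguments", {
  set.seed(31)
  for (i in 1:10) {
    a <- hexagon_res(center = rnorm(3, sd = 2), seq_id = 1)
    b <- hexagon_res(center = rnorm(3, sd = 2) + c(0, 0, 3.5), seq_id = 2)
    rot <- random_rotation()
    xyz <- apply_rigid(as.matrix(b[, c("x", "y", "z")]), rot, rnorm(3))
    b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    s1 <- detect_stacking(a, b)
    s2 <- detect_stacking(b, a)
    expect_equal(s1$distance, s2$distance, tolerance = 1e-12)
    expect_equal(s1$angle, s2$angle, tolerance = 1e-9)
  }
})

test_that("interplanar angle is invariant under rigid motion of the complex", {
  set.seed(41)
  a <- hexagon_res(center = c(0, 0, 0), seq_id = 1)
  b <- hexagon_res(center = c(1, 0.5, 3.4), seq_id = 2)
  s0 <- detect_stacking(a, b)
  for (i in 1:5) {
    rot <- random_rotation(); shift <- rnorm(3, sd = 20)
    move <- function(df) {
      xyz <- apply_rigid(as.matrix(df[, c("x", "y", "z")]), rot, shift)
      df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]; df
    }
    s1 <- detect_stacking(move(a), move(b))
    # acos conditioning near parallel limits angle precision to ~sqrt(eps)
    expect_lt(abs(s1$angle - s0$angle), 1e-4)
    expect_equal(s1$distance, s0$distance, tolerance = 1e-9)
    expect_lt(abs(s1$offset - s0$offset), 1e-6)
  }
})

test_that("polar contacts: planted distances, sorting, element filtering", {
  toy <- toy_fixture()
  a <- toy$model$atoms
  ser68 <- a[a$chain_id == "A" & a$seq_id == 68 &
               a$atom_name %in% c("OG", "N"), ]
  gsh <- a[a$chain_id == "A" & a$is_hetero &
             a$atom_name %in% c("O11", "O12"), ]
  cc <- polar_contacts(ser68, gsh, 3.5)
  expect_gte(nrow(cc), 2)
  expect_equal(cc$distance, sort(cc$distance))
  og_o11 <- cc[cc$atom_a == "OG" & cc$atom_b == "O11", ]
  expect_equal(og_o11$distance, 2.9, tolerance = 1e-9)
  n_o11 <- cc[cc$atom_a == "N" & cc$atom_b == "O11", ]
  expect_equal(n_o11$distance, 3.0, tolerance = 1e-9)
  # every min distance from {OG, N} within the hydrogen-bond window
  mins <- tapply(cc$distance, cc$atom_a, min)
  expect_true(all(mins >= 2.5 & mins <= 3.3))

  # far-apart groups yield nothing; carbons never appear
  far <- gsh; far$x <- far$x + 100
  expect_equal(nrow(polar_contacts(ser68, far, 3.5)), 0)
  cb <- a[a$chain_id == "A" & a$seq_id == 68 & a$atom_name == "CB", ]
  expect_equal(nrow(polar_contacts(cb, gsh, 10)), 0)
})

test_that("polar contacts equal a brute-force scan on random groups", {
  set.seed(51)
  for (i in 1:10) {
    ga <- random_group(sample(5:40, 1), chain = "A")
    gb <- random_group(sample(5:40, 1), chain = "B")
    cutoff <- runif(1, 2, 8)
    fast <- polar_contacts(ga, gb, cutoff)
    slow <- brute_polar(ga, gb, cutoff)
    n_slow <- if (is.null(slow)) 0L else nrow(slow)
    expect_equal(nrow(fast), n_slow)
    if (n_slow > 0) {
      key_fast <- sort(paste(fast$atom_a, fast$atom_b,
                             round(fast$distance, 9)))
      key_slow <- sort(paste(slow$atom_a, slow$atom_b,
                             round(slow$distance, 9)))
      expect_identical(key_fast, key_slow)
    }
  }
})
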