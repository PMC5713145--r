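test_that("d-spacing matches closed forms", {
  cubic <- crystal_cell(10, 10, 10)
  expect_equal(d_spacing(1, 0, 0, cubic), 10)
  expect_equal(d_spacing(1, 1, 1, cubic), 10 / sqrt(3))
  tet <- crystal_cell(58.07, 58.07, 150.56)
  expect_equal(d_spacing(0, 0, 2, tet), 75.28)
  # general metric-tensor form vs orthorhombic closed form
  set.seed(1)
  for (i in 1:20) {
    cl <- crystal_cell(runif(1, 5, 100), runif(1, 5, 100), runif(1, 5, 100))
    h <- sample(-5:5, 1); k <- sample(-5:5, 1); l <- sample(-5:5, 1)
    if (h == 0 && k == 0 && l == 0) next
    expect_equal(d_spacing(h, k, l, cl),
                 1 / sqrt((h / cl$a)^2 + (k / cl$b)^2 + (l / cl$c)^2))
  }
  expect_error(d_spacing(0, 0, 0, cubic), class = "mx_validation_error")
})

test_that("unit-cell compatibility uses the 1% pair-mean rule", {
  a <- crystal_cell(58.07, 58.07, 150.56)
  expect_true(cells_compatible(a, a))
  expect_true(cells_compatible(a, crystal_cell(58.09, 58.07, 150.56))) # 0.03%
  expect_false(cells_compatible(a, crystal_cell(59.00, 58.07, 150.56))) # 1.59%
  expect_false(cells_compatible(crystal_cell(10, 10, 10, gamma = 90),
                                crystal_cell(10, 10, 10, gamma = 92)))
})

test_that("cell validation rejects bad parameters", {
  expect_error(crystal_cell(-1, 10, 10), class = "mx_validation_error")
  expect_error(crystal_cell(10, 10, 10, alpha = 181),
               class = "mx_validation_error")
  expect_error(space_group(47), class = "mx_validation_error")
})

test_that("ASU reduction is constant on orbits and idempotent", {
  set.seed(7)
  for (sgn in c(1, 19, 92, 94, 96)) {
    sg <- space_group(sgn)
    for (rep in 1:10) {
      hkl <- sample(c(-6:-1, 1:6), 3, replace = TRUE)
      # brute-force orbit: all rotational equivalents and Friedel mates
      orbit <- unique(do.call(rbind, lapply(sg$rot, function(R)
        rbind(hkl %*% R, -hkl %*% R))))
      keys <- reduce_to_asu(orbit[, 1], orbit[, 2], orbit[, 3], sg)
      expect_equal(nrow(unique(keys[, c("h", "k", "l")])), 1)
      # idempotence
      again <- reduce_to_asu(keys$h[1], keys$k[1], keys$l[1], sg)
      expect_equal(again[, c("h", "k", "l")], keys[1, c("h", "k", "l")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("Friedel handling follows the anomalous flag", {
  # P1, Friedel's law true: mates share a key
  k <- reduce_to_asu(c(1, -1), c(2, -2), c(3, -3), space_group(1))
  expect_equal(k$h[1], k$h[2])
  expect_equal(k$l[1], k$l[2])
  # anomalous on: same base indices, opposite parity
  k96 <- reduce_to_asu(c(1, -1), c(2, -2), c(3, -3), space_group(96),
                       anomalous = TRUE)
  expect_equal(k96[1, c("h", "k", "l")], k96[2, c("h", "k", "l")],
               ignore_attr = TRUE)
  expect_setequal(k96$friedel, c("plus", "minus"))
  # centric reflections never get a minus parity (here: hk0 zone of 422)
  kc <- reduce_to_asu(c(1, -1), c(2, -2), c(0, 0), space_group(96),
                      anomalous = TRUE)
  expect_true(all(kc$centric))
  expect_true(all(kc$friedel == "plus"))
})

test_that("unique-reflection count equals exhaustive enumeration in P1", {
  cubic <- crystal_cell(10, 10, 10)
  # oracle: enumerate |h|,|k|,|l| <= 2, keep d >= 5, pair Friedel mates by hand
  grid <- expand.grid(h = -2:2, k = -2:2, l = -2:2)
  grid <- grid[rowSums(abs(grid)) > 0, ]
  d <- 10 / sqrt(grid$h^2 + grid$k^2 + grid$l^2)
  grid <- grid[d >= 5, ]
  canon <- apply(grid, 1, function(v) {
    m <- rbind(v, -v)
    paste(m[order(m[, 1], m[, 2], m[, 3], decreasing = TRUE)[1], ],
          collapse = ",")
  })
  expect_equal(count_unique(cubic, 1, 5), length(unique(canon)))
  expect_equal(count_unique(cubic, 1, 5, anomalous = TRUE), nrow(grid))
})

test_that("unique counts are monotone in d_min and the anomalous flag", {
  cl <- crystal_cell(20, 25, 30)
  for (sgn in c(1, 19, 96)) {
    n2 <- count_unique(cl, sgn, 2)
    n4 <- count_unique(cl, sgn, 4)
    expect_lte(n4, n2)
    expect_gte(count_unique(cl, sgn, 2, anomalous = TRUE), n2)
  }
})

test_that("systematic absences follow the screw-axis rules", {
  # P212121: odd axial reflections absent
  expect_true(mxclust:::is_absent(rbind(c(1, 0, 0)), space_group(19)))
  expect_false(mxclust:::is_absent(rbind(c(2, 0, 0)), space_group(19)))
  expect_true(mxclust:::is_absent(rbind(c(0, 3, 0)), space_group(19)))
  expect_false(mxclust:::is_absent(rbind(c(1, 2, 3)), space_group(19)))
  # P41212: 00l present only for l = 4n; h00 absent for odd h
  expect_true(mxclust:::is_absent(rbind(c(0, 0, 2)), space_group(92)))
  expect_false(mxclust:::is_absent(rbind(c(0, 0, 4)), space_group(92)))
  expect_true(mxclust:::is_absent(rbind(c(1, 0, 0)), space_group(92)))
  # P43212 shares the 00l = 4n rule
  expect_true(mxclust:::is_absent(rbind(c(0, 0, 6)), space_group(96)))
  expect_false(mxclust:::is_absent(rbind(c(0, 0, 8)), space_group(96)))
})

test_that("space-group tables are valid operator sets", {
  for (sgn in c(1, 19, 92, 94, 96)) {
    sg <- space_group(sgn)
    dets <- vapply(sg$rot, det, numeric(1))
    expect_true(all(abs(abs(dets) - 1) < 1e-12))
    # closure of the rotation parts
    reps <- unique(vapply(sg$rot, function(R) paste(R, collapse = ","),
                          character(1)))
    prods <- outer(seq_along(sg$rot), seq_along(sg$rot),
                   Vectorize(function(i, j)
                     paste(sg$rot[[i]] %*% sg$rot[[j]], collapse = ",")))
    expect_true(all(prods %in% reps))
  }
})
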