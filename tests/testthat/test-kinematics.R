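test_that("displacement gradients are exact on affine fields", {
  u0 <- make_displacement_field("translation", nx = 12, ny = 10)
  g0 <- displacement_gradient(u0)
  expect_true(all(abs(unlist(g0)) < 1e-12))

  s <- 2.6
  X <- matrix(rep((0:11) * s, each = 10), 10, 12)
  u <- displacement_field(0.1 * X, 0 * X, pixel_size = s)
  g <- displacement_gradient(u)
  expect_equal(g$dux_dx, matrix(0.1, 10, 12), tolerance = 1e-12)
  expect_true(all(abs(g$duy_dx) < 1e-12))
})

test_that("displacement gradients match a loop-based stencil oracle", {
  set.seed(8)
  nx <- 9; ny <- 7; s <- 2
  ux <- matrix(rnorm(nx * ny), ny, nx)
  uy <- matrix(rnorm(nx * ny), ny, nx)
  g <- displacement_gradient(displacement_field(ux, uy, pixel_size = s))
  oracle <- matrix(NA_real_, ny, nx)
  for (j in 1:ny) for (i in 1:nx) {
    if (i == 1) oracle[j, i] <- (ux[j, 2] - ux[j, 1]) / s
    else if (i == nx) oracle[j, i] <- (ux[j, nx] - ux[j, nx - 1]) / s
    else oracle[j, i] <- (ux[j, i + 1] - ux[j, i - 1]) / (2 * s)
  }
  expect_equal(g$dux_dx, oracle, tolerance = 1e-12)
})

test_that("deformation gradients give the analytic Jacobians", {
  for (kind in c("zero", "translation", "dilation", "shear", "radial")) {
    u <- make_displacement_field(kind, nx = 20, ny = 20)
    dg <- deformation_gradient(displacement_gradient(u))
    det_true <- attr(u, "detF")
    interior <- cbind(rep(3:18, times = 16), rep(3:18, each = 16))
    tol <- if (kind == "radial") 1e-4 else 1e-12
    expect_equal(dg$detF[interior], det_true[interior], tolerance = tol)
  }
  u <- make_displacement_field("dilation", s = 0.1)
  expect_equal(deformation_gradient(displacement_gradient(u))$detF[5, 5], 1.21,
               tolerance = 1e-12)
  u <- make_displacement_field("shear", gamma = 0.7)
  expect_equal(deformation_gradient(displacement_gradient(u))$detF[5, 5], 1,
               tolerance = 1e-12)
})

test_that("strain tensors are symmetric and vanish for small rigid rotations", {
  th <- 1e-3
  nx <- 15; ny <- 15; s <- 1
  X <- matrix(rep((0:(nx - 1)) * s, each = ny), ny, nx)
  Y <- matrix(rep((0:(ny - 1)) * s, times = nx), ny, nx)
  ux <- (cos(th) - 1) * X - sin(th) * Y
  uy <- sin(th) * X + (cos(th) - 1) * Y
  eps <- strain_tensor(displacement_gradient(displacement_field(ux, uy, s)))
  expect_lt(max(abs(eps$eps_xx)), th^2)
  expect_lt(max(abs(eps$eps_xy)), th^2)

  u1 <- displacement_field(0.05 * X, 0 * X, s)
  e1 <- strain_tensor(displacement_gradient(u1))
  expect_equal(e1$eps_xx[3, 3], 0.05, tolerance = 1e-12)
  expect_equal(e1$eps_yy[3, 3], 0, tolerance = 1e-12)

  u2 <- displacement_field(0.3 * Y, 0 * X, s)
  e2 <- strain_tensor(displacement_gradient(u2))
  expect_equal(e2$eps_xy[3, 3], 0.15, tolerance = 1e-12)
})

test_that("the measured density ratio is the Jacobian determinant", {
  u <- make_displacement_field("zero")
  expect_true(all(density_ratio_from_displacement(u)$xi == 1))
  u <- make_displacement_field("dilation", s = 0.1)
  m <- density_ratio_from_displacement(u)
  expect_equal(m$xi[4, 4], 1.21, tolerance = 1e-12)
  expect_gt(min(m$xi), 1)   # spreading: earlier/later ratio above one
  u <- make_displacement_field("shear", gamma = 0.5)
  expect_equal(max(abs(density_ratio_from_displacement(u)$xi - 1)), 0,
               tolerance = 1e-12)
})

test_that("computational ratios track frame pairs and the tissue mask", {
  g <- sim_grid(0, 0, 10, 16, 16)
  # density halves every frame; tissue shrinks over time
  ser <- fake_series(g, times = (0:10) / 12,
                     rho_fun = function(x, y, j) 4000 * 2^(-(j - 1)),
                     inside_fun = function(x, y, j) sqrt((x - 75)^2 + (y - 75)^2) < 80 - 5 * j)
  m1 <- computational_density_ratio(ser, 1, 1)
  expect_true(all(m1$xi[m1$mask] == 2))
  m0 <- computational_density_ratio(ser, 3, 0 + 5)
  expect_true(all(m0$xi[m0$mask] == 2^5))
  # a node inside at j but outside at j+delta is off-mask with the 0 sentinel
  ring <- ser$inside[[1]] & !ser$inside[[6]]
  expect_true(any(ring))
  m <- computational_density_ratio(ser, 1, 5)
  expect_true(all(m$xi[ring] == 0))
  expect_true(all(!m$mask[ring]))
  expect_error(computational_density_ratio(ser, 9, 5), "out of range")
})

test_that("ratios compose multiplicatively across frame pairs", {
  g <- sim_grid(0, 0, 10, 16, 16)
  ser <- fake_series(g, times = (0:10) / 12,
                     rho_fun = function(x, y, j) 4000 * 1.07^(-(j - 1)),
                     inside_fun = function(x, y, j) TRUE)
  m_a <- computational_density_ratio(ser, 1, 3)
  m_b <- computational_density_ratio(ser, 4, 3)
  m_ab <- computational_density_ratio(ser, 1, 6)
  expect_equal(m_ab$xi, m_a$xi * m_b$xi, tolerance = 1e-10)
})

test_that("bilinear interpolation onto the grid is exact for bilinear fields", {
  g <- sim_grid(0, 0, 20, 16, 16)
  # pixel grid covering the computational grid, offset origin
  s <- 12
  npx <- 30; npy <- 30
  px0 <- -10; py0 <- -10
  X <- matrix(rep(px0 + (0:(npx - 1)) * s, each = npy), npy, npx)
  Y <- matrix(rep(py0 + (0:(npy - 1)) * s, times = npx), npy, npx)
  f <- 1 + 0.001 * X + 0.002 * Y
  map <- density_ratio_map(f, x0 = px0, y0 = py0, spacing = s)
  onto <- interpolate_ratio_to_grid(map, g)
  target <- outer(g$ys, g$xs, function(y, x) 1 + 0.001 * x + 0.002 * y)
  expect_equal(onto$xi, target, tolerance = 1e-12)
  expect_true(all(onto$mask))

  cmap <- density_ratio_map(matrix(3.3, npy, npx), x0 = px0, y0 = py0, spacing = s)
  expect_true(all(abs(interpolate_ratio_to_grid(cmap, g)$xi - 3.3) < 1e-12))
})

test_that("a node is masked whenever any surrounding pixel is masked", {
  g <- sim_grid(0, 0, 20, 16, 16)
  s <- 12; npx <- 30; npy <- 30; px0 <- -10; py0 <- -10
  mask <- matrix(TRUE, npy, npx)
  mask[14, 13] <- FALSE
  map <- density_ratio_map(matrix(2, npy, npx), mask,
                           x0 = px0, y0 = py0, spacing = s)
  onto <- interpolate_ratio_to_grid(map, g)
  # pixel (14, 13) sits at x = 134, y = 146: it surrounds grid nodes with
  # x in (122, 146) and y in (134, 158), i.e. the node (140, 140) only
  jx <- which(g$xs == 140)
  expect_false(onto$mask[which(g$ys == 140), jx])
  expect_equal(onto$xi[which(g$ys == 140), jx], 0)
  expect_true(onto$mask[which(g$ys == 160), jx])
  expect_true(onto$mask[which(g$ys == 100), jx])

  small <- density_ratio_map(matrix(1, 4, 4), x0 = 0, y0 = 0, spacing = 10)
  expect_error(interpolate_ratio_to_grid(small, g), "does not cover")
})
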