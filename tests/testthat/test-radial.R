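test_that("a constant frame averages to the constant in every populated bin", {
  g <- centred_geom(64)
  beam <- beam_geometry(1.5, 0.2)
  fr <- matrix(42, 64, 64)
  prof <- radial_average(fr, g, beam, nbins = 40)
  expect_true(all(prof$values[prof$counts > 0] == 42))
  expect_true(all(is.na(prof$values[prof$counts == 0])))
  expect_equal(length(prof$values), 40)
  expect_equal(length(prof$q_edges), 41)
})

test_that("values in one shared bin are averaged with equal weight", {
  g <- centred_geom(16)
  beam <- beam_geometry(1.5, 0.2)
  fr <- matrix(0, 16, 16)
  fr[1, 1] <- 10; fr[16, 16] <- 30   # corners: same radius, same q
  qm <- q_map(g, beam)
  expect_equal(qm[1, 1], qm[16, 16], tolerance = 1e-12)
  qc <- qm[1, 1]
  # a single bin tight around the corner q holds exactly the 4 corner pixels
  prof <- radial_average(fr, g, beam, nbins = 1,
                         q_range = qc * c(1 - 1e-9, 1 + 1e-9))
  expect_equal(prof$counts, 4)
  expect_equal(prof$values, (10 + 30 + 0 + 0) / 4)
})

test_that("a synthetic ring lands in the expected q bins", {
  g <- centred_geom(128)
  beam <- beam_geometry(1.5, 0.2)
  qmax <- max(q_map(g, beam), na.rm = TRUE)
  q0 <- 0.6 * qmax; w <- 0.05 * qmax
  fr <- gen_ring_frame(g, beam, q0, w, value = 100)
  prof <- radial_average(fr, g, beam, nbins = 50, q_range = c(0, qmax))
  mid <- prof$q_mid
  inside <- which(mid > q0 - w + diff(mid)[1] & mid < q0 + w - diff(mid)[1])
  outside <- which(mid < q0 - 2 * w | mid > q0 + 2 * w)
  expect_true(all(prof$values[inside] == 100))
  expect_true(all(prof$values[outside][prof$counts[outside] > 0] == 0))
})

test_that("masking a 60-degree sector barely changes the ring profile", {
  g <- centred_geom(256)
  beam <- beam_geometry(1.5, 0.2)
  qmax <- max(q_map(g, beam), na.rm = TRUE)
  fr <- gen_ring_frame(g, beam, 0.5 * qmax, 0.08 * qmax, value = 100)
  full <- radial_average(fr, g, beam, nbins = 60, q_range = c(0, qmax))
  ang <- atan2(g$y_map, g$x_map)
  mask <- (ang > 0 & ang < pi / 3) * 1
  part <- radial_average(fr, g, beam, mask = mask, nbins = 60,
                         q_range = c(0, qmax))
  both <- full$counts > 0 & part$counts > 0
  rel <- abs(part$values[both] - full$values[both]) / 100  # vs ring intensity
  expect_lt(max(rel), 0.01)
})

test_that("radial averaging is permutation-invariant and validates input", {
  g <- centred_geom(32)
  beam <- beam_geometry(1.5, 0.2)
  fr <- matrix(rnorm(32 * 32), 32, 32)
  p1 <- radial_average(fr, g, beam, nbins = 20)
  # histogram accumulation has no pixel-order dependence by construction;
  # check against an explicit per-bin tapply recomputation
  qm <- q_map(g, beam)
  bin <- findInterval(qm, p1$q_edges, rightmost.closed = TRUE)
  ref <- vapply(seq_len(20), function(b)
    if (any(bin == b)) mean(fr[bin == b]) else NA_real_, numeric(1))
  expect_equal(p1$values, ref)
  expect_error(radial_average(matrix(0, 8, 8), g, beam), "shape")
  expect_warning(radial_average(fr, g, beam, mask = matrix(1, 32, 32)),
                 "masked")
})

test_that("nodes are strict local minima in the search range", {
  expect_equal(find_nodes(c(1, 0, 1, 0, 1)), c(2, 4))
  expect_equal(find_nodes(1:10), integer(0))
  expect_equal(find_nodes(c(1, 1)), integer(0))
  x <- seq(0, 2 * pi, length.out = 201)
  tr <- sin(x)^2
  nodes <- find_nodes(tr)
  expect_equal(length(nodes), 1)           # interior minimum at pi only
  expect_equal(x[nodes], pi, tolerance = 0.05)
  expect_equal(find_nodes(c(1, 0, 1, 0, 1), search_range = c(3, 5)), 4)
})

test_that("node distance reports bins, q units, or NA when undefined", {
  expect_equal(node_distance(c(1, 0, 1, 0, 1)), 2)
  expect_true(is.na(node_distance(1:10)))
  expect_true(is.na(node_distance(c(1, 0, 1))))
  g <- centred_geom(128)
  beam <- beam_geometry(1.5, 0.2)
  fr <- gen_sphere_frame(g, beam, diameter = 40)
  prof <- radial_average(fr, g, beam, nbins = 200)
  nd_bins <- node_distance(prof)
  nd_q <- node_distance(prof, units = "q")
  expect_equal(nd_q, nd_bins * diff(prof$q_mid)[1], tolerance = 1e-9)
})

test_that("node distance scales inversely with sphere diameter", {
  g <- centred_geom(128)
  beam <- beam_geometry(1.0, 0.1)
  qmax <- max(q_map(g, beam), na.rm = TRUE)
  nd <- vapply(c(20, 40, 80), function(dia) {
    fr <- gen_sphere_frame(g, beam, diameter = dia)
    prof <- radial_average(fr, g, beam, nbins = 200, q_range = c(0, qmax))
    node_distance(prof, units = "q")
  }, numeric(1))
  expect_equal(nd[1] / nd[2], 2, tolerance = 0.1)
  expect_equal(nd[2] / nd[3], 2, tolerance = 0.1)
  # theoretical spacing: (x2 - x1)/R with tan(x) = x roots
  expect_equal(nd[2], (7.7253 - 4.4934) / 20, tolerance = 0.05)
})

test_that("Cartesian autocorrelation matches the direct-sum oracle", {
  img <- withr::with_seed(8, matrix(rnorm(64), 8, 8))
  ac <- autocorrelate_cartesian(img)
  expect_equal(ac, oracle_autocorr(img), tolerance = 1e-10)
  expect_equal(ac[1, 1], sum(img^2), tolerance = 1e-10)
  # point-inversion symmetry: ac[i, j] = ac[-i mod n, -j mod n]
  expect_equal(ac[2, 3], ac[8, 7], tolerance = 1e-10)
  # delta image: all mass at zero shift
  delta <- matrix(0, 8, 8); delta[3, 5] <- 2
  acd <- autocorrelate_cartesian(delta)
  expect_equal(acd[1, 1], 4)
  expect_equal(sum(abs(acd)) - abs(acd[1, 1]), 0, tolerance = 1e-10)
  # constant image stays constant at sum(x^2)
  expect_true(all(abs(autocorrelate_cartesian(matrix(3, 4, 4)) - 144) < 1e-9))
})

test_that("polar angular autocorrelation reflects rotational symmetry", {
  n <- 65
  ctr <- (n + 1) / 2
  r2 <- outer((1:n) - ctr, (1:n) - ctr, function(a, b) sqrt(a^2 + b^2))
  iso <- exp(-r2 / 10)
  ap <- autocorrelate_polar(iso, nradii = 16, nangles = 90)
  flat <- apply(ap, 1, function(row) max(row) - min(row))
  expect_lt(max(flat / pmax(abs(ap[, 1]), 1e-12)), 1e-4)
  # two-fold symmetric image: peak at angular lag pi
  ang <- outer((1:n) - ctr, (1:n) - ctr, function(a, b) atan2(a, b))
  two <- exp(-r2 / 10) * (1 + cos(2 * ang))
  ap2 <- autocorrelate_polar(two, nradii = 16, nangles = 90)
  ridge <- ap2[10, ]
  expect_equal(which.max(ridge[2:89]) + 1, 46, tolerance = 1)  # lag pi = bin 46
  expect_true(all(autocorrelate_polar(matrix(0, n, n)) == 0))
})

test_that("power spectrum is centred, Parseval-consistent and shift-invariant", {
  img <- withr::with_seed(9, matrix(rnorm(16 * 16), 16, 16))
  ps <- power_spectrum(img)
  expect_equal(sum(ps) / length(img), sum(img^2), tolerance = 1e-9)
  shifted <- img[c(5:16, 1:4), c(9:16, 1:8)]
  expect_equal(power_spectrum(shifted), ps, tolerance = 1e-9)
  const <- power_spectrum(matrix(2, 8, 8))
  expect_equal(const[5, 5], (2 * 64)^2)
  expect_equal(sum(const) - const[5, 5], 0, tolerance = 1e-9)
})
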