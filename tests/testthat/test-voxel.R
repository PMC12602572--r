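# small in-code voxel fixture: labelled blocks with controllable structure
make_voxel_fixture <- function(n_t = 120, grid = c(4, 2, 1), labels = NULL,
                               series = NULL, voxel_mm = 3, tr = 2,
                               seed = 1) {
  set.seed(seed)
  if (is.null(labels)) labels <- array(1L, dim = grid)
  nv <- prod(grid)
  if (is.null(series)) series <- matrix(rnorm(n_t * nv), n_t, nv)
  # series is time x voxel; array() needs voxel-major: transpose first
  dat <- array(t(series), dim = c(grid, n_t))
  voxel_panel(dat, voxel_size_mm = voxel_mm, parcellation = labels, tr = tr)
}

test_that("IC of two voxels is the absolute pairwise correlation", {
  set.seed(4)
  x <- rnorm(200)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(200)
  vp <- make_voxel_fixture(200, c(2, 1, 1), series = cbind(x, y))
  ic <- intrinsic_connectivity(vp)
  r <- abs(stats::cor(x, y))
  expect_equal(as.numeric(ic[!is.na(ic)]), rep(r, 2), tolerance = 1e-12)
})

test_that("an independent voxel has IC near zero", {
  set.seed(5)
  n <- 3000
  shared <- rnorm(n)
  series <- cbind(shared + 0.1 * rnorm(n), shared + 0.1 * rnorm(n),
                  rnorm(n))
  vp <- make_voxel_fixture(n, c(3, 1, 1), series = series)
  ic <- intrinsic_connectivity(vp)
  expect_lt(ic[3, 1, 1], 0.08)
  expect_gt(ic[1, 1, 1], 0.5)
})

test_that("full-rank SVD reduction equals the direct computation", {
  set.seed(6)
  vp <- make_voxel_fixture(60, c(3, 3, 1), seed = 6)
  ic_full <- intrinsic_connectivity(vp, n_components = 9)
  fl <- hemilat:::flatten_voxels(vp)
  r <- stats::cor(fl$ts)
  direct <- sqrt((rowSums(r^2) - 1) / (ncol(r) - 1))
  expect_equal(as.numeric(ic_full[!is.na(ic_full)]), direct,
               tolerance = 1e-8)
  # and a genuinely truncated rank changes the map
  ic_k2 <- intrinsic_connectivity(vp, n_components = 2)
  expect_false(isTRUE(all.equal(ic_full, ic_k2, tolerance = 1e-4)))
})

test_that("LCOR of a two-voxel mask equals the plain correlation", {
  set.seed(7)
  x <- rnorm(150); y <- 0.5 * x + rnorm(150)
  vp <- make_voxel_fixture(150, c(2, 1, 1), series = cbind(x, y))
  lc <- local_correlation(vp, fwhm_mm = 40)
  expect_equal(as.numeric(lc[!is.na(lc)]), rep(stats::cor(x, y), 2),
               tolerance = 1e-12)
})

test_that("LCOR limits: shared signal gives 1, independence gives ~0", {
  n <- 400
  shared <- matrix(rep(rnorm(n), 6), n, 6)
  vp <- make_voxel_fixture(n, c(3, 2, 1), series = shared)
  lc <- local_correlation(vp)
  expect_equal(as.numeric(lc[!is.na(lc)]), rep(1, 6), tolerance = 1e-7)

  set.seed(8)
  vp2 <- make_voxel_fixture(4000, c(3, 2, 1), seed = 8)
  lc2 <- local_correlation(vp2)
  expect_lt(max(abs(lc2), na.rm = TRUE), 0.1)
})

test_that("LCOR kernel width interpolates neighbour and global correlation", {
  # line of voxels with correlation decaying along the line
  set.seed(9)
  n <- 600
  base <- rnorm(n)
  series <- sapply(0:5, function(k) {
    w <- 0.95^k
    w * base + sqrt(1 - w^2) * rnorm(n)
  })
  vp <- make_voxel_fixture(n, c(6, 1, 1), series = series, voxel_mm = 3)
  r <- stats::cor(series)
  # fwhm 2 mm on a 3 mm grid: only the two nearest neighbours carry weight
  narrow <- local_correlation(vp, fwhm_mm = 2)
  wide <- local_correlation(vp, fwhm_mm = 1e5)
  v <- 3  # middle voxel
  nn_mean <- mean(r[v, c(v - 1, v + 1)])
  glob_mean <- mean(r[v, -v])
  expect_equal(narrow[v, 1, 1], nn_mean, tolerance = 1e-9)
  expect_equal(wide[v, 1, 1], glob_mean, tolerance = 1e-6)
})

test_that("IC and LCOR are invariant to per-voxel affine rescaling", {
  set.seed(10)
  vp <- make_voxel_fixture(80, c(2, 2, 1), seed = 10)
  fl <- hemilat:::flatten_voxels(vp)
  scaled <- sweep(fl$ts, 2, c(2, 3, 0.5, 10), `*`)
  scaled <- sweep(scaled, 2, c(1, -5, 0, 2), `+`)
  vp2 <- make_voxel_fixture(80, c(2, 2, 1), series = scaled)
  expect_equal(intrinsic_connectivity(vp), intrinsic_connectivity(vp2),
               tolerance = 1e-10)
  expect_equal(local_correlation(vp), local_correlation(vp2),
               tolerance = 1e-10)
  # IC (squared correlations) also survives a sign flip
  flipped <- sweep(fl$ts, 2, c(-1, 1, -1, 1), `*`)
  vp3 <- make_voxel_fixture(80, c(2, 2, 1), series = flipped)
  expect_equal(intrinsic_connectivity(vp), intrinsic_connectivity(vp3),
               tolerance = 1e-10)
})

test_that("fALFF hits its analytic limits on sinusoids and white noise", {
  n <- 300; tr <- 2
  t_s <- (seq_len(n) - 1) * tr
  in_band <- sin(2 * pi * 0.05 * t_s)
  out_band <- sin(2 * pi * 0.2 * t_s)
  expect_equal(falff_series(in_band, tr), 1, tolerance = 0.05)
  expect_equal(falff_series(out_band, tr), 0, tolerance = 0.05)

  # white noise: fALFF ~ sqrt(band width / Nyquist) = sqrt(0.082 / 0.25)
  set.seed(11)
  reps <- replicate(200, falff_series(rnorm(n), tr))
  expect_equal(mean(reps), sqrt(0.082 / 0.25), tolerance = 0.02)
})

test_that("fALFF is scale invariant and monotone in in-band fraction", {
  set.seed(12)
  n <- 240; tr <- 2
  t_s <- (seq_len(n) - 1) * tr
  sig <- sin(2 * pi * 0.04 * t_s)
  noise <- rnorm(n)
  x <- sig + noise
  expect_equal(falff_series(7 * x, tr), falff_series(x, tr),
               tolerance = 1e-12)
  fr <- vapply(c(0.3, 1, 3), function(a)
    falff_series(a * sig + noise, tr), numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_true(is.na(falff_series(rep(2, n), tr)))
})

test_that("voxel maps aggregate to region means with missing propagation", {
  atlas <- make_toy_atlas(1, 1)  # rois 1, 2 paired; 3 midline
  map <- array(NA_real_, c(3, 2, 1))
  parc <- array(0L, c(3, 2, 1))
  parc[1:2, 1, 1] <- 1L; parc[3, 1, 1] <- 2L; parc[1:2, 2, 1] <- 2L
  map[1, 1, 1] <- 0.2; map[2, 1, 1] <- 0.4   # roi 1: mean 0.3
  map[3, 1, 1] <- 0.6                        # roi 2: one voxel missing
  agg <- aggregate_to_rois(map, parc, atlas, metric = "IC")
  expect_equal(agg$value[agg$roi == "Region 001 L"], 0.3)
  expect_equal(agg$value[agg$roi == "Region 001 R"], 0.6)

  map[] <- NA_real_
  agg2 <- aggregate_to_rois(map, parc, atlas)
  expect_true(all(is.na(agg2$value)))

  badparc <- parc; badparc[1, 1, 1] <- 42L
  expect_error(aggregate_to_rois(map, badparc, atlas), "42")
})

test_that("aggregation is invariant to voxel order", {
  set.seed(13)
  atlas <- make_toy_atlas(2)
  parc <- block_parcellation(c(4, 2, 1), atlas)
  map <- array(runif(8), c(4, 2, 1))
  class(map) <- c("voxel_metric_map", class(map))
  a1 <- aggregate_to_rois(map, parc, atlas)
  perm <- array(0L, dim = dim(parc))
  # permute voxels within each region label
  for (l in unique(as.vector(parc))) {
    idx <- which(parc == l)
    perm[idx] <- sample(idx)
  }
  map2 <- array(map[perm], dim = dim(map))
  a2 <- aggregate_to_rois(map2, parc, atlas)
  expect_equal(a1$value, a2$value, tolerance = 1e-12)
})

test_that("single-voxel masks are rejected", {
  vp <- make_voxel_fixture(60, c(2, 1, 1),
                           labels = array(c(1L, 0L), c(2, 1, 1)))
  expect_error(intrinsic_connectivity(vp), "at least 2")
  expect_error(local_correlation(vp), "at least 2")
})
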