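# DEW subtraction, k-factor estimation and ROI quantification.

mkimg <- function(values, grid) ccdew:::new_cc_image(values, grid)

test_that("DEW subtraction is pixel-wise with clamping accounted", {
  g <- image_grid(nx = 2, ny = 1, pixel_mm = 1, z = 90)
  peak <- mkimg(matrix(c(2, 1), 2, 1), g)
  scat <- mkimg(matrix(c(1, 2), 2, 1), g)
  d <- dew_subtract(peak, scat, k = 1)
  expect_equal(as.numeric(d$dew_image), c(1, 0))
  expect_equal(d$negatives_clamped, 1)
  expect_equal(as.numeric(d$unclamped), c(1, -1))
  # peak == scatter -> zero image, nothing clamped
  d2 <- dew_subtract(peak, peak, k = 1)
  expect_true(all(unclass(d2$dew_image) == 0))
  expect_equal(d2$negatives_clamped, 0)
  # zero scatter -> dew equals peak for any k
  zero <- mkimg(matrix(0, 2, 1), g)
  for (k in c(0, 1, 1.06, 3)) {
    expect_equal(unclass(dew_subtract(peak, zero, k = k)$dew_image),
                 unclass(peak))
  }
  # linearity before clamping: dew(aP, aS) = a dew(P, S)
  a <- 2.7
  pa <- mkimg(a * unclass(peak), g)
  sa <- mkimg(a * unclass(scat), g)
  expect_equal(unclass(dew_subtract(pa, sa, k = 1.3)$unclamped),
               a * unclass(dew_subtract(peak, scat, k = 1.3)$unclamped))
  # dew image never exceeds the control image (crosstalk never amplified)
  expect_true(all(unclass(d$dew_image) <= unclass(peak)))
  # grid mismatch refused
  g2 <- image_grid(nx = 2, ny = 1, pixel_mm = 2, z = 90)
  expect_error(dew_subtract(peak, mkimg(matrix(0, 2, 1), g2)), "grid")
})

test_that("k-factor is the weighted peak/scatter count ratio", {
  # flat spectrum with equal bin populations across 166-186 -> k = 1 exactly
  sums <- seq(166.5, 185.5, by = 1)
  flat <- make_events(E1 = 60, E2 = sums - 60)
  expect_identical(estimate_k(flat), 1)
  # 53 peak-window vs 50 scatter-window events -> 1.06
  fix <- make_events(E1 = 60, E2 = c(rep(110, 53), rep(120, 50)))
  expect_equal(estimate_k(fix), 1.06, tolerance = 1e-12)
  # invariant under uniform weight rescaling
  fix$weight <- 7.3
  expect_equal(estimate_k(fix), 1.06, tolerance = 1e-12)
  # empty scatter window is an error
  expect_error(estimate_k(make_events(E1 = 60, E2 = 110)), "scatter window")
})

test_that("ROI integration uses the centre-in-disc rule", {
  g <- image_grid() # 1 mm pixels, centres at half-integers
  ones <- mkimg(matrix(1, g$nx, g$ny), g)
  roi <- roi_spec(c(0, 0), 15)
  # brute-force enumeration of pixel centres inside the disc
  n_inside <- sum(outer(g$xs^2, g$ys^2, `+`) <= 15^2)
  expect_equal(roi_integrate(ones, roi), n_inside)
  expect_gt(n_inside, 600) # sanity: close to pi * 15^2
  # zero image integrates to zero
  expect_equal(roi_integrate(mkimg(matrix(0, g$nx, g$ny), g), roi), 0)
  # point image outside a disjoint ROI contributes nothing
  m <- matrix(0, g$nx, g$ny)
  m[which.min(abs(g$xs - 30.5)), which.min(abs(g$ys - 0.5))] <- 5
  expect_equal(roi_integrate(mkimg(m, g), roi_spec(c(-30, 0), 15)), 0)
  # ROI entirely off the grid is an error
  expect_error(roi_integrate(ones, roi_spec(c(500, 500), 3)), "overlaps")
})

test_that("crosstalk tables assemble control and DEW ROI integrals", {
  g <- image_grid(nx = 80, ny = 80, pixel_mm = 1, z = 90)
  blob <- function(cx, cy, amp) {
    m <- amp * exp(-(outer((g$xs - cx)^2, (g$ys - cy)^2, `+`)) / 50)
    mkimg(m, g)
  }
  entry <- function(ratio, cross) {
    peak <- mkimg(unclass(blob(30, 0, 10)) + unclass(blob(-30, 0, cross)), g)
    scat <- blob(-30, 0, cross * 0.9)
    list(ratio = ratio, bp = dew_subtract(peak, scat, k = 1))
  }
  runs <- list(entry(0, 0.01), entry(10, 1), entry(50, 5))
  tab <- crosstalk_curves(runs)
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 3 * 1 * 2 * 2)
  ctl <- tab[tab$image == "control" & tab$roi == "left", ]
  dew <- tab[tab$image == "dew" & tab$roi == "left", ]
  # control grows with the high-energy activity; DEW suppressed below it
  expect_true(all(diff(ctl$intensity) > 0))
  expect_true(all(dew$intensity <= ctl$intensity))
  # the right ROI is insensitive to the subtraction of a left-side blob
  rctl <- tab[tab$image == "control" & tab$roi == "right", ]
  rdew <- tab[tab$image == "dew" & tab$roi == "right", ]
  expect_equal(rdew$intensity, rctl$intensity, tolerance = 0.02)
})
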