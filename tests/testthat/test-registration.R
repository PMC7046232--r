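test_that("mutual information is maximal for self and near zero for shuffles", {
  img <- small_foot(seed = 5)
  self_mi <- mutual_information(img, img)
  other <- small_foot(seed = 6)
  expect_gte(self_mi, mutual_information(img, other))
  # shuffling one image destroys the association (within histogram bias)
  shuf <- img
  set.seed(1)
  shuf$data <- matrix(sample(img$data), nrow(img$data))
  expect_lt(mutual_information(img, shuf), 0.15 * self_mi)
  # constant images carry no information
  const <- pressure_image(matrix(1, 10, 10), spacing = 3)
  expect_equal(mutual_information(const, const), 0)
})

test_that("rigid registration recovers the identity and known perturbations", {
  img <- small_foot(seed = 7)
  t_id <- rigid_register(img, img, es_config(seed = 1))
  expect_lt(abs(t_id$angle) * 180 / pi, 0.5)
  expect_lt(sqrt(sum(t_id$translation^2)), 0.5)

  tr <- rigid_transform2d(10 * pi / 180, c(6, -9), center_of_pressure(img))
  moved <- apply_transform(img, tr)
  rec <- rigid_register(moved, img, es_config(seed = 2))
  comp <- compose_rigid(tr, rec)   # applied then recovered ~ identity
  expect_lt(abs(comp$angle) * 180 / pi, 1)
  expect_lt(sqrt(sum(comp$translation^2)), 1)
  # accepted metric trace is monotone non-decreasing
  expect_true(all(diff(attr(rec, "trace")) >= 0))
})

test_that("registration of disjoint identical blobs recovers their offset", {
  m <- matrix(0, 40, 40)
  blob <- outer(exp(-((1:9 - 5) / 2)^2), exp(-((1:9 - 5) / 2)^2)) * 50
  a <- m; a[5:13, 5:13] <- blob
  b <- m; b[25:33, 21:29] <- blob
  ia <- pressure_image(a, spacing = 3)
  ib <- pressure_image(b, spacing = 3)
  rec <- rigid_register(ia, ib, es_config(seed = 3))
  # transform maps fixed-grid points into the moving image
  delta <- center_of_pressure(ia) - center_of_pressure(ib)
  moved_cop <- apply_rigid_points(rec, matrix(center_of_pressure(ib), 1))
  expect_lt(sqrt(sum((moved_cop - center_of_pressure(ia))^2)), 3)  # 1 px
})

test_that("demons leaves identical silhouettes alone and fixes dilations", {
  img <- small_foot(seed = 8)
  s <- compute_silhouette(img)
  f_id <- demons_register(s, s)
  expect_lt(max(sqrt(f_id$ux^2 + f_id$uy^2)) / s$spacing[1], 0.5)

  dil <- silhouette_mask(plantarmap:::cpp_gauss_smooth(s$data * 1, 1.2) > 0.25,
                         spacing = 3)
  f <- demons_register(s, dil)
  expect_gte(attr(f, "dice_after"), 0.97)
  expect_gt(f$jacobian_min, 0)
  # Dice never decreases relative to the pre-deformation overlap
  expect_gte(attr(f, "dice_after"), attr(f, "dice_before"))
})

test_that("demons is diffeomorphic and monotone across perturbed pairs", {
  img <- small_foot(seed = 9)
  s <- compute_silhouette(img)
  for (k in 1:4) {
    tr <- with_seed(k, rigid_transform2d(runif(1, -0.04, 0.04),
                                         runif(2, -4, 4),
                                         center_of_pressure(img)))
    moved <- compute_silhouette(apply_transform(img, tr))
    f <- demons_register(moved, s)
    expect_gt(f$jacobian_min, 0)
    expect_gte(attr(f, "dice_after"), attr(f, "dice_before"))
  }
  empty <- silhouette_mask(matrix(0, nrow(s$data), ncol(s$data)),
                           spacing = 3)
  expect_error(demons_register(empty, s), "non-empty")
})

test_that("within-foot averaging aligns repeats back to the reference", {
  img <- small_foot(seed = 10)
  expect_identical(align_and_average_foot(list(img)), img)
  avg_same <- align_and_average_foot(list(img, img, img), seed = 1)
  rel <- sqrt(sum((avg_same$data - img$data)^2)) / sqrt(sum(img$data^2))
  expect_lt(rel, 1e-6)  # identity transforms are found for identical images

  perturbed <- lapply(1:2, function(k) {
    tr <- with_seed(k + 10, rigid_transform2d(runif(1, -0.06, 0.06),
                                              runif(2, -5, 5),
                                              center_of_pressure(img)))
    apply_transform(img, tr)
  })
  imgs <- c(list(img), perturbed)
  avg <- align_and_average_foot(imgs, seed = 0)
  # the reference enters with the identity transform, and the average sits
  # in the reference's frame
  trs <- attr(avg, "transforms")
  ref <- attr(avg, "reference")
  expect_equal(trs[[ref]]$angle, 0)
  rel <- sqrt(sum((avg$data - imgs[[ref]]$data)^2)) /
    sqrt(sum(imgs[[ref]]$data^2))
  expect_lt(rel, 0.02)
})
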