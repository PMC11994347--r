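# Stage 3: nucleus detection, density normalization, score aggregation.

test_that("the reference detector finds nothing on blank glass", {
  expect_equal(nrow(reference_detect(array(1, c(64, 64, 3)))), 0L)
})

test_that("the reference detector counts well-separated planted lymphocytes exactly", {
  area_mm2 <- 512 * 512 * (0.25 / 1000)^2
  sp <- slide_spec(512, 512, mpp = 0.25,
                   regions = list(region_rect(0, 0, 512, 512, "tumor")),
                   nuclei_density = list(tumor = c(lymphocyte = 12 / area_mm2,
                                                   other = 0)),
                   min_separation_px = 30, seed = 3)
  sl <- generate_slide(sp)
  patch <- read_region(open_slide(sl$path), 0, 0, 512, 512)
  det <- reference_detect(patch)
  expect_equal(nrow(det), 12L)
  expect_true(all(det$cell_kind == "lymphocyte"))
  # centroids sit on the planted centers (within a pixel)
  nuc <- sl$truth$nuclei[order(sl$truth$nuclei$x, sl$truth$nuclei$y), ]
  det <- det[order(det$x, det$y), ]
  expect_lt(max(abs(det$x - nuc$x)), 1)
  expect_lt(max(abs(det$y - nuc$y)), 1)
})

test_that("large nuclei are classified 'other' by the area rule", {
  area_mm2 <- 512 * 512 * (0.25 / 1000)^2
  sp <- slide_spec(512, 512, mpp = 0.25,
                   regions = list(region_rect(0, 0, 512, 512, "stroma")),
                   nuclei_density = list(stroma = c(lymphocyte = 0,
                                                    other = 10 / area_mm2)),
                   min_separation_px = 40, seed = 5)
  sl <- generate_slide(sp)
  det <- reference_detect(read_region(open_slide(sl$path), 0, 0, 512, 512))
  expect_equal(nrow(det), 10L)
  expect_true(all(det$cell_kind == "other"))
})

test_that("detections are equivariant to integer translation of content", {
  base <- array(1, c(96, 96, 3))
  nucleus <- til_generator_palette()$lymphocyte / 255
  paint <- function(img, cx, cy, r = 5) {
    for (dx in -r:r) for (dy in -r:r)
      if (dx^2 + dy^2 <= r^2)
        img[cy + dy, cx + dx, ] <- nucleus
    img
  }
  a <- paint(base, 30, 40)
  b <- paint(base, 30 + 17, 40 + 9)
  da <- reference_detect(a)
  db <- reference_detect(b)
  expect_equal(nrow(da), 1L)
  expect_equal(db$x - da$x, 17)
  expect_equal(db$y - da$y, 9)
})

test_that("patch density evaluates its normalization exactly", {
  expect_equal(patch_density(0, 768, 0.25), 0)
  # (768 * 0.25)^2 = 36864 um^2
  expect_equal(patch_density(100, 768, 0.25), 100 / 36864 * 1e6)
  expect_equal(patch_density(100, 768, 0.25), 2712.673611, tolerance = 1e-9)
  # halving mpp quadruples density
  expect_equal(patch_density(100, 768, 0.125),
               4 * patch_density(100, 768, 0.25))
  # linearity in the count
  expect_equal(patch_density(2 * 37, 512, 0.5), 2 * patch_density(37, 512, 0.5))
  expect_error(patch_density(10, 0, 0.25), class = "til_domain_error")
  expect_error(patch_density(10, 768, -1), class = "til_domain_error")
  expect_error(patch_density(-1, 768, 0.25), class = "til_domain_error")
})

test_that("patch density agrees with exact rational arithmetic on integer inputs", {
  # with mpp = p/q, d = c * 1e6 * q^2 / (P^2 * p^2): numerator and
  # denominator stay below 2^53, so double division is the exact
  # rational value
  withr::with_seed(101, {
    c_i <- sample(0:10000, 1000, replace = TRUE)
    P <- sample(64:2048, 1000, replace = TRUE)
    p <- sample(1:8, 1000, replace = TRUE)
    q <- sample(1:30, 1000, replace = TRUE)
  })
  for (k in seq_len(1000)) {
    exact <- (c_i[k] * 1e6 * q[k]^2) / (P[k]^2 * p[k]^2)
    got <- patch_density(c_i[k], P[k], p[k] / q[k])
    expect_equal(got, exact, tolerance = 1e-12)
  }
})

test_that("slide and patient scores aggregate as means of means", {
  expect_equal(slide_score(c(1000, 2000, 3000)), 2000)
  expect_equal(slide_score(42), 42)
  withr::with_seed(7, d <- runif(50, 0, 5000))
  expect_equal(slide_score(d), slide_score(rev(d)))
  expect_error(slide_score(numeric(0)), class = "til_empty_error")

  # patient score is the mean of slide means, not the pooled patch mean
  expect_equal(patient_score(list(rep(100, 10), 300)), 200)
  expect_false(isTRUE(all.equal(patient_score(list(rep(100, 10), 300)),
                                mean(c(rep(100, 10), 300)))))
  expect_equal(patient_score(list(d)), slide_score(d))  # k = 1 reduction
  expect_equal(patient_score(list(d, d, d)), slide_score(d))
  expect_error(patient_score(list(d, numeric(0))), class = "til_empty_error")
})

test_that("k = 1 reduction holds on random inputs", {
  for (seed in 1:20) {
    withr::with_seed(seed, d <- runif(sample(1:30, 1), 0, 8000))
    expect_identical(patient_score(list(d)), slide_score(d))
  }
})

test_that("oracle quantification recovers the planted density within 5%", {
  sl <- fixture_two_class_slide(width = 1536, height = 1536, mpp = 0.5,
                                lymph = 1500, other = 500, seed = 42)
  s <- open_slide(sl$path)
  rec <- patch_records("s", x = rep(c(0L, 768L), 2), y = rep(c(0L, 768L), each = 2),
                       patch_size = 768L, label = rep(c("tumor", "stroma"), 2))
  q <- quantify_patches(rec, s, oracle_quantifier(sl$truth))
  expect_true(q$result$evaluable)
  expect_equal(q$result$til_score, 1500, tolerance = 0.05)
  # counts partition exactly across the grid (centroid assignment)
  expect_equal(sum(q$records$til_count), sum(sl$truth$regions$n_lymphocyte))

  # doubling every count doubles the slide score
  expect_equal(slide_score(patch_density(2 * q$records$til_count, 768, 0.5)),
               2 * q$result$til_score)
})

test_that("a slide with no lymphocytes scores zero; no patches means no score", {
  sl <- fixture_slide(width = 512, height = 512, mpp = 1, lymph = 0,
                      other = 300, seed = 15)
  s <- open_slide(sl$path)
  rec <- patch_records("s", c(0L, 256L), 0L, 256L, label = "tumor")
  q <- quantify_patches(rec, s, oracle_quantifier(sl$truth))
  expect_equal(q$result$til_score, 0)

  empty <- quantify_patches(filter_prognostic(
    patch_records("s", 0L, 0L, 256L, label = "necrosis")), s,
    oracle_quantifier(sl$truth))
  expect_false(empty$result$evaluable)
  expect_true(is.na(empty$result$til_score))
})
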