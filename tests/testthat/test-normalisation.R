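test_that("rescale maps to [0,1], is idempotent, zeros constants", {
  expect_equal(rescale(c(0, 50, 200)), c(0, 0.25, 1))
  x <- runif(100, -5, 20)
  r <- rescale(x)
  expect_equal(range(r), c(0, 1))
  expect_equal(rescale(r), r)
  expect_warning(z <- rescale(c(7, 7, 7)), class = "radharm_degenerate")
  expect_equal(z, c(0, 0, 0))
})

test_that("znorm centres and scales by population SD, affine-invariantly", {
  expect_equal(znorm(c(1, 2, 3)), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(znorm(c(1, 2, 3))[1], -1.224745, tolerance = 1e-6)
  set.seed(1)
  x <- rnorm(200)
  z <- znorm(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(znorm(z), z, tolerance = 1e-10)
  expect_equal(znorm(3.2 * x + 7), z, tolerance = 1e-10)
  expect_warning(z0 <- znorm(c(4, 4)), class = "radharm_degenerate")
  expect_equal(z0, c(0, 0))
})

test_that("histogram matching maps quantiles onto the template", {
  expect_equal(histogram_match(c(1, 2, 3, 4), c(10, 20, 30, 40)),
               c(10, 20, 30, 40))
  x <- c(5, 1, 9, 3, 7)
  expect_equal(histogram_match(x, x), x)  # self-matching identity
  set.seed(1)
  src <- rnorm(300); tpl <- rexp(500)
  out <- histogram_match(src, tpl)
  expect_equal(cor(src, out, method = "spearman"), 1)
  expect_lt(suppressWarnings(ks.test(out, tpl))$statistic, 0.05)
  expect_error(histogram_match(numeric(0), tpl), class = "radharm_bad_input")
})

test_that("PLHM landmarks are monotone and affine-invariant in training", {
  set.seed(2)
  x <- rgamma(2000, 2, 1)
  single <- fit_plhm(list(x))
  expect_false(is.unsorted(single$standard_landmarks))
  expect_equal(single$standard_landmarks[1], 0)
  expect_equal(single$standard_landmarks[length(single$standard_landmarks)], 1)

  # affine copies share mapped landmarks, so the average equals either
  both <- fit_plhm(list(x, 5 * x + 2))
  expect_equal(both$standard_landmarks, single$standard_landmarks,
               tolerance = 1e-10)
})

test_that("PLHM sends input deciles onto the standard landmarks", {
  set.seed(3)
  lm <- fit_plhm(list(rnorm(3000, 50, 10), rnorm(3000, 52, 11)))
  y <- apply_plhm(rnorm(4000, 200, 40), lm)
  got <- quantile(y, lm$percentile_grid / 100, names = FALSE)
  expect_equal(got, lm$standard_landmarks, tolerance = 0.01)

  # fixed point: input whose grid percentiles equal the landmarks
  z <- apply_plhm(y, lm)
  expect_equal(quantile(z, lm$percentile_grid / 100, names = FALSE),
               lm$standard_landmarks, tolerance = 0.01)

  expect_warning(w <- apply_plhm(rep(3, 10), lm),
                 class = "radharm_degenerate")
  expect_equal(w, rep(0.5, 10))
})

test_that("PLHM collapses affine distortions of a common distribution", {
  set.seed(4)
  base <- function(n) rgamma(n, 3, 0.5)
  a <- 30 * base(800) + 100
  b <- 2 * base(800) + 7
  lm <- fit_plhm(list(base(1000)))
  before <- jsd(a, b)
  after <- jsd(apply_plhm(a, lm), apply_plhm(b, lm))
  expect_lt(after, before / 10)
})

test_that("landmark sets survive a JSON round trip", {
  set.seed(5)
  lm <- fit_plhm(list(rnorm(500)), training_centre = "A")
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$standard_landmarks, lm$standard_landmarks)
  expect_identical(back$training_centre, "A")
})

test_that("normalisation scopes: whole transforms all voxels, roi leaves background", {
  st <- toy_study()
  expect_identical(apply_normalisation(st, "O")$voxels, st$voxels)

  w <- apply_normalisation(st, "R", "whole")
  expect_equal(range(w$voxels), c(0, 1))

  r <- apply_normalisation(st, "R", "roi")
  for (lab in 1:3)
    expect_equal(range(r$voxels[st$mask == lab]), c(0, 1))
  expect_identical(r$voxels[st$mask == 0L], st$voxels[st$mask == 0L])

  # whole vs roi differ on the myocardium when ROI ranges differ
  expect_false(isTRUE(all.equal(w$voxels[st$mask == 2L],
                                r$voxels[st$mask == 2L])))

  expect_error(apply_normalisation(st, "PLHM", "whole"),
               class = "radharm_missing_fit")
})

test_that("all four transforms are rank-preserving within scope", {
  st <- toy_study()
  studies <- list(st)
  for (m in c("R", "N", "HM", "PLHM")) {
    fit <- fit_normalisation(studies, m, "roi", reference_centre = "unknown")
    out <- apply_normalisation(st, m, "roi", fit)
    for (lab in 1:3) {
      a <- st$voxels[st$mask == lab]
      b <- out$voxels[st$mask == lab]
      expect_equal(cor(a, b, method = "spearman"), 1, tolerance = 1e-12)
    }
  }
})

test_that("reference fitting picks the largest centre by default", {
  spec <- cohort_spec(counts = data.frame(centre = c("A", "B"),
                                          healthy = c(2L, 5L),
                                          HCM = c(0L, 0L)), seed = 8)
  profs <- list(A = centre_profile("A", max_intensity = 100, noise_sd = 1),
                B = centre_profile("B", max_intensity = 900, noise_sd = 9))
  studies <- generate_cohort(spec, profs, phases = "ED")
  lm <- fit_normalisation(studies, "PLHM", "whole")
  expect_identical(lm$training_centre, "B")
  tpl <- fit_normalisation(studies, "HM", "whole")
  expect_s3_class(tpl, "histogram_template")
})
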