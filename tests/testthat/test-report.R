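test_that("single-view slab study yields a unit As/Ap ratio", {
  study <- run_study(make_slab(), list(angulation(0, 0)),
                     refine_max_edge_mm = 4)
  expect_equal(nrow(study), 1)
  expect_equal(study$ld_mm, 0)
  expect_equal(study$sid_mm, 973)
  expect_equal(study$ssd_mm, 590)
  expect_equal(study$ratio_as_ap, 1, tolerance = 0.01)
  expect_true(is.na(study$error))
  expect_null(attr(study, "overlaps"))
})

test_that("studies reject duplicate view names and record per-view failures", {
  dup <- tibble::tibble(name = c("A", "A"), primary_deg = c(0, 10),
                        secondary_deg = c(0, 0))
  expect_error(run_study(make_slab(), dup), "duplicate")
  # a lateral view is unreachable by panning; the run continues
  vv <- tibble::tibble(name = c("PA", "left lateral"),
                       primary_deg = c(0, 90), secondary_deg = c(0, 0))
  study <- suppressWarnings(run_study(make_slab(), vv, refine_max_edge_mm = 6))
  expect_true(is.na(study$error[1]))
  expect_match(study$error[2], "horizontal")
  expect_true(is.na(study$sid_mm[2]))
})

test_that("summaries use the sample standard deviation", {
  s <- summarize_column(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, stats::sd(c(2, 4, 4, 4, 5, 5, 7, 9)))
  expect_equal(summarize_column(rep(3, 5))$sd, 0)
  expect_error(summarize_column(3), "two values")
})

test_that("overlap statistics cover all unordered pairs including zeros", {
  m <- matrix(0, 10, 10)
  diag(m) <- NA
  dimnames(m) <- list(letters[1:10], letters[1:10])
  zero <- overlap_stats(m)
  expect_equal(zero$count_nonzero, 0)
  expect_equal(zero$n_pairs, 45)
  expect_equal(zero$sum_mm2, 0)
  m[2, 1] <- m[1, 2] <- 100
  m[7, 4] <- m[4, 7] <- 50
  s <- overlap_stats(m)
  expect_equal(s$count_nonzero, 2)
  expect_equal(s$sum_mm2, 150)
  expect_equal(s$mean_mm2, 150 / 45)
  asym <- m; asym[1, 2] <- 5
  expect_error(overlap_stats(asym), "symmetric")
})

test_that("pearson_ci matches a brute-force covariance computation", {
  set.seed(77)
  for (k in 1:200) {
    n <- sample(4:40, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n) + 0.5 * x
    got <- pearson_ci(x, y)
    r_bf <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, r_bf, tolerance = 1e-12)
    z <- atanh(r_bf)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
    expect_equal(c(got$ci_low, got$ci_high), ci, tolerance = 1e-12)
  }
  expect_equal(pearson_ci(1:10, 2 * (1:10) + 1)$r, 1)
  expect_error(pearson_ci(1:10, rep(1, 10)), "constant")
  expect_error(pearson_ci(1:3, 1:3), "four")
})

test_that("per-view CSV round-trip reproduces summaries exactly", {
  study <- run_study(make_cylinder(radius_mm = 110),
                     pci_views()[c(1, 2, 9), ], refine_max_edge_mm = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_per_view(study, path)
  back <- read_per_view(path)
  expect_identical(summarize_column(back$ssd_mm),
                   summarize_column(study$ssd_mm))
  expect_identical(summarize_column(back$as_mm2),
                   summarize_column(study$as_mm2))
})

test_that("reference fixtures load with the documented shapes", {
  g <- reference_geometry("male")
  expect_equal(nrow(g), 10)
  expect_named(g, c("name", "table_height_cm", "ld_mm", "ccd_mm",
                    "total_panning_mm", "sid_mm", "ssd_mm", "ap_mm2",
                    "as_mm2", "ratio_as_ap"))
  m <- reference_overlap("female")
  expect_s3_class(m, "overlap_matrix")
  expect_equal(dim(unclass(m)), c(10, 10))
  expect_true(all(is.na(diag(unclass(m)))))
  expect_equal(unclass(m)[lower.tri(m)], t(unclass(m))[lower.tri(m)])
})

test_that("overlap CSV writer emits a lower-triangle table", {
  m <- reference_overlap("male")
  path <- withr::local_tempfile(fileext = ".csv")
  write_overlaps(m, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$name, rownames(m))
  expect_true(all(is.na(as.matrix(back[, -1])[upper.tri(matrix(0, 10, 10), diag = TRUE)])))
  expect_equal(back[["PA 0"]][2], m[2, 1])
})

test_that("tidy/glance/autoplot work on a small study", {
  study <- run_study(make_cylinder(radius_mm = 110),
                     pci_views()[c(1, 2, 6), ], refine_max_edge_mm = 5)
  td <- tidy(study)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "beamskin_study"))
  gl <- glance(study)
  expect_equal(gl$n_views, 3)
  expect_equal(gl$overlap_n_pairs, 3)
  expect_equal(gl$ssd_mm_mean, mean(study$ssd_mm))
  expect_s3_class(autoplot(study), "ggplot")
  expect_s3_class(autoplot(attr(study, "overlaps")), "ggplot")
  fm <- format_study(study)
  expect_true(all(fm$sid_mm == round(fm$sid_mm)))
})
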