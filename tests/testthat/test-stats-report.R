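# Batch metrics, Pearson correlation matrix, report serialization.

test_that("compute_all_metrics routes metrics through their preconditions", {
  cube <- make_primitive("cube")
  rec <- compute_all_metrics(cube, reference = cube, plane_normal = NULL)
  expect_equal(rec$OI, 0)
  expect_equal(rec$S, 6)
  expect_equal(rec$V, 1)
  expect_equal(rec$sv_ratio, 6)
  expect_true(is.na(rec$Sp))

  # open flat patch: rugosity present, volume and S/V absent
  patch <- make_primitive("flat_patch")
  rec2 <- compute_all_metrics(patch, plane_normal = c(0, 0, 1))
  expect_true(is.na(rec2$V))
  expect_true(is.na(rec2$sv_ratio))
  expect_equal(rec2$rugosity, 1, tolerance = 1e-9)

  # synthetic pair with explicit coiling-plane normal: everything present
  pair <- test_pair(0.5)
  rec3 <- compute_all_metrics(pair$ornamented, reference = pair$smooth,
                              plane_normal = c(0, 0, 1))
  expect_true(all(is.finite(c(rec3$S, rec3$S_ref, rec3$V, rec3$Sp, rec3$OI,
                              rec3$sv_ratio, rec3$rugosity))))
  # caller-supplied shape ratios pass through untouched
  rec4 <- compute_all_metrics(cube, plane_normal = NULL,
                              shape_ratios = c(U_D = 0.4, W_H = 1.2))
  expect_equal(rec4$U_D, 0.4)
  expect_equal(rec4$W_H, 1.2)
  expect_true(is.na(rec4$W_D))
})

test_that("pearson_matrix matches hand computation and the two-pass oracle", {
  df <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5))
  m <- pearson_matrix(df, c("x", "y"))
  expect_equal(m$r["x", "y"], 0.8)  # cov 2 over sd product 2.5

  df2 <- tibble::tibble(a = 1:6, b = 2 * (1:6), c = -(1:6))
  m2 <- pearson_matrix(df2, c("a", "b", "c"))
  expect_equal(m2$r["a", "b"], 1)
  expect_equal(m2$r["a", "c"], -1)
  expect_true(all(diag(m2$r) == 1))
  expect_equal(m2$r, t(m2$r))

  # random tables against the brute-force product-moment oracle
  set.seed(7)
  for (rep in 1:4) {
    n <- sample(5:100, 1)
    tab <- tibble::tibble(u = rnorm(n), v = rnorm(n) + 0.5 * rnorm(n),
                          w = runif(n))
    tab$v[sample(n, 3)] <- NA  # exercise pairwise-complete handling
    m3 <- pearson_matrix(tab, c("u", "v", "w"))
    for (pairvars in list(c("u", "v"), c("u", "w"), c("v", "w"))) {
      o <- brute_pearson(tab[[pairvars[1]]], tab[[pairvars[2]]])
      expect_equal(m3$r[pairvars[1], pairvars[2]], o$r, tolerance = 1e-12)
      expect_equal(m3$p[pairvars[1], pairvars[2]], o$p, tolerance = 1e-12)
      expect_identical(m3$n[pairvars[1], pairvars[2]], as.integer(o$n))
    }
  }
})

test_that("significance stars are a pure threshold function of p", {
  p_grid <- c(1e-6, 0.0009999, 0.001, 0.0011, 0.009, 0.01, 0.011, 0.049,
              0.05, 0.051, 0.5, 1)
  expected <- c("***", "***", "**", "**", "**", "*", "*", "*", "", "", "",
                "")
  df <- tibble::tibble(p = p_grid)
  got <- conchmetrics:::significance_stars(p_grid)
  expect_identical(got, expected)
  expect_identical(conchmetrics:::significance_stars(NA_real_),
                   NA_character_)
})

test_that("constant variables are reported undefined, not zero", {
  df <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5), z = rep(3, 5))
  expect_warning(m <- pearson_matrix(df, c("x", "y", "z")), "constant")
  expect_true(is.na(m$r["x", "z"]))
  expect_true(is.na(m$p["y", "z"]))
  expect_false(is.na(m$r["x", "y"]))
  expect_true("z" %in% m$undefined)
})

test_that("holm adjustment only ever weakens the stars", {
  set.seed(11)
  tab <- tibble::tibble(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  tab$b <- tab$a + 0.3 * rnorm(20)
  raw <- pearson_matrix(tab, c("a", "b", "c"))
  adj <- pearson_matrix(tab, c("a", "b", "c"), adjust = "holm")
  expect_true(all(adj$p >= raw$p - 1e-15))
})

test_that("reports round-trip losslessly and render OI as percent", {
  pair <- test_pair(0.5)
  recs <- dplyr::bind_rows(
    compute_all_metrics(pair$ornamented, reference = pair$smooth,
                        plane_normal = c(0, 0, 1),
                        specimen_id = "ribbed"),
    compute_all_metrics(make_primitive("cube"),
                        reference = make_primitive("cube"),
                        plane_normal = NULL, specimen_id = "cube"),
    compute_all_metrics(make_primitive("flat_patch"),
                        plane_normal = c(0, 0, 1), specimen_id = "patch")
  )
  dir <- withr::local_tempdir()
  files <- write_report(recs, matrix = NULL, dir = dir)
  tab <- readr::read_csv(files[["metrics_csv"]], show_col_types = FALSE)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$S_mm2, recs$S, tolerance = 1e-9)
  expect_equal(tab$OI_fraction, recs$OI, tolerance = 1e-9)
  expect_identical(tab$OI_percent[tab$specimen_id == "cube"], "0.00%")
  expect_true(is.na(tab$V_mm3[tab$specimen_id == "patch"]))

  js <- jsonlite::fromJSON(files[["metrics_json"]])
  expect_equal(js$S_mm2, recs$S, tolerance = 1e-12)

  # empty record list: header-only CSV, no error
  files0 <- write_report(recs[0, ], dir = withr::local_tempdir())
  tab0 <- readr::read_csv(files0[["metrics_csv"]], show_col_types = FALSE)
  expect_identical(nrow(tab0), 0L)
  expect_true("OI_fraction" %in% names(tab0))

  # correlation with an undefined cell serializes as JSON null
  df <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5), z = rep(3, 5))
  m <- suppressWarnings(pearson_matrix(df, c("x", "y", "z")))
  dir2 <- withr::local_tempdir()
  files2 <- write_report(recs, matrix = m, dir = dir2)
  corr <- jsonlite::fromJSON(files2[["correlations_json"]])
  expect_true(is.na(corr$r[1, 3]))
  long <- readr::read_csv(files2[["correlations_csv"]],
                          show_col_types = FALSE)
  expect_identical(nrow(long), 3L)
  expect_identical(names(long), c("var1", "var2", "r", "p", "stars", "n"))
})

test_that("tidy and autoplot work on correlation matrices", {
  df <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5), z = 5:1)
  m <- pearson_matrix(df, c("x", "y", "z"))
  long <- tidy(m)
  expect_identical(nrow(long), 3L)
  expect_true(all(abs(long$r) <= 1))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
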