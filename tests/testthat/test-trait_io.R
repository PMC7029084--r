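test_that("reading a trait table preserves rows and flags bad cells", {
  f <- write_tmp(c("sp,grp,mass,clutch",
                   "Rana temporaria,Anura,35.2,800",
                   "Bufo bufo,Anura,0,1200",
                   "Triturus cristatus,Caudata,8.1,abc"), ".csv")
  schema <- list(species = "sp", group = "grp", body_mass = "mass",
                 traits = c(clutch_size = "clutch"),
                 units = c(body_mass = "g", clutch_size = "count"))
  expect_warning(tab <- read_trait_table(f, schema), "non-positive")
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 3)                       # row count preserved
  expect_true(is.na(tab$body_mass[2]))             # zero mass -> missing
  expect_true(is.na(tab$clutch_size[3]))           # non-numeric -> missing
  expect_equal(attr(tab, "units")[["clutch_size"]], "count")
})

test_that("duplicate species and missing species column are hard errors", {
  f <- write_tmp(c("sp,mass,clutch",
                   "Rana temporaria,35,800",
                   "Rana  temporaria ,40,900"), ".csv")  # same after cleaning
  schema <- list(species = "sp", body_mass = "mass",
                 traits = c(clutch_size = "clutch"))
  expect_error(read_trait_table(f, schema), "Rana temporaria")
  expect_error(read_trait_table(f, list(species = "nope",
                                        traits = c(clutch_size = "clutch"))),
               "species column")
})

test_that("write -> read round-trip preserves values and missingness", {
  tab <- make_toy_table()
  f <- tempfile(fileext = ".tsv")
  write_trait_table(tab, f)
  schema <- list(species = "species", group = "group", body_mass = "body_mass",
                 traits = c(clutch_size = "clutch_size",
                            larval_period = "larval_period"),
                 units = attr(tab, "units"))
  back <- read_trait_table(f, schema)
  expect_equal(back$body_mass, tab$body_mass)
  expect_equal(back$clutch_size, tab$clutch_size)
  expect_identical(is.na(back$larval_period), is.na(tab$larval_period))
  expect_equal(back$larval_period, tab$larval_period)
})

test_that("harmonize_min_max averages, falls back, warns on inversion, and is idempotent", {
  df <- data.frame(species = c("a", "b", "c", "d"), group = "G",
                   body_mass = c(1, 2, 3, 4),
                   cs_min = c(10, 7, 20, NA), cs_max = c(20, NA, 10, NA))
  tab <- trait_table(df, traits = character(0), units = c(body_mass = "g"))
  expect_warning(
    out <- harmonize_min_max(tab, list(c(min = "cs_min", max = "cs_max",
                                         out = "clutch_size"))),
    "min > max")
  expect_equal(out$clutch_size, c(15, 7, 15, NA))   # mean, fallback, order-insensitive
  expect_true("clutch_size" %in% attr(out, "traits"))
  again <- suppressWarnings(
    harmonize_min_max(out, list(c(min = "cs_min", max = "cs_max",
                                  out = "clutch_size"))))
  expect_equal(again$clutch_size, out$clutch_size)  # idempotent
})

test_that("subset_group pools member labels and warns on empty subsets", {
  tab <- make_toy_table()
  anura <- subset_group(tab, group_spec("Anura", "Anura"))
  expect_equal(nrow(anura), 3)
  pooled <- subset_group(tab, group_spec("all", c("Anura", "Caudata",
                                                  "Gymnophiona")))
  expect_equal(nrow(pooled), 6)
  expect_warning(empty <- subset_group(anura, group_spec("Caudata", "Caudata")),
                 "matches no rows")
  expect_equal(nrow(empty), 0)
})

test_that("paired_log10 keeps complete pairs only and flags tiny samples", {
  tab <- make_toy_table()
  pl <- paired_log10(tab, "larval_period")
  expect_equal(pl$n, 5)                        # one missing larval period
  expect_false("Salamandra eps" %in% pl$species)
  expect_equal(length(pl$x), length(pl$y))
  expect_true(pl$n <= min(sum(!is.na(tab$body_mass)),
                          sum(!is.na(tab$larval_period))))
  # simple log10 example
  df <- data.frame(species = c("a", "b", "c"), group = "G",
                   body_mass = c(10, 100, NA), tr = c(1, 10, 5))
  t2 <- trait_table(df, "tr", c(body_mass = "g", tr = "u"))
  p2 <- paired_log10(t2, "tr")
  expect_equal(p2$x, c(1, 2))
  expect_equal(p2$y, c(0, 1))
  expect_true(p2$insufficient)                 # only 2 complete pairs
  df$tr <- NA_real_
  t3 <- trait_table(df, "tr", c(body_mass = "g", tr = "u"))
  expect_true(paired_log10(t3, "tr")$insufficient)
})
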