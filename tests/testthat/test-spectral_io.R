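make_meta_dataset <- function() {
  set.seed(8)
  meta <- data.frame(spectrum_id = c("a_r1", "a_r2", "b_r1"),
                     subject_id = c("a", "a", "b"),
                     group = c("allergic", "allergic", "tolerized"),
                     batch = c("batch1", "batch1", "batch2"),
                     replicate = c(1L, 2L, 1L))
  spectral_dataset(seq(900, 1100, by = 4),
                   matrix(abs(rnorm(3 * 51, 0.4, 0.1)), 3), meta)
}

test_that("wide CSV round trip preserves data and metadata", {
  ds <- make_meta_dataset()
  path <- file.path(withr::local_tempdir(), "spec")
  files <- write_dataset(ds, path, "wide-csv")
  # wavenumber column + one column per spectrum
  header <- strsplit(readLines(paste0(path, ".csv"), n = 1), ",")[[1]]
  expect_length(header, 4L)

  back <- read_dataset(path, "wide-csv")
  expect_equal(back$wavenumbers, ds$wavenumbers, tolerance = 1e-9)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-9)
  expect_identical(back$meta$group, ds$meta$group)
  expect_identical(back$meta$batch, ds$meta$batch)
  expect_identical(back$meta$subject_id, ds$meta$subject_id)
})

test_that("wide CSV contract errors: empty dataset, missing metadata, bad cells", {
  ds <- make_meta_dataset()
  tmp <- withr::local_tempdir()
  expect_error(write_dataset(ds[integer(0)], file.path(tmp, "x")),
               "at least 2 grid points|empty")

  path <- file.path(tmp, "spec")
  write_dataset(ds, path, "wide-csv")
  meta <- read.table(paste0(path, "_meta.tsv"), sep = "\t", header = TRUE)
  write.table(meta[meta$spectrum_id != "a_r2", ], paste0(path, "_meta.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(path, "wide-csv"), "a_r2")

  lines <- readLines(paste0(path, ".csv"))
  lines[3] <- sub("^([^,]*),[^,]*", "\\1,oops", lines[3])
  writeLines(lines, paste0(path, ".csv"))
  expect_error(read_dataset(path, "wide-csv"), "non-numeric")
})

test_that("JCAMP-DX round trip preserves spectra and metadata labels", {
  ds <- make_meta_dataset()
  path <- file.path(withr::local_tempdir(), "spec")
  write_dataset(ds, path, "jcamp-dx")
  back <- read_dataset(paste0(path, ".jdx"), "jcamp-dx")
  expect_equal(back$wavenumbers, ds$wavenumbers, tolerance = 1e-9)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(back$meta$group, ds$meta$group)
  expect_identical(back$meta$batch, ds$meta$batch)
})

test_that("descending-grid JCAMP input is normalized to an ascending grid", {
  jdx <- file.path(withr::local_tempdir(), "desc.jdx")
  writeLines(c(
    "##TITLE=desc",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##FIRSTX=1000", "##LASTX=996", "##NPOINTS=5",
    "##XFACTOR=1", "##YFACTOR=1",
    "##XYDATA=(X++(Y..Y))",
    "1000 5 4 3",
    "997 2 1",
    "##END="), jdx)
  ds <- read_dataset(jdx, "jcamp-dx")
  expect_equal(ds$wavenumbers, 996:1000)
  expect_equal(as.vector(ds$intensities), c(1, 2, 3, 4, 5))
  # reading what write_dataset emits never re-reverses
  out <- file.path(withr::local_tempdir(), "again")
  write_dataset(ds, out, "jcamp-dx")
  again <- read_dataset(paste0(out, ".jdx"), "jcamp-dx")
  expect_equal(again$wavenumbers, ds$wavenumbers)
  expect_equal(again$intensities, ds$intensities, ignore_attr = TRUE)
})

test_that("SQZ/DIF/DUP (DIFDUP) ordinates decode to their AFFN values", {
  # y = 1 2 3 3 2 1 35 35 -4: SQZ start A1=1, DIF +1 +1 (J, dup T),
  # 0 (%), -1 -1 (j, jT ...), jump to SQZ C5=35, DUP T, then DIF -39 (l9)
  jdx <- file.path(withr::local_tempdir(), "difdup.jdx")
  writeLines(c(
    "##TITLE=difdup",
    "##JCAMP-DX=4.24",
    "##FIRSTX=100", "##LASTX=108", "##NPOINTS=9",
    "##XFACTOR=1", "##YFACTOR=0.5",
    "##XYDATA=(X++(Y..Y))",
    "100AJT%jTC5Tl9",
    "##END="), jdx)
  ds <- read_dataset(jdx, "jcamp-dx")
  expect_equal(as.vector(ds$intensities),
               0.5 * c(1, 2, 3, 3, 2, 1, 35, 35, -4))

  # DIF-mode line break: next line starts with an X value and a checkpoint
  jdx2 <- file.path(withr::local_tempdir(), "dif2.jdx")
  writeLines(c(
    "##TITLE=dif2",
    "##FIRSTX=1", "##LASTX=6", "##NPOINTS=6",
    "##XYDATA=(X++(Y..Y))",
    "1A0JJ",
    "4A2JJJ",       # checkpoint 12 repeats the previous ordinate
    "##END="), jdx2)
  ds2 <- read_dataset(jdx2, "jcamp-dx")
  expect_equal(as.vector(ds2$intensities), c(10, 11, 12, 13, 14, 15))
})

test_that("XYPOINTS blocks parse and unsupported forms are rejected", {
  jdx <- file.path(withr::local_tempdir(), "xy.jdx")
  writeLines(c(
    "##TITLE=pts",
    "##XYPOINTS=(XY..XY)",
    "900.0, 0.10; 902.0, 0.20",
    "904.0, 0.15",
    "##END="), jdx)
  ds <- read_dataset(jdx, "jcamp-dx")
  expect_equal(ds$wavenumbers, c(900, 902, 904))
  expect_equal(as.vector(ds$intensities), c(0.10, 0.20, 0.15))

  bad <- file.path(withr::local_tempdir(), "bad.jdx")
  writeLines(c("##TITLE=bad", "##XYDATA=(XY..XY)", "##END="), bad)
  expect_error(read_dataset(bad, "jcamp-dx"), "unsupported XYDATA form")
})

test_that("grid mismatches across JCAMP spectra name the offender", {
  jdx <- file.path(withr::local_tempdir(), "mix.jdx")
  writeLines(c(
    "##TITLE=first",
    "##FIRSTX=1", "##LASTX=3", "##NPOINTS=3",
    "##XYDATA=(X++(Y..Y))", "1 1 2 3", "##END=",
    "##TITLE=second",
    "##FIRSTX=2", "##LASTX=4", "##NPOINTS=3",
    "##XYDATA=(X++(Y..Y))", "2 1 2 3", "##END="), jdx)
  expect_error(read_dataset(jdx, "jcamp-dx"), "second")
})

test_that("synthetic datasets survive a seeded round trip field by field", {
  g <- generate_dataset(tiny_config())
  path <- file.path(withr::local_tempdir(), "sim")
  write_dataset(g$dataset, path, "wide-csv")
  back <- read_dataset(path, "wide-csv")
  expect_equal(back$intensities, g$dataset$intensities, tolerance = 1e-9)
  expect_identical(back$meta, g$dataset$meta)
})
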